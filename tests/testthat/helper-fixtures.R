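# Small hand-built fixtures shared across test files.

enz_row <- function(ec, organisms, is_rle, categories) {
  tibble::tibble(ec = ec, organisms = list(organisms), is_rle = is_rle,
                 categories = list(categories))
}

# Four-enzyme toy: R1 is rate-limiting; all live in hsa.
toy_enzymes <- function() {
  dplyr::bind_rows(
    enz_row("1.1.1.1", "hsa", TRUE, "Carbohydrate"),
    enz_row("2.2.2.2", "hsa", FALSE, "Lipid"),
    enz_row("3.3.3.3", "hsa", FALSE, "Carbohydrate"),
    enz_row("4.4.4.4", "hsa", FALSE, "Nucleotide")
  )
}

toy_products <- function() {
  tibble::tibble(organism = "hsa",
                 ec = c("1.1.1.1", "1.1.1.1", "4.4.4.4"),
                 compound = c("C00001", "C00002", "C00002"))
}

toy_inhibitions <- function() {
  tibble::tibble(organism = "hsa",
                 compound = c("C00001", "C00002"),
                 target_ec = c("2.2.2.2", "3.3.3.3"),
                 in_vivo = TRUE)
}

write_tsv_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Random link tables over a small enzyme universe, for property tests.
random_dataset <- function(seed, n_enz = 12, n_cmp = 8, n_org = 4) {
  set.seed(seed)
  orgs <- paste0("org", seq_len(n_org))
  ecs <- sprintf("1.1.%d.%d", seq_len(n_enz), seq_len(n_enz))
  cmps <- sprintf("C%05d", seq_len(n_cmp))
  enzymes <- tibble::tibble(
    ec = ecs, organisms = list(orgs),
    is_rle = seq_len(n_enz) <= n_enz / 3,
    categories = purrr::map(sample(pathway_categories(), n_enz, TRUE), identity)
  )
  products <- tibble::tibble(
    organism = sample(orgs, 3 * n_enz, TRUE),
    ec = sample(ecs, 3 * n_enz, TRUE),
    compound = sample(cmps, 3 * n_enz, TRUE)
  ) |> dplyr::distinct()
  inhibitions <- tibble::tibble(
    organism = sample(orgs, 3 * n_cmp, TRUE),
    compound = sample(cmps, 3 * n_cmp, TRUE),
    target_ec = sample(ecs, 3 * n_cmp, TRUE),
    in_vivo = TRUE
  ) |> dplyr::distinct()
  list(enzymes = enzymes, products = products, inhibitions = inhibitions)
}
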