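#' Configuration for the synthetic-data generator
#'
#' Parameters of the generative model behind [simulate_dataset()]. The
#' defaults describe a scaled-down five-organism study: a shared enzyme pool
#' with a rate-limiting subset, organism membership and link recurrence
#' planting cross-organism conservation, an elevated probability that
#' RLE products act as in-vivo inhibitors, preferential selection of RLEs as
#' inhibition targets, and co-occurrence coupling of the phylogenetic
#' profiles of enzymes joined by a pair (applied with extra strength when
#' both members are rate-limiting). Setting `inhibitor_boost = 1`,
#' `rle_target_boost = 1` and `rho_pair = 0` yields a null model that is
#' exchangeable between rate-limiting and common enzymes.
#'
#' @param seed Integer seed; the same configuration (seed included) always
#'   produces identical datasets.
#' @param n_organisms Number of organisms (default 5; the first five use the
#'   conventional labels hsa, mmu, rno, sce, eco).
#' @param n_enzymes Size of the global enzyme pool.
#' @param rle_fraction Fraction of enzymes flagged rate-limiting.
#' @param n_compounds Size of the compound pool.
#' @param products_per_enzyme Mean products per enzyme (Poisson, truncated
#'   at 1).
#' @param p_inhibitor_base Probability that a produced compound not made by
#'   any RLE acts as an in-vivo inhibitor.
#' @param inhibitor_boost Multiplier on that probability for RLE-produced
#'   compounds (>= 1; capped at probability 1).
#' @param targets_per_inhibitor Mean targets per inhibitor compound
#'   (Poisson, truncated at 1).
#' @param rle_target_boost Relative sampling weight of rate-limiting enzymes
#'   when targets are drawn (>= 1).
#' @param n_prokaryotes,n_eukaryotes Genome-panel composition (23 + 59).
#' @param p_presence_base Background per-genome presence probability.
#' @param rho_pair Profile-coupling strength in `[0, 1]` for pairs with a
#'   rate-limiting provider; pairs of two RLEs use `min(1, 1.5 * rho_pair)`.
#' @param p_shared_across_organisms Probability that an enzyme, or a link,
#'   recurs in an organism other than its home organism.
#' @param p_in_vivo Probability that an inhibition annotation is in-vivo.
#' @return A validated list of class `rleinhib_config`.
#' @export
simulate_config <- function(seed = 1L, n_organisms = 5, n_enzymes = 300,
                            rle_fraction = 0.2, n_compounds = 600,
                            products_per_enzyme = 2, p_inhibitor_base = 0.15,
                            inhibitor_boost = 3, targets_per_inhibitor = 2,
                            rle_target_boost = 2, n_prokaryotes = 23,
                            n_eukaryotes = 59, p_presence_base = 0.4,
                            rho_pair = 0.3, p_shared_across_organisms = 0.7,
                            p_in_vivo = 0.9) {
  cfg <- list(seed = as.integer(seed), n_organisms = n_organisms,
              n_enzymes = n_enzymes, rle_fraction = rle_fraction,
              n_compounds = n_compounds,
              products_per_enzyme = products_per_enzyme,
              p_inhibitor_base = p_inhibitor_base,
              inhibitor_boost = inhibitor_boost,
              targets_per_inhibitor = targets_per_inhibitor,
              rle_target_boost = rle_target_boost,
              n_prokaryotes = n_prokaryotes, n_eukaryotes = n_eukaryotes,
              p_presence_base = p_presence_base, rho_pair = rho_pair,
              p_shared_across_organisms = p_shared_across_organisms,
              p_in_vivo = p_in_vivo)
  probs <- c("rle_fraction", "p_inhibitor_base", "p_presence_base",
             "rho_pair", "p_shared_across_organisms", "p_in_vivo")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      rlang::abort(sprintf("`%s` must be in [0, 1], got %g", p, cfg[[p]]))
    }
  }
  for (b in c("inhibitor_boost", "rle_target_boost")) {
    if (cfg[[b]] < 1) rlang::abort(sprintf("`%s` must be >= 1", b))
  }
  for (cnt in c("n_organisms", "n_enzymes", "n_compounds", "n_prokaryotes",
                "n_eukaryotes")) {
    if (cfg[[cnt]] < 1) rlang::abort(sprintf("`%s` must be >= 1", cnt))
  }
  if (cfg$products_per_enzyme < 0 || cfg$targets_per_inhibitor < 0) {
    rlang::abort("count means must be >= 0")
  }
  class(cfg) <- "rleinhib_config"
  cfg
}

organism_labels <- function(n) {
  base <- c("hsa", "mmu", "rno", "sce", "eco")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("org%02d", seq(length(base) + 1L, n)))
}

# Poisson truncated to >= 1 (emptiness would break table invariants)
rpois_min1 <- function(n, lambda) pmax(1L, stats::rpois(n, lambda))

#' Generate a synthetic multi-organism dataset
#'
#' Draws a complete dataset — enzyme, product, inhibition and presence
#' tables plus the genome panel — from the generative model described in
#' [simulate_config()], together with the realised ground truth (planted
#' rate-limiting set, inhibitor compounds, profile-coupling assignments).
#' Identical configurations produce identical datasets.
#'
#' The model, in order: (1) a global enzyme pool with EC-like identifiers,
#' a planted rate-limiting subset, one or two pathway categories each, a
#' home organism and Bernoulli recurrence in the others; (2) per-enzyme
#' product sets over a global compound pool, instantiated per organism with
#' the same recurrence rule; (3) compounds become in-vivo inhibitors with a
#' probability boosted when some rate-limiting enzyme produces them, and
#' draw their targets with rate-limiting enzymes up-weighted; (4) a
#' background Bernoulli presence matrix over the genome panel, then for
#' each inhibited target the profile is coupled to one provider's profile by
#' positionwise copying (probability `rho_pair`, or `min(1, 1.5*rho_pair)`
#' when both members are rate-limiting; pairs with a common provider are
#' never coupled). Copying reads the uncoupled background profile of the
#' provider, so coupling is order-independent.
#'
#' @param config A [simulate_config()] object.
#' @return A list of class `rleinhib_dataset` with elements `enzymes`,
#'   `products`, `inhibitions`, `presence`, `panel`, `ground_truth`,
#'   `config`.
#' @export
simulate_dataset <- function(config = simulate_config()) {
  stopifnot(inherits(config, "rleinhib_config"))
  set.seed(config$seed)
  cfg <- config

  orgs <- organism_labels(cfg$n_organisms)
  n_org <- length(orgs)
  n_enz <- cfg$n_enzymes

  # --- enzyme pool ---------------------------------------------------------
  ecs <- sprintf("%d.%d.%d.%d",
                 sample(1:6, n_enz, replace = TRUE),
                 sample(1:9, n_enz, replace = TRUE),
                 sample(1:99, n_enz, replace = TRUE),
                 seq_len(n_enz))
  n_rle <- max(1L, round(n_enz * cfg$rle_fraction))
  is_rle <- logical(n_enz)
  is_rle[sample.int(n_enz, n_rle)] <- TRUE

  cats <- pathway_categories()
  cat1 <- sample(cats, n_enz, replace = TRUE)
  has2 <- stats::runif(n_enz) < 0.3
  cat2 <- sample(cats, n_enz, replace = TRUE)
  categories <- purrr::pmap(list(cat1, cat2, has2), function(c1, c2, h) {
    sort(unique(c(c1, if (h) c2)))
  })

  home <- sample.int(n_org, n_enz, replace = TRUE)
  membership <- matrix(stats::runif(n_enz * n_org) <
                         cfg$p_shared_across_organisms, n_enz, n_org)
  membership[cbind(seq_len(n_enz), home)] <- TRUE

  enzymes <- tibble::tibble(
    ec = ecs,
    organisms = purrr::map(seq_len(n_enz),
                           function(i) sort(orgs[membership[i, ]])),
    is_rle = is_rle,
    categories = categories
  )

  # --- products ------------------------------------------------------------
  compounds <- sprintf("C%05d", seq_len(cfg$n_compounds))
  n_prod <- rpois_min1(n_enz, cfg$products_per_enzyme)
  g_enz <- rep(seq_len(n_enz), n_prod)
  g_cmp <- sample.int(cfg$n_compounds, sum(n_prod), replace = TRUE)
  gprod <- dplyr::distinct(tibble::tibble(enz = g_enz, cmp = g_cmp))

  np <- nrow(gprod)
  pe <- rep(gprod$enz, each = n_org)
  pc <- rep(gprod$cmp, each = n_org)
  po <- rep(seq_len(n_org), times = np)
  keep <- membership[cbind(pe, po)] &
    (home[pe] == po | stats::runif(np * n_org) < cfg$p_shared_across_organisms)
  products <- tibble::tibble(organism = orgs[po[keep]], ec = ecs[pe[keep]],
                             compound = compounds[pc[keep]])

  # --- inhibitors and their targets ---------------------------------------
  produced <- sort(unique(gprod$cmp))
  rle_made <- sort(unique(gprod$cmp[is_rle[gprod$enz]]))
  p_inh <- ifelse(produced %in% rle_made,
                  pmin(1, cfg$p_inhibitor_base * cfg$inhibitor_boost),
                  cfg$p_inhibitor_base)
  inhibitor_cmp <- produced[stats::runif(length(produced)) < p_inh]

  w <- ifelse(is_rle, cfg$rle_target_boost, 1)
  n_tgt <- rpois_min1(length(inhibitor_cmp), cfg$targets_per_inhibitor)
  i_cmp <- rep(inhibitor_cmp, n_tgt)
  i_tgt <- sample.int(n_enz, sum(n_tgt), replace = TRUE, prob = w)
  ginh <- dplyr::distinct(tibble::tibble(cmp = i_cmp, tgt = i_tgt))
  ginh$in_vivo <- stats::runif(nrow(ginh)) < cfg$p_in_vivo

  ni <- nrow(ginh)
  ie <- rep(ginh$tgt, each = n_org)
  ic <- rep(ginh$cmp, each = n_org)
  iv <- rep(ginh$in_vivo, each = n_org)
  io <- rep(seq_len(n_org), times = ni)
  keep <- membership[cbind(ie, io)] &
    (home[ie] == io | stats::runif(ni * n_org) < cfg$p_shared_across_organisms)
  inhibitions <- tibble::tibble(organism = orgs[io[keep]],
                                compound = compounds[ic[keep]],
                                target_ec = ecs[ie[keep]],
                                in_vivo = iv[keep])

  # --- presence matrix with planted profile coupling ----------------------
  panel <- genome_panel(cfg$n_prokaryotes, cfg$n_eukaryotes)
  n_gen <- nrow(panel)
  base <- matrix(as.integer(stats::runif(n_enz * n_gen) <
                              cfg$p_presence_base), n_enz, n_gen)
  pres <- base

  gpairs <- dplyr::inner_join(gprod, ginh[ginh$in_vivo, ],
                              by = "cmp", relationship = "many-to-many") |>
    dplyr::distinct(provider = .data$enz, target = .data$tgt) |>
    dplyr::filter(.data$provider != .data$target) |>
    dplyr::mutate(
      rho_eff = dplyr::case_when(
        is_rle[.data$provider] & is_rle[.data$target] ~
          pmin(1, 1.5 * cfg$rho_pair),
        is_rle[.data$provider] ~ cfg$rho_pair,
        TRUE ~ 0
      )
    )
  coupling <- gpairs |>
    dplyr::filter(.data$rho_eff > 0) |>
    dplyr::arrange(.data$target, dplyr::desc(.data$rho_eff), .data$provider) |>
    dplyr::distinct(.data$target, .keep_all = TRUE)
  if (nrow(coupling) > 0) {
    for (i in seq_len(nrow(coupling))) {
      copy <- stats::runif(n_gen) < coupling$rho_eff[i]
      pres[coupling$target[i], copy] <- base[coupling$provider[i], copy]
    }
  }
  presence <- dplyr::bind_cols(
    tibble::tibble(ec = ecs),
    tibble::as_tibble(stats::setNames(as.data.frame(pres), panel$genome))
  )

  ground_truth <- list(
    rle_ecs = sort(ecs[is_rle]),
    inhibitor_compounds = sort(compounds[ginh$cmp[ginh$in_vivo]]),
    rle_produced_compounds = sort(compounds[rle_made]),
    coupling = tibble::tibble(provider_ec = ecs[coupling$provider],
                              target_ec = ecs[coupling$target],
                              rho_eff = coupling$rho_eff),
    config = unclass(cfg)
  )

  out <- list(enzymes = enzymes,
              products = dplyr::arrange(products, .data$organism, .data$ec,
                                        .data$compound),
              inhibitions = dplyr::arrange(inhibitions, .data$organism,
                                           .data$compound, .data$target_ec),
              presence = presence, panel = panel,
              ground_truth = ground_truth, config = cfg)
  class(out) <- "rleinhib_dataset"
  out
}

#' @export
print.rleinhib_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic inhibitory-network dataset: %d enzymes (%d rate-limiting), %d organisms,\n  %d product links, %d inhibition links, %d-genome panel (seed %d)\n",
    nrow(x$enzymes), sum(x$enzymes$is_rle), length(organism_labels(x$config$n_organisms)),
    nrow(x$products), nrow(x$inhibitions), nrow(x$panel), x$config$seed))
  invisible(x)
}

#' Write or read a dataset as TSV tables
#'
#' `write_dataset()` writes `enzymes.tsv`, `products.tsv`, `inhibitions.tsv`,
#' `presence.tsv` and `panel.tsv` into a directory, plus `manifest.json`
#' (configuration echo, MD5 file hashes and the ground truth when the
#' dataset carries one). `read_dataset()` reads the tables back; the
#' round-trip reproduces the in-memory tables exactly.
#'
#' @param dataset An `rleinhib_dataset` (or a plain list with the same
#'   table elements).
#' @param dir Output (input) directory.
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a list with `enzymes`, `products`, `inhibitions`, `presence`,
#'   `panel`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_enzyme_table(dataset$enzymes, file.path(dir, "enzymes.tsv"))
  write_product_table(dataset$products, file.path(dir, "products.tsv"))
  write_inhibition_table(dataset$inhibitions, file.path(dir, "inhibitions.tsv"))
  write_presence_matrix(dataset$presence, file.path(dir, "presence.tsv"))
  readr::write_tsv(dataset$panel, file.path(dir, "panel.tsv"),
                   progress = FALSE)
  files <- c("enzymes.tsv", "products.tsv", "inhibitions.tsv",
             "presence.tsv", "panel.tsv")
  manifest <- list(
    config = if (!is.null(dataset$config)) unclass(dataset$config),
    md5 = as.list(tools::md5sum(file.path(dir, files))),
    ground_truth = dataset$ground_truth
  )
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  panel <- readr::read_tsv(file.path(dir, "panel.tsv"),
                           col_types = "cc", progress = FALSE)
  list(
    enzymes = read_enzyme_table(file.path(dir, "enzymes.tsv")),
    products = read_product_table(file.path(dir, "products.tsv")),
    inhibitions = read_inhibition_table(file.path(dir, "inhibitions.tsv")),
    presence = read_presence_matrix(file.path(dir, "presence.tsv"), panel),
    panel = panel
  )
}
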