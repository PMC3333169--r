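test_that("pair construction is the within-organism compound join", {
  enz <- toy_enzymes()
  # minimal join: one product, one matching inhibition
  pairs <- build_pairs(tibble::tibble(organism = "hsa", ec = "1.1.1.1",
                                      compound = "C00001"),
                       tibble::tibble(organism = "hsa", compound = "C00001",
                                      target_ec = "2.2.2.2", in_vivo = TRUE),
                       enz)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$provider_ec, "1.1.1.1")
  expect_equal(pairs$target_ec, "2.2.2.2")
  expect_true(pairs$provider_is_rle)
  expect_false(pairs$self_pair)

  # exhaustive cartesian join on a shared compound: 2 producers x 2 targets
  pairs <- build_pairs(
    tibble::tibble(organism = "hsa", ec = c("1.1.1.1", "2.2.2.2"),
                   compound = "C00001"),
    tibble::tibble(organism = "hsa", compound = "C00001",
                   target_ec = c("3.3.3.3", "4.4.4.4"), in_vivo = TRUE),
    enz)
  expect_equal(nrow(pairs), 4)

  # no shared compound: empty
  pairs <- build_pairs(tibble::tibble(organism = "hsa", ec = "1.1.1.1",
                                      compound = "C00001"),
                       tibble::tibble(organism = "hsa", compound = "C00002",
                                      target_ec = "2.2.2.2", in_vivo = TRUE),
                       enz)
  expect_equal(nrow(pairs), 0)
})

test_that("pairs respect organism boundaries, in-vivo filter and self-pair policy", {
  enz <- dplyr::bind_rows(
    enz_row("1.1.1.1", c("hsa", "mmu"), TRUE, "Carbohydrate"),
    enz_row("2.2.2.2", c("hsa", "mmu"), FALSE, "Lipid"))
  products <- tibble::tibble(organism = "hsa", ec = "1.1.1.1",
                             compound = "C00001")
  inhibitions <- tibble::tibble(
    organism = c("mmu", "hsa", "hsa"),
    compound = "C00001",
    target_ec = c("2.2.2.2", "2.2.2.2", "1.1.1.1"),
    in_vivo = c(TRUE, FALSE, TRUE))

  # mmu inhibition never joins the hsa product; hsa in-vitro row is dropped
  pairs <- build_pairs(products, inhibitions, enz)
  expect_equal(nrow(pairs), 1)
  expect_true(pairs$self_pair)
  expect_equal(nrow(build_pairs(products, inhibitions, enz,
                                keep_self_pairs = FALSE)), 0)
  # in-vitro rows enter only when the filter is released
  pairs <- build_pairs(products, inhibitions, enz, in_vivo_only = FALSE)
  expect_equal(nrow(pairs), 2)

  expect_error(
    build_pairs(tibble::tibble(organism = "hsa", ec = "9.9.9.9",
                               compound = "C00001"),
                inhibitions, enz),
    "9\\.9\\.9\\.9")
})

test_that("pair counts match a triple-loop join oracle on random inputs", {
  for (seed in 1:10) {
    d <- random_dataset(seed)
    pairs <- build_pairs(d$products, d$inhibitions, d$enzymes)
    # independent oracle: enumerate every product x inhibition combination
    expected <- 0L
    seen <- character()
    for (i in seq_len(nrow(d$products))) {
      for (j in seq_len(nrow(d$inhibitions))) {
        if (d$products$organism[i] == d$inhibitions$organism[j] &&
            d$products$compound[i] == d$inhibitions$compound[j]) {
          key <- paste(d$products$organism[i], d$products$ec[i],
                       d$inhibitions$target_ec[j], d$products$compound[i])
          if (!key %in% seen) {
            seen <- c(seen, key)
            expected <- expected + 1L
          }
        }
      }
    }
    expect_equal(nrow(pairs), expected, label = paste("seed", seed))
  }
})

test_that("inhibitor production stats count distinct compounds and round as printed", {
  enz <- toy_enzymes()
  stats <- inhibitor_production_stats(toy_products(), toy_inhibitions(), enz)
  # both inhibitors (C00001, C00002) are products of the one RLE
  expect_equal(stats$n_inhibitors, 2)
  expect_equal(stats$n_rle_produced, 2)
  expect_equal(stats$fraction, 1)
  expect_equal(stats$percent, 100L)

  # no RLEs at all: fraction 0
  enz0 <- dplyr::mutate(enz, is_rle = FALSE)
  expect_equal(inhibitor_production_stats(toy_products(), toy_inhibitions(),
                                          enz0)$fraction, 0)

  # no in-vivo inhibitors: undefined fraction
  none <- dplyr::mutate(toy_inhibitions(), in_vivo = FALSE)
  stats <- inhibitor_production_stats(toy_products(), none, enz,
                                      organism = "hsa")
  expect_true(is.na(stats$fraction))

  # integer percent rounds ties away from zero: 1/8 = 12.5% -> 13%
  enz8 <- dplyr::bind_rows(
    enz_row("1.1.1.1", "hsa", TRUE, "Others"),
    enz_row("2.2.2.2", "hsa", FALSE, "Others"))
  prods <- tibble::tibble(organism = "hsa",
                          ec = c("1.1.1.1", rep("2.2.2.2", 7)),
                          compound = sprintf("C%05d", 1:8))
  inhs <- tibble::tibble(organism = "hsa", compound = sprintf("C%05d", 1:8),
                         target_ec = "2.2.2.2", in_vivo = TRUE)
  expect_equal(inhibitor_production_stats(prods, inhs, enz8)$percent, 13L)
})

test_that("coverage report counts distinct entities on the three-edge toy", {
  enz <- toy_enzymes()
  # R1 -> E2, R1 -> E3, E4 -> E3
  pairs <- build_pairs(toy_products(), toy_inhibitions(), enz)
  expect_equal(nrow(pairs), 3)
  cov <- coverage_report(pairs)
  expect_equal(cov$providers_all, 2)
  expect_equal(cov$providers_rle, 1)
  expect_equal(cov$targets_all, 2)
  expect_equal(cov$targets_by_rle, 2)
  expect_equal(cov$frac_targets_by_rle, 1)
  expect_equal(cov$frac_providers_rle, 0.5)

  # empty network: zero counts, undefined fractions
  cov0 <- rleinhib:::coverage_one(pairs[0, ])
  expect_equal(cov0$providers_all, 0)
  expect_true(is.na(cov0$frac_providers_rle))

  # saturation: every provider rate-limiting
  sat <- dplyr::mutate(pairs, provider_is_rle = TRUE)
  expect_equal(coverage_report(sat)$frac_providers_rle, 1)
})

test_that("per-category coverage uses provider categories for providers, target's for targets", {
  enz <- toy_enzymes()
  pairs <- build_pairs(toy_products(), toy_inhibitions(), enz)
  cov <- coverage_report(pairs, by_category = TRUE)
  carb <- cov[cov$category == "Carbohydrate", ]
  # providers in Carbohydrate: only R1; targets in Carbohydrate: only E3
  expect_equal(carb$providers_all, 1)
  expect_equal(carb$providers_rle, 1)
  expect_equal(carb$targets_all, 1)
  lip <- cov[cov$category == "Lipid", ]
  expect_equal(lip$providers_all, 0)
  expect_equal(lip$targets_all, 1)  # E2
})

test_that("adding links never decreases coverage counts", {
  d <- random_dataset(3)
  base_pairs <- build_pairs(d$products, d$inhibitions, d$enzymes)
  base_cov <- coverage_report(base_pairs, organism = "org1")
  more_inh <- dplyr::bind_rows(
    d$inhibitions,
    tibble::tibble(organism = "org1", compound = d$products$compound[1],
                   target_ec = d$enzymes$ec[8], in_vivo = TRUE))
  more_cov <- coverage_report(build_pairs(d$products, more_inh, d$enzymes),
                              organism = "org1")
  for (col in c("targets_all", "targets_by_rle", "targets_rle")) {
    expect_gte(more_cov[[col]], base_cov[[col]])
  }
  more_prod <- dplyr::bind_rows(
    d$products,
    tibble::tibble(organism = "org1", ec = d$enzymes$ec[9],
                   compound = d$inhibitions$compound[1]))
  more_cov <- coverage_report(build_pairs(more_prod, d$inhibitions, d$enzymes),
                              organism = "org1")
  expect_gte(more_cov$providers_all, base_cov$providers_all)
})

test_that("target enrichment uses the organism's enzyme population", {
  enz <- dplyr::bind_rows(
    enz_row("1.1.1.1", "hsa", TRUE, "Carbohydrate"),
    enz_row("2.2.2.2", "hsa", TRUE, "Carbohydrate"),
    enz_row("3.3.3.3", "hsa", FALSE, "Carbohydrate"),
    enz_row("4.4.4.4", "hsa", FALSE, "Carbohydrate"),
    enz_row("5.5.5.5", "mmu", FALSE, "Carbohydrate"))
  pairs <- tibble::tibble(
    organism = "hsa", provider_ec = "3.3.3.3",
    target_ec = c("1.1.1.1", "2.2.2.2"), compound = "C00001",
    provider_is_rle = FALSE, target_is_rle = TRUE,
    provider_categories = list("Carbohydrate"),
    target_categories = list("Carbohydrate"), self_pair = FALSE)
  res <- enrichment_rle_targets(pairs, enz)
  # population is the 4 hsa enzymes (mmu enzyme excluded), K = 2 RLEs,
  # sample = 2 targets, both rate-limiting
  expect_equal(res[c("k", "n", "K", "N")],
               tibble::tibble(k = 2L, n = 2L, K = 2L, N = 4L))
  expect_equal(res$p_value, 1 / choose(4, 2))
  expect_lt(res$p_value, 1)

  expect_warning(
    res <- enrichment_rle_targets(pairs, enz, category = "Lipid"),
    "empty stratum")
  expect_true(is.na(res$p_value))
})

test_that("cross-pathway isolation partitions pairs by category overlap", {
  mk <- function(prov_cats, targ_cats) {
    tibble::tibble(organism = "hsa", provider_ec = "1.1.1.1",
                   target_ec = "2.2.2.2", compound = "C00001",
                   provider_is_rle = TRUE, target_is_rle = FALSE,
                   provider_categories = list(prov_cats),
                   target_categories = list(targ_cats), self_pair = FALSE)
  }
  expect_equal(nrow(cross_pathway_pairs(mk("Carbohydrate", "Lipid"))), 1)
  expect_equal(nrow(cross_pathway_pairs(mk(c("Carbohydrate", "Lipid"),
                                           "Lipid"))), 0)
  expect_equal(nrow(cross_pathway_pairs(mk("Lipid", "Lipid"))), 0)
  # the looser criterion keeps overlapping-but-different sets
  expect_equal(nrow(cross_pathway_pairs(mk(c("Carbohydrate", "Lipid"), "Lipid"),
                                        criterion = "not_identical")), 1)

  # retained + complement partition the input, disjointly
  d <- random_dataset(5)
  pairs <- build_pairs(d$products, d$inhibitions, d$enzymes)
  kept <- cross_pathway_pairs(pairs)
  key <- function(p) paste(p$organism, p$provider_ec, p$target_ec, p$compound)
  expect_setequal(c(key(kept), setdiff(key(pairs), key(kept))), key(pairs))
  expect_equal(nrow(kept) + length(setdiff(key(pairs), key(kept))),
               nrow(pairs))
})

test_that("cross-pathway matrix tallies distinct targets per category cell", {
  enz <- dplyr::bind_rows(
    enz_row("1.1.1.1", "hsa", TRUE, "Carbohydrate"),
    enz_row("2.2.2.2", "hsa", FALSE, "Carbohydrate"),
    enz_row("3.3.3.3", "hsa", FALSE, "Lipid"),
    enz_row("4.4.4.4", "hsa", FALSE, "Nucleotide"))
  # single edge RLE(Carbohydrate) -> E(Lipid)
  one <- tibble::tibble(organism = "hsa", provider_ec = "1.1.1.1",
                        target_ec = "3.3.3.3", compound = "C00001",
                        provider_is_rle = TRUE, target_is_rle = FALSE,
                        provider_categories = list("Carbohydrate"),
                        target_categories = list("Lipid"), self_pair = FALSE)
  mat <- cross_pathway_matrix(one)
  cell <- mat[mat$source_category == "Carbohydrate" &
                mat$target_category == "Lipid", ]
  expect_equal(cell$targets_by_rle, 1)
  expect_equal(cell$targets_by_all, 1)
  expect_equal(cell$fraction, 1)
  expect_equal(sum(mat$targets_by_all), 1)

  # same target hit by RLE and non-RLE providers of one source category:
  # the denominator counts the target once
  two <- dplyr::bind_rows(
    one, dplyr::mutate(one, provider_ec = "2.2.2.2", provider_is_rle = FALSE))
  cell <- cross_pathway_matrix(two)
  cell <- cell[cell$source_category == "Carbohydrate" &
                 cell$target_category == "Lipid", ]
  expect_equal(cell$targets_by_all, 1)
  expect_equal(cell$fraction, 1)
})

test_that("cross-pathway matrix matches a nested-loop tally on a 12-edge toy", {
  d <- random_dataset(7, n_enz = 15, n_cmp = 10, n_org = 1)
  pairs <- cross_pathway_pairs(build_pairs(d$products, d$inhibitions,
                                           d$enzymes))
  mat <- cross_pathway_matrix(pairs)
  # independent tally: loop over every cell and every pair
  for (i in seq_len(nrow(mat))) {
    all_t <- character(); rle_t <- character()
    for (j in seq_len(nrow(pairs))) {
      if (mat$source_category[i] %in% pairs$provider_categories[[j]] &&
          mat$target_category[i] %in% pairs$target_categories[[j]]) {
        all_t <- union(all_t, pairs$target_ec[j])
        if (pairs$provider_is_rle[j]) rle_t <- union(rle_t, pairs$target_ec[j])
      }
    }
    expect_equal(mat$targets_by_all[i], length(all_t))
    expect_equal(mat$targets_by_rle[i], length(rle_t))
  }
})

test_that("fractions reported by network stats are in [0,1] or NA", {
  for (seed in 1:5) {
    d <- random_dataset(seed)
    pairs <- build_pairs(d$products, d$inhibitions, d$enzymes)
    cov <- coverage_report(pairs, by_category = TRUE)
    fr <- unlist(cov[grepl("^frac_", names(cov))])
    expect_true(all(is.na(fr) | (fr >= 0 & fr <= 1)))
    mat <- cross_pathway_matrix(cross_pathway_pairs(pairs))
    expect_true(all(is.na(mat$fraction) |
                      (mat$fraction >= 0 & mat$fraction <= 1)))
  }
})
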