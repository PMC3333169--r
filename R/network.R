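#' Construct inhibiting enzyme pairs
#'
#' An inhibiting pair (provider, target) exists in an organism when some
#' product link says the provider produces a compound there and some
#' inhibition link says the same compound inhibits the target there. The
#' join is strictly within-organism: inhibitor annotations are never
#' transferred between organisms. Only in-vivo inhibitions enter by default.
#' Pairs are deduplicated on (organism, provider, target, compound);
#' self-pairs (autoinhibition of the producing enzyme) are retained but
#' flagged, and can be dropped with `keep_self_pairs = FALSE`.
#'
#' @param products Product tibble (`organism`, `ec`, `compound`).
#' @param inhibitions Inhibition tibble (`organism`, `compound`, `target_ec`,
#'   `in_vivo`).
#' @param enzymes Enzyme tibble; supplies rate-limiting flags and pathway
#'   categories. Links referencing an EC absent from this table are an
#'   integrity error listing every offender.
#' @param organism Optional single organism to restrict to (default: all).
#' @param in_vivo_only Keep only in-vivo inhibitions (default `TRUE`).
#' @param keep_self_pairs Retain provider == target pairs (default `TRUE`).
#' @return A tibble with columns `organism`, `provider_ec`, `target_ec`,
#'   `compound`, `provider_is_rle`, `target_is_rle`, `provider_categories`,
#'   `target_categories` (list-columns), `self_pair`.
#' @export
build_pairs <- function(products, inhibitions, enzymes, organism = NULL,
                        in_vivo_only = TRUE, keep_self_pairs = TRUE) {
  if (!is.null(organism)) {
    products <- dplyr::filter(products, .data$organism %in% !!organism)
    inhibitions <- dplyr::filter(inhibitions, .data$organism %in% !!organism)
  }
  if (in_vivo_only) inhibitions <- dplyr::filter(inhibitions, .data$in_vivo)

  unknown <- unique(c(setdiff(products$ec, enzymes$ec),
                      setdiff(inhibitions$target_ec, enzymes$ec)))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("link(s) reference EC(s) absent from the enzyme table: %s",
                         paste(sort(unknown), collapse = ", ")))
  }

  pairs <- dplyr::inner_join(
    dplyr::distinct(products, .data$organism, provider_ec = .data$ec,
                    .data$compound),
    dplyr::distinct(inhibitions, .data$organism, .data$compound,
                    .data$target_ec),
    by = c("organism", "compound"),
    relationship = "many-to-many"
  ) |>
    dplyr::distinct(.data$organism, .data$provider_ec, .data$target_ec,
                    .data$compound)

  idx <- match(pairs$provider_ec, enzymes$ec)
  tdx <- match(pairs$target_ec, enzymes$ec)
  pairs$provider_is_rle <- enzymes$is_rle[idx]
  pairs$target_is_rle <- enzymes$is_rle[tdx]
  pairs$provider_categories <- enzymes$categories[idx]
  pairs$target_categories <- enzymes$categories[tdx]
  pairs$self_pair <- pairs$provider_ec == pairs$target_ec
  if (!keep_self_pairs) pairs <- dplyr::filter(pairs, !.data$self_pair)
  dplyr::arrange(pairs, .data$organism, .data$provider_ec, .data$target_ec,
                 .data$compound)
}

rle_ecs <- function(enzymes) enzymes$ec[enzymes$is_rle]

organisms_in <- function(...) {
  sort(unique(unlist(lapply(list(...), function(tab) tab$organism))))
}

#' Inhibitor production by rate-limiting enzymes
#'
#' For each organism, counts the distinct compounds that act as in-vivo
#' inhibitors there, and how many of those are produced (same organism) by
#' at least one rate-limiting enzyme. The fraction is also reported as an
#' integer percentage (nearest integer, ties away from zero), matching the
#' convention used for per-organism headline figures.
#'
#' @inheritParams build_pairs
#' @return A tibble with one row per organism: `organism`, `n_inhibitors`,
#'   `n_rle_produced`, `fraction`, `percent`. `fraction` is `NA` when the
#'   organism has no in-vivo inhibitors.
#' @export
inhibitor_production_stats <- function(products, inhibitions, enzymes,
                                       organism = NULL) {
  orgs <- organism %||% organisms_in(products, inhibitions)
  rles <- rle_ecs(enzymes)
  purrr::map_dfr(orgs, function(org) {
    inh <- unique(inhibitions$compound[inhibitions$organism == org &
                                         inhibitions$in_vivo])
    rle_made <- unique(products$compound[products$organism == org &
                                           products$ec %in% rles])
    n_inh <- length(inh)
    n_rle <- length(intersect(inh, rle_made))
    frac <- if (n_inh == 0) NA_real_ else n_rle / n_inh
    tibble::tibble(organism = org, n_inhibitors = n_inh,
                   n_rle_produced = n_rle, fraction = frac,
                   percent = percent_int(frac))
  })
}

# nearest integer, ties away from zero (round() rounds half to even)
percent_int <- function(frac) {
  ifelse(is.na(frac), NA_integer_,
         as.integer(trunc(100 * frac + sign(frac) * 0.5)))
}

#' Enrichment of in-vivo inhibitors among RLE products
#'
#' Tests whether the in-vivo inhibitors of an organism are over-represented
#' among the compounds produced by rate-limiting enzymes, against the
#' population of all distinct product compounds of the organism:
#' N = product compounds, K = those produced by at least one RLE,
#' n = product compounds that are in-vivo inhibitors, k = inhibitors
#' produced by at least one RLE. Upper-tail hypergeometric, raw p.
#'
#' @inheritParams build_pairs
#' @return A tibble with one row per organism: `organism`, `k`, `n`, `K`,
#'   `N`, `p_value` (`NA` with a warning when the organism has no product
#'   compounds or no inhibitors).
#' @export
production_enrichment <- function(products, inhibitions, enzymes,
                                  organism = NULL) {
  orgs <- organism %||% organisms_in(products, inhibitions)
  rles <- rle_ecs(enzymes)
  purrr::map_dfr(orgs, function(org) {
    pool <- unique(products$compound[products$organism == org])
    rle_made <- unique(products$compound[products$organism == org &
                                           products$ec %in% rles])
    inh <- intersect(unique(inhibitions$compound[inhibitions$organism == org &
                                                   inhibitions$in_vivo]), pool)
    if (length(pool) == 0 || length(inh) == 0) {
      rlang::warn(sprintf("production_enrichment: no testable compounds for %s", org))
      return(tibble::tibble(organism = org, k = NA_integer_, n = NA_integer_,
                            K = NA_integer_, N = NA_integer_,
                            p_value = NA_real_))
    }
    res <- hypergeometric_tail(k = length(intersect(inh, rle_made)),
                               n = length(inh), K = length(rle_made),
                               N = length(pool))
    dplyr::bind_cols(tibble::tibble(organism = org), res)
  })
}

coverage_one <- function(pairs, category = NULL) {
  if (!is.null(category)) {
    prov <- pairs[purrr::map_lgl(pairs$provider_categories,
                                 function(v) category %in% v), ]
    targ <- pairs[purrr::map_lgl(pairs$target_categories,
                                 function(v) category %in% v), ]
  } else {
    prov <- targ <- pairs
  }
  providers_all <- dplyr::n_distinct(prov$provider_ec)
  providers_rle <- dplyr::n_distinct(prov$provider_ec[prov$provider_is_rle])
  targets_all <- dplyr::n_distinct(targ$target_ec)
  targets_by_rle <- dplyr::n_distinct(targ$target_ec[targ$provider_is_rle])
  targets_rle <- dplyr::n_distinct(targ$target_ec[targ$target_is_rle])
  rle_targets_by_rle <- dplyr::n_distinct(
    targ$target_ec[targ$target_is_rle & targ$provider_is_rle])
  safe_frac <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    category = category %||% "All",
    providers_all = providers_all, providers_rle = providers_rle,
    targets_all = targets_all, targets_by_rle = targets_by_rle,
    targets_rle = targets_rle, rle_targets_by_rle = rle_targets_by_rle,
    frac_providers_rle = safe_frac(providers_rle, providers_all),
    frac_targets_by_rle = safe_frac(targets_by_rle, targets_all),
    frac_targets_rle = safe_frac(targets_rle, targets_all),
    frac_rle_targets_by_rle = safe_frac(rle_targets_by_rle, targets_rle)
  )
}

#' Provider/target coverage report
#'
#' Distinct-entity counts of the inhibitory network per organism: inhibitor
#' providers (all and rate-limiting), inhibited targets (all, reachable from
#' at least one RLE provider, rate-limiting, and rate-limiting targets hit by
#' at least one RLE provider), with the derived fractions. Counts are over
#' distinct EC numbers, never link multiplicity. With `by_category = TRUE`
#' the report is additionally stratified by pathway category (an enzyme
#' counts once in each of its categories; provider stats use the provider's
#' categories, target stats the target's).
#'
#' @param pairs Pair tibble from [build_pairs()].
#' @param organism Optional organism(s) to restrict to.
#' @param by_category Add per-category rows in addition to the `"All"` row.
#' @return A tibble with one row per organism (and category), with count
#'   columns and `frac_*` columns in `[0, 1]` (`NA` when the denominator is
#'   zero).
#' @export
coverage_report <- function(pairs, organism = NULL, by_category = FALSE) {
  orgs <- organism %||% sort(unique(pairs$organism))
  purrr::map_dfr(orgs, function(org) {
    sub <- pairs[pairs$organism == org, ]
    rows <- coverage_one(sub)
    if (by_category) {
      rows <- dplyr::bind_rows(
        rows, purrr::map_dfr(pathway_categories(),
                             function(cat) coverage_one(sub, cat)))
    }
    dplyr::bind_cols(tibble::tibble(organism = org), rows)
  })
}

enzymes_of <- function(enzymes, org, category = NULL) {
  keep <- purrr::map_lgl(enzymes$organisms, function(v) org %in% v)
  if (!is.null(category)) {
    keep <- keep & purrr::map_lgl(enzymes$categories,
                                  function(v) category %in% v)
  }
  enzymes[keep, ]
}

#' Enrichment of rate-limiting enzymes among inhibited targets
#'
#' Tests whether the distinct inhibited targets of an organism (optionally
#' within one pathway category) are enriched in rate-limiting enzymes.
#' Population: all enzymes of the organism in the dataset (in the category);
#' successes: RLEs among them; sample: distinct inhibited target ECs;
#' observed successes: targets that are RLEs. Upper-tail hypergeometric,
#' raw p (no multiplicity correction).
#'
#' @param pairs Pair tibble from [build_pairs()].
#' @param enzymes Enzyme tibble.
#' @param organism Optional organism(s) (default: all in `pairs`).
#' @param category Optional single pathway category.
#' @return A tibble with one row per organism: `organism`, `category`, `k`,
#'   `n`, `K`, `N`, `p_value` (`NA` with a warning when the stratum is
#'   empty).
#' @export
enrichment_rle_targets <- function(pairs, enzymes, organism = NULL,
                                   category = NULL) {
  orgs <- organism %||% sort(unique(pairs$organism))
  purrr::map_dfr(orgs, function(org) {
    pop <- enzymes_of(enzymes, org, category)
    sub <- pairs[pairs$organism == org, ]
    if (!is.null(category)) {
      sub <- sub[purrr::map_lgl(sub$target_categories,
                                function(v) category %in% v), ]
    }
    targets <- unique(sub$target_ec)
    targets <- intersect(targets, pop$ec)
    if (nrow(pop) == 0 || length(targets) == 0) {
      rlang::warn(sprintf(
        "enrichment_rle_targets: empty stratum for %s%s", org,
        if (is.null(category)) "" else paste0(" / ", category)))
      return(tibble::tibble(organism = org, category = category %||% "All",
                            k = NA_integer_, n = NA_integer_, K = NA_integer_,
                            N = NA_integer_, p_value = NA_real_))
    }
    res <- hypergeometric_tail(
      k = sum(targets %in% rle_ecs(enzymes)),
      n = length(targets),
      K = sum(pop$is_rle),
      N = nrow(pop))
    dplyr::bind_cols(tibble::tibble(organism = org,
                                    category = category %||% "All"), res)
  })
}

#' Isolate cross-pathway inhibiting pairs
#'
#' Keeps pairs whose provider and target belong to different pathway
#' categories. For multi-category enzymes the default criterion is
#' disjointness of the two category sets (the conservative reading);
#' `criterion = "not_identical"` keeps any pair whose sets differ.
#'
#' @param pairs Pair tibble from [build_pairs()].
#' @param criterion `"disjoint"` (default) or `"not_identical"`.
#' @return The retained pairs; together with the dropped complement they
#'   partition the input.
#' @export
cross_pathway_pairs <- function(pairs,
                                criterion = c("disjoint", "not_identical")) {
  criterion <- match.arg(criterion)
  keep <- switch(criterion,
    disjoint = purrr::map2_lgl(pairs$provider_categories,
                               pairs$target_categories,
                               function(a, b) length(intersect(a, b)) == 0),
    not_identical = purrr::map2_lgl(pairs$provider_categories,
                                    pairs$target_categories,
                                    function(a, b) !setequal(a, b))
  )
  pairs[keep, ]
}

#' Cross-pathway inhibition matrix
#'
#' For each ordered (source, target) pathway-category cell, counts the
#' distinct target ECs in the target category inhibited by any provider in
#' the source category, the subset inhibited by rate-limiting providers, and
#' their ratio. Input should be the cross-pathway pair subset from
#' [cross_pathway_pairs()].
#'
#' @param pairs Cross-pathway pair tibble.
#' @param organism Optional organism(s) (default: all in `pairs`).
#' @return A tibble with one row per organism and 6x6 category cell:
#'   `organism`, `source_category`, `target_category`, `targets_by_rle`,
#'   `targets_by_all`, `fraction` (`NA` when no targets in the cell).
#' @export
cross_pathway_matrix <- function(pairs, organism = NULL) {
  orgs <- organism %||% sort(unique(pairs$organism))
  cats <- pathway_categories()
  grid <- tidyr::expand_grid(organism = orgs, source_category = cats,
                             target_category = cats)
  purrr::pmap_dfr(grid, function(organism, source_category, target_category) {
    sub <- pairs[pairs$organism == organism, ]
    sub <- sub[purrr::map_lgl(sub$provider_categories,
                              function(v) source_category %in% v) &
                 purrr::map_lgl(sub$target_categories,
                                function(v) target_category %in% v), ]
    all_t <- dplyr::n_distinct(sub$target_ec)
    rle_t <- dplyr::n_distinct(sub$target_ec[sub$provider_is_rle])
    tibble::tibble(organism = organism, source_category = source_category,
                   target_category = target_category,
                   targets_by_rle = rle_t, targets_by_all = all_t,
                   fraction = if (all_t == 0) NA_real_ else rle_t / all_t)
  })
}
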