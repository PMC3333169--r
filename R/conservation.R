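#' Find inhibiting pairs conserved across organisms
#'
#' A pair is identified by (provider, target) — the mediating compound is
#' carried as an attribute, not part of the identity (set
#' `per_compound = TRUE` to key by compound as well) — and is conservative
#' when it occurs in at least `min_organisms` organisms. The provider's
#' rate-limiting status is the global flag carried on the pairs.
#'
#' @param pairs Pair tibble from [build_pairs()], covering all organisms.
#' @param min_organisms Minimum number of organisms (default 3; must be
#'   at least 2).
#' @param per_compound Include the mediating compound in the pair identity.
#' @return A tibble with columns `provider_ec`, `target_ec` (and `compound`
#'   when `per_compound`), `n_organisms`, `organisms` (list), `compounds`
#'   (list; union over organisms), `provider_is_rle`.
#' @export
find_conservative_pairs <- function(pairs, min_organisms = 3,
                                    per_compound = FALSE) {
  if (min_organisms < 2) {
    rlang::abort("`min_organisms` must be at least 2")
  }
  keys <- c("provider_ec", "target_ec", if (per_compound) "compound")
  pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_organisms = dplyr::n_distinct(.data$organism),
      organisms = list(sort(unique(.data$organism))),
      compounds = list(sort(unique(.data$compound))),
      provider_is_rle = .data$provider_is_rle[1],
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_organisms >= min_organisms) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}

#' Conservative pairs initiated by a compound
#'
#' Counts the conservative pairs whose mediating-compound set contains the
#' given compound (i.e. the compound initiates the pair in at least one
#' organism where the pair occurs; with `in_all = TRUE`, the compound must
#' mediate it wherever it occurs), and the subset whose provider is a
#' rate-limiting enzyme.
#'
#' @param conservative_pairs Tibble from [find_conservative_pairs()].
#' @param compound Compound identifier (e.g. `"C00008"` for ADP,
#'   `"C00020"` for AMP).
#' @param in_all Require the compound to mediate the pair in every organism
#'   (default `FALSE`: at least one).
#' @return A one-row tibble: `compound`, `n_pairs`, `n_rle_pairs`.
#' @export
compound_initiation <- function(conservative_pairs, compound,
                                in_all = FALSE) {
  hit <- purrr::map_lgl(conservative_pairs$compounds,
                        function(v) compound %in% v)
  if (in_all && nrow(conservative_pairs) > 0) {
    # per-organism compound sets are not retained; "in all" collapses to the
    # pair being mediated by this compound alone
    hit <- hit & lengths(conservative_pairs$compounds) == 1L
  }
  tibble::tibble(
    compound = compound,
    n_pairs = sum(hit),
    n_rle_pairs = sum(hit & conservative_pairs$provider_is_rle)
  )
}

#' Compare rate-limiting initiation of two compounds
#'
#' Upper-tail hypergeometric test on the 2x2 table formed by two
#' compound-initiation summaries: population N = all pairs initiated by
#' either compound, K = those with a rate-limiting provider, sample n =
#' pairs initiated by the first compound, k = first-compound pairs with a
#' rate-limiting provider. Small p means the first compound's pairs are
#' over-represented among rate-limiting-provider pairs (e.g. ADP vs AMP).
#'
#' @param summary_a,summary_b One-row tibbles from [compound_initiation()].
#' @return A tibble with `compound_a`, `compound_b`, `k`, `n`, `K`, `N`,
#'   `p_value` (`NA` with a warning on a degenerate table).
#' @export
compound_preference_test <- function(summary_a, summary_b) {
  N <- summary_a$n_pairs + summary_b$n_pairs
  K <- summary_a$n_rle_pairs + summary_b$n_rle_pairs
  head_cols <- tibble::tibble(compound_a = summary_a$compound,
                              compound_b = summary_b$compound)
  if (summary_a$n_pairs == 0 || summary_b$n_pairs == 0 || K == 0) {
    rlang::warn("compound_preference_test: degenerate table; returning NA result")
    return(dplyr::bind_cols(head_cols,
                            tibble::tibble(k = NA_integer_, n = NA_integer_,
                                           K = NA_integer_, N = NA_integer_,
                                           p_value = NA_real_)))
  }
  dplyr::bind_cols(
    head_cols,
    hypergeometric_tail(k = summary_a$n_rle_pairs, n = summary_a$n_pairs,
                        K = K, N = N))
}
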