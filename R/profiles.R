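#' Build a phylogenetic profile
#'
#' Looks up the 0/1 presence vector of an enzyme over the genome panel. In
#' strict mode (default) an EC absent from the presence matrix is an error;
#' in lenient mode it yields an all-zero profile with a warning, so that
#' downstream Jaccard scores treat the enzyme as never observed.
#'
#' @param ec EC number to look up.
#' @param presence Presence tibble from [read_presence_matrix()] (column
#'   `ec` plus one 0/1 column per panel genome).
#' @param strict Error on a missing EC (default `TRUE`).
#' @return A named integer vector of 0/1 values, one per panel genome, in
#'   panel order.
#' @export
build_profile <- function(ec, presence, strict = TRUE) {
  stopifnot(length(ec) == 1)
  i <- match(ec, presence$ec)
  genomes <- setdiff(names(presence), "ec")
  if (is.na(i)) {
    if (strict) rlang::abort(sprintf("no profile for EC %s", ec))
    rlang::warn(sprintf("no profile for EC %s; using an all-zero profile", ec))
    return(stats::setNames(integer(length(genomes)), genomes))
  }
  bits <- as.integer(unlist(presence[i, genomes]))
  stats::setNames(bits, genomes)
}

#' Positional agreement counts for two profiles
#'
#' Counts the four position-wise combinations of two equal-length 0/1
#' profiles: `m11` (both present), `m01` (first absent, second present),
#' `m10` (first present, second absent), `m00` (both absent). The counts
#' always sum to the panel size.
#'
#' @param a,b Profiles: 0/1 vectors of equal length.
#' @return A one-row tibble with columns `m11`, `m01`, `m10`, `m00`.
#' @export
profile_pair_counts <- function(a, b) {
  if (length(a) != length(b)) {
    rlang::abort(sprintf("profile lengths differ: %d vs %d",
                         length(a), length(b)))
  }
  stopifnot(all(a %in% c(0, 1)), all(b %in% c(0, 1)))
  a <- as.logical(a); b <- as.logical(b)
  tibble::tibble(m11 = sum(a & b), m01 = sum(!a & b),
                 m10 = sum(a & !b), m00 = sum(!a & !b))
}

#' Jaccard coefficient from agreement counts
#'
#' `J = m11 / (m01 + m10 + m11)`: joint absences (`m00`) never enter the
#' score, so adding genomes where both enzymes are missing leaves J
#' unchanged. When both profiles are all-zero the score is undefined and
#' `NA` is returned.
#'
#' @param counts Counts from [profile_pair_counts()] (or any list with
#'   `m11`, `m01`, `m10`).
#' @return A number in `[0, 1]`, or `NA` when undefined.
#' @export
#' @examples
#' jaccard(profile_pair_counts(c(1, 1, 0, 1), c(1, 0, 1, 1)))  # 0.5
jaccard <- function(counts) {
  den <- counts$m11 + counts$m01 + counts$m10
  ifelse(den == 0, NA_real_, counts$m11 / den)
}

#' @rdname jaccard
#' @param a,b Profiles: 0/1 vectors of equal length.
#' @export
jaccard_similarity <- function(a, b) jaccard(profile_pair_counts(a, b))

profile_matrix <- function(ecs, presence, strict = TRUE) {
  genomes <- setdiff(names(presence), "ec")
  i <- match(ecs, presence$ec)
  if (anyNA(i)) {
    missing <- unique(ecs[is.na(i)])
    if (strict) {
      rlang::abort(sprintf("no profile for EC(s): %s",
                           paste(missing, collapse = ", ")))
    }
    rlang::warn(sprintf("no profile for %d EC(s); using all-zero profiles",
                        length(missing)))
  }
  m <- matrix(0L, length(ecs), length(genomes))
  ok <- !is.na(i)
  m[ok, ] <- as.matrix(presence[i[ok], genomes])
  m
}

#' Score inhibiting pairs by profile similarity
#'
#' Collapses pairs to distinct (organism, provider, target) — so a pair
#' mediated by several compounds is scored once — and computes the Jaccard
#' coefficient of the two members' phylogenetic profiles. Pair classes are
#' nested: every pair is `common`, pairs with a rate-limiting provider are
#' additionally `rle_provider`, and pairs whose two members are both
#' rate-limiting are additionally `rle_both`. Undefined scores (both
#' profiles all-zero) are kept as `NA` here and excluded, with a logged
#' count, when class means are formed.
#'
#' @param pairs Pair tibble from [build_pairs()].
#' @param presence Presence tibble.
#' @param strict Error on ECs without a profile; if `FALSE`, all-zero
#'   profiles are substituted with a warning.
#' @return A tibble with columns `organism`, `provider_ec`, `target_ec`,
#'   `rle_provider`, `rle_both`, `jaccard`.
#' @export
score_pairs <- function(pairs, presence, strict = TRUE) {
  scored <- dplyr::distinct(pairs, .data$organism, .data$provider_ec,
                            .data$target_ec, .data$provider_is_rle,
                            .data$target_is_rle)
  a <- profile_matrix(scored$provider_ec, presence, strict)
  b <- profile_matrix(scored$target_ec, presence, strict)
  m11 <- rowSums(a == 1L & b == 1L)
  den <- m11 + rowSums(a != b)
  tibble::tibble(
    organism = scored$organism,
    provider_ec = scored$provider_ec,
    target_ec = scored$target_ec,
    rle_provider = scored$provider_is_rle,
    rle_both = scored$provider_is_rle & scored$target_is_rle,
    jaccard = ifelse(den == 0, NA_real_, m11 / den)
  )
}

#' Welch's unequal-variance t-test between two score groups
#'
#' One-sided by default (`alternative = "greater"`: the first group's mean
#' exceeds the second's), since the scientific hypotheses here are
#' directional — pairs involving rate-limiting enzymes are expected to show
#' *higher* profile similarity. Uses the Welch statistic with
#' Welch-Satterthwaite degrees of freedom. Groups with fewer than two
#' defined scores, or two exactly constant groups, yield an `NA` result
#' with a warning rather than an error.
#'
#' @param scores_a,scores_b Numeric score vectors (`NA`s dropped).
#' @param alternative `"greater"` (default), `"two.sided"` or `"less"`.
#' @param label_a,label_b Group labels carried into the result.
#' @return An object of class `rle_welch`: a list with `t_statistic`, `df`,
#'   `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`, `alternative` and the
#'   labels. Use [tidy()] for a one-row tibble.
#' @export
welch_t_test <- function(scores_a, scores_b,
                         alternative = c("greater", "two.sided", "less"),
                         label_a = "a", label_b = "b") {
  alternative <- match.arg(alternative)
  a <- scores_a[!is.na(scores_a)]
  b <- scores_b[!is.na(scores_b)]
  out <- list(group_a = label_a, group_b = label_b,
              n_a = length(a), n_b = length(b),
              mean_a = if (length(a)) mean(a) else NA_real_,
              mean_b = if (length(b)) mean(b) else NA_real_,
              t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
              alternative = alternative)
  class(out) <- "rle_welch"
  if (length(a) < 2 || length(b) < 2) {
    rlang::warn("welch_t_test: fewer than two defined scores in a group; returning NA result")
    return(out)
  }
  ht <- tryCatch(
    stats::t.test(a, b, alternative = alternative, var.equal = FALSE),
    error = function(e) NULL)
  if (is.null(ht)) {
    rlang::warn("welch_t_test: degenerate groups (essentially constant data); returning NA result")
    return(out)
  }
  out$t_statistic <- unname(ht$statistic)
  out$df <- unname(ht$parameter)
  out$p_value <- ht$p.value
  out
}

#' @export
print.rle_welch <- function(x, ...) {
  cat(sprintf(
    "Welch two-sample t-test (%s): %s (n=%d, mean=%.4g) vs %s (n=%d, mean=%.4g)\n",
    x$alternative, x$group_a, x$n_a, x$mean_a, x$group_b, x$n_b, x$mean_b))
  cat(sprintf("  t = %.4g, df = %.3g, p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' @rdname welch_t_test
#' @param x An `rle_welch` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.rle_welch <- function(x, ...) {
  tibble::tibble(group_a = x$group_a, group_b = x$group_b,
                 n_a = x$n_a, n_b = x$n_b,
                 mean_a = x$mean_a, mean_b = x$mean_b,
                 t_statistic = x$t_statistic, df = x$df,
                 p_value = x$p_value, alternative = x$alternative)
}

#' @rdname welch_t_test
#' @exportS3Method generics::glance
#' @export
glance.rle_welch <- function(x, ...) tidy(x)

#' Profile-similarity analysis of pair classes
#'
#' Mean Jaccard similarity of the three nested pair classes (all pairs; pairs
#' with a rate-limiting provider; pairs where both members are rate-limiting)
#' with the two directional Welch comparisons — `rle_provider` vs `common`
#' and `rle_both` vs `rle_provider` — either per organism (default) or
#' pooled over distinct (provider, target) pairs across organisms.
#' Undefined Jaccard scores are excluded from means and tests, with a
#' message reporting how many were dropped.
#'
#' @param pairs Pair tibble from [build_pairs()].
#' @param presence Presence tibble.
#' @param by_organism Stratify by organism (default `TRUE`); if `FALSE`,
#'   pairs are pooled and deduplicated across organisms.
#' @param alternative Passed to [welch_t_test()].
#' @param strict Passed to [score_pairs()].
#' @return A list of class `rle_profile_analysis` with `class_means` (tibble:
#'   `organism`, `pair_class`, `n`, `mean_jaccard`) and `comparisons`
#'   (tibble: one row per Welch comparison).
#' @export
profile_similarity_analysis <- function(pairs, presence, by_organism = TRUE,
                                        alternative = "greater",
                                        strict = TRUE) {
  scored <- score_pairs(pairs, presence, strict = strict)
  if (!by_organism) {
    # one profile per EC, so the score does not depend on the organism
    scored <- scored |>
      dplyr::distinct(.data$provider_ec, .data$target_ec, .data$rle_provider,
                      .data$rle_both, .data$jaccard) |>
      dplyr::mutate(organism = "all", .before = 1)
  }
  n_undef <- sum(is.na(scored$jaccard))
  if (n_undef > 0) {
    message(sprintf(
      "profile_similarity_analysis: excluded %d pair(s) with undefined Jaccard",
      n_undef))
  }
  scored <- scored[!is.na(scored$jaccard), ]

  one_org <- function(sub) {
    classes <- list(common = sub$jaccard,
                    rle_provider = sub$jaccard[sub$rle_provider],
                    rle_both = sub$jaccard[sub$rle_both])
    means <- purrr::imap_dfr(classes, function(x, nm) {
      tibble::tibble(pair_class = nm, n = length(x),
                     mean_jaccard = if (length(x)) mean(x) else NA_real_)
    })
    comps <- dplyr::bind_rows(
      tidy(welch_t_test(classes$rle_provider, classes$common,
                        alternative = alternative,
                        label_a = "rle_provider", label_b = "common")),
      tidy(welch_t_test(classes$rle_both, classes$rle_provider,
                        alternative = alternative,
                        label_a = "rle_both", label_b = "rle_provider"))
    )
    list(means = means, comps = comps)
  }

  orgs <- sort(unique(scored$organism))
  parts <- purrr::map(orgs, function(org) one_org(scored[scored$organism == org, ]))
  out <- list(
    class_means = purrr::map2_dfr(orgs, parts, function(org, p) {
      dplyr::bind_cols(tibble::tibble(organism = org), p$means)
    }),
    comparisons = purrr::map2_dfr(orgs, parts, function(org, p) {
      dplyr::bind_cols(tibble::tibble(organism = org), p$comps)
    }),
    n_undefined = n_undef
  )
  class(out) <- "rle_profile_analysis"
  out
}

#' @export
print.rle_profile_analysis <- function(x, ...) {
  cat("Phylogenetic-profile similarity by pair class\n")
  print(x$class_means)
  cat("\nWelch comparisons\n")
  print(x$comparisons)
  invisible(x)
}
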