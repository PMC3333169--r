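#' Run the full inhibitory-network analysis
#'
#' Orchestrates every stage on one dataset: referential-integrity
#' validation, pair construction, per-organism inhibitor-production stats
#' and enrichment, coverage reports (overall and per pathway category),
#' rate-limiting-target enrichment, the cross-pathway pair subset and 6x6
#' matrix, profile-similarity class means with Welch comparisons,
#' conservative pairs and the two compound-initiation summaries with their
#' preference test. Results are returned as a list of tibbles and, when
#' `out_dir` is given, written as TSV tables plus a single `summary.json`.
#' Every table carries the package version and a configuration hash;
#' reruns with identical inputs and options produce byte-identical files.
#' The reporter only assembles numbers computed by the stage functions —
#' it never recomputes and never judges significance.
#'
#' @param dataset A list with `enzymes`, `products`, `inhibitions`,
#'   `presence` (e.g. from [simulate_dataset()] or [read_dataset()]).
#' @param out_dir Optional output directory for the report bundle.
#' @param in_vivo_only Restrict to in-vivo inhibitions (default `TRUE`).
#' @param keep_self_pairs Retain autoinhibition pairs (default `TRUE`).
#' @param cross_criterion Cross-pathway criterion, `"disjoint"` or
#'   `"not_identical"`.
#' @param min_organisms Conservation threshold (default 3).
#' @param adp_compound,amp_compound Compound identifiers for the
#'   initiation comparison (defaults `"C00008"`, `"C00020"`).
#' @param alternative Alternative hypothesis for the Welch comparisons.
#' @return A list of class `rleinhib_report` with elements `pairs`,
#'   `production_stats`, `production_enrichment`, `coverage`,
#'   `target_enrichment`, `cross_pairs`, `cross_matrix`, `profile_analysis`,
#'   `conservative_pairs`, `initiation`, `initiation_test`, `meta`.
#' @export
run_full_analysis <- function(dataset, out_dir = NULL, in_vivo_only = TRUE,
                              keep_self_pairs = TRUE,
                              cross_criterion = "disjoint",
                              min_organisms = 3,
                              adp_compound = "C00008",
                              amp_compound = "C00020",
                              alternative = "greater") {
  enz <- dataset$enzymes
  issues <- validate_dataset(enz, dataset$products, dataset$inhibitions)
  if (any(issues$severity == "error")) {
    bad <- issues[issues$severity == "error", ]
    rlang::abort(c("dataset failed referential-integrity validation",
                   stats::setNames(paste(bad$issue, bad$detail, sep = ": "),
                                   rep("x", nrow(bad)))))
  }

  opts <- list(in_vivo_only = in_vivo_only,
               keep_self_pairs = keep_self_pairs,
               cross_criterion = cross_criterion,
               min_organisms = min_organisms,
               adp_compound = adp_compound, amp_compound = amp_compound,
               alternative = alternative)
  meta <- list(
    pipeline_version = as.character(utils::packageVersion("rleinhib")),
    config_hash = digest::digest(list(opts = opts,
                                      config = dataset$ground_truth$config)),
    options = opts,
    n_validation_warnings = sum(issues$severity == "warning")
  )

  pairs <- build_pairs(dataset$products, dataset$inhibitions, enz,
                       in_vivo_only = in_vivo_only,
                       keep_self_pairs = keep_self_pairs)
  prod_stats <- inhibitor_production_stats(dataset$products,
                                           dataset$inhibitions, enz)
  prod_enr <- production_enrichment(dataset$products, dataset$inhibitions, enz)
  coverage <- coverage_report(pairs, by_category = TRUE)
  tgt_enr <- enrichment_rle_targets(pairs, enz)
  cross <- cross_pathway_pairs(pairs, criterion = cross_criterion)
  cross_mat <- cross_pathway_matrix(cross)
  prof <- profile_similarity_analysis(pairs, dataset$presence,
                                      alternative = alternative,
                                      strict = FALSE)
  cons <- find_conservative_pairs(pairs, min_organisms = min_organisms)
  init <- dplyr::bind_rows(compound_initiation(cons, adp_compound),
                           compound_initiation(cons, amp_compound))
  init_test <- compound_preference_test(init[1, ], init[2, ])

  report <- list(pairs = pairs, production_stats = prod_stats,
                 production_enrichment = prod_enr, coverage = coverage,
                 target_enrichment = tgt_enr, cross_pairs = cross,
                 cross_matrix = cross_mat, profile_analysis = prof,
                 conservative_pairs = cons, initiation = init,
                 initiation_test = init_test, meta = meta)
  class(report) <- "rleinhib_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  invisible(report)
}

flatten_pairs <- function(pairs) {
  dplyr::mutate(pairs,
                provider_categories = collapse_list_field(.data$provider_categories),
                target_categories = collapse_list_field(.data$target_categories))
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tab, name) {
    readr::write_tsv(tab, file.path(out_dir, name), progress = FALSE)
  }
  w(flatten_pairs(report$pairs), "pairs.tsv")
  w(report$production_stats, "production_stats.tsv")
  w(report$production_enrichment, "production_enrichment.tsv")
  w(report$coverage, "coverage.tsv")
  w(report$target_enrichment, "target_enrichment.tsv")
  w(flatten_pairs(report$cross_pairs), "cross_pathway_pairs.tsv")
  w(report$cross_matrix, "cross_pathway_matrix.tsv")
  w(report$profile_analysis$class_means, "profile_class_means.tsv")
  w(report$profile_analysis$comparisons, "profile_comparisons.tsv")
  cons <- dplyr::mutate(report$conservative_pairs,
                        organisms = collapse_list_field(.data$organisms),
                        compounds = collapse_list_field(.data$compounds))
  w(cons, "conservative_pairs.tsv")
  w(report$initiation, "compound_initiation.tsv")
  w(report$initiation_test, "initiation_test.tsv")

  summary <- list(
    meta = report$meta,
    production = report$production_stats,
    production_enrichment = report$production_enrichment,
    coverage_all = report$coverage[report$coverage$category == "All", ],
    target_enrichment = report$target_enrichment,
    profile_class_means = report$profile_analysis$class_means,
    profile_comparisons = report$profile_analysis$comparisons,
    n_undefined_jaccard = report$profile_analysis$n_undefined,
    n_conservative_pairs = nrow(report$conservative_pairs),
    initiation = report$initiation,
    initiation_test = report$initiation_test
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(out_dir)
}

#' @export
print.rleinhib_report <- function(x, ...) {
  cat(sprintf("Inhibitory-network analysis report (pipeline %s)\n",
              x$meta$pipeline_version))
  cat(sprintf("  %d inhibiting pair records across %d organism(s); %d conservative pair(s)\n",
              nrow(x$pairs), dplyr::n_distinct(x$pairs$organism),
              nrow(x$conservative_pairs)))
  cat("\nInhibitor production by rate-limiting enzymes:\n")
  print(x$production_stats)
  cat("\nProfile-similarity class means:\n")
  print(x$profile_analysis$class_means)
  invisible(x)
}
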