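#' The six KEGG pathway categories
#'
#' Metabolic enzymes are tallied under six high-level KEGG pathway
#' categories. Every category label in an enzyme table must come from this
#' vocabulary; unknown labels are rejected at parse time.
#'
#' @return Character vector of the six admissible category labels.
#' @export
#' @examples
#' pathway_categories()
pathway_categories <- function() {
  c("Carbohydrate", "Lipid", "Nucleotide", "AminoAcid", "CofactorVitamin",
    "Others")
}

#' Reference genome panel for phylogenetic profiles
#'
#' Builds the ordered panel of reference genomes over which presence/absence
#' profiles are defined. The default panel has 82 genomes: 23 prokaryotes
#' followed by 59 eukaryotes. Genome identifiers are placeholders unless a
#' custom vector is supplied; the order is fixed for the lifetime of an
#' analysis.
#'
#' @param n_prokaryotes,n_eukaryotes Panel composition (defaults 23 and 59).
#' @param genomes Optional character vector of genome identifiers (must be
#'   unique and of length `n_prokaryotes + n_eukaryotes`).
#' @return A tibble with columns `genome` and `kingdom`
#'   (`"prokaryote"`/`"eukaryote"`), one row per panel genome, in panel order.
#' @export
#' @examples
#' panel <- genome_panel()
#' nrow(panel)
genome_panel <- function(n_prokaryotes = 23, n_eukaryotes = 59,
                         genomes = NULL) {
  n <- n_prokaryotes + n_eukaryotes
  if (is.null(genomes)) {
    genomes <- c(sprintf("prok%02d", seq_len(n_prokaryotes)),
                 sprintf("euk%02d", seq_len(n_eukaryotes)))
  }
  if (length(genomes) != n) {
    rlang::abort(sprintf("`genomes` must have length %d, got %d",
                         n, length(genomes)))
  }
  if (anyDuplicated(genomes)) {
    rlang::abort("genome identifiers must be unique")
  }
  tibble::tibble(
    genome = as.character(genomes),
    kingdom = rep(c("prokaryote", "eukaryote"),
                  c(n_prokaryotes, n_eukaryotes))
  )
}

# EC-number patterns: full "a.b.c.d" and partial with "-" in trailing fields
ec_pattern_full <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$"
ec_pattern_partial <- "^[0-9]+(\\.([0-9]+|-)){3}$"

is_valid_ec <- function(ec) grepl(ec_pattern_partial, ec)
is_partial_ec <- function(ec) is_valid_ec(ec) & !grepl(ec_pattern_full, ec)

# list fields are kept sorted so that write/read round-trips are exact
split_list_field <- function(x) {
  purrr::map(strsplit(as.character(x), ",", fixed = TRUE),
             function(v) sort(unique(trimws(v[nzchar(trimws(v))]))))
}

collapse_list_field <- function(x) {
  purrr::map_chr(x, function(v) paste(sort(v), collapse = ","))
}

parse_flag <- function(x) {
  out <- rep(NA, length(x))
  xl <- tolower(trimws(as.character(x)))
  out[xl %in% c("1", "true", "t", "yes")] <- TRUE
  out[xl %in% c("0", "false", "f", "no")] <- FALSE
  out
}

read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    rlang::abort(sprintf("%s: missing required column(s): %s",
                         path, paste(missing, collapse = ", ")))
  }
  tab
}

abort_lines <- function(path, what, lines) {
  # +1 for the header row, so the number matches the file as seen in an editor
  rlang::abort(sprintf("%s: %s at line(s) %s", path, what,
                       paste(lines + 1L, collapse = ", ")))
}

#' Read an enzyme table
#'
#' Reads a TSV with columns `ec`, `organisms`, `is_rle`, `categories`.
#' `organisms` and `categories` are comma-separated lists. Rows sharing an EC
#' number are merged: organisms and categories are unioned and the
#' rate-limiting flag is OR-combined (a message reports how many merges
#' happened). Malformed EC numbers, empty organism lists, unparseable flags
#' and category labels outside [pathway_categories()] are errors naming the
#' offending line.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `ec` (character), `organisms` (list of
#'   character), `is_rle` (logical), `categories` (list of character).
#' @export
read_enzyme_table <- function(path) {
  tab <- read_tsv_strict(path, c("ec", "organisms", "is_rle", "categories"))
  n <- nrow(tab)
  line <- seq_len(n)

  bad_ec <- which(!is_valid_ec(tab$ec))
  if (length(bad_ec) > 0) abort_lines(path, "malformed EC number", bad_ec)

  organisms <- split_list_field(tab$organisms)
  empty_org <- which(lengths(organisms) == 0)
  if (length(empty_org) > 0) abort_lines(path, "empty organism list", empty_org)

  is_rle <- parse_flag(tab$is_rle)
  bad_flag <- which(is.na(is_rle))
  if (length(bad_flag) > 0) abort_lines(path, "unparseable is_rle flag", bad_flag)

  categories <- split_list_field(tab$categories)
  empty_cat <- which(lengths(categories) == 0)
  if (length(empty_cat) > 0) abort_lines(path, "empty category list", empty_cat)
  known <- pathway_categories()
  bad_cat <- which(purrr::map_lgl(categories, function(v) any(!v %in% known)))
  if (length(bad_cat) > 0) {
    labels <- unique(unlist(purrr::map(categories[bad_cat],
                                       function(v) setdiff(v, known))))
    abort_lines(path, sprintf("unknown pathway category (%s)",
                              paste(labels, collapse = ", ")), bad_cat)
  }

  enz <- tibble::tibble(ec = tab$ec, organisms = organisms,
                        is_rle = is_rle, categories = categories)
  n_dup <- sum(duplicated(enz$ec))
  if (n_dup > 0) {
    message(sprintf("read_enzyme_table: merged %d duplicate EC row(s)", n_dup))
    enz <- enz |>
      dplyr::group_by(.data$ec) |>
      dplyr::summarise(
        organisms = list(sort(unique(unlist(.data$organisms)))),
        is_rle = any(.data$is_rle),
        categories = list(sort(unique(unlist(.data$categories)))),
        .groups = "drop"
      )
  }
  enz
}

#' Read a product table
#'
#' Reads a TSV with columns `organism`, `ec`, `compound`, one row per
#' organism-specific link between a producing enzyme and a compound.
#' Exact-duplicate rows are dropped with a logged count.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `organism`, `ec`, `compound`.
#' @export
read_product_table <- function(path) {
  tab <- read_tsv_strict(path, c("organism", "ec", "compound"))
  tab <- tab[c("organism", "ec", "compound")]
  bad_ec <- which(!is_valid_ec(tab$ec))
  if (length(bad_ec) > 0) abort_lines(path, "malformed EC number", bad_ec)
  dedupe_logged(tab, "read_product_table")
}

#' Read an inhibition table
#'
#' Reads a TSV with columns `organism`, `compound`, `target_ec`, `in_vivo`,
#' one row per organism-specific annotation that a compound inhibits an
#' enzyme. Exact-duplicate rows are dropped with a logged count.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `organism`, `compound`, `target_ec`,
#'   `in_vivo` (logical).
#' @export
read_inhibition_table <- function(path) {
  tab <- read_tsv_strict(path, c("organism", "compound", "target_ec", "in_vivo"))
  bad_ec <- which(!is_valid_ec(tab$target_ec))
  if (length(bad_ec) > 0) abort_lines(path, "malformed EC number", bad_ec)
  in_vivo <- parse_flag(tab$in_vivo)
  bad_flag <- which(is.na(in_vivo))
  if (length(bad_flag) > 0) abort_lines(path, "unparseable in_vivo flag", bad_flag)
  out <- tibble::tibble(organism = tab$organism, compound = tab$compound,
                        target_ec = tab$target_ec, in_vivo = in_vivo)
  dedupe_logged(out, "read_inhibition_table")
}

dedupe_logged <- function(tab, who) {
  n_dup <- sum(duplicated(tab))
  if (n_dup > 0) {
    message(sprintf("%s: dropped %d exact-duplicate row(s)", who, n_dup))
    tab <- dplyr::distinct(tab)
  }
  tab
}

#' Read a presence/absence matrix
#'
#' Reads a TSV whose first column is `ec` and whose remaining columns are the
#' panel genomes, in panel order, with 0/1 entries. Column names must match
#' `panel$genome` exactly (a mismatch is a configuration error); entries
#' outside {0, 1} are parse errors.
#'
#' @param path Path to the TSV file.
#' @param panel Genome panel tibble from [genome_panel()].
#' @return A tibble with column `ec` plus one integer 0/1 column per panel
#'   genome.
#' @export
read_presence_matrix <- function(path, panel = genome_panel()) {
  tab <- read_tsv_strict(path, "ec")
  cols <- setdiff(names(tab), "ec")
  if (!identical(cols, panel$genome)) {
    rlang::abort(sprintf(
      "%s: presence columns do not match the genome panel (%d column(s) vs %d panel genomes, or order differs)",
      path, length(cols), nrow(panel)))
  }
  if (anyDuplicated(tab$ec)) {
    rlang::abort(sprintf("%s: duplicated EC row(s): %s", path,
                         paste(unique(tab$ec[duplicated(tab$ec)]), collapse = ", ")))
  }
  vals <- as.matrix(tab[cols])
  suppressWarnings(storage.mode(vals) <- "integer")
  if (anyNA(vals) || !all(vals %in% c(0L, 1L))) {
    bad <- which(rowSums(is.na(vals) | !(vals == 0L | vals == 1L)) > 0)
    abort_lines(path, "presence value outside {0,1}", bad)
  }
  dplyr::bind_cols(tibble::tibble(ec = tab$ec), tibble::as_tibble(vals))
}

#' @rdname read_enzyme_table
#' @param enzymes An enzyme tibble as returned by [read_enzyme_table()].
#' @export
write_enzyme_table <- function(enzymes, path) {
  out <- tibble::tibble(
    ec = enzymes$ec,
    organisms = collapse_list_field(enzymes$organisms),
    is_rle = as.integer(enzymes$is_rle),
    categories = collapse_list_field(enzymes$categories)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_product_table
#' @param products A product tibble.
#' @export
write_product_table <- function(products, path) {
  readr::write_tsv(products, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_inhibition_table
#' @param inhibitions An inhibition tibble.
#' @export
write_inhibition_table <- function(inhibitions, path) {
  out <- dplyr::mutate(inhibitions, in_vivo = as.integer(.data$in_vivo))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_presence_matrix
#' @param presence A presence tibble (`ec` plus one column per genome).
#' @export
write_presence_matrix <- function(presence, path) {
  readr::write_tsv(presence, path, progress = FALSE)
  invisible(path)
}

#' Validate referential integrity of a dataset
#'
#' Checks every product and inhibition link against the enzyme table: the
#' referenced EC must exist and must list the link's organism. Partial EC
#' numbers (e.g. `"1.1.1.-"`) are accepted but flagged. The check is total: it
#' either returns an empty tibble or enumerates every violation.
#'
#' @param enzymes Enzyme tibble ([read_enzyme_table()]).
#' @param products Product tibble ([read_product_table()]).
#' @param inhibitions Inhibition tibble ([read_inhibition_table()]).
#' @return A tibble with columns `table`, `severity` (`"error"`/`"warning"`),
#'   `issue`, `detail`; zero rows when the dataset is clean.
#' @export
validate_dataset <- function(enzymes, products, inhibitions) {
  issues <- list()
  add <- function(table, severity, issue, detail) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      table = table, severity = severity, issue = issue, detail = detail)
  }

  org_of <- stats::setNames(enzymes$organisms, enzymes$ec)
  check_links <- function(tab, ec_col, table) {
    ecs <- tab[[ec_col]]
    unknown <- !ecs %in% enzymes$ec
    for (i in which(unknown)) {
      add(table, "error", "unknown EC",
          sprintf("%s (organism %s)", ecs[i], tab$organism[i]))
    }
    for (i in which(!unknown)) {
      if (!tab$organism[i] %in% org_of[[ecs[i]]]) {
        add(table, "error", "organism not listed for EC",
            sprintf("%s not listed for %s", tab$organism[i], ecs[i]))
      }
    }
  }
  check_links(products, "ec", "products")
  check_links(inhibitions, "target_ec", "inhibitions")

  partial <- enzymes$ec[is_partial_ec(enzymes$ec)]
  for (ec in partial) add("enzymes", "warning", "partial EC number", ec)

  if (length(issues) == 0) {
    return(tibble::tibble(table = character(), severity = character(),
                          issue = character(), detail = character()))
  }
  dplyr::bind_rows(issues)
}
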