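# Reading, validating and curating cross-linguistic category-system
# records, plus the colour-naming consensus count and parity summaries.

utils::globalVariables(c(
  "glottocode", "language", "size", ".symcat_row", "term", "chip",
  "participant", "family", "domain", "parity", "n", "max_frac"
))

#' Read category-system records from a CSV file
#'
#' Expects a UTF-8 comma-separated file with a header and at least the
#' columns `language`, `glottocode`, `family`, `domain`, `size`
#' (a `source` column is carried through if present). Sizes must be positive
#' integers; a non-integer size is an error naming the offending row. Rows
#' with a missing or empty glottocode are retained but flagged
#' `excluded_from_regression`, since records without a glottocode cannot be
#' assigned a language family.
#'
#' @param path path to a CSV file
#' @return a tibble of system records with derived columns `parity`
#'   (`"odd"`/`"even"`) and `excluded_from_regression`
#' @export
read_system_records <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("language", "glottocode", "family", "domain", "size")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(raw$size) | !grepl("^[0-9]+$", raw$size) |
                 as.integer(raw$size) < 1L)
  if (length(bad) > 0) {
    stop("size must be a positive integer; offending row(s): ",
         paste(bad, collapse = ", "), " (size = ",
         paste(raw$size[bad], collapse = ", "), ")", call. = FALSE)
  }
  validate_system_records(
    dplyr::mutate(
      raw,
      size = as.integer(size),
      source = if ("source" %in% names(raw)) raw$source else NA_character_
    )
  )
}

#' Validate and derive columns of a system-record table
#'
#' Derives `parity` from `size` and flags rows without a usable glottocode.
#' Used by [read_system_records()] and by the synthetic-survey generator so
#' in-memory and on-disk records share one contract.
#'
#' @param records data frame with at least `language`, `glottocode`,
#'   `family`, `domain`, `size`
#' @return tibble with `parity` and `excluded_from_regression` columns
#' @export
validate_system_records <- function(records) {
  stopifnot(all(c("language", "glottocode", "family", "domain", "size")
                %in% names(records)))
  if (any(is.na(records$size)) || any(records$size < 1L)) {
    stop("size must be a positive integer", call. = FALSE)
  }
  tibble::as_tibble(records) |>
    dplyr::mutate(
      size = as.integer(size),
      parity = ifelse(size %% 2L == 0L, "even", "odd"),
      excluded_from_regression = is.na(glottocode) | glottocode == ""
    )
}

#' Deduplicate records by glottocode, conservatively
#'
#' Keeps one record per glottocode within a domain. When duplicate records
#' agree in parity, the first is kept. When they disagree, the record whose
#' parity *contradicts* the predicted parity of the domain is kept — the
#' conservative choice with respect to the parity hypothesis (e.g. with a
#' predicted even preference, the odd-numbered duplicate is retained). With
#' `predicted_parity = "none"` the first record is kept and a warning is
#' issued. Records with a missing glottocode cannot be matched and pass
#' through untouched.
#'
#' @param records a system-record tibble (one domain)
#' @param predicted_parity `"odd"`, `"even"` or `"none"`
#' @return deduplicated tibble, original row order preserved
#' @export
dedupe_by_glottocode <- function(records,
                                 predicted_parity = c("none", "odd", "even")) {
  predicted_parity <- match.arg(predicted_parity)
  records <- validate_system_records(records)

  matched <- which(!records$excluded_from_regression)
  pick <- function(idx) {
    if (length(idx) == 1L) return(idx)
    parities <- records$parity[idx]
    if (length(unique(parities)) == 1L) return(idx[1])
    if (predicted_parity == "none") {
      warning("duplicate glottocode '", records$glottocode[idx[1]],
              "' with mixed parities and no predicted parity; keeping the ",
              "first record", call. = FALSE)
      return(idx[1])
    }
    contra <- if (predicted_parity == "even") "odd" else "even"
    idx[which(parities == contra)[1]]
  }
  kept <- vapply(split(matched, records$glottocode[matched]), pick, integer(1))
  keep_idx <- sort(c(which(records$excluded_from_regression),
                     unname(kept)))
  records[keep_idx, , drop = FALSE]
}

#' Keep only the largest system per language
#'
#' For domains where a language may field several systems of nested
#' resolution (e.g. moieties inside sections inside subsections), retains
#' the single largest system for each language; ties keep the first record.
#'
#' @param records a system-record tibble (one domain)
#' @return tibble with one row per language
#' @export
largest_per_language <- function(records) {
  records <- validate_system_records(records)
  records$.symcat_row <- seq_len(nrow(records))
  out <- records |>
    dplyr::group_by(language) |>
    dplyr::slice_max(size, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- out[order(out$.symcat_row), , drop = FALSE]
  out$.symcat_row <- NULL
  out
}

#' Count colour terms by participant consensus
#'
#' Applies the consensus rule for colour-naming matrices: a term counts
#' towards the system size when it was provided by at least
#' `threshold` of the participants for at least one chip (the boundary is
#' inclusive, so with 10 participants and `threshold = 0.6`, 6 users
#' suffice). The denominator is the number of distinct participants in the
#' table.
#'
#' @param naming data frame with columns `participant`, `chip`, `term`;
#'   at most one term per participant x chip
#' @param threshold consensus fraction in (0, 1]; default 0.6
#' @return integer: number of consensus terms
#' @export
count_color_terms <- function(naming, threshold = 0.6) {
  stopifnot(all(c("participant", "chip", "term") %in% names(naming)))
  if (nrow(naming) == 0) stop("`naming` is empty", call. = FALSE)
  if (!(threshold > 0 && threshold <= 1)) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  dup <- duplicated(naming[, c("participant", "chip")])
  if (any(dup)) {
    stop("each (participant, chip) pair may carry at most one term",
         call. = FALSE)
  }
  n_participants <- length(unique(naming$participant))
  per_chip <- naming |>
    dplyr::count(term, chip) |>
    dplyr::group_by(term) |>
    dplyr::summarise(max_frac = max(n) / n_participants, .groups = "drop")
  sum(per_chip$max_frac >= threshold)
}

#' Summarise the parity composition of a set of system records
#'
#' Computes the size histogram, the odd/even counts, and whether every size
#' is a power of two (with 1 = 2^0 counting as a power of two — relevant
#' only as a documented corner case, since the substantive powers-of-two
#' observation concerns sizes 2, 4 and 8).
#'
#' @param records a system-record tibble, or an integer vector of sizes
#' @return an object of class `symcat_parity_summary`: list with
#'   `size_histogram` (named integer vector), `n_odd`, `n_even`,
#'   `all_powers_of_two`
#' @export
parity_summary <- function(records) {
  sizes <- if (is.data.frame(records)) records$size else as.integer(records)
  if (length(sizes) == 0) stop("no records to summarise", call. = FALSE)
  if (anyNA(sizes) || any(sizes < 1L)) {
    stop("sizes must be positive integers", call. = FALSE)
  }
  hist <- table(factor(sizes, levels = sort(unique(sizes))))
  structure(
    list(
      size_histogram = stats::setNames(as.integer(hist), names(hist)),
      n_odd = sum(sizes %% 2L == 1L),
      n_even = sum(sizes %% 2L == 0L),
      all_powers_of_two = all(bitwAnd(sizes, sizes - 1L) == 0L)
    ),
    class = "symcat_parity_summary"
  )
}

#' @export
print.symcat_parity_summary <- function(x, ...) {
  cat("<parity summary |", x$n_odd, "odd,", x$n_even, "even",
      if (x$all_powers_of_two) "| all sizes powers of two", ">\n")
  sizes <- names(x$size_histogram)
  cat(" sizes: ", paste0(sizes, ":", x$size_histogram, collapse = "  "),
      "\n")
  invisible(x)
}

#' Serialize a parity summary to JSON
#' @param summary a `symcat_parity_summary`
#' @param path optional output file
#' @return JSON string (invisibly when writing to `path`)
#' @export
parity_summary_json <- function(summary, path = NULL) {
  payload <- list(
    size_histogram = as.list(summary$size_histogram),
    n_odd = summary$n_odd,
    n_even = summary$n_even,
    all_powers_of_two = summary$all_powers_of_two
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
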