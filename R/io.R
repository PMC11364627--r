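#' Read respondent data from a delimited file
#'
#' Reads a CSV with one row per respondent: a `country` column plus the eight
#' analysed item columns named as in the schema. Files that additionally
#' carry a dropped-item column (e.g. `entering_nature_reserves`) are
#' accepted; the column is removed before anything else happens. Missing
#' responses are empty cells or `NA`.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema An [item_schema()].
#' @return A [response_matrix()].
#' @export
read_responses <- function(path, schema = item_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (nrow(df) == 0L) stop("empty responses file: ", path)
  if (!"country" %in% names(df))
    stop("responses file must have a 'country' column")
  df <- df[, setdiff(names(df), schema$dropped_items), drop = FALSE]
  need <- schema$all_items
  if (!setequal(setdiff(names(df), "country"), need))
    stop("unknown column set in ", path, ": have {",
         paste(setdiff(names(df), "country"), collapse = ", "),
         "}, need {", paste(need, collapse = ", "), "}")
  items <- as.matrix(df[, need, drop = FALSE])
  storage.mode(items) <- "double"
  obs <- items[!is.na(items)]
  if (any(obs != round(obs)))
    stop("non-integer Likert value in ", path)
  response_matrix(items, df$country, schema)
}

#' Write respondent data to CSV
#'
#' Inverse of [read_responses()]; missing cells are written as empty fields.
#'
#' @param mat A [response_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(mat, path) {
  df <- data.frame(country = mat$country, mat$items, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a country-index table
#'
#' One row per country with the five numeric indices used in the screen:
#' CO2 (fossil CO2 emissions), EPI (Environmental Performance Index), GBI
#' (Global Biodiversity Index), NIS (number of reported invasive species)
#' and LPI (Legatum Prosperity Index).
#'
#' @param path CSV path with columns `country, CO2, EPI, GBI, NIS, LPI`.
#' @return Data frame with upper-cased, unique country codes.
#' @export
read_index_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("country", "CO2", "EPI", "GBI", "NIS", "LPI")
  if (!all(need %in% names(df)))
    stop("index table must have columns ", paste(need, collapse = ", "))
  df$country <- toupper(df$country)
  if (anyDuplicated(df$country))
    stop("duplicated country codes in index table")
  df[, need]
}

#' Load a packaged fixture table
#'
#' Three printed summary tables ship with the package as plain CSV:
#' `"table1"` — per-country sample sizes and main-item mean/SD summaries for
#' the 37 surveyed countries; `"table2"` — the eight response-type profiles
#' (main-item and discrimination mean/SD); `"table3"` — the Spearman r and p
#' of each (response type, country index) pair.
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`.
#' @return A data frame.
#' @examples
#' tab1 <- load_fixture("table1")
#' sum(tab1$n)  # 4441 respondents
#' @export
load_fixture <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  file <- switch(name,
                 table1 = "table1_country_item_summaries.csv",
                 table2 = "table2_response_type_profiles.csv",
                 table3 = "table3_type_index_correlations.csv")
  path <- system.file("extdata", file, package = "resptyper")
  if (!nzchar(path)) stop("fixture not found: ", name)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read country fingerprints
#'
#' Fingerprints are stored as a CSV with a `country` column and one column
#' `type_<i>` per response type; proportions round-trip losslessly at 12
#' significant digits.
#'
#' @param fp A `fingerprint_set` (see [compute_fingerprints()]).
#' @param path Output path.
#' @return `path` invisibly; for the reader, a `fingerprint_set`.
#' @export
write_fingerprints <- function(fp, path) {
  stopifnot(inherits(fp, "fingerprint_set"))
  if (nrow(fp$matrix) == 0L) stop("empty fingerprint set")
  df <- data.frame(country = fp$countries,
                   signif(fp$matrix, 12), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "country"), drop = FALSE])
  fingerprint_set(m, toupper(df$country))
}

#' Write a correlation screen to CSV
#'
#' One row per (response type, index) cell with Spearman r, p, the number of
#' countries used, and the moderate/significant flags.
#'
#' @param cells An `association_table` (see [correlate_fingerprints()]) or
#'   its `cells` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlations <- function(cells, path) {
  if (inherits(cells, "association_table")) cells <- cells$cells
  if (!is.data.frame(cells) || nrow(cells) == 0L)
    stop("empty correlation table")
  num <- vapply(cells, is.numeric, logical(1))
  cells[num] <- lapply(cells[num], signif, digits = 12)
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}
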