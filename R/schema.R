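#' Item schema of the biodiversity-loss questionnaire
#'
#' The survey asks respondents to rate, on a 1 ("minor impact") to 5
#' ("major impact") Likert scale, how strongly each presented driver
#' contributes to the decline of global biodiversity. Five items are the
#' established main drivers; three are distractor ("minor") drivers with
#' negligible global impact; one further distractor, entering nature
#' reserves, was presented to respondents but is excluded from all analysis.
#'
#' @param main_items Character vector of the five main-driver column names.
#' @param minor_items Character vector of the three minor-driver column names.
#' @param dropped_items Character vector of presented-but-excluded column
#'   names. Columns with these names are silently removed on read and never
#'   enter any computation.
#' @return An object of class `item_schema` with elements `main_items`,
#'   `minor_items`, `dropped_items`, `all_items` (main then minor) and
#'   `labels`, a named character vector of display labels.
#' @examples
#' sch <- item_schema()
#' sch$main_items
#' @export
item_schema <- function(main_items = c("climate_change", "exploitation",
                                       "invasive_species", "habitat_loss",
                                       "pollution"),
                        minor_items = c("electromagnetic_pollution",
                                        "factory_vehicle_noise",
                                        "the_internet"),
                        dropped_items = "entering_nature_reserves") {
  main_items <- as.character(main_items)
  minor_items <- as.character(minor_items)
  if (length(main_items) != 5L)
    stop("schema requires exactly 5 main items, got ", length(main_items))
  if (length(minor_items) != 3L)
    stop("schema requires exactly 3 minor items, got ", length(minor_items))
  if (anyDuplicated(c(main_items, minor_items, dropped_items)))
    stop("item names must be distinct")
  labels <- c(climate_change = "climate change",
              exploitation = "exploitation",
              invasive_species = "invasive species",
              habitat_loss = "habitat loss",
              pollution = "pollution",
              electromagnetic_pollution = "electromagnetic pollution",
              factory_vehicle_noise = "factory and vehicle noise",
              the_internet = "the internet",
              entering_nature_reserves = "entering nature reserves")
  structure(list(main_items = main_items,
                 minor_items = minor_items,
                 dropped_items = as.character(dropped_items),
                 all_items = c(main_items, minor_items),
                 labels = labels),
            class = "item_schema")
}

#' @export
print.item_schema <- function(x, ...) {
  cat("Questionnaire item schema\n")
  cat("  main drivers: ", paste(x$main_items, collapse = ", "), "\n")
  cat("  minor drivers:", paste(x$minor_items, collapse = ", "), "\n")
  cat("  dropped:      ", paste(x$dropped_items, collapse = ", "), "\n")
  invisible(x)
}

# Internal: validate an item matrix (n x 8, values in 1..5 or NA).
validate_items <- function(items, schema, where = "items") {
  if (!is.matrix(items)) items <- as.matrix(items)
  if (ncol(items) != length(schema$all_items))
    stop(where, ": expected ", length(schema$all_items), " item columns, got ",
         ncol(items))
  bad <- which(!is.na(items) & (items < 1 | items > 5))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(items)) + 1
    j <- ((bad[1] - 1) %/% nrow(items)) + 1
    stop(where, ": value ", items[bad[1]], " outside 1..5 at row ", i,
         ", column '", schema$all_items[j], "'")
  }
  invisible(items)
}

#' Construct a response matrix
#'
#' A response matrix couples a numeric item matrix (one row per respondent,
#' one column per analysed item, values in 1..5 or `NA` for item non-response)
#' with the country code of each respondent and the item schema.
#'
#' @param items Numeric matrix or data frame, `n x 8`, columns ordered as
#'   `schema$all_items`; values in 1..5 or `NA`.
#' @param country Character vector of length `n`; codes are upper-cased.
#' @param schema An [item_schema()].
#' @return An object of class `response_matrix` with elements `items`
#'   (numeric matrix with item column names), `country`, `schema`.
#' @export
response_matrix <- function(items, country, schema = item_schema()) {
  items <- as.matrix(items)
  storage.mode(items) <- "double"
  country <- toupper(as.character(country))
  if (nrow(items) != length(country))
    stop("items has ", nrow(items), " rows but country has length ",
         length(country))
  if (any(!nzchar(country) | is.na(country)))
    stop("country codes must be non-empty")
  if (!is.null(colnames(items))) {
    if (!setequal(colnames(items), schema$all_items))
      stop("item columns do not match schema: ",
           paste(setdiff(colnames(items), schema$all_items), collapse = ", "))
    items <- items[, schema$all_items, drop = FALSE]
  } else {
    colnames(items) <- schema$all_items
  }
  validate_items(items, schema)
  structure(list(items = items, country = country, schema = schema),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Response matrix: ", nrow(x$items), " respondents, ",
      length(unique(x$country)), " countries, ",
      sum(is.na(x$items)), " missing cells\n", sep = "")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$items)
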