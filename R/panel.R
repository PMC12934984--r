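# County-year panel container and validation.

#' @keywords internal
.panel_columns <- function() {
  c("county_id", "year", "deaths", "population", "drug_court",
    "possession_arrests", "persons_arrests", "property_arrests",
    "crime_rate", "hidta", "democrat_da", "urban", "mua",
    "uninsured_pct", "poverty_pct", "unemployed_pct", "disabled_pct",
    "food_stamps_pct", "public_assistance_pct", "no_hs_diploma_pct",
    "otp_count")
}

.binary_fields <- c("drug_court", "hidta", "democrat_da", "urban", "mua")
.pct_fields <- c("uninsured_pct", "poverty_pct", "unemployed_pct",
                 "disabled_pct", "food_stamps_pct", "public_assistance_pct",
                 "no_hs_diploma_pct")
.count_fields <- c("deaths", "possession_arrests", "persons_arrests",
                   "property_arrests", "otp_count")
# fields that must be observed for every transition year (>= window[1] + 1);
# deaths and population must be observed for the whole window.
.covariate_fields <- setdiff(.panel_columns(),
                             c("county_id", "year", "deaths", "population"))

#' Construct a county-year panel from a data frame
#'
#' Validates the rectangular county-by-year structure and all field
#' invariants of the overdose death panel: integer non-negative death counts
#' \eqn{Y_{it}}, positive populations \eqn{P_{it}}, a binary drug-court
#' exposure \eqn{D_{it}}, arrest counts, and socioeconomic / healthcare
#' covariates. Deaths and population are required for every year of the
#' window; all other covariates are required only from the first transition
#' year onward (the baseline year enters the model through its death count
#' alone), so they may be `NA` in the baseline year.
#'
#' @param df data frame with one row per (county, year); see
#'   [panel_columns()] for the required columns.
#' @param window integer length-2 vector, first and last calendar year.
#'   Defaults to the years present in `df`.
#' @return a `county_panel`: the sorted data frame with attributes
#'   `counties`, `years`, `window`.
#' @export
as_county_panel <- function(df, window = NULL) {
  required <- .panel_columns()
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$county_id <- as.character(df$county_id)
  df$year <- as.integer(df$year)
  if (is.null(window)) window <- range(df$year)
  window <- as.integer(window)
  years <- seq(window[1], window[2])
  df <- df[df$year %in% years, , drop = FALSE]
  counties <- sort(unique(df$county_id))

  # rectangular grid: every county in every year, no duplicates
  key <- paste(df$county_id, df$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (county, year) row: (",
         sub("\r", ", ", dup, fixed = TRUE), ")", call. = FALSE)
  }
  grid <- expand.grid(county_id = counties, year = years,
                      stringsAsFactors = FALSE)
  gkey <- paste(grid$county_id, grid$year, sep = "\r")
  absent <- setdiff(gkey, key)
  if (length(absent) > 0) {
    stop("panel is not a complete county x year grid; first missing cell: (",
         sub("\r", ", ", absent[1], fixed = TRUE), ")", call. = FALSE)
  }

  df <- df[order(df$county_id, df$year), required, drop = FALSE]
  rownames(df) <- NULL
  transition <- df$year >= window[1] + 1L

  .check_cell <- function(bad, what) {
    if (any(bad)) {
      i <- which(bad)[1]
      stop(what, " at (", df$county_id[i], ", ", df$year[i], ")",
           call. = FALSE)
    }
  }
  .check_cell(is.na(df$deaths) | df$deaths < 0 | df$deaths != round(df$deaths),
              "deaths must be a non-negative integer")
  .check_cell(is.na(df$population) | df$population <= 0,
              "population must be positive")
  for (f in .covariate_fields) {
    .check_cell(transition & is.na(df[[f]]),
                paste0("covariate '", f, "' missing for a transition year"))
  }
  for (f in .binary_fields) {
    v <- df[[f]]
    .check_cell(!is.na(v) & !(v %in% c(0, 1)),
                paste0("binary field '", f, "' outside {0,1}"))
  }
  for (f in .pct_fields) {
    v <- df[[f]]
    .check_cell(!is.na(v) & (v < 0 | v > 100),
                paste0("percentage field '", f, "' outside [0,100]"))
  }
  for (f in setdiff(.count_fields, "deaths")) {
    v <- df[[f]]
    .check_cell(!is.na(v) & (v < 0 | v != round(v)),
                paste0("count field '", f, "' must be a non-negative integer"))
  }

  structure(df, class = c("county_panel", "data.frame"),
            counties = counties, years = years, window = window)
}

#' Required panel columns
#' @return character vector of column names in canonical order.
#' @export
panel_columns <- function() .panel_columns()

#' Load a county-year panel from CSV
#'
#' @param path CSV file with a header row and one row per (county, year).
#' @param window optional length-2 year range; rows outside it are dropped and
#'   the grid must be complete inside it.
#' @return a `county_panel` (see [as_county_panel()]).
#' @export
load_panel <- function(path, window = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_county_panel(df, window = window)
}

#' Write a panel to CSV (round-trips through [load_panel()])
#' @param panel a `county_panel`
#' @param path output CSV path
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel)[, .panel_columns()], path,
                   row.names = FALSE)
  invisible(path)
}

#' @export
print.county_panel <- function(x, ...) {
  w <- attr(x, "window")
  cat("county_panel:", length(attr(x, "counties")), "counties x years",
      w[1], "-", w[2], "(", nrow(x), "rows )\n")
  print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' Panel accessors
#' @param panel a `county_panel`
#' @return `panel_counties`: county identifiers; `panel_years`: modeled years.
#' @export
panel_counties <- function(panel) attr(panel, "counties")

#' @rdname panel_counties
#' @export
panel_years <- function(panel) attr(panel, "years")

# deaths / population / exposure as county x year matrices (rows sorted by id)
.panel_matrix <- function(panel, field) {
  counties <- attr(panel, "counties")
  years <- attr(panel, "years")
  m <- matrix(panel[[field]][order(match(panel$county_id, counties),
                                   panel$year)],
              nrow = length(counties), ncol = length(years), byrow = TRUE,
              dimnames = list(counties, years))
  m
}

#' Validate a panel against an adjacency graph
#'
#' Produces a report rather than throwing: fatal findings (`errors`) cover
#' invariant violations and county sets that disagree between panel and graph;
#' non-fatal findings (`warnings`) cover a drug-court exposure that reverts
#' from 1 back to 0 within a county (courts are expected to persist once
#' opened) and a disconnected adjacency graph (the ICAR prior then applies a
#' sum-to-zero constraint per connected component).
#'
#' @param panel a `county_panel`
#' @param graph an `adjacency_graph`
#' @return a `validation_report` with `errors` and `warnings` character
#'   vectors; the panel is usable for fitting iff `errors` is empty.
#' @export
validate_panel <- function(panel, graph) {
  errors <- character(0)
  warnings <- character(0)

  pc <- attr(panel, "counties")
  gc_ <- graph_nodes(graph)
  only_panel <- setdiff(pc, gc_)
  only_graph <- setdiff(gc_, pc)
  if (length(only_panel) > 0) {
    errors <- c(errors, paste0("counties absent from adjacency graph: ",
                               paste(only_panel, collapse = ", ")))
  }
  if (length(only_graph) > 0) {
    errors <- c(errors, paste0("graph nodes absent from panel: ",
                               paste(only_graph, collapse = ", ")))
  }

  d <- .panel_matrix(panel, "drug_court")
  for (i in seq_len(nrow(d))) {
    v <- d[i, !is.na(d[i, ])]
    if (length(v) > 1 && any(diff(v) < 0)) {
      warnings <- c(warnings, paste0("county ", rownames(d)[i],
                                     ": drug_court indicator reverts 1 -> 0"))
    }
  }

  if (length(only_panel) == 0 && length(only_graph) == 0 &&
      n_components(graph) > 1) {
    warnings <- c(warnings, paste0("adjacency graph has ", n_components(graph),
                                   " connected components; ICAR sum-to-zero ",
                                   "applied per component"))
  }

  structure(list(errors = errors, warnings = warnings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation report:", length(x$errors), "error(s),",
      length(x$warnings), "warning(s)\n")
  for (e in x$errors) cat("  error:  ", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Is the panel usable for fitting?
#' @param report a `validation_report`
#' @export
is_valid <- function(report) length(report$errors) == 0
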