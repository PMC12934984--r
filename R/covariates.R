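# Derived covariates: targeting index + tertile bins, principal-component
# poverty and healthcare-access indices, standardized design matrices.

#' Arrest targeting index
#'
#' Ratio of drug possession arrests (excluding marijuana) to the total number
#' of arrests for crimes against persons or against property; dividing by
#' person/property arrests adjusts for overall police activity. Undefined
#' when the denominator is zero: such county-years get `NA` with a warning
#' and are excluded from tertile fitting.
#'
#' @param possession,persons,property non-negative arrest counts (vectorized).
#' @return numeric ratio(s); `NA` where `persons + property == 0`.
#' @export
targeting_index <- function(possession, persons, property) {
  if (any(c(possession, persons, property) < 0, na.rm = TRUE)) {
    stop("arrest counts must be non-negative", call. = FALSE)
  }
  denom <- persons + property
  out <- ifelse(denom > 0, possession / denom, NA_real_)
  if (any(denom == 0, na.rm = TRUE)) {
    warning(sum(denom == 0, na.rm = TRUE),
            " county-year(s) with zero person/property arrests: ",
            "targeting index undefined (NA)", call. = FALSE)
  }
  out
}

#' Fit tertile bins for the targeting index
#'
#' Cutoffs are the 1/3 and 2/3 empirical quantiles of the pooled county-year
#' values (type-1 / empirical-CDF quantiles by default). Classification rule:
#' strictly below the lower cutoff is `low`, strictly above the upper cutoff
#' is `high`, everything else (including the cutoffs themselves) is `middle`,
#' the reference bin.
#'
#' @param values numeric vector of pooled targeting-index values; `NA`s are
#'   dropped.
#' @param type quantile type passed to [stats::quantile()] (default 1).
#' @return a `tertile_bins` object with `lower_cutoff`, `upper_cutoff`.
#' @export
fit_tertiles <- function(values, type = 1) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    stop("need at least 3 non-missing values to fit tertiles", call. = FALSE)
  }
  q <- unname(stats::quantile(values, probs = c(1 / 3, 2 / 3), type = type))
  structure(list(lower_cutoff = q[1], upper_cutoff = q[2],
                 labels = c("low", "middle", "high"), quantile_type = type),
            class = "tertile_bins")
}

#' @export
print.tertile_bins <- function(x, ...) {
  cat(sprintf("tertile_bins: low < %.4g <= middle <= %.4g < high\n",
              x$lower_cutoff, x$upper_cutoff))
  invisible(x)
}

#' Classify values into tertile bins
#' @param bins a `tertile_bins`
#' @param values numeric vector
#' @return factor with levels low/middle/high (`NA` propagates).
#' @export
classify_tertiles <- function(bins, values) {
  out <- ifelse(is.na(values), NA_character_,
                ifelse(values < bins$lower_cutoff, "low",
                       ifelse(values > bins$upper_cutoff, "high", "middle")))
  factor(out, levels = bins$labels)
}

.transition_rows <- function(panel) {
  panel$year >= attr(panel, "window")[1] + 1L
}

#' Fit a first-principal-component index
#'
#' Standardizes the named variables over the pooled transition-year
#' county-years (the index mixes percentages, binary flags and counts, so
#' the decomposition is on the correlation scale), then takes the leading
#' eigenvector of the correlation structure as a unit-norm loading vector.
#' The sign is anchored: the loading of `orientation_anchor` is forced
#' positive, so that higher index values correspond to worse conditions.
#'
#' @param panel a `county_panel`
#' @param variable_names at least two panel columns.
#' @param orientation_anchor one of `variable_names`.
#' @return an `index_model` with `variable_names`, `weights` (unit norm),
#'   `centers`, `scales`, `orientation_anchor`, `explained_variance`.
#' @export
fit_principal_index <- function(panel, variable_names, orientation_anchor) {
  if (length(variable_names) < 2) {
    stop("need at least two variables for a principal-component index",
         call. = FALSE)
  }
  if (!orientation_anchor %in% variable_names) {
    stop("orientation_anchor must be one of the index variables",
         call. = FALSE)
  }
  rows <- .transition_rows(panel)
  X <- as.matrix(as.data.frame(panel)[rows, variable_names, drop = FALSE])
  centers <- colMeans(X)
  scales <- apply(X, 2, stats::sd)
  zero <- scales <= .Machine$double.eps
  if (any(zero)) {
    stop("zero-variance index variable: ",
         paste(variable_names[zero], collapse = ", "), call. = FALSE)
  }
  Z <- scale(X, center = centers, scale = scales)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  w <- pc$rotation[, 1]
  if (w[orientation_anchor] < 0) w <- -w
  structure(list(variable_names = variable_names,
                 weights = w,
                 centers = centers,
                 scales = scales,
                 orientation_anchor = orientation_anchor,
                 explained_variance = pc$sdev[1]^2 / sum(pc$sdev^2)),
            class = "index_model")
}

#' @export
print.index_model <- function(x, ...) {
  cat("index_model (first principal component), anchor:",
      x$orientation_anchor, "\n")
  print(round(x$weights, 4))
  cat(sprintf("explained variance share: %.3f\n", x$explained_variance))
  invisible(x)
}

#' Score an index on a panel
#'
#' Projects the stored-standardization of each county-year onto the loading
#' vector: `score = weights . (x - centers) / scales`. Rows with a missing
#' index variable (e.g. the baseline year) score `NA`.
#'
#' @param model an `index_model`
#' @param panel a `county_panel`
#' @return numeric vector aligned with the panel rows.
#' @export
score_index <- function(model, panel) {
  missing_vars <- setdiff(model$variable_names, names(panel))
  if (length(missing_vars) > 0) {
    stop("panel lacks index variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(as.data.frame(panel)[, model$variable_names, drop = FALSE])
  Z <- sweep(sweep(X, 2, model$centers), 2, model$scales, "/")
  drop(Z %*% model$weights)
}

.poverty_vars <- c("poverty_pct", "unemployed_pct", "disabled_pct",
                   "food_stamps_pct", "no_hs_diploma_pct")
.healthcare_vars <- c("uninsured_pct", "mua", "otp_count")

#' Fit all covariate transformers on a panel
#'
#' Fits, pooled over the transition-year county-years: the targeting-index
#' tertile bins, the poverty index (percent in poverty, unemployed, disabled,
#' on food stamps, without a HS diploma; anchored on `poverty_pct`), the
#' healthcare-access index (percent uninsured, medically-underserved flag,
#' opioid treatment provider count; anchored on `uninsured_pct`), and the
#' pooled mean/sd standardization constants for the continuous design columns
#' (crime rate and the two indices).
#'
#' @param panel a validated `county_panel`
#' @param quantile_type tertile quantile rule (default type 1).
#' @return a `covariate_transformers` object, serializable with
#'   [write_transformers()].
#' @export
fit_transformers <- function(panel, quantile_type = 1) {
  rows <- .transition_rows(panel)
  ti <- targeting_index(panel$possession_arrests[rows],
                        panel$persons_arrests[rows],
                        panel$property_arrests[rows])
  bins <- fit_tertiles(ti, type = quantile_type)
  poverty <- fit_principal_index(panel, .poverty_vars, "poverty_pct")
  healthcare <- fit_principal_index(panel, .healthcare_vars, "uninsured_pct")

  pov_scores <- score_index(poverty, panel)[rows]
  hc_scores <- score_index(healthcare, panel)[rows]
  std <- list(
    crime_rate = list(center = mean(panel$crime_rate[rows]),
                      scale = stats::sd(panel$crime_rate[rows])),
    poverty_index = list(center = mean(pov_scores),
                         scale = stats::sd(pov_scores)),
    healthcare_index = list(center = mean(hc_scores),
                            scale = stats::sd(hc_scores)))
  for (nm in names(std)) {
    if (std[[nm]]$scale <= .Machine$double.eps) {
      stop("zero-variance continuous covariate: ", nm, call. = FALSE)
    }
  }
  structure(list(tertiles = bins, poverty = poverty, healthcare = healthcare,
                 standardization = std),
            class = "covariate_transformers")
}

#' @export
print.covariate_transformers <- function(x, ...) {
  cat("covariate_transformers\n")
  print(x$tertiles)
  cat(sprintf("  poverty index EV share %.3f; healthcare index EV share %.3f\n",
              x$poverty$explained_variance, x$healthcare$explained_variance))
  invisible(x)
}

#' Design-matrix covariate names
#' @return character vector of the main-effect column names, in order.
#' @export
main_effect_names <- function() {
  c("low_targeting", "high_targeting", "crime_rate", "hidta",
    "democrat_da", "urban", "poverty_index", "healthcare_index")
}

#' Build design matrices for the transition years
#'
#' One row per (county, transition year), transition years being every
#' modeled year after the baseline. The main-effect block holds the
#' low/high-targeting dummies (middle tertile is the reference), the
#' standardized crime rate, the binary HIDTA / Democrat-DA / urban flags,
#' and the standardized poverty and healthcare indices. The exposure vector
#' is the drug-court indicator \eqn{D_{it}}. When the model spec requests
#' interactions, the interaction block is the elementwise product of the
#' exposure with every main-effect column.
#'
#' @param panel a validated `county_panel`
#' @param graph the `adjacency_graph` (county sets must agree)
#' @param spec a [model_spec()]
#' @param transformers fitted [fit_transformers()] output; fitted on `panel`
#'   if `NULL`. Pass the training-time transformers when scoring new data.
#' @return a `design_matrices` object: `X` (main effects), `exposure`,
#'   `Z` (interactions or `NULL`), `county`, `year` row indices, plus the
#'   transformers used.
#' @export
build_design <- function(panel, graph, spec, transformers = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!setequal(attr(panel, "counties"), graph_nodes(graph))) {
    stop("panel and adjacency graph disagree on the county set",
         call. = FALSE)
  }
  if (is.null(transformers)) transformers <- fit_transformers(panel)
  rows <- which(.transition_rows(panel))
  df <- as.data.frame(panel)[rows, , drop = FALSE]

  ti <- suppressWarnings(
    targeting_index(df$possession_arrests, df$persons_arrests,
                    df$property_arrests))
  if (any(is.na(ti))) {
    i <- which(is.na(ti))[1]
    stop("targeting index undefined (zero person/property arrests) at (",
         df$county_id[i], ", ", df$year[i], ")", call. = FALSE)
  }
  bin <- classify_tertiles(transformers$tertiles, ti)

  std <- transformers$standardization
  stdz <- function(v, nm) (v - std[[nm]]$center) / std[[nm]]$scale
  X <- cbind(
    low_targeting = as.numeric(bin == "low"),
    high_targeting = as.numeric(bin == "high"),
    crime_rate = stdz(df$crime_rate, "crime_rate"),
    hidta = df$hidta,
    democrat_da = df$democrat_da,
    urban = df$urban,
    poverty_index = stdz(score_index(transformers$poverty, panel)[rows],
                         "poverty_index"),
    healthcare_index = stdz(score_index(transformers$healthcare, panel)[rows],
                            "healthcare_index"))
  exposure <- df$drug_court
  Z <- NULL
  if (spec$include_interactions) {
    Z <- X * exposure
    colnames(Z) <- paste0("drug_court:", colnames(X))
  }
  structure(list(X = X, exposure = exposure, Z = Z,
                 county = df$county_id, year = df$year,
                 counties = attr(panel, "counties"),
                 transition_years = sort(unique(df$year)),
                 transformers = transformers,
                 include_interactions = spec$include_interactions),
            class = "design_matrices")
}

#' @export
print.design_matrices <- function(x, ...) {
  cat("design_matrices:", nrow(x$X), "county-transition-years,",
      ncol(x$X), "main effects,",
      if (is.null(x$Z)) "no interactions" else
        paste(ncol(x$Z), "interactions"), "\n")
  invisible(x)
}

# --- transformer serialization (JSON sidecar) -------------------------------

.index_to_list <- function(m) {
  list(variable_names = m$variable_names,
       weights = as.list(setNames(as.numeric(m$weights), m$variable_names)),
       centers = as.list(setNames(as.numeric(m$centers), m$variable_names)),
       scales = as.list(setNames(as.numeric(m$scales), m$variable_names)),
       orientation_anchor = m$orientation_anchor,
       explained_variance = m$explained_variance)
}

.index_from_list <- function(l) {
  nm <- unlist(l$variable_names)
  structure(list(variable_names = nm,
                 weights = setNames(unlist(l$weights)[nm], nm),
                 centers = setNames(unlist(l$centers)[nm], nm),
                 scales = setNames(unlist(l$scales)[nm], nm),
                 orientation_anchor = l$orientation_anchor,
                 explained_variance = l$explained_variance),
            class = "index_model")
}

#' Serialize / restore fitted transformers
#'
#' Counterfactual runs must reuse the exact training-time transforms, so the
#' fitted tertile cutoffs, PCA loadings and standardization constants
#' round-trip through a JSON sidecar.
#'
#' @param transformers a `covariate_transformers`
#' @param path JSON file path
#' @export
write_transformers <- function(transformers, path) {
  x <- list(
    tertiles = list(lower_cutoff = transformers$tertiles$lower_cutoff,
                    upper_cutoff = transformers$tertiles$upper_cutoff,
                    quantile_type = transformers$tertiles$quantile_type),
    poverty = .index_to_list(transformers$poverty),
    healthcare = .index_to_list(transformers$healthcare),
    standardization = transformers$standardization)
  # digits = I(17): doubles must survive the round trip bit-exactly, the
  # tertile cutoffs are order statistics of the data and sit on boundaries
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_transformers
#' @export
read_transformers <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  bins <- structure(list(lower_cutoff = x$tertiles$lower_cutoff,
                         upper_cutoff = x$tertiles$upper_cutoff,
                         labels = c("low", "middle", "high"),
                         quantile_type = x$tertiles$quantile_type),
                    class = "tertile_bins")
  std <- lapply(x$standardization, function(s)
    list(center = s$center, scale = s$scale))
  structure(list(tertiles = bins,
                 poverty = .index_from_list(x$poverty),
                 healthcare = .index_from_list(x$healthcare),
                 standardization = std),
            class = "covariate_transformers")
}
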