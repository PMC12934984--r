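# Counterfactual scenarios: modify the exposure (and targeting dummies),
# propagate the posterior-predictive recursion, and aggregate changes in
# deaths and death rates at county and state level.

.cf_covariates_allowed <- c("low_targeting", "high_targeting")

#' Define a counterfactual scenario
#'
#' Built-in scenarios: `no_courts` (every \eqn{D_{it} = 0}; what would have
#' happened without the existing courts), `universal_courts` (every
#' \eqn{D_{it} = 1}), and `universal_courts_no_high_targeting`
#' (\eqn{D_{it} = 1} and every high-targeting indicator set to 0, i.e.
#' those county-years reassigned to the reference tertile; low-targeting
#' dummies untouched). `custom` takes explicit overrides. Overrides may only
#' touch the exposure and the targeting dummies; interaction columns are
#' rebuilt as exact products downstream.
#'
#' Sign convention (matching "positive = protective effect of courts"):
#' `no_courts` reports counterfactual minus observed; the two adoption
#' scenarios report observed minus counterfactual.
#'
#' @param name scenario name.
#' @param exposure_override scalar 0/1 replacing every \eqn{D_{it}}
#'   (custom only), or `NULL` to leave the exposure alone.
#' @param covariate_override named list, names in
#'   `c("low_targeting", "high_targeting")`, values scalar replacements.
#' @param reporting_mask optional county ids to include in county-level
#'   output; never affects statewide summaries.
#' @param sign `"cf_minus_obs"` or `"obs_minus_cf"`; set automatically for
#'   the built-in scenarios.
#' @return a `scenario` object.
#' @export
scenario <- function(name = c("no_courts", "universal_courts",
                              "universal_courts_no_high_targeting", "custom"),
                     exposure_override = NULL, covariate_override = NULL,
                     reporting_mask = NULL, sign = NULL) {
  name <- match.arg(name)
  if (name == "no_courts") {
    exposure_override <- 0
    sign <- sign %||% "cf_minus_obs"
  } else if (name == "universal_courts") {
    exposure_override <- 1
    sign <- sign %||% "obs_minus_cf"
  } else if (name == "universal_courts_no_high_targeting") {
    exposure_override <- 1
    covariate_override <- list(high_targeting = 0)
    sign <- sign %||% "obs_minus_cf"
  } else {
    sign <- sign %||% "cf_minus_obs"
  }
  if (!is.null(covariate_override)) {
    bad <- setdiff(names(covariate_override), .cf_covariates_allowed)
    if (length(bad) > 0) {
      stop("scenario may not override covariate(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = name, exposure_override = exposure_override,
                 covariate_override = covariate_override,
                 reporting_mask = reporting_mask,
                 sign_convention = match.arg(sign, c("cf_minus_obs",
                                                     "obs_minus_cf"))),
            class = "scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a scenario to design matrices
#'
#' Replaces the exposure and any overridden targeting dummies, then rebuilds
#' the interaction block (if present) as the exact elementwise product of the
#' new exposure with the new main-effect columns. All other columns pass
#' through unchanged; an empty custom scenario returns the design bitwise
#' identical.
#'
#' @param design a `design_matrices`
#' @param scen a [scenario()]
#' @export
apply_scenario <- function(design, scen) {
  stopifnot(inherits(scen, "scenario"))
  out <- design
  if (!is.null(scen$exposure_override)) {
    out$exposure <- rep(as.numeric(scen$exposure_override),
                        length(design$exposure))
  }
  for (nm in names(scen$covariate_override)) {
    out$X[, nm] <- as.numeric(scen$covariate_override[[nm]])
  }
  if (!is.null(design$Z)) {
    out$Z <- out$X * out$exposure
    colnames(out$Z) <- colnames(design$Z)
  }
  out
}

#' Posterior-predictive expected death counts
#'
#' For each posterior draw, propagates the log-rate recursion from each
#' county's baseline \eqn{\alpha_i} through the (possibly scenario-modified)
#' transition years and forms \eqn{P_{it}\,\lambda_{it}}. The
#' posterior-predictive mean of a Poisson equals the posterior mean of its
#' mean, so no count sampling is needed for point estimates; per-draw values
#' are retained for interval computation.
#'
#' @param samples a `posterior_samples`
#' @param panel the observed `county_panel` (for populations)
#' @param design observed or scenario-modified `design_matrices`
#' @return a `predicted_counts` object: `mean` (county x year matrix over
#'   all modeled years) and `draws` (draws x county x year array).
#' @export
posterior_mean_counts <- function(samples, panel, design) {
  counties <- design$counties
  if (!setequal(counties, attr(panel, "counties")) ||
      !setequal(counties, samples$counties)) {
    stop("county sets of samples, panel and design do not match",
         call. = FALSE)
  }
  tyears <- design$transition_years
  years <- c(min(tyears) - 1L, tyears)
  n <- length(counties); T_ <- length(years)
  m <- draws_matrix(samples)
  S <- nrow(m)

  alpha <- m[, paste0("alpha[", counties, "]"), drop = FALSE]
  phi <- m[, paste0("phi[", counties, "]"), drop = FALSE]
  beta <- m[, paste0("beta[", colnames(design$X), "]"), drop = FALSE]
  beta0 <- m[, "beta0"]
  delta <- m[, "delta"]

  # per-draw transition increments, one column per design row
  E <- beta %*% t(design$X) + outer(delta, design$exposure) + beta0
  if (!is.null(design$Z)) {
    gcols <- paste0("gamma[", colnames(design$X), "]")
    if (!all(gcols %in% colnames(m))) {
      stop("design has interactions but samples were fit without them",
           call. = FALSE)
    }
    E <- E + m[, gcols, drop = FALSE] %*% t(design$Z)
  }
  ri <- match(design$county, counties)
  E <- E + phi[, ri, drop = FALSE]

  P <- .panel_matrix(panel, "population")[counties, as.character(years)]
  cf <- array(NA_real_, dim = c(S, n, T_),
              dimnames = list(NULL, counties, years))
  for (i in seq_len(n)) {
    cols <- which(ri == i)
    cols <- cols[order(design$year[cols])]
    lr <- alpha[, i] + cbind(0, t(apply(E[, cols, drop = FALSE], 1, cumsum)))
    cf[, i, ] <- exp(lr) * rep(P[i, ], each = S)
  }
  mean_mat <- apply(cf, c(2, 3), mean)
  structure(list(mean = mean_mat, draws = cf, counties = counties,
                 years = years, transition_years = tyears),
            class = "predicted_counts")
}

#' @export
print.predicted_counts <- function(x, ...) {
  cat("predicted_counts:", dim(x$draws)[1], "draws x",
      length(x$counties), "counties x", length(x$years), "years\n")
  invisible(x)
}

#' Aggregate counterfactual changes in deaths and death rates
#'
#' Per draw and county, over the transition years: the change in counts is
#' the signed sum of yearly differences between counterfactual and reference
#' counts; the change in rate divides each yearly difference by that year's
#' population before averaging over years (reported per 10,000 persons).
#' Statewide, the count change is the sum of county changes and the rate
#' change is the average over all counties, per draw; point estimates are
#' posterior means (so the aggregation identities hold exactly) and 95%
#' equal-tailed intervals are order-statistic quantiles over draws.
#'
#' The default reference is the observed death counts \eqn{Y_{it}}. Passing
#' another `predicted_counts` (e.g. the fit under the unmodified design)
#' compares predicted to predicted per draw, which yields exact zeros for an
#' identity scenario.
#'
#' @param cf_counts `predicted_counts` under the scenario
#' @param panel the observed `county_panel`
#' @param scen the [scenario()] (provides the sign convention and mask)
#' @param reference `"observed"` or a `predicted_counts` object
#' @return a `cf_summary`: `per_county` data.frame (masked by the scenario's
#'   `reporting_mask` if any), `statewide` list with point estimates and CIs,
#'   `sign_convention`.
#' @export
summarize_changes <- function(cf_counts, panel, scen, reference = "observed") {
  stopifnot(inherits(cf_counts, "predicted_counts"), inherits(scen, "scenario"))
  counties <- cf_counts$counties
  tyears <- as.character(cf_counts$transition_years)
  S <- dim(cf_counts$draws)[1]

  P <- .panel_matrix(panel, "population")[counties, tyears, drop = FALSE]
  if (any(is.na(P))) stop("population missing for a modeled year",
                          call. = FALSE)
  cf <- cf_counts$draws[, , tyears, drop = FALSE]
  if (identical(reference, "observed")) {
    Yt <- .panel_matrix(panel, "deaths")[counties, tyears, drop = FALSE]
    ref <- aperm(array(Yt, dim = c(dim(Yt), S)), c(3, 1, 2))
  } else if (inherits(reference, "predicted_counts")) {
    if (dim(reference$draws)[1] != S) {
      stop("reference draws do not align with counterfactual draws",
           call. = FALSE)
    }
    ref <- reference$draws[, counties, tyears, drop = FALSE]
  } else {
    stop("reference must be \"observed\" or a predicted_counts object",
         call. = FALSE)
  }

  sgn <- if (scen$sign_convention == "cf_minus_obs") 1 else -1
  diff <- sgn * (cf - ref)                        # draws x county x year
  count_change <- apply(diff, c(1, 2), sum)       # draws x county
  rate_draws <- sweep(diff, c(2, 3), P, "/")
  rate_change <- apply(rate_draws, c(1, 2), mean) * 1e4

  state_count <- rowSums(count_change)
  state_rate <- rowMeans(rate_change)

  per_county <- data.frame(
    county_id = counties,
    count_change = colMeans(count_change),
    count_ci_lower = apply(count_change, 2, function(x) .ci_quantiles(x)[1]),
    count_ci_upper = apply(count_change, 2, function(x) .ci_quantiles(x)[3]),
    rate_change_per_10k = colMeans(rate_change),
    rate_ci_lower = apply(rate_change, 2, function(x) .ci_quantiles(x)[1]),
    rate_ci_upper = apply(rate_change, 2, function(x) .ci_quantiles(x)[3]),
    stringsAsFactors = FALSE, row.names = NULL)

  statewide <- list(
    count_change = mean(state_count),
    count_ci = .ci_quantiles(state_count)[c(1, 3)],
    rate_change_per_10k = mean(state_rate),
    rate_ci = .ci_quantiles(state_rate)[c(1, 3)])

  shown <- per_county
  if (!is.null(scen$reporting_mask)) {
    shown <- per_county[per_county$county_id %in% scen$reporting_mask, ,
                        drop = FALSE]
  }
  structure(list(scenario = scen$name, per_county = shown,
                 per_county_all = per_county, statewide = statewide,
                 sign_convention = scen$sign_convention,
                 draws = list(state_count = state_count,
                              state_rate = state_rate)),
            class = "cf_summary")
}

#' @export
print.cf_summary <- function(x, ...) {
  cat("counterfactual scenario:", x$scenario,
      "(", x$sign_convention, ")\n")
  cat(sprintf("  statewide count change: %.1f (%.1f, %.1f)\n",
              x$statewide$count_change, x$statewide$count_ci[1],
              x$statewide$count_ci[2]))
  cat(sprintf("  statewide rate change per 10k: %.3f (%.3f, %.3f)\n",
              x$statewide$rate_change_per_10k, x$statewide$rate_ci[1],
              x$statewide$rate_ci[2]))
  invisible(x)
}

#' One-call counterfactual analysis
#'
#' Applies the scenario to the design, computes posterior-predictive counts,
#' and summarizes changes against the observed deaths.
#'
#' @inheritParams posterior_mean_counts
#' @param scen a [scenario()]
#' @param reference passed to [summarize_changes()]
#' @export
counterfactual <- function(samples, panel, design, scen,
                           reference = "observed") {
  cf_design <- apply_scenario(design, scen)
  cf_counts <- posterior_mean_counts(samples, panel, cf_design)
  summarize_changes(cf_counts, panel, scen, reference = reference)
}
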