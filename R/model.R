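# Generative model: Poisson likelihood with an autoregressive log-rate
# recursion, ICAR spatial prior on the county growth effects, and
# independent parameter priors — exposed as pure log-density functions.

#' Model specification
#'
#' The growth model for county \eqn{i} and transition year \eqn{t}:
#' \deqn{\log \lambda_{it} = \log \lambda_{i,t-1} + \beta_0 + x_{it}'\beta +
#'       D_{it}\delta + z_{it}'\gamma + \phi_i}
#' with \eqn{\lambda_{it}} the latent death rate per person, baseline
#' \eqn{\log \lambda_{i,1} = \alpha_i}, and \eqn{Y_{it} \sim
#' \mathrm{Poisson}(P_{it}\lambda_{it})}. Model 1 omits the interaction
#' block \eqn{z_{it} = D_{it} x_{it}} (`include_interactions = FALSE`);
#' Model 2 includes it. \eqn{\phi} carries an intrinsic CAR prior with
#' precision \eqn{\tau} and a per-component sum-to-zero constraint.
#'
#' Priors: \eqn{\alpha_i \sim N(a_0, s_0^2)} (log deaths-per-person scale);
#' \eqn{\beta_0, \beta, \delta, \gamma \sim N(0, c^2)} on the
#' log-rate-ratio scale; \eqn{\tau \sim \mathrm{Gamma}(shape, rate)}.
#'
#' @param include_interactions logical; `TRUE` for Model 2.
#' @param main_effect_names_ covariate names of the main-effect block.
#' @param prior_coef_scale sd `c` of the coefficient priors (default 10).
#' @param prior_baseline_location,prior_baseline_scale `a0`, `s0` of the
#'   baseline log-rate prior (defaults -8.5, 3: weakly informative around
#'   ~2 deaths per 10,000 person-years).
#' @param prior_tau_shape,prior_tau_rate Gamma prior on the ICAR precision
#'   (defaults 1, 0.01).
#' @return a `model_spec`.
#' @export
model_spec <- function(include_interactions = FALSE,
                       main_effect_names_ = main_effect_names(),
                       prior_coef_scale = 10,
                       prior_baseline_location = -8.5,
                       prior_baseline_scale = 3,
                       prior_tau_shape = 1,
                       prior_tau_rate = 0.01) {
  stopifnot(prior_coef_scale > 0, prior_baseline_scale > 0,
            prior_tau_shape > 0, prior_tau_rate > 0)
  interaction_names <- if (include_interactions) {
    paste0("drug_court:", main_effect_names_)
  } else {
    character(0)
  }
  structure(list(include_interactions = isTRUE(include_interactions),
                 main_effect_names = main_effect_names_,
                 interaction_names = interaction_names,
                 prior_coef_scale = prior_coef_scale,
                 prior_baseline_location = prior_baseline_location,
                 prior_baseline_scale = prior_baseline_scale,
                 prior_tau_shape = prior_tau_shape,
                 prior_tau_rate = prior_tau_rate),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", if (x$include_interactions) "Model 2 (interactions)"
      else "Model 1 (main effects)", "\n")
  invisible(x)
}

#' Serialize / restore a model spec as JSON
#' @param spec a `model_spec`; `path` a JSON file path.
#' @export
write_model_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_spec
#' @param path JSON file path
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_spec(include_interactions = x$include_interactions,
             main_effect_names_ = x$main_effect_names,
             prior_coef_scale = x$prior_coef_scale,
             prior_baseline_location = x$prior_baseline_location,
             prior_baseline_scale = x$prior_baseline_scale,
             prior_tau_shape = x$prior_tau_shape,
             prior_tau_rate = x$prior_tau_rate)
}

#' One realization of all model unknowns
#'
#' The public constructor enforces the ParameterState invariants: `tau > 0`
#' and the ICAR sum-to-zero constraint — `phi` is hard-centered within each
#' connected component of the graph, so a violating state cannot be built.
#'
#' @param alpha per-county baseline log rates (named by county or in
#'   `graph_nodes(graph)` order).
#' @param beta0 global drift intercept.
#' @param beta named main-effect coefficients.
#' @param delta drug-court coefficient.
#' @param gamma named interaction coefficients, or `NULL` for Model 1.
#' @param phi per-county spatial growth effects.
#' @param tau ICAR precision (> 0).
#' @param graph the `adjacency_graph` defining components for centering.
#' @return a `parameter_state`.
#' @export
parameter_state <- function(alpha, beta0, beta, delta, gamma = NULL,
                            phi, tau, graph) {
  nodes <- graph_nodes(graph)
  stopifnot(length(alpha) == length(nodes), length(phi) == length(nodes))
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0) {
    stop("tau must be a positive scalar", call. = FALSE)
  }
  alpha <- setNames(as.numeric(alpha), nodes)
  phi <- setNames(.center_phi(as.numeric(phi), graph), nodes)
  structure(list(alpha = alpha, beta0 = as.numeric(beta0),
                 beta = beta, delta = as.numeric(delta), gamma = gamma,
                 phi = phi, tau = tau),
            class = "parameter_state")
}

#' ICAR log kernel
#'
#' The pairwise-difference intrinsic CAR kernel
#' \deqn{-\frac{\tau}{2} \sum_{(i,j) \in E} (\phi_i - \phi_j)^2}
#' up to an additive constant; equal to \eqn{-(\tau/2)\,\phi' (D - W)\,\phi}
#' with \eqn{D} the degree matrix and \eqn{W} the adjacency matrix. Invariant
#' to adding a constant to `phi` within a connected component, hence improper
#' without the sum-to-zero constraint.
#'
#' @param phi numeric vector indexed by `graph_nodes(graph)`.
#' @param graph an `adjacency_graph`.
#' @param tau positive precision.
#' @return log density up to an additive constant.
#' @export
icar_log_kernel <- function(phi, graph, tau) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (length(phi) != length(graph_nodes(graph))) {
    stop("phi must have one entry per graph node", call. = FALSE)
  }
  ei <- .edge_index(graph)
  if (nrow(ei) == 0) return(0)
  d <- phi[ei[, 1]] - phi[ei[, 2]]
  -(tau / 2) * sum(d * d)
}

# county x year matrix of log rates; columns = baseline year + transitions.
# The AR recursion makes log lambda_it = alpha_i + cumulative sum over
# transitions s <= t of (beta0 + x'beta + D delta + z'gamma + phi_i).
.compute_log_rates <- function(state, design) {
  counties <- design$counties
  tyears <- design$transition_years
  years <- c(min(tyears) - 1L, tyears)
  n <- length(counties); T_ <- length(years)

  eta <- design$X %*% state$beta + design$exposure * state$delta + state$beta0
  if (!is.null(design$Z)) {
    if (is.null(state$gamma)) {
      stop("design has interactions but state has no gamma", call. = FALSE)
    }
    eta <- eta + design$Z %*% state$gamma
  }
  eta <- drop(eta) + state$phi[match(design$county, counties)]

  em <- matrix(0, n, T_, dimnames = list(counties, years))
  em[cbind(match(design$county, counties),
           match(design$year, years))] <- eta
  lr <- t(apply(em, 1, cumsum)) + state$alpha[counties]
  dimnames(lr) <- list(counties, years)
  lr
}

#' Log rate for one county-year
#'
#' For the baseline year returns \eqn{\alpha_i}; for transition years the
#' recursion \eqn{\log\lambda_{i,t-1} + \beta_0 + x_{it}'\beta + D_{it}\delta
#' + z_{it}'\gamma + \phi_i}, compounded from the baseline. Units: log deaths
#' per person.
#'
#' @param state a `parameter_state`
#' @param design a `design_matrices`
#' @param county county identifier
#' @param year calendar year within the modeled window
#' @export
log_rate <- function(state, design, county, year) {
  lr <- .compute_log_rates(state, design)
  if (!county %in% rownames(lr)) stop("unknown county: ", county,
                                      call. = FALSE)
  if (!as.character(year) %in% colnames(lr)) {
    stop("year ", year, " outside the modeled window", call. = FALSE)
  }
  lr[county, as.character(year)]
}

#' Poisson log likelihood of the panel
#'
#' Sum over all county-years of the Poisson log pmf of \eqn{Y_{it}} with
#' mean \eqn{P_{it}\exp(\log\lambda_{it})}.
#'
#' @param state a `parameter_state`
#' @param panel a `county_panel`
#' @param design a `design_matrices` built from the panel
#' @export
log_likelihood <- function(state, panel, design) {
  Y <- .panel_matrix(panel, "deaths")
  P <- .panel_matrix(panel, "population")
  if (any(Y < 0) || any(Y != round(Y))) {
    stop("death counts must be non-negative integers", call. = FALSE)
  }
  lr <- .compute_log_rates(state, design)
  yrs <- colnames(lr)
  sum(stats::dpois(Y[rownames(lr), yrs], P[rownames(lr), yrs] * exp(lr),
                   log = TRUE))
}

.log_prior <- function(state, spec) {
  lp <- sum(stats::dnorm(state$alpha, spec$prior_baseline_location,
                         spec$prior_baseline_scale, log = TRUE)) +
    stats::dnorm(state$beta0, 0, spec$prior_coef_scale, log = TRUE) +
    sum(stats::dnorm(state$beta, 0, spec$prior_coef_scale, log = TRUE)) +
    stats::dnorm(state$delta, 0, spec$prior_coef_scale, log = TRUE) +
    stats::dgamma(state$tau, shape = spec$prior_tau_shape,
                  rate = spec$prior_tau_rate, log = TRUE)
  if (!is.null(state$gamma)) {
    lp <- lp + sum(stats::dnorm(state$gamma, 0, spec$prior_coef_scale,
                                log = TRUE))
  }
  lp
}

#' Unnormalized log posterior
#'
#' `log_likelihood + icar_log_kernel + log priors`, with the sum-to-zero
#' constraint on `phi` guaranteed by the [parameter_state()] constructor.
#'
#' @inheritParams log_likelihood
#' @param graph the `adjacency_graph`
#' @param spec the `model_spec` holding the prior hyperparameters
#' @export
log_posterior <- function(state, panel, design, graph, spec) {
  log_likelihood(state, panel, design) +
    icar_log_kernel(state$phi, graph, state$tau) +
    .log_prior(state, spec)
}
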