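# Model fitting, convergence diagnostics, and posterior summary tables.

#' MCMC configuration
#'
#' @param chains number of chains (>= 2 for diagnostics; default 4).
#' @param warmup adaptation iterations discarded per chain (default 1000).
#' @param iter kept iterations per chain (default 1000).
#' @param max_leapfrog maximum leapfrog steps per HMC proposal; the actual
#'   path length is jittered in `[max/2, max]`.
#' @param target_accept dual-averaging acceptance target (default 0.8).
#' @param init_step initial step size before adaptation.
#' @export
mcmc_config <- function(chains = 4, warmup = 1000, iter = 1000,
                        max_leapfrog = 16, target_accept = 0.8,
                        init_step = 0.2) {
  stopifnot(chains >= 1, warmup >= 50, iter >= 1)
  structure(list(chains = chains, warmup = warmup, iter = iter,
                 max_leapfrog = max_leapfrog, target_accept = target_accept,
                 init_step = init_step),
            class = "mcmc_config")
}

#' Fit the Poisson autoregressive spatial model by MCMC
#'
#' Samples the joint posterior of the baseline log rates, drift, covariate
#' and drug-court coefficients, interaction coefficients (Model 2), ICAR
#' spatial effects, and the ICAR precision, by Hamiltonian Monte Carlo with a
#' conjugate Gibbs step for the precision. The spatial effects are sampled in
#' the Laplacian eigenbasis with the null space removed, so the per-component
#' sum-to-zero constraint holds exactly in every draw. Identical seed, config
#' and data produce identical draws.
#'
#' @param panel a validated `county_panel`
#' @param graph the `adjacency_graph`
#' @param design [build_design()] output consistent with `spec`
#' @param spec a [model_spec()]
#' @param mcmc an [mcmc_config()]
#' @param seed integer RNG seed
#' @return a `posterior_samples` object: per-chain draw matrices with named
#'   columns (`alpha[county]`, `beta0`, `beta[...]`, `delta`, `gamma[...]`,
#'   `phi[county]`, `tau`, `lp__`), plus sampler metadata.
#' @export
fit_model <- function(panel, graph, design, spec, mcmc = mcmc_config(),
                      seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), inherits(mcmc, "mcmc_config"))
  if (spec$include_interactions && is.null(design$Z)) {
    stop("spec requests interactions but design has no interaction block",
         call. = FALSE)
  }
  if (!spec$include_interactions && !is.null(design$Z)) {
    stop("design has an interaction block but spec is Model 1", call. = FALSE)
  }
  basis <- .icar_basis(graph)
  lin <- .linearize(panel, design, spec, basis)

  # initialize baselines at the empirical baseline log rate, then find the
  # MAP: its Hessian Cholesky preconditions every chain
  Y1 <- .panel_matrix(panel, "deaths")[lin$counties, 1]
  P1 <- .panel_matrix(panel, "population")[lin$counties, 1]
  init0 <- numeric(lin$d)
  init0[lin$idx$alpha] <- log((Y1 + 0.5) / P1)
  laplace <- .laplace_mode(lin, spec, init0)

  chains <- vector("list", mcmc$chains)
  meta <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    chain_seed <- (as.integer(seed) + 104729L * ch) %% 2147483647L
    res <- .run_chain(lin, spec, mcmc, laplace, chain_seed)
    chains[[ch]] <- res$draws
    meta[[ch]] <- res[c("step_size", "n_divergent", "accept_rate")]
  }
  n_div <- sum(vapply(meta, `[[`, 0L, "n_divergent"))
  if (n_div > 0) {
    warning("sampler reported ", n_div, " divergent/rejected trajectories; ",
            "inspect diagnostics()", call. = FALSE)
  }
  structure(list(chains = chains, seed = as.integer(seed), spec = spec,
                 mcmc = mcmc, counties = lin$counties,
                 transition_years = design$transition_years,
                 chain_meta = meta),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("posterior_samples:", length(x$chains), "chains x",
      nrow(x$chains[[1]]), "draws,", ncol(x$chains[[1]]),
      "quantities; mean acceptance",
      sprintf("%.2f", mean(vapply(x$chain_meta, `[[`, 0, "accept_rate"))),
      "\n")
  invisible(x)
}

#' Pooled draw matrix (chains stacked)
#' @param samples a `posterior_samples`
#' @param pars optional column subset
#' @export
draws_matrix <- function(samples, pars = NULL) {
  m <- do.call(rbind, samples$chains)
  if (!is.null(pars)) {
    missing_ <- setdiff(pars, colnames(m))
    if (length(missing_) > 0) stop("unknown parameter(s): ",
                                   paste(missing_, collapse = ", "),
                                   call. = FALSE)
    m <- m[, pars, drop = FALSE]
  }
  m
}

# user-facing term -> draw column
.term_column <- function(samples, term) {
  cols <- colnames(samples$chains[[1]])
  cand <- if (term == "drug_court") "delta"
          else if (grepl("^drug_court:", term)) {
            paste0("gamma[", sub("^drug_court:", "", term), "]")
          } else paste0("beta[", term, "]")
  if (cand %in% cols) return(cand)
  if (term %in% cols) return(term)
  stop("unknown term: ", term, call. = FALSE)
}

# Order-statistic (type-1) quantiles so that monotone transforms commute
# with the interval exactly.
.ci_quantiles <- function(x, probs = c(0.025, 0.5, 0.975)) {
  unname(stats::quantile(x, probs = probs, type = 1))
}

.summarize_coef <- function(draws, term, estimate = "median") {
  q <- .ci_quantiles(draws)
  est <- if (estimate == "mean") mean(draws) else q[2]
  data.frame(term = term,
             estimate = exp(est),
             ci_lower = exp(q[1]),
             ci_upper = exp(q[3]),
             percent_positive = mean(draws > 0),
             stringsAsFactors = FALSE)
}

#' Rate-ratio summary table
#'
#' One row per term: the exponentiated posterior median (rate ratio scale),
#' the exponentiated 2.5% / 97.5% coefficient quantiles, and the posterior
#' probability that the rate ratio exceeds one (`percent_positive`,
#' fraction of draws with coefficient strictly > 0). Terms are covariate
#' names for main effects, `"drug_court"` for the exposure, and
#' `"drug_court:<covariate>"` for interactions.
#'
#' @param samples a `posterior_samples`
#' @param terms character vector of term names; defaults to the drug-court
#'   term plus all interactions present.
#' @param estimate `"median"` (default, transform-equivariant) or `"mean"`
#'   (exponentiated posterior mean of the coefficient).
#' @return data.frame with columns term, estimate, ci_lower, ci_upper,
#'   percent_positive; attribute `credible` flags terms whose 95% CI
#'   excludes a rate ratio of 1.
#' @export
rate_ratio_table <- function(samples, terms = NULL, estimate = "median") {
  cols <- colnames(samples$chains[[1]])
  if (is.null(terms)) {
    terms <- "drug_court"
    g <- grep("^gamma\\[", cols, value = TRUE)
    terms <- c(terms, paste0("drug_court:", sub("^gamma\\[(.*)\\]$", "\\1", g)))
  }
  m <- draws_matrix(samples)
  out <- do.call(rbind, lapply(terms, function(tm) {
    .summarize_coef(m[, .term_column(samples, tm)], tm, estimate)
  }))
  rownames(out) <- NULL
  attr(out, "credible") <- out$ci_lower > 1 | out$ci_upper < 1
  out
}

#' Posterior summary of a linear combination of coefficients
#'
#' Forms, per draw, the weighted sum of the named coefficients (e.g. the
#' drug-court main effect plus an interaction, giving the combined effect in
#' a subgroup) and summarizes it exactly like [rate_ratio_table()].
#'
#' @param samples a `posterior_samples`
#' @param weights named numeric vector, names being term names.
#' @inheritParams rate_ratio_table
#' @export
linear_combination <- function(samples, weights, estimate = "median") {
  stopifnot(length(weights) > 0, !is.null(names(weights)))
  m <- draws_matrix(samples)
  comb <- numeric(nrow(m))
  for (tm in names(weights)) {
    comb <- comb + weights[[tm]] * m[, .term_column(samples, tm)]
  }
  label <- paste(sprintf("%g*%s", unname(weights), names(weights)),
                 collapse = " + ")
  out <- .summarize_coef(comb, label, estimate)
  rownames(out) <- NULL
  out
}

# --- convergence diagnostics ------------------------------------------------

.split_chains <- function(chain_list, col) {
  unlist(lapply(chain_list, function(ch) {
    x <- ch[, col]
    h <- floor(length(x) / 2)
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
}

.rhat_basic <- function(seqs) {
  S <- length(seqs[[1]])
  means <- vapply(seqs, mean, 0)
  vars <- vapply(seqs, stats::var, 0)
  W <- mean(vars)
  B <- S * stats::var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((S - 1) / S * W + B / S) / W)
}

.rank_normalize <- function(seqs) {
  x <- unlist(seqs)
  z <- stats::qnorm((rank(x, ties.method = "average") - 3 / 8) /
                    (length(x) + 1 / 4))
  S <- length(seqs[[1]])
  lapply(seq_along(seqs), function(i) z[(i - 1) * S + seq_len(S)])
}

.ess_basic <- function(seqs) {
  S <- length(seqs[[1]])
  M <- length(seqs)
  vars <- vapply(seqs, stats::var, 0)
  W <- mean(vars)
  means <- vapply(seqs, mean, 0)
  varplus <- (S - 1) / S * W + S * stats::var(means) / S
  if (!is.finite(varplus) || varplus <= 0) return(NA_real_)
  max_lag <- S - 1
  acov <- vapply(seqs, function(x) {
    a <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(max_lag + 1))
  rho <- 1 - (W - rowMeans(acov)) / varplus
  # Geyer initial monotone positive sequence
  total <- 0; t <- 1
  prev_pair <- Inf
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    total <- total + pair
    t <- t + 2
  }
  tau_int <- -1 + 2 * total
  max(M * S / max(tau_int, 1 / (M * S)), 0)
}

#' MCMC convergence diagnostics
#'
#' Rank-normalized split-\eqn{\hat R} and bulk effective sample size per
#' scalar parameter, following the modern (rank-based) recipe. Needs at
#' least two chains. A constant (zero-variance) parameter is flagged with
#' `NA` diagnostics rather than an error.
#'
#' @param samples a `posterior_samples`
#' @param pars optional parameter subset (column names).
#' @return data.frame with columns `param`, `rhat`, `ess_bulk`.
#' @export
diagnostics <- function(samples, pars = NULL) {
  if (length(samples$chains) < 2) {
    stop("diagnostics require at least 2 chains", call. = FALSE)
  }
  cols <- colnames(samples$chains[[1]])
  cols <- setdiff(if (is.null(pars)) cols else intersect(pars, cols), "lp__")
  out <- lapply(cols, function(cl) {
    seqs <- .split_chains(samples$chains, cl)
    if (all(vapply(seqs, function(s) stats::var(s) == 0, TRUE))) {
      return(data.frame(param = cl, rhat = NA_real_, ess_bulk = NA_real_,
                        stringsAsFactors = FALSE))
    }
    z <- .rank_normalize(seqs)
    data.frame(param = cl, rhat = .rhat_basic(z), ess_bulk = .ess_basic(z),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
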