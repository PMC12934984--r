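# Internal sampler machinery. The log rate is linear in
# (alpha, beta0, beta, delta, gamma, u) where phi = V u lies in the
# Laplacian eigenbasis with the null space removed, so the posterior is a
# log-concave Poisson GLM with Gaussian priors: gradients and Hessians are
# exact. Each chain preconditions HMC with the Cholesky factor of the
# Laplace (MAP) Hessian, which removes the posterior correlations that
# defeat diagonal mass matrices, and gives tau a conjugate Gibbs update
# between HMC sweeps.

# Linearized model: y ~ Pois(exp(M theta + logP)) with block priors.
.linearize <- function(panel, design, spec, basis) {
  counties <- design$counties
  tyears <- design$transition_years
  years <- c(min(tyears) - 1L, tyears)
  n <- length(counties)
  T_ <- length(years)

  Y <- .panel_matrix(panel, "deaths")[counties, as.character(years)]
  P <- .panel_matrix(panel, "population")[counties, as.character(years)]

  ri <- match(design$county, counties)
  ci <- match(design$year, years)
  cum_col <- function(v) {
    em <- matrix(0, n, T_)
    em[cbind(ri, ci)] <- v
    as.vector(t(apply(em, 1, cumsum)))
  }

  Xall <- cbind(design$X, drug_court = design$exposure)
  if (!is.null(design$Z)) Xall <- cbind(Xall, design$Z)
  Mcov <- vapply(seq_len(ncol(Xall)), function(k) cum_col(Xall[, k]),
                 numeric(n * T_))

  Ialpha <- kronecker(matrix(1, T_, 1), diag(n))
  U <- kronecker(matrix(seq_len(T_) - 1L, ncol = 1), basis$V)

  p <- ncol(design$X)
  p2 <- if (is.null(design$Z)) 0L else ncol(design$Z)
  M <- cbind(Ialpha, rep(seq_len(T_) - 1L, each = n),
             Mcov[, seq_len(p), drop = FALSE],
             Mcov[, p + 1L],
             if (p2 > 0) Mcov[, p + 1L + seq_len(p2), drop = FALSE],
             U)
  idx <- list(alpha = seq_len(n),
              beta0 = n + 1L,
              beta = n + 1L + seq_len(p),
              delta = n + p + 2L,
              gamma = if (p2 > 0) n + p + 2L + seq_len(p2) else integer(0),
              u = n + p + p2 + 2L + seq_len(basis$rank))
  d <- n + p + p2 + 2L + basis$rank

  prior_mean <- numeric(d)
  prior_mean[idx$alpha] <- spec$prior_baseline_location
  prior_prec <- numeric(d)
  prior_prec[idx$alpha] <- 1 / spec$prior_baseline_scale^2
  fixed <- c(idx$beta0, idx$beta, idx$delta, idx$gamma)
  prior_prec[fixed] <- 1 / spec$prior_coef_scale^2
  # u-block precision is tau * lambda, filled in per evaluation

  names_ <- c(paste0("alpha[", counties, "]"), "beta0",
              paste0("beta[", colnames(design$X), "]"), "delta",
              if (p2 > 0) paste0("gamma[", colnames(design$X), "]"),
              paste0("u", seq_len(basis$rank)))

  list(M = M, Mt = t(M), y = as.vector(Y), logP = log(as.vector(P)),
       idx = idx, d = d, prior_mean = prior_mean, prior_prec = prior_prec,
       lgamma_y = sum(lgamma(as.vector(Y) + 1)),
       basis = basis, counties = counties, names = names_)
}

.prior_prec_vec <- function(lin, tau) {
  prec <- lin$prior_prec
  prec[lin$idx$u] <- tau * lin$basis$lambda
  prec
}

# log posterior (up to a constant) and gradient at theta, tau fixed
.lp_grad <- function(theta, lin, tau) {
  eta <- drop(lin$M %*% theta) + lin$logP
  if (any(eta > 690)) return(list(lp = -Inf, grad = NULL))
  mu <- exp(eta)
  dev <- theta - lin$prior_mean
  prec <- .prior_prec_vec(lin, tau)
  lp <- sum(lin$y * eta) - sum(mu) - lin$lgamma_y -
    0.5 * sum(prec * dev * dev)
  grad <- drop(lin$Mt %*% (lin$y - mu)) - prec * dev
  list(lp = lp, grad = grad)
}

# Newton ascent to the MAP with tau updated to its conditional mean;
# returns the mode, tau_hat, and the upper Cholesky factor of the Hessian.
.laplace_mode <- function(lin, spec, init, max_iter = 50, tol = 1e-8) {
  theta <- init
  tau <- 1
  lp_old <- -Inf
  for (iter in seq_len(max_iter)) {
    u <- theta[lin$idx$u]
    tau <- (spec$prior_tau_shape + lin$basis$rank / 2) /
      (spec$prior_tau_rate + 0.5 * sum(lin$basis$lambda * u * u))
    fg <- .lp_grad(theta, lin, tau)
    eta <- drop(lin$M %*% theta) + lin$logP
    mu <- exp(pmin(eta, 690))
    H <- crossprod(lin$M * mu, lin$M)
    diag(H) <- diag(H) + .prior_prec_vec(lin, tau)
    step <- solve(H, fg$grad)
    # damped Newton: halve until the log posterior improves
    s <- 1
    repeat {
      cand <- theta + s * step
      lp_new <- .lp_grad(cand, lin, tau)$lp
      if (is.finite(lp_new) && lp_new >= fg$lp - 1e-12) break
      s <- s / 2
      if (s < 1e-6) { cand <- theta; lp_new <- fg$lp; break }
    }
    theta <- cand
    if (abs(lp_new - lp_old) < tol * (abs(lp_new) + 1)) break
    lp_old <- lp_new
  }
  eta <- drop(lin$M %*% theta) + lin$logP
  mu <- exp(pmin(eta, 690))
  H <- crossprod(lin$M * mu, lin$M)
  diag(H) <- diag(H) + .prior_prec_vec(lin, tau)
  list(theta = theta, tau = tau, chol_H = chol(H))
}

# One chain: HMC in the Laplace-preconditioned space theta = mode + A x
# (A = R^{-1}, R the upper Cholesky of the MAP Hessian; x is approximately
# standard normal), dual-averaging step size, Gibbs for tau.
.run_chain <- function(lin, spec, mcmc, laplace, chain_seed) {
  set.seed(chain_seed)
  d <- lin$d
  R <- laplace$chol_H
  mode <- laplace$theta
  to_theta <- function(x) mode + backsolve(R, x)        # A x, A = R^{-1}
  grad_x <- function(g) backsolve(R, g, transpose = TRUE)  # A' g

  x <- stats::rnorm(d, 0, 0.1)
  theta <- to_theta(x)
  tau <- laplace$tau

  warmup <- mcmc$warmup
  iter <- mcmc$iter
  Lmax <- mcmc$max_leapfrog
  target <- mcmc$target_accept

  eps <- mcmc$init_step
  da <- list(mu = log(10 * eps), log_eps_bar = log(eps), H_bar = 0, m = 0)
  gamma_da <- 0.05; t0 <- 10; kappa <- 0.75

  fg <- .lp_grad(theta, lin, tau)
  if (!is.finite(fg$lp)) stop("non-finite log posterior at initialization")
  lp <- fg$lp; gx <- grad_x(fg$grad)

  draws <- matrix(NA_real_, iter, d + 2L)
  n_div <- 0L; acc_sum <- 0; n_prop <- 0

  for (it in seq_len(warmup + iter)) {
    p0 <- stats::rnorm(d)
    L <- sample.int(Lmax, 1)
    # leapfrog in x-space with unit mass
    xp <- x; pp <- p0 + 0.5 * eps * gx
    ok <- TRUE
    for (l in seq_len(L)) {
      xp <- xp + eps * pp
      fgp <- .lp_grad(to_theta(xp), lin, tau)
      if (!is.finite(fgp$lp)) { ok <- FALSE; break }
      gxp <- grad_x(fgp$grad)
      pp <- pp + (if (l < L) eps else 0.5 * eps) * gxp
    }
    if (!ok) {
      alpha_acc <- 0
      if (it > warmup) n_div <- n_div + 1L
    } else {
      H0 <- -lp + 0.5 * sum(p0 * p0)
      H1 <- -fgp$lp + 0.5 * sum(pp * pp)
      alpha_acc <- min(1, exp(H0 - H1))
      if (is.finite(alpha_acc) && stats::runif(1) < alpha_acc) {
        x <- xp; theta <- to_theta(x); lp <- fgp$lp; gx <- gxp
      } else {
        alpha_acc <- if (is.finite(alpha_acc)) alpha_acc else 0
      }
    }
    if (it > warmup) { acc_sum <- acc_sum + alpha_acc; n_prop <- n_prop + 1 }

    # Gibbs update of tau given u (conjugate under the eigenbasis prior)
    u <- theta[lin$idx$u]
    tau <- stats::rgamma(1,
                         shape = spec$prior_tau_shape + lin$basis$rank / 2,
                         rate = spec$prior_tau_rate +
                           0.5 * sum(lin$basis$lambda * u * u))
    fg <- .lp_grad(theta, lin, tau)  # prior term depends on the new tau
    lp <- fg$lp; gx <- grad_x(fg$grad)

    if (it <= warmup) {
      da$m <- da$m + 1
      da$H_bar <- (1 - 1 / (da$m + t0)) * da$H_bar +
        (target - alpha_acc) / (da$m + t0)
      log_eps <- da$mu - sqrt(da$m) / gamma_da * da$H_bar
      w_da <- da$m^(-kappa)
      da$log_eps_bar <- w_da * log_eps + (1 - w_da) * da$log_eps_bar
      eps <- exp(log_eps)
      if (it == warmup) eps <- exp(da$log_eps_bar)
    } else {
      draws[it - warmup, ] <- c(theta, tau, lp)
    }
  }
  colnames(draws) <- c(lin$names, "tau", "lp__")
  # report phi = V u instead of the basis coordinates
  phi_draws <- draws[, lin$idx$u, drop = FALSE] %*% t(lin$basis$V)
  colnames(phi_draws) <- paste0("phi[", lin$counties, "]")
  keep <- setdiff(colnames(draws), lin$names[lin$idx$u])
  out <- cbind(draws[, keep, drop = FALSE], phi_draws)
  list(draws = out, step_size = eps, n_divergent = n_div,
       accept_rate = acc_sum / max(n_prop, 1))
}
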