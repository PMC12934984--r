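# helper: a hand-built design for a single county with controllable columns
one_county_design <- function(years = 2018:2020, exposure = rep(0, length(years)),
                              high_targeting = rep(0, length(years)),
                              interactions = FALSE) {
  X <- matrix(0, length(years), 8,
              dimnames = list(NULL, main_effect_names()))
  X[, "high_targeting"] <- high_targeting
  Z <- if (interactions) {
    z <- X * exposure
    colnames(z) <- paste0("drug_court:", colnames(X))
    z
  }
  structure(list(X = X, exposure = exposure, Z = Z,
                 county = rep("A", length(years)), year = years,
                 counties = "A", transition_years = years,
                 transformers = NULL, include_interactions = interactions),
            class = "design_matrices")
}

one_node_graph <- function() adjacency_graph("A", matrix(character(0), ncol = 2))

one_county_state <- function(design, alpha = log(2e-4), beta0 = 0, delta = 0,
                             gamma_ht = NULL) {
  gamma <- NULL
  if (!is.null(design$Z)) {
    gamma <- setNames(rep(0, 8), main_effect_names())
    if (!is.null(gamma_ht)) gamma["high_targeting"] <- gamma_ht
  }
  parameter_state(alpha = alpha, beta0 = beta0,
                  beta = setNames(rep(0, 8), main_effect_names()),
                  delta = delta, gamma = gamma, phi = 0, tau = 1,
                  graph = one_node_graph())
}

test_that("ICAR kernel matches the Laplacian quadratic form oracle", {
  # trivial anchors
  g <- make_test_graph()
  expect_equal(icar_log_kernel(rep(3.7, 4), g, tau = 2.5), 0)
  g2 <- adjacency_graph(c("A", "B"), rbind(c("A", "B")))
  expect_equal(icar_log_kernel(c(1, -1), g2, tau = 1), -2)
  expect_error(icar_log_kernel(c(1, -1), g2, tau = 0), "tau")

  # dense-matrix oracle on random graphs
  set.seed(31)
  for (rep in 1:10) {
    gr <- random_graph(sample(4:9, 1))
    n <- length(graph_nodes(gr))
    phi <- rnorm(n)
    tau <- rexp(1) + 0.1
    Q <- graph_laplacian(gr)
    expect_equal(icar_log_kernel(phi, gr, tau),
                 -(tau / 2) * drop(t(phi) %*% Q %*% phi),
                 tolerance = 1e-10)
  }
})

test_that("ICAR kernel is invariant to per-component constant shifts", {
  g <- adjacency_graph(c("A", "B", "C", "D"),
                       rbind(c("A", "B"), c("C", "D")))  # two components
  phi <- c(0.3, -0.9, 1.2, 0.4)
  comp <- graph_components(g)
  shifted <- phi + c(5, -2)[comp]
  expect_equal(icar_log_kernel(phi, g, 1.7),
               icar_log_kernel(shifted, g, 1.7), tolerance = 1e-10)
})

test_that("log_rate: identity transition when nothing is active", {
  d <- one_county_design()
  s <- one_county_state(d)
  lrs <- sapply(2017:2020, function(y) log_rate(s, d, "A", y))
  expect_equal(lrs, rep(log(2e-4), 4))
  expect_error(log_rate(s, d, "A", 2030), "window")
  expect_error(log_rate(s, d, "B", 2018), "unknown county")
})

test_that("log_rate: drug court multiplies consecutive-year rates by 0.84", {
  d <- one_county_design(exposure = c(1, 1, 1))
  s <- one_county_state(d, delta = log(0.84))
  r <- exp(log_rate(s, d, "A", 2019) - log_rate(s, d, "A", 2018))
  expect_equal(r, 0.84, tolerance = 1e-12)
  # compounding from the baseline
  expect_equal(exp(log_rate(s, d, "A", 2020) - log_rate(s, d, "A", 2017)),
               0.84^3, tolerance = 1e-12)
})

test_that("log_rate: high-targeting interaction cancels the court benefit", {
  # hand multiplication of the two printed point estimates: 0.84 x 1.21
  d <- one_county_design(exposure = c(1, 1, 1), high_targeting = c(1, 1, 1),
                         interactions = TRUE)
  s <- one_county_state(d, delta = log(0.84), gamma_ht = log(1.21))
  r <- exp(log_rate(s, d, "A", 2019) - log_rate(s, d, "A", 2018))
  expect_equal(r, 0.84 * 1.21, tolerance = 1e-12)
  expect_equal(r, 1.0164, tolerance = 1e-12)
})

test_that("beta0 translation compounds across transition years", {
  panel <- make_test_panel()
  graph <- make_test_graph()
  spec <- model_spec(FALSE)
  design <- build_design(panel, graph, spec)
  mk <- function(b0) {
    set.seed(5)
    parameter_state(alpha = rnorm(4, -8, 0.3), beta0 = b0,
                    beta = rnorm(8, 0, 0.05), delta = -0.1,
                    phi = rnorm(4, 0, 0.1), tau = 2, graph = graph)
  }
  s0 <- mk(0); sc <- mk(0.25)
  for (y in 2018:2023) {
    expect_equal(log_rate(sc, design, "C2", y),
                 log_rate(s0, design, "C2", y) + 0.25 * (y - 2017),
                 tolerance = 1e-10)
  }
  expect_true(all(is.finite(exp(sapply(2017:2023, function(y)
    log_rate(s0, design, "C1", y))))))
})

test_that("log likelihood equals the per-cell Poisson oracle", {
  panel <- make_test_panel()
  graph <- make_test_graph()
  spec <- model_spec(TRUE)
  design <- build_design(panel, graph, spec)
  set.seed(12)
  for (rep in 1:5) {
    state <- parameter_state(alpha = rnorm(4, -8.6, 0.4), beta0 = rnorm(1, 0, 0.1),
                             beta = setNames(rnorm(8, 0, 0.08),
                                             main_effect_names()),
                             delta = rnorm(1, 0, 0.1),
                             gamma = setNames(rnorm(8, 0, 0.08),
                                              main_effect_names()),
                             phi = rnorm(4, 0, 0.2), tau = rexp(1) + 0.5,
                             graph = graph)
    # independent oracle: walk each county's years, accumulating the linear
    # predictor row by row, and sum dpois cell by cell
    total <- 0
    for (ci in panel_counties(panel)) {
      lr <- state$alpha[[ci]]
      rowY <- panel$deaths[panel$county_id == ci]
      rowP <- panel$population[panel$county_id == ci]
      total <- total + dpois(rowY[1], rowP[1] * exp(lr), log = TRUE)
      idx <- which(design$county == ci)
      idx <- idx[order(design$year[idx])]
      for (k in seq_along(idx)) {
        r <- idx[k]
        lr <- lr + state$beta0 + sum(design$X[r, ] * state$beta) +
          design$exposure[r] * state$delta +
          sum(design$Z[r, ] * state$gamma) + state$phi[[ci]]
        total <- total + dpois(rowY[k + 1], rowP[k + 1] * exp(lr), log = TRUE)
      }
    }
    expect_equal(log_likelihood(state, panel, design), total,
                 tolerance = 1e-10)
  }
})

test_that("all-zero deaths give -sum(mu), linear in population", {
  df <- make_test_df()
  df$deaths <- 0L
  panel <- as_county_panel(df)
  graph <- make_test_graph()
  design <- build_design(panel, graph, model_spec(FALSE))
  state <- parameter_state(alpha = rep(-8.5, 4), beta0 = 0.1,
                           beta = setNames(rep(0, 8), main_effect_names()),
                           delta = 0, phi = rep(0, 4), tau = 1, graph = graph)
  ll1 <- log_likelihood(state, panel, design)
  df2 <- df
  df2$population <- df2$population * 2L
  ll2 <- log_likelihood(state, as_county_panel(df2), design)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
})

test_that("log posterior is the sum of its pieces", {
  panel <- make_test_panel()
  graph <- make_test_graph()
  spec <- model_spec(TRUE)
  design <- build_design(panel, graph, spec)
  set.seed(77)
  state <- parameter_state(alpha = rnorm(4, -8.6, 0.4), beta0 = 0.08,
                           beta = setNames(rnorm(8, 0, 0.05),
                                           main_effect_names()),
                           delta = -0.2,
                           gamma = setNames(rnorm(8, 0, 0.05),
                                            main_effect_names()),
                           phi = rnorm(4, 0, 0.3), tau = 3, graph = graph)
  manual <- log_likelihood(state, panel, design) +
    icar_log_kernel(state$phi, graph, state$tau) +
    sum(dnorm(state$alpha, spec$prior_baseline_location,
              spec$prior_baseline_scale, log = TRUE)) +
    dnorm(state$beta0, 0, spec$prior_coef_scale, log = TRUE) +
    sum(dnorm(state$beta, 0, spec$prior_coef_scale, log = TRUE)) +
    dnorm(state$delta, 0, spec$prior_coef_scale, log = TRUE) +
    sum(dnorm(state$gamma, 0, spec$prior_coef_scale, log = TRUE)) +
    dgamma(state$tau, spec$prior_tau_shape, rate = spec$prior_tau_rate,
           log = TRUE)
  expect_equal(log_posterior(state, panel, design, graph, spec), manual,
               tolerance = 1e-10)

  # with very diffuse priors, posterior differences track likelihood + kernel
  flat <- model_spec(TRUE, prior_coef_scale = 1e6,
                     prior_baseline_scale = 1e6)
  state2 <- state
  state2$delta <- state$delta + 0.3
  lhs <- log_posterior(state2, panel, design, graph, flat) -
    log_posterior(state, panel, design, graph, flat)
  rhs <- log_likelihood(state2, panel, design) -
    log_likelihood(state, panel, design)
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("the constructor enforces sum-to-zero phi and positive tau", {
  graph <- make_test_graph()
  s <- parameter_state(alpha = rep(-8, 4), beta0 = 0,
                       beta = setNames(rep(0, 8), main_effect_names()),
                       delta = 0, phi = c(4, 3, 2, 1), tau = 1, graph = graph)
  expect_equal(sum(s$phi), 0, tolerance = 1e-8)
  # per-component centering on a disconnected graph
  g2 <- adjacency_graph(c("C1", "C2", "C3", "C4"),
                        rbind(c("C1", "C2"), c("C3", "C4")))
  s2 <- parameter_state(alpha = rep(-8, 4), beta0 = 0,
                        beta = setNames(rep(0, 8), main_effect_names()),
                        delta = 0, phi = c(9, 1, 7, 3), tau = 1, graph = g2)
  comp <- graph_components(g2)
  for (k in unique(comp)) {
    expect_equal(sum(s2$phi[comp == k]), 0, tolerance = 1e-8)
  }
  expect_error(parameter_state(alpha = rep(-8, 4), beta0 = 0,
                               beta = rep(0, 8), delta = 0,
                               phi = rep(0, 4), tau = -1, graph = graph),
               "tau")
})

test_that("model spec round-trips through JSON", {
  spec <- model_spec(TRUE, prior_coef_scale = 5, prior_tau_rate = 0.02)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_spec(spec, path)
  back <- read_model_spec(path)
  expect_equal(back, spec)
})
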