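test_that("apply_scenario rewrites exposure and rebuilds interactions", {
  s <- shared_sim()
  d <- s$design

  nc <- apply_scenario(d, scenario("no_courts"))
  expect_true(all(nc$exposure == 0))
  expect_true(all(nc$Z == 0))

  uc <- apply_scenario(d, scenario("universal_courts"))
  expect_true(all(uc$exposure == 1))
  expect_identical(unname(uc$Z), unname(uc$X))
  expect_identical(uc$X, d$X)

  un <- apply_scenario(d, scenario("universal_courts_no_high_targeting"))
  expect_true(all(un$exposure == 1))
  expect_true(all(un$X[, "high_targeting"] == 0))
  expect_identical(un$X[, "low_targeting"], d$X[, "low_targeting"])
  expect_identical(unname(un$Z), unname(un$X * un$exposure))

  # identity: custom scenario with no overrides is bitwise identical
  expect_identical(apply_scenario(d, scenario("custom")), d)

  expect_error(scenario("custom",
                        covariate_override = list(poverty_index = 0)),
               "may not override")
})

test_that("posterior_mean_counts matches a naive per-draw loop oracle", {
  s <- shared_sim()
  fit <- shared_fit()
  # thin to a few draws for the brute-force loop
  thin <- fit
  thin$chains <- lapply(fit$chains, function(ch) ch[1:10, , drop = FALSE])
  pmc <- posterior_mean_counts(thin, s$panel, s$design)

  m <- draws_matrix(thin)
  counties <- s$design$counties
  years <- pmc$years
  P <- sapply(years, function(y)
    s$panel$population[s$panel$year == y][match(counties,
      s$panel$county_id[s$panel$year == y])])
  for (si in c(1, 7, 20)) {
    for (ci in c(1, 9, 20)) {
      cid <- counties[ci]
      lr <- m[si, paste0("alpha[", cid, "]")]
      expect_equal(unname(pmc$draws[si, ci, 1]), unname(P[ci, 1] * exp(lr)),
                   tolerance = 1e-10)
      idx <- which(s$design$county == cid)
      idx <- idx[order(s$design$year[idx])]
      for (k in seq_along(idx)) {
        r <- idx[k]
        lr <- lr + m[si, "beta0"] +
          sum(s$design$X[r, ] * m[si, paste0("beta[", colnames(s$design$X),
                                             "]")]) +
          s$design$exposure[r] * m[si, "delta"] +
          sum(s$design$Z[r, ] * m[si, paste0("gamma[", colnames(s$design$X),
                                             "]")]) +
          m[si, paste0("phi[", cid, "]")]
        expect_equal(unname(pmc$draws[si, ci, k + 1]),
                     unname(P[ci, k + 1] * exp(lr)),
                     tolerance = 1e-10)
      }
    }
  }
  # the reported mean is the draw average
  expect_equal(pmc$mean, apply(pmc$draws, c(2, 3), mean), tolerance = 1e-12)
})

test_that("identity scenario changes are exactly zero against the fitted reference", {
  s <- shared_sim()
  fit <- shared_fit()
  base <- posterior_mean_counts(fit, s$panel, s$design)
  ident <- scenario("custom")
  cf <- posterior_mean_counts(fit, s$panel, apply_scenario(s$design, ident))
  summ <- summarize_changes(cf, s$panel, ident, reference = base)
  expect_true(all(summ$per_county_all$count_change == 0))
  expect_true(all(summ$per_county_all$rate_change_per_10k == 0))
  expect_identical(summ$statewide$count_change, 0)
  expect_identical(summ$statewide$rate_change_per_10k, 0)
})

test_that("statewide aggregation identities hold per draw", {
  s <- shared_sim()
  fit <- shared_fit()
  scen <- scenario("no_courts")
  cf <- posterior_mean_counts(fit, s$panel, apply_scenario(s$design, scen))
  summ <- summarize_changes(cf, s$panel, scen)

  # point estimates: statewide = sum / mean of per-county values
  expect_equal(summ$statewide$count_change,
               sum(summ$per_county_all$count_change), tolerance = 1e-9)
  expect_equal(summ$statewide$rate_change_per_10k,
               mean(summ$per_county_all$rate_change_per_10k),
               tolerance = 1e-9)

  # per-draw: recompute the statewide quantities from the raw draws
  tyears <- as.character(cf$transition_years)
  Y <- sapply(cf$transition_years, function(y)
    s$panel$deaths[s$panel$year == y][match(cf$counties,
      s$panel$county_id[s$panel$year == y])])
  P <- sapply(cf$transition_years, function(y)
    s$panel$population[s$panel$year == y][match(cf$counties,
      s$panel$county_id[s$panel$year == y])])
  S <- dim(cf$draws)[1]
  for (si in c(1, S %/% 2, S)) {
    diff <- cf$draws[si, , tyears] - Y
    expect_equal(summ$draws$state_count[si], sum(diff), tolerance = 1e-9)
    expect_equal(summ$draws$state_rate[si], mean(rowMeans(diff / P)) * 1e4,
                 tolerance = 1e-9)
  }
})

test_that("sign conventions orient positive as protective", {
  s <- shared_sim()
  fit <- shared_fit()
  nc <- counterfactual(fit, s$panel, s$design, scenario("no_courts"))
  uc <- counterfactual(fit, s$panel, s$design, scenario("universal_courts"))
  expect_equal(nc$sign_convention, "cf_minus_obs")
  expect_equal(uc$sign_convention, "obs_minus_cf")
})

test_that("monotonicity: protective degenerate posterior, fitted reference", {
  s <- shared_sim()
  fit <- shared_fit()
  # degenerate posterior: delta < 0, all interactions zero, shared otherwise
  degen <- fit
  degen$chains <- lapply(fit$chains, function(ch) {
    ch <- ch[1:5, , drop = FALSE]
    ch[, "delta"] <- -0.3
    ch[, grep("^gamma\\[", colnames(ch))] <- 0
    ch
  })
  base <- posterior_mean_counts(degen, s$panel, s$design)
  scen <- scenario("no_courts")
  cf <- posterior_mean_counts(degen, s$panel, apply_scenario(s$design, scen))
  summ <- summarize_changes(cf, s$panel, scen, reference = base)

  ever_treated <- unique(s$design$county[s$design$exposure == 1])
  never <- setdiff(s$design$counties, ever_treated)
  pc <- summ$per_county_all
  expect_true(all(pc$count_change[pc$county_id %in% never] == 0))
  expect_true(all(pc$count_change[pc$county_id %in% ever_treated] >= 0))
  expect_true(any(pc$count_change[pc$county_id %in% ever_treated] > 0))
})

test_that("reporting_mask filters county output but not statewide numbers", {
  s <- shared_sim()
  fit <- shared_fit()
  scen_all <- scenario("no_courts")
  scen_mask <- scenario("no_courts",
                        reporting_mask = s$design$counties[1:5])
  a <- counterfactual(fit, s$panel, s$design, scen_all)
  b <- counterfactual(fit, s$panel, s$design, scen_mask)
  expect_equal(nrow(b$per_county), 5)
  expect_equal(a$statewide, b$statewide)
  expect_equal(a$per_county_all, b$per_county_all)
})
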