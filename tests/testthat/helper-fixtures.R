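# Fixtures are built in code: a small deterministic 4-county panel for unit
# tests, and a lazily-cached simulated 20-county system with a fitted model,
# shared across test files.

# deterministic 4-county x 7-year panel with variation in every covariate
make_test_df <- function(years = 2017:2023, non_monotone = FALSE) {
  counties <- c("C1", "C2", "C3", "C4")
  pops <- c(C1 = 50000, C2 = 80000, C3 = 120000, C4 = 200000)
  court_start <- c(C1 = 2018, C2 = 2021, C3 = NA, C4 = NA)
  rows <- list()
  for (i in seq_along(counties)) {
    for (t in seq_along(years)) {
      y <- years[t]
      cid <- counties[i]
      dc <- as.integer(!is.na(court_start[cid]) && y >= court_start[cid])
      if (non_monotone && cid == "C1" && y >= 2022) dc <- 0L
      possession <- 40 + 15 * i + 3 * t
      persons <- 120 + 30 * i + 5 * t
      property <- 300 + 40 * i - 4 * t
      rows[[length(rows) + 1L]] <- data.frame(
        county_id = cid, year = y,
        deaths = (i + t) %/% 2 + i,
        population = pops[[cid]],
        drug_court = dc,
        possession_arrests = possession,
        persons_arrests = persons,
        property_arrests = property,
        crime_rate = (possession + persons + property) / pops[[cid]],
        hidta = as.integer(i %in% c(2, 4)),
        democrat_da = as.integer(i %in% c(1, 4)),
        urban = as.integer(i == 4),
        mua = as.integer(i %in% c(1, 3)),
        uninsured_pct = 10 + 1.5 * i + 0.2 * t,
        poverty_pct = 12 + 2 * i + 0.3 * t,
        unemployed_pct = 4 + 0.5 * i + 0.1 * t,
        disabled_pct = 10 + i + 0.15 * t,
        food_stamps_pct = 9 + 1.2 * i + 0.25 * t,
        public_assistance_pct = 1.5 + 0.3 * i + 0.05 * t,
        no_hs_diploma_pct = 11 + 1.1 * i - 0.1 * t,
        otp_count = (i + t) %% 4,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

make_test_panel <- function(...) as_county_panel(make_test_df(...))

# path graph C1-C2-C3-C4
make_test_graph <- function() {
  adjacency_graph(c("C1", "C2", "C3", "C4"),
                  rbind(c("C1", "C2"), c("C2", "C3"), c("C3", "C4")))
}

# a random connected-ish graph for oracle tests
random_graph <- function(n, p = 0.35) {
  nodes <- sprintf("N%02d", seq_len(n))
  edges <- NULL
  for (i in seq_len(n - 1)) {
    edges <- rbind(edges, c(nodes[i], nodes[i + 1]))  # spanning path
    if (i + 2 <= n) {
      for (j in (i + 2):n) {
        if (stats::runif(1) < p) edges <- rbind(edges, c(nodes[i], nodes[j]))
      }
    }
  }
  adjacency_graph(nodes, edges)
}

# hand-built posterior_samples with given per-chain draw matrices
fake_samples <- function(chains, counties = character(0)) {
  structure(list(chains = chains, seed = 1L,
                 spec = model_spec(include_interactions = TRUE),
                 mcmc = NULL, counties = counties,
                 transition_years = integer(0),
                 chain_meta = list()),
            class = "posterior_samples")
}

# lazily cached simulated system + fit, shared across test files
.shared <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.shared$sim)) {
    cfg <- truth_config(grid_shape = c(5, 4))
    panel <- simulate_panel(cfg, seed = 42)
    graph <- attr(panel, "truth")$graph
    spec <- model_spec(include_interactions = TRUE)
    design <- build_design(panel, graph, spec,
                           attr(panel, "truth")$transformers)
    .shared$sim <- list(cfg = cfg, panel = panel, graph = graph,
                        spec = spec, design = design)
  }
  .shared$sim
}

shared_fit <- function() {
  if (is.null(.shared$fit)) {
    s <- shared_sim()
    .shared$fit <- fit_model(s$panel, s$graph, s$design, s$spec,
                             mcmc = mcmc_config(chains = 2, warmup = 300,
                                                iter = 500),
                             seed = 7)
  }
  .shared$fit
}
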