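# Brute-force oracles and shared expensive fixtures for the test suite.

# Independent recursion (scalar, loop-free of package internals) used by
# the grid-search oracle.
oracle_rates <- function(eq, a_vec, b_vec, initial = 1.0) {
  I <- initial
  out <- numeric(4)
  for (j in 1:4) {
    I <- if (eq == 1) I * (1 - a_vec[j] - b_vec[j]) + b_vec[j]
         else I * (1 - a_vec[j]) * (1 - b_vec[j]) + b_vec[j]
    out[j] <- I
  }
  out
}

oracle_nll <- function(cells, rates_by_species) {
  tot <- 0
  for (i in seq_len(nrow(cells))) {
    p <- rates_by_species[[cells$species[i]]][cells$stage_ordinal[i] - 1L]
    p <- min(max(p, 1e-12), 1 - 1e-12)
    tot <- tot - (lchoose(cells$n[i], cells$k[i]) +
                    cells$k[i] * log(p) + (cells$n[i] - cells$k[i]) * log(1 - p))
  }
  tot
}

# exhaustive 1-D grid search for a single shared loss (gain null)
oracle_fit_1par <- function(cells, eq, coarse = 1e-3, fine = 1e-5) {
  nll_at <- function(a) {
    r <- oracle_rates(eq, rep(a, 4), rep(0, 4))
    oracle_nll(cells, list(A = r, B = r, C = r, D = r))
  }
  g <- seq(coarse, 1 - coarse, by = coarse)
  v <- vapply(g, nll_at, numeric(1))
  a0 <- g[which.min(v)]
  g2 <- seq(max(fine, a0 - coarse), min(1 - fine, a0 + coarse), by = fine)
  v2 <- vapply(g2, nll_at, numeric(1))
  list(a = g2[which.min(v2)], nll = min(v2))
}

# exhaustive 2-D grid search for shared loss + shared gain
oracle_fit_2par <- function(cells, eq, coarse = 5e-3, fine = 1e-4) {
  nll_at <- function(a, b) {
    r <- oracle_rates(eq, rep(a, 4), rep(b, 4))
    oracle_nll(cells, list(A = r, B = r, C = r, D = r))
  }
  g <- seq(coarse, 1 - coarse, by = coarse)
  best <- c(NA, NA, Inf)
  for (a in g) for (b in g) {
    v <- nll_at(a, b)
    if (v < best[3]) best <- c(a, b, v)
  }
  ga <- seq(max(fine, best[1] - coarse), min(1 - fine, best[1] + coarse), by = fine)
  gb <- seq(max(fine, best[2] - coarse), min(1 - fine, best[2] + coarse), by = fine)
  for (a in ga) for (b in gb) {
    v <- nll_at(a, b)
    if (v < best[3]) best <- c(a, b, v)
  }
  list(a = best[1], b = best[2], nll = best[3])
}

# build a likelihood cell table directly
make_cells <- function(species, stage_ordinal, n, k) {
  data.frame(species = species, stage_ordinal = stage_ordinal,
             stage = names(caste_stages())[stage_ordinal],
             n = n, k = k, stringsAsFactors = FALSE)
}

# the refined structure of the selected model: species-specific loss,
# single shared gain at the white-soldier stage, all other gains zero
refined_structure <- function(equation = 2) {
  model_spec(equation, "by_species", "by_stage",
             zero_mask = data.frame(kind = "gain", species = NA,
                                    stage = c("larva", "worker", "soldier")))
}

# Shared expensive computations, evaluated once per test run.
.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .test_cache)) {
    assign(name, force(expr), envir = .test_cache)
  }
  get(name, envir = .test_cache)
}

fixture_cells <- function() {
  cached("fixture_cells", pool(table1_fixture(), "by_colony_stage"))
}

grid_fits <- function() {
  cached("grid_fits", {
    lapply(enumerate_model_grid(), fit_model, cells = fixture_cells())
  })
}

grid_selection <- function() {
  cached("grid_selection",
         rank_and_weight(grid_fits(), c_hat = 2.9, n_eff = 47))
}

refined_fit <- function() {
  cached("refined_fit",
         fit_model(refined_structure(), fixture_cells(), compute_se = TRUE))
}

# recovery experiment used by the acceptance criteria: truth spanning the
# fitted loss range, paper-scale gain, 50 colonies/species, n = 200/stage
recovery_run <- function() {
  cached("recovery_run", {
    spec <- refined_structure()
    truth <- parameter_set(loss = c(0.23, 0.45, 0.63, 0.30),
                           gain = c(0, 0, 0.72, 0), spec = spec)
    cfg <- simulation_config(truth, colonies_per_species = 50,
                             per_stage_n = function(s) 200, seed = 20150211)
    recovery_experiment(cfg, replicates = 20,
                        settings = fit_settings(n_starts = 6))
  })
}
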