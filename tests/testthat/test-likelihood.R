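test_that("negative log-likelihood matches the closed-form binomial mass", {
  # one cell, 5 infected of 10, predicted rate 0.5 (global loss 0.5, eq 1)
  spec <- model_spec(1, "global", "null")
  pars <- parameter_set(0.5, 0)
  cells <- make_cells("A", 2L, 10L, 5L)
  expect_equal(negative_log_likelihood(spec, pars, cells),
               -(lchoose(10, 5) + 10 * log(0.5)), tolerance = 1e-10)

  # predictions equal to every empirical rate: saturated likelihood,
  # deviance zero
  spec2 <- model_spec(1, "by_species", "null")
  pars2 <- parameter_set(c(0.7, 0.4, 0.1, 0.9), 0)
  cells2 <- make_cells(c("A", "B"), c(2L, 2L), c(10L, 20L), c(3L, 12L))
  sat <- -sum(lchoose(c(10, 20), c(3, 12)) +
                c(3, 12) * log(c(0.3, 0.6)) + c(7, 8) * log(c(0.7, 0.4)))
  expect_equal(negative_log_likelihood(spec2, pars2, cells2), sat,
               tolerance = 1e-10)

  # structurally-zero prediction with infected observed: large but finite
  dead <- negative_log_likelihood(model_spec(1, "global", "null"),
                                  parameter_set(1, 0),
                                  make_cells("A", 3L, 10L, 4L))
  expect_true(is.finite(dead) && dead > 50)

  # stage-1 cells are excluded from the likelihood by contract
  expect_error(
    negative_log_likelihood(spec, pars, make_cells("A", 1L, 13L, 13L)),
    "stages 2-5")
})

test_that("maximum-likelihood fits agree with exhaustive grid search", {
  cells <- make_cells(c("A", "A"), c(2L, 3L), c(20L, 20L), c(6L, 3L))
  for (eq in 1:2) {
    oracle <- oracle_fit_1par(cells, eq)
    fit <- fit_model(model_spec(eq, "global", "null"), cells)
    expect_true(fit$converged)
    expect_equal(fit$theta, oracle$a, tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(fit$neg_log_lik, oracle$nll, tolerance = 1e-6)
  }

  cells2 <- make_cells(rep("A", 4), 2:5, rep(30L, 4), c(12L, 6L, 14L, 8L))
  for (eq in 1:2) {
    oracle <- oracle_fit_2par(cells2, eq)
    fit <- fit_model(model_spec(eq, "global", "global"), cells2)
    expect_true(fit$converged)
    expect_equal(unname(fit$theta), c(oracle$a, oracle$b), tolerance = 2e-3)
    expect_equal(fit$neg_log_lik, oracle$nll, tolerance = 1e-5)
  }
})

test_that("Hessian standard errors recover the binomial closed form", {
  # one free gain from an uninfected founder: a plain binomial proportion
  spec <- model_spec(1, "null", "global")
  cells <- make_cells("A", 2L, 100L, 50L)
  fit <- fit_model(spec, cells, initial_rate = 0)
  expect_equal(unname(fit$theta), 0.5, tolerance = 1e-5)
  se <- hessian_standard_errors(fit, cells)
  expect_equal(as.vector(se), sqrt(0.5 * 0.5 / 100), tolerance = 1e-3)
  expect_false(any(attr(se, "boundary")))

  # boundary fit (no infections): flagged, profile fallback SE is finite
  cells0 <- make_cells("A", 2L, 50L, 0L)
  fit0 <- fit_model(spec, cells0, initial_rate = 0)
  se0 <- hessian_standard_errors(fit0, cells0)
  expect_true(attr(se0, "boundary")[1])
  expect_true(is.finite(se0[1]) && se0[1] > 0)

  # tied cells share one free parameter and hence one SE
  fit_tied <- fit_model(model_spec(1, "global", "null"),
                        make_cells(c("A", "B"), c(2L, 2L), c(40L, 40L),
                                   c(10L, 14L)))
  expect_length(hessian_standard_errors(fit_tied,
                                        make_cells(c("A", "B"), c(2L, 2L),
                                                   c(40L, 40L), c(10L, 14L))),
                1L)
})

test_that("likelihood is invariant to cell order and aggregation constants", {
  cells <- fixture_cells()
  spec <- refined_structure()
  fit <- fit_model(spec, cells)

  shuffled <- cells[rev(seq_len(nrow(cells))), ]
  fit_sh <- fit_model(spec, shuffled)
  expect_equal(fit_sh$theta, fit$theta, tolerance = 1e-6)
  expect_equal(fit_sh$neg_log_lik, fit$neg_log_lik, tolerance = 1e-8)

  # by-species pooling changes the likelihood only by the binomial
  # coefficients: identical estimates, identical likelihood differences
  pooled <- pool(table1_fixture(), "by_species_stage")
  fit_sp <- fit_model(spec, pooled)
  expect_equal(fit_sp$theta, fit$theta, tolerance = 1e-6)
  alt <- model_spec(2, "by_species", "by_stage")
  d_colony <- fit_model(alt, cells)$neg_log_lik - fit$neg_log_lik
  d_species <- fit_model(alt, pooled)$neg_log_lik - fit_sp$neg_log_lik
  expect_equal(d_colony, d_species, tolerance = 1e-6)
})

test_that("adding free parameters never increases the minimized -lnL", {
  fits <- grid_fits()
  nll <- vapply(fits, function(f) f$neg_log_lik, numeric(1))
  nests <- function(p, q) {  # pattern p nested in q
    (p == q) || (p == "null") || (q == "by_both") ||
      (p == "global" && q %in% c("by_species", "by_stage"))
  }
  specs <- enumerate_model_grid()
  for (i in 1:28) for (j in 1:28) {
    si <- specs[[i]]; sj <- specs[[j]]
    if (si$equation != sj$equation) next
    if (nests(si$loss_pattern, sj$loss_pattern) &&
        nests(si$gain_pattern, sj$gain_pattern)) {
      expect_true(nll[j] <= nll[i] + 1e-4,
                  info = sprintf("model %d vs %d", i, j))
    }
  }
})

test_that("overdispersion estimation follows the stated conventions", {
  fx <- table1_fixture()
  expect_equal(estimate_overdispersion(fx, "fixed")$c_hat, 2.9)
  expect_equal(estimate_overdispersion(fx, "fixed", value = 1.7)$c_hat, 1.7)
  expect_error(estimate_overdispersion(fx, "fixed", value = 0), "positive")

  # clean binomial sampling under a common caste profile keeps the
  # Pearson ratio near 1 (the colony+caste GLZ is then well-specified);
  # colony heterogeneity inflates it well above 1
  shared <- parameter_set(loss = 0.4, gain = c(0, 0, 0.7, 0))
  clean <- simulate_dataset(simulation_config(
    shared, colonies_per_species = 25, per_stage_n = function(s) 100,
    seed = 5))
  c_clean <- estimate_overdispersion(clean, "pearson_full_model")$c_hat
  expect_lt(abs(c_clean - 1), 0.35)

  truth <- parameter_set(loss = c(0.23, 0.45, 0.63, 0.30),
                         gain = c(0, 0, 0.72, 0))
  messy <- simulate_dataset(simulation_config(
    truth, colonies_per_species = 25, per_stage_n = function(s) 100,
    colony_heterogeneity = 0.15, seed = 5))
  expect_gt(estimate_overdispersion(messy, "pearson_full_model")$c_hat, 1.5)
})
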