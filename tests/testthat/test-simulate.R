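sim_truth <- function() {
  parameter_set(loss = c(0.23, 0.45, 0.63, 0.30), gain = c(0, 0, 0.72, 0),
                spec = refined_structure())
}

test_that("the generator is seed-deterministic and respects the recursion", {
  cfg <- simulation_config(sim_truth(), colonies_per_species = 3,
                           per_stage_n = c(10, 15, 5, 12), seed = 31)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)
  expect_setequal(unique(d1$species), c("A", "B", "C", "D"))
  # queens emitted as certainly-infected stage-1 cells
  q <- d1[d1$stage == "queen", ]
  expect_true(all(q$n_tested == 1L & q$n_infected == 1L))

  # law of large numbers: one huge colony tracks the trajectory closely
  big <- simulation_config(sim_truth(), n_species = 1,
                           colonies_per_species = 1,
                           per_stage_n = function(s) 1e5, seed = 8)
  d <- simulate_dataset(big)
  emp <- d$n_infected[d$stage_ordinal %in% 2:5] /
    d$n_tested[d$stage_ordinal %in% 2:5]
  expected <- infection_trajectory(sim_truth(), "A", 2)$rate[2:5]
  expect_true(all(abs(emp - expected) < 0.005))

  # a different seed produces different data
  cfg2 <- cfg; cfg2$seed <- 32L
  expect_false(identical(simulate_dataset(cfg2)$n_infected, d1$n_infected))
})

test_that("pure-loss truth yields monotone declining pooled rates", {
  pure <- parameter_set(loss = c(0.2, 0.35, 0.5, 0.65), gain = 0,
                        spec = model_spec(2, "by_species", "null"))
  cfg <- simulation_config(pure, colonies_per_species = 5,
                           per_stage_n = function(s) 2000, seed = 77)
  cells <- pool(simulate_dataset(cfg), "by_species_stage")
  for (sp in c("A", "B", "C", "D")) {
    r <- cells$k[cells$species == sp] / cells$n[cells$species == sp]
    expect_true(all(diff(r) <= 0.01), info = sp)
  }
})

test_that("the table layout resampler reproduces realistic sparse designs", {
  cfg <- simulation_config(sim_truth(), colonies_per_species = 25,
                           per_stage_n = "table_layout", seed = 13)
  d <- simulate_dataset(cfg)
  n_per_colony <- tapply(d$stage_ordinal %in% 2:5, d$colony, sum)
  # the embedded table has colonies with 3 and with 4 sampled stages
  expect_true(any(n_per_colony < 4) && any(n_per_colony == 4))
  expect_true(all(d$n_infected <= d$n_tested))
})

test_that("recovery reports are complete and unbiased under the null gain", {
  spec <- refined_structure()
  truth0 <- parameter_set(loss = c(0.3, 0.4, 0.5, 0.6), gain = 0, spec = spec)
  cfg <- simulation_config(truth0, colonies_per_species = 20,
                           per_stage_n = function(s) 100, seed = 51)
  one <- recovery_experiment(cfg, replicates = 1)
  expect_equal(nrow(one$per_parameter), spec$K)
  expect_equal(one$n_converged + one$n_failed, 1L)

  rec <- recovery_experiment(cfg, replicates = 5)
  # with no true gain, the fitted white-soldier gain stays near zero
  gain_col <- grep("^b\\(", colnames(rec$estimates))
  expect_lt(stats::median(rec$estimates[, gain_col]), 0.05)
})

test_that("estimation error shrinks with per-stage sample size", {
  spec <- refined_structure()
  truth <- sim_truth()
  rmse_at <- function(n) {
    cfg <- simulation_config(truth, colonies_per_species = 10,
                             per_stage_n = function(s) n, seed = 400 + n)
    rec <- recovery_experiment(cfg, replicates = 4,
                               settings = fit_settings(n_starts = 6))
    mean(rec$per_parameter$rmse)
  }
  r50 <- rmse_at(50)
  r800 <- rmse_at(800)
  expect_lt(r800, r50)
  # square-root scaling predicts a fourfold reduction; allow a loose band
  expect_lt(r800, r50 / 1.8)
})
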