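test_that("the 28-model grid is stable, complete and correctly numbered", {
  grid <- enumerate_model_grid()
  expect_length(grid, 28L)
  expect_equal(vapply(grid, function(s) s$model_id, integer(1)), 1:28)
  expect_equal(vapply(grid, function(s) s$equation, integer(1)),
               rep(1:2, each = 14))

  m27 <- grid[[27]]
  expect_equal(m27$equation, 2L)
  expect_equal(m27$loss_pattern, "by_species")
  expect_equal(m27$gain_pattern, "by_stage")
  m1 <- grid[[1]]
  expect_equal(c(m1$equation, m1$loss_pattern, m1$gain_pattern),
               c(1L, "global", "global"))

  # golden structure: label and free-parameter count per model
  labels <- vapply(grid, function(s) s$label, character(1))
  Ks <- vapply(grid, n_free_params, integer(1))
  patt <- c("a(.,.)/b(.,.)", "a(s,.)/b(.,.)", "a(s,.)/b(s,.)",
            "a(.,.)/b(s,.)", "a(.,c)/b(.,.)", "a(.,c)/b(.,c)",
            "a(.,.)/b(.,c)", "a(s,c)/b(s,c)", "a(.,c)/b(s,c)",
            "a(s,.)/b(s,c)", "a(s,c)/b(.,c)", "a(s,c)/b(s,.)",
            "a(s,.)/b(.,c)", "a(.,c)/b(s,.)")
  expect_equal(labels, paste0("eq", rep(1:2, each = 14), " ", rep(patt, 2)))
  expect_equal(Ks, rep(c(2L, 5L, 8L, 5L, 5L, 8L, 5L, 32L, 20L, 20L, 20L,
                         20L, 8L, 8L), 2))
  # the two omitted lattice pairs are genuinely absent
  expect_false(any(vapply(grid, function(s) {
    (s$loss_pattern == "by_both" && s$gain_pattern == "global") ||
      (s$loss_pattern == "global" && s$gain_pattern == "by_both")
  }, logical(1))))
})

test_that("QAICc arithmetic follows the corrected-AIC formula", {
  # hand-checked instance: 2*254.43/2.9 + 2*9 + 2*9*10/(47-10)
  expect_equal(qaicc(254.43, 8, 2.9, 47, count_chat_param = TRUE),
               508.86 / 2.9 + 18 + 180 / 37, tolerance = 1e-12)
  expect_equal(round(qaicc(254.43, 8, 2.9, 47), 2), 198.33)

  # classical AIC limit: no overdispersion, huge effective sample
  expect_equal(qaicc(100, 3, 1, 1e9), 2 * 100 + 2 * 4, tolerance = 1e-5)

  # penalty is strictly monotone in K at equal fit
  expect_gt(qaicc(100, 6, 2.9, 47), qaicc(100, 5, 2.9, 47))

  expect_error(qaicc(100, 45, 2.9, 47), "n_eff")
  expect_error(qaicc(100, 5, 0, 47), "positive")
})

fake_fit <- function(id, eq, nll, K, converged = TRUE) {
  list(spec = list(model_id = id, equation = eq, loss_pattern = "global",
                   gain_pattern = "global"),
       neg_log_lik = nll, K = K, converged = converged, n_cells = 50L)
}

test_that("ranking, weights and equation support behave as probabilities", {
  # two identical models split the weight evenly
  tab <- rank_and_weight(list(fake_fit(1, 1, 120, 3), fake_fit(2, 2, 120, 3)),
                         c_hat = 2.9, n_eff = 47)
  expect_equal(tab$weight, c(0.5, 0.5))
  expect_equal(equation_support(tab), 0.5)
  expect_equal(tab$delta_qaicc, c(0, 0))

  # weights normalize and the ordering is invariant to a likelihood shift
  fits <- list(fake_fit(1, 1, 110, 2), fake_fit(2, 1, 114, 4),
               fake_fit(3, 2, 108, 5), fake_fit(4, 2, 121, 2))
  t1 <- rank_and_weight(fits, 2.9, 47)
  shifted <- lapply(fits, function(f) {
    f$neg_log_lik <- f$neg_log_lik + 37.5
    f
  })
  t2 <- rank_and_weight(shifted, 2.9, 47)
  expect_equal(sum(t1$weight), 1, tolerance = 1e-9)
  expect_equal(t1$model_id, t2$model_id)
  expect_equal(t1$weight, t2$weight, tolerance = 1e-9)
  expect_equal(sum(t1$delta_qaicc == 0), 1L)

  # non-converged members are reported, not silently dropped
  with_bad <- c(fits, list(fake_fit(5, 1, 90, 3, converged = FALSE)))
  expect_warning(t3 <- rank_and_weight(with_bad, 2.9, 47), "non-converged")
  expect_equal(nrow(t3), 5L)
  expect_true(is.na(t3$weight[t3$model_id == 5]))
  expect_equal(sum(t3$weight, na.rm = TRUE), 1, tolerance = 1e-9)

  # uniform weights over both halves of the grid: support 0.5 each
  unif <- lapply(1:28, function(i) fake_fit(i, if (i <= 14) 1 else 2, 100, 3))
  expect_equal(equation_support(rank_and_weight(unif, 2.9, 47)), 0.5)
})

test_that("refinement ties truly-equal parameters and never selects worse", {
  # data generated with genuinely equal losses for B and C
  spec <- model_spec(2, "by_species", "by_stage",
                     zero_mask = data.frame(kind = "gain", species = NA,
                                            stage = c("larva", "worker",
                                                      "soldier")))
  truth <- parameter_set(loss = c(0.2, 0.5, 0.5, 0.8),
                         gain = c(0, 0, 0.7, 0), spec = spec)
  cfg <- simulation_config(truth, colonies_per_species = 30,
                           per_stage_n = function(s) 150, seed = 99)
  cells <- pool(simulate_dataset(cfg), "by_colony_stage")
  fit <- fit_model(spec, cells, compute_se = TRUE)
  expect_true(fit$converged)

  ref <- refine_model(fit, cells, c_hat = 1, n_eff = nrow(cells))
  expect_equal(ref$status, "ok")
  sel_q <- ref$selection$qaicc[ref$selection$selected]
  start_q <- ref$selection$qaicc[1]
  expect_lte(sel_q, start_q + 1e-9)

  # the equal pair was tied: K drops, and the tied refit loses almost no fit
  tied <- ref$candidates[[2]]
  expect_equal(tied$K, fit$K - 1L)
  expect_lt(tied$neg_log_lik - fit$neg_log_lik, 2)
  expect_true(any(grepl("tie", ref$merge_log$action)))
  expect_true(any(grepl("a\\(B=C", ref$selection$label[ref$selection$selected]) |
                    grepl("B=C", tied$spec$par_info$label)))

  # well-separated parameters away from zero: refinement is the identity
  spread <- parameter_set(loss = c(0.15, 0.45, 0.7, 0.9), gain = c(0, 0, 0, 0),
                          spec = model_spec(2, "by_species", "null"))
  cfg2 <- simulation_config(spread, colonies_per_species = 40,
                            per_stage_n = function(s) 250, seed = 17)
  cells2 <- pool(simulate_dataset(cfg2), "by_colony_stage")
  fit2 <- fit_model(spread$spec, cells2, compute_se = TRUE)
  ref2 <- refine_model(fit2, cells2, c_hat = 1, n_eff = nrow(cells2))
  expect_length(ref2$candidates, 1L)
  expect_identical(ref2$selected$theta, fit2$theta)
})

test_that("selection recovers the generating structure from synthetic data", {
  spec <- refined_structure()
  truth <- parameter_set(loss = c(0.23, 0.45, 0.63, 0.30),
                         gain = c(0, 0, 0.72, 0), spec = spec)
  cfg <- simulation_config(truth, colonies_per_species = 40,
                           per_stage_n = function(s) 250, seed = 2024)
  hits <- 0L
  n_rep <- 5L
  for (r in seq_len(n_rep)) {
    cfg$seed <- 2024L + r
    cells <- pool(simulate_dataset(cfg), "by_colony_stage")
    fits <- lapply(enumerate_model_grid(), fit_model, cells = cells)
    tab <- rank_and_weight(fits, c_hat = 2.9, n_eff = 47)
    top <- tab[1, ]
    if (top$equation == 2 && top$loss_pattern == "by_species" &&
        top$gain_pattern == "by_stage") {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 4L)
})
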