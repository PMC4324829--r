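#' Configuration for the synthetic colony-data generator
#'
#' Describes a simulated study: true loss/gain parameters, recursion
#' variant, colony layout, per-stage sample sizes and the degree of
#' between-colony heterogeneity.  The defaults mirror the design of the
#' embedded screening study: 4 species, small numbers of colonies per
#' species, uneven per-stage sample sizes resampled from the embedded
#' table's pattern, and binomial (non-overdispersed) counts.
#'
#' @param true_params a [parameter_set()] of true loss/gain values.
#' @param equation recursion variant the data are generated from.
#' @param n_species number of species (1-4; codes A, B, ...).
#' @param colonies_per_species colonies simulated per species.
#' @param per_stage_n per-stage sample sizes: a length-4 vector (stages
#'   2-5), a function `(stage_ordinal) -> n`, or `"table_layout"` to
#'   resample the embedded table's uneven n pattern (including missing
#'   stages).
#' @param initial_rate stage-1 (queen) infection rate.
#' @param colony_heterogeneity beta-binomial intra-colony correlation
#'   `rho` in `[0, 1)`; 0 gives pure binomial sampling.
#' @param seed root RNG seed; per-colony substreams are derived from it
#'   by integer hashing so colonies are reproducible independently of
#'   generation order.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(true_params,
                              equation = 2,
                              n_species = 4L,
                              colonies_per_species = 4L,
                              per_stage_n = "table_layout",
                              initial_rate = 1.0,
                              colony_heterogeneity = 0,
                              seed = 1L) {
  stopifnot(inherits(true_params, "parameter_set"),
            equation %in% c(1, 2),
            n_species >= 1, n_species <= 4,
            colonies_per_species >= 1,
            colony_heterogeneity >= 0, colony_heterogeneity < 1)
  .check_prob(initial_rate, "initial_rate")
  structure(
    list(true_params = true_params, equation = equation,
         n_species = as.integer(n_species),
         colonies_per_species = as.integer(colonies_per_species),
         per_stage_n = per_stage_n, initial_rate = initial_rate,
         colony_heterogeneity = colony_heterogeneity,
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' The YAML mirrors the arguments of [simulation_config()]; `loss` and
#' `gain` follow the [parameter_set()] recycling rules (scalar,
#' per-species loss vector, per-stage gain vector, or 4x4 matrix).
#'
#' @param path YAML file path.
#' @return a `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  pars <- parameter_set(.yaml_mat(y$loss), .yaml_mat(y$gain))
  simulation_config(
    true_params = pars,
    equation = y$equation %||% 2,
    n_species = y$n_species %||% 4L,
    colonies_per_species = y$colonies_per_species %||% 4L,
    per_stage_n = y$per_stage_n %||% "table_layout",
    initial_rate = y$initial_rate %||% 1.0,
    colony_heterogeneity = y$colony_heterogeneity %||% 0,
    seed = y$seed %||% 1L)
}

.yaml_mat <- function(x) {
  if (is.list(x)) do.call(rbind, lapply(x, unlist)) else unlist(x)
}

# deterministic per-colony substream seed below 2^31
.colony_seed <- function(root, species_idx, colony_idx) {
  h <- (as.double(root) * 2654435.0 + species_idx * 97561.0 +
          colony_idx * 7919.0) %% 2147483629
  as.integer(h)
}

# the embedded table's per-colony stage-n layouts (stages 2..5; 0 = absent)
.table_layouts <- function() {
  fx <- table1_fixture()
  fx <- fx[fx$stage_ordinal %in% .model_stages & !is.na(fx$stage_ordinal), ]
  lay <- lapply(split(fx, fx$colony), function(d) {
    n <- integer(4)
    n[d$stage_ordinal - 1L] <- d$n_tested
    n
  })
  unname(lay)
}

#' Simulate a colony infection-count dataset
#'
#' For each colony, expected stage rates come from the loss/gain
#' recursion; infected counts are binomial draws at those rates, or
#' beta-binomial draws with mean `I` and intra-colony correlation `rho`
#' when `colony_heterogeneity > 0` (each colony x stage cell receives its
#' own beta-distributed rate, producing the between-colony overdispersion
#' visible in real screening tables).  Queen cells are emitted as (1, 1)
#' when `initial_rate = 1`, otherwise as a Bernoulli draw.
#'
#' The generator is fully reproducible from the config seed, and each
#' colony draws from its own hashed substream.
#'
#' @param config a [simulation_config()].
#' @return a colony dataset in the same format as [table1_fixture()].
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sp_codes <- names(species_codes())[seq_len(config$n_species)]
  rho <- config$colony_heterogeneity
  layouts <- if (identical(config$per_stage_n, "table_layout")) {
    .table_layouts()
  } else NULL

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })

  rows <- list()
  for (s in seq_along(sp_codes)) {
    traj <- infection_trajectory(config$true_params, sp_codes[s],
                                 config$equation, config$initial_rate)
    for (cc in seq_len(config$colonies_per_species)) {
      set.seed(.colony_seed(config$seed, s, cc))
      colony_id <- sprintf("S%s%02d", sp_codes[s], cc)
      ns <- if (!is.null(layouts)) {
        layouts[[sample.int(length(layouts), 1L)]]
      } else if (is.function(config$per_stage_n)) {
        vapply(.model_stages, config$per_stage_n, numeric(1))
      } else {
        rep_len(config$per_stage_n, 4L)
      }
      # queen cell
      qk <- if (config$initial_rate >= 1) 1L else
        stats::rbinom(1L, 1L, config$initial_rate)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp_codes[s], colony = colony_id, stage = "queen",
        n_tested = 1L, n_infected = qk, stringsAsFactors = FALSE)
      for (j in 1:4) {
        n <- as.integer(ns[j])
        if (n <= 0L) next
        I <- traj$rate[j + 1L]
        p <- if (rho > 0 && I > 0 && I < 1) {
          m <- (1 - rho) / rho
          stats::rbeta(1L, I * m, (1 - I) * m)
        } else I
        k <- stats::rbinom(1L, n, p)
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp_codes[s], colony = colony_id,
          stage = names(caste_stages())[j + 1L],
          n_tested = n, n_infected = k, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$stage_ordinal <- stage_ordinal(out$stage)
  out <- out[, c("species", "colony", "stage", "stage_ordinal",
                 "n_tested", "n_infected")]
  attr(out, "provenance") <- sprintf("synthetic dataset (seed %d)", config$seed)
  out
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates data from a known loss/gain structure, refits the
#' true [model_spec()] and summarises bias and RMSE per free parameter.
#' Optionally each replicate also runs the full 28-model selection and
#' records the rank of the true structure.
#'
#' @param config a [simulation_config()]; its `true_params` must carry a
#'   `spec` back-reference (the structure to refit).
#' @param replicates number of simulation replicates (>= 1).
#' @param spec the model structure to refit; defaults to
#'   `config$true_params$spec`.
#' @param settings optimizer settings for the refits.
#' @param include_selection if `TRUE`, run [enumerate_model_grid()] +
#'   [rank_and_weight()] per replicate and record the true model's rank
#'   (slower).
#' @param c_hat,n_eff QAICc preset for the optional selection step.
#' @return list with `per_parameter` (data.frame: parameter, true value,
#'   mean estimate, bias, rmse), `estimates` (replicate x parameter
#'   matrix), `n_converged`, `n_failed`, and `true_rank` (vector, when
#'   selection was run).
#' @export
recovery_experiment <- function(config, replicates,
                                spec = config$true_params$spec,
                                settings = fit_settings(n_starts = 8L),
                                include_selection = FALSE,
                                c_hat = 2.9, n_eff = NULL) {
  stopifnot(replicates >= 1)
  if (is.null(spec)) {
    stop("no model spec attached to the true parameter set", call. = FALSE)
  }
  true_theta <- .params_to_theta(spec, config$true_params)
  est <- matrix(NA_real_, replicates, spec$K,
                dimnames = list(NULL, spec$par_info$label))
  ranks <- rep(NA_integer_, replicates)
  n_failed <- 0L
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- .colony_seed(config$seed, 0L, r)
    dat <- simulate_dataset(cfg)
    cells <- pool(dat, "by_colony_stage")
    fit <- fit_model(spec, cells, settings, initial_rate = config$initial_rate)
    if (isTRUE(fit$converged)) {
      est[r, ] <- fit$theta
    } else {
      n_failed <- n_failed + 1L
    }
    if (include_selection) {
      grid <- enumerate_model_grid()
      fits <- lapply(grid, fit_model, cells = cells, settings = settings,
                     initial_rate = config$initial_rate)
      tab <- rank_and_weight(fits, c_hat = c_hat, n_eff = n_eff)
      target <- which(tab$equation == spec$equation &
                        tab$loss_pattern == spec$loss_pattern &
                        tab$gain_pattern == spec$gain_pattern)
      if (length(target)) ranks[r] <- target[1]
    }
  }
  ok <- stats::complete.cases(est)
  per_parameter <- data.frame(
    parameter = spec$par_info$label,
    true = true_theta,
    mean_estimate = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - true_theta,
    rmse = sqrt(colMeans((est[ok, , drop = FALSE] -
                            matrix(true_theta, sum(ok), spec$K,
                                   byrow = TRUE))^2)),
    stringsAsFactors = FALSE)
  list(per_parameter = per_parameter, estimates = est,
       n_converged = sum(ok), n_failed = n_failed,
       true_rank = if (include_selection) ranks else NULL)
}

# recover the free-parameter vector from a parameter set, checking tie
# consistency
.params_to_theta <- function(spec, params) {
  theta <- numeric(spec$K)
  for (kind in c("loss", "gain")) {
    map <- spec[[paste0(kind, "_map")]]
    m <- params[[kind]]
    for (id in sort(unique(map[map > 0L]))) {
      vals <- unique(m[map == id])
      if (length(vals) != 1L) {
        stop("parameter values not constant within tied group", call. = FALSE)
      }
      theta[id] <- vals
    }
    if (any(m[map == 0L] != 0)) {
      stop("non-zero value in a zero-constrained cell", call. = FALSE)
    }
  }
  theta
}
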