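#' Binomial negative log-likelihood of a loss/gain model
#'
#' Each cell (a colony x stage or species x stage aggregate of the
#' modelled stages 2-5) contributes the binomial log-probability mass of
#' its infected count `k` out of `n` at the model-expected infection rate
#' `I(s,c)` from [infection_trajectory()].  Predicted rates are clipped to
#' `[1e-12, 1 - 1e-12]` so that structurally-zero predictions (e.g. a
#' no-gain model after total loss) yield a large finite penalty rather
#' than `-Inf`.
#'
#' Because predictions depend on (species, stage) only, the two
#' aggregation modes give likelihoods differing by an additive constant
#' (the binomial coefficients): estimates, likelihood ratios and
#' information-criterion differences are identical in both modes.
#'
#' @param spec a [model_spec()].
#' @param params a [parameter_set()] consistent with `spec`.
#' @param cells pooled cells from [pool()]; modelled stages 2-5 only.
#' @param initial_rate stage-1 (queen) infection rate, default 1.
#' @return the negative log-likelihood (non-negative up to the binomial
#'   coefficients).
#' @export
negative_log_likelihood <- function(spec, params, cells, initial_rate = 1.0) {
  .check_cells(cells)
  pred <- .predicted_rates(params, spec$equation, initial_rate)
  pr <- pmin(pmax(pred[cbind(species_codes()[cells$species],
                             cells$stage_ordinal - 1L)], 1e-12), 1 - 1e-12)
  -sum(stats::dbinom(cells$k, cells$n, pr, log = TRUE))
}

.check_cells <- function(cells) {
  stopifnot(all(c("species", "stage_ordinal", "n", "k") %in% names(cells)))
  if (any(!cells$stage_ordinal %in% .model_stages)) {
    stop("likelihood cells must be restricted to stages 2-5 ",
         "(queens/kings are excluded)", call. = FALSE)
  }
  invisible(cells)
}

# 4x4 matrix of predicted rates, species x stage(2..5)
.predicted_rates <- function(params, equation, initial_rate) {
  a <- params$loss; b <- params$gain
  I <- matrix(0, 4, 4)
  Ip <- rep(initial_rate, 4)
  for (j in 1:4) {
    Ip <- if (equation == 1) Ip * (1 - a[, j] - b[, j]) + b[, j]
          else Ip * (1 - a[, j]) * (1 - b[, j]) + b[, j]
    I[, j] <- Ip
  }
  I
}

#' Optimizer settings for [fit_model()]
#'
#' @param n_starts number of multi-start points (Latin-hypercube draws on
#'   the probability scale, fixed seed).
#' @param seed RNG seed for the start grid.
#' @param maxit,reltol passed to [stats::optim()] (BFGS).
#' @param grad_tol maximum absolute logit-scale gradient component at the
#'   reported optimum for the fit to be flagged converged.
#' @export
fit_settings <- function(n_starts = 16L, seed = 20150211L, maxit = 500L,
                         reltol = 1e-10, grad_tol = 0.1) {
  list(n_starts = as.integer(n_starts), seed = as.integer(seed),
       maxit = as.integer(maxit), reltol = reltol, grad_tol = grad_tol)
}

#' Maximum-likelihood fit of a loss/gain model
#'
#' Free parameters are estimated on the logit scale (an unconstrained
#' reparametrisation of the `[0,1]` box) by BFGS from a fixed-seed
#' Latin-hypercube grid of starting points; the best final value is kept.
#' Multi-start matters here: tied structures can produce flat, multimodal
#' likelihood surfaces, and single-start fits of this model family are
#' unreliable.
#'
#' Internally the data are reduced to species x stage sufficient
#' statistics; the reported `neg_log_lik` is computed on the cells as
#' given (so it includes the binomial coefficients of the chosen
#' aggregation).
#'
#' @param spec a [model_spec()].
#' @param cells pooled cells (stages 2-5) from [pool()].
#' @param settings a [fit_settings()] list.
#' @param initial_rate stage-1 infection rate.
#' @param compute_se if `TRUE`, attach Hessian standard errors (see
#'   [hessian_standard_errors()]).
#' @return a `caste_fit` object: `spec`, `params` ([parameter_set()]),
#'   `theta` (free parameters, probability scale), `neg_log_lik`, `K`,
#'   `converged`, `boundary` flags, `n_cells`, optionally `se`.
#' @export
fit_model <- function(spec, cells, settings = fit_settings(),
                      initial_rate = 1.0, compute_se = FALSE) {
  .check_cells(cells)
  suff <- .suff_stats(cells)
  obj <- .make_objective(spec, suff, initial_rate)

  K <- spec$K
  if (K == 0L) {
    theta <- numeric(0)
    best <- list(value = obj(numeric(0)), par = numeric(0), convergence = 0L)
  } else {
    starts <- .start_grid(K, settings)
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- tryCatch(
        stats::optim(starts[i, ], obj, method = "BFGS",
                     control = list(maxit = settings$maxit,
                                    reltol = settings$reltol)),
        error = function(e) NULL)
      if (!is.null(o) && is.finite(o$value) &&
          (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) {
      return(structure(list(spec = spec, params = NULL, theta = NULL,
                            neg_log_lik = NA_real_, K = K, converged = FALSE,
                            boundary = NULL, n_cells = nrow(cells),
                            diagnostics = "all optimizer starts failed",
                            settings = settings, initial_rate = initial_rate),
                       class = "caste_fit"))
    }
  }

  theta <- stats::plogis(best$par)
  grad <- if (K > 0L) .num_grad(obj, best$par) else numeric(0)
  converged <- best$convergence == 0L &&
    (K == 0L || max(abs(grad)) < settings$grad_tol)
  params <- .theta_to_params(spec, theta)
  nll <- negative_log_likelihood(spec, params, cells, initial_rate)

  fit <- structure(
    list(spec = spec, params = params, theta = theta,
         neg_log_lik = nll, K = K, converged = converged,
         boundary = theta < 1e-6 | theta > 1 - 1e-6,
         n_cells = nrow(cells), max_grad = if (K > 0L) max(abs(grad)) else 0,
         settings = settings, initial_rate = initial_rate),
    class = "caste_fit")
  if (compute_se) fit$se <- hessian_standard_errors(fit, cells)
  fit
}

#' @export
print.caste_fit <- function(x, ...) {
  cat("caste_fit:", x$spec$label, "\n")
  cat(sprintf("  -lnL = %.4f  K = %d  converged = %s\n",
              x$neg_log_lik, x$K, x$converged))
  if (!is.null(x$theta) && length(x$theta)) {
    tab <- data.frame(parameter = x$spec$par_info$label,
                      estimate = round(x$theta, 4))
    if (!is.null(x$se)) tab$se <- round(x$se, 4)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

# species x stage sufficient statistics (counts summed per (s,c))
.suff_stats <- function(cells) {
  N <- K <- matrix(0, 4, 4)
  si <- species_codes()[cells$species]
  ci <- cells$stage_ordinal - 1L
  for (i in seq_along(si)) {
    N[si[i], ci[i]] <- N[si[i], ci[i]] + cells$n[i]
    K[si[i], ci[i]] <- K[si[i], ci[i]] + cells$k[i]
  }
  list(N = N, K = K, pos = which(N > 0))
}

# Bernoulli-part objective on the logit scale
.make_objective <- function(spec, suff, initial_rate) {
  lm <- spec$loss_map; gm <- spec$gain_map
  eq <- spec$equation
  lpos <- lm > 0L; gpos <- gm > 0L
  N <- suff$N; Kk <- suff$K; pos <- suff$pos
  function(th) {
    p <- stats::plogis(th)
    a <- matrix(0, 4, 4); b <- matrix(0, 4, 4)
    a[lpos] <- p[lm[lpos]]; b[gpos] <- p[gm[gpos]]
    I <- matrix(0, 4, 4); Ip <- rep(initial_rate, 4)
    for (j in 1:4) {
      Ip <- if (eq == 1) Ip * (1 - a[, j] - b[, j]) + b[, j]
            else Ip * (1 - a[, j]) * (1 - b[, j]) + b[, j]
      I[, j] <- Ip
    }
    pr <- pmin(pmax(I[pos], 1e-12), 1 - 1e-12)
    -sum(Kk[pos] * log(pr) + (N[pos] - Kk[pos]) * log1p(-pr))
  }
}

# fixed-seed Latin-hypercube start grid mapped to logit scale, leaving the
# caller's RNG stream untouched
.start_grid <- function(K, settings) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(settings$seed)
  u <- lhs::randomLHS(settings$n_starts, K)
  stats::qlogis(0.02 + 0.96 * u)
}

.num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' Hessian-based standard errors of a fitted model
#'
#' Central-difference Hessian of the negative log-likelihood at the
#' optimum, on the natural (probability) scale of the free parameters;
#' standard errors are the square roots of the diagonal of its inverse.
#' A parameter within numerical reach of the 0/1 boundary has no finite
#' Wald curvature; it is flagged and its SE is taken from a one-sided
#' likelihood profile (the displacement raising the negative
#' log-likelihood by 1.92, divided by 1.96), with the other parameters
#' held at the optimum.
#'
#' Tied cells share a single free parameter and therefore a single SE.
#'
#' @param fit a converged `caste_fit`.
#' @param cells the cells the model was fitted to.
#' @return numeric vector of standard errors (one per free parameter,
#'   `NA` where unavailable), with attributes `boundary` (logical flags)
#'   and `hessian_ok`.
#' @export
hessian_standard_errors <- function(fit, cells) {
  if (!isTRUE(fit$converged)) stop("fit has not converged", call. = FALSE)
  K <- fit$K
  if (K == 0L) return(numeric(0))
  .check_cells(cells)
  suff <- .suff_stats(cells)
  spec <- fit$spec
  objp <- function(p) {  # probability-scale objective
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    params <- .theta_to_params(spec, p)
    pred <- .predicted_rates(params, spec$equation, fit$initial_rate)
    pr <- pmin(pmax(pred[suff$pos], 1e-12), 1 - 1e-12)
    -sum(suff$K[suff$pos] * log(pr) +
           (suff$N[suff$pos] - suff$K[suff$pos]) * log1p(-pr))
  }
  p0 <- fit$theta
  h <- pmax(1e-5, 1e-4 * pmin(p0, 1 - p0))
  boundary <- p0 < 2 * h | p0 > 1 - 2 * h
  Hm <- matrix(NA_real_, K, K)
  free <- which(!boundary)
  for (i in free) for (j in free[free >= i]) {
    ei <- ej <- numeric(K); ei[i] <- h[i]; ej[j] <- h[j]
    if (i == j) {
      Hm[i, i] <- (objp(p0 + ei) - 2 * objp(p0) + objp(p0 - ei)) / h[i]^2
    } else {
      Hm[i, j] <- Hm[j, i] <-
        (objp(p0 + ei + ej) - objp(p0 + ei - ej) -
           objp(p0 - ei + ej) + objp(p0 - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  se <- rep(NA_real_, K)
  hess_ok <- FALSE
  if (length(free)) {
    V <- tryCatch(solve(Hm[free, free, drop = FALSE]), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)
      if (all(is.finite(d)) && all(d > 0)) {
        se[free] <- sqrt(d)
        hess_ok <- TRUE
      }
    }
  }
  # one-sided profile fallback for boundary parameters
  f0 <- objp(p0)
  for (j in which(boundary)) {
    inward <- p0[j] < 0.5
    g <- function(d) {
      p <- p0; p[j] <- if (inward) d else 1 - d
      objp(p) - f0 - stats::qchisq(0.95, 1) / 2
    }
    up <- tryCatch(stats::uniroot(g, c(if (inward) p0[j] else 1 - p0[j], 0.999),
                                  tol = 1e-7)$root,
                   error = function(e) NA_real_)
    if (is.finite(up)) se[j] <- abs(up - (if (inward) p0[j] else 1 - p0[j])) /
        stats::qnorm(0.975)
  }
  attr(se, "boundary") <- boundary
  attr(se, "hessian_ok") <- hess_ok
  se
}

#' Overdispersion factor for quasi-AIC corrections
#'
#' The variance-inflation factor `c-hat` scales the log-likelihood in
#' QAIC-type criteria.  Two conventions are offered besides a fixed
#' value: the Pearson chi-square (or the deviance) of the most complex
#' binomial GLZ with positive residual degrees of freedom — the additive
#' colony + caste model on colony x stage cells — divided by its residual
#' df.  On the embedded dataset these give 3.12 (Pearson) and 2.93
#' (deviance); the package default for selection presets is the
#' conventional fixed 2.9.
#'
#' @param data a colony dataset (colony-level aggregation is required for
#'   the model-based modes).
#' @param mode `"fixed"`, `"pearson_full_model"` or
#'   `"deviance_full_model"`.
#' @param value the fixed value (default 2.9); must be positive.
#' @return an object of class `overdispersion`: list with `c_hat` and
#'   `source`.
#' @export
estimate_overdispersion <- function(data,
                                    mode = c("fixed", "pearson_full_model",
                                             "deviance_full_model"),
                                    value = 2.9) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (!is.finite(value) || value <= 0) {
      stop("overdispersion must be positive", call. = FALSE)
    }
    return(structure(list(c_hat = value, source = "fixed"),
                     class = "overdispersion"))
  }
  glz <- fit_glz(data, terms = c("colony", "caste"))
  df <- glz$fit$df.residual
  if (df <= 0) stop("no residual degrees of freedom", call. = FALSE)
  c_hat <- if (mode == "pearson_full_model") {
    sum(stats::residuals(glz$fit, type = "pearson")^2) / df
  } else {
    stats::deviance(glz$fit) / df
  }
  structure(list(c_hat = c_hat, source = mode), class = "overdispersion")
}
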