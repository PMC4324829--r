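#' The 28-model loss/gain sharing grid
#'
#' Fourteen loss x gain sharing-pattern pairs, each under both recursion
#' variants (models 1-14 use equation 1, models 15-28 equation 2).  The
#' grid is not the full 16-pair lattice: the pairs `a(s,c) x b(.,.)` and
#' `a(.,.) x b(s,c)` are not part of the candidate set.
#'
#' @return a list of 28 [model_spec()] objects; element `i` carries
#'   `model_id = i`.
#' @export
enumerate_model_grid <- function() {
  pairs <- list(
    c("global", "global"),        # 1 / 15
    c("by_species", "global"),    # 2 / 16
    c("by_species", "by_species"),
    c("global", "by_species"),
    c("by_stage", "global"),
    c("by_stage", "by_stage"),
    c("global", "by_stage"),
    c("by_both", "by_both"),
    c("by_stage", "by_both"),
    c("by_species", "by_both"),
    c("by_both", "by_stage"),
    c("by_both", "by_species"),
    c("by_species", "by_stage"),  # 13 / 27
    c("by_stage", "by_species")
  )
  grid <- vector("list", 28L)
  for (eq in 1:2) for (i in seq_along(pairs)) {
    id <- (eq - 1L) * 14L + i
    spec <- model_spec(eq, pairs[[i]][1], pairs[[i]][2])
    spec$model_id <- id
    grid[[id]] <- spec
  }
  grid
}

#' Quasi-AIC with small-sample correction
#'
#' `QAICc = 2 * nll / c_hat + 2 K' + 2 K' (K' + 1) / (n_eff - K' - 1)`,
#' where `K' = K + 1` when the overdispersion factor is counted as an
#' estimated parameter (the default, standard QAIC practice).
#'
#' @param neg_log_lik minimized negative log-likelihood.
#' @param K number of free model parameters.
#' @param c_hat overdispersion factor (> 0).
#' @param n_eff effective sample size; must exceed `K' + 1` or the
#'   correction is undefined.
#' @param count_chat_param whether `c_hat` counts as one parameter.
#' @return the QAICc value.
#' @export
qaicc <- function(neg_log_lik, K, c_hat, n_eff, count_chat_param = TRUE) {
  if (!is.finite(c_hat) || c_hat <= 0) stop("c_hat must be positive", call. = FALSE)
  Kp <- K + as.integer(count_chat_param)
  if (n_eff <= Kp + 1) {
    stop("n_eff must exceed K + 1 (+1 for c_hat); correction undefined",
         call. = FALSE)
  }
  2 * neg_log_lik / c_hat + 2 * Kp + 2 * Kp * (Kp + 1) / (n_eff - Kp - 1)
}

#' Rank fitted models by QAICc and compute Akaike weights
#'
#' @param fits list of `caste_fit` objects (at least 2).
#' @param c_hat overdispersion factor.
#' @param n_eff effective sample size; defaults to the number of binomial
#'   cells the models were fitted to.
#' @param count_chat_param passed to [qaicc()].
#' @return a selection table (`data.frame`), rows sorted by QAICc
#'   ascending, with columns `model_id`, `equation`, `loss_pattern`,
#'   `gain_pattern`, `neg_log_lik`, `K`, `qaicc`, `delta_qaicc`, `weight`,
#'   `converged`.  Non-converged fits are excluded from ranking (kept as
#'   rows with `NA` weight) with a warning.
#' @export
rank_and_weight <- function(fits, c_hat = 2.9, n_eff = NULL,
                            count_chat_param = TRUE) {
  if (length(fits) < 2L) stop("need at least two fits to rank", call. = FALSE)
  if (is.null(n_eff)) n_eff <- fits[[1]]$n_cells
  rows <- lapply(fits, function(f) {
    data.frame(
      model_id = f$spec$model_id %||% NA_integer_,
      equation = f$spec$equation,
      loss_pattern = f$spec$loss_pattern,
      gain_pattern = f$spec$gain_pattern,
      neg_log_lik = f$neg_log_lik,
      K = f$K,
      converged = isTRUE(f$converged),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  if (any(!tab$converged)) {
    warning(sum(!tab$converged),
            " non-converged fit(s) excluded from ranking", call. = FALSE)
  }
  tab$qaicc <- NA_real_
  ok <- tab$converged & is.finite(tab$neg_log_lik)
  tab$qaicc[ok] <- vapply(which(ok), function(i) {
    tryCatch(qaicc(tab$neg_log_lik[i], tab$K[i], c_hat, n_eff,
                   count_chat_param),
             error = function(e) NA_real_)  # correction undefined at this K
  }, numeric(1))
  tab$delta_qaicc <- tab$qaicc - min(tab$qaicc, na.rm = TRUE)
  w <- exp(-tab$delta_qaicc / 2)
  tab$weight <- w / sum(w, na.rm = TRUE)
  tab <- tab[order(tab$qaicc), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "c_hat") <- c_hat
  attr(tab, "n_eff") <- n_eff
  attr(tab, "count_chat_param") <- count_chat_param
  tab
}

#' Total Akaike weight carried by the equation-2 models
#'
#' Interpreted as the probability, within the candidate set, that the
#' gain process operates during (rather than between) stages.
#'
#' @param rows a selection table from [rank_and_weight()].
#' @return a probability.
#' @export
equation_support <- function(rows) {
  sum(rows$weight[rows$equation == 2], na.rm = TRUE)
}

#' Post-selection refinement of the best model
#'
#' Greedy simplification of a fitted model guided by Wald 95% confidence
#' intervals on the natural scale: at each step, (i) if any free
#' parameter's CI contains 0, the one with the smallest `|estimate|/SE`
#' is fixed to 0; otherwise (ii) the most-overlapping pair of same-kind
#' parameters (both losses or both gains) with overlapping CIs is tied to
#' a single value.  The model is refit after every action.  All interim
#' specs are kept as candidates and the final selection is the candidate
#' with the lowest QAICc (which can be the unrefined model itself, so
#' refinement never selects a worse model than its starting point).
#'
#' @param best a converged `caste_fit` with SEs available (or computable).
#' @param cells the cells the model was fitted to.
#' @param c_hat,n_eff,count_chat_param QAICc preset, see [qaicc()].
#' @param settings optimizer settings for the refits.
#' @param max_steps safety cap on refinement actions.
#' @return an object of class `refinement`: list with `candidates` (list
#'   of fits), `selected` (the winning fit), `selection` (QAICc table over
#'   candidates), `merge_log` (data.frame of actions) and `status`.
#' @export
refine_model <- function(best, cells, c_hat = 2.9, n_eff = NULL,
                         count_chat_param = TRUE,
                         settings = best$settings, max_steps = 20L) {
  if (!isTRUE(best$converged)) stop("best fit has not converged", call. = FALSE)
  if (is.null(n_eff)) n_eff <- best$n_cells
  if (is.null(best$se)) best$se <- hessian_standard_errors(best, cells)
  if (all(is.na(best$se)) && best$K > 0L) {
    return(structure(list(candidates = list(best), selected = best,
                          selection = NULL, merge_log = NULL,
                          status = "skipped: no standard errors available"),
                     class = "refinement"))
  }

  z <- stats::qnorm(0.975)
  candidates <- list(best)
  merge_log <- data.frame(step = integer(), action = character(),
                          parameter = character(), detail = character(),
                          stringsAsFactors = FALSE)
  current <- best
  for (step in seq_len(max_steps)) {
    th <- current$theta; se <- current$se
    info <- current$spec$par_info
    if (is.null(info) || current$K <= 1L) break
    lo <- th - z * se; hi <- th + z * se

    # (i) zero the least-significant parameter whose CI covers 0
    cover0 <- which(!is.na(se) & lo <= 0)
    action <- NULL
    if (length(cover0)) {
      j <- cover0[which.min(abs(th[cover0]) / se[cover0])]
      new_spec <- .spec_zero(current$spec, j)
      action <- c("zero", info$label[j],
                  sprintf("estimate %.4f, CI [%.4f, %.4f]", th[j], lo[j], hi[j]))
    } else {
      # (ii) tie the most-overlapping same-kind pair
      best_overlap <- -Inf; pair <- NULL
      for (i in seq_len(current$K - 1L)) for (jj in (i + 1L):current$K) {
        if (info$kind[i] != info$kind[jj]) next
        if (is.na(se[i]) || is.na(se[jj])) next
        ov <- min(hi[i], hi[jj]) - max(lo[i], lo[jj])
        if (ov > 0 && ov > best_overlap) {
          best_overlap <- ov; pair <- c(i, jj)
        }
      }
      if (is.null(pair)) break
      new_spec <- .spec_tie(current$spec, pair[1], pair[2])
      action <- c("tie", paste(info$label[pair], collapse = " = "),
                  sprintf("CI overlap %.4f", best_overlap))
    }
    refit <- fit_model(new_spec, cells, settings,
                       initial_rate = current$initial_rate)
    if (!isTRUE(refit$converged)) {
      merge_log <- rbind(merge_log, data.frame(
        step = step, action = paste0(action[1], " (refit non-converged, kept)"),
        parameter = action[2], detail = action[3], stringsAsFactors = FALSE))
      candidates <- c(candidates, list(refit))
      break
    }
    refit$se <- hessian_standard_errors(refit, cells)
    merge_log <- rbind(merge_log, data.frame(
      step = step, action = action[1], parameter = action[2],
      detail = action[3], stringsAsFactors = FALSE))
    candidates <- c(candidates, list(refit))
    current <- refit
  }

  q <- vapply(candidates, function(f) {
    if (!isTRUE(f$converged)) return(NA_real_)
    tryCatch(qaicc(f$neg_log_lik, f$K, c_hat, n_eff, count_chat_param),
             error = function(e) NA_real_)
  }, numeric(1))
  sel <- which.min(q)
  selection <- data.frame(
    candidate = seq_along(candidates),
    label = vapply(candidates, function(f) f$spec$label, character(1)),
    K = vapply(candidates, function(f) f$K, numeric(1)),
    neg_log_lik = vapply(candidates, function(f) f$neg_log_lik, numeric(1)),
    qaicc = q, selected = seq_along(candidates) == sel,
    stringsAsFactors = FALSE)
  structure(list(candidates = candidates, selected = candidates[[sel]],
                 selection = selection, merge_log = merge_log,
                 status = "ok"),
            class = "refinement")
}

#' @export
print.refinement <- function(x, ...) {
  cat("refinement:", x$status, "\n")
  if (!is.null(x$merge_log) && nrow(x$merge_log)) {
    print(x$merge_log, row.names = FALSE)
  }
  if (!is.null(x$selection)) {
    cat("selected candidate:\n")
    print(x$selection[x$selection$selected, , drop = FALSE], row.names = FALSE)
  }
  invisible(x)
}
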