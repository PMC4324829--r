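#' Binomial GLZ of infection status on colony and caste
#'
#' Fits the descriptive generalized linear model: infection status (0/1)
#' with binomial errors and logistic link, with colony and/or caste as
#' categorical factors, optionally with their interaction.  The fit is
#' done on counts via `cbind(infected, uninfected)`, which yields exactly
#' the same estimates as expanding to Bernoulli rows.
#'
#' Cells at 0% or 100% can induce complete separation (infinite logit
#' estimates); these are detected and flagged, and the fit is still
#' returned.
#'
#' @param data a colony dataset; only the four offspring castes (stages
#'   2-5) enter the model.
#' @param terms subset of `c("colony", "caste", "colony:caste")`.
#' @return an object of class `glz_fit`: the underlying [stats::glm()]
#'   object, `coefficients`, `covariance`, `deviance`, `design_terms`,
#'   `aliased` term names and `separation` flags per cell.
#' @export
fit_glz <- function(data, terms = c("colony", "caste")) {
  allowed <- c("colony", "caste", "colony:caste")
  if (!length(terms) || any(!terms %in% allowed)) {
    stop("terms must be a non-empty subset of ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  castes <- c("larva", "worker", "white_soldier", "soldier")
  d <- data[data$stage %in% castes, , drop = FALSE]
  d$caste <- factor(d$stage, levels = castes)
  d$colony <- factor(d$colony)
  rhs <- paste(terms, collapse = " + ")
  fml <- stats::as.formula(paste("cbind(n_infected, n_tested - n_infected) ~", rhs))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = d))

  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  sep <- (d$n_infected == 0L | d$n_infected == d$n_tested) &
    (stats::fitted(fit) < 1e-8 | stats::fitted(fit) > 1 - 1e-8)
  separation <- d[sep, c("colony", "stage", "n_tested", "n_infected")]
  if (nrow(separation)) {
    warning("complete separation in ", nrow(separation),
            " cell(s); affected logit estimates are unbounded", call. = FALSE)
  }
  structure(
    list(fit = fit,
         coefficients = stats::coef(fit),
         covariance = stats::vcov(fit),
         deviance = stats::deviance(fit),
         design_terms = terms,
         data = d,
         aliased = aliased,
         separation = separation),
    class = "glz_fit")
}

#' Pairwise Wald comparisons of caste infection rates
#'
#' Wald tests of all pairwise caste contrasts from a [fit_glz()] fit that
#' contains the caste term, plus a compact letter display: castes are
#' sorted by pooled infection rate and greedily grouped so that castes
#' sharing a letter are not significantly different at `alpha`.
#'
#' @param glz a `glz_fit` containing `"caste"` among its design terms.
#' @param alpha significance level for the letter grouping (default 0.05).
#' @return list with `comparisons` (data.frame: caste_a, caste_b,
#'   wald_statistic, p_value, significant) and `letters` (named character
#'   vector caste -> letter group).
#' @export
wald_caste_tests <- function(glz, alpha = 0.05) {
  if (!"caste" %in% glz$design_terms) {
    stop("caste term not present in the GLZ", call. = FALSE)
  }
  castes <- levels(glz$data$caste)
  b <- glz$coefficients
  V <- glz$covariance
  contrast <- function(ci, cj) {
    v <- numeric(length(b)); names(v) <- names(b)
    ti <- paste0("caste", ci); tj <- paste0("caste", cj)
    if (ti %in% names(v)) v[ti] <- 1
    if (tj %in% names(v)) v[tj] <- v[tj] - 1
    v
  }
  rows <- list()
  for (i in seq_along(castes)) for (j in seq_along(castes)) {
    if (j <= i) next
    v <- contrast(castes[i], castes[j])
    est <- sum(v * ifelse(is.na(b), 0, b))
    var <- drop(t(v) %*% V %*% v)
    if (!is.finite(var) || var < 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        caste_a = castes[i], caste_b = castes[j],
        wald_statistic = NA_real_, p_value = NA_real_, significant = NA,
        stringsAsFactors = FALSE)
      next
    }
    w <- if (var == 0) 0 else est^2 / var
    p <- if (identical(castes[i], castes[j])) 1 else stats::pchisq(w, 1, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      caste_a = castes[i], caste_b = castes[j],
      wald_statistic = w, p_value = p, significant = p < alpha,
      stringsAsFactors = FALSE)
  }
  comparisons <- do.call(rbind, rows)

  # pooled rates drive the grouping order
  agg <- stats::aggregate(cbind(n_tested, n_infected) ~ caste,
                          data = glz$data, FUN = sum)
  rates <- agg$n_infected / agg$n_tested
  names(rates) <- as.character(agg$caste)
  letters_out <- .letter_groups(rates, comparisons)
  list(comparisons = comparisons, letters = letters_out)
}

# greedy insert-and-merge compact letter display
.letter_groups <- function(rates, comparisons) {
  ord <- names(sort(rates))
  sig <- function(a, b) {
    r <- comparisons[(comparisons$caste_a == a & comparisons$caste_b == b) |
                       (comparisons$caste_a == b & comparisons$caste_b == a), ]
    isTRUE(r$significant[1])
  }
  groups <- list()
  for (cs in ord) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (!any(vapply(groups[[g]], function(m) sig(cs, m), logical(1)))) {
        groups[[g]] <- c(groups[[g]], cs)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- cs
  }
  out <- stats::setNames(rep("", length(rates)), names(rates))
  for (g in seq_along(groups)) {
    for (m in groups[[g]]) out[m] <- paste0(out[m], letters[g])
  }
  out
}

#' Normal-approximation binomial confidence interval, in percent
#'
#' `p-hat +/- z * sqrt(p-hat (1 - p-hat) / n)`, truncated to `[0, 100]`%.
#' For the conventional 95% level the multiplier defaults to the two-SE
#' rule (`z = 2`) used in field reports of this kind; pass
#' `z = qnorm(0.975)` for the exact normal quantile, or any other value.
#'
#' @param n_infected,n_tested counts (`n_tested >= 1`).
#' @param level confidence level in (0,1).
#' @param z optional explicit multiplier; overrides `level`.
#' @return numeric length-2 vector `c(lower, upper)` in percent (not
#'   rounded; see [caste_summary_table()] for the integer-percent report
#'   form).
#' @export
binomial_ci_normal <- function(n_infected, n_tested, level = 0.95, z = NULL) {
  stopifnot(n_tested >= 1, n_infected >= 0, n_infected <= n_tested,
            level > 0, level < 1)
  if (is.null(z)) {
    z <- if (abs(level - 0.95) < 1e-12) 2 else stats::qnorm((1 + level) / 2)
  }
  p <- n_infected / n_tested
  half <- z * sqrt(p * (1 - p) / n_tested)
  100 * c(max(0, p - half), min(1, p + half))
}

#' Caste-level descriptive summary table
#'
#' Pooled infection rate, normal-approximation 95% CI (integer percent)
#' and Wald letter group for each of the four offspring castes, the
#' summary block of a colony screening report.
#'
#' @param data a colony dataset.
#' @param glz_terms design terms for the letter-group GLZ (default colony
#'   + caste, which adjusts the caste comparisons for colony effects).
#' @return `data.frame` with columns `caste`, `n_tested`, `n_infected`,
#'   `rate_pct`, `ci_lower_pct`, `ci_upper_pct`, `letter`.
#' @export
caste_summary_table <- function(data, glz_terms = c("colony", "caste")) {
  castes <- c("larva", "worker", "white_soldier", "soldier")
  cells <- pool(data, "by_species_stage", include_stages = castes)
  agg <- stats::aggregate(cbind(n, k) ~ stage, data = cells, FUN = sum)
  agg <- agg[match(castes, agg$stage), ]
  glz <- suppressWarnings(fit_glz(data, terms = glz_terms))
  lt <- wald_caste_tests(glz)$letters
  ci <- t(mapply(binomial_ci_normal, agg$k, agg$n))
  data.frame(
    caste = castes,
    n_tested = agg$n,
    n_infected = agg$k,
    rate_pct = round(100 * agg$k / agg$n, 2),
    ci_lower_pct = as.integer(round(ci[, 1])),
    ci_upper_pct = as.integer(round(ci[, 2])),
    letter = unname(lt[castes]),
    stringsAsFactors = FALSE)
}
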