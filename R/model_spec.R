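#' Loss/gain model structures
#'
#' A model spec fixes which recursion is used ([step_eq1()] or
#' [step_eq2()]) and how the loss matrix `a(s,c)` and gain matrix `b(s,c)`
#' are shared across species and stages:
#'
#' * `"global"`  — one value, `a(.,.)`
#' * `"by_species"` — one value per species, `a(s,.)`
#' * `"by_stage"` — one value per stage, `a(.,c)`
#' * `"by_both"` — a free value per species x stage cell, `a(s,c)`
#' * `"null"` — fixed to zero everywhere
#'
#' An optional `zero_mask` pins individual (species, stage) cells of
#' either matrix to zero, the device used by model refinement (e.g. "no
#' gain except at the white-soldier stage").  The free-parameter count
#' `K` is the number of distinct tied, non-zeroed parameters implied by
#' the patterns and the mask.
#'
#' @param equation recursion variant, 1 or 2.
#' @param loss_pattern,gain_pattern sharing pattern, see above.
#' @param zero_mask optional `data.frame` with columns `kind` (`"loss"` or
#'   `"gain"`), `species` (code or `NA` for all) and `stage` (label or
#'   ordinal 2-5, `NA` for all); each row zeroes the matching cells.
#' @param label optional display label.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(equation,
                       loss_pattern = c("global", "by_species", "by_stage",
                                        "by_both", "null"),
                       gain_pattern = c("global", "by_species", "by_stage",
                                        "by_both", "null"),
                       zero_mask = NULL, label = NULL) {
  loss_pattern <- match.arg(loss_pattern)
  gain_pattern <- match.arg(gain_pattern)
  if (!equation %in% c(1, 2)) stop("equation must be 1 or 2", call. = FALSE)
  spec <- structure(
    list(equation = as.integer(equation),
         loss_pattern = loss_pattern, gain_pattern = gain_pattern,
         zero_mask = zero_mask,
         loss_map = NULL, gain_map = NULL,   # explicit tie maps (refinement)
         label = label %||% sprintf("eq%d %s/%s", equation,
                                    .pattern_label("a", loss_pattern),
                                    .pattern_label("b", gain_pattern))),
    class = "model_spec"
  )
  .normalize_spec(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pattern_label <- function(sym, pattern) {
  switch(pattern,
         global = paste0(sym, "(.,.)"),
         by_species = paste0(sym, "(s,.)"),
         by_stage = paste0(sym, "(.,c)"),
         by_both = paste0(sym, "(s,c)"),
         null = paste0(sym, "=0"))
}

# default 4x4 integer index matrix (rows species, cols stages 2..5);
# equal indices are tied, 0 means fixed at zero
.pattern_map <- function(pattern) {
  m <- switch(pattern,
              global = matrix(1L, 4, 4),
              by_species = matrix(rep(1:4, 4), 4, 4),
              by_stage = matrix(rep(1:4, each = 4), 4, 4),
              by_both = matrix(seq_len(16L), 4, 4),
              null = matrix(0L, 4, 4))
  dimnames(m) <- list(names(species_codes()),
                      names(caste_stages())[.model_stages])
  m
}

# apply zero_mask rows to a map
.apply_mask <- function(map, mask, kind) {
  if (is.null(mask)) return(map)
  mk <- mask[mask$kind == kind, , drop = FALSE]
  for (i in seq_len(nrow(mk))) {
    srows <- if (is.na(mk$species[i])) 1:4 else species_codes()[[mk$species[i]]]
    st <- mk$stage[i]
    scols <- if (is.na(st)) 1:4 else {
      ord <- if (is.character(st)) caste_stages()[[st]] else as.integer(st)
      if (is.na(ord) || ord < 2L || ord > 5L) {
        stop("zero_mask stage must be a modelled stage (2-5)", call. = FALSE)
      }
      ord - 1L
    }
    map[srows, scols] <- 0L
  }
  map
}

# renumber maps so free loss parameters are 1..nl and gains nl+1..nl+ng,
# and attach parameter bookkeeping
.normalize_spec <- function(spec) {
  lm <- spec$loss_map %||% .apply_mask(.pattern_map(spec$loss_pattern),
                                       spec$zero_mask, "loss")
  gm <- spec$gain_map %||% .apply_mask(.pattern_map(spec$gain_pattern),
                                       spec$zero_mask, "gain")
  relabel <- function(m) {
    ids <- sort(unique(m[m > 0L]))
    m[] <- ifelse(m > 0L, match(m, ids), 0L)
    m
  }
  lm <- relabel(lm); gm <- relabel(gm)
  nl <- max(0L, lm); ng <- max(0L, gm)
  spec$loss_map <- lm
  spec$gain_map <- gm + ifelse(gm > 0L, nl, 0L)
  spec$K <- nl + ng
  spec$par_info <- .par_info(spec)
  spec
}

# human labels for the free parameters, e.g. "a(C,.)" or "b(.,white_soldier)"
.par_info <- function(spec) {
  desc <- function(map, sym, offset) {
    ids <- sort(unique(map[map > 0L]))
    if (!length(ids)) return(NULL)
    out <- lapply(ids, function(id) {
      w <- which(map == id, arr.ind = TRUE)
      sps <- sort(unique(rownames(map)[w[, 1]]))
      sts <- sort(unique(caste_stages()[colnames(map)[w[, 2]]]))
      sp_lab <- if (length(sps) == 4L) "." else paste(sps, collapse = "=")
      st_lab <- if (length(sts) == 4L) "."
                else paste(names(caste_stages())[sts], collapse = "=")
      data.frame(index = id, kind = if (sym == "a") "loss" else "gain",
                 label = sprintf("%s(%s,%s)", sym, sp_lab, st_lab),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  rbind(desc(spec$loss_map, "a", 0L), desc(spec$gain_map, "b", 0L))
}

#' Number of free parameters of a model spec
#' @param spec a [model_spec()].
#' @export
n_free_params <- function(spec) spec$K

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$label, " (K =", x$K, ")\n")
  if (!is.null(x$par_info)) print(x$par_info, row.names = FALSE)
  invisible(x)
}

# materialize a parameter_set from the free-parameter vector (probability
# scale, ordered by parameter index)
.theta_to_params <- function(spec, theta) {
  stopifnot(length(theta) == spec$K)
  fill <- function(map) {
    m <- matrix(0, 4, 4, dimnames = dimnames(map))
    pos <- map > 0L
    m[pos] <- theta[map[pos]]
    m
  }
  parameter_set(fill(spec$loss_map), fill(spec$gain_map), spec = spec)
}

# zero one free parameter (by index) of a spec; returns renormalized spec
.spec_zero <- function(spec, index) {
  spec$loss_map[spec$loss_map == index] <- 0L
  spec$gain_map[spec$gain_map == index] <- 0L
  spec$label <- .refined_label(spec$label)
  .normalize_spec(spec)
}

# tie two free parameters of the same kind; returns renormalized spec
.spec_tie <- function(spec, index_a, index_b) {
  keep <- min(index_a, index_b); drop <- max(index_a, index_b)
  spec$loss_map[spec$loss_map == drop] <- keep
  spec$gain_map[spec$gain_map == drop] <- keep
  spec$label <- .refined_label(spec$label)
  .normalize_spec(spec)
}

.refined_label <- function(label) {
  if (grepl(" \\[refined\\]$", label)) label else paste(label, "[refined]")
}
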