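#' Caste and stage vocabulary
#'
#' The developmental compartments of a *Cubitermes* colony are ordered
#' queen (1) -> larva (2) -> worker (3) -> white soldier (4) -> mature
#' soldier (5).  White soldiers (pre-soldiers) are the transitional molt
#' stage between workers and mature soldiers.  Kings are sampled and
#' reported alongside queens but sit outside the maternal-transmission
#' recursion; they are carried as a metadata stage with no ordinal.
#'
#' @return `caste_stages()` returns a named integer vector mapping stage
#'   labels to ordinals 1-5.  `species_codes()` returns the named vector
#'   of the four cryptic species codes (A-D) mapped to indices 1-4.
#' @export
caste_stages <- function() {
  c(queen = 1L, larva = 2L, worker = 3L, white_soldier = 4L, soldier = 5L)
}

#' @rdname caste_stages
#' @export
species_codes <- function() {
  c(A = 1L, B = 2L, C = 3L, D = 4L)
}

# stages that enter the loss/gain recursion likelihood
.model_stages <- 2:5

#' Convert between stage labels and ordinals
#'
#' Accepts either representation (the colony CSV dialect allows both) and
#' returns the canonical text label.  `"king"` is passed through unchanged.
#'
#' @param stage character or integer vector of stage labels/ordinals.
#' @return character vector of canonical labels.
#' @keywords internal
stage_label <- function(stage) {
  cs <- caste_stages()
  out <- character(length(stage))
  for (i in seq_along(stage)) {
    s <- stage[[i]]
    if (is.na(s)) stop("missing stage value", call. = FALSE)
    s_chr <- as.character(s)
    if (s_chr %in% names(cs) || identical(s_chr, "king")) {
      out[i] <- s_chr
    } else if (s_chr %in% as.character(cs)) {
      out[i] <- names(cs)[match(as.integer(s_chr), cs)]
    } else {
      stop("unknown stage label or ordinal: '", s_chr, "'", call. = FALSE)
    }
  }
  out
}

#' @keywords internal
stage_ordinal <- function(stage_labels) {
  cs <- caste_stages()
  ifelse(stage_labels == "king", NA_integer_, cs[stage_labels])
}
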