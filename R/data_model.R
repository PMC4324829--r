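#' Load a colony infection-count table
#'
#' Reads the package's colony CSV dialect: comma-separated, UTF-8, header
#' required, columns `species, colony, stage, n_tested, n_infected`.  The
#' `stage` column may use either text labels (`queen, king, larva, worker,
#' white_soldier, soldier`) or ordinals 1-5; canonical output uses text.
#' Rows with `n_tested = 0` (stages not sampled in a colony) are dropped
#' with a warning.
#'
#' @param path path to a CSV file.
#' @param strict if `TRUE` (default) any malformed row aborts with an error
#'   naming the row; if `FALSE` malformed rows are dropped with a warning.
#' @return a colony dataset: a `data.frame` with columns `species`,
#'   `colony`, `stage`, `stage_ordinal`, `n_tested`, `n_infected` and a
#'   `provenance` attribute.
#' @seealso [table1_fixture()] for the embedded 15-colony dataset,
#'   [pool()] for aggregation.
#' @export
load_colony_csv <- function(path, strict = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("species", "colony", "stage", "n_tested", "n_infected")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("colony CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("colony CSV contains no data rows", call. = FALSE)

  bad <- function(i, msg) {
    full <- sprintf("row %d: %s", i, msg)
    if (strict) stop(full, call. = FALSE)
    warning(full, " (row dropped)", call. = FALSE)
    FALSE
  }
  keep <- rep(TRUE, nrow(raw))
  stage_lab <- character(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    ok <- TRUE
    if (!raw$species[i] %in% names(species_codes())) {
      ok <- bad(i, paste0("unknown species code '", raw$species[i], "'"))
    }
    lab <- tryCatch(stage_label(raw$stage[i]), error = function(e) NULL)
    if (ok && is.null(lab)) {
      ok <- bad(i, paste0("unknown stage '", raw$stage[i], "'"))
    } else if (ok) {
      stage_lab[i] <- lab
    }
    nt <- suppressWarnings(as.integer(raw$n_tested[i]))
    ni <- suppressWarnings(as.integer(raw$n_infected[i]))
    if (ok && (is.na(nt) || is.na(ni) || nt < 0L || ni < 0L)) {
      ok <- bad(i, "counts must be non-negative integers")
    }
    if (ok && ni > nt) {
      ok <- bad(i, sprintf("n_infected (%d) exceeds n_tested (%d)", ni, nt))
    }
    keep[i] <- ok
  }
  raw <- raw[keep, , drop = FALSE]
  stage_lab <- stage_lab[keep]

  empty <- raw$n_tested == 0L
  if (any(empty)) {
    warning(sum(empty), " row(s) with n_tested = 0 dropped", call. = FALSE)
    raw <- raw[!empty, , drop = FALSE]
    stage_lab <- stage_lab[!empty]
  }

  out <- data.frame(
    species = raw$species,
    colony = raw$colony,
    stage = stage_lab,
    stage_ordinal = stage_ordinal(stage_lab),
    n_tested = as.integer(raw$n_tested),
    n_infected = as.integer(raw$n_infected),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(out[, c("colony", "stage")])
  if (any(dup)) {
    stop("duplicate (colony, stage) cell(s): ",
         paste(unique(paste(out$colony[dup], out$stage[dup])), collapse = ", "),
         call. = FALSE)
  }
  attr(out, "provenance") <- paste0("loaded from ", path)
  out
}

#' Write a colony dataset back to CSV
#'
#' Inverse of [load_colony_csv()]; stage labels are written as text.
#'
#' @param data a colony dataset.
#' @param path output path.
#' @export
write_colony_csv <- function(data, path) {
  utils::write.csv(
    data[, c("species", "colony", "stage", "n_tested", "n_infected")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

# Printed screening percentages and sample sizes for the 15 colonies.
# Infected counts are not printed per cell, only the percentage and n;
# they are reconstructed as round(pct/100 * n).  The reconstruction is
# over-determined by the printed per-colony totals, against which it is
# asserted below (all 15 reconcile exactly).
.table1_cells <- function() {
  txt <- "
species colony stage pct n
A T7  queen 100 1
A T7  larva 83 6
A T7  worker 70 10
A T7  white_soldier 50 4
A T7  soldier 100 6
A T16 queen 100 1
A T16 larva 87 15
A T16 worker 90 10
A T16 white_soldier 100 1
A T16 soldier 40 10
A T42 queen 100 1
A T42 king 100 1
A T42 larva 48 21
A T42 worker 40 10
A T42 white_soldier 75 4
A T42 soldier 80 20
B T5  queen 100 1
B T5  king 0 1
B T5  worker 0 15
B T5  white_soldier 80 5
B T5  soldier 0 3
B T26 queen 100 1
B T26 worker 0 9
B T26 white_soldier 75 4
B T26 soldier 10 10
B T34 queen 100 1
B T34 larva 68 19
B T34 worker 80 15
B T34 soldier 87 15
B T37 queen 100 1
B T37 king 100 1
B T37 worker 0 20
B T37 white_soldier 20 5
B T37 soldier 7 15
B T38 queen 100 1
B T38 king 100 1
B T38 larva 21 19
B T38 worker 25 12
B T38 white_soldier 100 1
B T38 soldier 50 14
C T17 queen 100 1
C T17 worker 88 16
C T17 white_soldier 100 1
C T17 soldier 0 1
C T24 queen 100 1
C T24 king 100 1
C T24 larva 64 25
C T24 worker 30 10
C T24 white_soldier 100 2
C T24 soldier 30 10
C T31 larva 90 10
C T31 worker 11 9
C T31 white_soldier 70 30
C T31 soldier 17 6
C T45 larva 70 10
C T45 worker 0 3
C T45 white_soldier 100 2
C T45 soldier 0 5
C T46 queen 100 1
C T46 larva 56 9
C T46 worker 0 10
C T46 white_soldier 67 3
C T46 soldier 0 10
C TX  queen 100 1
C TX  king 0 1
C TX  larva 80 10
C TX  worker 10 10
C TX  white_soldier 90 10
C TX  soldier 0 10
D TD1 queen 100 1
D TD1 king 100 1
D TD1 worker 10 10
D TD1 white_soldier 100 5
D TD1 soldier 40 10
"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

# printed per-colony totals (infected / tested) used to audit the
# reconstruction
.table1_totals <- function() {
  data.frame(
    colony = c("T7", "T16", "T42", "T5", "T26", "T34", "T37", "T38",
               "T17", "T24", "T31", "T45", "T46", "TX", "TD1"),
    infected = c(21L, 28L, 35L, 5L, 5L, 39L, 4L, 17L, 16L, 26L, 32L, 9L,
                 8L, 19L, 12L),
    tested = c(27L, 37L, 57L, 25L, 24L, 50L, 42L, 48L, 19L, 49L, 55L, 20L,
               33L, 42L, 27L),
    stringsAsFactors = FALSE
  )
}

#' The embedded 15-colony Wolbachia screening dataset
#'
#' Per-colony, per-stage infection counts for 555 individuals screened by
#' PCR across 15 *Cubitermes* colonies belonging to four cryptic species
#' (A-D).  Per-cell infected counts are reconstructed from the printed
#' percentage and sample size as `round(pct/100 * n)`; the reconstruction
#' is validated against all 15 printed per-colony totals at build time
#' (overall: 276/555 infected, 49.73%).
#'
#' Queens are stage-1 cells; kings are kept as a metadata stage outside
#' the caste recursion.
#'
#' @return a colony dataset (see [load_colony_csv()] for the format).
#' @export
table1_fixture <- function() {
  cells <- .table1_cells()
  k <- as.integer(round(cells$pct / 100 * cells$n))
  out <- data.frame(
    species = cells$species,
    colony = cells$colony,
    stage = cells$stage,
    stage_ordinal = stage_ordinal(cells$stage),
    n_tested = as.integer(cells$n),
    n_infected = k,
    stringsAsFactors = FALSE
  )
  # audit against the printed row totals
  tot <- .table1_totals()
  got_k <- tapply(out$n_infected, out$colony, sum)[tot$colony]
  got_n <- tapply(out$n_tested, out$colony, sum)[tot$colony]
  stopifnot(identical(as.integer(got_k), tot$infected),
            identical(as.integer(got_n), tot$tested))
  attr(out, "provenance") <- "embedded 15-colony Cubitermes screening table"
  out
}

#' Pool colony counts into species x stage or colony x stage cells
#'
#' Aggregation underlying both the descriptive caste rates and the
#' binomial likelihood.  Cells absent from every colony (e.g. larvae of
#' species D) are absent from the result, not zero-filled.
#'
#' @param data a colony dataset.
#' @param mode `"by_species_stage"` (sum counts over the colonies of each
#'   species) or `"by_colony_stage"` (one cell per colony x stage, i.e.
#'   the input cells of the modelled stages).
#' @param include_stages character vector of stage labels to keep
#'   (default: the four offspring castes entering the recursion).
#' @return a `data.frame` of cells with columns `species`, (`colony`,)
#'   `stage`, `stage_ordinal`, `n`, `k` and attribute `aggregation_mode`.
#' @export
pool <- function(data,
                 mode = c("by_species_stage", "by_colony_stage"),
                 include_stages = c("larva", "worker", "white_soldier", "soldier")) {
  mode <- match.arg(mode)
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  d <- data[data$stage %in% include_stages, , drop = FALSE]
  if (nrow(d) == 0L) stop("no cells left after stage filtering", call. = FALSE)
  if (mode == "by_species_stage") {
    agg <- stats::aggregate(cbind(n = n_tested, k = n_infected) ~ species + stage,
                            data = d, FUN = sum)
  } else {
    agg <- data.frame(species = d$species, colony = d$colony, stage = d$stage,
                      n = d$n_tested, k = d$n_infected,
                      stringsAsFactors = FALSE)
  }
  agg$stage_ordinal <- stage_ordinal(agg$stage)
  agg <- agg[order(agg$species, agg$stage_ordinal), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "aggregation_mode") <- mode
  agg
}
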