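#' Stage-to-stage infection recursions
#'
#' One caste transition under the two variants of the loss/gain model.
#' Let `I_prev` be the infection rate at the previous stage, `a` the
#' probability that an infected individual loses the symbiont over the
#' transition and `b` the probability that an uninfected individual gains
#' it.
#'
#' * `step_eq1()` applies the gain to the individuals that were uninfected
#'   at the *previous* stage:
#'   `I = (1 - a) I_prev + b (1 - I_prev) = I_prev (1 - a - b) + b`.
#' * `step_eq2()` lets the gain occur *during* the current stage, i.e. it
#'   applies to everyone uninfected after the loss has acted:
#'   `I = (1 - a) I_prev (1 - b) + b`.
#'
#' Both maps send `[0,1]^3` into `[0,1]` exactly (each is a convex
#' combination of probabilities), so no clamping is required.  They agree
#' whenever `a = 0` or `b = 0`, and `step_eq2 >= step_eq1` otherwise,
#' because the gain in the second variant acts on a pool enlarged by the
#' just-lost individuals.
#'
#' @param I_prev infection rate at the previous stage, in `[0,1]`.
#' @param a per-transition loss probability, in `[0,1]`.
#' @param b per-transition gain probability, in `[0,1]`.
#' @return the infection rate at the current stage.  All three arguments
#'   are vectorised together.
#' @export
step_eq1 <- function(I_prev, a, b) {
  .check_prob(I_prev, "I_prev"); .check_prob(a, "a"); .check_prob(b, "b")
  I_prev * (1 - a - b) + b
}

#' @rdname step_eq1
#' @export
step_eq2 <- function(I_prev, a, b) {
  .check_prob(I_prev, "I_prev"); .check_prob(a, "a"); .check_prob(b, "b")
  I_prev * (1 - a) * (1 - b) + b
}

.check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("'", name, "' must lie in [0,1]", call. = FALSE)
  }
  invisible(x)
}

#' Loss/gain parameter sets
#'
#' A parameter set holds the loss matrix `a(s,c)` and gain matrix `b(s,c)`
#' for the four species (rows A-D) and the four modelled transitions into
#' stages 2-5 (columns larva, worker, white_soldier, soldier).  Scalars
#' and vectors are recycled: a length-4 `loss` is interpreted per species,
#' a length-4 `gain` per stage (the orientations used by the sharing
#' patterns `a(s,.)` and `b(.,c)`).
#'
#' @param loss loss probabilities: scalar, per-species length-4 vector, or
#'   full 4x4 matrix (species x stage).
#' @param gain gain probabilities: scalar, per-stage length-4 vector, or
#'   full 4x4 matrix.
#' @param spec optional [model_spec()] back-reference recording the tying
#'   structure that generated the values.
#' @return an object of class `parameter_set` with elements `loss` and
#'   `gain` (4x4 matrices) and `spec`.
#' @export
parameter_set <- function(loss, gain, spec = NULL) {
  expand <- function(x, per_species) {
    if (is.matrix(x)) {
      stopifnot(dim(x) == c(4L, 4L))
      m <- x
    } else if (length(x) == 1L) {
      m <- matrix(x, 4L, 4L)
    } else if (length(x) == 4L) {
      m <- if (per_species) matrix(x, 4L, 4L) else matrix(x, 4L, 4L, byrow = TRUE)
    } else {
      stop("parameter values must be scalar, length 4, or a 4x4 matrix",
           call. = FALSE)
    }
    .check_prob(m, "parameter")
    dimnames(m) <- list(names(species_codes()),
                        names(caste_stages())[.model_stages])
    m
  }
  structure(
    list(loss = expand(loss, per_species = TRUE),
         gain = expand(gain, per_species = FALSE),
         spec = spec),
    class = "parameter_set"
  )
}

#' Expected infection trajectory of one species
#'
#' Applies the chosen step recursion from the queen (stage 1) through the
#' caste sequence to the mature soldier (stage 5).  The default initial
#' rate is 1: queens are the infection source under maternal inheritance
#' and every sampled queen in the embedded dataset was infected (13/13).
#'
#' @param params a [parameter_set()].
#' @param species species code (`"A"`-`"D"`) or index 1-4.
#' @param equation which recursion to use, `1` or `2` (see [step_eq1()]).
#' @param initial_rate infection rate at stage 1 (queen), default 1.
#' @return a `data.frame` with columns `species`, `stage`, `stage_ordinal`
#'   and `rate`, five rows (stages 1-5).
#' @export
infection_trajectory <- function(params, species, equation = 2,
                                 initial_rate = 1.0) {
  stopifnot(inherits(params, "parameter_set"))
  .check_prob(initial_rate, "initial_rate")
  s <- if (is.character(species)) {
    match(species, names(species_codes()))
  } else {
    as.integer(species)
  }
  if (is.na(s) || s < 1L || s > 4L) stop("unknown species", call. = FALSE)
  if (!equation %in% c(1, 2)) stop("equation must be 1 or 2", call. = FALSE)
  a <- params$loss[s, ]
  b <- params$gain[s, ]
  if (any(is.na(a)) || any(is.na(b))) {
    stop("parameter set incomplete for species ", names(species_codes())[s],
         call. = FALSE)
  }
  rates <- numeric(5L)
  rates[1L] <- initial_rate
  step <- if (equation == 1) step_eq1 else step_eq2
  for (j in 1:4) rates[j + 1L] <- step(rates[j], a[j], b[j])
  data.frame(
    species = names(species_codes())[s],
    stage = names(caste_stages()),
    stage_ordinal = 1:5,
    rate = rates,
    stringsAsFactors = FALSE
  )
}

#' Counterfactual trajectory with all gains suppressed
#'
#' The same recursion as [infection_trajectory()] but with every gain
#' parameter forced to zero, isolating the stochastic-loss component.
#' Comparing the two trajectories quantifies how much of the observed
#' white-soldier prevalence requires horizontal (re)acquisition.
#'
#' @inheritParams infection_trajectory
#' @export
counterfactual_no_gain <- function(params, species, equation = 2,
                                   initial_rate = 1.0) {
  nog <- parameter_set(params$loss, matrix(0, 4, 4), spec = params$spec)
  infection_trajectory(nog, species, equation, initial_rate)
}

#' Tidy trajectory table for all species
#'
#' @param params a [parameter_set()].
#' @param equation recursion variant.
#' @param initial_rate stage-1 rate.
#' @return long `data.frame` (species, stage, stage_ordinal, rate,
#'   variant) with `variant` in `{"with_gain", "no_gain"}`, exportable as
#'   tidy CSV.
#' @export
trajectory_table <- function(params, equation = 2, initial_rate = 1.0) {
  out <- lapply(names(species_codes()), function(sp) {
    with_g <- infection_trajectory(params, sp, equation, initial_rate)
    no_g <- counterfactual_no_gain(params, sp, equation, initial_rate)
    with_g$variant <- "with_gain"
    no_g$variant <- "no_gain"
    rbind(with_g, no_g)
  })
  do.call(rbind, out)
}
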