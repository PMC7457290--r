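# Two-phase Markov cohort model: weekly cycles for an initial six-week
# period, twelve-week cycles thereafter, with an absorbing death state fed
# by background mortality, accumulating quality-adjusted life years.

#' Build the two-phase cycle schedule
#'
#' The model runs six one-week cycles (the initial treatment phase) followed
#' by twelve-week maintenance cycles, so admissible horizons are
#' `6 + 12 m` weeks.
#'
#' @param horizon_weeks Total model horizon in weeks; must be at least 6
#'   with `(horizon_weeks - 6)` divisible by 12 (e.g. 6, 54, 258).
#' @return A data frame with one row per cycle: `cycle`, `phase`
#'   (`"initial"` or `"maintenance"`), `length_weeks` and `week_end`
#'   (cumulative weeks at the end of the cycle).
#' @examples
#' build_schedule(54)   # 6 weekly + 4 twelve-week cycles
#' @export
build_schedule <- function(horizon_weeks) {
  if (length(horizon_weeks) != 1L || horizon_weeks < 6 ||
      (horizon_weeks - 6) %% 12 != 0) {
    stop("horizon must be 6 + 12*m weeks for integer m >= 0; got ",
         horizon_weeks, call. = FALSE)
  }
  m <- (horizon_weeks - 6) / 12
  len <- c(rep(1, 6), rep(12, m))
  data.frame(
    cycle = seq_along(len),
    phase = rep(c("initial", "maintenance"), c(6, m)),
    length_weeks = len,
    week_end = cumsum(len)
  )
}

#' Raise a weekly transition matrix to a longer cycle length
#'
#' Under time homogeneity within a phase, the c-week transition matrix is
#' the c-th power of the weekly matrix.
#'
#' @param weekly_tpm Row-stochastic K x K matrix of weekly transition
#'   probabilities.
#' @param cycle_length_weeks Positive integer cycle length.
#' @return The matrix power, again row-stochastic.
#' @examples
#' m <- matrix(c(0.9, 0.1, 0, 1), 2, byrow = TRUE)
#' weekly_to_cycle_matrix(m, 2)
#' @export
weekly_to_cycle_matrix <- function(weekly_tpm, cycle_length_weeks) {
  check_stochastic(weekly_tpm, what = "weekly_tpm")
  if (cycle_length_weeks < 1 || cycle_length_weeks != round(cycle_length_weeks)) {
    stop("cycle_length_weeks must be a positive integer")
  }
  out <- diag(nrow(weekly_tpm))
  dimnames(out) <- dimnames(weekly_tpm)
  for (i in seq_len(cycle_length_weeks)) out <- out %*% weekly_tpm
  out
}

#' Embed background mortality as an absorbing death state
#'
#' Scales each living row of the K-state matrix by `1 - p_death` and routes
#' the removed mass to an appended absorbing death column, implementing the
#' assumption that background mortality is independent of the health-state
#' process and identical across treatment arms.
#'
#' @param tpm Row-stochastic K x K matrix over the living states.
#' @param p_death_cycle Probability of death within one cycle, in `[0, 1)`.
#' @return A (K+1) x (K+1) row-stochastic matrix whose last state ("death")
#'   is absorbing.
#' @examples
#' apply_mortality(diag(2), 0.5)
#' @export
apply_mortality <- function(tpm, p_death_cycle) {
  check_stochastic(tpm, what = "tpm")
  if (!is.numeric(p_death_cycle) || p_death_cycle < 0 || p_death_cycle >= 1) {
    stop("p_death_cycle must lie in [0, 1)")
  }
  K <- nrow(tpm)
  labels <- rownames(tpm) %||% as.character(seq_len(K))
  out <- rbind(cbind(tpm * (1 - p_death_cycle), rep(p_death_cycle, K)),
               c(rep(0, K), 1))
  dimnames(out) <- list(c(labels, "death"), c(labels, "death"))
  out
}

#' Per-cycle death probability from an annual mortality rate
#'
#' Converts an annual death probability to the probability of dying within a
#' cycle of `cycle_weeks` weeks under a constant hazard:
#' `1 - (1 - annual)^(cycle_weeks / 52)`.
#'
#' @param annual Annual probability of death in `[0, 1)`.
#' @param cycle_weeks Cycle length in weeks (vectorised).
#' @return Per-cycle death probabilities.
#' @examples
#' cycle_mortality(0.01, c(1, 12))
#' @export
cycle_mortality <- function(annual, cycle_weeks) {
  if (annual < 0 || annual >= 1) stop("annual must lie in [0, 1)")
  1 - (1 - annual)^(cycle_weeks / 52)
}

#' Specify a Markov cohort model run
#'
#' Collects and validates the configuration shared by both treatment arms:
#' state utilities, background mortality, the initial cohort distribution,
#' the horizon and discounting.
#'
#' @param utilities Per-state utility weights (unitless; 1 = full health,
#'   0 = death), one per living state.
#' @param initial_distribution Probability vector over the living states at
#'   week 0; must sum to 1.
#' @param horizon_weeks Model horizon; see [build_schedule()].
#' @param mortality Either a single per-cycle death probability applied to
#'   every cycle, or a vector with one probability per cycle of the
#'   schedule (use [cycle_mortality()] to derive these from an annual rate,
#'   since weekly and twelve-week cycles need different values).  Default 0.
#' @param discount_rate Annual discount rate on QALYs (default 0; the
#'   54-week base case is short enough that discounting is conventionally
#'   omitted).
#' @param half_cycle_correction If `TRUE`, each cycle's utility uses the
#'   average of the start- and end-of-cycle occupancies instead of the
#'   end-of-cycle occupancy.  Default `FALSE` (membership counted after the
#'   transition).
#' @param labels Optional state labels.
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec(utilities = c(1, 0.5), initial_distribution = c(1, 0),
#'             horizon_weeks = 54)
#' @export
cohort_spec <- function(utilities, initial_distribution, horizon_weeks,
                        mortality = 0, discount_rate = 0,
                        half_cycle_correction = FALSE,
                        labels = NULL) {
  K <- length(utilities)
  if (K < 1L) stop("need at least one living state")
  if (any(!is.finite(utilities))) stop("utilities must be finite")
  if (length(initial_distribution) != K) {
    stop("initial_distribution length must match utilities")
  }
  if (any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-9) {
    stop("initial_distribution must be non-negative and sum to 1")
  }
  sched <- build_schedule(horizon_weeks)
  if (!length(mortality) %in% c(1L, nrow(sched))) {
    stop("mortality must be a scalar or one value per cycle (",
         nrow(sched), " cycles)")
  }
  if (any(mortality < 0) || any(mortality >= 1)) {
    stop("mortality probabilities must lie in [0, 1)")
  }
  if (discount_rate < 0) stop("discount_rate must be non-negative")
  if (is.null(labels)) labels <- as.character(seq_len(K))
  structure(list(utilities = as.numeric(utilities),
                 initial_distribution = as.numeric(initial_distribution),
                 horizon_weeks = horizon_weeks,
                 schedule = sched,
                 mortality = rep(mortality, length.out = nrow(sched)),
                 discount_rate = discount_rate,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 labels = labels),
            class = "cohort_spec")
}

#' Run the Markov cohort model
#'
#' Propagates the initial cohort distribution through the cycle schedule,
#' applying the phase-1 matrix during the weekly cycles and the phase-2
#' matrix during the twelve-week cycles, with per-cycle background mortality
#' routed to an absorbing death state.  The per-cycle QALY contribution is
#' `sum(occupancy * utility) * cycle_length / 52`, discounted at the annual
#' rate to the end of the cycle; death accrues zero utility.
#'
#' @param spec A [cohort_spec()].
#' @param phase1_tpm Weekly K x K transition matrix used during the initial
#'   phase.
#' @param phase2_tpm Per-twelve-week K x K matrix for the maintenance phase.
#'   Defaults to `weekly_to_cycle_matrix(phase1_tpm, 12)`, i.e. time
#'   homogeneity; supply a separately estimated matrix when maintenance
#'   dynamics differ.
#' @return An object of class `cohort_trajectory`: a data frame with one
#'   row per cycle (plus the week-0 row) holding the occupancy of every
#'   state and of death, the cycle QALY and the cumulative QALY; total QALY
#'   in `attr(, "total_qaly")`.
#' @examples
#' spec <- cohort_spec(utilities = c(1, 0), initial_distribution = c(1, 0),
#'                     horizon_weeks = 6)
#' m <- matrix(c(0.5, 0.5, 0, 1), 2, byrow = TRUE)
#' run_cohort(spec, m)
#' @export
run_cohort <- function(spec, phase1_tpm, phase2_tpm = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  K <- length(spec$utilities)
  check_stochastic(phase1_tpm, what = "phase1_tpm")
  if (nrow(phase1_tpm) != K) stop("phase1_tpm dimension does not match spec")
  if (is.null(phase2_tpm)) {
    phase2_tpm <- weekly_to_cycle_matrix(phase1_tpm, 12)
  }
  check_stochastic(phase2_tpm, what = "phase2_tpm")
  if (nrow(phase2_tpm) != K) stop("phase2_tpm dimension does not match spec")

  sched <- spec$schedule
  occ <- c(spec$initial_distribution, 0)  # death appended
  u <- c(spec$utilities, 0)
  traj <- matrix(NA_real_, nrow(sched) + 1L, K + 1L)
  traj[1L, ] <- occ
  cycle_qaly <- numeric(nrow(sched))
  for (t in seq_len(nrow(sched))) {
    base <- if (sched$phase[t] == "initial") phase1_tpm else phase2_tpm
    M <- apply_mortality(base, spec$mortality[t])
    occ_new <- as.numeric(occ %*% M)
    occ_util <- if (spec$half_cycle_correction) (occ + occ_new) / 2 else occ_new
    disc <- (1 + spec$discount_rate)^(-sched$week_end[t] / 52)
    cycle_qaly[t] <- sum(occ_util * u) * sched$length_weeks[t] / 52 * disc
    occ <- occ_new
    traj[t + 1L, ] <- occ
  }
  out <- data.frame(
    cycle = c(0L, sched$cycle),
    week = c(0, sched$week_end),
    traj,
    cycle_qaly = c(0, cycle_qaly),
    cum_qaly = c(0, cumsum(cycle_qaly))
  )
  names(out)[3:(K + 3L)] <- c(paste0("state_", spec$labels), "death")
  attr(out, "total_qaly") <- sum(cycle_qaly)
  attr(out, "spec") <- spec
  class(out) <- c("cohort_trajectory", "data.frame")
  out
}

#' Total QALYs of a cohort trajectory
#'
#' @param trajectory A `cohort_trajectory` from [run_cohort()].
#' @return The cumulative discounted QALY over the horizon.
#' @export
total_qaly <- function(trajectory) {
  stopifnot(inherits(trajectory, "cohort_trajectory"))
  attr(trajectory, "total_qaly")
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  spec <- attr(x, "spec")
  cat("Markov cohort trajectory: ", length(spec$labels), " states + death, ",
      spec$horizon_weeks, " weeks (", nrow(x) - 1L, " cycles)\n", sep = "")
  cat(sprintf("Total QALYs: %.4f\n", attr(x, "total_qaly")))
  cat(sprintf("Final death occupancy: %.4f\n", x$death[nrow(x)]))
  invisible(x)
}

#' Plot state occupancy over time
#'
#' @param x A `cohort_trajectory`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cohort_trajectory <- function(x, ...) {
  spec <- attr(x, "spec")
  cols <- c(paste0("state_", spec$labels), "death")
  graphics::matplot(x$week, as.matrix(x[, cols]), type = "l", lty = 1,
                    xlab = "week", ylab = "occupancy", ...)
  graphics::legend("topright", legend = cols, col = seq_along(cols),
                   lty = 1, cex = 0.7)
  invisible(x)
}

#' Incremental QALYs between two treatment arms
#'
#' Runs the cohort model under a shared specification (same utilities,
#' mortality and initial distribution) with arm-specific transition
#' matrices and returns the QALY difference, first arm minus second.
#'
#' @param spec A [cohort_spec()] shared by both arms.
#' @param arm_a,arm_b Either a single weekly matrix (phase 2 defaults to its
#'   twelfth power) or a list `list(phase1 = , phase2 = )`.
#' @return A list with `qaly_a`, `qaly_b` and `difference = qaly_a - qaly_b`.
#' @export
incremental_qaly <- function(spec, arm_a, arm_b) {
  get_phases <- function(arm) {
    if (is.list(arm) && !is.null(arm$phase1)) {
      list(p1 = arm$phase1, p2 = arm$phase2)
    } else {
      list(p1 = arm, p2 = NULL)
    }
  }
  a <- get_phases(arm_a)
  b <- get_phases(arm_b)
  qa <- total_qaly(run_cohort(spec, a$p1, a$p2))
  qb <- total_qaly(run_cohort(spec, b$p1, b$p2))
  list(qaly_a = qa, qaly_b = qb, difference = qa - qb)
}
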