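# Probabilistic sensitivity analysis: propagate posterior uncertainty in
# both arms' transition matrices through the cohort model to a distribution
# of incremental QALYs.

#' Probabilistic sensitivity analysis over posterior transition matrices
#'
#' For each run, draws one transition matrix per arm (and per phase) from
#' the row-wise Dirichlet posteriors, runs the cohort model for both arms
#' under the shared specification, and records the incremental QALY.
#' Because estimation is fully Bayesian, this one sampling loop performs
#' both estimation-uncertainty propagation and sensitivity analysis.
#'
#' Source states with zero observations in both arms have, under a shared
#' prior, identical posteriors in the two arms; by default one draw per run
#' is shared between the arms for those rows, so that no spurious
#' between-arm difference is manufactured for states the trial never
#' observed.  Set `share_unobserved = FALSE` for fully independent draws.
#'
#' @param spec A [cohort_spec()] shared by both arms.
#' @param posterior_a,posterior_b A `tpm_fit` with a posterior (weekly
#'   matrix; the maintenance-phase matrix of each draw is its twelfth
#'   power), or a list `list(phase1 = fit, phase2 = fit)` of two fits when
#'   the maintenance phase was estimated separately (the phase-2 draw is
#'   then used as the per-cycle matrix directly).
#' @param n_runs Number of PSA runs (default 1000).
#' @param seed Optional integer seed; the whole run sequence is reproducible
#'   from it.
#' @param share_unobserved Share draws between arms for rows unobserved in
#'   both arms (default `TRUE`).
#' @return An object of class `tpm_psa` with per-run `qaly_a`, `qaly_b`,
#'   `inc_qaly`, plus `n_runs` and `seed`.  See [summary.tpm_psa()].
#' @export
run_psa <- function(spec, posterior_a, posterior_b, n_runs = 1000,
                    seed = NULL, share_unobserved = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (n_runs < 2) stop("n_runs must be at least 2")
  as_phases <- function(p) {
    if (inherits(p, "tpm_fit")) list(phase1 = p, phase2 = NULL)
    else if (is.list(p) && inherits(p$phase1, "tpm_fit")) p
    else stop("posteriors must be tpm_fit objects (or list(phase1=, phase2=))")
  }
  pa <- as_phases(posterior_a)
  pb <- as_phases(posterior_b)
  for (f in c(pa, pb)) {
    if (!is.null(f) && is.null(f$alpha)) {
      stop("trial-only fits carry no posterior; PSA needs a Bayesian fit")
    }
  }
  if (length(pa$phase1$labels) != length(pb$phase1$labels)) {
    stop("arms must share the state space")
  }

  if (!is.null(seed)) set.seed(seed)
  shared <- function(fa, fb) {
    if (is.null(fa) || is.null(fb)) return(logical(0))
    fa$n == 0L & fb$n == 0L &
      rowSums(abs(fa$alpha - fb$alpha)) < 1e-12
  }
  sh1 <- shared(pa$phase1, pb$phase1)
  sh2 <- shared(pa$phase2, pb$phase2)

  qa <- qb <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    d_a1 <- rdirichlet_rows(pa$phase1$alpha)
    d_b1 <- rdirichlet_rows(pb$phase1$alpha)
    if (share_unobserved && any(sh1)) d_b1[sh1, ] <- d_a1[sh1, ]
    if (is.null(pa$phase2)) {
      m_a <- list(phase1 = d_a1, phase2 = weekly_to_cycle_matrix(d_a1, 12))
      m_b <- list(phase1 = d_b1, phase2 = weekly_to_cycle_matrix(d_b1, 12))
    } else {
      d_a2 <- rdirichlet_rows(pa$phase2$alpha)
      d_b2 <- rdirichlet_rows(pb$phase2$alpha)
      if (share_unobserved && any(sh2)) d_b2[sh2, ] <- d_a2[sh2, ]
      m_a <- list(phase1 = d_a1, phase2 = d_a2)
      m_b <- list(phase1 = d_b1, phase2 = d_b2)
    }
    qa[r] <- total_qaly(run_cohort(spec, m_a$phase1, m_a$phase2))
    qb[r] <- total_qaly(run_cohort(spec, m_b$phase1, m_b$phase2))
  }
  structure(list(qaly_a = qa, qaly_b = qb, inc_qaly = qa - qb,
                 n_runs = n_runs, seed = seed),
            class = "tpm_psa")
}

#' Summarise a probabilistic sensitivity analysis
#'
#' @param object A `tpm_psa` from [run_psa()].
#' @param level Central interval coverage (default 0.95).
#' @param file Optional path; if given, the per-run incremental QALYs are
#'   written there as CSV.
#' @param ... Unused.
#' @return A list with `mean`, `sd` (n-1 denominator), `lower`, `upper`
#'   (percentile interval) and `n_runs`.
#' @export
summary.tpm_psa <- function(object, level = 0.95, file = NULL, ...) {
  x <- object$inc_qaly
  if (length(x) < 2) stop("need at least two runs to summarise")
  qs <- stats::quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  if (!is.null(file)) {
    utils::write.csv(data.frame(run = seq_along(x),
                                qaly_a = object$qaly_a,
                                qaly_b = object$qaly_b,
                                inc_qaly = x),
                     file, row.names = FALSE)
  }
  structure(list(mean = mean(x), sd = stats::sd(x),
                 lower = qs[1L], upper = qs[2L],
                 level = level, n_runs = object$n_runs),
            class = "summary.tpm_psa")
}

#' @export
print.summary.tpm_psa <- function(x, ...) {
  cat(sprintf("PSA over %d runs\n", x$n_runs))
  cat(sprintf("  incremental QALY: mean %.4f, SD %.4f\n", x$mean, x$sd))
  cat(sprintf("  central %.0f%% interval: [%.4f, %.4f]\n",
              100 * x$level, x$lower, x$upper))
  invisible(x)
}

#' @export
print.tpm_psa <- function(x, ...) {
  print(summary(x))
  invisible(x)
}
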