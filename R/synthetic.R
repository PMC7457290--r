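# Synthetic-data generators with known ground truth: true transition
# matrices with dominant diagonals, pooled multinomial trial counts, and
# noisy expert quartile assessments, so every pipeline stage can be
# validated end to end without external data.

#' Generate a random "true" transition probability matrix
#'
#' Rows are drawn from Dirichlet distributions centred on a
#' diagonal-weighted base matrix (elevated stay-probabilities, the pattern
#' real weekly health-state matrices show), with `concentration` controlling
#' how tightly the rows cluster around the base.
#'
#' @param K Number of states.
#' @param concentration Positive scalar; row i is drawn from
#'   `Dirichlet(concentration * base_i)`.  Default 30, giving realistic
#'   row-to-row variation around the base.
#' @param stay Base stay-probability on the diagonal (default 0.6, the
#'   order of magnitude seen in weekly severity-state data); off-diagonal
#'   base mass is spread uniformly.
#' @param seed Optional integer seed.
#' @return A K x K row-stochastic matrix.
#' @examples
#' gen_true_tpm(4, seed = 1)
#' @export
gen_true_tpm <- function(K, concentration = 30, stay = 0.6, seed = NULL) {
  if (concentration <= 0) stop("concentration must be positive")
  if (stay <= 0 || stay >= 1) stop("stay must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  base <- matrix((1 - stay) / (K - 1), K, K)
  diag(base) <- stay
  tpm <- rdirichlet_rows(concentration * base)
  dimnames(tpm) <- list(as.character(seq_len(K)), as.character(seq_len(K)))
  tpm
}

#' Simulate pooled trial transition counts from a known matrix
#'
#' Simulates `cohort_size` patients moving through the true weekly matrix
#' for `weeks` steps and pools all one-step transitions into a count table,
#' the same person-week pooling (and the same independence assumption) the
#' multinomial likelihood makes.  Row totals equal the person-weeks spent
#' in each source state; the grand total is `cohort_size * weeks`.
#'
#' @param true_tpm Row-stochastic weekly K x K matrix.
#' @param cohort_size Number of simulated patients.
#' @param weeks Number of weekly steps (default 4, one observation block).
#' @param initial_distribution Probability vector over states at week 0
#'   (default uniform).
#' @param seed Optional integer seed.
#' @param arm Arm label for the returned table.
#' @return A `transition_counts` object.
#' @examples
#' tpm <- gen_true_tpm(3, seed = 1)
#' simulate_trial(tpm, cohort_size = 50, weeks = 4, seed = 2)
#' @export
simulate_trial <- function(true_tpm, cohort_size, weeks = 4,
                           initial_distribution = NULL, seed = NULL,
                           arm = "synthetic") {
  check_stochastic(true_tpm, what = "true_tpm")
  if (cohort_size < 1) stop("cohort_size must be at least 1")
  if (weeks < 1) stop("weeks must be at least 1")
  K <- nrow(true_tpm)
  if (is.null(initial_distribution)) initial_distribution <- rep(1 / K, K)
  if (length(initial_distribution) != K ||
      abs(sum(initial_distribution) - 1) > 1e-9) {
    stop("initial_distribution must be a probability vector over the states")
  }
  if (!is.null(seed)) set.seed(seed)
  # occupancy counts evolve by row-wise multinomial draws; pooling the
  # per-row draws is distributionally identical to tracking patients
  occ <- as.numeric(stats::rmultinom(1, cohort_size, initial_distribution))
  counts <- matrix(0L, K, K)
  for (w in seq_len(weeks)) {
    occ_new <- numeric(K)
    for (i in seq_len(K)) {
      if (occ[i] > 0) {
        tr <- as.numeric(stats::rmultinom(1, occ[i], true_tpm[i, ]))
        counts[i, ] <- counts[i, ] + as.integer(tr)
        occ_new <- occ_new + tr
      }
    }
    occ <- occ_new
  }
  dimnames(counts) <- dimnames(true_tpm)
  count_table(counts, arm = arm)
}

#' Simulate one expert's quartile assessments for a source state
#'
#' Computes the exact marginal beta quartiles implied by a true Dirichlet
#' row (`Beta(alpha_i, alpha0 - alpha_i)` per destination) and perturbs
#' each on the log-odds scale with centred Gaussian noise, which keeps every
#' quartile inside (0, 1) without truncation; the three values of each
#' destination are re-sorted so `q1 < median < q3` always holds.  With
#' `noise_scale = 0` the assessment is exactly coherent and the elicitation
#' pipeline recovers the true row.
#'
#' @param true_alpha_row Positive Dirichlet parameters of the true row.
#' @param noise_scale Standard deviation of the log-odds perturbation
#'   (default 0; 0.1 is a moderately sloppy expert).
#' @param seed Optional integer seed.
#' @return A K x 3 matrix with columns `q1`, `median`, `q3`, suitable for
#'   [elicit_prior()].
#' @examples
#' simulate_expert(c(2, 2, 4))
#' @export
simulate_expert <- function(true_alpha_row, noise_scale = 0, seed = NULL) {
  if (any(true_alpha_row <= 0)) stop("true_alpha_row must be positive")
  if (noise_scale < 0) stop("noise_scale must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  a0 <- sum(true_alpha_row)
  q <- t(vapply(true_alpha_row, function(a) {
    stats::qbeta(c(0.25, 0.5, 0.75), a, a0 - a)
  }, numeric(3L)))
  if (noise_scale > 0) {
    lo <- log(q / (1 - q)) +
      matrix(stats::rnorm(length(q), sd = noise_scale), nrow(q))
    q <- 1 / (1 + exp(-lo))
    q <- t(apply(q, 1L, sort))
  }
  colnames(q) <- c("q1", "median", "q3")
  q
}
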