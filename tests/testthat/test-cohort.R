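test_that("the two-phase schedule covers the horizon exactly", {
  s54 <- build_schedule(54)
  expect_equal(nrow(s54), 10)
  expect_equal(sum(s54$length_weeks), 54)
  expect_equal(s54$length_weeks, c(rep(1, 6), rep(12, 4)))
  expect_equal(s54$phase, c(rep("initial", 6), rep("maintenance", 4)))

  s258 <- build_schedule(258)
  expect_equal(nrow(s258), 27)
  expect_equal(sum(s258$length_weeks), 258)

  expect_equal(build_schedule(6)$phase, rep("initial", 6))
  expect_error(build_schedule(55), "6 \\+ 12")
  expect_error(build_schedule(5), "6 \\+ 12")
})

test_that("weekly matrices power up to longer cycles", {
  m <- matrix(c(0.9, 0.1, 0, 1), 2, byrow = TRUE)
  expect_equal(weekly_to_cycle_matrix(m, 1), m)
  expect_equal(weekly_to_cycle_matrix(diag(3), 12), diag(3))
  expect_equal(weekly_to_cycle_matrix(m, 2),
               matrix(c(0.81, 0.19, 0, 1), 2, byrow = TRUE))
  set.seed(1)
  r <- rgamma(9, 1); r <- matrix(r, 3) / rowSums(matrix(r, 3))
  expect_true(all(abs(rowSums(weekly_to_cycle_matrix(r, 12)) - 1) < 1e-12))
  expect_error(weekly_to_cycle_matrix(matrix(1, 2, 2), 2), "sum to 1")
})

test_that("mortality embeds as an absorbing death state", {
  out <- apply_mortality(diag(2), 0.5)
  expect_equal(unname(out),
               matrix(c(0.5, 0, 0.5, 0, 0.5, 0.5, 0, 0, 1), 3, byrow = TRUE))
  m0 <- apply_mortality(diag(2), 0)
  expect_equal(m0[1:2, 3], c(0, 0), ignore_attr = TRUE)
  set.seed(2)
  r <- rgamma(16, 1); r <- matrix(r, 4) / rowSums(matrix(r, 4))
  out2 <- apply_mortality(r, 0.01)
  expect_true(all(abs(rowSums(out2) - 1) < 1e-12))
  expect_equal(out2[5, ], c(rep(0, 4), 1), ignore_attr = TRUE)
  expect_error(apply_mortality(diag(2), 1), "\\[0, 1\\)")
})

test_that("annual mortality converts to per-cycle probabilities", {
  expect_equal(cycle_mortality(0.01, 52), 0.01)
  expect_equal(cycle_mortality(0.01, c(1, 12)),
               1 - (1 - 0.01)^(c(1, 12) / 52))
  expect_equal(cycle_mortality(0, 12), 0)
})

test_that("a single healthy state accrues horizon/52 QALYs", {
  spec <- cohort_spec(utilities = c(1, 0), initial_distribution = c(1, 0),
                      horizon_weeks = 54)
  id <- diag(2)
  expect_equal(total_qaly(run_cohort(spec, id)), 54 / 52)
  spec0 <- cohort_spec(utilities = c(0, 0), initial_distribution = c(1, 0),
                       horizon_weeks = 54)
  set.seed(3)
  r <- rgamma(4, 1); r <- matrix(r, 2) / rowSums(matrix(r, 2))
  expect_equal(total_qaly(run_cohort(spec0, r)), 0)
})

test_that("the toy decay chain matches a hand-rolled recursion", {
  # start in state 1, leave with probability 0.5 each week, utilities (1, 0):
  # state-1 occupancy after t cycles is 0.5^t, each week worth 1/52
  spec <- cohort_spec(utilities = c(1, 0), initial_distribution = c(1, 0),
                      horizon_weeks = 6)
  m <- matrix(c(0.5, 0.5, 0, 1), 2, byrow = TRUE)
  traj <- run_cohort(spec, m)
  expect_equal(traj$state_1[-1], 0.5^(1:6))
  expect_equal(total_qaly(traj), sum(0.5^(1:6)) / 52)
  # half-cycle correction averages adjacent occupancies
  spec_hc <- cohort_spec(utilities = c(1, 0), initial_distribution = c(1, 0),
                         horizon_weeks = 6, half_cycle_correction = TRUE)
  occ <- 0.5^(0:6)
  expect_equal(total_qaly(run_cohort(spec_hc, m)),
               sum((occ[-7] + occ[-1]) / 2) / 52)
})

test_that("occupancy is conserved and death is monotone on the case study", {
  prior <- case_prior()
  fit <- fit_tpm(case_counts("risperidone"), strategy = "informative",
                 prior = prior)
  spec <- example_spec(horizon_weeks = 54,
                       mortality = cycle_mortality(0.02, c(rep(1, 6), rep(12, 4))))
  traj <- run_cohort(spec, coef(fit))
  occ <- as.matrix(traj[, c(paste0("state_", 1:8), "death")])
  expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
  expect_true(all(diff(traj$death) >= -1e-12))
  expect_lte(total_qaly(traj), 54 / 52 * max(spec$utilities) + 1e-12)
})

test_that("discounting shrinks QALYs at positive rates", {
  spec0 <- example_spec(horizon_weeks = 54)
  spec3 <- example_spec(horizon_weeks = 54, discount_rate = 0.03)
  fit <- fit_tpm(case_counts("risperidone"), strategy = "vague")
  expect_lt(total_qaly(run_cohort(spec3, coef(fit))),
            total_qaly(run_cohort(spec0, coef(fit))))
})

test_that("incremental QALYs are zero for identical arms, positive under dominance", {
  spec <- example_spec()
  fit <- fit_tpm(case_counts("risperidone"), strategy = "vague")
  res <- incremental_qaly(spec, coef(fit), coef(fit))
  expect_equal(res$difference, 0)
  # shift mass toward better (lower) states for arm A: stochastic dominance
  # with monotone utilities implies a positive QALY difference
  set.seed(4)
  for (rep in 1:5) {
    g <- matrix(rgamma(16, 2), 4)
    m_b <- g / rowSums(g)
    m_a <- m_b
    # move 10% of each row's mass from the worst to the best state
    shift <- 0.1 * m_a[, 4]
    m_a[, 4] <- m_a[, 4] - shift
    m_a[, 1] <- m_a[, 1] + shift
    spec4 <- cohort_spec(utilities = c(0.9, 0.7, 0.5, 0.3),
                         initial_distribution = rep(0.25, 4),
                         horizon_weeks = 54)
    expect_gt(incremental_qaly(spec4, m_a, m_b)$difference, 0)
  }
})

test_that("per-cycle mortality sequences are validated against the schedule", {
  expect_error(example_spec(horizon_weeks = 54, mortality = rep(0.01, 3)),
               "per cycle")
  expect_error(example_spec(horizon_weeks = 54, mortality = 1), "\\[0, 1\\)")
  expect_error(cohort_spec(utilities = c(1, 0),
                           initial_distribution = c(0.6, 0.6),
                           horizon_weeks = 6),
               "sum to 1")
})
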