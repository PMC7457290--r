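test_that("vague priors are flat with the requested mass", {
  expect_equal(make_vague_prior(8)$alpha, rep(0.125, 8))
  expect_equal(make_vague_prior(2)$alpha, c(0.5, 0.5))
  expect_equal(make_vague_prior(8, 8)$alpha, rep(1, 8))
  expect_error(make_vague_prior(1), "at least 2")
})

test_that("conjugate row update adds counts to hyperparameters", {
  prior <- case_prior()
  # risperidone state 2 under the expert prior, mass 1
  post <- posterior_row(scale_prior(prior[2, ], 1),
                        c(4, 98, 0, 11, 7, 1, 0, 0))
  expect_equal(post$mean[2], (0.4990 + 98) / 122, tolerance = 2e-4)
  expect_equal(sum(post$mean), 1)
  # cariprazine state 3: one observation, prior and data equally weighted
  post3 <- posterior_row(scale_prior(prior[3, ], 1), c(0, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(post3$mean[2], (0.1954 + 1) / 2, tolerance = 2e-4)
  # no data: posterior equals prior
  post0 <- posterior_row(scale_prior(prior[7, ], 1), rep(0L, 8))
  expect_equal(post0$mean, prior[7, ], ignore_attr = TRUE)
  expect_error(posterior_row(make_vague_prior(8), rep(0L, 4)), "length")
  expect_error(posterior_row(make_vague_prior(3), c(-1L, 0L, 1L)),
               "non-negative")
})

test_that("trial-only matrices use raw frequencies with absorbing empty rows", {
  fit <- fit_tpm(case_counts("risperidone"), strategy = "trial_only")
  expect_equal(coef(fit)[2, ], c(4, 98, 0, 11, 7, 1, 0, 0) / 121,
               ignore_attr = TRUE)
  expect_equal(coef(fit)[7, ], c(0, 0, 0, 0, 0, 0, 1, 0), ignore_attr = TRUE)
  expect_equal(coef(fit)[8, ], c(0, 0, 0, 0, 0, 0, 0, 1), ignore_attr = TRUE)
  fit_c <- fit_tpm(case_counts("cariprazine"), strategy = "trial_only")
  expect_equal(coef(fit_c)[3, ], c(0, 1, 0, 0, 0, 0, 0, 0), ignore_attr = TRUE)
  expect_null(fit$alpha)
})

test_that("every fitted point matrix is row-stochastic to 1e-12", {
  prior <- case_prior()
  for (arm in c("risperidone", "cariprazine")) {
    counts <- case_counts(arm)
    for (strat in c("trial_only", "vague", "informative")) {
      fit <- fit_tpm(counts, strategy = strat, prior = prior)
      expect_true(all(abs(rowSums(coef(fit)) - 1) < 1e-12),
                  label = paste(arm, strat))
      expect_true(all(coef(fit) >= 0))
    }
  }
})

test_that("posterior rows with no data equal the prior exactly", {
  prior <- case_prior()
  fit <- fit_tpm(case_counts("risperidone"), strategy = "informative",
                 prior = prior)
  expect_equal(fit$alpha[7, ], prior[7, ], ignore_attr = TRUE, tolerance = 5e-4)
  expect_equal(coef(fit)[7, ], prior[7, ] / sum(prior[7, ]),
               ignore_attr = TRUE)
  # posterior row mass = prior mass + n
  expect_equal(rowSums(fit$alpha), 1 + fit$n, ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("growing data overwhelms the prior (data dominance)", {
  prior <- case_prior()
  counts <- case_counts("risperidone")
  freq <- coef(fit_tpm(counts, strategy = "trial_only"))
  err <- sapply(c(1, 10, 100), function(m) {
    big <- count_table(counts$counts * as.integer(m))
    post <- coef(fit_tpm(big, strategy = "informative", prior = prior))
    obs <- counts$n > 0
    max(abs(post[obs, ] - freq[obs, ]))
  })
  expect_true(all(diff(err) < 0))
  # the deviation is bounded by prior_mass / (prior_mass + m * n_row)
  expect_lt(err[3], 1 / (1 + 100 * 2) + 1e-12)
})

test_that("identical counts under a shared prior give identical posteriors", {
  prior <- case_prior()
  counts <- case_counts("risperidone")
  f1 <- fit_tpm(counts, strategy = "informative", prior = prior)
  f2 <- fit_tpm(count_table(counts$counts), strategy = "informative",
                prior = prior)
  expect_equal(coef(f1), coef(f2), ignore_attr = TRUE)
})

test_that("posterior draws are reproducible, stochastic, and unbiased", {
  fit <- fit_tpm(toy_counts_2x2(), strategy = "vague")
  d1 <- simulate(fit, nsim = 5, seed = 99)
  d2 <- simulate(fit, nsim = 5, seed = 99)
  expect_identical(d1, d2)
  expect_true(all(abs(apply(d1, 3, rowSums) - 1) < 1e-12))

  # concentration limit: enormous alpha pins the row
  conc <- fit
  conc$alpha <- matrix(c(1e9, 1, 1, 1e9), 2, byrow = TRUE)
  d <- simulate(conc, nsim = 1, seed = 1)
  expect_equal(d[1, , 1], c(1, 0), tolerance = 1e-3, ignore_attr = TRUE)

  # empirical mean within 3 SE of the Dirichlet mean, per cell
  n_draws <- 20000
  draws <- simulate(fit, nsim = n_draws, seed = 3)
  a0 <- rowSums(fit$alpha)
  mean_true <- fit$alpha / a0
  se <- sqrt(fit$alpha * (a0 - fit$alpha) / (a0^2 * (a0 + 1))) / sqrt(n_draws)
  emp <- apply(draws, c(1, 2), mean)
  expect_true(all(abs(emp - mean_true) < 3 * se))
})

test_that("Monte-Carlo posterior mean agrees with the closed form", {
  fit <- fit_tpm(toy_counts_2x2(), strategy = "vague")
  mc <- mc_posterior_mean(fit, n_samples = 5000, burn_in = 100, seed = 5)
  expect_true(all(abs(mc$mean - coef(fit)) < 3 * mc$se))
  # zero-count row: MC mean hovers at the prior mean
  ct <- count_table(matrix(c(0L, 0L, 2L, 8L), 2, byrow = TRUE))
  fit0 <- fit_tpm(ct, strategy = "vague")
  mc0 <- mc_posterior_mean(fit0, n_samples = 4000, burn_in = 0, seed = 6)
  expect_true(all(abs(mc0$mean[1, ] - 0.5) < 3 * mc0$se[1, ]))
  # single draw degenerates gracefully
  mc1 <- mc_posterior_mean(fit, n_samples = 1, burn_in = 0, seed = 7)
  expect_true(all(abs(rowSums(mc1$mean) - 1) < 1e-12))
  expect_true(all(!is.finite(mc1$se)))
})

test_that("informative fits demand a usable prior", {
  expect_error(fit_tpm(toy_counts_2x2(), strategy = "informative"), "prior")
  expect_error(fit_tpm(toy_counts_2x2(), strategy = "informative",
                       prior = matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE)),
               "positive mass")
})
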