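# Shared fixtures built in code: packaged case-study inputs and small toys.

case_prior <- function() read_matrix(bayestpm_fixture("table1_expert_prior.csv"))

case_freq <- function(arm) {
  read_frequency_table(bayestpm_fixture(sprintf("table2_%s.csv", arm)),
                       arm = arm)
}

case_counts <- function(arm) as_count_table(case_freq(arm))

table3_expected <- function(arm, strategy) {
  df <- read.csv(bayestpm_fixture("table3_expected.csv"), check.names = FALSE)
  as.matrix(df[df$arm == arm & df$prior == strategy, as.character(1:8)])
}

# utilities and initial distribution used for the worked cohort example:
# monotone declining utility over the eight severity states, cohort started
# proportional to the pooled person-week exposure of the trial (states 7-8
# empty, as in the trial)
example_utilities <- function() seq(0.85, 0.35, length.out = 8)

example_initial <- function() {
  w <- c(5, 237, 3, 739, 104, 690, 0, 0)
  w / sum(w)
}

example_spec <- function(horizon_weeks = 54, ...) {
  cohort_spec(utilities = example_utilities(),
              initial_distribution = example_initial(),
              horizon_weeks = horizon_weeks, ...)
}

toy_counts_2x2 <- function() {
  count_table(matrix(c(5L, 1L, 2L, 8L), 2, byrow = TRUE))
}
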