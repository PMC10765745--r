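# Printed life-table and estimator columns of the 300-subject worked example
# (transcribed cell by cell).  The cumulative columns CI/AN/KM of the source
# table were accumulated from the rounded 3-decimal per-row values, so exact
# computation from the integer counts can differ from them by up to one unit
# in the last printed digit; tests compare those columns with that tolerance
# and the per-row columns exactly.
table_one_printed <- data.frame(
  time = c(0.0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 1.0, 1.1, 1.2, 1.3, 2.1),
  n    = c(300, 196, 115, 65, 49, 36, 25, 18, 15, 11, 7, 5, 3, 1),
  d_ae = c(29, 21, 11, 4, 6, 1, 3, 0, 2, 1, 0, 0, 1, 1),
  d_rl = c(75, 60, 39, 12, 7, 10, 4, 3, 2, 3, 2, 2, 1, 0),
  S    = c(0.653, 0.383, 0.217, 0.163, 0.120, 0.083, 0.060, 0.050, 0.037,
           0.023, 0.017, 0.010, 0.003, 0.000),
  h    = c(0.097, 0.107, 0.096, 0.062, 0.122, 0.028, 0.120, 0.000, 0.133,
           0.091, 0.000, 0.000, 0.333, 1.000),
  hS   = c(0.097, 0.070, 0.037, 0.013, 0.020, 0.003, 0.010, 0.000, 0.007,
           0.003, 0.000, 0.000, 0.003, 0.003),
  CI   = c(0.097, 0.167, 0.204, 0.217, 0.237, 0.240, 0.250, 0.250, 0.257,
           0.260, 0.260, 0.260, 0.263, 0.266),
  AN   = c(0.097, 0.204, 0.300, 0.362, 0.484, 0.512, 0.632, 0.632, 0.765,
           0.856, 0.856, 0.856, 1.189, 2.189),
  KM   = c(0.097, 0.194, 0.271, 0.316, 0.400, 0.416, 0.486, 0.486, 0.555,
           0.595, 0.595, 0.595, 0.730, 1.000)
)

# A small censored competing-risks sample used across tests.
censored_toy <- function() {
  crsample(time = c(0.5, 1.0, 1.0, 1.5, 2.0, 2.5, 3.0),
           status = c(1, 1, 0, 1, 1, 0, 1),
           cause = c(1, 2, NA, 1, 2, NA, 1))
}

# Simulated sample with independent exponential censoring, for oracle
# comparisons that need all three of events, competing events and censoring.
simulated_censored <- function(n = 400, seed = 42) {
  simulate_dataset(scenario_registry()[["4"]], n = n, seed = seed,
                   censoring_rate = 1)
}
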