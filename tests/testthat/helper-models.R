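# shared fixtures: reference kinetic models and an independent
# exponential-mixture generator used as the oracle for fit tests

ref_model <- function(...) reference_two_motor_model(...)

fast_motor <- function() motor_spec(0.005, 8, "fast")
slow_motor <- function() motor_spec(0.0025, 0.05, "slow")

# draw n dwells from an exponential mixture directly (independent of the
# Gillespie simulator): the oracle generator for fitting tests
rmix_dwells <- function(n, amplitudes, rates) {
  comp <- sample(seq_along(amplitudes), n, replace = TRUE, prob = amplitudes)
  stats::rexp(n, rates[comp])
}

# hand-made binding events table for digitization tests
make_events <- function(start, duration) {
  ev <- data.frame(start = start, duration = duration,
                   motor_index = 1L, species = "hot", censored = FALSE)
  class(ev) <- c("binding_events", "data.frame")
  ev
}
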