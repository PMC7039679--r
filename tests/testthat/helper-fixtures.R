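# Shared fixtures: basket-cell-like ground truths used across recovery tests.
bc_truth <- list(
  r_m = 158.5,      # megaohm
  tau_ms = 20.8,    # ms; c_m = tau/r_m = 131.2 pF
  v_rest = -56.9,   # mV
  sag_index = 0.83,
  threshold = -41.9, # mV
  amplitude = 57.4,  # mV
  half_width = 0.74, # ms
  ahp = 10.3,        # mV
  adaptation = 0.43
)
bc_truth$c_m <- bc_truth$tau_ms / bc_truth$r_m * 1e3

# ISI sequence whose last-3-over-first ratio is exactly the target adaptation.
adaptation_isis <- function(target = bc_truth$adaptation, first = 50, n_late = 9) {
  c(first, rep(first * target, n_late))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
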