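test_that("resting potential is the pre-stimulus baseline mean", {
  flat <- sweep_trace(rep(-60, 4000), dt = 5e-5, clamp_mode = "current_clamp")
  expect_equal(resting_potential(flat), -60)

  fam <- gen_passive_steps(-20, r_m = 158.5, c_m = bc_truth$c_m,
                           v_rest = -56.9, noise_sd = 0.3, seed = 2)
  expect_equal(resting_potential(fam$sweeps[[1]]), -56.9,
               tolerance = 3 * 0.3 / sqrt(0.5 / 5e-5))

  early <- sweep_trace(rep(-60, 4000), dt = 5e-5, clamp_mode = "current_clamp",
                       stim = step_protocol(0, 0.1))
  expect_error(resting_potential(early), "baseline")
})

test_that("input resistance is exact on noiseless families and robust to ordering/exclusion", {
  fam <- gen_passive_steps(c(-20, -10, 10, 20), r_m = 100, c_m = 200,
                           noise_sd = 0, seed = 1)
  expect_equal(input_resistance(fam$sweeps)$r_m, 100, tolerance = 1e-4)

  # reordering the steps leaves the estimate unchanged
  expect_equal(input_resistance(rev(fam$sweeps))$r_m,
               input_resistance(fam$sweeps)$r_m)

  # a step deflecting > 15 mV is excluded; slope identical to the refit
  # of the family without it (oracle)
  big <- gen_passive_steps(-200, r_m = 100, c_m = 200, noise_sd = 0, seed = 1)
  with_big <- input_resistance(c(fam$sweeps, big$sweeps))
  expect_false(with_big$steps$included[[5]])
  expect_equal(with_big$r_m, input_resistance(fam$sweeps)$r_m)

  expect_error(input_resistance(big$sweeps), ">= 3 steps")
})

test_that("input resistance recovers the generator truth within 2% at 0.3 mV noise", {
  fam <- gen_passive_steps(c(-20, -15, -10, -5, 5, 10, 15, 20),
                           r_m = bc_truth$r_m, c_m = bc_truth$c_m,
                           v_rest = bc_truth$v_rest, noise_sd = 0.3, seed = 1)
  expect_rel(input_resistance(fam$sweeps)$r_m, bc_truth$r_m, 0.02)
})

test_that("time constant fit is exact on noiseless data and bounded-checked", {
  fam <- gen_passive_steps(rep(-20, 3), r_m = 100, c_m = 200, step_onset = 0.1,
                           step_duration = 0.4, post_duration = 0.1,
                           noise_sd = 0, seed = 1)
  fit <- time_constant(fam$sweeps, r_m = 100)
  expect_equal(fit$tau_ms, 20, tolerance = 1e-3)
  expect_equal(fit$c_m, 200, tolerance = 0.1)

  # capacitance arithmetic: tau / Rm
  expect_equal(bc_truth$tau_ms / bc_truth$r_m * 1e3, 131.2, tolerance = 0.05)

  slow <- gen_passive_steps(rep(-20, 2), r_m = 500, c_m = 1000, step_onset = 0.1,
                            step_duration = 3, post_duration = 0.1,
                            noise_sd = 0, seed = 1)
  expect_error(time_constant(slow$sweeps, tau_guess_ms = 500), "outside")
})

test_that("time constant recovers the generator truth within 3% from 20 noisy repeats", {
  fam <- gen_passive_steps(rep(-20, 20), r_m = bc_truth$r_m, c_m = bc_truth$c_m,
                           v_rest = bc_truth$v_rest, step_onset = 0.1,
                           step_duration = 0.4, post_duration = 0.1,
                           noise_sd = 0.3, seed = 2)
  expect_rel(time_constant(fam$sweeps)$tau_ms, bc_truth$tau_ms, 0.03)
})

test_that("sag index is 1 for passive cells and matches its defining arithmetic", {
  fam <- gen_passive_steps(c(-180, -150, -120, -90), r_m = 158.5,
                           c_m = bc_truth$c_m, v_rest = -56.9,
                           step_duration = 1, noise_sd = 0, seed = 1)
  res <- sag_index(fam$sweeps, v_rest = -56.9)
  expect_equal(res$sag_index, 1, tolerance = 1e-3)

  # hand case: V_rest -60, V_hyp(I*) -85, V_sag(I*) -80 -> 0.8
  expect_equal((-60 - (-80)) / (-60 - (-85)), 0.8)

  expect_error(sag_index(fam$sweeps[1:3], v_rest = -56.9), ">= 4")
  # -80 mV outside the sampled V_sag range: no extrapolation
  weak <- gen_passive_steps(c(-20, -15, -10, -5), r_m = 158.5,
                            c_m = bc_truth$c_m, v_rest = -56.9,
                            step_duration = 1, noise_sd = 0, seed = 1)
  expect_error(sag_index(weak$sweeps, v_rest = -56.9), "extrapolate")
})

test_that("sag index recovers the generator truth within 0.02 at 0.2 mV noise", {
  g <- sag_fraction_for_index(bc_truth$sag_index, tau_ms = bc_truth$tau_ms,
                              tau_sag_ms = 150, step_duration = 1)
  i_center <- (-80 - bc_truth$v_rest) / (bc_truth$r_m * 1e-3 * (1 - g))
  fam <- gen_passive_steps(i_center * seq(0.7, 1.3, length.out = 6),
                           r_m = bc_truth$r_m, c_m = bc_truth$c_m,
                           v_rest = bc_truth$v_rest, step_duration = 1,
                           post_duration = 0.2, noise_sd = 0.2,
                           sag = list(g_fraction = g, tau_sag_ms = 150), seed = 3)
  expect_equal(mean(fam$truth$steps$sag_index), bc_truth$sag_index, tolerance = 1e-3)
  res <- sag_index(fam$sweeps, v_rest = bc_truth$v_rest)
  expect_equal(res$sag_index, bc_truth$sag_index, tolerance = 0.02)
})

test_that("spike detection ignores flat traces and sub-criterion ramps", {
  flat <- sweep_trace(rep(-60, 4000), dt = 5e-5, clamp_mode = "current_clamp")
  expect_length(detect_spikes(flat)$spike_times, 0)

  # a 5 mV/ms ramp never reaches the 10 mV/ms criterion
  ramp <- sweep_trace(-60 + 5 * (0:4000) * 5e-5 * 1e3, dt = 5e-5,
                      clamp_mode = "current_clamp")
  expect_length(detect_spikes(ramp)$spike_times, 0)

  coarse <- sweep_trace(rep(-60, 100), dt = 2e-4, clamp_mode = "current_clamp")
  expect_error(detect_spikes(coarse), "dt")
})

test_that("spike detection finds every generated spike at its peak time", {
  tr <- gen_ap_train(rep(30, 9), noise_sd = 0)  # 10 spikes
  sp <- detect_spikes(tr$sweep)
  expect_length(sp$spike_times, 10)
  expect_equal(sp$spike_times, tr$truth$spikes$t_peak, tolerance = 5e-5 + 1e-9)
})

test_that("ap_features measures a triangular spike's half-width from geometry", {
  # 1 ms linear rise (60 mV/ms), 2 ms linear fall, amplitude 60 mV:
  # half-amplitude crossings at 0.5 ms (rise) and 1 ms into the fall -> 1.5 ms
  dt <- 5e-5
  base <- -60
  up <- seq(0, 60, by = 60 * dt * 1e3)
  down <- seq(60, 0, by = -30 * dt * 1e3)
  v <- c(rep(base, 2000), base + up, base + down[-1], rep(base, 2000))
  sw <- sweep_trace(v, dt = dt, clamp_mode = "current_clamp")
  sp <- detect_spikes(sw)
  expect_length(sp$spike_times, 1)
  feats <- ap_features(sw, sp, which = 1)
  expect_equal(feats$half_width, 1.5, tolerance = 0.06)
  expect_equal(feats$amplitude, 60, tolerance = 1.5)
  expect_equal(feats$max_rise, 60, tolerance = 2)
})

test_that("ap feature recovery matches generator truth on noiseless trains", {
  tr <- gen_ap_train(adaptation_isis(), threshold = bc_truth$threshold,
                     amplitude = bc_truth$amplitude,
                     half_width = bc_truth$half_width, ahp = bc_truth$ahp,
                     noise_sd = 0)
  sp <- detect_spikes(tr$sweep)
  feats <- ap_features(tr$sweep, sp, which = 1)
  expect_equal(feats$threshold, bc_truth$threshold, tolerance = 0.5)
  expect_equal(feats$half_width, bc_truth$half_width, tolerance = 5e-5 * 1e3)
  expect_equal(feats$amplitude, bc_truth$amplitude, tolerance = 0.2)
  expect_equal(feats$ahp, bc_truth$ahp, tolerance = 0.1)
})

test_that("train statistics implement the late-over-first ISI rule", {
  mk_train <- function(isis_ms) {
    tr <- gen_ap_train(isis_ms, noise_sd = 0)
    detect_spikes(tr$sweep)
  }
  # equal ISIs -> ratio 1
  expect_equal(train_stats(mk_train(rep(25, 6)))$adaptation_ratio, 1,
               tolerance = 1e-6)
  # hand case: ISIs 10,20,30,40,40,40 -> mean(40,40,40)/10 = 4
  expect_equal(train_stats(mk_train(c(20, 30, 40, 40, 40, 40)))$adaptation_ratio,
               mean(c(40, 40, 40)) / 20, tolerance = 1e-6)
  # with 3 ISIs, the last 2 are used
  expect_equal(train_stats(mk_train(c(20, 30, 40)))$adaptation_ratio,
               mean(c(30, 40)) / 20, tolerance = 1e-6)
  # < 3 spikes: frequency still returned, ratio missing
  one <- train_stats(mk_train(numeric(0)))
  expect_true(is.na(one$adaptation_ratio))
  expect_equal(one$firing_frequency, 1 / 0.8)
})

test_that("parameter recovery is unbiased across seeds at study noise levels", {
  r_ms <- vapply(1:10, function(s) {
    fam <- gen_passive_steps(c(-20, -15, -10, -5, 5, 10, 15, 20),
                             r_m = bc_truth$r_m, c_m = bc_truth$c_m,
                             v_rest = bc_truth$v_rest, step_duration = 1,
                             noise_sd = 0.3, seed = s)
    input_resistance(fam$sweeps)$r_m
  }, numeric(1))
  expect_rel(mean(r_ms), bc_truth$r_m, 0.02)
  taus <- vapply(1:6, function(s) {
    fam <- gen_passive_steps(rep(-20, 20), r_m = bc_truth$r_m,
                             c_m = bc_truth$c_m, v_rest = bc_truth$v_rest,
                             step_onset = 0.1, step_duration = 0.4,
                             post_duration = 0.05, noise_sd = 0.3, seed = 100 + s)
    time_constant(fam$sweeps)$tau_ms
  }, numeric(1))
  expect_rel(mean(taus), bc_truth$tau_ms, 0.02)
})

test_that("membrane_properties assembles the full per-cell record", {
  fam <- gen_passive_steps(c(-20, -10, 10, 20), r_m = 158.5, c_m = bc_truth$c_m,
                           v_rest = -56.9, step_duration = 1, noise_sd = 0, seed = 1)
  tau_fam <- gen_passive_steps(rep(-20, 3), r_m = 158.5, c_m = bc_truth$c_m,
                               v_rest = -56.9, step_onset = 0.1,
                               step_duration = 0.4, post_duration = 0.05,
                               noise_sd = 0, seed = 2)
  tr <- gen_ap_train(adaptation_isis(), noise_sd = 0)
  row <- membrane_properties(fam$sweeps, tau_fam$sweeps, train_sweep = tr$sweep)
  expect_s3_class(row, "tbl_df")
  expect_identical(nrow(row), 1L)
  expect_equal(row$r_m, 158.5, tolerance = 0.1)
  expect_equal(row$adaptation_ratio, bc_truth$adaptation, tolerance = 1e-3)
  expect_true(is.na(row$sag_index))
})
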