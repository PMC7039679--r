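test_that("Nernst potential has its defining symmetries", {
  a <- c(KCl = 10)
  b <- c(KCl = 100)
  expect_equal(nernst(a, a, "Cl", -1, 33), 0)
  expect_equal(nernst(a, b, "Cl", -1, 33), -nernst(b, a, "Cl", -1, 33))
  # monotone in ln([out]/[in])
  outs <- c(20, 50, 100, 200)
  es <- vapply(outs, function(o) nernst(a, c(KCl = o), "K", +1, 33), numeric(1))
  expect_true(all(diff(es) > 0))
  # monovalent cation, 10 in / 100 out, 25 C -> +59.2 mV
  expect_equal(nernst(c(K = 10), c(K = 100), "K", +1, 25), 59.2, tolerance = 0.05)
  expect_error(nernst(c(KCl = 0), b, "Cl", -1, 33), "positive")
})

test_that("the chloride reversal of the K-gluconate internal against aCSF is -67 mV", {
  expect_equal(ion_concentration(solution_kgluconate_internal(), "Cl"), 11)
  expect_equal(ion_concentration(solution_acsf(), "Cl"), 141.5)
  e_cl <- nernst(solution_kgluconate_internal(), solution_acsf(),
                 ion = "Cl", z = -1, temperature = 33)
  expect_equal(round(e_cl), -67)
})

test_that("event measurement handles flat traces, clean events, and windows", {
  flat <- sweep_trace(rep(0, 8000), dt = 5e-5, clamp_mode = "voltage_clamp",
                      holding = -40)
  ev <- measure_events(flat, pulse_times = c(0.05, 0.07, 0.09, 0.11))
  expect_true(all(ev$is_failure))
  expect_true(all(ev$amplitude == 0))

  # single noiseless PSC of true peak -50 pA: 2.5 nS * -20 mV driving force
  g <- gen_synaptic_trace(0.05, g_gaba = 2.5, v_hold = -80, e_gaba = -60,
                          noise_sd = 0, jitter_ms = 0, seed = 1)
  ev1 <- measure_events(g$sweeps[[1]], pulse_times = 0.05)
  expect_false(ev1$is_failure)
  expect_equal(ev1$amplitude, -50, tolerance = 0.5)
  expect_identical(ev1$polarity, "inward")
  expect_equal(ev1$latency_ms, 1, tolerance = 0.3)

  expect_error(measure_events(flat, pulse_times = c(0.05, 0.06), window_ms = 15),
               "overlaps")
})

test_that("measured failure fraction tracks the generator truth", {
  g <- gen_synaptic_trace(0.05, n_sweeps = 200, g_gaba = 1.5, failure_p = 0.3,
                          v_hold = -40, e_gaba = -60, noise_sd = 0, seed = 7)
  ev <- measure_events(g$sweeps, polarity = "outward")
  expect_equal(mean(ev$is_failure), mean(g$truth$is_failure))
  ci <- stats::qbinom(c(0.005, 0.995), 200, 0.3) / 200
  expect_gte(mean(ev$is_failure), ci[1])
  expect_lte(mean(ev$is_failure), ci[2])
})

test_that("unitary statistics implement the amplitude/potency/CV/PPR definitions", {
  ev <- function(amps, pulse = 1) {
    tibble::tibble(trial = seq_along(amps), pulse = pulse, amplitude = amps,
                   is_failure = amps == 0, latency_ms = ifelse(amps == 0, NA, 1),
                   polarity = "outward")
  }
  # {80, 100, 120}: mean 100, sample SD 20, CV 0.2
  e1 <- ev(rep(c(80, 100, 120), 4))
  s1 <- unitary_stats(e1)
  expect_equal(s1$amplitude, 100)
  expect_equal(s1$cv, sd(rep(c(80, 100, 120), 4)) / 100)
  expect_equal(unitary_stats(ev(c(80, 100, 120, 80, 100, 120, 80, 100, 120, 100)))$cv,
               sd(c(80, 100, 120, 80, 100, 120, 80, 100, 120, 100)) / 100)

  # 50% failures, success amplitude -100 -> amplitude -50, potency -100
  e2 <- ev(rep(c(-100, 0), 6))
  s2 <- unitary_stats(e2)
  expect_equal(s2$amplitude, -50)
  expect_equal(s2$potency, -100)
  expect_equal(s2$failure_rate, 0.5)

  # identical first and second responses -> PPR exactly 1
  e3 <- dplyr::bind_rows(ev(rep(-80, 12), pulse = 1), ev(rep(-80, 12), pulse = 2))
  expect_equal(unitary_stats(e3)$ppr, 1)

  expect_error(unitary_stats(ev(rep(-80, 5))), ">= 10")
  expect_true(is.na(unitary_stats(ev(rep(0, 12)))$potency))
})

test_that("amplitude equals potency times success rate by construction", {
  g <- gen_synaptic_trace(0.05, n_sweeps = 50, g_gaba = 1.5, failure_p = 0.25,
                          cv_q = 0.4, v_hold = -40, e_gaba = -60,
                          noise_sd = 0, seed = 3)
  s <- unitary_stats(measure_events(g$sweeps, polarity = "outward"))
  expect_equal(s$amplitude, s$potency * (1 - s$failure_rate), tolerance = 1e-9)
})

test_that("PPR on depressing synthetic trains recovers the generator's amplitude law", {
  # fast-decaying events so the first response's tail does not overlap the
  # second measurement window
  pt <- c(0.1, 0.12)
  g <- gen_synaptic_trace(pt, n_sweeps = 300, g_gaba = 1.5, failure_p = 0.2,
                          cv_q = 0.3, depression_f = 0.7, v_hold = -40,
                          e_gaba = -60, tau_decay_gaba = 3, noise_sd = 0,
                          seed = 11)
  s <- unitary_stats(measure_events(g$sweeps, polarity = "outward"))
  truth_ppr <- mean(g$truth$peak_pA[g$truth$pulse == 2]) /
    mean(g$truth$peak_pA[g$truth$pulse == 1])
  expect_rel(s$ppr, truth_ppr, 0.05)
})

test_that("event kinetics: decay fit, instant rise, and scale invariance", {
  g <- gen_synaptic_trace(0.02, g_gaba = 1, tau_rise_gaba = 0.5,
                          tau_decay_gaba = 10, v_hold = -40, e_gaba = -60,
                          noise_sd = 0, jitter_ms = 0, seed = 1)
  k <- event_kinetics(g$sweeps[[1]])
  expect_equal(k$decay_tau_ms, 10, tolerance = 0.5)

  # instantaneous rise: rise time below two samples
  dt <- 5e-5
  step_ev <- sweep_trace(c(rep(0, 100), 50 * exp(-(0:2000) * dt / 8e-3)),
                         dt = dt, clamp_mode = "voltage_clamp")
  expect_lt(event_kinetics(step_ev)$rise_time_ms, 2 * dt * 1e3)

  dbl <- g$sweeps[[1]]
  dbl$samples <- dbl$samples * 2
  k2 <- event_kinetics(dbl)
  expect_equal(k2$rise_time_ms, k$rise_time_ms)
  expect_equal(k2$decay_tau_ms, k$decay_tau_ms, tolerance = 1e-6)
  expect_equal(k2$peak_pA, 2 * k$peak_pA)
})

test_that("conductance conversion follows G = I / (V - E) with sign checking", {
  expect_equal(to_conductance(0, -40, -60), 0)
  expect_equal(to_conductance(200, -40, -60), 10)        # GABA, outward
  expect_equal(to_conductance(-100, -30, 0), 10 / 3, tolerance = 1e-9)  # Glu, inward
  expect_error(to_conductance(-100, -40, -60), "mis-assigned")
  expect_error(to_conductance(100, -58, -60), "5 mV")
})

test_that("conductance round-trips generator truth within 2% at low noise", {
  g <- gen_synaptic_trace(0.05, n_sweeps = 10, g_gaba = 1.5, v_hold = -40,
                          e_gaba = -60, noise_sd = 0.2, jitter_ms = 0, seed = 5)
  ev <- measure_events(g$sweeps, polarity = "outward")
  gs <- vapply(ev$amplitude, to_conductance, numeric(1), v_hold = -40, e_rev = -60)
  expect_rel(mean(gs), mean(g$truth$conductance), 0.02)
})

test_that("polarity dissociation recovers both conductances from isolated responses", {
  # pure GABA: glutamate conductance 0, ratio infinite
  gaba <- gen_synaptic_trace(0.05, n_sweeps = 5, g_gaba = 10, v_hold = -40,
                             e_gaba = -60, noise_sd = 0.2, jitter_ms = 0, seed = 2)
  sp <- split_components(gaba$sweeps, pulse_times = 0.05, v_hold = -40)
  expect_equal(sp$components$g_nS[sp$components$component == "Glu"], 0)
  expect_identical(sp$ratio, Inf)
  expect_rel(sp$components$g_nS[sp$components$component == "GABA"], 10, 0.05)

  # glutamate isolated (GABA blocked): inward-only response
  glu <- gen_synaptic_trace(0.05, n_sweeps = 5, g_gaba = 0, g_ampa = 1,
                            v_hold = -40, noise_sd = 0.2, jitter_ms = 0, seed = 3)
  spg <- split_components(glu$sweeps, pulse_times = 0.05, v_hold = -40)
  expect_rel(spg$components$g_nS[spg$components$component == "Glu"], 1, 0.05)

  # ratio of the two isolated measurements: truth 10 within 5%
  ratio <- sp$components$g_nS[sp$components$component == "GABA"] /
    spg$components$g_nS[spg$components$component == "Glu"]
  expect_rel(ratio, 10, 0.05)

  # zero driving force refused
  expect_error(split_components(gaba$sweeps, pulse_times = 0.05, v_hold = -60),
               "polarity dissociation")
})

test_that("DSI suppression arithmetic", {
  expect_equal(dsi(rep(-200, 6), rep(-50, 6))$suppression_pct, 75)
  expect_equal(dsi(rep(-200, 6), rep(-200, 6))$suppression_pct, 0)
  expect_equal(dsi(rep(-200, 6), rep(0, 6))$suppression_pct, 100)
  expect_error(dsi(rep(0, 6), rep(-50, 6)), "zero")
  expect_error(dsi(rep(-200, 3), rep(-50, 6)))
})
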