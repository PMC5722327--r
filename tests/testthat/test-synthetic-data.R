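test_that("a single-component excitation is a pure sinusoid of half the p-p amplitude", {
  w <- make_excitation(excitation_spec(component_freqs = 8, peak_to_peak = 2))
  expect_equal(max(w$p_cmh2o) - min(w$p_cmh2o), 2, tolerance = 1e-12)
  expect_equal(max(abs(w$p_cmh2o)), 1, tolerance = 1e-9)
  # single tone: spectrum concentrated at 8 Hz
  P <- Mod(fft(w$p_cmh2o))
  k8 <- 8 * 16 + 1  # df = 1/16 Hz over a 16 s record
  expect_gt(P[k8] / max(P[-c(k8, length(P) - k8 + 2)]), 1e9)
})

test_that("the default multisine hits the exact peak-to-peak amplitude", {
  w <- make_excitation(excitation_spec())
  expect_equal(max(w$p_cmh2o) - min(w$p_cmh2o), 2, tolerance = 1e-12)
})

test_that("phase seeds change the waveform but not the component magnitudes", {
  s1 <- excitation_spec(phase_seed = 1)
  s2 <- excitation_spec(phase_seed = 2)
  w1 <- make_excitation(s1)$p_cmh2o
  w2 <- make_excitation(s2)$p_cmh2o
  expect_gt(max(abs(w1 - w2)), 0.01)
  k <- s1$component_freqs * 16 + 1
  m1 <- Mod(fft(w1))[k]
  m2 <- Mod(fft(w2))[k]
  # equal-amplitude components, so magnitude ratios across seeds are constant
  expect_equal(m1 / m1[1], m2 / m2[1], tolerance = 1e-9)
})

test_that("excitation energy outside the component bins is negligible before noise", {
  w <- make_excitation(excitation_spec())$p_cmh2o
  P <- Mod(fft(w))^2
  half <- P[seq_len(length(w) / 2 + 1)]
  k <- seq(4, 32, 2) * 16 + 1
  leak <- max(half[-c(1, k)]) / min(half[k])
  expect_lt(10 * log10(leak), -200)
})

test_that("off-grid or out-of-band component frequencies are rejected", {
  expect_error(excitation_spec(component_freqs = 5.1), class = "oscillab_validation_error")
  expect_error(excitation_spec(component_freqs = c(2, 8)), class = "oscillab_validation_error")
  expect_error(excitation_spec(component_freqs = 40), class = "oscillab_validation_error")
  expect_error(excitation_spec(peak_to_peak = 0), class = "oscillab_validation_error")
})

test_that("flow through a pure resistor is Ohmic and in phase with pressure", {
  rec <- synthesize_record(mech_model("pure_resistor", R = 2),
                           excitation_spec(component_freqs = 8),
                           noise_spec_none(), seed = 1)
  expect_equal(rec$q_lps, rec$p_cmh2o / 2, tolerance = 1e-12)
  expect_equal(max(rec$q_lps), 0.5, tolerance = 1e-9)
})

test_that("noiseless synthesis inverts to the model impedance at every component bin", {
  for (m in list(ric_model(),
                 mech_model("eric", R = 3, I = 0.01, C = 0.02, S = -0.05),
                 mech_model("two_compartment", R = 4, I = 0.02, C = 0.03,
                            branch2 = list(R = 6, I = 0.01, C = 0.02)))) {
    rec <- synthesize_record(m, excitation_spec(), noise_spec_none(), seed = 1)
    k <- seq(4, 32, 2) * 16 + 1  # direct full-record FFT, independent of Welch
    zhat <- fft(rec$p_cmh2o)[k] / fft(rec$q_lps)[k]
    ztrue <- eval_impedance(m, seq(4, 32, 2))$z
    expect_lt(max(Mod(zhat - ztrue) / Mod(ztrue)), 1e-6)
  }
})

test_that("record synthesis is bit-reproducible from its seed", {
  a <- synthesize_record(ric_model(), excitation_spec(), noise_spec(), seed = 7)
  b <- synthesize_record(ric_model(), excitation_spec(), noise_spec(), seed = 7)
  expect_identical(a$p_cmh2o, b$p_cmh2o)
  expect_identical(a$q_lps, b$q_lps)
  c <- synthesize_record(ric_model(), excitation_spec(), noise_spec(), seed = 8)
  expect_false(identical(a$p_cmh2o, c$p_cmh2o))
})

test_that("breathing alone does not bias impedance at the component bins", {
  ns <- noise_spec(pressure_noise_sd = 0, flow_noise_sd = 0)  # breathing on, sensors clean
  rec <- synthesize_record(ric_model(), excitation_spec(), ns, seed = 1)
  mi <- measure_impedance(rec)
  ztrue <- eval_impedance(ric_model(), mi$freq_hz)$z
  expect_lt(max(Mod(mi$z - ztrue) / Mod(ztrue)), 0.01)
})

test_that("the default cohort has 23/21/24 subjects and three exams each", {
  co <- generate_cohort(master_seed = 3, keep_records = FALSE)
  expect_equal(nrow(co), 68L)
  expect_equal(as.integer(table(co$group)[c("control", "NE", "AE")]), c(23L, 21L, 24L))
  recs <- subject_records(co[1, ], master_seed = 3)
  expect_length(recs, 3L)
  expect_equal(nrow(co) * 3L, 204L)
})

test_that("zero-variance groups produce identical subjects", {
  g <- group_config("flat", 4, r_mean = 3, c_mean = 0.02, i_mean = 0.01)
  co <- generate_cohort(g, master_seed = 1, keep_records = FALSE)
  expect_equal(length(unique(co$r)), 1L)
  expect_equal(length(unique(co$c)), 1L)
})

test_that("sampled plateau resistance concentrates around the group mean", {
  g <- group_config("control", 500, r_mean = 2.77, r_sd = 0.23,
                    c_mean = 0.02, i_mean = 0.01)
  co <- generate_cohort(g, master_seed = 9, keep_records = FALSE)
  expect_lt(abs(mean(co$r) - 2.77), 3 * 0.23 / sqrt(500))
})

test_that("cohort regeneration from the master seed is exact", {
  co <- generate_cohort(default_groups()[1, ], master_seed = 5, keep_records = FALSE)
  r1 <- subject_records(co[4, ], master_seed = 5)
  r2 <- subject_records(co[4, ], master_seed = 5)
  expect_identical(r1[[2]]$p_cmh2o, r2[[2]]$p_cmh2o)
  expect_identical(r1[[2]]$q_lps, r2[[2]]$q_lps)
  # exams differ from each other through their noise draws
  expect_false(identical(r1[[1]]$q_lps, r1[[2]]$q_lps))
})
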