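#' Multisine excitation specification
#'
#' Describes the pseudorandom multisine pressure excitation applied at the
#' mouth: equal-amplitude sinusoids at fixed frequencies with seeded uniform
#' random phases, rescaled so the waveform's peak-to-peak amplitude is exact.
#' Defaults follow the standard measurement protocol: components every 2 Hz
#' from 4 to 32 Hz, 2 cmH2O peak-to-peak, digitised at 1024 Hz for 16 s.
#'
#' Component frequencies must lie in [4, 32] Hz and be aligned with the FFT
#' bin grid of the 4096-point analysis blocks (integer multiples of
#' `fs / 4096`), so that spectral estimation sees each component in a single
#' bin.
#'
#' @param component_freqs Component frequencies in Hz.
#' @param peak_to_peak Peak-to-peak pressure amplitude, cmH2O.
#' @param fs Sampling rate, samples/s.
#' @param duration Record duration, s.
#' @param phase_seed Integer seed for the component phases.
#' @return An object of class `excitation_spec`.
#' @export
excitation_spec <- function(component_freqs = seq(4, 32, by = 2),
                            peak_to_peak = 2, fs = 1024, duration = 16,
                            phase_seed = 1L) {
  if (!is.numeric(component_freqs) || length(component_freqs) == 0L ||
      any(component_freqs < 4 - 1e-9) || any(component_freqs > 32 + 1e-9)) {
    abort("Component frequencies must lie within [4, 32] Hz.",
          class = "oscillab_validation_error")
  }
  df <- fs / 4096
  k <- component_freqs / df
  if (any(abs(k - round(k)) > 1e-8)) {
    abort("Component frequencies must be integer multiples of fs/4096 (bin-aligned).",
          class = "oscillab_validation_error")
  }
  if (!is.numeric(peak_to_peak) || peak_to_peak <= 0) {
    abort("`peak_to_peak` must be positive.", class = "oscillab_validation_error")
  }
  stopifnot(fs > 0, duration > 0)
  structure(
    list(component_freqs = sort(as.numeric(component_freqs)),
         peak_to_peak = peak_to_peak, fs = fs, duration = duration,
         phase_seed = as.integer(phase_seed)),
    class = "excitation_spec"
  )
}

#' Disturbance and sensor-noise specification
#'
#' Models the disturbances present in a real forced-oscillation exam: the
#' subject breathes spontaneously during the measurement, and pressure/flow
#' transducers add sensor noise. Breathing is modelled as a single
#' low-frequency flow sinusoid plus its Ohmic pressure response -- the
#' simplest disturbance that stresses the coherence quality gate without
#' claiming physiological fidelity. Sensor noise is independent Gaussian
#' white noise on each channel.
#'
#' @param breathing_freq Breathing frequency, Hz. Must be below the lowest
#'   excitation component.
#' @param breathing_flow_amplitude Breathing flow amplitude, L/s.
#' @param pressure_noise_sd Pressure sensor noise SD, cmH2O.
#' @param flow_noise_sd Flow sensor noise SD, L/s.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(breathing_freq = 0.25, breathing_flow_amplitude = 0.4,
                       pressure_noise_sd = 0.02, flow_noise_sd = 0.01) {
  vals <- c(breathing_freq, breathing_flow_amplitude, pressure_noise_sd, flow_noise_sd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("All noise parameters must be finite and non-negative.",
          class = "oscillab_validation_error")
  }
  structure(
    list(breathing_freq = breathing_freq,
         breathing_flow_amplitude = breathing_flow_amplitude,
         pressure_noise_sd = pressure_noise_sd,
         flow_noise_sd = flow_noise_sd),
    class = "noise_spec"
  )
}

#' Silent (disturbance-free) noise specification
#'
#' Convenience constructor for noiseless synthesis: no breathing, no sensor
#' noise. Useful for exact recovery checks.
#' @return A `noise_spec` with all disturbances set to zero.
#' @export
noise_spec_none <- function() {
  noise_spec(breathing_freq = 0.25, breathing_flow_amplitude = 0,
             pressure_noise_sd = 0, flow_noise_sd = 0)
}

# Per-component amplitudes and phases of the rescaled multisine.
excitation_phasors <- function(spec) {
  k <- length(spec$component_freqs)
  phases <- withr::with_seed(spec$phase_seed, runif(k, 0, 2 * pi))
  n <- round(spec$fs * spec$duration)
  t <- (seq_len(n) - 1) / spec$fs
  raw <- rowSums(vapply(
    seq_len(k),
    function(i) cos(2 * pi * spec$component_freqs[i] * t + phases[i]),
    numeric(n)
  ))
  scale <- spec$peak_to_peak / (max(raw) - min(raw))
  list(freqs = spec$component_freqs, amplitudes = rep(scale, k),
       phases = phases, t = t, wave = raw * scale)
}

#' Generate the multisine excitation pressure waveform
#'
#' @param spec An [excitation_spec()].
#' @return A tibble with columns `t_s` (time, s) and `p_cmh2o` (pressure,
#'   cmH2O). The waveform is a sum of equal-amplitude cosines at the
#'   component frequencies with seeded pseudorandom phases, rescaled so that
#'   `max(p) - min(p)` equals `peak_to_peak` exactly.
#' @examples
#' w <- make_excitation(excitation_spec(component_freqs = 8))
#' max(w$p_cmh2o) - min(w$p_cmh2o)
#' @export
make_excitation <- function(spec = excitation_spec()) {
  stopifnot(inherits(spec, "excitation_spec"))
  ph <- excitation_phasors(spec)
  tibble::tibble(t_s = ph$t, p_cmh2o = ph$wave)
}

#' Synthesize a forced-oscillation pressure-flow record
#'
#' Forward-simulates one 16 s exam: the multisine excitation pressure is
#' passed through a known mechanical impedance to obtain the oscillatory
#' flow (steady-state phasor solution per component, \eqn{Q(f) = P(f)/Z(f)}),
#' a spontaneous-breathing flow sinusoid and its Ohmic pressure response are
#' superimposed, and independent Gaussian sensor noise is added to both
#' channels. Fully reproducible from `seed`.
#'
#' @param model A [mech_model()]; the ground-truth impedance.
#' @param excitation An [excitation_spec()].
#' @param noise A [noise_spec()] (use [noise_spec_none()] for noiseless
#'   records).
#' @param seed Integer seed controlling the sensor-noise draws.
#' @return A tibble of class `fot_record` with columns `t_s`, `p_cmh2o`,
#'   `q_lps`, carrying the true model and generation specs as attributes
#'   (`meta`).
#' @examples
#' rec <- synthesize_record(mech_model("pure_resistor", R = 2),
#'                          excitation_spec(component_freqs = 8),
#'                          noise_spec_none(), seed = 1)
#' @export
synthesize_record <- function(model, excitation = excitation_spec(),
                              noise = noise_spec(), seed = 1L) {
  stopifnot(inherits(model, "fot_model"), inherits(excitation, "excitation_spec"),
            inherits(noise, "noise_spec"))
  if (noise$breathing_flow_amplitude > 0 &&
      noise$breathing_freq >= min(excitation$component_freqs)) {
    abort("Breathing frequency must be below the lowest excitation component.",
          class = "oscillab_validation_error")
  }
  ph <- excitation_phasors(excitation)
  zf <- eval_impedance(model, ph$freqs)$z
  if (any(Mod(zf) == 0)) {
    abort("Model impedance is singular at an excitation component.",
          class = "oscillab_singular_error")
  }
  t <- ph$t
  p <- ph$wave
  q <- rowSums(vapply(
    seq_along(ph$freqs),
    function(i) {
      (ph$amplitudes[i] / Mod(zf[i])) *
        cos(2 * pi * ph$freqs[i] * t + ph$phases[i] - Arg(zf[i]))
    },
    numeric(length(t))
  ))
  if (noise$breathing_flow_amplitude > 0) {
    qb <- noise$breathing_flow_amplitude * sin(2 * pi * noise$breathing_freq * t)
    # Ohmic pressure response: resistive part of the model at the breathing rate
    r_eff <- Re(eval_impedance(model, noise$breathing_freq)$z)
    q <- q + qb
    p <- p + r_eff * qb
  }
  if (noise$pressure_noise_sd > 0 || noise$flow_noise_sd > 0) {
    nz <- withr::with_seed(as.integer(seed), {
      list(p = rnorm(length(t), 0, noise$pressure_noise_sd),
           q = rnorm(length(t), 0, noise$flow_noise_sd))
    })
    p <- p + nz$p
    q <- q + nz$q
  }
  out <- tibble::tibble(t_s = t, p_cmh2o = p, q_lps = q)
  attr(out, "meta") <- list(model = model, excitation = excitation,
                            noise = noise, seed = as.integer(seed))
  class(out) <- c("fot_record", class(out))
  out
}

#' @describeIn synthesize_record Plot the pressure and flow traces.
#' @param object A `fot_record`.
#' @param ... Unused.
#' @exportS3Method
autoplot.fot_record <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "t_s", "p_cmh2o", "q_lps"),
    c("p_cmh2o", "q_lps"),
    names_to = "channel", values_to = "value"
  )
  long$channel <- factor(long$channel, levels = c("p_cmh2o", "q_lps"),
                         labels = c("Pressure (cmH2O)", "Flow (L/s)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL)
}

#' Group configuration for cohort simulation
#'
#' Defines one study group: its label, size, and the ground-truth parameter
#' distributions from which each subject's extended-RIC model is drawn
#' (independent normals, truncated at physical bounds).
#'
#' @param label Group label (e.g. `"control"`, `"NE"`, `"AE"`).
#' @param n Number of subjects, > 0.
#' @param r_mean,r_sd Plateau resistance R, cmH2O.s/L.
#' @param s_mean,s_sd Resistance slope S, cmH2O.s/L per Hz.
#' @param i_mean,i_sd Inertance I, cmH2O.s^2/L.
#' @param c_mean,c_sd Compliance C, L/cmH2O.
#' @return A one-row tibble of class `group_config`.
#' @export
group_config <- function(label, n,
                         r_mean, r_sd = 0,
                         s_mean = 0, s_sd = 0,
                         i_mean = 0.01, i_sd = 0,
                         c_mean = 0.02, c_sd = 0) {
  if (!is.numeric(n) || n < 1) abort("`n` must be positive.", class = "oscillab_validation_error")
  sds <- c(r_sd, s_sd, i_sd, c_sd)
  if (any(sds < 0)) abort("SDs must be non-negative.", class = "oscillab_validation_error")
  out <- tibble::tibble(label = as.character(label), n = as.integer(n),
                        r_mean = r_mean, r_sd = r_sd, s_mean = s_mean, s_sd = s_sd,
                        i_mean = i_mean, i_sd = i_sd, c_mean = c_mean, c_sd = c_sd)
  class(out) <- c("group_config", class(out))
  out
}

#' Default simulated study groups
#'
#' Three groups mirroring a cohort of healthy controls, patients with
#' sickle-cell anaemia and normal spirometry (NE), and patients with
#' abnormal (restrictive) spirometry (AE), sized 23/21/24. Plateau
#' resistances for the control and AE groups use the published group
#' means/SDs (2.77 +/- 0.23 and 3.91 +/- 0.57 cmH2O.s/L); the remaining
#' distributions are calibration choices that reproduce the qualitative
#' disease contrasts: resistance up, compliance (hence Cdyn) down, resonance
#' frequency up and resistance slope S more negative with disease severity.
#'
#' @return A tibble with one row per group.
#' @export
default_groups <- function() {
  dplyr::bind_rows(
    group_config("control", 23, r_mean = 2.77, r_sd = 0.23,
                 s_mean = -0.020, s_sd = 0.010,
                 i_mean = 0.010, i_sd = 0.001,
                 c_mean = 0.020, c_sd = 0.003),
    group_config("NE", 21, r_mean = 2.95, r_sd = 0.35,
                 s_mean = -0.045, s_sd = 0.015,
                 i_mean = 0.010, i_sd = 0.001,
                 c_mean = 0.016, c_sd = 0.003),
    group_config("AE", 24, r_mean = 3.91, r_sd = 0.57,
                 s_mean = -0.080, s_sd = 0.020,
                 i_mean = 0.010, i_sd = 0.001,
                 c_mean = 0.011, c_sd = 0.002)
  )
}

# Deterministic per-(subject, purpose) seed derivation, bounded below 2^31.
derive_seed <- function(master_seed, subject_index, stream) {
  (as.double(master_seed) * 48271 + subject_index * 1299709 + stream * 7919) %%
    2147483647
}

truncated_draw <- function(seed, means, sds, max_tries = 100) {
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(max_tries)) {
      r <- rnorm(1, means["r"], sds["r"])
      s <- rnorm(1, means["s"], sds["s"])
      ii <- rnorm(1, means["i"], sds["i"])
      cc <- rnorm(1, means["c"], sds["c"])
      ok <- r > 0.1 && cc > 0.001 && ii >= 0 && (r + s * 32) > 0.1
      if (ok) return(c(r = r, s = s, i = ii, c = cc))
    }
    abort("Could not draw physically plausible model parameters after 100 tries.",
          class = "oscillab_generation_error")
  })
}

#' Simulate a cohort of subjects with known ground truth
#'
#' Draws one extended-RIC ground-truth model per subject from its group's
#' parameter distributions (truncated at physical bounds: R > 0.1 with
#' positive resistance across the band, C > 0.001, I >= 0; up to 100
#' redraws) and synthesizes `n_exams` forced-oscillation records per subject
#' (three exams by default, matching the measure-three-average protocol).
#' Everything is deterministic given `master_seed`: subject truths and each
#' record's sensor noise derive their seeds from `(master_seed, subject
#' index, exam index)`.
#'
#' @param groups A tibble of group rows as returned by [group_config()] /
#'   [default_groups()].
#' @param master_seed Integer master seed.
#' @param n_exams Records synthesized per subject.
#' @param excitation,noise Specs passed to [synthesize_record()].
#' @param keep_records If `FALSE`, only the truth table is returned (no
#'   `records` list-column); records can be regenerated deterministically.
#' @return A tibble of class `fot_cohort` with one row per subject: columns
#'   `subject_id`, `group`, true parameters `r`, `s`, `i`, `c`, and (if
#'   `keep_records`) a `records` list-column of `fot_record`s.
#' @export
generate_cohort <- function(groups = default_groups(), master_seed = 1L,
                            n_exams = 3L, excitation = excitation_spec(),
                            noise = noise_spec(), keep_records = TRUE) {
  stopifnot(is.data.frame(groups), all(groups$n > 0))
  master_seed <- as.integer(master_seed)
  truth <- purrr::pmap_dfr(
    list(seq_len(nrow(groups))),
    function(gi) {
      g <- groups[gi, ]
      purrr::map_dfr(seq_len(g$n), function(si) {
        idx <- sum(groups$n[seq_len(gi - 1)]) + si
        draw <- truncated_draw(
          derive_seed(master_seed, idx, 0),
          means = c(r = g$r_mean, s = g$s_mean, i = g$i_mean, c = g$c_mean),
          sds = c(r = g$r_sd, s = g$s_sd, i = g$i_sd, c = g$c_sd)
        )
        tibble::tibble(subject_id = sprintf("S%03d", idx), subject_index = idx,
                       group = g$label, r = draw[["r"]], s = draw[["s"]],
                       i = draw[["i"]], c = draw[["c"]])
      })
    }
  )
  if (keep_records) {
    truth$records <- purrr::map2(truth$subject_index, seq_len(nrow(truth)), function(idx, row) {
      subject_records(truth[row, ], master_seed, n_exams, excitation, noise)
    })
  }
  attr(truth, "master_seed") <- master_seed
  attr(truth, "n_exams") <- as.integer(n_exams)
  attr(truth, "excitation") <- excitation
  attr(truth, "noise") <- noise
  class(truth) <- c("fot_cohort", class(truth))
  truth
}

#' Regenerate the records of one cohort subject
#'
#' @param subject One row of a [generate_cohort()] table.
#' @param master_seed The cohort's master seed.
#' @param n_exams Number of exams.
#' @param excitation,noise Generation specs.
#' @return A list of `n_exams` `fot_record`s.
#' @export
subject_records <- function(subject, master_seed, n_exams = 3L,
                            excitation = excitation_spec(), noise = noise_spec()) {
  model <- mech_model("eric", R = subject$r, I = subject$i, C = subject$c,
                      S = subject$s)
  purrr::map(seq_len(n_exams), function(e) {
    synthesize_record(model, excitation, noise,
                      seed = derive_seed(master_seed, subject$subject_index, e))
  })
}
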