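#' Resistive oscillometry parameters
#'
#' Fits the ordinary least-squares line \eqn{Re\,Z(f) = R0 + S f} to the
#' real part of the measured impedance over the QC-passing components in
#' the 4--16 Hz band. Returns the intercept resistance `r0`, the resistance
#' slope `s` (a marker of ventilation heterogeneity; near zero in health,
#' progressively more negative with peripheral involvement), the mean
#' resistance `rm` over the same band, and the 4 Hz resistance `r4`.
#'
#' @param mi A `fot_impedance` (QC flags honoured when present).
#' @param band Fitting band in Hz, default `c(4, 16)`.
#' @return A one-row tibble with columns `r0`, `s`, `rm`, `r4` and
#'   `r4_available`.
#' @export
extract_resistive <- function(mi, band = c(4, 16)) {
  stopifnot(inherits(mi, "fot_impedance"))
  use <- mi$freq_hz >= band[1] - 1e-9 & mi$freq_hz <= band[2] + 1e-9
  if ("qc_pass" %in% names(mi)) use <- use & mi$qc_pass
  d <- mi[use, ]
  if (nrow(d) < 2L) {
    abort("Fewer than 2 usable components in the resistive fitting band.",
          class = "oscillab_insufficient_data_error")
  }
  fit <- coef(lm(rrs ~ freq_hz, data = d))
  i4 <- which(abs(d$freq_hz - 4) < 1e-9)
  r4 <- if (length(i4)) d$rrs[i4[1]] else NA_real_
  tibble::tibble(r0 = unname(fit[1]), s = unname(fit[2]), rm = mean(d$rrs),
                 r4 = r4, r4_available = length(i4) > 0L)
}

#' Reactive oscillometry parameters
#'
#' Reduces the measured reactance curve to the mean reactance `xm` over the
#' full measured band, the resonance frequency `fr` (linear interpolation of
#' the first negative-to-positive zero crossing of X between bracketing
#' components; linearly extrapolated beyond the band, and flagged, when X is
#' negative everywhere), the dynamic compliance
#' `cdyn = -1 / (2 pi f X(f))` evaluated at the lowest measured frequency
#' (4 Hz) when `X(4) < 0`, and the impedance modulus at 4 Hz
#' `z4 = sqrt(R4^2 + X(4)^2)` -- the total mechanical load on the
#' respiratory muscles.
#'
#' Note that `cdyn` is an apparent compliance: the inertial reactance at
#' 4 Hz makes it differ from the model compliance C even in a noiseless
#' RIC system.
#'
#' @param mi A `fot_impedance` (QC flags honoured when present).
#' @param band Averaging band for `xm`, default `c(4, 32)`.
#' @param allow_extrapolation Extrapolate `fr` beyond the measured band when
#'   no crossing is observed.
#' @return A one-row tibble with columns `xm`, `fr`, `fr_extrapolated`,
#'   `cdyn`, `cdyn_defined`, `z4`.
#' @export
extract_reactive <- function(mi, band = c(4, 32), allow_extrapolation = TRUE) {
  stopifnot(inherits(mi, "fot_impedance"))
  use <- mi$freq_hz >= band[1] - 1e-9 & mi$freq_hz <= band[2] + 1e-9
  if ("qc_pass" %in% names(mi)) use <- use & mi$qc_pass
  d <- mi[use, ]
  if (nrow(d) < 2L) {
    abort("Fewer than 2 usable components in the reactive band.",
          class = "oscillab_insufficient_data_error")
  }
  i4 <- which(abs(d$freq_hz - 4) < 1e-9)
  if (!length(i4)) {
    abort("The 4 Hz component is required for Cdyn and Z4.",
          class = "oscillab_insufficient_data_error")
  }
  x4 <- d$xrs[i4[1]]
  r4 <- d$rrs[i4[1]]
  xm <- mean(d$xrs)
  z4 <- sqrt(r4^2 + x4^2)

  f <- d$freq_hz; x <- d$xrs
  fr <- NA_real_; extrapolated <- FALSE
  zero_idx <- which(x == 0)
  if (length(zero_idx)) {
    fr <- f[zero_idx[1]]
    if (length(zero_idx) == length(x)) fr <- NA_real_  # identically zero: no crossing
  } else {
    cross <- which(x[-length(x)] < 0 & x[-1] > 0)
    if (length(cross)) {
      i <- cross[1]  # first crossing from below
      fr <- f[i] + (0 - x[i]) * (f[i + 1] - f[i]) / (x[i + 1] - x[i])
    } else if (all(x < 0) && allow_extrapolation && length(x) >= 2) {
      n <- length(x)
      slope <- (x[n] - x[n - 1]) / (f[n] - f[n - 1])
      if (slope > 0) {
        fr <- f[n] - x[n] / slope
        extrapolated <- TRUE
      }
    }
  }

  cdyn_defined <- is.finite(x4) && x4 < 0
  cdyn <- if (cdyn_defined) -1 / (2 * pi * 4 * x4) else NA_real_

  tibble::tibble(xm = xm, fr = fr, fr_extrapolated = extrapolated,
                 cdyn = cdyn, cdyn_defined = cdyn_defined, z4 = z4)
}

#' Extract the eight oscillometry parameters for one subject
#'
#' Composition of the per-subject pipeline: each exam's record is reduced to
#' impedance with [measure_impedance()] (unless already-measured
#' `fot_impedance` objects are supplied), exams passing the coherence gate
#' are averaged with [average_exams()], and the resistive and reactive
#' parameter sets are extracted from the mean curve.
#'
#' @param exams A list of `fot_record`s or QC-flagged `fot_impedance`s
#'   (typically the three exams of one subject).
#' @param window A [window_spec()] used when `exams` are raw records.
#' @param coherence_min Coherence QC threshold.
#' @param xm_band Averaging band for the mean reactance.
#' @return A one-row tibble with `r0`, `rm`, `r4`, `s`, `xm`, `fr`, `cdyn`,
#'   `z4`, QC columns (`n_exams_used`, flags), in measurement units.
#' @export
extract_fot_parameters <- function(exams, window = window_spec(),
                                   coherence_min = 0.9, xm_band = c(4, 32)) {
  if (inherits(exams, "fot_record") || inherits(exams, "fot_impedance")) {
    exams <- list(exams)
  }
  mis <- purrr::map(exams, function(e) {
    if (inherits(e, "fot_impedance")) {
      if (!"qc_pass" %in% names(e)) e <- coherence_qc(e, coherence_min)
      e
    } else {
      measure_impedance(e, window = window, coherence_min = coherence_min)
    }
  })
  avg <- average_exams(mis)
  res <- extract_resistive(avg)
  rea <- extract_reactive(avg, band = xm_band)
  dplyr::bind_cols(
    res[, c("r0", "rm", "r4", "s")],
    rea[, c("xm", "fr", "cdyn", "z4")],
    tibble::tibble(n_exams_used = attr(avg, "n_exams_used"),
                   r4_available = res$r4_available,
                   fr_extrapolated = rea$fr_extrapolated,
                   cdyn_defined = rea$cdyn_defined)
  )
}

#' Oscillometry feature table for a simulated cohort
#'
#' Runs the full measurement chain for every subject of a
#' [generate_cohort()] table: synthesize (or reuse) the subject's exams,
#' estimate impedance, apply coherence QC, average exams, and extract the
#' eight parameters. Subjects whose exams all fail QC are returned with
#' missing parameters and `n_exams_used = 0`.
#'
#' @param cohort A `fot_cohort` tibble.
#' @param window A [window_spec()].
#' @param coherence_min Coherence QC threshold.
#' @return A tibble with `subject_id`, `group`, the eight parameter columns
#'   and QC annotations: the subject-by-feature table consumed by the
#'   statistics, ROC and machine-learning layers.
#' @export
cohort_features <- function(cohort, window = window_spec(), coherence_min = 0.9) {
  stopifnot(inherits(cohort, "fot_cohort"))
  master_seed <- attr(cohort, "master_seed")
  n_exams <- attr(cohort, "n_exams") %||% 3L
  excitation <- attr(cohort, "excitation") %||% excitation_spec()
  noise <- attr(cohort, "noise") %||% noise_spec()
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    subj <- cohort[i, ]
    recs <- if ("records" %in% names(cohort)) {
      subj$records[[1]]
    } else {
      subject_records(subj, master_seed, n_exams, excitation, noise)
    }
    row <- tryCatch(
      extract_fot_parameters(recs, window = window, coherence_min = coherence_min),
      oscillab_qc_error = function(e) {
        tibble::tibble(r0 = NA_real_, rm = NA_real_, r4 = NA_real_, s = NA_real_,
                       xm = NA_real_, fr = NA_real_, cdyn = NA_real_, z4 = NA_real_,
                       n_exams_used = 0L, r4_available = FALSE,
                       fr_extrapolated = FALSE, cdyn_defined = FALSE)
      }
    )
    dplyr::bind_cols(tibble::tibble(subject_id = subj$subject_id, group = subj$group), row)
  })
}
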