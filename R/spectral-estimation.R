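#' Block-FFT (Welch) analysis window specification
#'
#' Controls the averaged-periodogram estimator: 4096-point blocks with 50%
#' overlap by default, matching the measurement protocol, with a Hann taper
#' and per-block linear detrending to suppress breathing leakage into the
#' lowest excitation component. A rectangular taper with no detrending is
#' available for exact noiseless checks.
#'
#' @param block_len Block length in samples.
#' @param overlap Overlap fraction in `[0, 1)`.
#' @param taper `"hann"` or `"rectangular"`.
#' @param detrend Per-block detrending: `"linear"`, `"mean"` or `"none"`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(block_len = 4096, overlap = 0.5,
                        taper = c("hann", "rectangular"),
                        detrend = c("linear", "mean", "none")) {
  taper <- match.arg(taper)
  detrend <- match.arg(detrend)
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1) {
    abort("`overlap` must lie in [0, 1).", class = "oscillab_validation_error")
  }
  if (!is.numeric(block_len) || block_len < 8) {
    abort("`block_len` must be a positive number of samples.", class = "oscillab_validation_error")
  }
  structure(list(block_len = as.integer(block_len), overlap = overlap,
                 taper = taper, detrend = detrend),
            class = "window_spec")
}

detrend_block <- function(x, kind) {
  switch(kind,
         none = x,
         mean = x - mean(x),
         linear = {
           n <- length(x)
           t <- seq_len(n)
           fit <- stats::lm.fit(cbind(1, t), x)
           x - fit$fitted.values
         })
}

#' Averaged cross-spectra of a pressure-flow record
#'
#' Welch-style averaged periodogram over all maximal overlapping blocks:
#' each block is detrended, tapered, FFT'd, and the auto-spectra of pressure
#' (`gpp`) and flow (`gqq`) and the cross-spectrum (`gpq`, pressure times
#' conjugate flow) are averaged across blocks. Bin spacing is
#' `fs / block_len`.
#'
#' @param record A `fot_record` (or any data frame with columns `t_s`,
#'   `p_cmh2o`, `q_lps` sampled uniformly).
#' @param window A [window_spec()].
#' @param fs Sampling rate; taken from the time column when `NULL`.
#' @return A tibble of class `fot_spectra` with columns `freq_hz`, `gpp`,
#'   `gqq` (real) and `gpq` (complex), covering bins 0 .. Nyquist. The
#'   number of averaged blocks is stored in attribute `n_blocks`.
#' @export
welch_cross_spectra <- function(record, window = window_spec(), fs = NULL) {
  stopifnot(is.data.frame(record), all(c("p_cmh2o", "q_lps") %in% names(record)))
  p <- record$p_cmh2o
  q <- record$q_lps
  n <- length(p)
  if (is.null(fs)) {
    if (!"t_s" %in% names(record) || n < 2) {
      abort("Provide `fs` or a `t_s` column.", class = "oscillab_validation_error")
    }
    fs <- 1 / (record$t_s[2] - record$t_s[1])
  }
  L <- window$block_len
  if (n < L) {
    abort("Record is shorter than one analysis block.", class = "oscillab_length_error")
  }
  hop <- max(1L, as.integer(round(L * (1 - window$overlap))))
  starts <- seq(1L, n - L + 1L, by = hop)
  w <- if (window$taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / L)
  } else {
    rep(1, L)
  }
  nb <- L %/% 2 + 1L
  gpp <- numeric(nb); gqq <- numeric(nb); gpq <- complex(nb)
  for (s in starts) {
    idx <- s:(s + L - 1L)
    pb <- detrend_block(p[idx], window$detrend) * w
    qb <- detrend_block(q[idx], window$detrend) * w
    P <- fft(pb)[seq_len(nb)]
    Q <- fft(qb)[seq_len(nb)]
    gpp <- gpp + Re(P * Conj(P))
    gqq <- gqq + Re(Q * Conj(Q))
    gpq <- gpq + P * Conj(Q)
  }
  scale <- 1 / (length(starts) * sum(w^2) * fs)
  out <- tibble::tibble(freq_hz = (seq_len(nb) - 1) * fs / L,
                        gpp = gpp * scale, gqq = gqq * scale, gpq = gpq * scale)
  attr(out, "n_blocks") <- length(starts)
  attr(out, "fs") <- fs
  attr(out, "window") <- window
  class(out) <- c("fot_spectra", class(out))
  out
}

#' Respiratory impedance and coherence at the excitation components
#'
#' Evaluates the flow-referenced spectral estimator
#' \eqn{Z(f) = G_{pq}(f) / G_{qq}(f)} (which attenuates flow-independent
#' output noise) and the magnitude-squared coherence
#' \eqn{\gamma^2(f) = |G_{pq}|^2 / (G_{pp} G_{qq})} at the excitation
#' component bins only. Each component frequency must coincide with an FFT
#' bin of the analysis blocks.
#'
#' @param spectra Output of [welch_cross_spectra()].
#' @param component_freqs Excitation component frequencies, Hz.
#' @return A tibble of class `fot_impedance` with columns `freq_hz`, `z`
#'   (complex), `rrs`, `xrs`, `coherence`. Apply [coherence_qc()] to add
#'   quality flags.
#' @export
impedance_from_spectra <- function(spectra, component_freqs) {
  stopifnot(inherits(spectra, "fot_spectra"))
  df <- spectra$freq_hz[2] - spectra$freq_hz[1]
  k <- component_freqs / df
  if (any(abs(k - round(k)) > 1e-6)) {
    abort("Component frequencies must coincide with FFT bins.",
          class = "oscillab_grid_error")
  }
  idx <- round(k) + 1L
  if (any(idx < 1L | idx > nrow(spectra))) {
    abort("Component frequency outside the spectral grid.", class = "oscillab_grid_error")
  }
  gqq <- spectra$gqq[idx]
  if (any(gqq == 0)) {
    abort("Flow auto-spectrum is zero at an excitation component.",
          class = "oscillab_degenerate_error")
  }
  z <- spectra$gpq[idx] / gqq
  coh <- Mod(spectra$gpq[idx])^2 / (spectra$gpp[idx] * gqq)
  coh <- pmin(pmax(coh, 0), 1)
  out <- tibble::tibble(freq_hz = as.numeric(component_freqs), z = z,
                        rrs = Re(z), xrs = Im(z), coherence = coh)
  class(out) <- c("fot_impedance", class(out))
  out
}

#' Coherence quality gate
#'
#' Flags each excitation component with `qc_pass = coherence >= threshold`
#' (inclusive at the boundary) and the whole exam with
#' `exam_pass = all(qc_pass)`: one adequacy criterion per test, with the
#' per-frequency flags retained for diagnostics.
#'
#' @param mi A `fot_impedance`.
#' @param threshold Minimal acceptable coherence (default 0.9).
#' @return `mi` with a `qc_pass` column and attributes `exam_pass` and
#'   `coherence_threshold`.
#' @export
coherence_qc <- function(mi, threshold = 0.9) {
  stopifnot(inherits(mi, "fot_impedance"))
  if (threshold < 0 || threshold > 1) {
    abort("Coherence threshold must lie in [0, 1].", class = "oscillab_validation_error")
  }
  mi$qc_pass <- mi$coherence >= threshold
  attr(mi, "exam_pass") <- all(mi$qc_pass)
  attr(mi, "coherence_threshold") <- threshold
  mi
}

#' Estimate impedance from a record in one call
#'
#' Convenience chain: [welch_cross_spectra()] then
#' [impedance_from_spectra()] then [coherence_qc()]. Component frequencies
#' default to the record's generating excitation when available.
#'
#' @inheritParams welch_cross_spectra
#' @param component_freqs Excitation components; defaults to the record's
#'   metadata.
#' @param coherence_min QC threshold.
#' @return A QC-flagged `fot_impedance`.
#' @export
measure_impedance <- function(record, window = window_spec(),
                              component_freqs = NULL, coherence_min = 0.9) {
  if (is.null(component_freqs)) {
    meta <- attr(record, "meta")
    if (is.null(meta)) {
      abort("`component_freqs` must be given for records without metadata.",
            class = "oscillab_validation_error")
    }
    component_freqs <- meta$excitation$component_freqs
  }
  sp <- welch_cross_spectra(record, window)
  coherence_qc(impedance_from_spectra(sp, component_freqs), coherence_min)
}

#' Average the impedance of repeated exams
#'
#' Implements the measure-three-average protocol: the final impedance is the
#' complex mean of `Z` across the exams that passed the coherence gate. An
#' exam whose `exam_pass` attribute is `FALSE` is excluded; if no exam
#' passes, a subject-level QC failure condition is signalled.
#'
#' @param exams A list of QC-flagged `fot_impedance` objects on the same
#'   frequency grid.
#' @return A `fot_impedance` with mean `z`, `rrs`, `xrs` and `coherence`,
#'   `qc_pass` all `TRUE`, and attributes `exam_pass = TRUE` and
#'   `n_exams_used`.
#' @export
average_exams <- function(exams) {
  stopifnot(is.list(exams), length(exams) >= 1L)
  ok <- purrr::map_lgl(exams, function(e) isTRUE(attr(e, "exam_pass")))
  if (!any(ok)) {
    abort("No exam passed the coherence quality gate.", class = "oscillab_qc_error")
  }
  keep <- exams[ok]
  f0 <- keep[[1]]$freq_hz
  for (e in keep) {
    if (length(e$freq_hz) != length(f0) || any(abs(e$freq_hz - f0) > 1e-9)) {
      abort("Exams must share the same frequency grid.", class = "oscillab_validation_error")
    }
  }
  zbar <- Reduce(`+`, purrr::map(keep, "z")) / length(keep)
  coh <- Reduce(`+`, purrr::map(keep, "coherence")) / length(keep)
  out <- tibble::tibble(freq_hz = f0, z = zbar, rrs = Re(zbar), xrs = Im(zbar),
                        coherence = coh, qc_pass = TRUE)
  attr(out, "exam_pass") <- TRUE
  attr(out, "n_exams_used") <- length(keep)
  class(out) <- c("fot_impedance", class(out))
  out
}

#' @describeIn impedance_from_spectra Plot measured resistance and reactance
#'   with coherence shown by point colour.
#' @param object A `fot_impedance`.
#' @param ... Unused.
#' @exportS3Method
autoplot.fot_impedance <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "freq_hz", "rrs", "xrs", "coherence"),
    c("rrs", "xrs"),
    names_to = "component", values_to = "value"
  )
  long$component <- factor(long$component, levels = c("rrs", "xrs"),
                           labels = c("Resistance Rrs", "Reactance Xrs"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$freq_hz, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$coherence)) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Impedance (cmH2O.s/L)",
                  colour = expression(gamma^2))
}
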