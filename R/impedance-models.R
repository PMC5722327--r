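#' Mechanical models of respiratory input impedance
#'
#' Constructs a forward mechanical model of the respiratory system used as
#' ground truth throughout the simulation pipeline. Four topologies are
#' available:
#'
#' * `"pure_resistor"`: \eqn{Z(f) = R}, no reactance.
#' * `"ric"`: series resistance--inertance--compliance,
#'   \eqn{Z(f) = R + j(2\pi f I - 1/(2\pi f C))}.
#' * `"eric"`: extended RIC in which the resistive part depends linearly on
#'   frequency, \eqn{Re\,Z(f) = R + S f}; the reactance is identical to the
#'   RIC model. This variant produces the negative frequency dependence of
#'   resistance (S < 0) that marks ventilation heterogeneity, which a single
#'   RIC branch cannot generate.
#' * `"two_compartment"`: two RIC branches combined in parallel,
#'   \eqn{Z = Z_1 Z_2 / (Z_1 + Z_2)}, a minimal surrogate for parallel
#'   heterogeneity of the lung periphery.
#'
#' The reactance sign convention is inertial-positive and compliant-negative:
#' at low frequency the compliant term dominates and \eqn{X < 0}; the two
#' contributions cancel at the resonance frequency.
#'
#' @param variant Model topology, one of `"pure_resistor"`, `"ric"`,
#'   `"eric"`, `"two_compartment"`.
#' @param R Resistance in cmH2O.s/L. Must be positive.
#' @param I Inertance in cmH2O.s^2/L. Must be non-negative (required > 0 for
#'   a defined resonance).
#' @param C Compliance in L/cmH2O. Must be positive for reactive variants.
#' @param S Resistance slope in cmH2O.s/L per Hz (`"eric"` only). The
#'   resistive part must remain positive over the 4--32 Hz measurement band.
#' @param branch2 For `"two_compartment"`, a named list `list(R=, I=, C=)`
#'   giving the second parallel branch.
#'
#' @return An object of class `fot_model`.
#' @examples
#' m <- mech_model("ric", R = 2.77, I = 0.01, C = 0.02)
#' eval_impedance(m, c(4, 16, 32))
#' resonance_frequency(m)
#' @export
mech_model <- function(variant = c("ric", "eric", "pure_resistor", "two_compartment"),
                       R, I = 0, C = NULL, S = 0, branch2 = NULL) {
  variant <- match.arg(variant)
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0) {
    abort("`R` must be a single positive number (cmH2O.s/L).", class = "oscillab_model_error")
  }
  if (!is.numeric(I) || length(I) != 1L || !is.finite(I) || I < 0) {
    abort("`I` must be a single non-negative number (cmH2O.s^2/L).", class = "oscillab_model_error")
  }
  if (variant %in% c("ric", "eric", "two_compartment")) {
    if (is.null(C) || !is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0) {
      abort("`C` must be a single positive number (L/cmH2O) for reactive models.",
            class = "oscillab_model_error")
    }
  }
  if (variant == "eric") {
    if (!is.numeric(S) || length(S) != 1L || !is.finite(S)) {
      abort("`S` must be a single finite number (cmH2O.s/L per Hz).",
            class = "oscillab_model_error")
    }
    if (R + S * 32 <= 0) {
      abort("eric model has non-positive resistance within the 4-32 Hz band.",
            class = "oscillab_model_error")
    }
  } else {
    S <- 0
  }
  if (variant == "two_compartment") {
    ok <- is.list(branch2) && all(c("R", "I", "C") %in% names(branch2)) &&
      branch2$R > 0 && branch2$I >= 0 && branch2$C > 0
    if (!ok) {
      abort("two_compartment requires `branch2 = list(R =, I =, C =)` with R > 0, I >= 0, C > 0.",
            class = "oscillab_model_error")
    }
    branch2 <- branch2[c("R", "I", "C")]
  } else {
    branch2 <- NULL
  }
  structure(
    list(variant = variant, R = R, I = I, C = if (is.null(C)) NA_real_ else C,
         S = S, branch2 = branch2),
    class = "fot_model"
  )
}

#' @export
print.fot_model <- function(x, ...) {
  cat("<fot_model> variant:", x$variant, "\n")
  cat("  R =", x$R, "cmH2O.s/L")
  if (x$variant != "pure_resistor") cat(", I =", x$I, "cmH2O.s^2/L, C =", x$C, "L/cmH2O")
  if (x$variant == "eric") cat(", S =", x$S, "cmH2O.s/L/Hz")
  cat("\n")
  if (!is.null(x$branch2)) {
    cat("  branch2: R =", x$branch2$R, ", I =", x$branch2$I, ", C =", x$branch2$C, "\n")
  }
  invisible(x)
}

series_impedance <- function(R, I, C, S, freqs) {
  w <- 2 * pi * freqs
  complex(real = R + S * freqs, imaginary = w * I - 1 / (w * C))
}

#' Evaluate a mechanical model's impedance spectrum
#'
#' Computes the complex respiratory input impedance of a [mech_model()] at a
#' set of frequencies. Frequencies are in Hz throughout; angular conversion
#' happens inside the formulas.
#'
#' @param model A `fot_model`.
#' @param freqs Numeric vector of strictly positive frequencies (Hz).
#'
#' @return A tibble of class `fot_spectrum` with columns `freq_hz`, `z`
#'   (complex impedance, cmH2O.s/L), `rrs` (resistance, its real part) and
#'   `xrs` (reactance, its imaginary part).
#' @examples
#' eval_impedance(mech_model("pure_resistor", R = 3), c(4, 16))
#' @export
eval_impedance <- function(model, freqs) {
  stopifnot(inherits(model, "fot_model"))
  if (!is.numeric(freqs) || length(freqs) == 0L || any(!is.finite(freqs)) || any(freqs <= 0)) {
    abort("`freqs` must be positive finite frequencies in Hz.", class = "oscillab_domain_error")
  }
  z <- switch(
    model$variant,
    pure_resistor = complex(real = rep(model$R, length(freqs)), imaginary = rep(0, length(freqs))),
    ric = series_impedance(model$R, model$I, model$C, 0, freqs),
    eric = series_impedance(model$R, model$I, model$C, model$S, freqs),
    two_compartment = {
      z1 <- series_impedance(model$R, model$I, model$C, 0, freqs)
      z2 <- series_impedance(model$branch2$R, model$branch2$I, model$branch2$C, 0, freqs)
      z1 * z2 / (z1 + z2)
    }
  )
  out <- tibble::tibble(freq_hz = as.numeric(freqs), z = z, rrs = Re(z), xrs = Im(z))
  class(out) <- c("fot_spectrum", class(out))
  out
}

#' Closed-form resonance frequency of a series RIC branch
#'
#' The resonance frequency is where the inertial and compliant contributions
#' to reactance cancel: \eqn{f_r = 1 / (2\pi \sqrt{I C})}. Defined for the
#' `"ric"` and `"eric"` variants (the resistance slope of the eric model does
#' not affect reactance). For two-compartment models use a numeric
#' zero-crossing of [eval_impedance()] instead.
#'
#' @param model A `fot_model` with variant `"ric"` or `"eric"` and `I > 0`.
#' @return Resonance frequency in Hz.
#' @examples
#' resonance_frequency(mech_model("ric", R = 2.77, I = 0.01, C = 0.02))
#' @export
resonance_frequency <- function(model) {
  stopifnot(inherits(model, "fot_model"))
  if (!model$variant %in% c("ric", "eric")) {
    abort("Closed-form resonance is defined for 'ric' and 'eric' variants only.",
          class = "oscillab_unsupported_error")
  }
  if (model$I <= 0) {
    abort("Resonance is undefined for zero inertance.", class = "oscillab_domain_error")
  }
  1 / (2 * pi * sqrt(model$I * model$C))
}

#' @describeIn eval_impedance Plot resistance and reactance against frequency.
#' @param object A `fot_spectrum`.
#' @param ... Unused.
#' @exportS3Method
autoplot.fot_spectrum <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "freq_hz", "rrs", "xrs"),
    c("rrs", "xrs"),
    names_to = "component", values_to = "value"
  )
  long$component <- factor(long$component, levels = c("rrs", "xrs"),
                           labels = c("Resistance Rrs", "Reactance Xrs"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$freq_hz, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Impedance (cmH2O.s/L)")
}
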