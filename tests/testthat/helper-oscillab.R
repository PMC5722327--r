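# Shared fixtures, all generated in code.

ric_model <- function(R = 2.77, I = 0.01, C = 0.02) {
  mech_model("ric", R = R, I = I, C = C)
}

# Exact estimator configuration: bin-aligned noiseless signals are untouched.
exact_window <- function() {
  window_spec(taper = "rectangular", detrend = "none")
}

# Hand-built measured-impedance tibble for unit tests of the extractors.
fake_impedance <- function(freqs, rrs, xrs, coherence = 1) {
  z <- complex(real = rrs, imaginary = xrs)
  out <- tibble::tibble(freq_hz = freqs, z = z, rrs = rrs, xrs = xrs,
                        coherence = rep_len(coherence, length(freqs)))
  class(out) <- c("fot_impedance", class(out))
  out
}

# Two-group feature table with one informative feature and pure-noise ones.
planted_feature_table <- function(n_per_group = 20, n_noise = 2, shift = 3,
                                  seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    tbl <- tibble::tibble(
      group = rep(c("control", "AE"), each = n_per_group),
      signal = rnorm(n) + rep(c(0, shift), each = n_per_group)
    )
    for (j in seq_len(n_noise)) tbl[[paste0("noise", j)]] <- rnorm(n)
    tbl
  })
}

trapezoid_area <- function(curve) {
  pts <- curve$points[order(curve$points$fpr, curve$points$tpr), ]
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

# Brute-force Mann-Whitney pair counting (independent oracle).
pair_count_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
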