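#' Resample a diameter trace into the 1 Hz pupillary rhythm
#'
#' Collapses the frame-rate diameter signal into non-overlapping 1 s block
#' means (a 1 s window with a 1 s stride), the "pupillary rhythm". Within
#' each window only valid samples contribute, so blinks shorter than one
#' second never empty a window and cost nothing; windows with no valid
#' sample at all are filled by linear interpolation between neighboring
#' defined values (edge windows take the nearest defined value).
#'
#' @param trace Tibble with columns `diameter_px` and `valid` (e.g. from
#'   [extract_trace()] or [simulate_trace()]); the frame rate is taken from
#'   the `fps` attribute, or inferred from `t_s`, or given explicitly.
#' @param fps Frames per second of the trace.
#' @return A tibble `(t_s, diameter_px, valid_fraction)` with one row per
#'   second and attribute `rate = 1`; class `pupillary_rhythm` is prepended
#'   for plotting.
#' @examples
#' tr <- simulate_trace("pre2D", duration = 30, seed = 1)
#' resample_rhythm(tr)
#' @export
resample_rhythm <- function(trace, fps = NULL) {
  fps <- fps %||% attr(trace, "fps") %||%
    (if ("t_s" %in% names(trace)) round(1 / median(diff(trace$t_s))) else NULL)
  if (is.null(fps) || !is.finite(fps) || fps < 1) {
    abort("Cannot determine the frame rate; supply `fps`.")
  }
  w <- as.integer(round(fps))
  n_win <- floor(nrow(trace) / w)
  if (n_win < 2) abort("Trace must span at least 2 seconds.")
  if (!any(trace$valid)) abort("Trace has no valid samples.")
  idx <- rep(seq_len(n_win), each = w)
  d <- trace$diameter_px[seq_len(n_win * w)]
  v <- trace$valid[seq_len(n_win * w)]
  d[!v] <- NA_real_
  means <- tapply(d, idx, mean, na.rm = TRUE)
  means[is.nan(means)] <- NA_real_
  vfrac <- tapply(v, idx, mean)
  filled <- zoo::na.approx(as.numeric(means), na.rm = FALSE, rule = 2)
  out <- tibble::tibble(t_s = seq_len(n_win) - 1,
                        diameter_px = as.numeric(filled),
                        valid_fraction = as.numeric(vfrac))
  attr(out, "rate") <- 1
  class(out) <- c("pupillary_rhythm", class(out))
  out
}

#' Mean and standard deviation of the pupillary rhythm (mPD, sPD)
#'
#' The two time-domain sickness indicators: the arithmetic mean and the
#' sample (n - 1) standard deviation of the 1 Hz rhythm, in pixels.
#'
#' @param rhythm Tibble with a `diameter_px` column (>= 2 rows).
#' @return One-row tibble `(mPD, sPD)`.
#' @export
rhythm_mean_sd <- function(rhythm) {
  x <- rhythm$diameter_px
  if (length(x) < 2) abort("Need at least 2 rhythm values for mPD/sPD.")
  tibble::tibble(mPD = mean(x), sPD = sd(x))
}

#' One-sided power spectrum of the pupillary rhythm
#'
#' Mean-subtracts the rhythm, applies a periodic Hanning window (or a
#' rectangular one for normalization checks), takes the discrete Fourier
#' transform and keeps the one-sided power in (0, 0.5\] Hz — the DC bin is
#' excluded, since the ~35 px mean would otherwise swamp every other bin.
#' Power is normalized as `2 |X_k|^2 / N` (Nyquist bin not doubled), so
#' with a rectangular window the retained power sums to
#' `sum((x - mean(x))^2)` (Parseval).
#'
#' @param rhythm Tibble with `diameter_px` (>= 8 rows) at 1 Hz.
#' @param window `"hanning"` (default) or `"rectangular"`.
#' @return A tibble `(freq_hz, power)` of class `rhythm_spectrum`, with
#'   attributes `dominant_bin`, `dominant_power`, `total_power`, `window`.
#' @export
rhythm_spectrum <- function(rhythm, window = c("hanning", "rectangular")) {
  window <- match.arg(window)
  x <- if (is.data.frame(rhythm)) rhythm$diameter_px else as.numeric(rhythm)
  n <- length(x)
  if (n < 8) abort("Need at least 8 rhythm samples for a spectrum.")
  x0 <- x - mean(x)
  w <- if (window == "hanning") {
    0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
  } else rep(1, n)
  X <- fft(x0 * w)
  kmax <- floor(n / 2)
  k <- seq_len(kmax)
  power <- 2 * Mod(X[k + 1])^2 / n
  if (n %% 2 == 0) power[kmax] <- power[kmax] / 2  # Nyquist bin not doubled
  out <- tibble::tibble(freq_hz = k / n, power = power)
  attr(out, "dominant_bin") <- which.max(power)
  attr(out, "dominant_power") <- max(power)
  attr(out, "total_power") <- sum(power)
  attr(out, "window") <- window
  class(out) <- c("rhythm_spectrum", class(out))
  out
}

#' Pupillary rhythm coherence (PRC) ratio
#'
#' The frequency-domain sickness indicator: the power in the dominant peak
#' band divided by the power everywhere else in the 0-0.5 Hz range,
#' `PRC = P_dominant / (P_total - P_dominant)`. A rhythm locked to one
#' frequency gives a high ratio; a broadband, irregular rhythm — the
#' motion-sickness signature — gives a low one.
#'
#' @param spectrum A [rhythm_spectrum()] tibble.
#' @param band_halfwidth Dominant band half-width in bins around the peak
#'   (default 0, a single bin).
#' @return The PRC ratio (scalar). `Inf` with a warning when essentially
#'   all power sits in the peak band (degenerate rhythm).
#' @export
prc_ratio <- function(spectrum, band_halfwidth = 0) {
  total <- attr(spectrum, "total_power") %||% sum(spectrum$power)
  if (!isTRUE(total > 0)) abort("Total spectral power must be positive.")
  dom <- attr(spectrum, "dominant_bin") %||% which.max(spectrum$power)
  band <- max(1, dom - band_halfwidth):min(nrow(spectrum), dom + band_halfwidth)
  p_band <- sum(spectrum$power[band])
  denom <- total - p_band
  if (denom < 1e-12) {
    warn("Degenerate spectrum: all power in the dominant band; PRC is Inf.")
    return(Inf)
  }
  p_band / denom
}

#' Compute the three sickness indicators from a diameter trace
#'
#' Composition of the rhythm pipeline: 1 Hz resampling, mPD/sPD, Hanning
#' spectrum and PRC ratio.
#'
#' @param trace Diameter trace (see [resample_rhythm()]).
#' @param band_halfwidth Passed to [prc_ratio()].
#' @param fps Frame rate override.
#' @return One-row tibble `(mPD, sPD, prc)`; `prc` is `NA` when the rhythm
#'   carries no spectral power at all (a constant signal).
#' @examples
#' features_from_trace(simulate_trace("postHMD", duration = 60, seed = 1))
#' @export
features_from_trace <- function(trace, band_halfwidth = 0, fps = NULL) {
  rhythm <- resample_rhythm(trace, fps = fps)
  ms <- rhythm_mean_sd(rhythm)
  spec <- rhythm_spectrum(rhythm)
  prc <- if (attr(spec, "total_power") <= 1e-12) NA_real_ else {
    prc_ratio(spec, band_halfwidth)
  }
  tibble::tibble(mPD = ms$mPD, sPD = ms$sPD, prc = prc)
}
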