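# Shared fixture builders (small frames keep the detection tests quick).

small_frame <- function(cx = 100, cy = 75, r = 20, width = 200, height = 150,
                        ...) {
  render_eye_frame(width = width, height = height, pupil_center = c(cx, cy),
                   pupil_radius = r, ...)
}

small_params <- function(r_min = 10, r_max = 35, ...) {
  cde_params(r_min = r_min, r_max = r_max, ...)
}

# a constant-diameter trace with explicit validity
constant_trace <- function(n, value = 35, fps = 30, valid = rep(TRUE, n)) {
  d <- rep(value, n)
  d[!valid] <- NA_real_
  out <- tibble::tibble(frame = seq_len(n) - 1L, t_s = (seq_len(n) - 1) / fps,
                        diameter_px = d, valid = valid)
  attr(out, "fps") <- fps
  out
}

# rhythm tibble straight from values (already at 1 Hz)
rhythm_from_values <- function(x) {
  out <- tibble::tibble(t_s = seq_along(x) - 1, diameter_px = x,
                        valid_fraction = 1)
  attr(out, "rate") <- 1
  class(out) <- c("pupillary_rhythm", class(out))
  out
}

# hand-built spectrum object for closed-form PRC checks
spectrum_from_powers <- function(power) {
  out <- tibble::tibble(freq_hz = seq_along(power) / (2 * length(power)),
                        power = power)
  attr(out, "dominant_bin") <- which.max(power)
  attr(out, "dominant_power") <- max(power)
  attr(out, "total_power") <- sum(power)
  attr(out, "window") <- "hanning"
  class(out) <- c("rhythm_spectrum", class(out))
  out
}

# well-separated two-class feature table
separable_features <- function(n_per_class = 10, gap = 10, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    tibble::tibble(
      subject = seq_len(2 * n_per_class),
      condition = rep(c("2D", "HMD"), each = n_per_class),
      mPD = c(rnorm(n_per_class, 35, 0.5), rnorm(n_per_class, 35 + gap, 0.5)),
      sPD = c(rnorm(n_per_class, 1.3, 0.1), rnorm(n_per_class, 2.5, 0.1)),
      prc = c(rnorm(n_per_class, 0.5, 0.05), rnorm(n_per_class, 0.05, 0.01)))
  })
}
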