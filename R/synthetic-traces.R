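#' Session presets for the four viewing conditions
#'
#' Returns the generator parameters used to emulate pupil-diameter dynamics
#' before/after viewing ordinary 2D content and immersive HMD content. The
#' numbers are anchored to the exemplar values the method was developed
#' against: a stable, narrowband rhythm around 35 px with sPD near 1.3 px
#' and a spectral-coherence (PRC) ratio near 0.5 in every condition except
#' post-HMD, where the mean rises to ~43 px, sPD to ~2.5 px and the rhythm
#' becomes broadband (PRC below 0.1).
#'
#' @param condition One of `"pre2D"`, `"post2D"`, `"preHMD"`, `"postHMD"`.
#' @return A one-row tibble of `simulate_trace()` parameters.
#' @export
session_preset <- function(condition = c("pre2D", "post2D", "preHMD", "postHMD")) {
  condition <- match.arg(condition)
  if (condition == "postHMD") {
    tibble::tibble(condition = condition, base_diameter = 43,
                   dominant_freq = 0.1, dominant_amplitude = 0.3,
                   broadband_sd = 2.5)
  } else {
    tibble::tibble(condition = condition, base_diameter = 35,
                   dominant_freq = 0.1, dominant_amplitude = 1.3,
                   broadband_sd = 0.9)
  }
}

#' Simulate a 30 fps pupil-diameter trace
#'
#' The model is `diameter(t) = base + A sin(2*pi*f*t + phi) + b(t)` where
#' `b(t)` is a broadband disturbance: white Gaussian across seconds, held
#' piecewise-constant within each second so that its power lies inside the
#' analysed 0-0.5 Hz band and survives the 1 s block-averaging that builds
#' the pupillary rhythm. Blinks arrive as a Poisson process and mark samples
#' invalid (diameters during blinks are not fabricated).
#'
#' @param condition Optional preset name (see [session_preset()]); explicit
#'   arguments override preset values.
#' @param duration Recording length, seconds (default 300, a 5-min session).
#' @param fps Frames per second (default 30).
#' @param base_diameter Mean pupil diameter, pixels.
#' @param diameter_sd Between-session sd of the baseline, pixels; a single
#'   baseline offset is drawn per call.
#' @param dominant_freq Frequency of the dominant rhythm component, Hz
#'   (must lie in (0, 0.5]).
#' @param dominant_amplitude Amplitude of the dominant component, pixels.
#' @param broadband_sd Sd of the broadband disturbance, pixels.
#' @param blink_rate Blink events per minute.
#' @param blink_duration Blink length, seconds (must be < `duration`).
#' @param seed RNG seed; fixed seed gives a bit-identical trace.
#'
#' @return A tibble `(frame, t_s, diameter_px, valid)` with attribute
#'   `fps`; diameters on invalid (blink) samples are `NA`.
#' @examples
#' tr <- simulate_trace("postHMD", duration = 60, seed = 1)
#' mean(tr$diameter_px, na.rm = TRUE)
#' @export
simulate_trace <- function(condition = NULL,
                           duration = 300, fps = 30,
                           base_diameter = 35, diameter_sd = 0,
                           dominant_freq = 0.1, dominant_amplitude = 1.3,
                           broadband_sd = 0.9,
                           blink_rate = 10, blink_duration = 0.2,
                           seed = NULL) {
  if (!is.null(condition)) {
    p <- session_preset(condition)
    if (missing(base_diameter)) base_diameter <- p$base_diameter
    if (missing(dominant_freq)) dominant_freq <- p$dominant_freq
    if (missing(dominant_amplitude)) dominant_amplitude <- p$dominant_amplitude
    if (missing(broadband_sd)) broadband_sd <- p$broadband_sd
  }
  if (dominant_freq <= 0 || dominant_freq > 0.5) {
    abort("`dominant_freq` must lie in (0, 0.5] Hz.")
  }
  n <- floor(duration * fps)
  if (n < 2) abort("`duration * fps` must give at least 2 samples.")
  if (blink_duration >= duration) abort("`blink_duration` must be shorter than `duration`.")

  local_seed(seed, {
    t_s <- (seq_len(n) - 1) / fps
    base <- base_diameter + if (diameter_sd > 0) rnorm(1, 0, diameter_sd) else 0
    phi <- runif(1, 0, 2 * pi)
    n_sec <- ceiling(duration)
    b_sec <- if (broadband_sd > 0) rnorm(n_sec, 0, broadband_sd) else numeric(n_sec)
    d <- base +
      dominant_amplitude * sin(2 * pi * dominant_freq * t_s + phi) +
      b_sec[pmin(floor(t_s), n_sec - 1) + 1]
    valid <- rep(TRUE, n)
    n_blinks <- rpois(1, blink_rate * duration / 60)
    if (n_blinks > 0) {
      starts <- runif(n_blinks, 0, duration - blink_duration)
      for (s in starts) valid[t_s >= s & t_s < s + blink_duration] <- FALSE
    }
    d[!valid] <- NA_real_
    out <- tibble::tibble(frame = seq_len(n) - 1L, t_s = t_s,
                          diameter_px = d, valid = valid)
    attr(out, "fps") <- fps
    out
  })
}

# rating probabilities per condition; scaled by severity and clipped to [0,1]
ssq_item_rate <- function(condition, severity_scale) {
  base <- switch(condition,
                 pre2D = 0.015, preHMD = 0.015, post2D = 0.03,
                 postHMD = 0.12,
                 abort(sprintf("Unknown condition '%s'.", condition)))
  pmin(pmax(base * severity_scale, 0), 1)
}

#' Simulate one 16-item Simulator Sickness Questionnaire response
#'
#' Item ratings are drawn as Binomial(3, p) with a condition-dependent rate
#' p, so expected severity orders post-HMD >> post-2D > pre-viewing, the
#' pattern a sickness-inducing HMD session produces.
#'
#' @param condition `"pre2D"`, `"post2D"`, `"preHMD"` or `"postHMD"`.
#' @param severity_scale Non-negative multiplier on the rating rate; 0
#'   yields an all-zero response.
#' @param seed RNG seed.
#' @return A one-row tibble with columns `condition`, `item01` ... `item16`
#'   (ratings in 0-3).
#' @export
simulate_ssq <- function(condition = "postHMD", severity_scale = 1, seed = NULL) {
  if (severity_scale < 0) abort("`severity_scale` must be >= 0.")
  p <- ssq_item_rate(condition, severity_scale)
  ratings <- local_seed(seed, rbinom(16, 3, p))
  out <- tibble::as_tibble(as.list(stats::setNames(
    as.integer(ratings), sprintf("item%02d", 1:16))))
  dplyr::bind_cols(tibble::tibble(condition = condition), out)
}

#' Simulate a labeled within-subject cohort
#'
#' Generates, for each subject, the four recording sessions of the study
#' design (pre/post x 2D/HMD): a 5-min diameter trace per session run
#' through the actual rhythm-feature pipeline, plus an SSQ response. Under
#' the `"strong"` preset post-HMD sessions show the motion-sickness
#' signature (mPD and sPD up, PRC ratio down, SSQ up) with per-subject
#' severity variation; `"weak"` shrinks the effects to 30%; `"null"` makes
#' all four sessions exchangeable draws from the same pre-viewing regime.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param effect_preset `"strong"`, `"weak"` or `"null"`.
#' @param duration Session length in seconds (default 300).
#' @param seed RNG seed for the whole cohort.
#' @return A tibble with one row per subject x condition x phase:
#'   `(subject, condition, phase, mPD, sPD, prc, ssq_total, ssq_N, ssq_O,
#'   ssq_D)`. The raw SSQ item table is attached as attribute `ssq_items`.
#' @examples
#' co <- simulate_cohort(4, "strong", duration = 60, seed = 1)
#' dplyr::group_by(co, condition, phase) |> dplyr::summarise(m = mean(mPD))
#' @export
simulate_cohort <- function(n_subjects = 24,
                            effect_preset = c("strong", "weak", "null"),
                            duration = 300, seed = NULL) {
  effect_preset <- match.arg(effect_preset)
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.")
  eff <- switch(effect_preset, strong = 1, weak = 0.3, null = 0)

  local_seed(seed, {
    rows <- list(); items <- list()
    for (i in seq_len(n_subjects)) {
      b_i <- rnorm(1, 0, 1.5)                      # subject baseline offset
      s_i <- max(0.2, rnorm(1, 1, 0.3))            # subject severity
      for (cond in c("2D", "HMD")) {
        for (phase in c("pre", "post")) {
          session <- paste0(phase, cond)
          sick <- eff > 0 && session == "postHMD"
          base <- 35 + b_i + if (sick) 8 * s_i * eff else 0
          bb <- 0.9 + if (sick) 1.6 * s_i * eff else 0
          amp <- if (sick) max(0.2, 1.3 - 1.0 * s_i * eff) else 1.3
          tr <- simulate_trace(duration = duration, base_diameter = base,
                               dominant_amplitude = amp, broadband_sd = bb,
                               seed = NULL)
          ft <- features_from_trace(tr)
          sev <- if (eff == 0) {
            resp_cond <- "pre2D"; 1
          } else {
            resp_cond <- session; s_i
          }
          resp <- simulate_ssq(resp_cond, severity_scale = sev)
          sc <- score_ssq(resp)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            subject = i, condition = cond, phase = phase,
            mPD = ft$mPD, sPD = ft$sPD, prc = ft$prc,
            ssq_total = sc$ssq_total, ssq_N = sc$N, ssq_O = sc$O, ssq_D = sc$D)
          resp$subject <- i; resp$phase <- phase
          resp$condition <- cond
          items[[length(items) + 1L]] <- resp
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "ssq_items") <- dplyr::bind_rows(items)
    attr(out, "effect_preset") <- effect_preset
    out
  })
}
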