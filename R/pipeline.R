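#' End-to-end pipeline configuration
#'
#' Bundles every tunable of the frames-to-decision chain so a serialized
#' config plus a seed reproduces identical outputs.
#'
#' @param fps Frame rate of incoming sessions.
#' @param cde A [cde_params()] object.
#' @param glint_threshold Saturation threshold for glint detection.
#' @param threshold_coefs Auto-threshold coefficients (see
#'   [compute_threshold()]).
#' @param band_halfwidth Dominant-band half-width for the PRC ratio.
#' @param classifier A [classifier_spec()].
#' @param decision_window_s Length of the rolling rhythm window the online
#'   decision is computed on, seconds. 60 s trades the 5-min offline
#'   window for responsiveness.
#' @param decision_step_s Stride between successive online decisions.
#' @param seed Default RNG seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fps = 30, cde = cde_params(),
                            glint_threshold = 250,
                            threshold_coefs = c(b_mean = -0.418,
                                                b_max = 1.051,
                                                intercept = 7.973),
                            band_halfwidth = 0,
                            classifier = classifier_spec("svm_rbf"),
                            decision_window_s = 60, decision_step_s = 10,
                            seed = 1) {
  structure(list(fps = fps, cde = cde, glint_threshold = glint_threshold,
                 threshold_coefs = threshold_coefs,
                 band_halfwidth = band_halfwidth, classifier = classifier,
                 decision_window_s = decision_window_s,
                 decision_step_s = decision_step_s, seed = seed),
            class = "pipeline_config")
}

session_features <- function(session, config) {
  trace <- if (is.data.frame(session)) session
  else extract_trace(session, config$cde, fps = config$fps,
                     glint_threshold = config$glint_threshold,
                     threshold_coefs = config$threshold_coefs)
  features_from_trace(trace, band_halfwidth = config$band_halfwidth,
                      fps = attr(trace, "fps") %||% config$fps)
}

#' Offline training: labeled sessions to a frozen model artifact
#'
#' Turns labeled training material into a classifier artifact. Sessions
#' may arrive as frame lists (run through detection), as diameter traces
#' (run through the rhythm pipeline), or as an already-computed feature
#' table with columns `mPD`, `sPD`, `prc` and the label column.
#'
#' @param training Either a feature data frame (with a `condition`
#'   column), or a list with elements `sessions` (list of frame lists or
#'   trace tibbles) and `labels` (character vector).
#' @param config A [pipeline_config()].
#' @param seed RNG seed for training.
#' @return A list of class `ms_artifact`: the fitted `ms_model`, the
#'   config, and a hash binding the two.
#' @export
run_offline_training <- function(training, config = pipeline_config(),
                                 seed = config$seed) {
  feats <- if (is.data.frame(training)) {
    tibble::as_tibble(training)
  } else {
    if (is.null(training$sessions) || is.null(training$labels)) {
      abort("`training` needs `sessions` and `labels` (or a feature table).")
    }
    if (length(training$sessions) != length(training$labels)) {
      abort("Each training session needs a label.")
    }
    ft <- purrr::map_dfr(training$sessions, session_features, config = config)
    ft$condition <- training$labels
    ft
  }
  model <- fit_classifier(feats, config$classifier, seed = seed)
  structure(list(model = model, config = config,
                 config_hash = rlang::hash(list(config, feats)),
                 n_sessions = nrow(feats)),
            class = "ms_artifact")
}

#' Online decision: one session to a motion-sickness call
#'
#' Processes a session with the artifact's frozen model. The rhythm is
#' evaluated on a rolling window (`decision_window_s`), advancing by
#' `decision_step_s`, so the decision updates as each window completes;
#' the final row is the current call.
#'
#' @param artifact An `ms_artifact` from [run_offline_training()].
#' @param session A frame list or a diameter-trace tibble.
#' @param config Config override (defaults to the artifact's).
#' @return A tibble with one row per completed window:
#'   `(window_start_s, window_end_s, mPD, sPD, prc, score, label)`, where
#'   `label` is `"motion_sickness"` or `"normal"`.
#' @export
run_online_decision <- function(artifact, session, config = artifact$config) {
  if (!inherits(artifact, "ms_artifact")) abort("`artifact` must be an ms_artifact.")
  trace <- if (is.data.frame(session)) session
  else extract_trace(session, config$cde, fps = config$fps,
                     glint_threshold = config$glint_threshold,
                     threshold_coefs = config$threshold_coefs)
  fps <- attr(trace, "fps") %||% config$fps
  dur <- nrow(trace) / fps
  win <- config$decision_window_s
  if (dur < win) {
    abort(sprintf("Session (%.1f s) shorter than the %.0f s decision window.",
                  dur, win))
  }
  starts <- seq(0, dur - win, by = config$decision_step_s)
  purrr::map_dfr(starts, function(s) {
    seg <- trace[trace$t_s >= s & trace$t_s < s + win, , drop = FALSE]
    attr(seg, "fps") <- fps
    ft <- features_from_trace(seg, band_halfwidth = config$band_halfwidth,
                              fps = fps)
    score <- predict(artifact$model, ft, type = "score")
    lab <- predict(artifact$model, ft, type = "label")
    tibble::tibble(window_start_s = s, window_end_s = s + win,
                   mPD = ft$mPD, sPD = ft$sPD, prc = ft$prc,
                   score = score,
                   label = ifelse(lab == artifact$model$positive,
                                  "motion_sickness", "normal"))
  })
}
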