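#' Render a synthetic infrared eye frame with known ground truth
#'
#' Draws the canonical dark-pupil IR image the detection chain expects: a
#' bright sclera background, a darker iris disk, a darkest pupil disk and a
#' saturated corneal glint, plus optional additive Gaussian noise clipped to
#' the 8-bit range. The generated pupil center and radius are attached as
#' ground truth so detection accuracy can be scored exactly.
#'
#' Coordinates are 0-based with `x` running along columns and `y` along
#' rows; pixel centers sit at integer coordinates. A pixel belongs to a disk
#' when its center lies within the disk radius (inclusive).
#'
#' @param width,height Frame size in pixels. Defaults mirror a 960 x 400
#'   IR eye camera, scaled down 1:2 to keep single frames light.
#' @param pupil_center Numeric `(x, y)` of the pupil center, pixels.
#' @param pupil_radius Pupil radius in pixels.
#' @param pupil_intensity,iris_intensity,sclera_intensity Gray levels
#'   (0-255); must satisfy pupil < iris < sclera. The glint is always 255.
#' @param iris_radius Iris radius in pixels (concentric with the pupil).
#' @param glint_center `(x, y)` of the corneal glint, or `NULL` for the
#'   default offset just above-right of the pupil center. `NA` omits the
#'   glint entirely.
#' @param glint_radius Glint radius in pixels.
#' @param noise_sd Standard deviation of additive Gaussian noise, gray
#'   levels.
#' @param occluded If `TRUE`, renders an eyelid-closed (blink) frame: a
#'   featureless lid at the iris gray level with noise, no pupil, no glint.
#' @param frame_index Integer index carried through to the trace.
#' @param seed RNG seed for the noise; `NULL` uses the current stream.
#'
#' @return An object of class `eye_frame`: a list with `pixels` (numeric
#'   matrix, rows = y, cols = x, gray 0-255), `frame_index`, and `truth`, a
#'   one-row tibble `(cx, cy, r, glint_x, glint_y, occluded)`.
#' @examples
#' fr <- render_eye_frame(width = 200, height = 150,
#'                        pupil_center = c(100, 75), pupil_radius = 20)
#' fr$truth
#' @export
render_eye_frame <- function(width = 480, height = 200,
                             pupil_center = c(width / 2, height / 2),
                             pupil_radius = 20,
                             pupil_intensity = 30,
                             iris_intensity = 140,
                             sclera_intensity = 220,
                             iris_radius = pupil_radius * 2.5,
                             glint_center = NULL,
                             glint_radius = 3,
                             noise_sd = 0,
                             occluded = FALSE,
                             frame_index = 0L,
                             seed = NULL) {
  stopifnot(width >= 8, height >= 8, pupil_radius >= 0, noise_sd >= 0)
  if (!(pupil_intensity < iris_intensity && iris_intensity < sclera_intensity)) {
    abort("Intensities must satisfy pupil < iris < sclera.")
  }
  cx <- pupil_center[[1]]; cy <- pupil_center[[2]]
  if (!occluded) {
    if (cx - pupil_radius < 0 || cx + pupil_radius > width - 1 ||
        cy - pupil_radius < 0 || cy + pupil_radius > height - 1) {
      abort("Pupil circle must lie fully inside the frame.")
    }
  }
  if (is.null(glint_center)) {
    glint_center <- c(cx + 0.4 * pupil_radius, cy - 0.3 * pupil_radius)
  }
  has_glint <- !occluded && !anyNA(glint_center)

  # pixel-center coordinate grids (0-based)
  xg <- matrix(rep(0:(width - 1), each = height), nrow = height)
  yg <- matrix(rep(0:(height - 1), times = width), nrow = height)

  px <- matrix(sclera_intensity, nrow = height, ncol = width)
  if (occluded) {
    px[] <- iris_intensity
  } else {
    d2 <- (xg - cx)^2 + (yg - cy)^2
    px[d2 <= iris_radius^2] <- iris_intensity
    px[d2 <= pupil_radius^2] <- pupil_intensity
    if (has_glint) {
      g2 <- (xg - glint_center[[1]])^2 + (yg - glint_center[[2]])^2
      px[g2 <= glint_radius^2] <- 255
    }
  }
  if (noise_sd > 0) {
    px <- local_seed(seed, px + rnorm(length(px), 0, noise_sd))
    px <- pmin(pmax(px, 0), 255)
  }
  structure(
    list(
      pixels = px,
      frame_index = as.integer(frame_index),
      truth = tibble::tibble(
        cx = if (occluded) NA_real_ else cx,
        cy = if (occluded) NA_real_ else cy,
        r = if (occluded) NA_real_ else pupil_radius,
        glint_x = if (has_glint) glint_center[[1]] else NA_real_,
        glint_y = if (has_glint) glint_center[[2]] else NA_real_,
        occluded = occluded
      )
    ),
    class = "eye_frame"
  )
}

#' @export
print.eye_frame <- function(x, ...) {
  cat(sprintf("<eye_frame %dx%d px, frame %d%s>\n",
              ncol(x$pixels), nrow(x$pixels), x$frame_index,
              if (isTRUE(x$truth$occluded)) ", occluded" else ""))
  invisible(x)
}

frame_pixels <- function(frame) {
  if (inherits(frame, "eye_frame")) frame$pixels
  else if (is.matrix(frame)) frame
  else abort("Expected an `eye_frame` or a numeric matrix of gray levels.")
}

#' Write synthetic frames to a directory as PNG plus a ground-truth CSV
#'
#' Frames are written as 8-bit grayscale PNG named `frame_000000.png`,
#' `frame_000001.png`, ... so lexicographic order is time order, with a
#' sidecar `truth.csv` holding `(frame, cx, cy, r)`.
#'
#' @param frames List of `eye_frame` objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths of the written PNG files.
#' @export
write_frames <- function(frames, dir) {
  stopifnot(length(frames) >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    paths[[i]] <- file.path(dir, sprintf("frame_%06d.png", i - 1L))
    png::writePNG(frames[[i]]$pixels / 255, paths[[i]])
  }
  truth <- purrr::map_dfr(frames, "truth")
  truth$frame <- seq_along(frames) - 1L
  readr::write_csv(truth[, c("frame", "cx", "cy", "r")],
                   file.path(dir, "truth.csv"))
  invisible(paths)
}

#' Read a directory of grayscale frames into `eye_frame` objects
#'
#' @param dir Directory containing PNG frames; lexicographic file order is
#'   taken as time order.
#' @return List of `eye_frame` objects (without ground truth).
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) abort(sprintf("No PNG frames found in '%s'.", dir))
  purrr::imap(files, function(f, i) {
    px <- png::readPNG(f)
    if (length(dim(px)) == 3) px <- px[, , 1]
    structure(list(pixels = px * 255, frame_index = i - 1L,
                   truth = tibble::tibble(cx = NA_real_, cy = NA_real_,
                                          r = NA_real_, glint_x = NA_real_,
                                          glint_y = NA_real_, occluded = NA)),
              class = "eye_frame")
  })
}
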