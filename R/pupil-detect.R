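#' Automatic binarization threshold from frame brightness
#'
#' Computes the gray-level threshold used to separate the dark pupil from
#' the rest of the IR image, as a fixed linear function of the frame's mean
#' and maximum brightness:
#' `threshold = -0.418 * B_mean + 1.051 * B_max + 7.973`, clipped to
#' \[0, 255\]. The coefficients come from a regression calibrated on an IR
#' eye-imaging rig; they are exposed so other cameras can re-fit them.
#'
#' @param frame An `eye_frame` or numeric gray-level matrix.
#' @param coefs Named numeric vector `c(b_mean, b_max, intercept)`.
#' @return Threshold gray level (scalar).
#' @examples
#' compute_threshold(matrix(c(100, 150), 1))  # from B_mean = 125, B_max = 150
#' @export
compute_threshold <- function(frame,
                              coefs = c(b_mean = -0.418, b_max = 1.051,
                                        intercept = 7.973)) {
  px <- frame_pixels(frame)
  if (length(px) == 0) abort("Empty frame.")
  thr <- coefs[["b_mean"]] * mean(px) + coefs[["b_max"]] * max(px) +
    coefs[["intercept"]]
  min(max(thr, 0), 255)
}

#' Binarize a frame: dark pixels below threshold become foreground
#'
#' @param frame An `eye_frame` or gray-level matrix.
#' @param threshold Gray-level cutoff; pixels strictly below it are 1.
#' @return Logical matrix mask (TRUE = dark / candidate pupil).
#' @export
binarize <- function(frame, threshold = compute_threshold(frame)) {
  frame_pixels(frame) < threshold
}

# connected components of a logical mask -> tibble(label, size, cx, cy)
# centroids in 0-based (x = col, y = row) coordinates, sorted by size desc
mask_components <- function(mask, k = Inf) {
  if (!any(mask)) {
    return(tibble::tibble(label = integer(), size = integer(),
                          cx = double(), cy = double()))
  }
  lab <- as.integer(EBImage::bwlabel(mask * 1))
  idx <- which(lab > 0L)
  lab <- lab[idx]
  nr <- nrow(mask)
  ys <- (idx - 1L) %% nr          # 0-based row
  xs <- (idx - 1L) %/% nr         # 0-based col
  size <- tabulate(lab)
  sums <- rowsum(cbind(xs, ys), lab)
  out <- tibble::tibble(label = seq_along(size), size = size,
                        cx = as.numeric(sums[, 1]) / size,
                        cy = as.numeric(sums[, 2]) / size)
  out <- out[order(-out$size), ]
  head(out, k)
}

#' Locate the corneal glint (saturated IR reflection)
#'
#' Finds the largest connected region of near-saturated pixels and returns
#' its centroid; the glint anchors pupil-candidate selection when several
#' circular edges are found.
#'
#' @param frame An `eye_frame` or gray-level matrix.
#' @param glint_threshold Gray level at/above which a pixel counts as
#'   saturated (default 250).
#' @return One-row tibble `(found, cx, cy, size)`; `cx`/`cy` are `NA` when
#'   no saturated region exists.
#' @export
detect_glint <- function(frame, glint_threshold = 250) {
  px <- frame_pixels(frame)
  comp <- mask_components(px >= glint_threshold, k = 1)
  if (nrow(comp) == 0) {
    tibble::tibble(found = FALSE, cx = NA_real_, cy = NA_real_, size = 0L)
  } else {
    tibble::tibble(found = TRUE, cx = comp$cx, cy = comp$cy, size = comp$size)
  }
}

#' Parameters of the circular edge detector
#'
#' @param r_min,r_max Radius search range, pixels (`0 < r_min < r_max`).
#' @param sigma Scale of the Gaussian smoothing applied along the radial
#'   derivative, pixels.
#' @param n_angles Number of contour samples per circle (>= 16).
#' @param center_search_radius Half-width of the square center search
#'   window around each candidate, pixels.
#' @param score_floor Minimum edge score (gray levels per pixel of radial
#'   contrast) for a fit to count as a detection.
#' @return A list of class `cde_params`.
#' @export
cde_params <- function(r_min = 10, r_max = 40, sigma = 1.5, n_angles = 64,
                       center_search_radius = 10, score_floor = 2) {
  stopifnot(r_min > 0, r_max > r_min, sigma > 0, n_angles >= 16,
            center_search_radius >= 0, score_floor >= 0)
  structure(list(r_min = r_min, r_max = r_max, sigma = sigma,
                 n_angles = n_angles,
                 center_search_radius = center_search_radius,
                 score_floor = score_floor),
            class = "cde_params")
}

# bilinear interpolation of px (rows = y, cols = x, 0-based coords), clamped
bilinear_sample <- function(px, x, y) {
  h <- nrow(px); w <- ncol(px)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + x0 * h; i10 <- y0 + 1 + x1 * h
  i01 <- y1 + 1 + x0 * h; i11 <- y1 + 1 + x1 * h
  px[i00] * (1 - fx) * (1 - fy) + px[i10] * fx * (1 - fy) +
    px[i01] * (1 - fx) * fy + px[i11] * fx * fy
}

# mean contour intensity profile over radii for a set of centers:
# returns matrix [n_centers x n_radii]
contour_profiles <- function(px, cx, cy, radii, n_angles) {
  theta <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  ct <- cos(theta); st <- sin(theta)
  nc <- length(cx); nr <- length(radii); na <- n_angles
  # arrays ordered [center, radius, angle]
  rc <- rep(radii, each = nc)                       # nc*nr
  xs <- rep(cx, times = nr) + outer(rc, ct)         # (nc*nr) x na
  ys <- rep(cy, times = nr) + outer(rc, st)
  v <- bilinear_sample(px, as.numeric(xs), as.numeric(ys))
  dim(v) <- c(nc * nr, na)
  matrix(rowMeans(v), nrow = nc, ncol = nr)
}

# Gaussian smoothing of each row of m along columns (truncated at 3*sigma)
smooth_rows <- function(m, sigma) {
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-hw):hw)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- ncol(m)
  out <- matrix(0, nrow(m), n)
  for (j in seq_len(n)) {
    lo <- max(1, j - hw); hi <- min(n, j + hw)
    kk <- k[(lo - j + hw + 1):(hi - j + hw + 1)]
    kk <- kk / sum(kk)
    out[, j] <- m[, lo:hi, drop = FALSE] %*% kk
  }
  out
}

# best (x0, y0, r, score) over an explicit center grid; the radius is
# refined to sub-pixel precision by a parabolic fit through the smoothed
# radial-derivative peak and its two neighbours
cde_search <- function(px, centers_x, centers_y, params, refine_r = TRUE) {
  radii <- seq(params$r_min - 1, params$r_max + 1)
  prof <- contour_profiles(px, centers_x, centers_y, radii, params$n_angles)
  nr <- length(radii)
  deriv <- (prof[, 3:nr, drop = FALSE] - prof[, 1:(nr - 2), drop = FALSE]) / 2
  sm <- abs(smooth_rows(deriv, params$sigma))
  best_r_idx <- max.col(sm, ties.method = "first")
  best_score <- sm[cbind(seq_len(nrow(sm)), best_r_idx)]
  i <- which.max(best_score)
  j <- best_r_idx[[i]]
  r_best <- radii[j + 1]
  if (refine_r && j > 1 && j < ncol(sm)) {
    y1 <- sm[i, j - 1]; y2 <- sm[i, j]; y3 <- sm[i, j + 1]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > 1e-12) {
      delta <- 0.5 * (y1 - y3) / denom
      if (is.finite(delta) && abs(delta) <= 0.5) r_best <- r_best + delta
    }
  }
  list(x0 = centers_x[[i]], y0 = centers_y[[i]],
       r = r_best, score = best_score[[i]])
}

#' Circular edge detection (Daugman-style integro-differential operator)
#'
#' For each candidate center, maximizes over center position and radius the
#' Gaussian-smoothed radial derivative of the normalized contour integral
#' of image intensity — the circle along which brightness changes fastest
#' with radius. The contour integral is the mean of `n_angles` bilinearly
#' interpolated samples on the circle (the `1/(2*pi*r)` normalization); the
#' radial derivative is a central difference over `r +/- 1` px, smoothed
#' along r by a Gaussian of scale `sigma`. The center search runs on an
#' integer grid around each candidate (coarse stride-2 pass plus a local
#' refinement).
#'
#' @param frame An `eye_frame` or gray-level matrix.
#' @param candidates Data frame with columns `cx`, `cy` (0-based pixel
#'   coordinates of starting centers), e.g. dark-mask component centroids.
#' @param params A [cde_params()] object.
#' @return A tibble of fits, one per candidate, ranked by `edge_score`:
#'   `(x0, y0, r, diameter, edge_score, valid)`. `valid` requires the
#'   fitted circle to lie inside the frame and the score to reach
#'   `params$score_floor`. Candidates whose whole search region falls
#'   outside the frame are dropped; the result may have zero rows.
#' @export
circular_edge_detect <- function(frame, candidates, params = cde_params()) {
  px <- frame_pixels(frame)
  if (is.null(nrow(candidates)) || nrow(candidates) == 0) {
    abort("`candidates` must contain at least one (cx, cy) row.")
  }
  h <- nrow(px); w <- ncol(px)
  fits <- purrr::pmap_dfr(candidates[, c("cx", "cy")], function(cx, cy) {
    R <- params$center_search_radius
    cx0 <- round(cx); cy0 <- round(cy)
    offs <- if (R > 0) unique(c(seq(-R, R, by = 2), R)) else 0
    gx <- cx0 + offs; gy <- cy0 + offs
    gx <- gx[gx >= 0 & gx <= w - 1]; gy <- gy[gy >= 0 & gy <= h - 1]
    if (length(gx) == 0 || length(gy) == 0) return(NULL)
    grid <- expand.grid(x = gx, y = gy)
    coarse <- cde_search(px, grid$x, grid$y, params)
    # refine +/- 1 px around the coarse optimum
    rg <- expand.grid(x = coarse$x0 + (-1:1), y = coarse$y0 + (-1:1))
    rg <- rg[rg$x >= 0 & rg$x <= w - 1 & rg$y >= 0 & rg$y <= h - 1, ]
    fine <- cde_search(px, rg$x, rg$y, params)
    inside <- fine$x0 - fine$r >= 0 && fine$x0 + fine$r <= w - 1 &&
      fine$y0 - fine$r >= 0 && fine$y0 + fine$r <= h - 1
    tibble::tibble(x0 = fine$x0, y0 = fine$y0, r = fine$r,
                   diameter = 2 * fine$r, edge_score = fine$score,
                   valid = inside && fine$score >= params$score_floor &&
                     fine$r >= params$r_min && fine$r <= params$r_max)
  })
  if (nrow(fits) == 0) return(invalid_fit()[0, ])
  dplyr::arrange(fits, dplyr::desc(.data$edge_score))
}

invalid_fit <- function() {
  tibble::tibble(x0 = NA_real_, y0 = NA_real_, r = NA_real_,
                 diameter = NA_real_, edge_score = NA_real_, valid = FALSE)
}

#' Select the pupil among candidate circle fits using the glint
#'
#' When several circular edges are detected, the fit whose center lies
#' closest to the corneal glint is taken as the pupil; with a single fit it
#' is returned directly, and with none an invalid placeholder is returned.
#'
#' @param fits Tibble of fits from [circular_edge_detect()].
#' @param glint One-row tibble from [detect_glint()], or `NULL`.
#' @return A one-row tibble in the same shape as `fits`.
#' @export
select_pupil <- function(fits, glint = NULL) {
  if (is.null(fits) || nrow(fits) == 0) return(invalid_fit())
  fits <- fits[fits$valid, , drop = FALSE]
  if (nrow(fits) == 0) return(invalid_fit())
  if (nrow(fits) == 1) return(fits)
  if (!is.null(glint) && isTRUE(glint$found)) {
    d2 <- (fits$x0 - glint$cx)^2 + (fits$y0 - glint$cy)^2
    fits[which.min(d2), ]
  } else {
    fits[which.max(fits$edge_score), ]
  }
}

#' Detect the pupil in a single frame
#'
#' Runs the full per-frame chain: auto threshold, binarization, candidate
#' centers from the largest dark components, circular edge detection, and
#' glint-anchored selection.
#'
#' @inheritParams circular_edge_detect
#' @param k_candidates Number of largest dark components used as candidate
#'   centers.
#' @param glint_threshold Saturation threshold for [detect_glint()].
#' @param threshold_coefs Coefficients for [compute_threshold()].
#' @return One-row tibble `(x0, y0, r, diameter, edge_score, valid)`.
#' @export
detect_pupil <- function(frame, params = cde_params(), k_candidates = 3,
                         glint_threshold = 250,
                         threshold_coefs = c(b_mean = -0.418, b_max = 1.051,
                                             intercept = 7.973)) {
  px <- frame_pixels(frame)
  thr <- compute_threshold(px, threshold_coefs)
  cand <- mask_components(binarize(px, thr), k = k_candidates)
  if (nrow(cand) == 0) return(invalid_fit())
  # ignore specks smaller than the smallest admissible pupil
  cand <- cand[cand$size >= pi * params$r_min^2 / 4, , drop = FALSE]
  if (nrow(cand) == 0) return(invalid_fit())
  fits <- circular_edge_detect(px, cand, params)
  select_pupil(fits, detect_glint(px, glint_threshold))
}

#' Extract a pupil-diameter trace from a frame sequence
#'
#' Applies [detect_pupil()] to every frame; frames where no admissible
#' circular edge is found (e.g. eyelid-closed frames) are marked invalid
#' and carry no diameter, mirroring a recording chain that simply does not
#' compute a diameter when the pupil is not visible.
#'
#' @param frames List of `eye_frame` objects or gray-level matrices, in
#'   time order.
#' @param params A [cde_params()] object.
#' @param fps Frames per second of the sequence.
#' @param ... Passed to [detect_pupil()].
#' @return A tibble `(frame, t_s, diameter_px, valid, cx, cy, r,
#'   edge_score)` with attribute `fps`.
#' @export
extract_trace <- function(frames, params = cde_params(), fps = 30, ...) {
  if (length(frames) < 1) abort("`frames` must contain at least one frame.")
  fits <- purrr::map_dfr(frames, function(f) detect_pupil(f, params, ...))
  out <- tibble::tibble(
    frame = seq_along(frames) - 1L,
    t_s = (seq_along(frames) - 1L) / fps,
    diameter_px = fits$diameter,
    valid = fits$valid,
    cx = fits$x0, cy = fits$y0, r = fits$r, edge_score = fits$edge_score)
  attr(out, "fps") <- fps
  out
}
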