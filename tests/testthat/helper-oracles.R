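# Independent oracles used across the suite. Each re-implements the
# quantity under test by a different route (brute force, closed form,
# direct enumeration) so agreement is informative.

# Count of integer pixel centers inside a disk, by per-pixel distance check.
oracle_disk_pixel_count <- function(cx, cy, r, width, height) {
  n <- 0L
  for (x in 0:(width - 1)) {
    for (y in 0:(height - 1)) {
      if ((x - cx)^2 + (y - cy)^2 <= r^2) n <- n + 1L
    }
  }
  n
}

# Exhaustive integer-grid maximization of the circular-edge objective:
# same contour-mean / central-difference / Gaussian-smoothing definition,
# but evaluated pointwise with no search shortcuts.
oracle_cde <- function(px, cx_range, cy_range, r_min, r_max,
                       n_angles = 64, sigma = 1.5) {
  theta <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  radii <- (r_min - 1):(r_max + 1)
  h <- nrow(px); w <- ncol(px)
  sample_circle <- function(x0, y0, r) {
    xs <- pmin(pmax(x0 + r * cos(theta), 0), w - 1)
    ys <- pmin(pmax(y0 + r * sin(theta), 0), h - 1)
    x0i <- floor(xs); y0i <- floor(ys)
    x1i <- pmin(x0i + 1, w - 1); y1i <- pmin(y0i + 1, h - 1)
    fx <- xs - x0i; fy <- ys - y0i
    v <- px[cbind(y0i + 1, x0i + 1)] * (1 - fx) * (1 - fy) +
      px[cbind(y0i + 1, x1i + 1)] * fx * (1 - fy) +
      px[cbind(y1i + 1, x0i + 1)] * (1 - fx) * fy +
      px[cbind(y1i + 1, x1i + 1)] * fx * fy
    mean(v)
  }
  hw <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-hw):hw)^2 / (2 * sigma^2))
  best <- list(score = -Inf)
  for (x0 in cx_range) {
    for (y0 in cy_range) {
      prof <- vapply(radii, function(r) sample_circle(x0, y0, r), 0)
      nr <- length(prof)
      deriv <- (prof[3:nr] - prof[1:(nr - 2)]) / 2
      sm <- numeric(length(deriv))
      for (j in seq_along(deriv)) {
        lo <- max(1, j - hw); hi <- min(length(deriv), j + hw)
        kk <- kern[(lo - j + hw + 1):(hi - j + hw + 1)]
        sm[j] <- sum(deriv[lo:hi] * kk) / sum(kk)
      }
      sc <- abs(sm)
      j <- which.max(sc)
      if (sc[j] > best$score) {
        best <- list(x0 = x0, y0 = y0, r = radii[j + 1], score = sc[j])
      }
    }
  }
  best
}

# AUC as the Mann-Whitney pair-counting statistic (ties count 1/2).
oracle_auc_pairs <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# ANCOVA group F via explicit normal equations: full model vs baseline-only
# model, extra-sum-of-squares F-test.
oracle_ancova_F <- function(baseline, outcome, group) {
  g <- as.numeric(factor(group)) - 1
  X_full <- cbind(1, baseline, g)
  X_red <- cbind(1, baseline)
  beta_f <- solve(t(X_full) %*% X_full, t(X_full) %*% outcome)
  beta_r <- solve(t(X_red) %*% X_red, t(X_red) %*% outcome)
  rss_f <- sum((outcome - X_full %*% beta_f)^2)
  rss_r <- sum((outcome - X_red %*% beta_r)^2)
  df2 <- length(outcome) - 3
  list(F = (rss_r - rss_f) / (rss_f / df2),
       partial_eta_sq = (rss_r - rss_f) / ((rss_r - rss_f) + rss_f))
}

# First-order partial correlation, closed form from pairwise correlations.
oracle_partial_r <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); rzy <- cor(z, y)
  (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
}

# Two-pass streaming mean/sd.
oracle_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  list(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
}
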