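# Shared fixtures: analytic shapes and brute-force feature oracles.
# All fixtures are built in code; the oracles are deliberately written
# as plain pixel loops, independent of the package's vectorized code.

disc_mask <- function(R, size = 2 * R + 11) {
  c0 <- (size + 1) / 2
  outer(seq_len(size), seq_len(size),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= R^2)
}

ellipse_mask <- function(a, b, phi = 0, size = 2 * max(a, b) + 11) {
  c0 <- (size + 1) / 2
  outer(seq_len(size), seq_len(size), function(i, j) {
    u <- (i - c0) * cos(phi) + (j - c0) * sin(phi)
    v <- -(i - c0) * sin(phi) + (j - c0) * cos(phi)
    (u / a)^2 + (v / b)^2 <= 1
  })
}

square_mask <- function(side, size = side + 10) {
  m <- matrix(FALSE, size, size)
  o <- floor((size - side) / 2)
  m[o + seq_len(side), o + seq_len(side)] <- TRUE
  m
}

uniform_region <- function(mask, value = 1, ...) {
  cell_region(mask, matrix(value, nrow(mask), ncol(mask)), ...)
}

# random blob mask: union of a few discs, plus random intensities
random_blob_region <- function(seed, size = 41) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  for (k in 1:3) {
    cy <- sample(12:(size - 12), 1); cx <- sample(12:(size - 12), 1)
    R <- sample(4:8, 1)
    m <- m | outer(seq_len(size), seq_len(size),
                   function(i, j) (i - cy)^2 + (j - cx)^2 <= R^2)
  }
  ch <- matrix(runif(size^2, 0.1, 3), size)
  cell_region(m, ch)
}

# ---- brute-force oracles (explicit loops over mask pixels) ----------

brute_intensity <- function(region) {
  v <- c()
  for (i in seq_len(nrow(region$mask)))
    for (j in seq_len(ncol(region$mask)))
      if (region$mask[i, j]) v <- c(v, region$channel[i, j])
  c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
    min = min(v), max = max(v), sum = sum(v))
}

# Direct summation version of the intensity-weighted descriptors
# (symmetry, radial); returns a named list.
brute_star_sums <- function(region) {
  px <- which(region$mask, arr.ind = TRUE)
  I <- numeric(nrow(px))
  for (k in seq_len(nrow(px))) I[k] <- region$channel[px[k, 1], px[k, 2]]
  tot <- 0; cy <- 0; cx <- 0
  for (k in seq_along(I)) {
    tot <- tot + I[k]
    cy <- cy + I[k] * (px[k, 1] - 1)
    cx <- cx + I[k] * (px[k, 2] - 1)
  }
  cy <- cy / tot; cx <- cx / tot
  r <- theta <- numeric(length(I))
  for (k in seq_along(I)) {
    dy <- (px[k, 1] - 1) - cy; dx <- (px[k, 2] - 1) - cx
    r[k] <- sqrt(dy^2 + dx^2); theta[k] <- atan2(dx, dy)
  }
  rbar <- sum(I * r) / tot
  sym <- c()
  for (X in 0:1) {
    w <- if (X == 0) I else I * exp(-r / rbar)
    for (Y in 2:5) {
      re <- 0; im <- 0
      for (k in seq_along(I)) {
        re <- re + w[k] * cos(Y * theta[k])
        im <- im + w[k] * sin(Y * theta[k])
      }
      sym <- c(sym, sqrt(re^2 + im^2) / sum(w))
    }
  }
  reldev <- sqrt(sum(I * (r - rbar)^2) / tot) / rbar
  list(symmetry = sym, radial_mean = rbar, radial_reldev = reldev)
}

# Brute-force Gaussian smoothing + derivative filters for the texture
# oracle: explicit convolution with a truncated sampled kernel.
brute_gauss_smooth <- function(img, sigma) {
  half <- max(2, ceiling(3 * sigma))
  ker <- outer(-half:half, -half:half,
               function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  ker <- ker / sum(ker)
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img)))
    for (j in seq_len(ncol(img))) {
      s <- 0
      for (a in -half:half)
        for (b in -half:half) {
          ii <- i + a; jj <- j + b
          v <- if (ii >= 1 && ii <= nrow(img) && jj >= 1 &&
                     jj <= ncol(img)) img[ii, jj] else 0
          s <- s + ker[a + half + 1, b + half + 1] * v
        }
      out[i, j] <- s
    }
  out
}

# ---- cohort helpers -------------------------------------------------

small_cohort <- function(..., seed = 1) {
  cohort_config(n_group0 = 3, n_group1 = 3, cells_per_individual = 60,
                seed = seed, ...)
}

# Individual-level AUC for a config, in-sample scoring.
cohort_auc <- function(cfg, marker_set = "combined") {
  tab <- simulate_feature_table(cfg)
  m <- suppressWarnings(fit_cell_classifier(
    tab, cfg$group_labels, marker_set = marker_set))
  im <- aggregate_individual_means(score_cells(m, tab))
  roc_individuals(im$mean_probability, im$group,
                  positive = cfg$group_labels[2])$auc
}
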