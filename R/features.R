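# The canonical 31-feature morphometric engine.
#
# Per (region, channel) pairing: 4 basic morphology + 5 intensity +
# 18 intensity-distribution descriptors (8 symmetry, 4 threshold
# compactness, 2 axial, 2 radial, 2 profile) + 4 texture responses.

#' A cell region: a pixel mask paired with an intensity channel
#'
#' @param mask Logical (or 0/1) matrix; `TRUE` pixels belong to the
#'   region. Must be non-empty.
#' @param channel 2-D intensity matrix of the same size; finite,
#'   non-negative.
#' @param pixel_size Physical pixel size (length per px).
#' @param id Optional label used in error messages (e.g. "mito/cell 12").
#' @return Object of class `cell_region`.
#' @export
cell_region <- function(mask, channel, pixel_size = 1, id = NULL) {
  mask <- as_matrix(mask) > 0
  channel <- as_matrix(channel)
  if (!all(dim(mask) == dim(channel)))
    stop("mask and channel dimensions differ", call. = FALSE)
  if (!any(mask)) stop("empty region mask", call. = FALSE)
  vals <- channel[mask]
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("region intensities must be finite and >= 0", call. = FALSE)
  structure(list(mask = mask, channel = channel,
                 pixel_size = pixel_size,
                 id = if (is.null(id)) "region" else as.character(id)),
            class = "cell_region")
}

# (row, col) coordinates of mask pixels, 0-based.
region_coords <- function(region) {
  idx <- which(region$mask, arr.ind = TRUE)
  cbind(row = idx[, 1] - 1, col = idx[, 2] - 1)
}

# Marching-squares perimeter: total length of the 0.5-level contour of
# the mask after light anti-aliasing (Gaussian sigma 0.8), which removes
# most of the staircase bias of contouring a binary grid (a binary
# contour overestimates a circle's perimeter by ~7%). Falls back to the
# binary contour for masks too thin to survive smoothing.
mask_perimeter <- function(mask) {
  pad <- matrix(0, nrow(mask) + 8, ncol(mask) + 8)
  pad[5:(nrow(mask) + 4), 5:(ncol(mask) + 4)] <- mask * 1
  contour_len <- function(z) {
    cl <- contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                       z = z, levels = 0.5)
    sum(vapply(cl, function(ct)
      sum(sqrt(diff(ct$x)^2 + diff(ct$y)^2)), 0))
  }
  p <- contour_len(as_matrix(EBImage::gblur(pad, 0.8)))
  if (p <= 0) p <- contour_len(pad)
  p
}

#' Basic morphology: area, length, width, roundness
#'
#' Area is the pixel count scaled by `pixel_size^2`. Length and width
#' are the full extents of the mask projected on the first and second
#' principal axes of its pixel covariance (plus one pixel width).
#' Roundness is `4 * pi * area / perimeter^2` with the perimeter taken
#' from the marching-squares contour of the mask, clipped to (0, 1].
#'
#' @param region A [cell_region()]; mask must have >= 4 px.
#' @return Named numeric vector `area`, `length`, `width`, `roundness`.
#' @export
basic_morphology <- function(region) {
  stopifnot(inherits(region, "cell_region"))
  xy <- region_coords(region)
  n <- nrow(xy)
  if (n < 4) stop("mask must contain at least 4 pixels", call. = FALSE)
  ps <- region$pixel_size
  area_px <- n
  cv <- cov(xy) * (n - 1) / n
  ev <- eigen(cv, symmetric = TRUE)
  proj <- sweep(xy, 2, colMeans(xy)) %*% ev$vectors
  len <- (diff(range(proj[, 1])) + 1) * ps
  wid <- (diff(range(proj[, 2])) + 1) * ps
  per <- mask_perimeter(region$mask)
  roundness <- min(1, 4 * pi * area_px / per^2)
  c(area = area_px * ps^2, length = len, width = wid,
    roundness = roundness)
}

#' Intensity statistics over a region
#'
#' @param region A [cell_region()].
#' @return Named vector `mean`, `sd`, `min`, `max`, `sum`; `sd` is 0
#'   for a single-pixel region.
#' @export
intensity_features <- function(region) {
  stopifnot(inherits(region, "cell_region"))
  v <- region$channel[region$mask]
  s <- if (length(v) > 1) sd(v) else 0
  c(mean = mean(v), sd = s, min = min(v), max = max(v), sum = sum(v))
}

# Normalized distance-transform depth of the mask interior, in [0, 1].
mask_depth <- function(mask) {
  pad <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1
  dm <- as_matrix(EBImage::distmap(EBImage::Image(pad)))
  d <- dm[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
  d / max(d, 1e-12)
}

#' Intensity-distribution descriptors (symmetry, compactness, axial,
#' radial, profile)
#'
#' Eighteen descriptors of how intensity is arranged inside the region,
#' all computed about the intensity-weighted centroid with polar pixel
#' coordinates `(r, theta)`:
#'
#' * `symmetry.sXY` (8): `|sum(w exp(i Y theta))| / sum(w)` for
#'   `Y = 2..5`, with radial weighting `w = I` (`X = 0`) or
#'   `w = I exp(-r / rbar)` (`X = 1`), `rbar` the intensity-weighted
#'   mean radius. 0 for a radially symmetric pattern, up to 1 for mass
#'   concentrated on `Y` nodal directions.
#' * `compactness.qQQ` (4): for the brightest fraction
#'   `q = 0.1, 0.2, 0.3, 0.4` of in-mask pixels (ties broken toward the
#'   centroid), `sqrt(n_q / pi) / (sqrt(2) R_g)` where `R_g` is the RMS
#'   distance of those pixels from their own centroid; 1 for a solid
#'   disc, < 1 for scattered bright pixels.
#' * `axial.length`, `axial.ratio` (2): `4 sqrt(lambda1)` and
#'   `sqrt(lambda2 / lambda1)` from the mask pixel covariance
#'   eigenvalues `lambda1 >= lambda2`.
#' * `radial.mean`, `radial.reldev` (2): intensity-weighted mean radius
#'   and its relative deviation.
#' * `profile.inner`, `profile.depth` (2): fraction of intensity deeper
#'   than half the maximum mask depth, and mean intensity-weighted
#'   normalized depth, with depth from the in-mask distance transform.
#'
#' @param region A [cell_region()] with >= 4 px and positive total
#'   intensity.
#' @return Named numeric vector of 18 values.
#' @export
star_features <- function(region) {
  stopifnot(inherits(region, "cell_region"))
  xy <- region_coords(region)
  if (nrow(xy) < 4) stop("mask must contain at least 4 pixels",
                         call. = FALSE)
  I <- region$channel[region$mask]
  tot <- sum(I)
  if (tot <= 0)
    stop("zero total intensity in ", region$id, call. = FALSE)
  ps <- region$pixel_size

  cy <- sum(I * xy[, 1]) / tot
  cx <- sum(I * xy[, 2]) / tot
  dy <- xy[, 1] - cy
  dx <- xy[, 2] - cx
  r <- sqrt(dy^2 + dx^2)
  theta <- atan2(dx, dy)
  rbar <- sum(I * r) / tot

  sym <- numeric(8)
  k <- 0
  for (X in 0:1) {
    w <- if (X == 0) I else I * exp(-r / max(rbar, 1e-12))
    sw <- sum(w)
    for (Y in 2:5) {
      k <- k + 1
      sym[k] <- Mod(sum(w * exp(1i * Y * theta))) / sw
    }
  }
  names(sym) <- paste0("symmetry.s", c("02", "03", "04", "05",
                                       "12", "13", "14", "15"))

  ord <- order(-I, r)
  comp <- vapply(c(0.1, 0.2, 0.3, 0.4), function(q) {
    nq <- ceiling(q * length(I))
    sel <- ord[seq_len(nq)]
    my <- mean(xy[sel, 1]); mx <- mean(xy[sel, 2])
    rg <- sqrt(mean((xy[sel, 1] - my)^2 + (xy[sel, 2] - mx)^2))
    if (rg < 1e-12) 1 else sqrt(nq / pi) / (sqrt(2) * rg)
  }, 0)
  names(comp) <- paste0("compactness.q", c("10", "20", "30", "40"))

  n <- nrow(xy)
  cv <- cov(xy) * (n - 1) / n
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ax <- c(axial.length = 4 * sqrt(max(ev[1], 0)) * ps,
          axial.ratio = if (ev[1] <= 0) 1 else
            sqrt(max(ev[2], 0) / ev[1]))

  reldev <- if (rbar < 1e-12) 0 else
    sqrt(sum(I * (r - rbar)^2) / tot) / rbar
  rad <- c(radial.mean = rbar * ps, radial.reldev = reldev)

  d <- mask_depth(region$mask)[region$mask]
  prof <- c(profile.inner = sum(I[d >= 0.5]) / tot,
            profile.depth = sum(I * d) / tot)

  c(sym, comp, ax, rad, prof)
}

# Central-difference derivatives of a matrix (zero-padded edges).
shift_mat <- function(m, dr, dc) {
  out <- matrix(0, nrow(m), ncol(m))
  r_src <- seq_len(nrow(m)) + dr
  c_src <- seq_len(ncol(m)) + dc
  ok_r <- r_src >= 1 & r_src <= nrow(m)
  ok_c <- c_src >= 1 & c_src <= ncol(m)
  out[ok_r, ok_c] <- m[r_src[ok_r], c_src[ok_c]]
  out
}

#' Texture responses: spot, hole, edge, valley
#'
#' Filter-bank texture descriptors built from the Hessian of the
#' Gaussian-smoothed channel (scale `sigma`), with eigenvalues
#' `h1 <= h2`. Responses are sign-consistent so each filter selects one
#' structure class: `spot` is the region mean of `sqrt(h1 h2)` where
#' both eigenvalues are negative (isotropic bright granules; zero on a
#' pure ridge, whose larger eigenvalue vanishes), `hole` the same where
#' both are positive (dark pits), `edge` the mean gradient magnitude,
#' and `valley` the mean of `max(0, -h1 - 3 |h2|)` (bright smooth
#' filaments: full curvature across the ridge and none along it score
#' fully; any appreciable second curvature, as in a blob, suppresses
#' the response). Each is
#' normalized by the region mean intensity. The region is eroded by
#' `ceil(2 sigma)` px before averaging to suppress the mask-boundary
#' response; if erosion empties the mask, the full mask is used and a
#' message emitted.
#'
#' @param region A [cell_region()] with >= 9 px.
#' @param scale Gaussian smoothing sigma in px.
#' @return Named vector `spot`, `hole`, `edge`, `valley`.
#' @export
ser_texture <- function(region, scale = 1) {
  stopifnot(inherits(region, "cell_region"))
  check_scalar(scale, "scale", lower = 0.3)
  if (sum(region$mask) < 9)
    stop("mask must contain at least 9 pixels", call. = FALSE)
  sm <- as_matrix(EBImage::gblur(region$channel, scale))
  gx <- (shift_mat(sm, 0, 1) - shift_mat(sm, 0, -1)) / 2
  gy <- (shift_mat(sm, 1, 0) - shift_mat(sm, -1, 0)) / 2
  sxx <- shift_mat(sm, 0, 1) + shift_mat(sm, 0, -1) - 2 * sm
  syy <- shift_mat(sm, 1, 0) + shift_mat(sm, -1, 0) - 2 * sm
  sxy <- (shift_mat(sm, 1, 1) + shift_mat(sm, -1, -1) -
            shift_mat(sm, 1, -1) - shift_mat(sm, -1, 1)) / 4
  lap <- sxx + syy
  aniso <- sqrt((sxx - syy)^2 + 4 * sxy^2)
  h1 <- (lap - aniso) / 2
  h2 <- (lap + aniso) / 2
  spot_resp <- sqrt(pmax(0, h1 * h2)) * (h2 <= 0)
  hole_resp <- sqrt(pmax(0, h1 * h2)) * (h1 >= 0)
  valley_resp <- pmax(0, -h1 - 3 * abs(h2))

  er <- ceiling(2 * scale)
  brush <- EBImage::makeBrush(2 * er + 1, shape = "disc")
  eroded <- as_matrix(EBImage::erode(EBImage::Image(region$mask * 1),
                                     brush)) > 0
  if (!any(eroded)) {
    message("erosion emptied region ", region$id,
            "; using the full mask")
    eroded <- region$mask
  }
  mu <- mean(region$channel[eroded])
  mu <- max(mu, 1e-12)
  c(spot = mean(spot_resp[eroded]) / mu,
    hole = mean(hole_resp[eroded]) / mu,
    edge = mean(sqrt(gx^2 + gy^2)[eroded]) / mu,
    valley = mean(valley_resp[eroded]) / mu)
}

#' All 31 features of one marker
#'
#' @param region A [cell_region()].
#' @param texture_scale Gaussian sigma for [ser_texture()].
#' @return Named numeric vector of 31 values, names matching
#'   [marker_feature_names()].
#' @export
marker_features <- function(region, texture_scale = 1) {
  bm <- basic_morphology(region)
  names(bm) <- paste0("morph.", names(bm))
  int <- intensity_features(region)
  names(int) <- paste0("intensity.", names(int))
  star <- star_features(region)
  tex <- ser_texture(region, texture_scale)
  names(tex) <- paste0("texture.", names(tex))
  out <- c(bm, int, star, tex)
  stopifnot(identical(names(out), marker_feature_names()))
  out
}

#' Extract the 124-feature table from a segmented field
#'
#' For every segmented cell, computes 31 features for each marker
#' pairing: `nucleus` = (nucleus mask, nucleus channel), `mito` =
#' (cell region, mitochondria channel), `aat` = (cell region, tubulin
#' channel), `cell` = (cell region, phase-contrast channel). Cells
#' whose features fail to compute (e.g. zero intensity) are dropped
#' with a message; the run continues.
#'
#' @param field A `field_image` (5 channels).
#' @param nuclei,cells Paired `label_mask` objects from segmentation.
#' @param metadata Optional named list of metadata values (e.g.
#'   `individual_id`, `group`, `treatment`, `run`) recycled to every
#'   row.
#' @param texture_scale Gaussian sigma for the texture features.
#' @return A `data.frame`: one row per surviving cell, `cell_id` plus
#'   metadata columns, then the 124 feature columns of
#'   [feature_names()].
#' @export
extract_cell_features <- function(field, nuclei, cells,
                                  metadata = list(), texture_scale = 1) {
  stopifnot(inherits(field, "field_image"),
            inherits(nuclei, "label_mask"), inherits(cells, "label_mask"))
  need <- c("nucleus", "mito", "aat", "phase")
  if (!all(need %in% names(field$channels)))
    stop("field must contain channels: ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- sort(setdiff(unique(as.vector(cells$labels)), 0L))
  ps <- field$pixel_size
  pairing <- list(nucleus = "nucleus", mito = "mito",
                  aat = "aat", cell = "phase")
  rows <- lapply(ids, function(k) {
    tryCatch({
      vals <- unlist(lapply(names(pairing), function(m) {
        msk <- if (m == "nucleus") nuclei$labels == k else
          cells$labels == k
        reg <- cell_region(msk, field$channels[[pairing[[m]]]],
                           pixel_size = ps,
                           id = paste0(m, "/cell ", k))
        v <- marker_features(reg, texture_scale)
        names(v) <- paste0(m, ".", names(v))
        v
      }))
      stopifnot(identical(names(vals), feature_names()))
      cbind(data.frame(cell_id = k),
            as.data.frame(as.list(vals), check.names = FALSE))
    }, error = function(e) {
      message("dropping cell ", k, ": ", conditionMessage(e))
      NULL
    })
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(cbind(data.frame(cell_id = integer(0)),
                 as.data.frame(matrix(numeric(0), 0,
                                      length(feature_names()),
                                      dimnames = list(NULL,
                                                      feature_names())),
                               check.names = FALSE)))
  out <- do.call(rbind, rows)
  for (nm in rev(names(metadata)))
    out <- cbind(setNames(data.frame(rep(metadata[[nm]], nrow(out)),
                                     stringsAsFactors = FALSE), nm), out)
  rownames(out) <- NULL
  out
}
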