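#' Scene specification for a rendered multichannel field
#'
#' Describes one synthetic imaging field: how many cells to place, the
#' canvas size, the morphology parameters that a "genotype" controls,
#' and the per-channel noise. The renderer draws five aligned channels
#' (nucleus stain, mitochondria, acetylated alpha-tubulin, whole-cell
#' mask stain, phase contrast) plus ground-truth label masks.
#'
#' @param n_cells Number of cells to place (>= 1).
#' @param image_size Canvas side in pixels (square field).
#' @param cell_radius Mean cell body radius, px.
#' @param protrusions Number of cell-boundary protrusion lobes.
#' @param protrusion_amp Relative protrusion amplitude in `[0, 0.5]`.
#' @param nucleus_radius Nucleus semi-major axis, px.
#' @param nucleus_ecc Nucleus eccentricity in `[0, 0.95]` (0 = circle).
#' @param mito_count Mitochondrial blobs per cell.
#' @param mito_length Blob semi-major axis, px.
#' @param mito_aspect Blob elongation (major/minor axis ratio, >= 1).
#' @param tubulin_count Tubulin filament strokes per cell.
#' @param tubulin_intensity Filament brightness (arbitrary units).
#' @param poisson_scale Photon scale for Poisson shot noise (0 disables).
#' @param gaussian_sd Additive Gaussian read-noise SD.
#' @param pixel_size Physical pixel size (length units per px).
#' @param seed Integer seed; rendering is deterministic given the spec.
#' @return An object of class `scene_spec`.
#' @seealso [render_field()]
#' @export
scene_spec <- function(n_cells = 12, image_size = 256,
                       cell_radius = 18, protrusions = 5,
                       protrusion_amp = 0.25,
                       nucleus_radius = 7, nucleus_ecc = 0.6,
                       mito_count = 12, mito_length = 3, mito_aspect = 3,
                       tubulin_count = 8, tubulin_intensity = 1,
                       poisson_scale = 200, gaussian_sd = 0.01,
                       pixel_size = 1, seed = 1) {
  check_scalar(n_cells, "n_cells", lower = 1, integer = TRUE)
  check_scalar(image_size, "image_size", lower = 32, integer = TRUE)
  check_scalar(cell_radius, "cell_radius", lower = 4)
  check_scalar(protrusions, "protrusions", lower = 0, integer = TRUE)
  check_scalar(protrusion_amp, "protrusion_amp", lower = 0, upper = 0.5)
  check_scalar(nucleus_radius, "nucleus_radius", lower = 2)
  check_scalar(nucleus_ecc, "nucleus_ecc", lower = 0, upper = 0.95)
  check_scalar(mito_count, "mito_count", lower = 0, integer = TRUE)
  check_scalar(mito_length, "mito_length", lower = 1)
  check_scalar(mito_aspect, "mito_aspect", lower = 1)
  check_scalar(tubulin_count, "tubulin_count", lower = 0, integer = TRUE)
  check_scalar(tubulin_intensity, "tubulin_intensity", lower = 0)
  check_scalar(poisson_scale, "poisson_scale", lower = 0)
  check_scalar(gaussian_sd, "gaussian_sd", lower = 0)
  check_scalar(pixel_size, "pixel_size", lower = 1e-9)
  check_scalar(seed, "seed", integer = TRUE)
  structure(as.list(environment()), class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("<scene_spec> ", x$n_cells, " cells on ", x$image_size, "x",
      x$image_size, " px, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Rasterize a star-shaped boundary r(theta) = R (1 + amp cos(k theta + ph))
# around (cy, cx); returns a logical matrix of the full field size.
raster_star <- function(size, cy, cx, R, k, amp, ph) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  dy <- rows - cy; dx <- cols - cx
  r <- sqrt(dy^2 + dx^2)
  theta <- atan2(dx, dy)
  r <= R * (1 + amp * cos(k * theta + ph))
}

# Rasterize a rotated ellipse with semi-axes (a, b) at angle phi.
raster_ellipse <- function(size, cy, cx, a, b, phi) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  dy <- rows - cy; dx <- cols - cx
  u <- dy * cos(phi) + dx * sin(phi)
  v <- -dy * sin(phi) + dx * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Render one synthetic multichannel field
#'
#' Places `n_cells` non-overlapping cells and draws the five channels:
#' `nucleus` (smoothed ellipses), `mito` (elongated blobs inside the
#' cytoplasm), `aat` (filament strokes radiating from the nucleus),
#' `cellmask` (filled cell bodies with protrusions) and `phase`
#' (textured cell body). Channels get Poisson shot noise plus Gaussian
#' read noise and are non-negative. Ground-truth nucleus/cell/blob label
#' masks and the per-cell morphology parameters are returned alongside
#' so segmentation and feature extraction can be tested against a known
#' answer.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `field_image`: a list with `channels`
#'   (named list of 5 matrices), `pixel_size`, `provenance`, and
#'   `ground_truth` (`nucleus_labels`, `cell_labels`, `mito_labels`
#'   integer matrices and a `cells` data.frame of planted parameters).
#' @export
render_field <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  size <- spec$image_size
  Rmax <- spec$cell_radius * (1 + spec$protrusion_amp)
  margin <- ceiling(Rmax) + 2
  if (2 * margin >= size)
    stop("image_size ", size, " too small for cells of radius ",
         spec$cell_radius, call. = FALSE)

  with_seed(spec$seed, {
    # -- placement: rejection-sample centers at >= 2 Rmax separation
    centers <- matrix(NA_real_, spec$n_cells, 2)
    for (i in seq_len(spec$n_cells)) {
      ok <- FALSE
      for (try in seq_len(300)) {
        p <- runif(2, margin, size - margin)
        if (i == 1 ||
            all(sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                              matrix(p, i - 1, 2, byrow = TRUE))^2)) >
                2 * Rmax + 2)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not place cell ", i, " of ", spec$n_cells,
             " without overlap; enlarge image_size or reduce n_cells",
             call. = FALSE)
      centers[i, ] <- p
    }

    zero <- matrix(0, size, size)
    ch <- list(nucleus = zero, mito = zero, aat = zero,
               cellmask = zero, phase = zero)
    nuc_lab <- matrix(0L, size, size)
    cell_lab <- matrix(0L, size, size)
    mito_lab <- matrix(0L, size, size)
    cells <- vector("list", spec$n_cells)
    n_blob <- 0L

    for (i in seq_len(spec$n_cells)) {
      cy <- centers[i, 1]; cx <- centers[i, 2]
      ph <- runif(1, 0, 2 * pi)
      body <- raster_star(size, cy, cx, spec$cell_radius,
                          spec$protrusions, spec$protrusion_amp, ph)
      nphi <- runif(1, 0, pi)
      b_ax <- spec$nucleus_radius * sqrt(1 - spec$nucleus_ecc^2)
      nuc <- raster_ellipse(size, cy, cx, spec$nucleus_radius, b_ax, nphi)
      nuc <- nuc & body
      cell_lab[body] <- i
      nuc_lab[nuc] <- i
      ch$cellmask <- ch$cellmask + body * 0.9
      ch$nucleus <- ch$nucleus + nuc * 1.0
      ch$phase <- ch$phase + body * 0.5

      cyto_idx <- which(body & !nuc)
      if (spec$mito_count > 0 && length(cyto_idx)) {
        pick <- cyto_idx[sample.int(length(cyto_idx),
                                    min(spec$mito_count, length(cyto_idx)))]
        for (p in pick) {
          n_blob <- n_blob + 1L
          brow <- (p - 1) %% size + 1
          bcol <- (p - 1) %/% size + 1
          bphi <- runif(1, 0, pi)
          blob <- raster_ellipse(size, brow, bcol, spec$mito_length,
                                 spec$mito_length / spec$mito_aspect,
                                 bphi) & body
          ch$mito <- ch$mito + blob * 0.8
          mito_lab[blob] <- n_blob
        }
      }

      if (spec$tubulin_count > 0) {
        for (f in seq_len(spec$tubulin_count)) {
          ang <- runif(1, 0, 2 * pi)
          rmax_f <- spec$cell_radius *
            (1 + spec$protrusion_amp * cos(spec$protrusions * ang + ph))
          tt <- seq(0.2, 0.95, length.out = 60) * rmax_f
          rr <- pmin(pmax(round(cy + tt * cos(ang)), 1), size)
          cc <- pmin(pmax(round(cx + tt * sin(ang)), 1), size)
          idx <- cbind(rr, cc)[body[cbind(rr, cc)], , drop = FALSE]
          ch$aat[idx] <- ch$aat[idx] + spec$tubulin_intensity * 0.6
        }
      }

      cells[[i]] <- data.frame(
        cell = i, row = cy, col = cx,
        cell_radius = spec$cell_radius, protrusions = spec$protrusions,
        nucleus_radius = spec$nucleus_radius,
        nucleus_ecc = spec$nucleus_ecc,
        mito_aspect = spec$mito_aspect)
    }

    # textured phase-contrast body
    ch$phase <- ch$phase *
      (1 + 0.3 * as_matrix(EBImage::gblur(matrix(rnorm(size^2), size), 1.5)))

    smooth_and_noise <- function(m, sigma) {
      m <- as_matrix(EBImage::gblur(m, sigma))
      if (spec$poisson_scale > 0)
        m <- rpois(length(m), pmax(m, 0) * spec$poisson_scale) /
          spec$poisson_scale
      pmax(matrix(m + rnorm(length(m), sd = spec$gaussian_sd), size), 0)
    }
    ch$nucleus <- smooth_and_noise(ch$nucleus, 1.5)
    ch$mito <- smooth_and_noise(ch$mito, 0.8)
    ch$aat <- smooth_and_noise(ch$aat, 0.8)
    ch$cellmask <- smooth_and_noise(ch$cellmask, 1.5)
    ch$phase <- smooth_and_noise(ch$phase, 1.0)

    structure(list(
      channels = ch, pixel_size = spec$pixel_size,
      provenance = list(seed = spec$seed, n_cells = spec$n_cells,
                        image_size = size),
      ground_truth = list(nucleus_labels = nuc_lab,
                          cell_labels = cell_lab,
                          mito_labels = mito_lab,
                          cells = do.call(rbind, cells))
    ), class = "field_image")
  })
}

#' @export
print.field_image <- function(x, ...) {
  cat("<field_image> ", x$provenance$image_size, "x",
      x$provenance$image_size, " px, ", x$provenance$n_cells,
      " planted cells, channels: ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a field image as a multipage TIFF
#'
#' One page per channel, in the order of `field$channels`; intensities
#' are scaled jointly so the brightest pixel across channels maps to 1.
#' A sidecar `<path>.json` records channel names, pixel size and the
#' intensity scale so the field can be read back losslessly (up to
#' 16-bit quantization).
#'
#' @param field A `field_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  scale <- max(1e-12, max(vapply(field$channels, max, 0)))
  pages <- lapply(field$channels, function(m) m / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(channels = names(field$channels), pixel_size = field$pixel_size,
         intensity_scale = scale, provenance = field$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multipage TIFF written by [write_field_tiff()]
#' @param path TIFF path (expects the sidecar `<path>.json`).
#' @return A `field_image` without ground truth.
#' @export
read_field_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  ch <- lapply(pages, function(m) as_matrix(m) * meta$intensity_scale)
  names(ch) <- meta$channels
  structure(list(channels = ch, pixel_size = meta$pixel_size,
                 provenance = as.list(meta$provenance),
                 ground_truth = NULL),
            class = "field_image")
}

#' Write a label mask as 16-bit TIFF
#' @param labels Integer label matrix (0 = background).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label mask written by [write_label_tiff()]
#' @param path TIFF path.
#' @return Integer label matrix.
#' @export
read_label_tiff <- function(path) {
  m <- as_matrix(tiff::readTIFF(path))
  matrix(as.integer(round(m * 65535)), nrow(m))
}
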