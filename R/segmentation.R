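# Nucleus and cytoplasm segmentation.
#
# Functional equivalents of the "find nuclei" / "find cytoplasm" stages
# of commercial HCS software: Otsu threshold on a smoothed channel,
# distance-transform watershed to split touching nuclei, and
# seeded (Voronoi-style) propagation of nucleus labels over the
# thresholded whole-cell channel.

#' Construct a label mask
#'
#' @param labels Integer matrix; 0 = background, k > 0 = object k.
#' @param pixel_size Physical pixel size (length per px).
#' @return Object of class `label_mask`.
#' @export
label_mask <- function(labels, pixel_size = 1) {
  labels <- matrix(as.integer(round(as_matrix(labels))),
                   nrow(as_matrix(labels)))
  if (any(labels < 0)) stop("labels must be >= 0", call. = FALSE)
  structure(list(labels = labels, pixel_size = pixel_size),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat("<label_mask> ", nrow(x$labels), "x", ncol(x$labels), " px, ",
      n_objects(x), " objects\n", sep = "")
  invisible(x)
}

#' Number of objects in a label mask
#' @param mask A `label_mask`.
#' @return Integer count of distinct positive labels.
#' @export
n_objects <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  length(setdiff(unique(as.vector(mask$labels)), 0L))
}

# Relabel positive labels to consecutive 1..K preserving order; apply the
# same mapping to a paired mask so nucleus/cell labels stay matched.
relabel_consecutive <- function(labels, paired = NULL) {
  keep <- sort(setdiff(unique(as.vector(labels)), 0L))
  map <- integer(max(c(labels, 0L)) + 1L)
  map[keep + 1L] <- seq_along(keep)
  out <- matrix(map[labels + 1L], nrow(labels))
  if (is.null(paired)) return(out)
  paired_out <- matrix(ifelse(paired %in% keep, map[paired + 1L], 0L),
                       nrow(paired))
  list(labels = out, paired = paired_out)
}

# Otsu threshold of a smoothed channel; returns a logical matrix.
threshold_channel <- function(img, sigma = 2,
                              method = c("otsu", "quantile"),
                              quantile_level = 0.75) {
  method <- match.arg(method)
  img <- as_matrix(img)
  if (max(img) <= 0) return(img > 0)
  sm <- as_matrix(EBImage::gblur(img, sigma))
  sm01 <- (sm - min(sm)) / max(1e-12, diff(range(sm)))
  thr <- if (method == "otsu") EBImage::otsu(EBImage::Image(sm01))
  else quantile(sm01, quantile_level)
  sm01 > thr
}

#' Find nuclei in the nucleus-stain channel
#'
#' Gaussian-smooths the channel (sigma 2 px), thresholds it (Otsu by
#' default), splits touching nuclei by watershed on the distance
#' transform, and removes components below `min_area`. An all-zero
#' image yields an empty mask, not an error.
#'
#' @param nucleus_channel 2-D intensity matrix.
#' @param min_area Minimum object area in px^2 (>= 1).
#' @param threshold_method `"otsu"` or `"quantile"`.
#' @param pixel_size Physical pixel size.
#' @return A `label_mask` with one label per nucleus.
#' @export
find_nuclei <- function(nucleus_channel, min_area = 40,
                        threshold_method = c("otsu", "quantile"),
                        pixel_size = 1) {
  check_scalar(min_area, "min_area", lower = 1)
  img <- as_matrix(nucleus_channel)
  if (length(img) == 0) stop("empty image", call. = FALSE)
  bw <- threshold_channel(img, sigma = 2, method = threshold_method)
  if (!any(bw)) return(label_mask(matrix(0L, nrow(img), ncol(img)),
                                  pixel_size))
  dm <- EBImage::distmap(EBImage::Image(bw * 1))
  wt <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- matrix(as.integer(as_matrix(wt)), nrow(img))
  sizes <- tabulate(lab[lab > 0])
  lab[lab > 0 & sizes[pmax(lab, 1L)] < min_area] <- 0L
  label_mask(relabel_consecutive(lab), pixel_size)
}

#' Find per-cell cytoplasm regions seeded at nuclei
#'
#' Marker-controlled propagation of nucleus labels over the thresholded
#' whole-cell channel (Voronoi region growing on the image manifold).
#' Each cytoplasm region keeps the label of its nucleus and always
#' contains every pixel of that nucleus; a nucleus with no surrounding
#' cell signal keeps its nucleus footprint as its cell region (a message
#' is emitted).
#'
#' @param cell_channel 2-D intensity matrix of the whole-cell stain.
#' @param nuclei `label_mask` of nuclei from [find_nuclei()].
#' @return A `label_mask` of cell regions, labels matching `nuclei`.
#' @export
find_cytoplasm <- function(cell_channel, nuclei) {
  stopifnot(inherits(nuclei, "label_mask"))
  img <- as_matrix(cell_channel)
  if (!all(dim(img) == dim(nuclei$labels)))
    stop("cell channel and nuclei mask have different dimensions",
         call. = FALSE)
  seeds <- nuclei$labels
  fg <- threshold_channel(img, sigma = 2) | seeds > 0
  sm <- as_matrix(EBImage::gblur(img, 2))
  ct <- EBImage::propagate(EBImage::Image(sm), EBImage::Image(seeds),
                           mask = EBImage::Image(fg))
  lab <- matrix(as.integer(as_matrix(ct)), nrow(img))
  lab[seeds > 0] <- seeds[seeds > 0]      # nuclei always inside their cell
  lonely <- setdiff(unique(seeds[seeds > 0]), unique(lab[lab > 0]))
  if (length(lonely))
    message("nuclei without surrounding cell signal kept as their own ",
            "cell region: ", paste(lonely, collapse = ", "))
  label_mask(lab, nuclei$pixel_size)
}

#' Filter paired cell/nucleus masks
#'
#' Removes cells touching the field border (if `exclude_border`) and
#' cells or nuclei smaller than `min_area`, then relabels both masks
#' consecutively with matching labels.
#'
#' @param cells,nuclei Paired `label_mask` objects (same label set).
#' @param min_area Minimum area (px^2) for both the cell and its
#'   nucleus.
#' @param exclude_border Drop cells whose region touches the image
#'   border.
#' @return List with elements `cells` and `nuclei` (filtered masks).
#' @export
filter_cells <- function(cells, nuclei, min_area = 40,
                         exclude_border = TRUE) {
  stopifnot(inherits(cells, "label_mask"), inherits(nuclei, "label_mask"))
  lab <- cells$labels; nlab <- nuclei$labels
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (length(ids) == 0)
    return(list(cells = cells, nuclei = nuclei))
  border <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
  drop <- integer(0)
  if (exclude_border) drop <- setdiff(unique(border), 0L)
  area_cell <- tabulate(lab[lab > 0], nbins = max(ids))
  area_nuc <- tabulate(nlab[nlab > 0], nbins = max(ids))
  drop <- union(drop, ids[area_cell[ids] < min_area |
                            area_nuc[ids] < min_area])
  lab[lab %in% drop] <- 0L
  nlab[nlab %in% drop] <- 0L
  rl <- relabel_consecutive(lab, nlab)
  list(cells = label_mask(rl$labels, cells$pixel_size),
       nuclei = label_mask(rl$paired, nuclei$pixel_size))
}
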