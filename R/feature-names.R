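#' The canonical per-marker feature set
#'
#' Each marker contributes exactly 31 features, grouped in eight families:
#' 4 basic morphology (`morph`), 5 intensity statistics (`intensity`),
#' 8 radial-symmetry scores (`symmetry`), 4 threshold-compactness scores
#' (`compactness`), 2 principal-axis descriptors (`axial`), 2 radial
#' intensity-distribution descriptors (`radial`), 2 depth-profile
#' descriptors (`profile`) and 4 texture responses (`texture`).
#'
#' @return Character vector of 31 `<family>.<name>` strings, in canonical
#'   column order.
#' @seealso [feature_names()] for the full 124-column scheme.
#' @export
#' @examples
#' length(marker_feature_names())  # 31
marker_feature_names <- function() {
  c(
    paste0("morph.", c("area", "length", "width", "roundness")),
    paste0("intensity.", c("mean", "sd", "min", "max", "sum")),
    paste0("symmetry.s", c("02", "03", "04", "05", "12", "13", "14", "15")),
    paste0("compactness.q", c("10", "20", "30", "40")),
    paste0("axial.", c("length", "ratio")),
    paste0("radial.", c("mean", "reldev")),
    paste0("profile.", c("inner", "depth")),
    paste0("texture.", c("spot", "hole", "edge", "valley"))
  )
}

#' Marker names of the four-channel profiling panel
#'
#' `nucleus` (DNA stain), `mito` (mitochondrial stain), `aat`
#' (acetylated alpha-tubulin stain) and `cell` (label-free phase
#' contrast over the whole-cell region).
#'
#' @return Character vector of length 4.
#' @export
marker_names <- function() c("nucleus", "mito", "aat", "cell")

#' Full 124-column feature naming scheme
#'
#' Column names follow `<marker>.<family>.<name>`; 31 features for each of
#' the four markers, 124 in total. The order is fixed: all features of a
#' marker are contiguous, markers in the order of [marker_names()].
#'
#' @param markers Markers to include (default all four).
#' @return Character vector of feature column names.
#' @export
#' @examples
#' length(feature_names())            # 124
#' head(feature_names("mito"), 3)
feature_names <- function(markers = marker_names()) {
  markers <- match.arg(markers, marker_names(), several.ok = TRUE)
  as.character(unlist(lapply(markers, function(m)
    paste0(m, ".", marker_feature_names()))))
}

#' Resolve a marker set to its feature columns
#'
#' A marker set is one of the four single markers or `"combined"`
#' (all 124 features).
#'
#' @param marker_set `"nucleus"`, `"mito"`, `"aat"`, `"cell"` or
#'   `"combined"`.
#' @return Character vector of feature column names.
#' @export
marker_set_columns <- function(marker_set = c("combined", marker_names())) {
  marker_set <- match.arg(marker_set)
  if (marker_set == "combined") feature_names() else feature_names(marker_set)
}

#' Family of each feature column
#' @noRd
feature_family <- function(cols = feature_names()) {
  sub("^[^.]+\\.([^.]+)\\..*$", "\\1", cols)
}

#' Marker of each feature column
#' @noRd
feature_marker <- function(cols = feature_names()) {
  sub("^([^.]+)\\..*$", "\\1", cols)
}

#' Feature-value accounting for a cohort
#'
#' Bookkeeping used to sanity-check dataset sizes: the number of feature
#' values a cohort contributes is `cells x features` when all markers are
#' profiled jointly, or `features_per_marker x markers x cells` when
#' counted per marker panel. This is metadata-only arithmetic; no cells
#' are simulated.
#'
#' @param n_cells Number of cells.
#' @param per_marker If `TRUE`, count as
#'   `features_per_marker * n_markers * n_cells`; otherwise as
#'   `n_cells * total_features`. Both give the same number; the two forms
#'   mirror how per-marker and combined analyses are usually reported.
#' @return Integer count of feature values.
#' @export
#' @examples
#' feature_value_count(4370, per_marker = TRUE)  # 541880
feature_value_count <- function(n_cells, per_marker = FALSE) {
  check_scalar(n_cells, "n_cells", lower = 0, integer = TRUE)
  n_per_marker <- length(marker_feature_names())
  n_markers <- length(marker_names())
  if (per_marker) n_per_marker * n_markers * n_cells
  else n_cells * n_per_marker * n_markers
}
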