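#' Configuration for a simulated case/control cohort
#'
#' Defines the statistical structure of a simulated fibroblast cohort at
#' the feature-table level: two groups of individuals, a fixed number of
#' cells per individual, a group mean shift planted on a subset of the
#' 124 features, Gaussian per-individual random effects shared by all of
#' an individual's cells, equicorrelated noise within each feature
#' family, and an optional treatment that reverts a fraction of the
#' planted shift on selected markers.
#'
#' The feature model for cell `c` of individual `i` in group `g` is
#' `x = baseline + g * delta * (1 - reversion * treated) + b_i + e`,
#' where `delta = effect_size * sqrt(1 + individual_sd^2)` on affected
#' features (0 elsewhere), `b_i ~ N(0, individual_sd)` per feature, and
#' `e` has unit variance with correlation `within_family_corr` between
#' features of the same `(marker, family)` block. `effect_size` is
#' therefore the group difference in pooled cell-level SD units.
#'
#' @param n_group0,n_group1 Number of individuals per group (>= 1).
#' @param cells_per_individual Cells simulated per individual (>= 1).
#' @param effect_size Group mean shift on affected features, in pooled
#'   cell-level SD units (>= 0).
#' @param affected_count How many of the 124 features carry the shift.
#'   Affected features are spread round-robin across the four markers so
#'   every marker subset carries signal.
#' @param individual_sd SD of the per-individual random effect (same
#'   units as the unit-variance cell noise).
#' @param within_family_corr Correlation in `[0, 1)` among noise of
#'   features in the same feature family.
#' @param treatment_reversion Fraction in `[0, 1]` of the planted shift
#'   removed by simulated treatment (on `reverted_markers` only).
#' @param reverted_markers Markers whose affected features respond to
#'   treatment; default all four. Unlisted markers keep their full shift
#'   in treated cells, emulating a drug that rescues only some
#'   organelle phenotypes.
#' @param baseline_mean Baseline feature mean (arbitrary units).
#' @param group_labels Labels for groups coded 0 and 1.
#' @param run_label Run identifier stored in the metadata.
#' @param seed Integer seed; identical configs give bit-identical tables.
#' @return An object of class `cohort_config`.
#' @seealso [simulate_feature_table()]
#' @export
cohort_config <- function(n_group0 = 9, n_group1 = 10,
                          cells_per_individual = 500,
                          effect_size = 1.5, affected_count = 40,
                          individual_sd = 0.3, within_family_corr = 0.3,
                          treatment_reversion = 0,
                          reverted_markers = marker_names(),
                          baseline_mean = 10,
                          group_labels = c("control", "case"),
                          run_label = "run1", seed = 1) {
  check_scalar(n_group0, "n_group0", lower = 1, integer = TRUE)
  check_scalar(n_group1, "n_group1", lower = 1, integer = TRUE)
  check_scalar(cells_per_individual, "cells_per_individual", lower = 1,
               integer = TRUE)
  check_scalar(effect_size, "effect_size", lower = 0)
  check_scalar(affected_count, "affected_count", lower = 0, integer = TRUE)
  if (affected_count > length(feature_names()))
    stop("`affected_count` cannot exceed ", length(feature_names()),
         " features", call. = FALSE)
  check_scalar(individual_sd, "individual_sd", lower = 0)
  check_scalar(within_family_corr, "within_family_corr", lower = 0,
               upper = 1 - 1e-9)
  check_scalar(treatment_reversion, "treatment_reversion", lower = 0,
               upper = 1)
  reverted_markers <- match.arg(reverted_markers, marker_names(),
                                several.ok = TRUE)
  stopifnot(length(group_labels) == 2L, !anyDuplicated(group_labels))
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(
    n_group0 = as.integer(n_group0), n_group1 = as.integer(n_group1),
    cells_per_individual = as.integer(cells_per_individual),
    effect_size = effect_size, affected_count = as.integer(affected_count),
    individual_sd = individual_sd, within_family_corr = within_family_corr,
    treatment_reversion = treatment_reversion,
    reverted_markers = reverted_markers,
    baseline_mean = baseline_mean,
    group_labels = as.character(group_labels),
    run_label = as.character(run_label), seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$n_group0, " + ", x$n_group1,
      " individuals x ", x$cells_per_individual, " cells, effect ",
      x$effect_size, " SD on ", x$affected_count, "/124 features, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Indices of the affected features for a config
#'
#' Affected features are assigned round-robin across markers (feature 1
#' of each marker, then feature 2 of each marker, ...) so that signal is
#' spread over all marker subsets.
#' @param config A [cohort_config()].
#' @return Integer indices into [feature_names()].
#' @export
affected_feature_indices <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_m <- length(marker_names())
  n_f <- length(marker_feature_names())
  round_robin <- as.vector(vapply(seq_len(n_f), function(j)
    (seq_len(n_m) - 1L) * n_f + j, integer(n_m)))
  head(round_robin, config$affected_count)
}

# Planted per-feature mean shift for one group-1 cell (untreated).
planted_shift <- function(config) {
  delta <- numeric(length(feature_names()))
  delta[affected_feature_indices(config)] <-
    config$effect_size * sqrt(1 + config$individual_sd^2)
  delta
}

# Draw an n x 124 noise matrix with block-equicorrelated unit-variance
# noise: features of the same (marker, family) block share a common
# component with weight sqrt(rho).
draw_cell_noise <- function(n, rho) {
  cols <- feature_names()
  block <- paste(feature_marker(cols), feature_family(cols))
  block_id <- match(block, unique(block))
  z_block <- matrix(rnorm(n * max(block_id)), n)
  z_feat <- matrix(rnorm(n * length(cols)), n)
  sqrt(rho) * z_block[, block_id, drop = FALSE] + sqrt(1 - rho) * z_feat
}

#' Simulate a per-cell feature table with planted cohort structure
#'
#' Generates the cohort defined by a [cohort_config()]: every individual
#' contributes `cells_per_individual` rows of 124 named features plus
#' metadata columns `individual_id`, `group`, `treatment` and `run`.
#' With `include_treated = TRUE`, a treated copy of every group-1
#' individual is appended (fresh cells, same individual random effects)
#' in which the planted shift on `reverted_markers` is multiplied by
#' `1 - treatment_reversion`. The untreated block is identical whether
#' or not treated cells are requested.
#'
#' @param config A [cohort_config()].
#' @param include_treated Also emit treated copies of group-1
#'   individuals.
#' @return A `data.frame` with metadata columns followed by the 124
#'   feature columns of [feature_names()].
#' @export
#' @examples
#' tab <- simulate_feature_table(cohort_config(
#'   n_group0 = 2, n_group1 = 2, cells_per_individual = 20, seed = 7))
#' dim(tab)  # 80 rows, 4 + 124 columns
simulate_feature_table <- function(config, include_treated = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  cols <- feature_names()
  delta <- planted_shift(config)
  rev_mask <- feature_marker(cols) %in% config$reverted_markers
  delta_treated <- delta * ifelse(rev_mask, 1 - config$treatment_reversion, 1)

  n_ind <- config$n_group0 + config$n_group1
  ids <- c(sprintf("%s%02d", config$group_labels[1],
                   seq_len(config$n_group0)),
           sprintf("%s%02d", config$group_labels[2],
                   seq_len(config$n_group1)))
  grp <- rep(config$group_labels, c(config$n_group0, config$n_group1))

  with_seed(config$seed, {
    b <- matrix(rnorm(n_ind * length(cols), sd = config$individual_sd),
                n_ind, dimnames = list(ids, cols))
    one_block <- function(ind, treatment) {
      i <- match(ind, ids)
      is_case <- grp[i] == config$group_labels[2]
      shift <- if (!is_case) 0 else if (treatment == "treated")
        delta_treated else delta
      x <- draw_cell_noise(config$cells_per_individual,
                           config$within_family_corr)
      x <- sweep(x, 2, config$baseline_mean + shift + b[i, ], "+")
      colnames(x) <- cols
      cbind(data.frame(individual_id = ind, group = grp[i],
                       treatment = treatment, run = config$run_label,
                       stringsAsFactors = FALSE),
            as.data.frame(x))
    }
    blocks <- lapply(ids, one_block, treatment = "untreated")
    if (include_treated) {
      treated_ids <- ids[grp == config$group_labels[2]]
      blocks <- c(blocks, lapply(treated_ids, one_block,
                                 treatment = "treated"))
    }
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out
  })
}

#' Metadata column names of a feature table
#' @noRd
metadata_columns <- function() c("individual_id", "group", "treatment", "run")

# Validate a feature table and return its feature column names.
check_feature_table <- function(table, require = feature_names()) {
  stopifnot(is.data.frame(table))
  missing <- setdiff(require, names(table))
  if (length(missing))
    stop("feature table is missing columns: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", call. = FALSE)
  invisible(require)
}
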