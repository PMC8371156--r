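# Negative-control normalization and run-to-run reproducibility.

#' Fit per-run negative-control normalization parameters
#'
#' Computes, for every `(run, feature)` pair, the mean and SD of the
#' feature over negative-control cells (healthy controls), so that all
#' values can be expressed as control z-scores per run. Features whose
#' control SD is below `1e-12` are flagged and later passed through
#' unscaled rather than dropped, preserving the 124-column contract.
#'
#' @param table Feature table with `run` metadata and the 124 feature
#'   columns.
#' @param control Either the group label of the negative controls
#'   (default `"control"`) or a predicate `function(table) -> logical`
#'   selecting control rows.
#' @param min_control_cells Minimum control cells required per run.
#' @return Object of class `normalization_params`.
#' @export
fit_control_normalizer <- function(table, control = "control",
                                   min_control_cells = 30) {
  cols <- check_feature_table(table)
  sel <- if (is.function(control)) control(table)
  else table$group == control
  if (!any(sel)) stop("no control cells selected", call. = FALSE)
  runs <- unique(table$run)
  missing <- setdiff(runs, unique(table$run[sel]))
  if (length(missing))
    stop("runs without control cells: ",
         paste(missing, collapse = ", "), call. = FALSE)
  low <- runs[vapply(runs, function(r) sum(sel & table$run == r), 0) <
                min_control_cells]
  if (length(low))
    stop("fewer than ", min_control_cells, " control cells in run(s): ",
         paste(low, collapse = ", "), call. = FALSE)
  params <- do.call(rbind, lapply(runs, function(r) {
    sub <- as.matrix(table[sel & table$run == r, cols])
    mu <- colMeans(sub)
    sig <- apply(sub, 2, sd)
    data.frame(run = r, feature = cols, mean = mu, sd = sig,
               flagged = sig < 1e-12, row.names = NULL)
  }))
  structure(list(params = params, control = control),
            class = "normalization_params")
}

#' @export
print.normalization_params <- function(x, ...) {
  cat("<normalization_params> ", length(unique(x$params$run)),
      " run(s) x ", length(unique(x$params$feature)), " features, ",
      sum(x$params$flagged), " flagged\n", sep = "")
  invisible(x)
}

#' Apply control normalization to a feature table
#'
#' Transforms every feature value to
#' `(x - mean_control_run) / sd_control_run` using the parameters from
#' [fit_control_normalizer()]. Flagged near-zero-variance features are
#' centered but not scaled (a warning lists them). Metadata columns are
#' unchanged.
#'
#' @param table Feature table.
#' @param params A `normalization_params` covering every run in
#'   `table`.
#' @return Normalized feature table, same shape as `table`.
#' @export
apply_normalizer <- function(table, params) {
  stopifnot(inherits(params, "normalization_params"))
  cols <- check_feature_table(table)
  missing <- setdiff(unique(table$run), unique(params$params$run))
  if (length(missing))
    stop("no normalization parameters for run(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- table
  flagged <- character(0)
  for (r in unique(table$run)) {
    pr <- params$params[params$params$run == r, ]
    pr <- pr[match(cols, pr$feature), ]
    idx <- which(table$run == r)
    x <- as.matrix(table[idx, cols])
    scale <- ifelse(pr$flagged, 1, pr$sd)
    x <- sweep(sweep(x, 2, pr$mean), 2, scale, "/")
    out[idx, cols] <- x
    flagged <- union(flagged, pr$feature[pr$flagged])
  }
  if (length(flagged))
    warning("near-zero-variance feature(s) passed through unscaled: ",
            paste(head(flagged, 5), collapse = ", "),
            if (length(flagged) > 5) " ...", call. = FALSE)
  out
}

#' Run-to-run reproducibility check
#'
#' Tests whether two acquisition runs of the same individuals are
#' morphologically distinguishable: cells of both tables are pooled,
#' run membership is used as the 0/1 outcome of a logistic regression
#' on the combined features, and per-individual mean probabilities are
#' compared between runs. If no individual's mean run-A and run-B
#' probabilities differ by more than `margin`, the runs are declared
#' reproducible (the classifier found no individual-consistent batch
#' signal; all probabilities then sit near 0.5).
#'
#' @param tableA,tableB Feature tables for the two runs, sharing
#'   individuals.
#' @param margin Maximum tolerated per-individual difference of mean
#'   probabilities between runs.
#' @param marker_set Feature subset to use (default `"combined"`).
#' @return List with `per_individual` (data.frame: individual, mean
#'   probability per run, difference), `max_difference`, `reproducible`.
#' @export
run_reproducibility_check <- function(tableA, tableB, margin = 0.05,
                                      marker_set = "combined") {
  check_feature_table(tableA)
  check_feature_table(tableB)
  shared <- intersect(unique(tableA$individual_id),
                      unique(tableB$individual_id))
  if (length(shared) == 0)
    stop("the two tables share no individuals", call. = FALSE)
  a <- tableA[tableA$individual_id %in% shared, ]
  b <- tableB[tableB$individual_id %in% shared, ]
  a$.run_code <- "runA"
  b$.run_code <- "runB"
  pooled <- rbind(a, b)
  pooled$group <- pooled$.run_code
  pooled$treatment <- "untreated"

  # out-of-fold probabilities (2 folds, alternating cells within each
  # individual x run stratum) so that run-specific noise memorized by
  # the fit cannot masquerade as a batch effect
  strata <- paste(pooled$individual_id, pooled$.run_code)
  fold <- unlist(lapply(split(seq_len(nrow(pooled)), strata),
                        function(i) seq_along(i) %% 2L))[
                          order(unlist(split(seq_len(nrow(pooled)),
                                             strata)))]
  p <- rep(NA_real_, nrow(pooled))
  for (f in 0:1) {
    model <- suppressWarnings(fit_cell_classifier(
      pooled[fold != f, , drop = FALSE],
      group_coding = c("runA", "runB"), marker_set = marker_set))
    p[fold == f] <-
      score_cells(model,
                  pooled[fold == f, , drop = FALSE])$cells$probability
  }
  per <- do.call(rbind, lapply(shared, function(id) {
    pa <- p[pooled$individual_id == id & pooled$.run_code == "runA"]
    pb <- p[pooled$individual_id == id & pooled$.run_code == "runB"]
    data.frame(individual_id = id, mean_runA = mean(pa),
               mean_runB = mean(pb),
               difference = abs(mean(pa) - mean(pb)))
  }))
  list(per_individual = per,
       max_difference = max(per$difference),
       reproducible = max(per$difference) < margin)
}
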