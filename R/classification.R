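# Per-cell binary logistic-regression scoring.

# Ridge-penalized IRLS for logistic regression; intercept unpenalized.
# Used as the fallback under quasi-separation (lambda 1e-6) so that
# coefficients stay finite while sum(fitted) = n1 still holds exactly.
ridge_logistic <- function(X1, y, lambda, maxit = 100, tol = 1e-10) {
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X1 * w)
    beta_new <- solve(XtW %*% X1 + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  beta
}

#' Fit the per-cell binary logistic-regression scorer
#'
#' Maximum-likelihood logistic regression of group membership on the
#' standardized features of a marker subset. Cells of the group coded 0
#' and the group coded 1 are the two classes; the fitted model predicts,
#' for every cell, a probability score in `[0, 1]` interpreted as
#' resemblance to the group coded 1. Standardization constants (per-
#' feature mean and SD of the training cells) are stored in the model so
#' that transfer scoring of new tables uses the training scale. The fit
#' is unpenalized by default; if quasi-separation is detected (the IRLS
#' warns of fitted probabilities at 0/1 or fails to converge), the model
#' is refit with a tiny ridge penalty (`1e-6`) and a warning is issued.
#'
#' @param table Feature table; must contain a `group` column and the
#'   marker subset's feature columns. Only rows with
#'   `treatment == "untreated"` are used if a `treatment` column is
#'   present (treated cells never enter fitting).
#' @param group_coding Length-2 character vector: the group coded 0,
#'   then the group coded 1. Defaults to the order of first appearance.
#' @param marker_set `"nucleus"`, `"mito"`, `"aat"`, `"cell"` or
#'   `"combined"`.
#' @param min_cells_per_class Minimum training cells per class.
#' @return Object of class `scoring_model`.
#' @export
fit_cell_classifier <- function(table, group_coding = NULL,
                                marker_set = "combined",
                                min_cells_per_class = 10) {
  cols <- marker_set_columns(marker_set)
  check_feature_table(table, cols)
  if (!"group" %in% names(table))
    stop("feature table has no `group` column", call. = FALSE)
  if ("treatment" %in% names(table))
    table <- table[table$treatment == "untreated", , drop = FALSE]
  groups <- unique(as.character(table$group))
  if (is.null(group_coding)) group_coding <- groups
  if (length(group_coding) != 2)
    stop("exactly two groups are required; found: ",
         paste(groups, collapse = ", "), call. = FALSE)
  if (!all(groups %in% group_coding))
    stop("table contains groups outside `group_coding`: ",
         paste(setdiff(groups, group_coding), collapse = ", "),
         call. = FALSE)
  y <- as.numeric(table$group == group_coding[2])
  if (min(sum(y == 0), sum(y == 1)) < min_cells_per_class)
    stop("need at least ", min_cells_per_class,
         " cells in each class", call. = FALSE)

  X <- as.matrix(table[, cols])
  bad <- cols[!apply(X, 2, function(v) all(is.finite(v)))]
  if (length(bad))
    stop("non-finite feature values in column(s): ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ...", call. = FALSE)
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  constant <- scale < 1e-12
  scale[constant] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  use <- !constant
  X1 <- cbind(1, Xs[, use, drop = FALSE])

  separated <- FALSE
  fit <- withCallingHandlers(
    glm.fit(X1, y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || !fit$converged) {
    warning("quasi-separation detected for marker set '", marker_set,
            "'; refitting with ridge penalty 1e-6", call. = FALSE)
    beta_all <- ridge_logistic(X1, y, lambda = 1e-6)
  } else {
    beta_all <- coef(fit)
  }
  beta <- numeric(length(cols))
  beta[use] <- beta_all[-1]

  train_pairs <- unique(data.frame(
    individual_id = if ("individual_id" %in% names(table))
      as.character(table$individual_id) else NA_character_,
    treatment = if ("treatment" %in% names(table))
      as.character(table$treatment) else "untreated",
    stringsAsFactors = FALSE))

  structure(list(
    coefficients = setNames(beta, cols),
    intercept = unname(beta_all[1]),
    center = setNames(center, cols),
    scale = setNames(scale, cols),
    constant = setNames(constant, cols),
    marker_set = marker_set,
    coding = setNames(c(0, 1), group_coding),
    n_train = c(n0 = sum(y == 0), n1 = sum(y == 1)),
    training = train_pairs,
    separation_fallback = separated || !fit$converged
  ), class = "scoring_model")
}

#' @export
print.scoring_model <- function(x, ...) {
  cat("<scoring_model> marker set '", x$marker_set, "', ",
      length(x$coefficients), " features; coding: ",
      names(x$coding)[1], " = 0, ", names(x$coding)[2], " = 1; ",
      "trained on ", x$n_train[1], " + ", x$n_train[2], " cells",
      if (x$separation_fallback) " (ridge fallback)", "\n", sep = "")
  invisible(x)
}

#' Score cells with a fitted model
#'
#' Computes `p = plogis(b0 + b' x_std)` for every row, standardizing
#' with the model's stored training constants (essential when the model
#' is transferred to cells it was not fitted on).
#'
#' @param model A `scoring_model`.
#' @param table Feature table containing the model's feature columns.
#' @return Object of class `probability_scores`: list with `cells`
#'   (data.frame of metadata plus `probability`), `marker_set`,
#'   `coding`.
#' @export
score_cells <- function(model, table) {
  stopifnot(inherits(model, "scoring_model"))
  cols <- names(model$coefficients)
  check_feature_table(table, cols)
  X <- as.matrix(table[, cols])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  p <- plogis(model$intercept + drop(Xs %*% model$coefficients))
  meta <- intersect(c(metadata_columns(), "cell_id"), names(table))
  cells <- cbind(table[, meta, drop = FALSE],
                 data.frame(probability = p))
  rownames(cells) <- NULL
  structure(list(cells = cells, marker_set = model$marker_set,
                 coding = model$coding),
            class = "probability_scores")
}

#' @export
print.probability_scores <- function(x, ...) {
  cat("<probability_scores> ", nrow(x$cells), " cells, marker set '",
      x$marker_set, "'\n", sep = "")
  invisible(x)
}

#' Per-individual mean probability scores
#'
#' The unit of all downstream group statistics: the arithmetic mean of
#' each individual's cell probabilities (kept separate per treatment if
#' several treatments are present).
#'
#' @param scores A `probability_scores`.
#' @return data.frame with one row per individual (x treatment):
#'   `individual_id`, `group`, `treatment` (if present), `n_cells`,
#'   `mean_probability`.
#' @export
aggregate_individual_means <- function(scores) {
  stopifnot(inherits(scores, "probability_scores"))
  cells <- scores$cells
  if (!"individual_id" %in% names(cells) ||
      any(is.na(cells$individual_id)))
    stop("every cell must carry an `individual_id`", call. = FALSE)
  keys <- intersect(c("individual_id", "group", "treatment"),
                    names(cells))
  agg <- aggregate(cells["probability"], by = cells[keys], FUN = mean)
  cnt <- aggregate(list(n_cells = cells$probability), by = cells[keys],
                   FUN = length)
  out <- merge(agg, cnt, by = keys, sort = TRUE)
  names(out)[names(out) == "probability"] <- "mean_probability"
  out[order(out$individual_id), c(keys, "n_cells", "mean_probability")]
}

#' Per-group probability histogram
#'
#' Counts of cell probability scores in equal-width bins over `[0, 1]`,
#' per group, together with both group mean scores (the "dotted lines"
#' of a score-distribution plot).
#'
#' @param scores A `probability_scores`.
#' @param bins Number of equal-width bins (>= 2).
#' @return List with `breaks` (length `bins + 1`), `counts` (matrix,
#'   one row per group) and `group_means`.
#' @export
probability_histogram <- function(scores, bins = 50) {
  stopifnot(inherits(scores, "probability_scores"))
  check_scalar(bins, "bins", lower = 2, integer = TRUE)
  breaks <- seq(0, 1, length.out = bins + 1)
  groups <- unique(as.character(scores$cells$group))
  counts <- t(vapply(groups, function(g) {
    p <- scores$cells$probability[scores$cells$group == g]
    bin <- pmin(pmax(findInterval(p, breaks, rightmost.closed = TRUE),
                     1L), bins)
    tabulate(bin, nbins = bins)
  }, integer(bins)))
  rownames(counts) <- groups
  means <- vapply(groups, function(g)
    mean(scores$cells$probability[scores$cells$group == g]), 0)
  list(breaks = breaks, counts = counts, group_means = means)
}

#' Serialize a scoring model to JSON
#' @param model A `scoring_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scoring_model <- function(model, path) {
  stopifnot(inherits(model, "scoring_model"))
  out <- unclass(model)
  for (nm in c("coefficients", "center", "scale", "constant",
               "coding", "n_train"))
    out[[nm]] <- as.list(out[[nm]])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scoring model written by [write_scoring_model()]
#' @param path JSON path.
#' @return A `scoring_model`.
#' @export
read_scoring_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("coefficients", "center", "scale", "constant",
               "coding", "n_train"))
    x[[nm]] <- unlist(x[[nm]])
  x$training <- as.data.frame(x$training, stringsAsFactors = FALSE)
  structure(x, class = "scoring_model")
}

#' Cross-validated per-cell probability scores
#'
#' Honest (out-of-fold) alternative to the default in-sample workflow:
#' individuals are assigned to `folds` folds (round-robin within group,
#' so folds are stratified), and each individual's cells are scored by
#' a model fitted without any cell of that individual. This removes the
#' two leakage routes of in-sample scoring — memorized per-individual
#' signatures and the shared in-sample group gap — and is the scoring
#' mode under which a no-effect cohort yields chance-level (AUC 0.5)
#' individual classification.
#'
#' @param table Feature table (untreated cells; `treatment` rows other
#'   than `"untreated"` are dropped as in [fit_cell_classifier()]).
#' @param group_coding Length-2 vector (group coded 0, group coded 1).
#' @param marker_set Feature subset, as in [fit_cell_classifier()].
#' @param folds Number of folds (>= 2; capped at the size of the
#'   smaller group so every fold keeps both classes).
#' @return A `probability_scores` with out-of-fold probabilities.
#' @export
score_cells_cv <- function(table, group_coding = NULL,
                           marker_set = "combined", folds = 5) {
  if ("treatment" %in% names(table))
    table <- table[table$treatment == "untreated", , drop = FALSE]
  if (!"individual_id" %in% names(table))
    stop("cross-validated scoring requires `individual_id`",
         call. = FALSE)
  groups <- unique(as.character(table$group))
  if (is.null(group_coding)) group_coding <- groups
  stopifnot(length(group_coding) == 2)
  check_scalar(folds, "folds", lower = 2, integer = TRUE)

  # deterministic round-robin fold assignment, stratified by group
  fold_of <- integer(0)
  for (g in group_coding) {
    ids <- sort(unique(table$individual_id[table$group == g]))
    fold_of[ids] <- (seq_along(ids) - 1L) %% folds + 1L
  }
  folds_used <- sort(unique(fold_of))
  p <- rep(NA_real_, nrow(table))
  for (f in folds_used) {
    test_ids <- names(fold_of)[fold_of == f]
    train <- table[!table$individual_id %in% test_ids, , drop = FALSE]
    test_rows <- which(table$individual_id %in% test_ids)
    model <- suppressWarnings(
      fit_cell_classifier(train, group_coding, marker_set))
    p[test_rows] <-
      score_cells(model, table[test_rows, , drop = FALSE])$cells$probability
  }
  meta <- intersect(c(metadata_columns(), "cell_id"), names(table))
  cells <- cbind(table[, meta, drop = FALSE],
                 data.frame(probability = p))
  rownames(cells) <- NULL
  structure(list(cells = cells, marker_set = marker_set,
                 coding = setNames(c(0, 1), group_coding)),
            class = "probability_scores")
}
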