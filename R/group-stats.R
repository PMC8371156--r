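# Group comparison statistics on per-individual mean probabilities.

#' Two-sample t-test on individual mean probabilities
#'
#' Student's t-test (equal variances by default; Welch via
#' `var_equal = FALSE`) comparing the per-individual mean probability
#' scores of the two groups. Degenerate inputs are guarded: two
#' identical constant groups give `t = 0, p = 1`; zero pooled variance
#' with different means gives an underflow-safe minimal p-value.
#'
#' @param means_g0,means_g1 Numeric vectors of individual means
#'   (>= 2 each).
#' @param var_equal Pool variances (classic Student test) if `TRUE`.
#' @return List with `t`, `p`, `mean_g0`, `mean_g1`, `df`.
#' @export
compare_groups_ttest <- function(means_g0, means_g1, var_equal = TRUE) {
  if (length(means_g0) < 2 || length(means_g1) < 2)
    stop("need at least 2 individuals per group", call. = FALSE)
  m0 <- mean(means_g0); m1 <- mean(means_g1)
  if (var(means_g0) + var(means_g1) < 1e-24) {
    if (abs(m1 - m0) < 1e-12)
      return(list(t = 0, p = 1, mean_g0 = m0, mean_g1 = m1,
                  df = length(means_g0) + length(means_g1) - 2))
    return(list(t = sign(m1 - m0) * Inf, p = .Machine$double.xmin,
                mean_g0 = m0, mean_g1 = m1,
                df = length(means_g0) + length(means_g1) - 2))
  }
  tt <- t.test(means_g1, means_g0, var.equal = var_equal)
  list(t = unname(tt$statistic), p = max(tt$p.value, .Machine$double.xmin),
       mean_g0 = m0, mean_g1 = m1, df = unname(tt$parameter))
}

#' Individual-level ROC analysis
#'
#' Sweeps a threshold over the per-individual mean probabilities and
#' reports the ROC curve (1 - specificity vs sensitivity) plus the AUC
#' computed by the Mann-Whitney identity (ties counted 1/2), which
#' equals the trapezoidal area under the curve. The unit of analysis is
#' the individual, not the cell: with `n0 + n1` people the curve has at
#' most `n0 + n1 + 1` points.
#'
#' @param individual_means Numeric vector of per-individual mean
#'   probabilities.
#' @param labels Group label per individual (two distinct values).
#' @param positive The label treated as positive (scores expected
#'   higher). Default: the group coded 1 by the table order, i.e. the
#'   second unique label.
#' @return Object of class `roc_result`: `auc`, `points` (data.frame
#'   `fpr`, `tpr`, `threshold`), `positive`.
#' @export
roc_individuals <- function(individual_means, labels, positive = NULL) {
  stopifnot(length(individual_means) == length(labels))
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2)
    stop("labels must contain exactly two classes; found: ",
         paste(lev, collapse = ", "), call. = FALSE)
  if (is.null(positive)) positive <- lev[2]
  if (!positive %in% lev)
    stop("`positive` label not present", call. = FALSE)
  pos <- individual_means[labels == positive]
  neg <- individual_means[labels != positive]

  # Mann-Whitney identity via midranks
  rk <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(rk[seq_along(pos)]) -
            length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))

  thr <- c(Inf, sort(unique(individual_means), decreasing = TRUE))
  points <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(neg >= t), 0),
    tpr = vapply(thr, function(t) mean(pos >= t), 0))
  structure(list(auc = auc, points = points, positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", format(x$auc, digits = 4),
      " (positive class: ", x$positive, ", ",
      nrow(x$points), " curve points)\n", sep = "")
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc A `roc_result` (or any data.frame with `fpr`, `tpr`).
#' @return Trapezoidal AUC; equals `roc$auc` up to floating point.
#' @export
trapezoid_auc <- function(roc) {
  pts <- if (inherits(roc, "roc_result")) roc$points else roc
  ord <- order(pts$fpr, pts$tpr)
  x <- pts$fpr[ord]; y <- pts$tpr[ord]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Fold difference between group mean probabilities
#'
#' The amplified effect-size readout of multi-feature scoring: the mean
#' probability of the group coded 1 divided by the mean probability of
#' the group coded 0.
#'
#' @param scores A `probability_scores`.
#' @return Single numeric fold value.
#' @export
fold_difference <- function(scores) {
  stopifnot(inherits(scores, "probability_scores"))
  g0 <- names(scores$coding)[scores$coding == 0]
  g1 <- names(scores$coding)[scores$coding == 1]
  m0 <- mean(scores$cells$probability[scores$cells$group == g0])
  m1 <- mean(scores$cells$probability[scores$cells$group == g1])
  if (!is.finite(m0) || m0 <= 0)
    stop("group '", g0, "' has zero mean probability", call. = FALSE)
  m1 / m0
}

#' Conventional single-feature baseline analysis
#'
#' The classical alternative to multi-feature scoring: take one named
#' feature (e.g. a mitochondrial aspect ratio), average it per
#' individual, compare groups with a Student's t-test and report the
#' ratio of group means. This is the baseline against which the
#' logistic-regression fold difference is compared.
#'
#' @param table Feature table with `group` and `individual_id`.
#' @param feature_name One of [feature_names()].
#' @param group_coding Length-2 vector (group coded 0, group coded 1);
#'   default order of first appearance.
#' @return List with `feature`, `mean_g0`, `mean_g1`, `t`, `p`,
#'   `fold` (= `mean_g1 / mean_g0`).
#' @export
conventional_feature_analysis <- function(table, feature_name,
                                          group_coding = NULL) {
  if (!feature_name %in% names(table))
    stop("unknown feature '", feature_name, "'; available: ",
         paste(head(intersect(feature_names(), names(table)), 6),
               collapse = ", "), " ...", call. = FALSE)
  if ("treatment" %in% names(table))
    table <- table[table$treatment == "untreated", , drop = FALSE]
  groups <- unique(as.character(table$group))
  if (is.null(group_coding)) group_coding <- groups
  stopifnot(length(group_coding) == 2)
  per <- aggregate(table[[feature_name]],
                   by = list(individual_id = table$individual_id,
                             group = table$group), FUN = mean)
  v0 <- per$x[per$group == group_coding[1]]
  v1 <- per$x[per$group == group_coding[2]]
  tt <- compare_groups_ttest(v0, v1)
  fold <- if (abs(mean(v0)) < 1e-12) NA_real_ else mean(v1) / mean(v0)
  list(feature = feature_name, mean_g0 = mean(v0), mean_g1 = mean(v1),
       t = tt$t, p = tt$p, fold = fold)
}
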