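# Classifier transfer to drug-treated cells and rescue classification.
#
# A frozen case-vs-control scoring model is applied, unchanged, to
# treated patient cells; if treatment pushes their probability scores
# back toward the control range, the phenotype is called rescued.

#' Score drug-treated cells with a frozen case/control model
#'
#' Applies a `scoring_model` trained on untreated case and control
#' cells to a table of treated cells, using the model's stored
#' standardization (no refitting). A leakage guard refuses models whose
#' training set contained treated cells or any of the
#' (individual, treated) pairs being scored.
#'
#' @param model A frozen `scoring_model` (untreated training cells
#'   only).
#' @param treated_table Feature table of treated cells (must carry a
#'   `treatment` column).
#' @return A `probability_scores` for the treated cells.
#' @export
score_treated <- function(model, treated_table) {
  stopifnot(inherits(model, "scoring_model"))
  if (!"treatment" %in% names(treated_table))
    stop("treated table must carry a `treatment` column", call. = FALSE)
  if (any(model$training$treatment != "untreated"))
    stop("model was trained on treated cells; transfer scoring ",
         "requires a model fitted to untreated cells only",
         call. = FALSE)
  pairs <- unique(paste(treated_table$individual_id,
                        treated_table$treatment))
  trained <- paste(model$training$individual_id,
                   model$training$treatment)
  if (any(pairs %in% trained))
    stop("model training set overlaps the treated cells being scored",
         call. = FALSE)
  score_cells(model, treated_table)
}

#' One-way ANOVA with Tukey HSD across control / patient / treated
#'
#' Compares the per-individual mean probabilities of three groups —
#' untreated controls, untreated patients, and drug-treated patients —
#' by one-way ANOVA, with Tukey's honest-significant-difference test
#' for the three pairwise contrasts.
#'
#' @param control_means,patient_means,treated_means Numeric vectors of
#'   individual mean probabilities (>= 2 each).
#' @param marker_set Optional marker-set label carried into the result.
#' @return Object of class `rescue_entry`: `F`, `p`, `group_means`,
#'   `tukey` (named p-values `treated_vs_control`,
#'   `treated_vs_patient`, `patient_vs_control`), `n`, `marker_set`.
#' @export
rescue_anova <- function(control_means, patient_means, treated_means,
                         marker_set = NA_character_) {
  if (min(length(control_means), length(patient_means),
          length(treated_means)) < 2)
    stop("need at least 2 individuals per group", call. = FALSE)
  df <- data.frame(
    value = c(control_means, patient_means, treated_means),
    group = factor(rep(c("control", "patient", "treated"),
                       c(length(control_means), length(patient_means),
                         length(treated_means))),
                   levels = c("control", "patient", "treated")))
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  get_p <- function(a, b) {
    rn <- rownames(tk)
    i <- which(rn == paste0(a, "-", b) | rn == paste0(b, "-", a))
    unname(tk[i, "p adj"])
  }
  structure(list(
    F = an["group", "F value"], p = an["group", "Pr(>F)"],
    group_means = c(control = mean(control_means),
                    patient = mean(patient_means),
                    treated = mean(treated_means)),
    tukey = c(treated_vs_control = get_p("treated", "control"),
              treated_vs_patient = get_p("treated", "patient"),
              patient_vs_control = get_p("patient", "control")),
    n = c(control = length(control_means),
          patient = length(patient_means),
          treated = length(treated_means)),
    marker_set = marker_set
  ), class = "rescue_entry")
}

#' @export
print.rescue_entry <- function(x, ...) {
  cat("<rescue_entry>", if (!is.na(x$marker_set))
    paste0(" [", x$marker_set, "]"),
    " F = ", format(x$F, digits = 4),
    ", p = ", format(x$p, digits = 4), "\n",
    "  means: control ", format(x$group_means["control"], digits = 3),
    ", patient ", format(x$group_means["patient"], digits = 3),
    ", treated ", format(x$group_means["treated"], digits = 3), "\n",
    "  Tukey p: treated-control ",
    format(x$tukey["treated_vs_control"], digits = 4),
    ", treated-patient ",
    format(x$tukey["treated_vs_patient"], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Classify rescue status from a Tukey comparison
#'
#' Formalizes the rescue call: `rescued` when treated cells differ from
#' untreated patient cells (`p < alpha`) but not from controls
#' (`p >= alpha`); `partial` when treated cells differ from neither but
#' their mean lies strictly between the patient and control means
#' (shifted away from the disease phenotype without reaching
#' significance); `not_rescued` otherwise. Both Tukey p-values are kept
#' in the report so borderline calls can be audited.
#'
#' @param entry A `rescue_entry` from [rescue_anova()].
#' @param alpha Significance level (default 0.05).
#' @return `"rescued"`, `"partial"` or `"not_rescued"`.
#' @export
classify_rescue <- function(entry, alpha = 0.05) {
  stopifnot(inherits(entry, "rescue_entry"))
  check_scalar(alpha, "alpha", lower = 0, upper = 1)
  p_tp <- entry$tukey[["treated_vs_patient"]]
  p_tc <- entry$tukey[["treated_vs_control"]]
  gm <- entry$group_means
  between <- (gm["treated"] - gm["patient"]) *
    (gm["control"] - gm["treated"]) > 0
  if (p_tp < alpha && p_tc >= alpha) "rescued"
  else if (p_tp >= alpha && p_tc >= alpha && between) "partial"
  else "not_rescued"
}

#' Per-marker-set rescue report
#'
#' Runs [rescue_anova()] and [classify_rescue()] for several marker
#' sets and assembles the results.
#'
#' @param entries Named list of `rescue_entry` objects (names = marker
#'   sets).
#' @param alpha Significance level for the rescue calls.
#' @return data.frame of class `rescue_report`: one row per marker set
#'   with F, p, group means, Tukey p-values and `rescue_status`.
#' @export
rescue_report <- function(entries, alpha = 0.05) {
  stopifnot(length(entries) > 0,
            all(vapply(entries, inherits, TRUE, "rescue_entry")))
  out <- do.call(rbind, lapply(names(entries), function(ms) {
    e <- entries[[ms]]
    data.frame(
      marker_set = ms, F = e$F, p = e$p,
      mean_control = e$group_means[["control"]],
      mean_patient = e$group_means[["patient"]],
      mean_treated = e$group_means[["treated"]],
      p_treated_vs_control = e$tukey[["treated_vs_control"]],
      p_treated_vs_patient = e$tukey[["treated_vs_patient"]],
      p_patient_vs_control = e$tukey[["patient_vs_control"]],
      rescue_status = classify_rescue(e, alpha),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("rescue_report", "data.frame")
  out
}
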