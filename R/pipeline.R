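# End-to-end orchestration: simulate -> (render/segment/extract) ->
# normalize -> classify -> stats -> treatment transfer.

#' Run the full profiling pipeline from one configuration
#'
#' Executes the enabled stages in order on a simulated cohort:
#'
#' 1. `simulate`: generate the per-cell feature table (plus treated
#'    copies of patient individuals when a treatment effect is
#'    configured);
#' 2. `render` (optional): render one demo multichannel field, segment
#'    it and extract its features end-to-end;
#' 3. `normalize`: z-score all features to the negative-control cells
#'    per run;
#' 4. `classify`/`stats`: for every requested marker set, fit the
#'    per-cell logistic scorer on untreated cells, aggregate
#'    per-individual means, and run the t-test, individual-level ROC
#'    and fold-difference analyses;
#' 5. `treat`: transfer each frozen model to the treated cells and
#'    classify rescue per marker set.
#'
#' Treated cells never enter classifier fitting (enforced by
#' [fit_cell_classifier()] and checked again here). Reruns with the
#' same config are bit-identical for all deterministic stages.
#'
#' @param config A named list or path to a YAML file. Recognized
#'   entries: `cohort` (arguments for [cohort_config()]),
#'   `include_treated` (default: `TRUE` when
#'   `cohort$treatment_reversion > 0`), `marker_sets` (default all four
#'   markers plus `"combined"`), `alpha` (default 0.05), `normalize`
#'   (default `TRUE`), `scene` (optional arguments for [scene_spec()]
#'   to exercise the image path), `out_dir` (optional output
#'   directory).
#' @param out_dir Output directory (overrides `config$out_dir`); if
#'   `NULL`, nothing is written.
#' @return Invisibly, a list with `config`, `table` (normalized feature
#'   table), `models`, `individual_means`, `stats` (per marker set:
#'   group means, t, p, AUC, fold), `rescue` (a [rescue_report()] or
#'   `NULL`) and `image_demo` (extracted features of the rendered
#'   field, or `NULL`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cohort <- do.call(cohort_config, config$cohort %||% list())
  include_treated <- config$include_treated %||%
    (cohort$treatment_reversion > 0)
  marker_sets <- config$marker_sets %||% c(marker_names(), "combined")
  alpha <- config$alpha %||% 0.05
  do_norm <- config$normalize %||% TRUE
  out_dir <- out_dir %||% config$out_dir

  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }

  # -- simulate ------------------------------------------------------
  log_stage("simulate", "cohort of ", cohort$n_group0, " + ",
            cohort$n_group1, " individuals, seed ", cohort$seed)
  table <- simulate_feature_table(cohort, include_treated = include_treated)

  # -- optional image-path demo -------------------------------------
  image_demo <- NULL
  if (!is.null(config$scene)) {
    log_stage("render", "demo field")
    field <- render_field(do.call(scene_spec, config$scene))
    nuc <- find_nuclei(field$channels$nucleus)
    cyt <- find_cytoplasm(field$channels$cellmask, nuc)
    flt <- filter_cells(cyt, nuc)
    image_demo <- extract_cell_features(
      field, flt$nuclei, flt$cells,
      metadata = list(run = cohort$run_label))
    log_stage("extract", nrow(image_demo), " cells x ",
              length(feature_names()), " features")
  }

  # -- normalize -----------------------------------------------------
  if (do_norm) {
    log_stage("normalize", "to '", cohort$group_labels[1],
              "' cells per run")
    params <- fit_control_normalizer(
      table[table$treatment == "untreated", ],
      control = cohort$group_labels[1],
      min_control_cells = min(30, cohort$n_group0 *
                                cohort$cells_per_individual))
    table <- apply_normalizer(table, params)
  }

  untreated <- table[table$treatment == "untreated", ]
  treated <- table[table$treatment == "treated", ]
  stopifnot(!any(untreated$treatment == "treated"))

  # -- classify + stats per marker set ------------------------------
  models <- list(); stats <- list(); means_tabs <- list()
  entries <- list()
  for (ms in marker_sets) {
    log_stage("classify", "marker set '", ms, "'")
    model <- fit_cell_classifier(untreated,
                                 group_coding = cohort$group_labels,
                                 marker_set = ms)
    scores <- score_cells(model, untreated)
    means <- aggregate_individual_means(scores)
    v0 <- means$mean_probability[means$group == cohort$group_labels[1]]
    v1 <- means$mean_probability[means$group == cohort$group_labels[2]]
    tt <- compare_groups_ttest(v0, v1)
    roc <- roc_individuals(means$mean_probability, means$group,
                           positive = cohort$group_labels[2])
    stats[[ms]] <- list(marker_set = ms,
                        mean_g0 = tt$mean_g0, mean_g1 = tt$mean_g1,
                        t = tt$t, p = tt$p, auc = roc$auc,
                        fold = fold_difference(scores))
    models[[ms]] <- model
    means_tabs[[ms]] <- cbind(marker_set = ms, means)

    if (nrow(treated) > 0) {
      tr_scores <- score_treated(model, treated)
      tr_means <- aggregate_individual_means(tr_scores)
      entries[[ms]] <- rescue_anova(v0, v1, tr_means$mean_probability,
                                    marker_set = ms)
    }
  }
  rescue <- if (length(entries)) rescue_report(entries, alpha) else NULL

  results <- list(config = list(cohort = unclass(cohort),
                                include_treated = include_treated,
                                marker_sets = marker_sets,
                                alpha = alpha, normalize = do_norm),
                  table = table,
                  models = models,
                  individual_means = do.call(rbind, means_tabs),
                  stats = stats, rescue = rescue,
                  image_demo = image_demo)

  # -- write artifacts ----------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(results$config, file.path(out_dir, "config.yaml"))
    write.csv(table, file.path(out_dir, "feature_table.csv"),
              row.names = FALSE)
    write.csv(results$individual_means,
              file.path(out_dir, "individual_means.csv"),
              row.names = FALSE)
    for (ms in names(models))
      write_scoring_model(models[[ms]],
                          file.path(out_dir,
                                    paste0("model_", ms, ".json")))
    jsonlite::write_json(
      list(stats = stats,
           rescue = if (is.null(rescue)) NULL else
             as.data.frame(rescue)),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (!is.null(image_demo))
      write.csv(image_demo, file.path(out_dir, "image_demo_features.csv"),
                row.names = FALSE)
    log_stage("write", "artifacts in ", out_dir)
  }
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
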