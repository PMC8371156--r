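# Logistic scorer: ML identities, separation handling, aggregation.

# scoring model with all-zero coefficients over the combined set
null_model <- function(coding = c(control = 0, case = 1)) {
  cols <- feature_names()
  structure(list(
    coefficients = setNames(numeric(124), cols), intercept = 0,
    center = setNames(numeric(124), cols),
    scale = setNames(rep(1, 124), cols),
    constant = setNames(rep(FALSE, 124), cols),
    marker_set = "combined", coding = coding,
    n_train = c(n0 = 0, n1 = 0),
    training = data.frame(individual_id = character(0),
                          treatment = character(0)),
    separation_fallback = FALSE), class = "scoring_model")
}

test_that("fitted probabilities sum to the class-1 count (mass balance)", {
  cfg <- cohort_config(n_group0 = 3, n_group1 = 4,
                       cells_per_individual = 200, effect_size = 0.3,
                       affected_count = 10, individual_sd = 0, seed = 2)
  tab <- simulate_feature_table(cfg)
  m <- fit_cell_classifier(tab, c("control", "case"))
  expect_false(m$separation_fallback)  # identity tested on the ML fit
  p <- score_cells(m, tab)$cells$probability
  n1 <- sum(tab$group == "case")
  expect_equal(sum(p), n1, tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  # in-sample fit orders the class means
  expect_gt(mean(p[tab$group == "case"]), mean(p[tab$group == "control"]))
})

test_that("with no signal the class-1 mean probability tracks prevalence", {
  cfg <- cohort_config(n_group0 = 2, n_group1 = 3,
                       cells_per_individual = 500, effect_size = 0,
                       individual_sd = 0, seed = 4)
  tab <- simulate_feature_table(cfg)
  m <- fit_cell_classifier(tab, c("control", "case"), marker_set = "aat")
  p <- score_cells(m, tab)$cells$probability
  prev <- mean(tab$group == "case")
  expect_equal(mean(p[tab$group == "case"]), prev, tolerance = 0.05)
})

test_that("a perfectly separating feature triggers the ridge fallback", {
  cfg <- cohort_config(n_group0 = 2, n_group1 = 2,
                       cells_per_individual = 50, effect_size = 0,
                       seed = 5)
  tab <- simulate_feature_table(cfg)
  tab$nucleus.morph.area <- ifelse(tab$group == "case", 100, 1)
  expect_warning(
    m <- fit_cell_classifier(tab, c("control", "case"),
                             marker_set = "nucleus"),
    "quasi-separation")
  expect_true(m$separation_fallback)
  p <- score_cells(m, tab)$cells$probability
  expect_true(all(p[tab$group == "case"] > 0.95))
  expect_true(all(p[tab$group == "control"] < 0.05))
  # mass balance holds under the ridge fallback too
  expect_equal(sum(p), sum(tab$group == "case"), tolerance = 1e-6)
})

test_that("a planted single-feature shift gets a coefficient of the right sign", {
  cfg <- cohort_config(n_group0 = 3, n_group1 = 3,
                       cells_per_individual = 200, effect_size = 1,
                       affected_count = 1, individual_sd = 0.1, seed = 6)
  tab <- simulate_feature_table(cfg)
  aff_col <- feature_names()[affected_feature_indices(cfg)]
  m <- suppressWarnings(fit_cell_classifier(tab, c("control", "case"),
                                            marker_set = "nucleus"))
  expect_gt(m$coefficients[aff_col], 0)
  expect_equal(names(which.max(abs(m$coefficients))), aff_col)
})

test_that("zero-coefficient models score every cell at 0.5", {
  cfg <- small_cohort(seed = 8)
  tab <- simulate_feature_table(cfg)
  s <- score_cells(null_model(), tab)
  expect_true(all(s$cells$probability == 0.5))
  # identical cells get identical scores
  m <- suppressWarnings(fit_cell_classifier(tab, c("control", "case")))
  dup <- rbind(tab[1, ], tab[1, ])
  sd2 <- score_cells(m, dup)$cells$probability
  expect_identical(sd2[1], sd2[2])
})

test_that("scores are invariant to affine rescaling of a feature", {
  cfg <- small_cohort(seed = 9, effect_size = 0.5)
  tab <- simulate_feature_table(cfg)
  tab2 <- tab
  tab2$mito.intensity.mean <- 13 * tab2$mito.intensity.mean - 5
  m1 <- fit_cell_classifier(tab, c("control", "case"), "mito")
  m2 <- fit_cell_classifier(tab2, c("control", "case"), "mito")
  expect_equal(score_cells(m1, tab)$cells$probability,
               score_cells(m2, tab2)$cells$probability,
               tolerance = 1e-8)
})

test_that("individual means aggregate cell scores exactly", {
  cfg <- small_cohort(seed = 10)
  tab <- simulate_feature_table(cfg)
  m <- suppressWarnings(fit_cell_classifier(tab, c("control", "case")))
  s <- score_cells(m, tab)
  im <- aggregate_individual_means(s)
  expect_equal(nrow(im), 6)
  # hand-computed mean for one individual
  id <- im$individual_id[1]
  expect_equal(im$mean_probability[1],
               mean(s$cells$probability[s$cells$individual_id == id]))
  # grand mean = cell-count-weighted mean of individual means
  expect_equal(mean(s$cells$probability),
               sum(im$mean_probability * im$n_cells) / sum(im$n_cells))
})

test_that("probability histograms conserve counts and localize constants", {
  cfg <- small_cohort(seed = 12)
  tab <- simulate_feature_table(cfg)
  s <- score_cells(null_model(), tab)
  h <- probability_histogram(s, bins = 50)
  expect_equal(sum(h$counts), nrow(tab))
  expect_equal(sum(h$counts > 0), 2)  # one occupied bin per group
  expect_equal(unname(h$group_means), c(0.5, 0.5))
  # uniform scores fill bins roughly evenly
  s$cells$probability <- with_unif <- seq(0.001, 0.999,
                                          length.out = nrow(tab))
  h2 <- probability_histogram(s, bins = 10)
  expect_equal(rowSums(h2$counts)[["case"]], sum(tab$group == "case"))
  expect_lt(max(colSums(h2$counts)) / min(colSums(h2$counts)), 1.5)
})

test_that("degenerate inputs are rejected with clear errors", {
  cfg <- small_cohort(seed = 13)
  tab <- simulate_feature_table(cfg)
  expect_error(fit_cell_classifier(tab[tab$group == "case", ],
                                   c("control", "case")), "cells in each")
  bad <- tab; bad$nucleus.morph.area[1] <- NA
  expect_error(fit_cell_classifier(bad, c("control", "case")),
               "nucleus.morph.area")
  m <- suppressWarnings(fit_cell_classifier(tab, c("control", "case")))
  expect_error(score_cells(m, tab[, -5]), "missing columns")
})

test_that("scoring models survive a JSON round trip", {
  cfg <- small_cohort(seed = 14, effect_size = 0.4)
  tab <- simulate_feature_table(cfg)
  m <- fit_cell_classifier(tab, c("control", "case"), "cell")
  path <- file.path(tempdir(), "model.json")
  write_scoring_model(m, path)
  m2 <- read_scoring_model(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(score_cells(m2, tab)$cells$probability,
               score_cells(m, tab)$cells$probability)
  unlink(path)
})

test_that("grouped cross-validation scores cells out of fold", {
  cfg <- cohort_config(n_group0 = 4, n_group1 = 4,
                       cells_per_individual = 60, effect_size = 1.5,
                       affected_count = 40, seed = 15)
  tab <- simulate_feature_table(cfg)
  s <- score_cells_cv(tab, c("control", "case"), marker_set = "aat",
                      folds = 4)
  expect_false(anyNA(s$cells$probability))
  expect_equal(nrow(s$cells), nrow(tab))
  # strong signal survives honest scoring
  im <- aggregate_individual_means(s)
  auc <- roc_individuals(im$mean_probability, im$group,
                         positive = "case")$auc
  expect_gt(auc, 0.9)
})
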