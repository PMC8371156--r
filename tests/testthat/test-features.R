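# Feature engine: analytic shapes, brute-force oracles, invariances.

test_that("feature naming scheme is 31 per marker, 124 combined", {
  expect_length(marker_feature_names(), 31)
  expect_length(feature_names(), 124)
  expect_false(anyDuplicated(feature_names()) > 0)
  for (m in marker_names())
    expect_length(feature_names(m), 31)
  expect_identical(marker_set_columns("combined"), feature_names())
  expect_identical(marker_set_columns("mito"), feature_names("mito"))
})

test_that("uniform disc matches analytic values", {
  R <- 20
  reg <- uniform_region(disc_mask(R))
  bm <- basic_morphology(reg)
  expect_equal(unname(bm["area"]), pi * R^2, tolerance = 0.02)
  expect_equal(unname(bm["length"] / bm["width"]), 1, tolerance = 0.02)
  expect_gt(bm["roundness"], 0.95)
  expect_lte(bm["roundness"], 1)

  st <- star_features(reg)
  # intensity-weighted mean radius of a uniform disc is 2R/3
  expect_equal(unname(st["radial.mean"]), 2 * R / 3, tolerance = 0.05)
  # relative radial deviation: sqrt(R^2/2 - (2R/3)^2) / (2R/3) = sqrt(1/8)
  expect_equal(unname(st["radial.reldev"]), sqrt(1 / 8), tolerance = 0.05)
  for (q in c("10", "20", "30", "40"))
    expect_equal(unname(st[paste0("compactness.q", q)]), 1,
                 tolerance = 0.05)
  expect_true(all(st[grep("^symmetry", names(st))] < 0.05))
  expect_equal(unname(st["axial.ratio"]), 1, tolerance = 0.05)
  expect_equal(unname(st["axial.length"]), 2 * R, tolerance = 0.05)
})

test_that("2:1 ellipse recovers axis ratio from extents and covariance", {
  reg <- uniform_region(ellipse_mask(20, 10, phi = 0.4))
  bm <- basic_morphology(reg)
  expect_equal(unname(bm["length"] / bm["width"]), 2, tolerance = 0.05)
  st <- star_features(reg)
  expect_equal(unname(st["axial.ratio"]), 0.5, tolerance = 0.05)
  expect_equal(unname(st["axial.length"]), 40, tolerance = 0.05)
})

test_that("square roundness approaches 4*pi*A/P^2 = pi/4", {
  reg <- uniform_region(square_mask(41))
  expect_equal(unname(basic_morphology(reg)["roundness"]), pi / 4,
               tolerance = 0.05)
})

test_that("intensity features match constants and brute-force sums", {
  msk <- disc_mask(6)
  reg <- uniform_region(msk, value = 7)
  iv <- intensity_features(reg)
  expect_equal(unname(iv), c(7, 0, 7, 7, 7 * sum(msk)))

  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  r1 <- cell_region(one, matrix(3, 5, 5))
  expect_equal(unname(intensity_features(r1)), c(3, 0, 3, 3, 3))

  reg <- random_blob_region(42)
  expect_equal(intensity_features(reg), brute_intensity(reg),
               tolerance = 1e-12)
})

test_that("intensity-weighted features equal brute-force summation", {
  for (seed in c(11, 12, 13)) {
    reg <- random_blob_region(seed)
    st <- star_features(reg)
    br <- brute_star_sums(reg)
    expect_equal(unname(st[grep("^symmetry", names(st))]), br$symmetry,
                 tolerance = 1e-9)
    expect_equal(unname(st["radial.mean"]), br$radial_mean,
                 tolerance = 1e-9)
    expect_equal(unname(st["radial.reldev"]), br$radial_reldev,
                 tolerance = 1e-9)
  }
})

test_that("two antipodal bright spots give 2-fold but not 3-fold symmetry", {
  size <- 41
  msk <- disc_mask(15, size)
  ch <- matrix(0, size, size)
  ch[21, 9] <- 5
  ch[21, 33] <- 5
  ch[msk & ch == 0] <- 1e-9   # keep total intensity dominated by spots
  st <- star_features(cell_region(msk, ch))
  expect_gt(st["symmetry.s02"], 0.99)
  expect_lt(st["symmetry.s03"], 0.01)
  expect_gt(st["symmetry.s04"], 0.99)
})

test_that("texture filters discriminate granules from filaments", {
  size <- 41
  msk <- disc_mask(15, size)
  flat <- ser_texture(cell_region(msk, matrix(1, size, size)))
  expect_true(all(abs(flat) < 1e-10))

  spot_img <- outer(1:size, 1:size, function(i, j)
    exp(-((i - 21)^2 + (j - 21)^2) / 8)) + 0.05
  line_img <- outer(1:size, 1:size, function(i, j)
    exp(-((j - 21)^2) / 4)) + 0.05
  s_spot <- ser_texture(cell_region(msk, spot_img))
  s_line <- ser_texture(cell_region(msk, line_img))
  expect_gt(s_spot["spot"], 1.5 * s_spot["valley"])
  expect_gt(s_line["valley"], 100 * s_line["spot"])
  expect_gt(s_line["edge"], s_line["spot"])
})

test_that("texture smoothing agrees with brute-force convolution", {
  set.seed(5)
  img <- matrix(runif(31^2), 31)
  sm_pkg <- EBImage::imageData(EBImage::gblur(img, 1))
  sm_brute <- brute_gauss_smooth(img, 1)
  interior <- 9:23
  expect_equal(sm_pkg[interior, interior], sm_brute[interior, interior],
               tolerance = 1e-4)
})

test_that("features are translation invariant and behave under gain", {
  reg <- random_blob_region(7, size = 61)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  reg2 <- cell_region(shift(reg$mask, 5, 9) > 0,
                      shift(reg$channel, 5, 9))
  f1 <- marker_features(reg)
  f2 <- marker_features(reg2)
  expect_equal(f1, f2, tolerance = 1e-8)

  # gain: intensity scales linearly, shape/distribution invariant
  reg3 <- cell_region(reg$mask, reg$channel * 3.7)
  f3 <- marker_features(reg3)
  int <- grep("^intensity", names(f1))
  expect_equal(unname(f3[int]), unname(f1[int] * 3.7), tolerance = 1e-9)
  inv <- grep("^(morph|symmetry|compactness|axial|radial|profile)",
              names(f1))
  expect_equal(f3[inv], f1[inv], tolerance = 1e-9)
})

test_that("morphology and symmetry are invariant to 90-degree rotation", {
  reg <- random_blob_region(9)
  reg_rot <- cell_region(t(reg$mask)[ncol(reg$mask):1, ],
                         t(reg$channel)[ncol(reg$channel):1, ])
  f1 <- marker_features(reg)
  f2 <- marker_features(reg_rot)
  keep <- grep("^(morph|symmetry|compactness|axial|radial)", names(f1))
  expect_equal(f1[keep], f2[keep], tolerance = 1e-6)
})

test_that("degenerate and invalid regions are handled as specified", {
  # 1-px-wide line: width 1, roundness still computed
  ln <- matrix(FALSE, 20, 20); ln[5:15, 10] <- TRUE
  bm <- basic_morphology(cell_region(ln, matrix(1, 20, 20)))
  expect_equal(unname(bm["width"]), 1)
  expect_true(bm["roundness"] > 0 && bm["roundness"] <= 1)
  # zero intensity names the region
  msk <- disc_mask(5)
  dark <- cell_region(msk, matrix(0, nrow(msk), ncol(msk)),
                      id = "mito/cell 3")
  expect_error(star_features(dark), "mito/cell 3")
  # too-small masks
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_error(basic_morphology(cell_region(one, matrix(1, 5, 5))),
               "4 pixels")
  expect_error(cell_region(matrix(FALSE, 4, 4), matrix(1, 4, 4)),
               "empty")
  expect_error(cell_region(msk, matrix(-1, nrow(msk), ncol(msk))),
               "finite")
})

test_that("extraction yields one 124-feature row per segmented cell", {
  field <- render_field(scene_spec(n_cells = 6, image_size = 220,
                                   seed = 21))
  gt_n <- label_mask(field$ground_truth$nucleus_labels)
  gt_c <- label_mask(field$ground_truth$cell_labels)
  tab <- extract_cell_features(field, gt_n, gt_c,
                               metadata = list(individual_id = "x",
                                               group = "g"))
  expect_equal(nrow(tab), 6)
  expect_true(all(feature_names() %in% names(tab)))
  expect_true(all(is.finite(as.matrix(tab[, feature_names()]))))
  expect_identical(tab$individual_id, rep("x", 6))
  # feature-value accounting identities
  expect_equal(feature_value_count(nrow(tab)), 6 * 124)
})
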