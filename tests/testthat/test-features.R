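test_that("a constant disk segments to one mask with the expected geometry", {
  d <- make_disk_field(n = 128, r = 20, h = 3000)
  cm <- segment_cells(d$height, min_area = 50)
  expect_equal(nrow(cm$info), 1)
  expect_equal(cm$info$area_px * 0.18^2, pi * 20^2 * 0.18^2,
               tolerance = 0.05)
  f <- extract_features(d$height, cm$labels, 1L, pixel_pitch = 0.18)
  expect_lt(f$eccentricity, 0.05)
  expect_gt(f$circularity, 0.95)
  expect_equal(f$mean_height_nm, 3000)
  expect_equal(f$max_height_nm, 3000)
  expect_equal(f$sd_height_nm, 0)
  expect_equal(f$height_skewness, 0)
  expect_equal(f$height_kurtosis, 0)
  expect_equal(f$entropy_bits, 0)
  # single quantization level
  expect_equal(f$glcm_energy, 1)
  expect_equal(f$glcm_contrast, 0)
  expect_false(f$border)
})

test_that("an all-background field yields no masks, not an error", {
  cm <- segment_cells(matrix(0, 64, 64))
  expect_equal(nrow(cm$info), 0)
  expect_true(all(cm$labels == 0))
})

test_that("well-separated disks give disjoint masks", {
  a <- make_disk_field(n = 192, r = 18, h = 2000, center = c(50, 50))
  b <- make_disk_field(n = 192, r = 18, h = 2500, center = c(140, 140))
  cm <- segment_cells(a$height + b$height)
  expect_equal(nrow(cm$info), 2)
  px1 <- which(cm$labels == 1); px2 <- which(cm$labels == 2)
  expect_length(intersect(px1, px2), 0)
  expect_gt(length(px1), 0)
  expect_gt(length(px2), 0)
})

test_that("ellipse eccentricity matches the closed form", {
  e <- make_ellipse_field(n = 192, a = 40, b = 20, h = 2000)
  f <- extract_features(e$height, e$labels, 1L, pixel_pitch = 0.18)
  expect_equal(f$eccentricity, sqrt(1 - 1 / 4), tolerance = 0.02)
  expect_equal(f$aspect_ratio, 2, tolerance = 0.04)
})

test_that("shape features are translation- and 90-degree-rotation invariant", {
  lp <- line_profile("E", 1, blend_m = 1)
  cfg <- sim_config(list(lp), seed = 1)
  set.seed(21)
  cell <- generate_cell_phantom(lp, cfg)
  h <- phase_to_height(cell$phase, cfg$wavelength, cfg$delta_n)
  lab <- ifelse(cell$mask, 1L, 0L)
  pad <- function(m, r0, c0, n = 420) {
    out <- matrix(0, n, n)
    out[r0 + seq_len(nrow(m)) - 1, c0 + seq_len(ncol(m)) - 1] <- m
    out
  }
  shape <- c("area_um2", "perimeter_um", "circularity", "eccentricity",
             "solidity", "aspect_ratio")
  f1 <- extract_features(pad(h, 10, 10), pad(lab, 10, 10), 1L, 0.18)
  f2 <- extract_features(pad(h, 90, 55), pad(lab, 90, 55), 1L, 0.18)
  f3 <- extract_features(pad(t(h[nrow(h):1, ]), 10, 10),
                         pad(t(lab[nrow(lab):1, ]), 10, 10), 1L, 0.18)
  for (s in shape) {
    expect_equal(f2[[s]], f1[[s]], tolerance = 1e-10)
    expect_equal(f3[[s]], f1[[s]], tolerance = 0.02)
  }
})

test_that("feature tables carry one row per cell with stable schema", {
  empty <- build_feature_table(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(em_feature_names() %in% names(empty)))

  lp <- list(line_profile("E", 5, blend_m = 0), line_profile("M", 5, blend_m = 1))
  cfg <- sim_config(lp, cells_per_field = 5, seed = 31)
  sim <- simulate_dataset(cfg)
  tab <- build_feature_table(sim$fields)
  expect_equal(nrow(tab), 10)
  expect_equal(unname(table(tab$line)[c("E", "M")]), c(5L, 5L),
               ignore_attr = TRUE)
  expect_false(anyNA(tab[, em_feature_names()]))

  # order invariance after row sort
  tab2 <- build_feature_table(rev(sim$fields))
  expect_equal(tab2[order(tab2$cell_id), ], tab[order(tab$cell_id), ],
               ignore_attr = TRUE)

  # duplicate field ids rejected
  expect_error(build_feature_table(list(sim$fields[[1]], sim$fields[[1]])),
               "duplicate field ids")
})

test_that("synthetic populations show the expected archetype contrasts", {
  tab <- small_archetypes()
  e <- tab[tab$blend == 0, ]; m <- tab[tab$blend == 1, ]
  expect_gt(mean(m$eccentricity), mean(e$eccentricity))
  expect_gt(mean(e$max_height_nm), mean(m$max_height_nm))
  expect_gt(mean(m$area_um2), mean(e$area_um2))
  # bounded feature invariants
  expect_true(all(tab$eccentricity >= 0 & tab$eccentricity < 1))
  expect_true(all(tab$circularity > 0 & tab$circularity <= 1))
  expect_true(all(tab$glcm_energy > 0 & tab$glcm_energy <= 1))
  expect_true(all(tab$solidity > 0 & tab$solidity <= 1))
})
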