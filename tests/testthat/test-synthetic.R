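test_that("default populations reproduce the study counts", {
  profs <- default_line_profiles()
  n <- vapply(profs, `[[`, integer(1), "n_cells")
  expect_equal(unname(n), c(332, 309, 307, 347))
  expect_equal(sum(n), 1295)
})

test_that("profile validation rejects out-of-range parameters", {
  expect_error(line_profile("x", -1), "non-negative")
  expect_error(line_profile("x", 5, blend_m = 1.5), "\\[0, 1\\]")
  expect_error(line_profile("x", 5, blend_beta = c(2, -1)), "positive")
  expect_error(line_profile("x", 5, area_dist = c(5, 0)), "sdlog > 0")
  expect_error(line_profile("x", 5, clustering_rate = 2), "\\[0, 1\\]")
  expect_error(sim_config(field_size = 32), "field_size")
})

test_that("degenerate eccentricity gives a disk-like phantom", {
  prof <- line_profile("disk", 1, blend_m = 0,
                       eccentricity_dist = c(0, Inf),
                       area_dist = c(log(150), 1e-6))
  cfg <- sim_config(list(prof), seed = 1)
  set.seed(5)
  cell <- generate_cell_phantom(prof, cfg)
  expect_lt(mask_ecc_oracle(cell$mask), 0.15)
  expect_true(all(cell$phase[!cell$mask] == 0))
  expect_true(all(cell$phase[cell$mask] >= 0))
})

test_that("archetype morphology is monotone in the blend fraction", {
  e_prof <- line_profile("E", 1, blend_m = 0)
  m_prof <- line_profile("M", 1, blend_m = 1)
  set.seed(11)
  de <- replicate(200, unlist(
    emscore:::draw_cell_params(e_prof)[c("eccentricity", "area_um2",
                                         "peak_height_nm")]))
  dm <- replicate(200, unlist(
    emscore:::draw_cell_params(m_prof)[c("eccentricity", "area_um2",
                                         "peak_height_nm")]))
  expect_gt(mean(dm["eccentricity", ]), mean(de["eccentricity", ]))
  expect_gt(mean(dm["area_um2", ]), mean(de["area_um2", ]))
  expect_lt(mean(dm["peak_height_nm", ]), mean(de["peak_height_nm", ]))

  # and on rendered phantoms, not just the drawn parameters
  cfg <- sim_config(list(e_prof, m_prof), seed = 1)
  set.seed(12)
  ecc_e <- replicate(25, mask_ecc_oracle(generate_cell_phantom(e_prof, cfg)$mask))
  ecc_m <- replicate(25, mask_ecc_oracle(generate_cell_phantom(m_prof, cfg)$mask))
  expect_gt(mean(ecc_m), mean(ecc_e))
})

test_that("texture granularity zero produces a smooth interior", {
  smooth_prof <- line_profile("s", 1, blend_m = 0, texture_granularity = 0)
  rough_prof <- line_profile("r", 1, blend_m = 0, texture_granularity = 0.3)
  cfg <- sim_config(list(smooth_prof, rough_prof), seed = 1)
  set.seed(3)
  feats <- lapply(list(smooth_prof, rough_prof), function(p) {
    cell <- generate_cell_phantom(p, cfg)
    h <- phase_to_height(cell$phase, cfg$wavelength, cfg$delta_n)
    extract_features(h, ifelse(cell$mask, 1L, 0L), 1L, cfg$pixel_pitch)
  })
  expect_gt(feats[[1]]$glcm_energy, 0.3)
  expect_gt(feats[[1]]$glcm_energy, 3 * feats[[2]]$glcm_energy)
  expect_lt(feats[[1]]$entropy_bits, feats[[2]]$entropy_bits)
})

test_that("field generation is deterministic and respects n_cells", {
  lp <- line_profile("E", 6, blend_m = 0)
  cfg <- sim_config(list(lp), field_size = 1024, cells_per_field = 6, seed = 42)
  f1 <- generate_field(cfg, "E")
  f2 <- generate_field(cfg, "E")
  expect_identical(f1$phase, f2$phase)
  expect_identical(f1$labels, f2$labels)
  expect_equal(nrow(f1$truth), 6)
  expect_setequal(unique(f1$labels[f1$labels > 0]), 1:6)
  expect_error(generate_field(cfg, "nope"), "not present")
})

test_that("an empty line yields an empty field", {
  lp <- line_profile("E", 0, blend_m = 0)
  cfg <- sim_config(list(lp), field_size = 256, seed = 1)
  f <- generate_field(cfg, "E")
  expect_true(all(f$phase == 0))
  expect_equal(nrow(f$truth), 0)
})

test_that("non-clustered placement keeps masks pairwise disjoint", {
  lp <- line_profile("E", 5, blend_m = 0, clustering_rate = 0)
  cfg <- sim_config(list(lp), field_size = 1024, cells_per_field = 5, seed = 8)
  f <- generate_field(cfg, "E")
  # no cell lost pixels to another: every placed mask kept its full area
  expect_equal(tabulate(f$labels[f$labels > 0], 5), f$truth$area_px)
  expect_equal(sort(unique(as.vector(f$labels))), 0:5)
})

test_that("hologram forward model produces two-beam fringes", {
  ph <- matrix(0, 128, 128)
  h <- render_hologram(ph, carrier = c(0.25, 0), noise_sd = 0)
  expect_true(all(h$intensity >= 0))
  # spectrum: DC and the +/- carrier peaks only (rows 33 and 97 = bins +/-32)
  P <- Mod(stats::fft(h$intensity))^2
  big <- which(P > 1e-6 * max(P))
  expect_equal(sort(big), c(1, 33, 97))
  # determinism with zero noise and fixed seed
  h2 <- render_hologram(ph, carrier = c(0.25, 0), noise_sd = 0)
  expect_identical(h$intensity, h2$intensity)
  hn1 <- render_hologram(ph, carrier = c(0.25, 0), noise_sd = 0.01, seed = 4)
  hn2 <- render_hologram(ph, carrier = c(0.25, 0), noise_sd = 0.01, seed = 4)
  expect_identical(hn1$intensity, hn2$intensity)
  expect_error(render_hologram(ph, noise_sd = -1), "noise_sd")
})
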