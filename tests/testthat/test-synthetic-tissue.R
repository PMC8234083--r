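test_that("layouts are deterministic given config and seed", {
  cfg <- phantom_config(n_follicles = 2, n_bcells_per_follicle = 30,
                        n_neutrophils = 5, n_other_cells = 20,
                        field_width_um = 400, field_height_um = 400, seed = 11)
  a <- generate_layout(cfg)
  b <- generate_layout(cfg)
  expect_identical(a$truth_cells, b$truth_cells)
  expect_identical(a$follicle_polygons, b$follicle_polygons)
  cfg2 <- phantom_config(n_follicles = 2, n_bcells_per_follicle = 30,
                         n_neutrophils = 5, n_other_cells = 20,
                         field_width_um = 400, field_height_um = 400,
                         seed = 12)
  expect_false(identical(generate_layout(cfg2)$truth_cells, a$truth_cells))
})

test_that("layout respects counts, bounds and hard-core spacing", {
  cfg <- phantom_config(n_follicles = 2, n_bcells_per_follicle = 50,
                        n_neutrophils = 10, n_other_cells = 30,
                        field_width_um = 500, field_height_um = 400, seed = 3)
  ph <- generate_layout(cfg)
  tc <- ph$truth_cells
  expect_equal(as.integer(table(tc$class)[c("Bcell", "neutrophil", "other")]),
               c(100L, 10L, 30L))
  expect_true(all(tc$x_um >= 0 & tc$x_um <= 500))
  expect_true(all(tc$y_um >= 0 & tc$y_um <= 400))
  dmat <- as.matrix(dist(tc[, c("x_um", "y_um")]))
  diag(dmat) <- Inf
  expect_gte(min(dmat), cfg$min_center_spacing_um)
  expect_length(ph$follicle_polygons, 2L)
})

test_that("near/far marker intensity ratio recovers the configured amplitude", {
  # brute-force nearest-neighbour distances, independent of the emitted column
  cfg <- phantom_config(n_follicles = 2, n_bcells_per_follicle = 50,
                        n_neutrophils = 10, field_width_um = 500,
                        field_height_um = 500, effect_amplitude = 2,
                        neutrophil_follicle_fraction = 1, seed = 23)
  tc <- generate_layout(cfg)$truth_cells
  b <- tc[tc$class == "Bcell", ]
  nn <- tc[tc$class == "neutrophil", ]
  d <- oracle_nearest(b$x_um, b$y_um, nn$x_um, nn$y_um)
  expect_equal(d, b$dist_nearest_neutrophil_um, tolerance = 1e-12)
  near <- d <= cfg$effect_radius_um
  expect_gte(sum(near), 5)  # the fixed seed populates the near group
  ratio <- mean(b$intensity_marker[near]) / mean(b$intensity_marker[!near])
  expect_equal(ratio, 2, tolerance = 0.25)
})

test_that("no-effect and no-neutrophil regimes use the far branch everywhere", {
  cfg1 <- phantom_config(effect_amplitude = 1, n_follicles = 2,
                         n_bcells_per_follicle = 60, n_neutrophils = 8,
                         field_width_um = 500, field_height_um = 500,
                         seed = 21)
  tc <- generate_layout(cfg1)$truth_cells
  b <- tc[tc$class == "Bcell", ]
  near <- b$dist_nearest_neutrophil_um <= cfg1$effect_radius_um
  # amplitude 1: near and far intensities come from the same distribution
  expect_gt(wilcox.test(b$intensity_marker[near],
                        b$intensity_marker[!near])$p.value, 0.001)

  cfg0 <- phantom_config(n_neutrophils = 0, n_follicles = 2,
                         n_bcells_per_follicle = 40, field_width_um = 400,
                         field_height_um = 400, seed = 5)
  tc0 <- generate_layout(cfg0)$truth_cells
  expect_true(all(is.na(tc0$dist_nearest_neutrophil_um)))
  b0 <- tc0[tc0$class == "Bcell", ]
  expect_equal(mean(b0$intensity_marker),
               cfg0$base_intensities[["marker"]], tolerance = 0.1)
})

test_that("overcrowded configurations fail with a density error", {
  cfg <- suppressWarnings(
    phantom_config(n_follicles = 1, n_bcells_per_follicle = 2000,
                   follicle_radius_um = 30, field_width_um = 200,
                   field_height_um = 200, seed = 1))
  expect_error(generate_layout(cfg), "density")
})

test_that("rendering paints discs at true intensities and conserves nuclei", {
  cfg <- phantom_config(field_width_um = 220, field_height_um = 220,
                        n_follicles = 1, n_bcells_per_follicle = 20,
                        n_neutrophils = 4, n_other_cells = 10,
                        background_amplitude = 0, background_offset = 0,
                        noise_sd = 0, seed = 9)
  ph <- render_image(generate_layout(cfg))
  tc <- ph$truth_cells
  expect_equal(dim(ph$image$DAPI), c(220L, 220L))
  # pixel value at each centroid equals the cell's true intensity
  for (i in seq_len(nrow(tc))) {
    r <- round(tc$y_um[i]) + 1L
    c <- round(tc$x_um[i]) + 1L
    expect_equal(ph$image$DAPI[r, c], tc$intensity_DAPI[i])
  }
  # nucleus conservation: connected components of the DAPI support
  lab <- EBImage::bwlabel(EBImage::Image(ph$image$DAPI > 0))
  expect_equal(max(lab), nrow(tc))
})

test_that("rendered channel content matches a direct rasterization oracle", {
  cfg <- phantom_config(field_width_um = 150, field_height_um = 150,
                        n_follicles = 1, n_bcells_per_follicle = 12,
                        n_neutrophils = 3, n_other_cells = 5,
                        background_amplitude = 0, background_offset = 0,
                        noise_sd = 0, seed = 13)
  ph <- render_image(generate_layout(cfg))
  tc <- ph$truth_cells
  r_px <- cfg$nucleus_radius_um / cfg$pixel_size_um
  oracle <- matrix(0, 150, 150)
  for (rr in 1:150) for (cc in 1:150) {
    x <- cc - 1; y <- rr - 1
    d2 <- (x - tc$x_um)^2 + (y - tc$y_um)^2
    hit <- d2 <= r_px^2
    if (any(hit)) oracle[rr, cc] <- max(tc$intensity_DAPI[hit])
  }
  expect_equal(ph$image$DAPI, oracle)
})

test_that("rendering refuses unresolvable pixel sizes and empty fields work", {
  cfg <- phantom_config(pixel_size_um = 3, nucleus_radius_um = 3, seed = 1)
  expect_error(render_image(generate_layout(cfg)), "unresolvable")
  cfg0 <- phantom_config(field_width_um = 100, field_height_um = 100,
                         n_follicles = 0, n_bcells_per_follicle = 0,
                         n_neutrophils = 0, n_other_cells = 0,
                         noise_sd = 0, background_amplitude = 0,
                         background_offset = 2, seed = 1)
  ph0 <- render_image(generate_layout(cfg0))
  expect_true(all(ph0$image$DAPI == 2))  # background field alone
})

test_that("cohorts are deterministic, censored and capped as configured", {
  cc <- cohort_config(n_per_arm = 30, seed = 4)
  a <- generate_cohort(cc)
  expect_identical(a, generate_cohort(cc))
  expect_equal(nrow(a), 60L)
  expect_true(all(a$time_days <= 1862))
  expect_true(all(a$event[a$time_days == 1862] == 0))
  # censor at 0: everything censored at time 0
  z <- generate_cohort(cohort_config(n_per_arm = 10, censor_time_days = 0,
                                     seed = 2))
  expect_true(all(z$time_days == 0) && all(z$event == 0))
})

test_that("uncapped exponential arm medians match the closed form", {
  cc <- cohort_config(n_per_arm = 400, hazard_high = 1 / 1500,
                      hazard_low = 3 / 1500, censor_time_days = 1e7,
                      cap_days = 1e7, seed = 6)
  coh <- generate_cohort(cc)
  expect_equal(median(coh$time_days[coh$group == "low"]),
               log(2) * 1500 / 3, tolerance = 0.15)
  expect_equal(median(coh$time_days[coh$group == "high"]),
               log(2) * 1500, tolerance = 0.15)
})
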