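geom300 <- list(width_um = 300, height_um = 300, pixel_size_um = 1)

test_that("bins follow the (lo, hi] convention with zero in the first bin", {
  b <- radial_bins()
  expect_equal(b$lo_um, c(0, 10, 30, 50, 100))
  expect_equal(b$hi_um, c(10, 30, 50, 100, Inf))
  expect_error(radial_bins(c(30, 10)), "increasing")
  tab <- data.frame(x_um = c(5, 0, 10, 10.001), y_um = c(0, 0, 0, 0),
                    mean_marker = 1, is_CD19pos = TRUE, is_CD66bpos = FALSE)
  refs <- data.frame(x_um = 0, y_um = 0)
  d <- nearest_reference_distance(tab, refs)
  expect_equal(d, c(5, 0, 10, 10.001))
  p <- compute_profile(rbind(tab,
                             data.frame(x_um = 0, y_um = 0, mean_marker = 0,
                                        is_CD19pos = FALSE,
                                        is_CD66bpos = TRUE)),
                       radial_bins(), geom300)
  # 5, 0 and 10 in bin 1 (boundary inclusive); 10.001 in bin 2
  expect_equal(p$n[1:2], c(3L, 1L))
})

test_that("nearest distances equal the all-pairs brute force exactly", {
  set.seed(10)
  tab <- toy_cell_table(n_b = 180, n_n = 20, seed = 10)
  targ <- tab[tab$is_CD19pos, ]
  refs <- tab[tab$is_CD66bpos, ]
  d <- nearest_reference_distance(targ, refs)
  expect_identical(d, oracle_nearest(targ$x_um, targ$y_um,
                                     refs$x_um, refs$y_um))
})

test_that("images without reference cells are excluded with a reason", {
  tab <- toy_cell_table(n_b = 20, n_n = 0)
  expect_error(nearest_reference_distance(tab[tab$is_CD19pos, ],
                                          tab[tab$is_CD66bpos, ]),
               "undefined")
  res <- profile_images(list(img = tab), radial_bins(), geom300)
  expect_length(res$profiles, 0L)
  expect_match(res$excluded[["img"]], "CD66b")
})

test_that("bin counts conserve the CD19+ total and empty bins stay NA", {
  tab <- toy_cell_table(n_b = 120, n_n = 6, seed = 4)
  p <- compute_profile(tab, radial_bins(), geom300)
  expect_equal(sum(p$n), sum(tab$is_CD19pos))
  expect_true(all(is.na(p$mean_intensity[p$n == 0])))
  expect_true(all(p$density[p$n > 0] >= 0))
  # bin areas partition the field
  expect_equal(sum(p$area_mm2), 300 * 300 / 1e6, tolerance = 1e-9)
})

test_that("a single all-encompassing bin normalizes to exactly one", {
  tab <- toy_cell_table(n_b = 80, n_n = 5, seed = 6)
  p <- normalize_profile(compute_profile(tab, radial_bins(numeric(0)),
                                         geom300))
  expect_equal(nrow(p), 1L)
  expect_equal(p$normalized_intensity, 1)
  expect_equal(p$normalized_density, 1)
})

test_that("normalization is scale invariant and flags zero denominators", {
  tab <- toy_cell_table(n_b = 100, n_n = 5, seed = 2)
  p1 <- normalize_profile(compute_profile(tab, radial_bins(), geom300))
  tab2 <- tab
  tab2$mean_marker <- tab2$mean_marker * 2
  p2 <- normalize_profile(compute_profile(tab2, radial_bins(), geom300))
  expect_equal(p1$normalized_intensity, p2$normalized_intensity,
               tolerance = 1e-12)
  tab0 <- tab
  tab0$mean_marker <- 0
  expect_error(normalize_profile(compute_profile(tab0, radial_bins(),
                                                 geom300)), "zero")
})

test_that("cells far from all references populate only the last bin", {
  tab <- data.frame(x_um = c(250, 280, 5), y_um = c(250, 280, 5),
                    mean_marker = c(1, 1, 0),
                    is_CD19pos = c(TRUE, TRUE, FALSE),
                    is_CD66bpos = c(FALSE, FALSE, TRUE))
  p <- compute_profile(tab, radial_bins(), geom300)
  expect_equal(p$n, c(0L, 0L, 0L, 0L, 2L))
})

test_that("proximity effect in the phantom is recovered from truth tables", {
  cfg <- phantom_config(effect_amplitude = 1.5, seed = 31)
  tab <- truth_cell_table(generate_layout(cfg))
  p <- normalize_profile(compute_profile(
    tab, radial_bins(), list(width_um = 800, height_um = 800,
                             pixel_size_um = 1)))
  expect_equal(p$mean_intensity[1] / p$mean_intensity[5], 1.5,
               tolerance = 0.2)
})

test_that("pooled comparison detects the effect and respects permutation", {
  geom <- list(width_um = 800, height_um = 800, pixel_size_um = 2)
  mk <- function(amp, n = 12, seed0 = 50) {
    tabs <- lapply(seq_len(n), function(i)
      truth_cell_table(generate_layout(
        phantom_config(effect_amplitude = amp, seed = seed0 + i))))
    names(tabs) <- paste0("img", seq_len(n))
    profile_images(tabs, radial_bins(), geom)$profiles
  }
  profs <- mk(1.5)
  cmp <- pool_and_compare(profs)
  expect_s3_class(cmp, "bin_comparison")
  expect_lt(cmp$kruskal$p.value, 0.05)
  pw15 <- cmp$pairwise[cmp$pairwise$bin_a == 1 & cmp$pairwise$bin_b == 5, ]
  expect_lt(pw15$p_adjusted, 0.05)
  expect_equal(cmp$m_comparisons, nrow(cmp$pairwise))
  # permuting the image order leaves the pooled result unchanged
  cmp_perm <- pool_and_compare(rev(profs))
  expect_equal(cmp$kruskal$p.value, cmp_perm$kruskal$p.value)
  expect_equal(sort(cmp$pairwise$p), sort(cmp_perm$pairwise$p))
  expect_error(pool_and_compare(profs[1]), ">= 2")
})

test_that("flat identical profiles show no detectable difference", {
  flat <- data.frame(image_id = "x", bin = 1:5, lo_um = c(0, 10, 30, 50, 100),
                     hi_um = c(10, 30, 50, 100, Inf),
                     normalized_intensity = 1)
  profs <- list(a = flat, b = flat, c = flat, d = flat)
  cmp <- pool_and_compare(profs)
  expect_equal(cmp$kruskal$statistic, 0)
  expect_equal(cmp$kruskal$p.value, 1)
  expect_true(all(cmp$pairwise$p_adjusted == 1))
})
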