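# build a cell table with specified log-ratio populations for one marker
ratio_table <- function(log_ratios, marker = "CD19", other = "CD66b") {
  n <- length(log_ratios)
  tab <- data.frame(image_id = "cal", cell_id = seq_len(n),
                    x_um = seq_len(n), y_um = seq_len(n))
  tab[[paste0("mean_", marker)]] <- exp(log_ratios) * 2
  tab[[paste0("bg_", marker)]] <- 2
  tab[[paste0("mean_", other)]] <- abs(rnorm(n, 1, 0.2))
  tab[[paste0("bg_", other)]] <- 2
  tab
}

test_that("calibration puts the cutoff strictly between bimodal modes", {
  set.seed(1)
  lr <- c(rnorm(200, 0, 0.2), rnorm(200, 1.5, 0.2))
  tab <- ratio_table(lr)
  for (pol in c("gmm", "otsu")) {
    thr <- calibrate_thresholds(tab, policy = pol,
                                fixed_cutoffs = NULL)
    cut_log <- log(thr$cutoffs[["CD19"]])
    expect_gt(cut_log, 0.3)
    expect_lt(cut_log, 1.2)
  }
})

test_that("calibration handles rare positive populations", {
  # 2% positives: the regime of sparse neutrophils
  set.seed(2)
  neg <- rnorm(490, -0.5, 0.3)
  pos <- rnorm(10, 2, 0.3)
  thr <- calibrate_thresholds(ratio_table(c(neg, pos), marker = "CD66b",
                                          other = "CD19"))
  cut_log <- log(thr$cutoffs[["CD66b"]])
  # the cut separates the populations: all positives kept, <= 2% leakage
  expect_true(all(pos > cut_log))
  expect_lte(mean(neg >= cut_log), 0.02)
})

test_that("fixed policy returns cutoffs unchanged; degenerate input errors", {
  thr <- calibrate_thresholds(NULL, policy = "fixed",
                              fixed_cutoffs = c(CD19 = 2, CD66b = 3.5))
  expect_equal(unname(thr$cutoffs), c(2, 3.5))
  tab <- ratio_table(rep(0.7, 50))
  expect_error(calibrate_thresholds(tab), "degenerate|failed")
})

test_that("pooled calibration of identical images equals single-image calibration", {
  set.seed(3)
  lr <- c(rnorm(100, 0, 0.2), rnorm(100, 1.5, 0.2))
  tab <- ratio_table(lr)
  single <- calibrate_thresholds(tab)
  pooled <- calibrate_thresholds(list(tab, tab, tab))
  expect_equal(single$cutoffs, pooled$cutoffs, tolerance = 1e-8)
})

test_that("classification applies ratio cutoffs and the epsilon floor", {
  tab <- data.frame(image_id = "t", cell_id = 1:3,
                    x_um = 1:3, y_um = 1:3,
                    mean_CD19 = c(10, 1, 5), bg_CD19 = c(2, 2, 0),
                    mean_CD66b = c(0.1, 0.1, 0.1), bg_CD66b = c(2, 2, 2))
  thr <- calibrate_thresholds(NULL, policy = "fixed",
                              fixed_cutoffs = c(CD19 = 2, CD66b = 2))
  cl <- classify_cells(tab, thr)
  expect_equal(cl$ratio_CD19[1], 5)
  expect_true(cl$is_CD19pos[1])
  expect_false(cl$is_CD19pos[2])
  # zero background hits the epsilon floor -> enormous ratio, still positive
  expect_equal(cl$ratio_CD19[3], 5 / thr$epsilon)
  expect_true(cl$is_CD19pos[3])
})

test_that("raising a cutoff never adds positives", {
  fix <- rendered_fixture()
  thr1 <- calibrate_thresholds(NULL, policy = "fixed",
                               fixed_cutoffs = c(CD19 = 1.5, CD66b = 1.5))
  thr2 <- calibrate_thresholds(NULL, policy = "fixed",
                               fixed_cutoffs = c(CD19 = 3, CD66b = 3))
  c1 <- classify_cells(fix$features, thr1, double_positive = "cd19-wins")
  c2 <- classify_cells(fix$features, thr2, double_positive = "cd19-wins")
  expect_true(all(c2$is_CD19pos <= c1$is_CD19pos))
  expect_true(all(c2$is_CD66bpos <= c1$is_CD66bpos))
})

test_that("double-positive policies behave as named", {
  tab <- data.frame(image_id = "t", cell_id = 1L, x_um = 0, y_um = 0,
                    mean_CD19 = 10, bg_CD19 = 1,
                    mean_CD66b = 10, bg_CD66b = 1)
  thr <- calibrate_thresholds(NULL, policy = "fixed",
                              fixed_cutoffs = c(CD19 = 2, CD66b = 2))
  ex <- classify_cells(tab, thr, double_positive = "exclude")
  expect_equal(ex$phenotype, "double")
  expect_false(ex$is_CD19pos || ex$is_CD66bpos)
  expect_equal(attr(ex, "n_double_positive"), 1L)
  w66 <- classify_cells(tab, thr, double_positive = "cd66b-wins")
  expect_equal(w66$phenotype, "neutrophil")
  w19 <- classify_cells(tab, thr, double_positive = "cd19-wins")
  expect_equal(w19$phenotype, "Bcell")
})

test_that("phantom phenotypes are recovered from the rendered image", {
  fix <- rendered_fixture()
  tc <- fix$phantom$truth_cells
  thr <- calibrate_thresholds(fix$features)
  cl <- classify_cells(fix$features, thr, marker_channel = "AID")
  # match each detected cell to its nearest truth cell
  idx <- apply(outer(cl$x_um, tc$x_um, "-")^2 +
                 outer(cl$y_um, tc$y_um, "-")^2, 1, which.min)
  truth_class <- tc$class[idx]
  agreement <- mean(((cl$phenotype == "Bcell") == (truth_class == "Bcell")) &
                    ((cl$phenotype == "neutrophil") ==
                       (truth_class == "neutrophil")))
  expect_gte(agreement, 0.95)
})

test_that("classification errors on missing marker columns", {
  thr <- calibrate_thresholds(NULL, policy = "fixed",
                              fixed_cutoffs = c(CD19 = 2, CD66b = 2))
  expect_error(classify_cells(data.frame(mean_CD19 = 1, bg_CD19 = 1), thr),
               "mean_CD66b")
})
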