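# One-dimensional two-class (Otsu) threshold on a numeric vector: the cut
# maximizing between-class variance, evaluated at midpoints between sorted
# unique values.
.otsu_1d <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2L) stop("degenerate distribution: all values identical")
  cuts <- (u[-1] + u[-length(u)]) / 2
  n <- length(x)
  best <- -Inf; best_cut <- cuts[1]
  for (cc in cuts) {
    lo <- x <= cc
    n1 <- sum(lo); n2 <- n - n1
    if (n1 == 0L || n2 == 0L) next
    bc <- n1 * n2 * (mean(x[lo]) - mean(x[!lo]))^2
    if (bc > best) { best <- bc; best_cut <- cc }
  }
  best_cut
}

# two-class equal-variance Gaussian mixture cut on a numeric vector:
# the point where the two component posteriors cross. Robust to heavily
# unbalanced classes (e.g. sparse neutrophils), where a between-class
# variance scan puts the cut inside the majority mode.
.gmm_cut <- function(x) {
  if (length(unique(x)) < 2L) stop("degenerate distribution: all values identical")
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  fit <- tryCatch(
    mclust::Mclust(x, G = 2, modelNames = "E", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || length(unique(round(fit$parameters$mean, 6))) < 2L)
    stop("two-class mixture calibration failed (unimodal ratios?): ",
         "supply a fixed cutoff")
  mu <- sort(fit$parameters$mean)
  pro <- fit$parameters$pro[order(fit$parameters$mean)]
  s2 <- fit$parameters$variance$sigmasq[1]
  # equal variances: posterior crossing is the shifted midpoint
  (mu[1] + mu[2]) / 2 + s2 * log(pro[1] / pro[2]) / (mu[2] - mu[1])
}

#' Calibrate signal-to-background positivity thresholds
#'
#' Positivity for CD19 and CD66b is defined on the ratio of a cell's mean
#' signal (subtracted layer) to its mean local background. Cutoffs are
#' calibrated on a subselection of images. The default policy fits a
#' two-class Gaussian mixture (equal variances) to the log-ratios and cuts
#' where the class posteriors cross — unlike a between-class variance scan
#' this stays correct when positives are rare (neutrophils are typically
#' 0.1-10% of cells). An Otsu-style variance scan and a fixed user cutoff
#' are available as alternatives.
#'
#' @param tables a `cell_table` or list of them (the calibration
#'   subselection).
#' @param policy `"gmm"` (default), `"otsu"` or `"fixed"`.
#' @param fixed_cutoffs named numeric, e.g. `c(CD19 = 2, CD66b = 2)`, for the
#'   fixed policy.
#' @param markers markers to calibrate.
#' @param epsilon floor applied to zero backgrounds before ratioing;
#'   default `1e-3`.
#' @return object of class `positivity_thresholds`: per-marker ratio cutoffs
#'   plus a provenance record (policy, calibration image ids).
#' @export
calibrate_thresholds <- function(tables, policy = c("gmm", "otsu", "fixed"),
                                 fixed_cutoffs = NULL,
                                 markers = c("CD19", "CD66b"),
                                 epsilon = 1e-3) {
  policy <- match.arg(policy)
  if (policy == "fixed") {
    if (is.null(fixed_cutoffs) || !all(markers %in% names(fixed_cutoffs)))
      stop("fixed policy needs 'fixed_cutoffs' for every marker")
    if (any(fixed_cutoffs[markers] <= 0)) stop("cutoffs must be > 0")
    return(structure(list(cutoffs = fixed_cutoffs[markers], policy = "fixed",
                          calibration_image_ids = character(0),
                          epsilon = epsilon),
                     class = "positivity_thresholds"))
  }
  if (inherits(tables, "data.frame")) tables <- list(tables)
  if (length(tables) < 1L) stop("need at least one calibration table")
  tab <- do.call(rbind, lapply(tables, as.data.frame))
  cutoffs <- setNames(numeric(length(markers)), markers)
  for (m in markers) {
    sig <- tab[[paste0("mean_", m)]]
    bg <- pmax(tab[[paste0("bg_", m)]], epsilon)
    if (is.null(sig)) stop("missing column mean_", m, " in calibration tables")
    ratio <- pmax(sig, epsilon) / bg
    cutoffs[m] <- exp(switch(policy,
                             gmm = .gmm_cut(log(ratio)),
                             otsu = .otsu_1d(log(ratio))))
  }
  structure(list(cutoffs = cutoffs, policy = policy,
                 calibration_image_ids = unique(tab$image_id),
                 epsilon = epsilon),
            class = "positivity_thresholds")
}

#' Classify cells as CD19+ and/or CD66b+ by signal-to-background ratio
#'
#' Flags a cell positive for a marker when its signal/background ratio meets
#' the calibrated cutoff. Double positives are, by default, excluded from both
#' phenotype sets (they are most often segmentation doublets); alternative
#' policies assign them to one marker.
#'
#' @param table a `cell_table` from [extract_features()].
#' @param thresholds a `positivity_thresholds` object.
#' @param marker_channel name of the activation/proliferation channel whose
#'   mean signal is copied to `mean_marker` (e.g. `"AID"`); optional.
#' @param double_positive `"exclude"`, `"cd66b-wins"` or `"cd19-wins"`.
#' @return the table with `ratio_CD19`, `ratio_CD66b`, `is_CD19pos`,
#'   `is_CD66bpos`, `phenotype` columns appended. The number of double
#'   positives is recorded in attribute `n_double_positive`.
#' @export
classify_cells <- function(table, thresholds, marker_channel = NULL,
                           double_positive = c("exclude", "cd66b-wins",
                                               "cd19-wins")) {
  double_positive <- match.arg(double_positive)
  stopifnot(inherits(thresholds, "positivity_thresholds"))
  eps <- thresholds$epsilon
  for (m in c("CD19", "CD66b")) {
    if (is.null(table[[paste0("mean_", m)]]))
      stop("missing column mean_", m)
    bg <- pmax(table[[paste0("bg_", m)]], eps)
    table[[paste0("ratio_", m)]] <- pmax(table[[paste0("mean_", m)]], 0) / bg
  }
  raw19 <- table$ratio_CD19 >= thresholds$cutoffs[["CD19"]]
  raw66 <- table$ratio_CD66b >= thresholds$cutoffs[["CD66b"]]
  dp <- raw19 & raw66
  table$is_CD19pos <- raw19
  table$is_CD66bpos <- raw66
  if (double_positive == "exclude") {
    table$is_CD19pos[dp] <- FALSE
    table$is_CD66bpos[dp] <- FALSE
  } else if (double_positive == "cd66b-wins") {
    table$is_CD19pos[dp] <- FALSE
  } else {
    table$is_CD66bpos[dp] <- FALSE
  }
  table$phenotype <- ifelse(table$is_CD19pos, "Bcell",
                            ifelse(table$is_CD66bpos, "neutrophil", "none"))
  table$phenotype[dp & double_positive == "exclude"] <- "double"
  if (!is.null(marker_channel)) {
    mm <- table[[paste0("mean_", marker_channel)]]
    if (is.null(mm)) stop("missing column mean_", marker_channel)
    table$mean_marker <- mm
  }
  attr(table, "n_double_positive") <- sum(dp)
  table
}
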