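# Shared fixtures (built in code, cached across test files) and independent
# brute-force oracles used to cross-check the implementation.

.fixtures <- new.env(parent = emptyenv())

# default-condition phantom rendered once and reused by the segmentation and
# phenotype tests (rendering + segmentation dominate suite runtime)
rendered_fixture <- function(seed = 7) {
  key <- paste0("rf", seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- phantom_config(seed = seed)
    ph <- render_image(generate_layout(cfg))
    splits <- preprocess_stack(ph$image)
    labels <- segment_nuclei(ph$image$DAPI, pixel_size_um = cfg$pixel_size_um)
    grown <- grow_regions(labels, 1, pixel_size_um = cfg$pixel_size_um)
    feats <- extract_features(grown, splits,
                              pixel_size_um = cfg$pixel_size_um,
                              image_id = paste0("fix", seed))
    .fixtures[[key]] <- list(config = cfg, phantom = ph, splits = splits,
                             labels = labels, grown = grown, features = feats)
  }
  .fixtures[[key]]
}

# O(n^2) nearest-neighbour oracle: explicit double loop, no vectorized path
# shared with the implementation
oracle_nearest <- function(tx, ty, rx, ry) {
  out <- numeric(length(tx))
  for (i in seq_along(tx)) {
    best <- Inf
    for (j in seq_along(rx)) {
      d <- sqrt((tx[i] - rx[j])^2 + (ty[i] - ry[j])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# even-odd rule point-in-polygon oracle (ray casting), boundary handled by a
# small epsilon snap to "inside"
oracle_point_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  inside <- logical(length(px))
  for (k in seq_along(px)) {
    x <- px[k]; y <- py[k]
    crossings <- 0L
    on_edge <- FALSE
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- vx[i]; y1 <- vy[i]; x2 <- vx[j]; y2 <- vy[j]
      # boundary check: point within eps of the segment
      seg2 <- (x2 - x1)^2 + (y2 - y1)^2
      t <- if (seg2 > 0) ((x - x1) * (x2 - x1) + (y - y1) * (y2 - y1)) / seg2 else 0
      t <- min(1, max(0, t))
      if ((x - (x1 + t * (x2 - x1)))^2 + (y - (y1 + t * (y2 - y1)))^2 < eps^2)
        on_edge <- TRUE
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xint) crossings <- crossings + 1L
      }
    }
    inside[k] <- on_edge || (crossings %% 2L == 1L)
  }
  inside
}

# hand-rolled product-limit (Kaplan-Meier) oracle
oracle_km <- function(time, event) {
  ut <- sort(unique(time))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, survival = surv)
}

# simple synthetic phenotyped table on a rectangular field
toy_cell_table <- function(n_b = 50, n_n = 5, width = 300, height = 300,
                           seed = 1, marker_mean = 10) {
  set.seed(seed)
  data.frame(
    cell_id = seq_len(n_b + n_n),
    x_um = runif(n_b + n_n, 0, width),
    y_um = runif(n_b + n_n, 0, height),
    mean_marker = rlnorm(n_b + n_n, log(marker_mean), 0.2),
    is_CD19pos = rep(c(TRUE, FALSE), c(n_b, n_n)),
    is_CD66bpos = rep(c(FALSE, TRUE), c(n_b, n_n)))
}
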