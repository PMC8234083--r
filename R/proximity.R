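#' Radial distance bins around reference cells
#'
#' Default edges follow the canonical 10/30/50/100/>100 um bins. Bins are
#' half-open `(lo, hi]` with distance 0 assigned to the first bin; the last
#' edge must be infinite so every distance falls in exactly one bin.
#'
#' @param edges_um strictly increasing finite inner edges, e.g.
#'   `c(10, 30, 50, 100)`; an infinite last edge is appended.
#' @return object of class `radial_bins`: data.frame with bin, lo_um, hi_um.
#' @export
radial_bins <- function(edges_um = c(10, 30, 50, 100)) {
  if (any(!is.finite(edges_um)) || any(diff(edges_um) <= 0) ||
      any(edges_um <= 0))
    stop("'edges_um' must be positive, finite and strictly increasing")
  lo <- c(0, edges_um)
  hi <- c(edges_um, Inf)
  structure(data.frame(bin = seq_along(lo), lo_um = lo, hi_um = hi),
            class = c("radial_bins", "data.frame"))
}

# assign distances to bins: (lo, hi], zero in bin 1
.bin_assign <- function(d, bins) {
  cut(d, breaks = c(bins$lo_um[1], bins$hi_um), labels = FALSE,
      include.lowest = TRUE, right = TRUE)
}

#' Distance from every target cell to its nearest reference cell
#'
#' Euclidean centroid distance in microns from each CD19+ (target) cell to
#' the nearest CD66b+ (reference) cell. Deterministic; errors when there are
#' no reference cells (the distance is undefined and the image should be
#' excluded upstream).
#'
#' @param targets,references data.frames with `x_um`, `y_um` columns.
#' @return numeric vector, one distance per target row.
#' @export
nearest_reference_distance <- function(targets, references) {
  if (nrow(references) == 0L)
    stop("no reference (CD66b+) cells: nearest distance undefined")
  if (nrow(targets) == 0L) return(numeric(0))
  nearest_dist(targets$x_um, targets$y_um,
               references$x_um, references$y_um)
}

#' Radius-binned marker intensity and density profile for one image
#'
#' Assigns every CD19+ cell to the distance bin of its nearest CD66b+ cell,
#' then computes per bin the number of cells, their mean marker intensity,
#' and their density (cells/mm^2) over the area of the image region whose
#' distance-to-nearest-reference falls in that bin. The bin areas come from a
#' pixelized distance map of the analyzable field, which accounts for image
#' borders explicitly. Empty bins report `n = 0` with `NA` means — never
#' zero, which would bias pooled averages.
#'
#' @param table phenotyped cell table with `x_um`, `y_um`, `is_CD19pos`,
#'   `is_CD66bpos` and `mean_marker` columns (see [classify_cells()] or
#'   [truth_cell_table()]).
#' @param bins a [radial_bins()].
#' @param geometry list with `width_um`, `height_um` and `pixel_size_um`
#'   used for the area distance map.
#' @param image_id identifier for the profile rows.
#' @return object of class `neighborhood_profile`: data.frame with one row
#'   per bin (image_id, bin, lo_um, hi_um, n, mean_intensity, area_mm2,
#'   density, normalized_intensity, normalized_density), normalized fields
#'   `NA` until [normalize_profile()] is applied.
#' @export
compute_profile <- function(table, bins = radial_bins(), geometry,
                            image_id = "image") {
  stopifnot(inherits(bins, "radial_bins"))
  if (is.null(geometry$width_um) || is.null(geometry$height_um) ||
      is.null(geometry$pixel_size_um))
    stop("geometry must supply width_um, height_um and pixel_size_um")
  refs <- table[table$is_CD66bpos, , drop = FALSE]
  targ <- table[table$is_CD19pos, , drop = FALSE]
  if (nrow(refs) == 0L)
    stop("no reference (CD66b+) cells: nearest distance undefined")

  ps <- geometry$pixel_size_um
  nc <- max(1L, round(geometry$width_um / ps))
  nr <- max(1L, round(geometry$height_um / ps))
  # distance of every pixel center to the nearest reference centroid
  m <- matrix(1, nr, nc)
  rows <- pmin(pmax(um_to_px(refs$y_um, ps), 1L), nr)
  cols <- pmin(pmax(um_to_px(refs$x_um, ps), 1L), nc)
  m[cbind(rows, cols)] <- 0
  dmap <- as.matrix(EBImage::distmap(EBImage::Image(m))) * ps
  area_px <- tabulate(.bin_assign(as.numeric(dmap), bins), nbins = nrow(bins))
  area_mm2 <- area_px * ps^2 / 1e6

  out <- data.frame(image_id = image_id, bin = bins$bin,
                    lo_um = bins$lo_um, hi_um = bins$hi_um,
                    n = 0L, mean_intensity = NA_real_,
                    area_mm2 = area_mm2, density = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(targ) > 0L) {
    d <- nearest_reference_distance(targ, refs)
    b <- .bin_assign(d, bins)
    out$n <- tabulate(b, nbins = nrow(bins))
    mi <- tapply(targ$mean_marker, factor(b, levels = bins$bin), mean)
    out$mean_intensity <- as.numeric(mi)
  }
  out$density <- ifelse(out$area_mm2 > 0, out$n / out$area_mm2, NA_real_)

  attr(out, "image_wide") <- list(
    mean_intensity = if (nrow(targ)) mean(targ$mean_marker) else NA_real_,
    density = nrow(targ) / (sum(area_px) * ps^2 / 1e6),
    n_targets = nrow(targ), n_references = nrow(refs))
  class(out) <- c("neighborhood_profile", "data.frame")
  out
}

#' Normalize a profile to its image-wide values
#'
#' Divides each bin's mean marker intensity by the image-wide mean over all
#' CD19+ cells, and each bin's density by the image-wide CD19+ density, so a
#' spatially structureless image gives values of 1 in every bin.
#'
#' @param profile a `neighborhood_profile` from [compute_profile()].
#' @return the profile with `normalized_intensity` and `normalized_density`
#'   columns filled. Errors if the image-wide denominators are zero (such
#'   images should be excluded).
#' @export
normalize_profile <- function(profile) {
  iw <- attr(profile, "image_wide")
  if (is.null(iw)) stop("profile lacks image-wide summaries")
  if (!is.finite(iw$mean_intensity) || iw$mean_intensity <= 0 ||
      !is.finite(iw$density) || iw$density <= 0)
    stop("image-wide mean intensity or density is zero: exclude this image")
  profile$normalized_intensity <- profile$mean_intensity / iw$mean_intensity
  profile$normalized_density <- profile$density / iw$density
  profile
}

#' Per-image profiles for a set of phenotyped tables
#'
#' Convenience wrapper: computes and normalizes one profile per image,
#' excluding (with a message) images without reference cells, without target
#' cells, or with zero image-wide denominators.
#'
#' @param tables named list of phenotyped cell tables.
#' @param bins a [radial_bins()].
#' @param geometry shared image geometry (see [compute_profile()]).
#' @return list with `profiles` (list of normalized profiles) and `excluded`
#'   (named character vector of reasons).
#' @export
profile_images <- function(tables, bins = radial_bins(), geometry) {
  profiles <- list(); excluded <- character(0)
  for (nm in names(tables)) {
    res <- tryCatch(
      normalize_profile(compute_profile(tables[[nm]], bins, geometry,
                                        image_id = nm)),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excluded[nm] <- res
      message("excluding image '", nm, "': ", res)
    } else {
      profiles[[nm]] <- res
    }
  }
  list(profiles = profiles, excluded = excluded)
}

#' Pool per-image profiles and compare bins
#'
#' Pools normalized per-bin values across images (one value per image and
#' bin) and compares the bins with a Kruskal-Wallis rank test; all pairwise
#' bin contrasts use Wilcoxon signed-rank tests on images contributing both
#' bins, Bonferroni-adjusted for the number of pairs performed.
#'
#' @param profiles list of normalized `neighborhood_profile`s (>= 2 images).
#' @param value which normalized column to compare,
#'   `"normalized_intensity"` (default) or `"normalized_density"`.
#' @return object of class `bin_comparison`: list with `pooled` (per-bin
#'   mean/sd/n across images), `kruskal` (statistic, df, p.value),
#'   `pairwise` (data.frame with bins, n pairs, raw and adjusted p),
#'   `m_comparisons`, and `value`.
#' @export
pool_and_compare <- function(profiles,
                             value = c("normalized_intensity",
                                       "normalized_density")) {
  value <- match.arg(value)
  if (length(profiles) < 2L) stop("need profiles from >= 2 images")
  long <- do.call(rbind, lapply(profiles, function(p)
    data.frame(image_id = p$image_id, bin = p$bin, v = p[[value]])))
  long <- long[is.finite(long$v), , drop = FALSE]

  pooled <- do.call(rbind, lapply(split(long, long$bin), function(d)
    data.frame(bin = d$bin[1], n_images = nrow(d), mean = mean(d$v),
               sd = sd(d$v))))
  kw <- if (length(unique(long$v)) == 1L) {
    # all values tied: no detectable difference by construction
    list(statistic = 0, parameter = length(unique(long$bin)) - 1L,
         p.value = 1)
  } else {
    kruskal.test(long$v, factor(long$bin))
  }

  bins_present <- sort(unique(long$bin))
  pairs <- if (length(bins_present) >= 2L) utils::combn(bins_present, 2L) else
    matrix(numeric(0), 2, 0)
  pw <- data.frame(bin_a = integer(0), bin_b = integer(0), n_pairs = integer(0),
                   p = numeric(0))
  wide <- matrix(NA_real_, nrow = length(profiles),
                 ncol = max(long$bin, 0),
                 dimnames = list(names(profiles) %||% seq_along(profiles), NULL))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    wide[i, p$bin] <- p[[value]]
  }
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ok <- is.finite(wide[, a]) & is.finite(wide[, b])
    pval <- if (sum(ok) < 3L) {
      NA_real_
    } else if (all(wide[ok, a] == wide[ok, b])) {
      1  # identical bins: nothing to detect
    } else {
      suppressWarnings(wilcox.test(wide[ok, a], wide[ok, b],
                                   paired = TRUE)$p.value)
    }
    pw <- rbind(pw, data.frame(bin_a = a, bin_b = b, n_pairs = sum(ok),
                               p = pval))
  }
  m <- nrow(pw)
  pw$p_adjusted <- pmin(pw$p * m, 1)
  structure(list(pooled = pooled,
                 kruskal = list(statistic = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p.value = kw$p.value),
                 pairwise = pw, m_comparisons = m, value = value),
            class = "bin_comparison")
}

#' @export
print.bin_comparison <- function(x, ...) {
  cat(sprintf("bin comparison on %s: Kruskal-Wallis chi-sq = %.3f (df %d), p = %.3g\n",
              x$value, x$kruskal$statistic, x$kruskal$df, x$kruskal$p.value))
  cat(sprintf("pairwise signed-rank tests, Bonferroni m = %d:\n", x$m_comparisons))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
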