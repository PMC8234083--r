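#' Segmentation parameters
#'
#' Policy for DAPI nuclear segmentation: Gaussian smoothing, automatic global
#' (Otsu) threshold, watershed on the distance transform to split touching
#' nuclei, and an area window that removes debris and clumps. All thresholds
#' are explicit here because the segmentation policy is part of the analysis
#' contract, not a black box.
#'
#' @param growth_um outward region growth applied after nuclear segmentation
#'   (default 1 um, approximating the whole-cell extent).
#' @param min_nucleus_area_um2,max_nucleus_area_um2 area window for accepted
#'   nuclei.
#' @param smoothing_scale_um sigma of the Gaussian smoothing before
#'   thresholding.
#' @param threshold_policy `"otsu"` (automatic global threshold on the
#'   smoothed DAPI) or `"fixed"` with `fixed_threshold` on raw intensities.
#' @param fixed_threshold used when `threshold_policy = "fixed"`.
#' @param watershed_tolerance minimum depth (in distance-map pixels) between
#'   two maxima for the watershed to split them.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(growth_um = 1,
                                min_nucleus_area_um2 = 7,
                                max_nucleus_area_um2 = 120,
                                smoothing_scale_um = 0.5,
                                threshold_policy = c("otsu", "fixed"),
                                fixed_threshold = NA_real_,
                                watershed_tolerance = 1) {
  threshold_policy <- match.arg(threshold_policy)
  if (growth_um < 0) stop("'growth_um' must be >= 0")
  if (min_nucleus_area_um2 >= max_nucleus_area_um2)
    stop("'min_nucleus_area_um2' must be < 'max_nucleus_area_um2'")
  if (threshold_policy == "fixed" && !is.finite(fixed_threshold))
    stop("fixed policy needs a finite 'fixed_threshold'")
  structure(list(growth_um = growth_um,
                 min_nucleus_area_um2 = min_nucleus_area_um2,
                 max_nucleus_area_um2 = max_nucleus_area_um2,
                 smoothing_scale_um = smoothing_scale_um,
                 threshold_policy = threshold_policy,
                 fixed_threshold = fixed_threshold,
                 watershed_tolerance = watershed_tolerance),
            class = "segmentation_params")
}

#' Segment nuclei on the DAPI channel
#'
#' Smooths, thresholds (Otsu by default), splits touching nuclei by a
#' watershed on the distance transform, removes regions outside the area
#' window and relabels sequentially. Label 0 is background.
#'
#' @param dapi a [channel_image()] for the DAPI channel, or a bare matrix
#'   with `pixel_size_um` supplied.
#' @param params a [segmentation_params()].
#' @param pixel_size_um needed when `dapi` is a bare matrix.
#' @return integer label matrix (class `nucleus_labels`, attribute
#'   `pixel_size_um`); empty images yield zero labels with a warning.
#' @export
segment_nuclei <- function(dapi, params = segmentation_params(),
                           pixel_size_um = NULL) {
  if (inherits(dapi, "channel_image")) {
    px <- dapi$pixels; ps <- dapi$pixel_size_um
  } else {
    px <- dapi; ps <- pixel_size_um
    if (is.null(ps)) stop("supply 'pixel_size_um' for a bare matrix")
  }
  rng <- range(px)
  empty <- function() {
    warning("blank DAPI image: no nuclei found")
    structure(matrix(0L, nrow(px), ncol(px)), pixel_size_um = ps,
              class = c("nucleus_labels", "matrix"))
  }
  if (diff(rng) == 0) return(empty())

  norm <- (px - rng[1]) / diff(rng)
  sm <- EBImage::gblur(EBImage::Image(norm),
                       sigma = max(params$smoothing_scale_um / ps, 0.3))
  if (params$threshold_policy == "otsu") {
    thr <- EBImage::otsu(sm, range = c(0, 1))
    mask <- as.matrix(sm) > thr
  } else {
    mask <- px > params$fixed_threshold
  }
  if (!any(mask)) return(empty())

  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::watershed(dm, tolerance = params$watershed_tolerance, ext = 1)
  lab <- as.matrix(EBImage::imageData(ws))

  # area filter in physical units, then sequential relabel
  areas <- tabulate(lab[lab > 0])
  px_area <- ps^2
  keep <- which(areas * px_area >= params$min_nucleus_area_um2 &
                areas * px_area <= params$max_nucleus_area_um2)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  pos <- lab > 0
  lab[pos] <- remap[lab[pos]]
  structure(matrix(as.integer(lab), nrow(px), ncol(px)),
            pixel_size_um = ps, class = c("nucleus_labels", "matrix"))
}

#' Grow labeled nuclear regions outward by a fixed physical distance
#'
#' Dilates each label by `growth_um`; contested pixels go to the nearest seed
#' label (Voronoi division of the growth zone), so labels never merge and the
#' label count is conserved. `growth_um = 0` returns the input unchanged.
#'
#' @param labels integer label matrix (0 = background).
#' @param growth_um outward growth in microns (>= 0).
#' @param pixel_size_um microns per pixel; defaults to the matrix attribute.
#' @return label matrix of the same shape and label set.
#' @export
grow_regions <- function(labels, growth_um = 1, pixel_size_um = NULL) {
  ps <- pixel_size_um %||% attr(labels, "pixel_size_um")
  if (is.null(ps)) stop("supply 'pixel_size_um'")
  if (growth_um < 0) stop("'growth_um' must be >= 0")
  lab <- matrix(as.numeric(labels), nrow(labels), ncol(labels))
  if (growth_um == 0 || !any(lab > 0)) {
    out <- matrix(as.integer(lab), nrow(lab), ncol(lab))
    attr(out, "pixel_size_um") <- ps
    return(out)
  }
  # distance of every pixel to the nearest labeled pixel, in pixels
  d <- as.matrix(EBImage::distmap(EBImage::Image((lab == 0) * 1)))
  mask <- d <= growth_um / ps
  grown <- EBImage::propagate(EBImage::Image(matrix(0, nrow(lab), ncol(lab))),
                              seeds = EBImage::Image(lab),
                              mask = EBImage::Image(mask * 1))
  out <- matrix(as.integer(EBImage::imageData(grown)), nrow(lab), ncol(lab))
  attr(out, "pixel_size_um") <- ps
  out
}

#' Extract per-cell features from signal and background layers
#'
#' One row per label: centroid in microns (pixel-center convention), nucleus
#' area, and the mean of every supplied channel's subtracted signal and
#' background layer over the (grown) cell mask — the per-cell local
#' background that positivity calls are later ratioed against.
#'
#' @param cell_labels label matrix (typically from [grow_regions()]).
#' @param splits named list of `background_split` objects (one per channel),
#'   as returned by [preprocess_stack()].
#' @param pixel_size_um microns per pixel; defaults to the label attribute.
#' @param image_id identifier copied into every row.
#' @return data.frame (class `cell_table`): cell_id, x_um, y_um,
#'   nucleus_area_um2, and `mean_<ch>` / `bg_<ch>` per channel.
#' @export
extract_features <- function(cell_labels, splits, pixel_size_um = NULL,
                             image_id = "image") {
  ps <- pixel_size_um %||% attr(cell_labels, "pixel_size_um")
  if (is.null(ps)) stop("supply 'pixel_size_um'")
  dims <- dim(cell_labels)
  for (nm in names(splits)) {
    if (!identical(dim(splits[[nm]]$subtracted), dims))
      stop(sprintf("channel '%s' shape (%s) does not match labels (%s)", nm,
                   paste(dim(splits[[nm]]$subtracted), collapse = "x"),
                   paste(dims, collapse = "x")))
  }
  v <- as.integer(cell_labels)
  pos <- v > 0L
  if (!any(pos)) {
    out <- data.frame(image_id = character(0), cell_id = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      nucleus_area_um2 = numeric(0))
    for (nm in names(splits)) {
      out[[paste0("mean_", nm)]] <- numeric(0)
      out[[paste0("bg_", nm)]] <- numeric(0)
    }
    class(out) <- c("cell_table", "data.frame")
    return(out)
  }
  ids <- sort(unique(v[pos]))
  f <- factor(v[pos], levels = ids)
  npix <- as.integer(table(f))
  rows <- ((seq_along(v) - 1L) %% dims[1]) + 1L  # y
  cols <- ((seq_along(v) - 1L) %/% dims[1]) + 1L # x
  mean_by <- function(x) as.numeric(tapply(x[pos], f, mean))
  out <- data.frame(image_id = image_id, cell_id = ids,
                    x_um = px_to_um(mean_by(cols), ps),
                    y_um = px_to_um(mean_by(rows), ps),
                    nucleus_area_um2 = npix * ps^2,
                    stringsAsFactors = FALSE)
  for (nm in names(splits)) {
    out[[paste0("mean_", nm)]] <- mean_by(as.numeric(splits[[nm]]$subtracted))
    out[[paste0("bg_", nm)]] <- mean_by(as.numeric(splits[[nm]]$background))
  }
  class(out) <- c("cell_table", "data.frame")
  out
}
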