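#' Write a multichannel stack as TIFF with a metadata sidecar
#'
#' Channels are stored as pages of one multipage TIFF (32-bit float, scaled
#' to [0, 1]); the physical pixel size, channel names and intensity scale go
#' to a JSON sidecar next to the image (`<path>.json`), so the micron
#' geometry survives the round trip.
#'
#' @param stack named list of numeric matrices with attribute
#'   `pixel_size_um`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  ps <- attr(stack, "pixel_size_um")
  if (is.null(ps)) stop("stack lacks 'pixel_size_um' attribute")
  scale_max <- max(1, max(vapply(stack, max, numeric(1))))
  pages <- lapply(stack, function(m) m / scale_max)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_um = ps, channels = names(stack),
               intensity_scale = scale_max)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multichannel stack written by [write_stack_tiff()]
#'
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return named list of matrices with attribute `pixel_size_um`.
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- setNames(lapply(pages, function(p) p * meta$intensity_scale),
                    meta$channels)
  attr(stack, "pixel_size_um") <- meta$pixel_size_um
  stack
}

#' Write follicle outlines as GeoJSON (micron coordinates)
#'
#' @param follicles list of polygons (data.frames with `x_um`, `y_um`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_follicles <- function(follicles, path) {
  feats <- lapply(seq_along(follicles), function(k) {
    p <- follicles[[k]]
    ring <- cbind(p$x_um, p$y_um)
    ring <- rbind(ring, ring[1, ])  # closed ring
    list(type = "Feature",
         properties = list(follicle_id = k),
         geometry = list(type = "Polygon",
                         coordinates = list(apply(ring, 1, as.list))))
  })
  gj <- list(type = "FeatureCollection", crs_units = "micron",
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read follicle outlines from GeoJSON written by [write_follicles()]
#'
#' @param path GeoJSON path.
#' @return list of data.frames with `x_um`, `y_um` (closing vertex dropped).
#' @export
read_follicles <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(v)
      c(as.numeric(v[[1]]), as.numeric(v[[2]]))))
    if (nrow(xy) > 1L && all(xy[1, ] == xy[nrow(xy), ]))
      xy <- xy[-nrow(xy), , drop = FALSE]
    data.frame(x_um = xy[, 1], y_um = xy[, 2])
  })
}

# deterministic CSV writer used by the pipeline (fixed row.names policy so
# reruns are byte-identical)
write_csv_out <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
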