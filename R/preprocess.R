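#' Construct a single-channel image with physical pixel size
#'
#' @param pixels numeric matrix (rows = y, cols = x), nonnegative.
#' @param pixel_size_um microns per pixel (> 0).
#' @param channel_name one of DAPI, CD19, CD66b, AID, Ki67.
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size_um, channel_name) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("'pixels' must be a non-empty matrix")
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be > 0")
  if (!channel_name %in% c("DAPI", "CD19", "CD66b", "AID", "Ki67"))
    stop("unknown channel name: ", channel_name)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel_name = channel_name),
            class = "channel_image")
}

#' Split a multichannel stack into channel images
#'
#' @param stack named list of numeric matrices with attribute `pixel_size_um`
#'   (as produced by [render_image()]), or with `pixel_size_um` passed
#'   explicitly.
#' @param pixel_size_um overrides the stack attribute when given.
#' @return list of [channel_image()] objects, order and names preserved.
#' @export
split_channels <- function(stack, pixel_size_um = NULL) {
  ps <- pixel_size_um %||% attr(stack, "pixel_size_um")
  if (is.null(ps)) stop("pixel size missing: supply 'pixel_size_um'")
  nm <- names(stack)
  if (is.null(nm) || any(nm == ""))
    stop("stack channels must be named")
  if (anyDuplicated(nm))
    stop("duplicate channel names in stack: ", paste(nm, collapse = ", "))
  setNames(lapply(nm, function(ch) channel_image(stack[[ch]], ps, ch)), nm)
}

#' Rolling-ball background subtraction
#'
#' Estimates the slowly varying background of a fluorescence channel as the
#' upper envelope traced by a ball of physical radius `ball_radius_um` rolled
#' under the intensity surface (a grayscale opening with a spherical
#' structuring element), and subtracts it. Features smaller than the ball are
#' preserved in the subtracted layer; the smooth background goes to the
#' background layer, mirroring the usual two-layer output of image
#' preprocessing pipelines.
#'
#' Because the envelope is a pointwise minimum construction, shot noise would
#' otherwise drag it to the lowest outlier pixels; a 3x3 mean filter is
#' therefore applied to the copy of the image used for background estimation
#' (the classic pre-smoothing step). For large radii the image is first
#' reduced by a block minimum (factor `radius_px / 16`, as in the classic
#' implementation), the ball is rolled at the reduced scale, and the
#' background is bilinearly re-enlarged. The background is finally capped at
#' the original image so that `subtracted + background == original` holds
#' exactly pixelwise and `subtracted >= 0` everywhere.
#'
#' @param channel a [channel_image()] (or plain matrix plus `pixel_size_um`).
#' @param ball_radius_um ball radius in microns; default 64.
#' @param pixel_size_um required if `channel` is a bare matrix.
#' @param presmooth apply the 3x3 mean filter before estimating the
#'   background (default TRUE); disable for noise-free images when the exact
#'   opening is wanted.
#' @param shrink logical; `NULL` (default) enables the block-min reduction
#'   automatically when the radius exceeds 16 px. `FALSE` forces the exact
#'   full-resolution opening.
#' @return an object of class `background_split`: list with `subtracted`,
#'   `background` matrices, `ball_radius_um`, `pixel_size_um`, `channel_name`.
#' @export
rolling_ball <- function(channel, ball_radius_um = 64, pixel_size_um = NULL,
                         presmooth = TRUE, shrink = NULL) {
  if (inherits(channel, "channel_image")) {
    px <- channel$pixels
    ps <- channel$pixel_size_um
    nm <- channel$channel_name
  } else {
    px <- channel
    ps <- pixel_size_um
    nm <- NA_character_
    if (is.null(ps)) stop("supply 'pixel_size_um' for a bare matrix")
  }
  if (ball_radius_um <= 0) stop("'ball_radius_um' must be > 0")
  r_px <- ball_radius_um / ps
  if (r_px < 1)
    stop(sprintf(paste0("ball radius %.3g um is below one pixel (%.3g um/px): ",
                        "use a larger radius or finer pixel size"),
                 ball_radius_um, ps))
  if (diff(range(px)) == 0) {
    # flat image: the ball rides the surface everywhere
    return(structure(list(subtracted = px * 0, background = px,
                          ball_radius_um = ball_radius_um, pixel_size_um = ps,
                          channel_name = nm),
                     class = "background_split"))
  }
  est <- px
  if (isTRUE(presmooth)) {
    kern <- matrix(1 / 9, 3, 3)
    est <- as.matrix(EBImage::filter2(EBImage::Image(px), kern,
                                      boundary = "replicate"))
  }
  s <- 1L
  if (is.null(shrink) || isTRUE(shrink)) {
    s <- max(1L, as.integer(floor(r_px / 16)))
  }
  if (s > 1L) {
    small <- .block_min_cpp(est, s)
    bg_small <- .ball_opening_cpp(small, r_px / s)
    bg <- as.matrix(EBImage::resize(EBImage::Image(bg_small),
                                    w = nrow(px), h = ncol(px)))
    bg <- pmin(bg, px)
  } else {
    bg <- pmin(.ball_opening_cpp(est, r_px), px)
  }
  structure(list(subtracted = px - bg, background = bg,
                 ball_radius_um = ball_radius_um, pixel_size_um = ps,
                 channel_name = nm),
            class = "background_split")
}

#' Background-subtract the marker channels of a stack
#'
#' Applies [rolling_ball()] to every channel except DAPI (the nuclear stain is
#' left untouched by default, matching the usual practice of subtracting only
#' the marker channels; set `include_dapi = TRUE` to subtract it too).
#'
#' @param stack named list of matrices with `pixel_size_um` attribute.
#' @param ball_radius_um ball radius in microns.
#' @param include_dapi also subtract the DAPI channel.
#' @return named list of `background_split` objects (DAPI entry carries a
#'   zero background when not subtracted).
#' @export
preprocess_stack <- function(stack, ball_radius_um = 64, include_dapi = FALSE) {
  chans <- split_channels(stack)
  lapply(chans, function(ch) {
    if (ch$channel_name == "DAPI" && !include_dapi) {
      structure(list(subtracted = ch$pixels,
                     background = matrix(0, nrow(ch$pixels), ncol(ch$pixels)),
                     ball_radius_um = NA_real_,
                     pixel_size_um = ch$pixel_size_um,
                     channel_name = ch$channel_name),
                class = "background_split")
    } else {
      rolling_ball(ch, ball_radius_um = ball_radius_um)
    }
  })
}
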