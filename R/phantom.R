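#' Configuration for a synthetic lymph-node tissue phantom
#'
#' Defines the ground-truth conditions under which phantom images are
#' generated: field geometry, cell counts, the hard-core spacing between cell
#' centers, and the proximity effect that elevates the activation/proliferation
#' marker in B cells lying within `effect_radius_um` of any neutrophil.
#' `effect_amplitude = 1` means no proximity effect (the null regime);
#' values above 1 multiply the marker intensity of near-neutrophil B cells.
#'
#' Defaults describe a 800x800 um field at 1 um/px with four B follicles
#' (radius 70 um, 100 B cells each), eight neutrophils of which half sit
#' inside follicles, and 150 unclassified cells — densities at which all five
#' canonical distance bins (10/30/50/100/>100 um) are populated in most
#' images while neutrophils stay sparse, as in lymph-node sections.
#'
#' @param field_width_um,field_height_um field size in microns.
#' @param pixel_size_um physical pixel size of the rendered image.
#' @param n_follicles number of B follicles.
#' @param follicle_radius_um follicle disc radius.
#' @param n_bcells_per_follicle B cells per follicle.
#' @param n_neutrophils total neutrophils in the field.
#' @param neutrophil_follicle_fraction fraction of neutrophils placed inside
#'   follicles (the rest are uniform over the field).
#' @param n_other_cells unclassified (DAPI-only) cells, uniform over the field.
#' @param nucleus_radius_um nucleus disc radius used for rendering.
#' @param min_center_spacing_um hard-core minimum distance between any two
#'   cell centers. Values below one nucleus diameter are allowed but flagged
#'   with a warning (rendered nuclei may overlap).
#' @param effect_radius_um range of the neutrophil proximity effect.
#' @param effect_amplitude multiplier f >= 0 applied to the marker intensity
#'   of B cells within `effect_radius_um` of any neutrophil; 1 = no effect.
#' @param intensity_sigma sigma of the lognormal cell-to-cell intensity noise
#'   (mean kept at 1 so expectations are the configured bases).
#' @param base_intensities named nonnegative means for channels DAPI, CD19,
#'   CD66b and the marker.
#' @param marker_name `"AID"` or `"Ki67"`.
#' @param background_amplitude,background_scale_um amplitude and smoothness
#'   scale of the slowly varying additive background field per channel.
#' @param background_offset constant autofluorescence floor added to the
#'   background field of every channel (tissue background never reaches
#'   zero; positivity ratios need a stable denominator).
#' @param noise_sd per-pixel Gaussian noise sd added at render time.
#' @param seed root RNG seed; child streams (layout, render) are derived from
#'   it with [derive_seed()].
#' @return an object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(field_width_um = 800,
                           field_height_um = 800,
                           pixel_size_um = 1,
                           n_follicles = 4,
                           follicle_radius_um = 70,
                           n_bcells_per_follicle = 100,
                           n_neutrophils = 8,
                           neutrophil_follicle_fraction = 0.5,
                           n_other_cells = 150,
                           nucleus_radius_um = 3,
                           min_center_spacing_um = 8,
                           effect_radius_um = 10,
                           effect_amplitude = 1,
                           intensity_sigma = 0.2,
                           base_intensities = c(DAPI = 100, CD19 = 80,
                                                CD66b = 80, marker = 60),
                           marker_name = "AID",
                           background_amplitude = 15,
                           background_scale_um = 120,
                           background_offset = 5,
                           noise_sd = 3,
                           seed = 1L) {
  cfg <- list(field_width_um = field_width_um,
              field_height_um = field_height_um,
              pixel_size_um = pixel_size_um,
              n_follicles = n_follicles,
              follicle_radius_um = follicle_radius_um,
              n_bcells_per_follicle = n_bcells_per_follicle,
              n_neutrophils = n_neutrophils,
              neutrophil_follicle_fraction = neutrophil_follicle_fraction,
              n_other_cells = n_other_cells,
              nucleus_radius_um = nucleus_radius_um,
              min_center_spacing_um = min_center_spacing_um,
              effect_radius_um = effect_radius_um,
              effect_amplitude = effect_amplitude,
              intensity_sigma = intensity_sigma,
              base_intensities = base_intensities,
              marker_name = marker_name,
              background_amplitude = background_amplitude,
              background_scale_um = background_scale_um,
              background_offset = background_offset,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  lens <- c("field_width_um", "field_height_um", "pixel_size_um",
            "follicle_radius_um", "nucleus_radius_um", "effect_radius_um",
            "background_scale_um")
  for (f in lens)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop(sprintf("'%s' must be a positive length", f))
  counts <- c("n_follicles", "n_bcells_per_follicle", "n_neutrophils",
              "n_other_cells")
  for (f in counts)
    if (cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      stop(sprintf("'%s' must be a nonnegative integer", f))
  if (cfg$effect_amplitude < 0) stop("'effect_amplitude' must be >= 0")
  if (cfg$min_center_spacing_um <= 0) stop("'min_center_spacing_um' must be > 0")
  if (cfg$noise_sd < 0 || cfg$background_amplitude < 0 ||
      cfg$background_offset < 0 || any(cfg$base_intensities < 0))
    stop("intensities, background amplitude and noise sd must be nonnegative")
  if (!all(c("DAPI", "CD19", "CD66b", "marker") %in% names(cfg$base_intensities)))
    stop("'base_intensities' needs entries DAPI, CD19, CD66b and marker")
  if (!marker_name %in% c("AID", "Ki67"))
    stop("'marker_name' must be \"AID\" or \"Ki67\"")
  if (cfg$neutrophil_follicle_fraction < 0 || cfg$neutrophil_follicle_fraction > 1)
    stop("'neutrophil_follicle_fraction' must be in [0, 1]")
  if (cfg$min_center_spacing_um < 2 * cfg$nucleus_radius_um)
    warning("min_center_spacing_um < nucleus diameter: rendered nuclei may overlap")
  structure(cfg, class = "phantom_config")
}

# rejection-sample n points from `draw()` keeping the hard-core constraint
# against already accepted points `px, py`; errors if the budget is exhausted.
.place_hardcore <- function(n, draw, px, py, spacing, what,
                            attempts_per_cell = 500L) {
  if (n == 0L) return(list(x = numeric(0), y = numeric(0)))
  xs <- numeric(n); ys <- numeric(n)
  budget <- attempts_per_cell * n
  placed <- 0L
  while (placed < n) {
    if (budget <= 0L)
      stop(sprintf(paste0("could not place all %d %s at hard-core spacing ",
                          "%.1f um: requested density is too high for the ",
                          "available area"), n, what, spacing))
    p <- draw()
    budget <- budget - 1L
    ok <- TRUE
    if (length(px))
      ok <- min((p[1] - px)^2 + (p[2] - py)^2) >= spacing^2
    if (ok && placed > 0L)
      ok <- min((p[1] - xs[1:placed])^2 + (p[2] - ys[1:placed])^2) >= spacing^2
    if (ok) {
      placed <- placed + 1L
      xs[placed] <- p[1]; ys[placed] <- p[2]
    }
  }
  list(x = xs, y = ys)
}

#' Generate a ground-truth cell layout (tissue phantom, no image yet)
#'
#' Places B follicles, then B cells (clustered inside follicle discs),
#' neutrophils (a configurable fraction inside follicles, the rest uniform)
#' and unclassified cells, all under a hard-core minimum spacing. Each B
#' cell's marker intensity is its configured base, multiplied by
#' `effect_amplitude` when the cell lies within `effect_radius_um` of any
#' neutrophil, times lognormal cell-to-cell noise with mean 1. Deterministic
#' given the config seed.
#'
#' @param config a [phantom_config()].
#' @return an object of class `tissue_phantom`: list with `config`,
#'   `truth_cells` (data.frame: cell_id, x_um, y_um, class, intensity_DAPI,
#'   intensity_CD19, intensity_CD66b, intensity_marker,
#'   dist_nearest_neutrophil_um) and `follicle_polygons` (list of data.frames
#'   with x_um, y_um vertices).
#' @export
generate_layout <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(derive_seed(config$seed, "layout"))
  W <- config$field_width_um; H <- config$field_height_um
  rf <- config$follicle_radius_um
  sp <- config$min_center_spacing_um
  margin <- config$nucleus_radius_um

  if (config$n_follicles > 0 && 2 * rf >= min(W, H))
    stop("follicle diameter exceeds the field: shrink follicles or enlarge field")

  # follicle centers: spaced discs away from the border
  fc <- .place_hardcore(config$n_follicles,
                        draw = function() c(runif(1, rf, W - rf),
                                            runif(1, rf, H - rf)),
                        px = numeric(0), py = numeric(0),
                        spacing = 2.2 * rf, what = "follicles",
                        attempts_per_cell = 2000L)

  in_field <- function() c(runif(1, margin, W - margin),
                           runif(1, margin, H - margin))
  in_follicle <- function(k) {
    th <- runif(1, 0, 2 * pi); rr <- rf * sqrt(runif(1))
    c(fc$x[k] + rr * cos(th), fc$y[k] + rr * sin(th))
  }

  px <- numeric(0); py <- numeric(0); cls <- character(0)

  # B cells, follicle by follicle
  for (k in seq_len(config$n_follicles)) {
    b <- .place_hardcore(config$n_bcells_per_follicle,
                         draw = function() in_follicle(k),
                         px = px, py = py, spacing = sp, what = "B cells")
    px <- c(px, b$x); py <- c(py, b$y)
    cls <- c(cls, rep("Bcell", config$n_bcells_per_follicle))
  }

  # neutrophils: some inside a randomly chosen follicle, rest uniform
  n_in <- if (config$n_follicles > 0)
    round(config$neutrophil_follicle_fraction * config$n_neutrophils) else 0L
  n_out <- config$n_neutrophils - n_in
  if (n_in > 0) {
    nin <- .place_hardcore(n_in,
                           draw = function() in_follicle(sample.int(config$n_follicles, 1L)),
                           px = px, py = py, spacing = sp, what = "neutrophils")
    px <- c(px, nin$x); py <- c(py, nin$y)
    cls <- c(cls, rep("neutrophil", n_in))
  }
  if (n_out > 0) {
    nout <- .place_hardcore(n_out, draw = in_field,
                            px = px, py = py, spacing = sp, what = "neutrophils")
    px <- c(px, nout$x); py <- c(py, nout$y)
    cls <- c(cls, rep("neutrophil", n_out))
  }

  # unclassified cells
  oth <- .place_hardcore(config$n_other_cells, draw = in_field,
                         px = px, py = py, spacing = sp, what = "other cells")
  px <- c(px, oth$x); py <- c(py, oth$y)
  cls <- c(cls, rep("other", config$n_other_cells))

  n <- length(px)
  base <- config$base_intensities
  ln_noise <- function(n) rlnorm(n, meanlog = -config$intensity_sigma^2 / 2,
                                 sdlog = config$intensity_sigma)

  is_b <- cls == "Bcell"; is_n <- cls == "neutrophil"
  dist_nn <- rep(NA_real_, n)
  if (any(is_n)) dist_nn <- nearest_dist(px, py, px[is_n], py[is_n])
  # the marker effect branch: within effect radius of any neutrophil
  near <- !is.na(dist_nn) & dist_nn <= config$effect_radius_um

  i_dapi <- base[["DAPI"]] * ln_noise(n)
  i_cd19 <- ifelse(is_b, base[["CD19"]] * ln_noise(n), 0)
  i_cd66 <- ifelse(is_n, base[["CD66b"]] * ln_noise(n), 0)
  f <- ifelse(is_b & near, config$effect_amplitude, 1)
  i_mark <- ifelse(is_b, base[["marker"]] * f * ln_noise(n), 0)

  truth <- data.frame(cell_id = seq_len(n), x_um = px, y_um = py,
                      class = cls,
                      intensity_DAPI = i_dapi,
                      intensity_CD19 = i_cd19,
                      intensity_CD66b = i_cd66,
                      intensity_marker = i_mark,
                      dist_nearest_neutrophil_um = dist_nn,
                      stringsAsFactors = FALSE)

  theta <- seq(0, 2 * pi, length.out = 65L)[-65L]
  polys <- lapply(seq_len(config$n_follicles), function(k)
    data.frame(x_um = fc$x[k] + rf * cos(theta),
               y_um = fc$y[k] + rf * sin(theta)))

  structure(list(config = config, truth_cells = truth,
                 follicle_polygons = polys, image = NULL),
            class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  tc <- x$truth_cells
  cat(sprintf("tissue_phantom: %g x %g um field, %d cells (%d B, %d neutrophil, %d other), %d follicles%s\n",
              x$config$field_width_um, x$config$field_height_um, nrow(tc),
              sum(tc$class == "Bcell"), sum(tc$class == "neutrophil"),
              sum(tc$class == "other"), length(x$follicle_polygons),
              if (is.null(x$image)) "" else ", rendered"))
  invisible(x)
}

# smooth positive background field: coarse Gaussian grid at the smoothness
# scale, bilinearly upsampled, squashed through a logistic to (0, amplitude)
.background_field <- function(nrow_px, ncol_px, pixel_size_um,
                              amplitude, scale_um, offset = 0) {
  if (amplitude == 0) return(matrix(offset, nrow_px, ncol_px))
  scale_px <- max(2, scale_um / pixel_size_um)
  gr <- max(2L, ceiling(nrow_px / scale_px) + 1L)
  gc <- max(2L, ceiling(ncol_px / scale_px) + 1L)
  coarse <- matrix(rnorm(gr * gc), gr, gc)
  up <- EBImage::resize(EBImage::Image(coarse), w = nrow_px, h = ncol_px)
  offset + amplitude * plogis(1.5 * as.matrix(up))
}

#' Render a phantom layout into a multichannel image
#'
#' Paints every cell as a disc of `nucleus_radius_um` in the DAPI channel and
#' at the cell's true intensity in its class channel (CD19 for B cells, CD66b
#' for neutrophils) and the marker channel; adds a smooth additive background
#' field and Gaussian pixel noise per channel. Overlapping discs combine by
#' maximum. Pixel convention: top-left origin, x = column, y = row, micron
#' position = (index - 1) * pixel size at pixel centers.
#'
#' @param phantom a `tissue_phantom` from [generate_layout()].
#' @return the phantom with `$image` set: a named list of numeric matrices
#'   (`DAPI`, `CD19`, `CD66b`, marker name), plus attribute `pixel_size_um`.
#' @export
render_image <- function(phantom) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  cfg <- phantom$config
  if (cfg$pixel_size_um >= cfg$nucleus_radius_um)
    stop("pixel_size_um >= nucleus_radius_um: cells are unresolvable at this sampling")
  set.seed(derive_seed(cfg$seed, "render"))
  ps <- cfg$pixel_size_um
  nc <- round(cfg$field_width_um / ps)   # columns = x
  nr <- round(cfg$field_height_um / ps)  # rows = y
  r_px <- cfg$nucleus_radius_um / ps

  chans <- c("DAPI", "CD19", "CD66b", cfg$marker_name)
  img <- setNames(lapply(chans, function(z) matrix(0, nr, nc)), chans)
  tc <- phantom$truth_cells

  paint <- function(mat, x_um, y_um, value) {
    cx <- x_um / ps + 1; cy <- y_um / ps + 1
    c0 <- max(1L, floor(cx - r_px)); c1 <- min(nc, ceiling(cx + r_px))
    r0 <- max(1L, floor(cy - r_px)); r1 <- min(nr, ceiling(cy + r_px))
    if (c0 > c1 || r0 > r1) return(mat)
    cols <- c0:c1; rows <- r0:r1
    d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
    block <- mat[rows, cols, drop = FALSE]
    hit <- d2 <= r_px^2
    block[hit] <- pmax(block[hit], value)
    mat[rows, cols] <- block
    mat
  }

  for (i in seq_len(nrow(tc))) {
    img$DAPI <- paint(img$DAPI, tc$x_um[i], tc$y_um[i], tc$intensity_DAPI[i])
    if (tc$intensity_CD19[i] > 0)
      img$CD19 <- paint(img$CD19, tc$x_um[i], tc$y_um[i], tc$intensity_CD19[i])
    if (tc$intensity_CD66b[i] > 0)
      img$CD66b <- paint(img$CD66b, tc$x_um[i], tc$y_um[i], tc$intensity_CD66b[i])
    if (tc$intensity_marker[i] > 0)
      img[[cfg$marker_name]] <- paint(img[[cfg$marker_name]],
                                      tc$x_um[i], tc$y_um[i],
                                      tc$intensity_marker[i])
  }

  for (ch in chans) {
    bg <- .background_field(nr, nc, ps, cfg$background_amplitude,
                            cfg$background_scale_um, cfg$background_offset)
    noise <- if (cfg$noise_sd > 0) matrix(rnorm(nr * nc, 0, cfg$noise_sd), nr, nc) else 0
    img[[ch]] <- pmax(img[[ch]] + bg + noise, 0)
  }
  attr(img, "pixel_size_um") <- ps
  phantom$image <- img
  phantom
}

#' Turn a phantom's ground truth into a phenotyped cell table
#'
#' Maps true classes onto the flags the downstream analysis expects, so the
#' proximity, follicle and survival stages can be exercised directly on known
#' truth without rendering and re-segmenting an image.
#'
#' @param phantom a `tissue_phantom`.
#' @return data.frame with cell_id, x_um, y_um, `mean_marker`, `is_CD19pos`,
#'   `is_CD66bpos` and `phenotype` columns.
#' @export
truth_cell_table <- function(phantom) {
  tc <- phantom$truth_cells
  data.frame(cell_id = tc$cell_id, x_um = tc$x_um, y_um = tc$y_um,
             mean_marker = tc$intensity_marker,
             is_CD19pos = tc$class == "Bcell",
             is_CD66bpos = tc$class == "neutrophil",
             phenotype = c(Bcell = "Bcell", neutrophil = "neutrophil",
                           other = "none")[tc$class],
             stringsAsFactors = FALSE)
}
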