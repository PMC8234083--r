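`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a root seed
#'
#' One root seed drives independent, named random streams (layout, render,
#' cohort, ...) so any pipeline stage can be regenerated in isolation.
#' The derivation is a small deterministic hash of the purpose string folded
#' into the root seed, kept inside the 32-bit integer range.
#'
#' @param seed integer root seed.
#' @param purpose character tag naming the stream, e.g. `"layout"`.
#' @param index optional integer (e.g. image number) for per-item streams.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, purpose, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(purpose)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(seed) + h + 7919 * index) %% 2147483647) + 1L
}

# Euclidean distance from each (ax, ay) to its nearest (bx, by), in chunks to
# bound memory. Returns numeric(length(ax)); errors if no reference points.
nearest_dist <- function(ax, ay, bx, by, chunk = 512L) {
  if (length(bx) == 0L) stop("no reference points: nearest distance undefined")
  n <- length(ax)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    d2 <- outer(ax[i:j], bx, "-")^2 + outer(ay[i:j], by, "-")^2
    out[i:j] <- sqrt(apply(d2, 1L, min))
    i <- j + 1L
  }
  out
}

# pixel-center coordinate convention for the whole package: top-left origin,
# x = column, y = row, micron position = (index - 1) * pixel_size_um.
px_to_um <- function(idx, pixel_size_um) (idx - 1) * pixel_size_um
um_to_px <- function(um, pixel_size_um) round(um / pixel_size_um) + 1L
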