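# Adaptive (local-mean) thresholding of height rasters.

#' Adaptive threshold parameters
#'
#' @param window Odd neighbourhood size in pixels (>= 3). `NULL` picks the
#'   default: half the smaller grid dimension, rounded up to odd. The window
#'   should span at least one planting interval so that every neighbourhood
#'   averages both canopy and ground; windows smaller than a single crown make
#'   the local mean track the crown surface itself and hollow out detections.
#' @param sensitivity Multiplier in (0, 1] applied to the local mean; a cell
#'   is foreground iff its height strictly exceeds `sensitivity * local mean`.
#'   Lower sensitivity raises the bar relative to the local mean and drops
#'   low canopy parts first.
#' @return A `threshold_params` object.
#' @export
threshold_params <- function(window = NULL, sensitivity = 0.9) {
  if (!is.null(window)) {
    window <- as.integer(window)
    if (window < 3L || window %% 2L == 0L)
      stop("`window` must be odd and >= 3")
  }
  if (!is.numeric(sensitivity) || sensitivity <= 0 || sensitivity > 1)
    stop("`sensitivity` must be in (0, 1]")
  structure(list(window = window, sensitivity = sensitivity),
            class = "threshold_params")
}

.default_window <- function(dims) {
  w <- ceiling(min(dims) / 2)
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  max(w, 3L)
}

# Windowed sums via summed-area tables, NA-aware: returns list(sum, count)
# of the non-NA cells in the (2k+1)^2 window clipped at the borders.
.window_stats <- function(v, window) {
  k <- (window - 1L) %/% 2L
  nr <- nrow(v); nc <- ncol(v)
  val <- v; val[is.na(v)] <- 0
  cnt <- matrix(as.numeric(!is.na(v)), nr, nc)
  sat <- function(m) {
    m <- apply(m, 2L, cumsum)
    t(apply(m, 1L, cumsum))
  }
  Sv <- sat(val); Sc <- sat(cnt)
  # pad with a zero row/col so (i1-1) lookups vectorize
  pad <- function(S) rbind(0, cbind(0, S))
  Sv <- pad(Sv); Sc <- pad(Sc)
  r1 <- pmax(seq_len(nr) - k, 1L); r2 <- pmin(seq_len(nr) + k, nr)
  c1 <- pmax(seq_len(nc) - k, 1L); c2 <- pmin(seq_len(nc) + k, nc)
  boxsum <- function(S) {
    S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
      S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  }
  list(sum = boxsum(Sv), count = boxsum(Sc))
}

#' Adaptive local-mean threshold of a height raster
#'
#' A cell is foreground iff its height strictly exceeds
#' `sensitivity x (local mean of non-nodata heights in the window centred on
#' it)`. Windows are clipped at the raster border and the mean is taken over
#' the cells actually present. Nodata cells are always background.
#'
#' @param r A [height_raster()].
#' @param params A [threshold_params()].
#' @return A logical foreground matrix of the raster's shape.
#' @export
adaptive_threshold <- function(r, params = threshold_params()) {
  stopifnot(inherits(r, "height_raster"), inherits(params, "threshold_params"))
  v <- r$values
  window <- params$window %||% .default_window(dim(v))
  if (sum(!is.na(v)) < 1L || all(is.na(v)))
    stop("adaptive threshold: raster is all nodata")
  if (sum(!is.na(v)) < window^2)
    warning("fewer non-nodata cells than one full window; local means are sparse")
  ws <- .window_stats(v, window)
  mu <- ws$sum / pmax(ws$count, 1)
  fg <- !is.na(v) & (v > params$sensitivity * mu)
  fg[is.na(v)] <- FALSE
  fg
}
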