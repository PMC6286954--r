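# Per-tree crown widths and projection area.

#' Crown metrics from a label raster
#'
#' For every crown label: the pixel count, the crown projection area
#' `CPA = pixel_count x resolution^2`, and the two orthogonal crown widths
#' from the row-aligned bounding box. `W1` is the extent parallel to the
#' planting row and `W2` perpendicular to it. For `row_angle = 0` the row
#' runs along the grid's column axis, so `W1` is the column extent. For other
#' angles the pixel-centre coordinates are rotated by `-row_angle` (degrees)
#' and axis-aligned extents are taken in the rotated frame; extents are
#' `max - min + 1` pixels, so a single-pixel crown has the physical size of
#' one pixel.
#'
#' @param labels Integer label matrix (0 = background), or a
#'   `crown_segmentation` object.
#' @param resolution Ground sampling distance, m/pixel (> 0). Taken from the
#'   segmentation object if one is given.
#' @param row_angle Planting-row direction in degrees anticlockwise from the
#'   column axis.
#' @return A tibble with columns `tree_id`, `W1_m`, `W2_m`, `CPA_m2`,
#'   `bbox_row_min`, `bbox_row_max`, `bbox_col_min`, `bbox_col_max`,
#'   `pixel_count`; one row per label, empty if there are no labels.
#' @export
crown_metrics <- function(labels, resolution = NULL, row_angle = 0) {
  if (inherits(labels, "crown_segmentation")) {
    resolution <- resolution %||% labels$resolution
    labels <- labels$labels
  }
  if (is.null(resolution) || resolution <= 0)
    stop("`resolution` must be a positive number")
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  ids <- sort(unique(labels[labels > 0]))
  empty <- tibble(
    tree_id = integer(), W1_m = numeric(), W2_m = numeric(), CPA_m2 = numeric(),
    bbox_row_min = integer(), bbox_row_max = integer(),
    bbox_col_min = integer(), bbox_col_max = integer(), pixel_count = integer()
  )
  if (length(ids) == 0L) return(empty)
  theta <- row_angle * pi / 180
  ct <- cos(-theta); st <- sin(-theta)
  rows <- row(labels); cols <- col(labels)
  res <- lapply(ids, function(k) {
    sel <- labels == k
    pr <- rows[sel]; pc <- cols[sel]
    # rotate pixel centres by -row_angle so the row lies along the x axis
    xr <- ct * pc - st * pr
    yr <- st * pc + ct * pr
    tibble(
      tree_id = k,
      W1_m = (max(xr) - min(xr) + 1) * resolution,
      W2_m = (max(yr) - min(yr) + 1) * resolution,
      CPA_m2 = length(pr) * resolution^2,
      bbox_row_min = min(pr), bbox_row_max = max(pr),
      bbox_col_min = min(pc), bbox_col_max = max(pc),
      pixel_count = length(pr)
    )
  })
  dplyr::bind_rows(res)
}

#' Field-survey crown projection area estimate
#'
#' The local empirical relation used for tape-measured peach crowns:
#' `CPA_f = coefficient x W1f x W2f`, with the default coefficient 0.65 (an
#' ellipse-like shape factor calibrated for the orchard; override it per
#' site).
#'
#' @param w1f,w2f Crown widths parallel and perpendicular to the row (m, > 0).
#'   Vectorized.
#' @param coefficient Shape coefficient (default 0.65).
#' @return Estimated crown projection area(s), m^2.
#' @export
field_cpa_estimate <- function(w1f, w2f, coefficient = 0.65) {
  if (any(!is.finite(w1f)) || any(!is.finite(w2f)) ||
      any(w1f <= 0) || any(w2f <= 0))
    stop("crown widths must be positive")
  coefficient * w1f * w2f
}
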