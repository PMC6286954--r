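# Winter-scene scaffold extraction: connected components -> convex hulls.

#' Label tree scaffolds in a binary mask
#'
#' Connected components of the (closed) scaffold mask; components smaller
#' than `min_area` pixels are discarded and the survivors are labelled
#' 1..K in raster-scan order of each component's first pixel.
#'
#' @param mask Logical matrix (e.g. from [close_scaffold()]).
#' @param connectivity 4 or 8 (default 8).
#' @param min_area Minimum component area in pixels.
#' @return Integer label matrix.
#' @export
label_trees <- function(mask, connectivity = 8L, min_area = 25L) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  storage.mode(mask) <- "logical"
  lab <- cc_label_cpp(mask, as.integer(connectivity))
  k <- max(lab)
  if (k > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = k)
    keep <- which(sizes >= min_area)
    if (length(keep) < k) {
      map <- integer(k)
      map[keep] <- seq_along(keep) # renumber, preserving raster-scan order
      lab[lab > 0L] <- map[lab[lab > 0L]]
    }
    k <- length(keep)
  }
  if (k == 0L) stop("no trees found: no component of at least ", min_area, " pixels")
  lab
}

# area centroid of a simple polygon (shoelace); x, y unclosed ring
.polygon_centroid <- function(x, y) {
  n <- length(x)
  xi <- x; yi <- y
  xj <- x[c(2:n, 1)]; yj <- y[c(2:n, 1)]
  cr <- xi * yj - xj * yi
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((xi + xj) * cr) / (6 * a), sum((yi + yj) * cr) / (6 * a))
}

# half-plane rasterization of a convex ring (cell centre inside or on edge)
.fill_convex <- function(hx, hy, rows, cols, eps = 1e-9) {
  n <- length(hx)
  px <- rep(cols, each = length(rows))
  py <- rep(rows, times = length(cols))
  # orient counter-clockwise in (x, y) by shoelace sign
  a2 <- sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)
  if (a2 < 0) { hx <- rev(hx); hy <- rev(hy) }
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & (cr >= -eps)
  }
  matrix(inside, nrow = length(rows), ncol = length(cols))
}

#' Convex scaffold polygons and centroids
#'
#' For each labelled scaffold, computes the convex hull of its pixel centres,
#' the filled hull mask (cell-centre rule), and the hull's area centroid.
#' Components whose pixels are collinear (including 1- and 2-pixel
#' components) are flagged `degenerate`; their "hull mask" is the component
#' itself and their centroid the pixel mean.
#'
#' @param labels Integer label matrix from [label_trees()].
#' @return A tibble of class `convex_scaffolds` with one row per tree:
#'   `tree_id`, `centroid_row`, `centroid_col`, `n_pixels`, `degenerate`, and
#'   list-columns `hull` (vertex matrix, columns `row`,`col`), `bbox`
#'   (`rmin, rmax, cmin, cmax` of the hull mask) and `mask` (local logical
#'   matrix over the bbox). Use [scaffold_hull_mask()] for a full-size mask.
#' @export
convex_scaffolds <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) stop("no labels present")
  rows_all <- row(labels); cols_all <- col(labels)
  out <- lapply(ids, function(k) {
    sel <- labels == k
    pr <- rows_all[sel]; pc <- cols_all[sel]
    hull_idx <- chull(pc, pr) # x = col, y = row
    hx <- pc[hull_idx]; hy <- pr[hull_idx]
    n <- length(hull_idx)
    a2 <- if (n >= 3) abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) else 0
    degenerate <- n < 3 || a2 < 1e-12
    if (degenerate) {
      cen <- c(mean(pc), mean(pr))
      rmin <- min(pr); rmax <- max(pr); cmin <- min(pc); cmax <- max(pc)
      loc <- matrix(FALSE, rmax - rmin + 1L, cmax - cmin + 1L)
      loc[cbind(pr - rmin + 1L, pc - cmin + 1L)] <- TRUE
    } else {
      cen <- .polygon_centroid(hx, hy)
      rmin <- min(hy); rmax <- max(hy); cmin <- min(hx); cmax <- max(hx)
      loc <- .fill_convex(hx, hy, rows = rmin:rmax, cols = cmin:cmax)
    }
    tibble(
      tree_id = k,
      centroid_row = cen[2], centroid_col = cen[1],
      n_pixels = length(pr),
      degenerate = degenerate,
      hull = list(cbind(row = hy, col = hx)),
      bbox = list(c(rmin = rmin, rmax = rmax, cmin = cmin, cmax = cmax)),
      mask = list(loc)
    )
  })
  res <- dplyr::bind_rows(out)
  attr(res, "grid_dim") <- dim(labels)
  class(res) <- c("convex_scaffolds", class(res))
  res
}

#' Materialize a scaffold's filled hull mask on the full grid
#'
#' @param scaffolds A `convex_scaffolds` tibble.
#' @param tree_id Tree id to materialize.
#' @param grid_dim Grid dimensions; defaults to those recorded at extraction.
#' @return Logical matrix.
#' @export
scaffold_hull_mask <- function(scaffolds, tree_id, grid_dim = NULL) {
  grid_dim <- grid_dim %||% attr(scaffolds, "grid_dim")
  i <- match(tree_id, scaffolds$tree_id)
  if (is.na(i)) stop("unknown tree_id: ", tree_id)
  bb <- scaffolds$bbox[[i]]
  m <- matrix(FALSE, grid_dim[1], grid_dim[2])
  m[bb["rmin"]:bb["rmax"], bb["cmin"]:bb["cmax"]] <- scaffolds$mask[[i]]
  m
}
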