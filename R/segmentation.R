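# Growing-season crown segmentation: markers from winter hulls, watershed,
# merging of unreached fragments.

#' Segmentation configuration
#'
#' @param closing_radius Diamond radius (px) for scaffold closing. Leaf-off
#'   orchard DSMs at sub-centimetre resolution typically need 50-80 px.
#' @param window,sensitivity Adaptive-threshold parameters, see
#'   [threshold_params()].
#' @param min_area Minimum scaffold component area (px) kept after closing.
#' @param connectivity Component connectivity, 4 or 8.
#' @param despeckle_min_area Minimum foreground component area (px) kept
#'   *before* closing; removes isolated noise responses that closing would
#'   inflate. Set to 0 to disable.
#' @param max_merge_area Optional guard: unlabelled foliage fragments larger
#'   than this (px) are left unmerged (label 0). Default `Inf` merges all.
#' @return A `segment_config` list.
#' @export
segment_config <- function(closing_radius = 50L, window = NULL,
                           sensitivity = 0.9, min_area = 25L,
                           connectivity = 8L, despeckle_min_area = 64L,
                           max_merge_area = Inf) {
  structure(list(
    closing_radius = as.integer(closing_radius),
    window = window, sensitivity = sensitivity,
    min_area = as.integer(min_area),
    connectivity = as.integer(connectivity),
    despeckle_min_area = as.integer(despeckle_min_area),
    max_merge_area = max_merge_area
  ), class = "segment_config")
}

#' Foliage foreground mask of a growing-season DSM
#'
#' Adaptive threshold of the field-masked foliated raster.
#'
#' @param r Foliated-season [height_raster()].
#' @param field A [polygon_mask()] or `NULL`.
#' @param params A [threshold_params()].
#' @return Logical foreground matrix.
#' @export
foliage_mask <- function(r, field = NULL, params = threshold_params()) {
  rm <- apply_polygon_mask(r, field)
  fg <- adaptive_threshold(rm, params)
  if (!any(fg)) stop("no crowns detected: foliage foreground is empty")
  fg
}

#' Build watershed markers from scaffold hulls
#'
#' Marker `k` covers `hull_mask(k)` intersected with the foliage foreground.
#' Where two hulls overlap, the pixel goes to the hull whose centroid is
#' nearer (ties to the lower `tree_id`). Trees whose intersection is empty
#' are reported in the `"unseeded"` attribute and absent from the markers.
#'
#' @param scaffolds A `convex_scaffolds` tibble ([convex_scaffolds()]).
#' @param foliage Logical foliage mask on the same grid.
#' @return Integer marker matrix with attribute `unseeded` (tree ids).
#' @export
build_markers <- function(scaffolds, foliage) {
  stopifnot(inherits(scaffolds, "convex_scaffolds"), is.matrix(foliage))
  gd <- attr(scaffolds, "grid_dim")
  if (!is.null(gd) && !identical(as.integer(gd), as.integer(dim(foliage))))
    stop("scaffold hulls and foliage mask are on different grids")
  nr <- nrow(foliage); nc <- ncol(foliage)
  markers <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(scaffolds))) {
    k <- scaffolds$tree_id[i]
    bb <- scaffolds$bbox[[i]]
    rows <- bb["rmin"]:bb["rmax"]; cols <- bb["cmin"]:bb["cmax"]
    loc <- scaffolds$mask[[i]] & foliage[rows, cols, drop = FALSE]
    if (!any(loc)) next
    idx <- which(loc, arr.ind = TRUE)
    pr <- rows[idx[, 1]]; pc <- cols[idx[, 2]]
    lin <- pr + (pc - 1L) * nr
    prev <- markers[lin]
    fresh <- prev == 0L
    markers[lin[fresh]] <- k
    if (any(!fresh)) {
      # contested pixel: nearer hull centroid wins, ties to lower tree_id
      pj <- which(!fresh)
      for (j in pj) {
        other <- prev[j]
        io <- match(other, scaffolds$tree_id)
        d_new <- (pr[j] - scaffolds$centroid_row[i])^2 +
                 (pc[j] - scaffolds$centroid_col[i])^2
        d_old <- (pr[j] - scaffolds$centroid_row[io])^2 +
                 (pc[j] - scaffolds$centroid_col[io])^2
        if (d_new < d_old || (d_new == d_old && k < other))
          markers[lin[j]] <- k
      }
    }
  }
  present <- unique(markers[markers > 0L])
  unseeded <- setdiff(scaffolds$tree_id, present)
  if (length(present) == 0L) stop("no markers: every hull misses the foliage mask")
  attr(markers, "unseeded") <- unseeded
  markers
}

#' Marker-controlled watershed on a height raster
#'
#' Floods the negated height surface (crowns are basins) from the marker
#' regions, restricted to the foliage mask. Marker pixels keep their labels;
#' every foliage pixel 8-connected to a marker receives exactly one label;
#' foliage components touching no marker stay 0 (see [merge_small_parts()]).
#' Flooding is fully deterministic: the highest unclaimed pixel is claimed
#' next, FIFO among equal heights, neighbours pushed in N, E, S, W, NE, SE,
#' SW, NW order from seeds taken in raster-scan order.
#'
#' @param r Foliated-season [height_raster()].
#' @param markers Integer marker matrix ([build_markers()]).
#' @param foliage Logical foliage mask.
#' @return Integer label matrix.
#' @export
marker_watershed <- function(r, markers, foliage) {
  stopifnot(inherits(r, "height_raster"))
  if (!any(markers > 0L)) stop("watershed needs at least one non-empty marker")
  storage.mode(markers) <- "integer"
  storage.mode(foliage) <- "logical"
  watershed_flood_cpp(r$values, markers, foliage)
}

#' Merge unlabelled foliage fragments into the nearest crown
#'
#' Each connected foliage component left with label 0 after flooding is
#' wholly assigned to the tree whose hull centroid is nearest (Euclidean
#' distance to the component's pixel centroid; ties to the lower `tree_id`).
#'
#' @param labels Integer label matrix from [marker_watershed()].
#' @param foliage Logical foliage mask.
#' @param scaffolds A `convex_scaffolds` tibble (supplies hull centroids).
#' @param max_merge_area Fragments larger than this stay unmerged.
#' @return Integer label matrix; with the default guard every foliage pixel
#'   ends up labelled.
#' @export
merge_small_parts <- function(labels, foliage, scaffolds, max_merge_area = Inf) {
  stopifnot(is.matrix(labels), is.matrix(foliage))
  if (!inherits(scaffolds, "convex_scaffolds") || nrow(scaffolds) == 0L)
    stop("no scaffolds to merge into")
  storage.mode(labels) <- "integer"
  orphan <- foliage & labels == 0L
  if (!any(orphan)) return(labels)
  comp <- cc_label_cpp(orphan, 8L)
  ncomp <- max(comp)
  rows <- row(comp); cols <- col(comp)
  cen_r <- scaffolds$centroid_row; cen_c <- scaffolds$centroid_col
  ids <- scaffolds$tree_id
  for (k in seq_len(ncomp)) {
    sel <- comp == k
    npix <- sum(sel)
    if (npix > max_merge_area) next
    pr <- mean(rows[sel]); pc <- mean(cols[sel])
    d2 <- (pr - cen_r)^2 + (pc - cen_c)^2
    best <- which(d2 == min(d2))
    lab <- min(ids[best]) # ties -> lower tree_id
    labels[sel] <- lab
  }
  labels
}

#' Segment individual crowns from a dual-season DSM pair
#'
#' End-to-end pipeline: (1) adaptive threshold + field mask on both scenes;
#' (2) despeckle, diamond closing, and component labelling of the leaf-off
#' scene, then per-tree convex hulls and centroids; (3) markers = hull x
#' foliage intersection, marker-controlled watershed on the foliated scene;
#' (4) merging of unreached foliage fragments. Deterministic for fixed inputs
#' and configuration.
#'
#' @param bare Leaf-off (bare-branch) [height_raster()].
#' @param foliated Growing-season [height_raster()], co-registered with
#'   `bare` (same shape and resolution).
#' @param field A [polygon_mask()] or `NULL`.
#' @param config A [segment_config()].
#' @return An object of class `crown_segmentation`: list with `labels`
#'   (integer matrix), `scaffolds` (`convex_scaffolds` tibble), `foliage`
#'   (logical mask), `unseeded` (tree ids with empty markers), `resolution`,
#'   and `stats` (per-stage counts).
#' @export
segment_trees <- function(bare, foliated, field = NULL,
                          config = segment_config()) {
  stopifnot(inherits(bare, "height_raster"), inherits(foliated, "height_raster"))
  if (!identical(dim(bare$values), dim(foliated$values)) ||
      abs(bare$resolution - foliated$resolution) > 1e-12)
    stop("not co-registered: rasters differ in shape or resolution")
  tp <- threshold_params(config$window, config$sensitivity)

  # winter: scaffold extraction
  bare_m <- apply_polygon_mask(bare, field)
  scaff_fg <- adaptive_threshold(bare_m, tp)
  if (!any(scaff_fg)) stop("scaffold stage: empty foreground in bare-branch scene")
  scaff_fg <- remove_speckle(scaff_fg, config$despeckle_min_area, config$connectivity)
  closed <- close_scaffold(scaff_fg, config$closing_radius)
  tree_lab <- label_trees(closed, config$connectivity, config$min_area)
  scaffolds <- convex_scaffolds(tree_lab)

  # summer: foliage mask, markers, watershed, merging
  foliage <- foliage_mask(foliated, field, tp)
  markers <- build_markers(scaffolds, foliage)
  flooded <- marker_watershed(foliated, markers, foliage)
  labels <- merge_small_parts(flooded, foliage, scaffolds, config$max_merge_area)

  stats <- list(
    n_scaffold_px = sum(scaff_fg),
    n_trees = nrow(scaffolds),
    n_foliage_px = sum(foliage),
    n_marker_px = sum(markers > 0L),
    n_unseeded = length(attr(markers, "unseeded")),
    n_merged_px = sum(labels > 0L) - sum(flooded > 0L)
  )
  structure(list(
    labels = labels, scaffolds = scaffolds, foliage = foliage,
    unseeded = attr(markers, "unseeded"),
    resolution = foliated$resolution, config = config, stats = stats
  ), class = "crown_segmentation")
}

#' @export
print.crown_segmentation <- function(x, ...) {
  cat(sprintf(
    "<crown_segmentation> %d trees, %d labelled px (%.2f m2), %d unseeded\n",
    x$stats$n_trees, sum(x$labels > 0L),
    sum(x$labels > 0L) * x$resolution^2, x$stats$n_unseeded
  ))
  invisible(x)
}
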