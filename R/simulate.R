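# Synthetic orchard scenes: paired bare-branch and foliated DSM rasters with
# ground truth, emulating UAV photogrammetry of an open-centre peach orchard.

#' Synthetic orchard specification
#'
#' Defines a rectangular planting of `n_rows x n_cols` trees. Planting rows
#' run along the raster's column axis (so `W1`, parallel to the row, is a
#' column extent). Each tree carries an open-centre scaffold — two
#' predominant limbs oriented perpendicular to the row plus minor limbs at
#' random azimuths, rendered as thin elevated ridges — and, in season, a
#' smooth dome (ellipsoidal-cap) crown. Scene heights are the ideal ground
#' plane + surfaces, plus i.i.d. Gaussian height noise, then a Gaussian
#' surface smoothing (`smooth_sd`, metres on the ground) that emulates the
#' low-pass character photogrammetric noise filtering imprints on real DSMs;
#' set `smooth_sd = 0` for raw white noise.
#'
#' @param n_rows,n_cols Number of planting rows and trees per row.
#' @param row_spacing,tree_spacing Spacing between rows / within a row (m).
#' @param margin Clearance between the outermost tree centres and the raster
#'   edge (m); must exceed the largest crown radius.
#' @param resolution Ground sampling distance (m/pixel), default 0.01.
#' @param crown_radius,crown_height Ranges (m) for per-tree crown radius and
#'   dome height.
#' @param scaffold_height Range (m) of scaffold ridge heights.
#' @param major_arm_length,minor_arm_length Limb length ranges (m).
#' @param major_arm_width,minor_arm_width Limb ridge widths (m).
#' @param n_minor_arms Minor limbs per tree.
#' @param overlap_factor In `[0, 1)`: 0 keeps the drawn radii (disjoint by
#'   construction when `tree_spacing > 2 * max(crown_radius)`); larger values
#'   inflate all radii by `1 + overlap_factor * tree_spacing /
#'   sum(crown_radius range)`, pushing neighbouring crowns into overlap.
#' @param noise_sd Standard deviation of the additive height noise (m).
#' @param smooth_sd Gaussian surface-smoothing scale (m); 0 disables.
#' @param ground_elevation Ground-plane height at the raster centre (m).
#' @param ground_slope Ground slope `c(per-row, per-col)` in m/m.
#' @param crown_profile `"dome"` (single ellipsoidal cap) or `"open_centre"`
#'   (two offset half-domes along the limb axis, giving the multi-maximum
#'   crowns that over-segment a naive watershed).
#' @param seed Integer seed fixing every random draw.
#' @return An `orchard_spec` list.
#' @export
orchard_spec <- function(n_rows = 3L, n_cols = 4L,
                         row_spacing = 6, tree_spacing = 6, margin = 3,
                         resolution = 0.01,
                         crown_radius = c(1.2, 1.5),
                         crown_height = c(2.0, 3.0),
                         scaffold_height = c(1.8, 2.8),
                         major_arm_length = c(1.0, 1.3),
                         minor_arm_length = c(0.6, 1.0),
                         major_arm_width = 0.12,
                         minor_arm_width = 0.06,
                         n_minor_arms = 4L,
                         overlap_factor = 0,
                         noise_sd = 0.02,
                         smooth_sd = 0.02,
                         ground_elevation = 0,
                         ground_slope = c(0, 0),
                         crown_profile = c("dome", "open_centre"),
                         seed = 1L) {
  crown_profile <- match.arg(crown_profile)
  stopifnot(
    n_rows >= 1, n_cols >= 1, row_spacing > 0, tree_spacing > 0,
    resolution > 0, margin > 0, noise_sd >= 0, smooth_sd >= 0,
    overlap_factor >= 0, overlap_factor < 1
  )
  structure(as.list(environment()), class = "orchard_spec")
}

# deterministic per-tree parameters; the scene seed governs everything
.tree_params <- function(spec) {
  set.seed(spec$seed %% .Machine$integer.max)
  grid <- expand.grid(row = seq_len(spec$n_rows), col = seq_len(spec$n_cols))
  n <- nrow(grid)
  infl <- 1 + spec$overlap_factor * spec$tree_spacing / sum(spec$crown_radius)
  tibble(
    tree_id = seq_len(n),
    # planting rows run along columns: within-row offset is a column offset
    centre_row_m = spec$margin + (grid$row - 1) * spec$row_spacing,
    centre_col_m = spec$margin + (grid$col - 1) * spec$tree_spacing,
    crown_radius_m = runif(n, spec$crown_radius[1], spec$crown_radius[2]) * infl,
    crown_height_m = runif(n, spec$crown_height[1], spec$crown_height[2]),
    scaffold_height_m = runif(n, spec$scaffold_height[1], spec$scaffold_height[2]),
    major_len_m = runif(n, spec$major_arm_length[1], spec$major_arm_length[2]),
    major_jitter = runif(n, -10, 10) * pi / 180,
    minor_angles = lapply(seq_len(n), function(i)
      runif(spec$n_minor_arms, 0, 2 * pi)),
    minor_len_m = lapply(seq_len(n), function(i)
      runif(spec$n_minor_arms, spec$minor_arm_length[1], spec$minor_arm_length[2])),
    lobe_offset_m = runif(n, 0.35, 0.5) # open-centre lobe offset, x radius
  )
}

.scene_dim <- function(spec) {
  nr <- round((2 * spec$margin + (spec$n_rows - 1) * spec$row_spacing) / spec$resolution)
  nc <- round((2 * spec$margin + (spec$n_cols - 1) * spec$tree_spacing) / spec$resolution)
  c(as.integer(nr), as.integer(nc))
}

.ground_plane <- function(spec, dims) {
  rr <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * spec$resolution
  cc <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * spec$resolution
  spec$ground_elevation +
    outer(rr * spec$ground_slope[1], cc * spec$ground_slope[2], "+")
}

# distance from pixel centres (metre coords) to the segment [a, a + L*u]
.seg_dist <- function(pr, pc, ar, ac, ur, uc, len) {
  t <- pmin(pmax((pr - ar) * ur + (pc - ac) * uc, 0), len)
  sqrt((pr - (ar + t * ur))^2 + (pc - (ac + t * uc))^2)
}

# render one tree's noiseless surface into the full-scene `surface` matrix;
# returns the updated surface and the tree's footprint bbox
.render_patch <- function(spec, dims, centre_r, centre_c, radius_m, fun) {
  res <- spec$resolution
  r0 <- max(1L, floor((centre_r - radius_m) / res)); r1 <- min(dims[1], ceiling((centre_r + radius_m) / res) + 1L)
  c0 <- max(1L, floor((centre_c - radius_m) / res)); c1 <- min(dims[2], ceiling((centre_c + radius_m) / res) + 1L)
  if (r0 > r1 || c0 > c1) stop("tree overflows the raster extent")
  rows <- r0:r1; cols <- c0:c1
  pr <- (rows - 0.5) * res; pc <- (cols - 0.5) * res
  h <- fun(rep(pr, times = length(cols)), rep(pc, each = length(rows)))
  list(rows = rows, cols = cols,
       h = matrix(h, length(rows), length(cols)))
}

.check_extent <- function(spec, params, reach) {
  dims <- .scene_dim(spec)
  lim_r <- dims[1] * spec$resolution; lim_c <- dims[2] * spec$resolution
  bad <- params$centre_row_m - reach < 0 | params$centre_row_m + reach > lim_r |
         params$centre_col_m - reach < 0 | params$centre_col_m + reach > lim_c
  if (any(bad)) stop("tree overflows the raster extent; increase `margin`")
}

#' Generate a bare-branch (leaf-off) scene
#'
#' Ground plane plus, per tree, an open-centre scaffold: two predominant
#' limbs perpendicular to the planting row and `n_minor_arms` minor limbs,
#' rendered as thin ridges at the tree's scaffold height. Deterministic for
#' a fixed spec.
#'
#' @param spec An [orchard_spec()].
#' @return A list: `raster` ([height_raster()]), `truth` (list with `trees`,
#'   the per-tree parameter tibble; `labels`, the integer footprint truth of
#'   the noiseless ridge set; `records`, [crown_metrics()] of those labels).
#' @export
generate_bare_scene <- function(spec) {
  stopifnot(inherits(spec, "orchard_spec"))
  params <- .tree_params(spec)
  dims <- .scene_dim(spec)
  reach <- max(params$major_len_m) + spec$major_arm_width
  .check_extent(spec, params, reach)
  surface <- matrix(0, dims[1], dims[2])
  labels <- matrix(0L, dims[1], dims[2])
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    arms <- list()
    # predominant limbs run perpendicular to the planting row (row axis)
    for (sgn in c(-1, 1)) {
      ang <- p$major_jitter + if (sgn > 0) 0 else pi
      arms[[length(arms) + 1L]] <- list(
        ur = cos(ang), uc = sin(ang), len = p$major_len_m,
        w = spec$major_arm_width
      )
    }
    for (j in seq_along(p$minor_angles[[1]])) {
      ang <- p$minor_angles[[1]][j]
      arms[[length(arms) + 1L]] <- list(
        ur = cos(ang), uc = sin(ang), len = p$minor_len_m[[1]][j],
        w = spec$minor_arm_width
      )
    }
    patch_fun <- function(pr, pc) {
      h <- numeric(length(pr))
      for (a in arms) {
        d <- .seg_dist(pr, pc, p$centre_row_m, p$centre_col_m, a$ur, a$uc, a$len)
        h[d <= a$w / 2] <- p$scaffold_height_m
      }
      h
    }
    pt <- .render_patch(spec, dims, p$centre_row_m, p$centre_col_m,
                        reach + 0.05, patch_fun)
    blk <- surface[pt$rows, pt$cols]
    surface[pt$rows, pt$cols] <- pmax(blk, pt$h)
    lb <- labels[pt$rows, pt$cols]
    lb[pt$h > 0 & lb == 0L] <- p$tree_id
    labels[pt$rows, pt$cols] <- lb
  }
  raster <- .finish_scene(spec, surface, noise_seed = spec$seed + 1L)
  truth <- list(
    trees = params, labels = labels,
    records = crown_metrics(labels, spec$resolution)
  )
  list(raster = raster, truth = truth)
}

.finish_scene <- function(spec, surface, noise_seed) {
  dims <- dim(surface)
  v <- .ground_plane(spec, dims) + surface
  if (spec$noise_sd > 0) {
    set.seed(noise_seed %% .Machine$integer.max)
    v <- v + matrix(rnorm(length(v), 0, spec$noise_sd), dims[1], dims[2])
  }
  if (spec$smooth_sd > 0)
    v <- gaussian_blur_cpp(v, spec$smooth_sd / spec$resolution)
  height_raster(v, spec$resolution)
}

# noiseless crown surface of tree i at metre coords (pr, pc)
.crown_surface_fun <- function(spec, p, growth_scale) {
  r <- p$crown_radius_m * growth_scale
  h <- p$crown_height_m
  if (spec$crown_profile == "dome") {
    function(pr, pc) {
      d2 <- (pr - p$centre_row_m)^2 + (pc - p$centre_col_m)^2
      h * sqrt(pmax(0, 1 - d2 / r^2))
    }
  } else {
    # two offset caps along the limb axis (row direction), echoing the
    # open-centre training; lobe radius shrinks so the footprint stays ~r
    off <- p$lobe_offset_m * r
    rl <- r - off
    function(pr, pc) {
      s <- numeric(length(pr))
      for (sgn in c(-1, 1)) {
        d2 <- (pr - (p$centre_row_m + sgn * off))^2 + (pc - p$centre_col_m)^2
        s <- pmax(s, h * sqrt(pmax(0, 1 - d2 / rl^2)))
      }
      s
    }
  }
}

#' Generate a foliated (growing-season) scene
#'
#' Per tree, a smooth dome crown `h * sqrt(max(0, 1 - (d/r)^2))` above the
#' ground plane, with the radius scaled by `growth_scale`; overlapping crowns
#' composite by pointwise maximum. Truth labels partition the union of the
#' noiseless footprints, contested pixels going to the taller surface (ties
#' to the lower `tree_id`); truth records are [crown_metrics()] of those
#' labels.
#'
#' @param spec An [orchard_spec()].
#' @param growth_scale Multiplier (> 0) on every crown radius.
#' @param noise_seed Seed for this scene's noise realization; defaults to
#'   `spec$seed + 2`.
#' @return A list: `raster` ([height_raster()]) and `truth` (list with
#'   `trees`, `labels`, `records`).
#' @export
generate_foliated_scene <- function(spec, growth_scale = 1, noise_seed = NULL) {
  stopifnot(inherits(spec, "orchard_spec"), growth_scale > 0)
  params <- .tree_params(spec)
  dims <- .scene_dim(spec)
  .check_extent(spec, params, max(params$crown_radius_m) * growth_scale)
  surface <- matrix(0, dims[1], dims[2])
  best <- matrix(0, dims[1], dims[2]) # tallest noiseless height so far
  labels <- matrix(0L, dims[1], dims[2])
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    fun <- .crown_surface_fun(spec, p, growth_scale)
    pt <- .render_patch(spec, dims, p$centre_row_m, p$centre_col_m,
                        p$crown_radius_m * growth_scale + 0.05, fun)
    blk <- surface[pt$rows, pt$cols]
    surface[pt$rows, pt$cols] <- pmax(blk, pt$h)
    bb <- best[pt$rows, pt$cols]
    lb <- labels[pt$rows, pt$cols]
    take <- pt$h > 0 & (pt$h > bb) # strict: ties stay with the lower id
    lb[take] <- p$tree_id
    bb[take] <- pt$h[take]
    best[pt$rows, pt$cols] <- bb
    labels[pt$rows, pt$cols] <- lb
  }
  raster <- .finish_scene(spec, surface,
                          noise_seed = noise_seed %||% (spec$seed + 2L))
  truth <- list(
    trees = params, labels = labels,
    records = crown_metrics(labels, spec$resolution)
  )
  list(raster = raster, truth = truth)
}

#' Generate a time series of foliated scenes
#'
#' One foliated scene per date, sharing tree positions and per-tree
#' parameters; only the crown radii change through `growth_scales` (and the
#' noise realization per date). The truth CPA table feeds [growth_rates()].
#'
#' @param spec An [orchard_spec()].
#' @param growth_scales Numeric vector of radius multipliers, one per date.
#' @param dates Vector of dates (Date or ISO-8601 strings), strictly
#'   increasing, same length as `growth_scales`.
#' @return A list: `scenes` (list of scene lists as from
#'   [generate_foliated_scene()]) and `truth_cpa` (tibble `tree_id`, `date`,
#'   `CPA_m2`).
#' @export
generate_time_series <- function(spec, growth_scales, dates) {
  dates <- as.Date(dates)
  if (length(growth_scales) != length(dates))
    stop("growth_scales and dates must have the same length")
  if (any(diff(dates) <= 0)) stop("dates must be strictly increasing")
  scenes <- vector("list", length(dates))
  cpa <- vector("list", length(dates))
  for (i in seq_along(dates)) {
    sc <- generate_foliated_scene(spec, growth_scales[i],
                                  noise_seed = spec$seed + 100L + i)
    scenes[[i]] <- sc
    cpa[[i]] <- dplyr::mutate(
      dplyr::select(sc$truth$records, "tree_id", "CPA_m2"),
      date = dates[i], .after = "tree_id"
    )
  }
  list(scenes = scenes, truth_cpa = dplyr::bind_rows(cpa))
}

#' Raster heat-map of a height raster
#'
#' @param object A [height_raster()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot height_raster
#' @export
autoplot.height_raster <- function(object, ...) {
  df <- tibble(
    row = as.vector(row(object$values)),
    col = as.vector(col(object$values)),
    height = as.vector(object$values)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = "height (m)") +
    ggplot2::theme_minimal()
}

#' Plot a crown label raster
#'
#' @param labels Integer label matrix or a `crown_segmentation` object.
#' @return A ggplot; background (0) is blank.
#' @export
plot_label_raster <- function(labels) {
  if (inherits(labels, "crown_segmentation")) labels <- labels$labels
  df <- tibble(
    row = as.vector(row(labels)),
    col = as.vector(col(labels)),
    label = as.vector(labels)
  )
  df <- df[df$label > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$label))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = "tree") +
    ggplot2::theme_minimal()
}

#' @method autoplot crown_segmentation
#' @export
autoplot.crown_segmentation <- function(object, ...) plot_label_raster(object)
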