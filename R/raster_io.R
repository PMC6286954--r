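# Height rasters, polygon field masks, and table I/O.
#
# Grid convention: `values[r, c]` with row 1 at the top, pixel centres at
# integer coordinates (r, c), half-open pixel extents. All geometry is done
# in pixel space scaled by `resolution` (metres/pixel); the optional origin
# is carried only for I/O. Nodata cells are NA internally.

#' Construct a height raster
#'
#' A height raster is a 2-D grid of surface heights in metres with a ground
#' sampling distance (`resolution`, metres/pixel). Invalid or masked cells
#' are stored as `NA`.
#'
#' @param values Numeric matrix of heights (metres); `NA` marks nodata.
#' @param resolution Ground sampling distance in metres/pixel (> 0).
#' @param origin Optional numeric `c(x, y)` world coordinate of the centre of
#'   pixel (1, 1); used only when reading/writing georeferenced files.
#' @return An object of class `height_raster`.
#' @export
height_raster <- function(values, resolution, origin = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must have at least one row and one column")
  if (!is.numeric(resolution) || length(resolution) != 1L || !is.finite(resolution) ||
      resolution <= 0)
    stop("`resolution` must be a single positive number")
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite heights present; use NA for nodata")
  storage.mode(values) <- "double"
  structure(
    list(values = values, resolution = as.numeric(resolution), origin = origin),
    class = "height_raster"
  )
}

#' @export
print.height_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<height_raster> %d x %d px @ %.4g m/px (%.4g x %.4g m), %d nodata cells\n",
    nrow(v), ncol(v), x$resolution,
    nrow(v) * x$resolution, ncol(v) * x$resolution, sum(is.na(v))
  ))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf("  height range: [%.3f, %.3f] m\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.height_raster <- function(x) dim(x$values)

.is_asc <- function(path) grepl("\\.asc$", path, ignore.case = TRUE)
.is_tif <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

#' Read a height raster
#'
#' Supports the Esri ASCII grid format (`.asc`, plain text, carries the cell
#' size and nodata sentinel) and single-band TIFF (`.tif`/`.tiff`) with an
#' accompanying JSON sidecar (`<file>.json`) holding `resolution`, and
#' optionally `nodata` and `origin`. Rectangular (non-square) pixels are
#' rejected.
#'
#' @param path Path to the raster file.
#' @param resolution Optional resolution override (m/pixel); required for a
#'   TIFF without sidecar.
#' @param band Band to read from a multi-band TIFF (an error is raised if the
#'   file is multi-band and `band` is not given).
#' @return A [height_raster()].
#' @export
read_height_raster <- function(path, resolution = NULL, band = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (.is_asc(path)) {
    r <- .read_asc(path)
    if (!is.null(resolution)) r$resolution <- resolution
    return(r)
  }
  if (.is_tif(path)) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) {
      if (is.null(band))
        stop("multi-band raster: select a band with `band =`")
      img <- img[, , band]
    }
    side <- .read_sidecar(path)
    res <- resolution %||% side$resolution
    if (is.null(res)) stop("resolution unknown: supply `resolution =` or a sidecar")
    if (length(res) == 2L) {
      if (abs(res[1] - res[2]) > 1e-12) stop("non-square pixels")
      res <- res[1]
    }
    if (!is.null(side$nodata)) img[img == side$nodata] <- NA
    return(height_raster(img, res, origin = side$origin))
  }
  stop("unsupported raster format (use .asc or .tif): ", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) return(list())
  jsonlite::fromJSON(sc, simplifyVector = TRUE)
}

.read_asc <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nhdr <- nhdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ASCII grid header missing: ", paste(miss, collapse = ", "))
  vals <- scan(path, what = double(), skip = nhdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("ASCII grid: expected ", nr * nc, " values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE) # first data row = top row
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  origin <- NULL
  if (!is.null(hdr$xllcorner) && !is.null(hdr$yllcorner))
    origin <- c(x = hdr$xllcorner + hdr$cellsize / 2,
                y = hdr$yllcorner + hdr$cellsize / 2)
  height_raster(m, hdr$cellsize, origin = origin)
}

#' Write a height raster
#'
#' Writes the Esri ASCII grid format (`.asc`); nodata cells are written as
#' the `nodata` sentinel. Values are written with enough digits for an exact
#' round-trip of integer-valued grids and ~1e-8 relative precision otherwise.
#'
#' @param r A [height_raster()].
#' @param path Output path ending in `.asc`.
#' @param nodata Sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_height_raster <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "height_raster"))
  if (!.is_asc(path))
    stop("unsupported output format (use .asc): ", path)
  .write_asc(r$values, r$resolution, path, nodata, r$origin)
}

.write_asc <- function(m, res, path, nodata, origin = NULL) {
  nr <- nrow(m); nc <- ncol(m)
  xll <- if (!is.null(origin)) origin[[1]] - res / 2 else 0
  yll <- if (!is.null(origin)) origin[[2]] - res / 2 else 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", res),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  m[is.na(m)] <- nodata
  # one text row per raster row, top row first
  txt <- apply(m, 1L, function(row) paste(sprintf("%.10g", row), collapse = " "))
  writeLines(txt, con)
  invisible(path)
}

#' Read / write a crown label raster
#'
#' Label rasters are non-negative integer grids (0 = background) stored as
#' ASCII grids; the round-trip is lossless.
#'
#' @param labels Integer matrix of crown labels.
#' @param path File path (`.asc`).
#' @param resolution Ground sampling distance recorded in the file.
#' @return `write_label_raster()` returns `path` invisibly;
#'   `read_label_raster()` returns a list with `labels` (integer matrix) and
#'   `resolution`.
#' @export
write_label_raster <- function(labels, path, resolution = 1) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  if (any(is.na(labels)) || any(labels < 0))
    stop("labels must be non-negative integers")
  .write_asc(labels, resolution, path, nodata = -1)
}

#' @rdname write_label_raster
#' @export
read_label_raster <- function(path) {
  r <- .read_asc(path)
  m <- r$values
  if (any(is.na(m))) m[is.na(m)] <- 0
  if (any(abs(m - round(m)) > 0)) stop("label raster contains non-integer values")
  storage.mode(m) <- "integer"
  list(labels = m, resolution = r$resolution)
}

# ---- polygon field mask ----------------------------------------------------

#' Construct a polygon mask
#'
#' A simple closed ring in the raster's pixel coordinate frame: `x` runs along
#' columns and `y` along rows, both in pixel units with pixel (1, 1) centred
#' at (1, 1).
#'
#' @param x,y Numeric vertex coordinates (>= 3 vertices, unclosed ring).
#' @return An object of class `polygon_mask`.
#' @export
polygon_mask <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  # drop an explicitly closed last vertex
  n <- length(x)
  if (n >= 2L && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  if (n < 3L) stop("polygon needs at least 3 vertices")
  if (.ring_self_intersects(x, y)) stop("polygon ring is self-intersecting")
  structure(list(x = as.numeric(x), y = as.numeric(y)), class = "polygon_mask")
}

.ring_self_intersects <- function(x, y) {
  n <- length(x)
  seg <- function(i) c(i, i %% n + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      si <- seg(i); sj <- seg(j)
      if (any(si %in% sj)) next # adjacent segments share a vertex
      if (.segments_cross(x[si[1]], y[si[1]], x[si[2]], y[si[2]],
                          x[sj[1]], y[sj[1]], x[sj[2]], y[sj[2]])) return(TRUE)
    }
  }
  FALSE
}

.segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o <- function(px, py, qx, qy, rx, ry) sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  o1 <- o(ax, ay, bx, by, cx, cy); o2 <- o(ax, ay, bx, by, dx, dy)
  o3 <- o(cx, cy, dx, dy, ax, ay); o4 <- o(cx, cy, dx, dy, bx, by)
  (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
}

#' Read a field-boundary polygon from GeoJSON
#'
#' Accepts a GeoJSON `Polygon` geometry, `Feature`, or `FeatureCollection`
#' (first feature); only the exterior ring is used. Coordinates may be in
#' pixel units (`frame = "pixel"`, the default) or in the world frame of a
#' raster's origin/resolution (`frame = "world"`, converted by
#' [apply_polygon_mask()]).
#'
#' @param path GeoJSON file path.
#' @param frame Coordinate frame of the file, `"pixel"` or `"world"`.
#' @return A `polygon_mask` (with a `frame` attribute).
#' @export
read_field_polygon <- function(path, frame = c("pixel", "world")) {
  frame <- match.arg(frame)
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geom <- switch(g$type %||% "",
    "FeatureCollection" = g$features[[1]]$geometry,
    "Feature" = g$geometry,
    "Polygon" = g,
    stop("unsupported GeoJSON type: ", g$type %||% "<missing>")
  )
  if (geom$type != "Polygon") stop("expected a Polygon geometry, got ", geom$type)
  ring <- geom$coordinates[[1]]
  x <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
  y <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
  m <- polygon_mask(x, y)
  attr(m, "frame") <- frame
  m
}

# Even-odd point-in-polygon, boundary-inclusive: a point on an edge (within
# eps) counts as inside, matching the cell-centre inclusion rule.
.points_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint[crosses])
    }
    # on-segment test
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - xi) * dx + (py - yi) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
      onedge <- onedge | d2 <= eps^2
    } else {
      onedge <- onedge | ((px - xi)^2 + (py - yi)^2 <= eps^2)
    }
    j <- i
  }
  inside | onedge
}

#' Apply a field-boundary polygon mask to a height raster
#'
#' Cells whose centres fall outside the polygon (even-odd rule, boundary
#' inclusive) are set to nodata; inside cells are untouched, so masking is
#' idempotent.
#'
#' @param r A [height_raster()].
#' @param m A [polygon_mask()], or `NULL` for no masking.
#' @return A masked [height_raster()] of identical shape.
#' @export
apply_polygon_mask <- function(r, m) {
  stopifnot(inherits(r, "height_raster"))
  if (is.null(m)) return(r)
  stopifnot(inherits(m, "polygon_mask"))
  vx <- m$x; vy <- m$y
  if (identical(attr(m, "frame"), "world")) {
    if (is.null(r$origin)) stop("world-frame polygon but raster has no origin")
    vx <- (vx - r$origin[[1]]) / r$resolution + 1
    vy <- (vy - r$origin[[2]]) / r$resolution + 1
  }
  nr <- nrow(r$values); nc <- ncol(r$values)
  px <- rep(seq_len(nc), each = nr)   # x = column
  py <- rep(seq_len(nr), times = nc)  # y = row
  keep <- .points_in_polygon(px, py, vx, vy)
  if (!any(keep)) stop("empty field region: polygon excludes every cell centre")
  v <- r$values
  v[!keep] <- NA
  height_raster(v, r$resolution, origin = r$origin)
}

# ---- tables ----------------------------------------------------------------

.crown_cols <- c("tree_id", "W1_m", "W2_m", "CPA_m2",
                 "bbox_row_min", "bbox_row_max", "bbox_col_min", "bbox_col_max")

#' Write / read a per-tree crown table
#'
#' CSV with columns `tree_id, W1_m, W2_m, CPA_m2, bbox_row_min, bbox_row_max,
#' bbox_col_min, bbox_col_max` (additional columns are preserved).
#'
#' @param records Data frame of crown records (see [crown_metrics()]).
#' @param path CSV path.
#' @return `write_crown_table()` returns `path` invisibly;
#'   `read_crown_table()` returns a tibble.
#' @export
write_crown_table <- function(records, path) {
  records <- as.data.frame(records)
  miss <- setdiff(.crown_cols, names(records))
  if (length(miss)) stop("crown table missing column: ", paste(miss, collapse = ", "))
  ord <- c(.crown_cols, setdiff(names(records), .crown_cols))
  write.csv(records[, ord, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_crown_table
#' @export
read_crown_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.crown_cols, names(df))
  if (length(miss)) stop("crown table missing column: ", paste(miss, collapse = ", "))
  as_tibble(df)
}

#' Read a reference-measurement table
#'
#' CSV with columns `tree_id`, `W1_m`, `W2_m` and optionally `CPA_m2`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_reference_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (colname in c("tree_id", "W1_m", "W2_m")) {
    if (!colname %in% names(df))
      stop("reference table missing column: ", colname)
  }
  as_tibble(df)
}

#' Export crown outlines as GeoJSON
#'
#' Traces the 0.5-level contour of each crown's label mask (marching squares)
#' and writes a GeoJSON FeatureCollection with one MultiPolygon feature per
#' tree, in pixel coordinates (x = column, y = row). Holes are not traced.
#'
#' @param labels Integer label matrix.
#' @param path Output GeoJSON path.
#' @return `path`, invisibly.
#' @export
write_crown_outlines <- function(labels, path) {
  ids <- sort(unique(labels[labels > 0]))
  feats <- lapply(ids, function(k) {
    mk <- matrix(0, nrow(labels) + 2L, ncol(labels) + 2L)
    mk[2:(nrow(labels) + 1L), 2:(ncol(labels) + 1L)] <- (labels == k) * 1
    # contourLines works on z[x, y]: feed rows as x (row index - 1 after pad)
    cl <- contourLines(x = seq_len(nrow(mk)) - 1, y = seq_len(ncol(mk)) - 1,
                       z = mk, levels = 0.5)
    rings <- lapply(cl, function(cc) {
      xs <- cc$y; ys <- cc$x # back to x = column, y = row
      coords <- Map(function(a, b) c(a, b), xs, ys)
      coords[[length(coords) + 1L]] <- coords[[1L]]
      list(coords)
    })
    list(
      type = "Feature",
      properties = list(tree_id = k),
      geometry = list(type = "MultiPolygon", coordinates = rings)
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
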