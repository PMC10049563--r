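#' Regular grid specification
#'
#' Planar, axis-aligned grid of square cells. Cell centers are at
#' `x_min + (col - 0.5) * cell_size`; rasters built on the grid are
#' stored north-up (row 1 is the top / maximum-y edge), matching the
#' ESRI ASCII grid convention.
#'
#' @param x_min,y_min Lower-left corner of the grid extent.
#' @param cell_size Cell edge length (> 0), same units as coordinates.
#' @param n_cols,n_rows Grid dimensions (>= 1).
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(x_min, y_min, cell_size, n_cols, n_rows) {
  stopifnot(cell_size > 0, n_cols >= 1, n_rows >= 1,
            is.finite(x_min), is.finite(y_min))
  structure(list(x_min = x_min, y_min = y_min, cell_size = cell_size,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param x,y Point coordinates to cover.
#' @param n_cells Approximate number of cells along the longer axis.
#' @param pad Fractional padding added around the bounding box.
#' @export
grid_over_points <- function(x, y, n_cells = 50, pad = 0.05) {
  rx <- range(x); ry <- range(y)
  span <- max(rx[2] - rx[1], ry[2] - ry[1])
  if (span == 0) span <- 1  # all points coincident
  cell <- span * (1 + 2 * pad) / n_cells
  x0 <- rx[1] - pad * span
  y0 <- ry[1] - pad * span
  grid_spec(x0, y0, cell,
            n_cols = ceiling((rx[2] + pad * span - x0) / cell),
            n_rows = ceiling((ry[2] + pad * span - y0) / cell))
}

.grid_centers <- function(grid) {
  xs <- grid$x_min + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  # north-up: row 1 is the top row
  ys <- grid$y_min + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * grid$cell_size
  list(x = xs, y = ys)
}

#' Inverse-distance-weighted interpolation
#'
#' Interpolates scattered point values onto a grid with
#' \eqn{\hat v = \sum_i w_i v_i / \sum_i w_i}, \eqn{w_i = d_i^{-p}},
#' using planar Euclidean distances. Points sharing coordinates are
#' averaged first. A cell whose center lies within `eps` of a sample
#' point takes that sample's value exactly. With `k_neighbors` set, only
#' the k nearest points contribute to each cell.
#'
#' @param x,y,values Sample coordinates and the quantity to interpolate.
#' @param grid A [grid_spec()].
#' @param power IDW power p (> 0); default 2.
#' @param k_neighbors Number of nearest points to use, or `NULL` for all.
#' @param eps Coincidence tolerance; default `1e-9 * cell_size`.
#' @return Object of class `idw_raster`: list with `grid`, `values`
#'   (n_rows x n_cols matrix, north-up) and `nodata` sentinel (-9999).
#' @export
idw_interpolate <- function(x, y, values, grid, power = 2,
                            k_neighbors = NULL, eps = NULL) {
  stopifnot(inherits(grid, "grid_spec"), power > 0,
            length(x) == length(y), length(x) == length(values))
  if (length(x) == 0L) stop("empty point set", call. = FALSE)
  if (is.null(eps)) eps <- 1e-9 * grid$cell_size

  # average duplicated locations so weights stay finite and well defined
  key <- paste(x, y, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(values, key, mean)
    first <- !duplicated(key)
    ord <- match(key[first], names(agg))
    x <- x[first]; y <- y[first]; values <- as.numeric(agg[ord])
  }

  ctr <- .grid_centers(grid)
  cx <- rep(ctr$x, each = grid$n_rows)   # column-major over the raster
  cy <- rep(ctr$y, times = grid$n_cols)
  d2 <- outer(cx, x, "-")^2 + outer(cy, y, "-")^2
  d <- sqrt(d2)

  if (!is.null(k_neighbors) && k_neighbors < length(x)) {
    keep <- t(apply(d, 1L, function(row) {
      row <= sort(row, partial = k_neighbors)[k_neighbors]
    }))
  } else {
    keep <- TRUE
  }

  w <- d^(-power) * keep
  hit <- d < eps
  vhat <- as.vector((w %*% values) / rowSums(w))
  if (any(hit)) {
    j <- which(hit, arr.ind = TRUE)
    vhat[j[, 1L]] <- values[j[, 2L]]
  }

  structure(list(grid = grid,
                 values = matrix(vhat, grid$n_rows, grid$n_cols),
                 nodata = -9999),
            class = "idw_raster")
}

#' Classify a raster surface
#'
#' Applies a classification scheme cellwise; returns an integer raster
#' of class indices (1 = least severe) carrying the labels.
#'
#' @param raster An `idw_raster`.
#' @param scheme A [classification_scheme()].
#' @return `idw_raster` whose `values` are integer class indices, with a
#'   `labels` element.
#' @export
classify_surface <- function(raster, scheme) {
  stopifnot(inherits(raster, "idw_raster"))
  cls <- classify(scheme, as.vector(raster$values))
  structure(list(grid = raster$grid,
                 values = matrix(as.integer(cls), raster$grid$n_rows,
                                 raster$grid$n_cols),
                 nodata = raster$nodata, labels = scheme$labels),
            class = "idw_raster")
}

#' Potential-ecological-risk surface
#'
#' Computes the summed risk index (PRI) per sample, interpolates it onto
#' the grid by IDW, and classifies every cell on the summed-risk scheme.
#'
#' @param samples Samples data frame with coordinates.
#' @param grid A [grid_spec()]; default covers the sample points.
#' @param refs Reference table.
#' @param power,k_neighbors Passed to [idw_interpolate()].
#' @return List with `surface` (PRI raster) and `classes` (classified
#'   raster, see [classify_surface()]).
#' @export
risk_surface <- function(samples, grid = NULL, refs = element_references(),
                         power = 2, k_neighbors = NULL) {
  .validate_samples(samples)
  pri <- build_index_table(samples, refs)$samples$pri
  if (is.null(grid)) grid <- grid_over_points(samples$x, samples$y)
  surf <- idw_interpolate(samples$x, samples$y, pri, grid,
                          power = power, k_neighbors = k_neighbors)
  list(surface = surf,
       classes = classify_surface(surf, classification_scheme("pri")))
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` raster with the standard six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows from north to south.
#'
#' @param raster An `idw_raster`.
#' @param path Output path.
#' @export
write_esri_ascii <- function(raster, path) {
  stopifnot(inherits(raster, "idw_raster"))
  g <- raster$grid
  header <- c(paste("ncols", g$n_cols), paste("nrows", g$n_rows),
              paste("xllcorner", g$x_min), paste("yllcorner", g$y_min),
              paste("cellsize", g$cell_size),
              paste("NODATA_value", raster$nodata))
  v <- raster$values
  v[!is.finite(v)] <- raster$nodata
  body <- apply(v, 1L, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}
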