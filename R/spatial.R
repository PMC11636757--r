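#' Inverse-distance-weighted interpolation at query points
#'
#' `z* = sum_i z_i d_i^-p / sum_i d_i^-p` over all data points (no
#' search radius). A query within `eps` of a data point returns that
#' point's value exactly, so the interpolant honours the data. The
#' result is a convex combination of the data values.
#'
#' @param x,y,z Data point coordinates and values (equal length,
#'   at least 1 point).
#' @param xout,yout Query coordinates (equal length).
#' @param p Distance-decay power (> 0), default 2.
#' @param eps Coincidence tolerance in coordinate units, default 1e-9.
#' @return Interpolated values at the query points.
#' @examples
#' idw(c(0, 1), c(0, 0), c(10, 20), 0.5, 0)   # midpoint -> 15
#' @export
idw <- function(x, y, z, xout, yout, p = 2, eps = 1e-9) {
  if (length(x) == 0) stop("empty point set")
  if (length(x) != length(y) || length(x) != length(z)) {
    stop("x, y, z lengths differ")
  }
  if (p <= 0) stop("power p must be > 0")
  vapply(seq_along(xout), function(i) {
    d <- sqrt((x - xout[i])^2 + (y - yout[i])^2)
    hit <- which(d < eps)
    if (length(hit)) return(z[hit[1]])
    w <- d^(-p)
    sum(z * w) / sum(w)
  }, numeric(1))
}

#' Planar raster grid
#'
#' Row 1 is the northernmost row (ESRI ASCII raster convention); cell
#' centres are offset half a cell from the lower-left corner.
#'
#' @param values Numeric matrix (rows = north to south).
#' @param xll,yll Lower-left corner of the grid extent.
#' @param cellsize Cell edge length (> 0).
#' @param nodata Sentinel for missing cells, default -9999.
#' @return Object of class `gw_grid`.
#' @export
gw_grid <- function(values, xll, yll, cellsize, nodata = -9999) {
  values <- as.matrix(values)
  if (cellsize <= 0) stop("cellsize must be > 0")
  if (nrow(values) < 1 || ncol(values) < 1) stop("empty grid")
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata),
            class = "gw_grid")
}

#' @export
print.gw_grid <- function(x, ...) {
  v <- x$values[x$values != x$nodata]
  cat("gw_grid: ", nrow(x$values), " x ", ncol(x$values),
      " cells of ", x$cellsize, ", origin (", x$xll, ", ", x$yll, ")\n",
      sep = "")
  if (length(v)) {
    cat(sprintf("  values: %.4g - %.4g\n", min(v), max(v)))
  }
  invisible(x)
}

# Cell-centre coordinates of a grid, row-major from the top row.
.grid_centres <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  xs <- grid$xll + (seq_len(nc) - 0.5) * grid$cellsize
  ys <- grid$yll + (nr - seq_len(nr) + 0.5) * grid$cellsize
  list(x = xs, y = ys)
}

#' Rasterise scattered values by IDW
#'
#' Evaluates [idw()] at every cell centre of a regular grid spanning
#' `bbox`. Deterministic for fixed inputs.
#'
#' @param x,y,z Data points.
#' @param bbox Extent `c(xmin, xmax, ymin, ymax)` containing at least
#'   one point.
#' @param cellsize Cell edge length (> 0).
#' @param p IDW power.
#' @param eps Coincidence tolerance.
#' @return A [gw_grid()].
#' @export
rasterize_idw <- function(x, y, z, bbox, cellsize, p = 2, eps = 1e-9) {
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) stop("degenerate bbox")
  inside <- x >= bbox[1] & x <= bbox[2] & y >= bbox[3] & y <= bbox[4]
  if (!any(inside)) stop("bbox contains no data points")
  nc <- max(1L, ceiling((bbox[2] - bbox[1]) / cellsize))
  nr <- max(1L, ceiling((bbox[4] - bbox[3]) / cellsize))
  g <- gw_grid(matrix(NA_real_, nr, nc), bbox[1], bbox[3], cellsize)
  cc <- .grid_centres(g)
  for (i in seq_len(nr)) {
    g$values[i, ] <- idw(x, y, z, cc$x, rep(cc$y[i], nc), p, eps)
  }
  g
}

#' Classify a grid into integer bands
#'
#' Left-closed classification (`value >= thresholds[k]` puts the cell
#' in class `k + 1`), matching the conventions of the EWQI ranks and
#' HI categories, so classifying a raster commutes with classifying
#' the underlying values. Nodata cells stay nodata.
#'
#' @param grid A [gw_grid()].
#' @param thresholds Strictly increasing cut points.
#' @param labels Optional class labels (length `length(thresholds)+1`),
#'   stored as an attribute.
#' @return A [gw_grid()] of integer classes (1-based).
#' @export
classify_grid <- function(grid, thresholds, labels = NULL) {
  if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing")
  }
  v <- grid$values
  cls <- matrix(findInterval(v, thresholds) + 1L, nrow(v), ncol(v))
  cls[v == grid$nodata] <- as.integer(grid$nodata)
  out <- gw_grid(cls, grid$xll, grid$yll, grid$cellsize, grid$nodata)
  if (!is.null(labels)) {
    if (length(labels) != length(thresholds) + 1) {
      stop("need one label per class")
    }
    attr(out, "labels") <- labels
  }
  out
}

#' Write a grid as an ESRI ASCII raster
#'
#' @param grid A [gw_grid()].
#' @param path Output file (`.asc`).
#' @return Invisibly, `path`.
#' @export
write_esri_ascii <- function(grid, path) {
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(grid$xll, scientific = FALSE)),
    paste("yllcorner", format(grid$yll, scientific = FALSE)),
    paste("cellsize", format(grid$cellsize, scientific = FALSE)),
    paste("NODATA_value", grid$nodata)
  ), con)
  utils::write.table(format(v, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path File written by [write_esri_ascii()] (or any compliant
#'   `.asc`).
#' @return A [gw_grid()]; nodata cells are `NA`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA_real_
  gw_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

#' Export a classified grid as a (row, col, class) CSV
#'
#' @param grid Integer-class grid from [classify_grid()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_class_csv <- function(grid, path) {
  v <- grid$values
  df <- data.frame(row = rep(seq_len(nrow(v)), ncol(v)),
                   col = rep(seq_len(ncol(v)), each = nrow(v)),
                   class = as.vector(v))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a grid
#'
#' @param x A [gw_grid()].
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.gw_grid <- function(x, ...) {
  cc <- .grid_centres(x)
  v <- x$values
  v[v == x$nodata] <- NA
  graphics::image(cc$x, rev(cc$y), t(v[nrow(v):1, , drop = FALSE]),
                  xlab = "x", ylab = "y", useRaster = TRUE, ...)
  invisible(x)
}
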