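# Gridded-layer container and spatial conventions.
#
# Conventions (shared by every module):
#   * values is a numeric matrix with row 1 the NORTHERNMOST row;
#   * the grid is cell-registered at its lower-left corner (x_ll, y_ll);
#   * cell (r, c) covers the half-open box
#       [x_ll + (c-1)*s, x_ll + c*s) x [y_ll + (nrow-r)*s, y_ll + (nrow-r+1)*s)
#     (1-based indices; east and north edges exclusive);
#   * missing cells are NA internally; `nodata` is only an I/O sentinel.

#' Construct a gridded layer
#'
#' A lightweight container for a single raster layer on a regular
#' longitude--latitude lattice with square cells, the universal spatial
#' object of this package. Row 1 of `values` is the northernmost row and
#' the grid is registered at the lower-left *corner*.
#'
#' @param values Numeric matrix; `NA` marks missing cells.
#' @param x_ll,y_ll Longitude/latitude of the lower-left corner (decimal
#'   degrees, cell-registered).
#' @param cell_size Cell edge in degrees (square cells; 2.5 arc-min is
#'   `2.5 / 60`).
#' @param nodata Sentinel written for `NA` cells on output.
#' @return An object of class `"Raster"`.
#' @export
#' @examples
#' r <- raster_grid(matrix(1:6, 2, 3), x_ll = 0, y_ll = 40, cell_size = 0.5)
#' dim(r$values)
raster_grid <- function(values, x_ll, y_ll, cell_size, nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  stopifnot(
    is.numeric(x_ll), is.numeric(y_ll),
    is.numeric(cell_size), cell_size > 0
  )
  structure(
    list(
      values = values,
      n_rows = nrow(values), n_cols = ncol(values),
      x_ll = as.numeric(x_ll), y_ll = as.numeric(y_ll),
      cell_size = as.numeric(cell_size),
      nodata = as.numeric(nodata)
    ),
    class = "Raster"
  )
}

#' @export
print.Raster <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<Raster> %d x %d cells, cell size %g deg\n  extent: lon [%g, %g), lat [%g, %g)\n",
    x$n_rows, x$n_cols, x$cell_size,
    x$x_ll, x$x_ll + x$n_cols * x$cell_size,
    x$y_ll, x$y_ll + x$n_rows * x$cell_size
  ))
  cat(sprintf(
    "  values: [%s, %s], %d NA of %d\n",
    format(suppressWarnings(min(v, na.rm = TRUE))),
    format(suppressWarnings(max(v, na.rm = TRUE))),
    sum(is.na(v)), length(v)
  ))
  invisible(x)
}

is_raster <- function(x) inherits(x, "Raster")

# same lattice (geometry), tolerating tiny float wobble in the corner
same_geometry <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$x_ll - b$x_ll) < tol && abs(a$y_ll - b$y_ll) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

stop_unless_aligned <- function(layers, what = "layers") {
  ref <- layers[[1L]]
  for (l in layers[-1L]) {
    if (!same_geometry(ref, l)) {
      stop(sprintf("%s do not share grid geometry", what), call. = FALSE)
    }
  }
  invisible(ref)
}

#' Cell-centre coordinates
#'
#' @param raster A [raster_grid()] object.
#' @return A list with `lon` (length `n_cols`) and `lat` (length `n_rows`,
#'   north to south) giving the centre coordinates of every column and row.
#' @export
cell_centers <- function(raster) {
  s <- raster$cell_size
  list(
    lon = raster$x_ll + (seq_len(raster$n_cols) - 0.5) * s,
    lat = raster$y_ll + (raster$n_rows - seq_len(raster$n_rows) + 0.5) * s
  )
}

# matrix of centre latitudes, same shape as values
lat_matrix <- function(raster) {
  matrix(cell_centers(raster)$lat,
    nrow = raster$n_rows, ncol = raster$n_cols, byrow = FALSE
  )
}

#' Locate points on the grid
#'
#' Maps longitude/latitude points to (row, col) indices under the half-open
#' cell convention: a point exactly on a shared edge belongs to the cell to
#' its east is *excluded* from — i.e. to the larger column / smaller (more
#' northern) row.
#'
#' @param raster A [raster_grid()] object.
#' @param lon,lat Numeric vectors of equal length, decimal degrees.
#' @return A two-column integer matrix with columns `row`, `col` (1-based).
#' @export
#' @examples
#' r <- raster_grid(matrix(0, 4, 4), 0, 0, 1)
#' cell_index(r, 0, 0)      # lower-left corner -> row 4, col 1
#' cell_index(r, 2, 2)      # interior edges -> east/north-exclusive
cell_index <- function(raster, lon, lat) {
  stopifnot(length(lon) == length(lat))
  s <- raster$cell_size
  x_max <- raster$x_ll + raster$n_cols * s
  y_max <- raster$y_ll + raster$n_rows * s
  bad <- lon < raster$x_ll | lon >= x_max | lat < raster$y_ll | lat >= y_max
  if (any(bad)) {
    stop(sprintf("%d point(s) outside the raster extent", sum(bad)),
      call. = FALSE
    )
  }
  col <- as.integer(floor((lon - raster$x_ll) / s)) + 1L
  row <- raster$n_rows - as.integer(floor((lat - raster$y_ll) / s))
  # guard float edge cases onto the lattice
  col <- pmin(pmax(col, 1L), raster$n_cols)
  row <- pmin(pmax(row, 1L), raster$n_rows)
  cbind(row = row, col = col)
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid I/O (the canonical, bit-exact interchange format here)

#' Read an ESRI ASCII grid
#'
#' Parses the `.asc` dialect with header keys `ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize` and optional
#' `NODATA_value` (case-insensitive). Centre-registered corners are
#' converted to the package's corner convention.
#'
#' @param path Path to the file.
#' @return A [raster_grid()] object; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("truncated ASCII grid: missing header", call. = FALSE)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(toks) == 2L && grepl("^[A-Za-z_]+$", toks[1L])) {
      key <- tolower(toks[1L])
      val <- suppressWarnings(as.numeric(toks[2L]))
      if (is.na(val)) {
        stop(sprintf("malformed ASCII grid header: key '%s' has non-numeric value '%s'",
          toks[1L], toks[2L]), call. = FALSE)
      }
      hdr[[key]] <- val
      n_hdr <- n_hdr + 1L
    } else {
      break
    }
  }
  for (need in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[need]])) {
      stop(sprintf("malformed ASCII grid header: missing key '%s'", need),
        call. = FALSE
      )
    }
  }
  s <- hdr$cellsize
  if (s <= 0) stop("malformed ASCII grid header: key 'cellsize' must be > 0", call. = FALSE)
  x_ll <- if (!is.null(hdr$xllcorner)) {
    hdr$xllcorner
  } else if (!is.null(hdr$xllcenter)) {
    hdr$xllcenter - s / 2
  } else {
    stop("malformed ASCII grid header: missing key 'xllcorner' (or 'xllcenter')",
      call. = FALSE
    )
  }
  y_ll <- if (!is.null(hdr$yllcorner)) {
    hdr$yllcorner
  } else if (!is.null(hdr$yllcenter)) {
    hdr$yllcenter - s / 2
  } else {
    stop("malformed ASCII grid header: missing key 'yllcorner' (or 'yllcenter')",
      call. = FALSE
    )
  }
  nodata <- hdr$nodata_value %||% -9999
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  vals <- scan(
    text = paste(lines[(n_hdr + 1L):length(lines)], collapse = "\n"),
    what = numeric(), quiet = TRUE
  )
  if (length(vals) != nr * nc) {
    stop(sprintf(
      "ASCII grid dimension mismatch: header promises %d x %d = %d values, found %d",
      nr, nc, nr * nc, length(vals)
    ), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, x_ll, y_ll, s, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Emits the six-line header followed by `n_rows` rows of space-separated
#' values, northern row first. `NA` cells are written as the nodata
#' sentinel. With the default `digits = 17` a write/read cycle reproduces
#' the doubles bit-identically.
#'
#' @param raster A [raster_grid()] object.
#' @param path Output path.
#' @param digits Significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, digits = 17L) {
  stopifnot(is_raster(raster))
  fmt <- sprintf("%%.%dg", as.integer(digits))
  m <- raster$values
  m[is.na(m)] <- raster$nodata
  hdr <- c(
    sprintf("ncols %d", raster$n_cols),
    sprintf("nrows %d", raster$n_rows),
    sprintf("xllcorner %.12g", raster$x_ll),
    sprintf("yllcorner %.12g", raster$y_ll),
    sprintf("cellsize %.12g", raster$cell_size),
    sprintf("NODATA_value %.12g", raster$nodata)
  )
  body <- apply(m, 1L, function(row) paste(sprintf(fmt, row), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Bilinear resampling onto a template lattice

#' Resample a layer onto a template grid by bilinear interpolation
#'
#' Each output cell centre takes the bilinear interpolation of the four
#' surrounding *source cell centres*. Output centres that fall outside the
#' source centre lattice, or whose 4-point stencil touches a missing cell,
#' are set to `NA` — no extrapolation is performed.
#'
#' @param source A [raster_grid()] to resample.
#' @param template A [raster_grid()] supplying the output geometry.
#' @return A `Raster` with the template's geometry.
#' @export
resample_bilinear <- function(source, template) {
  stopifnot(is_raster(source), is_raster(template))
  s <- source$cell_size
  src_xmax <- source$x_ll + source$n_cols * s
  src_ymax <- source$y_ll + source$n_rows * s
  tc <- cell_centers(template)
  if (max(tc$lon) < source$x_ll || min(tc$lon) >= src_xmax ||
    max(tc$lat) < source$y_ll || min(tc$lat) >= src_ymax) {
    stop("template extent is disjoint from the source extent", call. = FALSE)
  }
  # fractional (row, col) of each template centre on the source CENTRE lattice
  u <- (tc$lon - (source$x_ll + s / 2)) / s + 1 # 1-based float col
  y_top <- source$y_ll + (source$n_rows - 0.5) * s # centre lat of row 1
  v <- (y_top - tc$lat) / s + 1 # 1-based float row

  nr <- template$n_rows
  nc <- template$n_cols
  out <- matrix(NA_real_, nr, nc)

  c0 <- floor(u)
  r0 <- floor(v)
  # a centre exactly on the last lattice line is interpolated from the last pair
  c0[u == source$n_cols] <- source$n_cols - 1
  r0[v == source$n_rows] <- source$n_rows - 1
  wu <- u - c0
  wv <- v - r0
  ok_c <- c0 >= 1 & c0 + 1 <= source$n_cols
  ok_r <- r0 >= 1 & r0 + 1 <= source$n_rows
  V <- source$values
  for (i in which(ok_r)) {
    ri <- r0[i]
    ti <- wv[i]
    for (j in which(ok_c)) {
      cj <- c0[j]
      tj <- wu[j]
      v00 <- V[ri, cj]
      v01 <- V[ri, cj + 1]
      v10 <- V[ri + 1, cj]
      v11 <- V[ri + 1, cj + 1]
      if (is.na(v00) || is.na(v01) || is.na(v10) || is.na(v11)) next
      out[i, j] <- (1 - ti) * ((1 - tj) * v00 + tj * v01) +
        ti * ((1 - tj) * v10 + tj * v11)
    }
  }
  raster_grid(out, template$x_ll, template$y_ll, template$cell_size,
    nodata = template$nodata
  )
}

# ---------------------------------------------------------------------------
# Occurrence tables

#' Read an occurrence CSV
#'
#' Expects a header `species,longitude,latitude` with an optional `source`
#' column. Coordinates are validated to longitude `[-180, 180)` and
#' latitude `[-90, 90]`.
#'
#' @param path CSV path.
#' @return A data.frame of occurrence records.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("longitude", "latitude")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("occurrence CSV lacks column(s): %s", paste(miss, collapse = ", ")),
      call. = FALSE
    )
  }
  validate_occurrences(df)
  df
}

validate_occurrences <- function(df) {
  if (nrow(df) == 0L) stop("empty occurrence set", call. = FALSE)
  with(df, {
    if (any(longitude < -180 | longitude >= 180, na.rm = TRUE)) {
      stop("longitudes must lie in [-180, 180)", call. = FALSE)
    }
    if (any(latitude < -90 | latitude > 90, na.rm = TRUE)) {
      stop("latitudes must lie in [-90, 90]", call. = FALSE)
    }
  })
  invisible(df)
}
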