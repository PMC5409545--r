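# Regular interpolation grid and ESRI ASCII raster input/output.
#
# Coordinate convention (used everywhere in the package): cells are indexed
# (row, col) zero-based, row 0 at the southern edge; the centre of cell
# (row, col) is (x0 + (col + 0.5) * dx, y0 + (row + 0.5) * dy); the linear
# cell id is row * nx + col + 1 (1-based, row-major from the south-west).

#' Define a regular interpolation grid
#'
#' @param nx,ny number of cells in the x and y directions.
#' @param dx,dy cell spacing in projected km (default 1 km).
#' @param x0,y0 coordinates of the south-west corner (km).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(nx, ny, dx = 1, dy = 1, x0 = 0, y0 = 0) {
  stopifnot(is_count(nx), nx >= 1, is_count(ny), ny >= 1,
            is.numeric(dx), dx > 0, is.numeric(dy), dy > 0,
            is.finite(x0), is.finite(y0))
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 dx = as.numeric(dx), dy = as.numeric(dy),
                 x0 = as.numeric(x0), y0 = as.numeric(y0)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, spacing %g x %g km, origin (%g, %g)\n",
              x$nx, x$ny, x$dx, x$dy, x$x0, x$y0))
  invisible(x)
}

n_cells <- function(grid) grid$nx * grid$ny

#' Cell centres of a grid
#'
#' @param grid a [grid_spec()].
#' @return a data.frame with columns `cell`, `col`, `row`, `x`, `y`
#'   (row-major order from the south-west corner).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  col <- rep.int(seq_len(grid$nx) - 1L, grid$ny)
  row <- rep(seq_len(grid$ny) - 1L, each = grid$nx)
  data.frame(cell = seq_len(n_cells(grid)),
             col = col, row = row,
             x = grid$x0 + (col + 0.5) * grid$dx,
             y = grid$y0 + (row + 0.5) * grid$dy)
}

#' Write a gridded field as an ESRI ASCII raster
#'
#' Square cells are required by the format (`dx == dy`). Values are written
#' row by row from north to south, as the format prescribes.
#'
#' @param values numeric vector of length `nx * ny` in cell-id order.
#' @param grid a [grid_spec()].
#' @param path output file path.
#' @param digits significant digits to print (default 10).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(values, grid, path, digits = 10) {
  stopifnot(inherits(grid, "grid_spec"), length(values) == n_cells(grid))
  if (abs(grid$dx - grid$dy) > 1e-12)
    stop("ESRI ASCII rasters require square cells (dx == dy)", call. = FALSE)
  nodata <- -9999
  v <- values
  v[!is.finite(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$nx),
               sprintf("nrows %d", grid$ny),
               sprintf("xllcorner %.10g", grid$x0),
               sprintf("yllcorner %.10g", grid$y0),
               sprintf("cellsize %.10g", grid$dx),
               sprintf("NODATA_value %d", nodata)), con)
  m <- matrix(v, nrow = grid$ny, ncol = grid$nx, byrow = TRUE)
  for (r in rev(seq_len(grid$ny)))
    writeLines(paste(formatC(m[r, ], digits = digits, format = "g"),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file written by [write_esri_ascii()] or any conforming raster.
#' @return a list with elements `grid` (a [grid_spec()]) and `values`
#'   (numeric vector in cell-id order; NODATA becomes `NA`).
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path, call. = FALSE)
  grid <- grid_spec(nx = hdr$ncols, ny = hdr$nrows,
                    dx = hdr$cellsize, dy = hdr$cellsize,
                    x0 = hdr$xllcorner, y0 = hdr$yllcorner)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != n_cells(grid))
    stop("ESRI ASCII body does not match header dimensions", call. = FALSE)
  m <- matrix(vals, nrow = grid$ny, ncol = grid$nx, byrow = TRUE)
  v <- as.numeric(t(m[rev(seq_len(grid$ny)), , drop = FALSE]))
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA_real_
  list(grid = grid, values = v)
}
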