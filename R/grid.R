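#' Define a rectangular geographic analysis grid
#'
#' The analysis grid is a regular lattice of square cells in geographic
#' degrees, anchored at the lower-left corner. Cells are indexed 0-based,
#' row-major from the lower-left origin: cell id = row * n_cols + col, with
#' row 0 the southernmost row. An optional study mask marks the cells that
#' belong to the study region; records and raster values outside the mask
#' are treated as no-data.
#'
#' @param n_rows,n_cols number of grid rows (south to north) and columns
#'   (west to east).
#' @param cell_size cell edge length in decimal degrees (default 0.1).
#' @param origin_lon,origin_lat longitude/latitude of the lower-left corner
#'   of the grid.
#' @param study_mask logical vector of length `n_rows * n_cols` in cell-id
#'   order, `TRUE` for cells inside the study region. Default: all cells.
#' @return an object of class `grid_domain`.
#' @examples
#' g <- grid_domain(10, 10, cell_size = 0.1, origin_lon = -75, origin_lat = 0)
#' assign_cell(-74.95, 0.05, g)  # cell 0
#' @export
grid_domain <- function(n_rows, n_cols, cell_size = 0.1,
                        origin_lon = 0, origin_lat = 0, study_mask = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid must have at least one row and column")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  n <- n_rows * n_cols
  if (is.null(study_mask)) study_mask <- rep(TRUE, n)
  if (length(study_mask) != n || !is.logical(study_mask))
    stop("study_mask must be a logical vector of length n_rows * n_cols")
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 origin_lon = origin_lon, origin_lat = origin_lat,
                 study_mask = study_mask),
            class = "grid_domain")
}

#' @export
print.grid_domain <- function(x, ...) {
  cat(sprintf("grid_domain: %d x %d cells of %g deg, origin (%g, %g), %d masked-in\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat,
              sum(x$study_mask)))
  invisible(x)
}

grid_n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Map point coordinates to grid cell ids
#'
#' Cells are half-open intervals `[edge, edge + cell_size)` in both axes, so
#' a point on an interior shared edge belongs to the higher-index cell. The
#' outermost north and east edges are closed, so points on the exact outer
#' boundary of the grid are kept in the last row/column. Points outside the
#' grid (or, with `masked = TRUE`, outside the study mask) map to `NA`.
#'
#' @param lon,lat numeric vectors of coordinates in decimal degrees.
#' @param grid a [grid_domain()].
#' @param masked if `TRUE` (default), points in cells outside the study mask
#'   also return `NA`.
#' @return integer vector of 0-based cell ids, `NA` where unassigned.
#' @export
assign_cell <- function(lon, lat, grid, masked = TRUE) {
  stopifnot(inherits(grid, "grid_domain"))
  cs <- grid$cell_size
  # small epsilon so points arithmetically on a cell edge obey the
  # half-open rule despite floating-point representation error
  col <- floor((lon - grid$origin_lon) / cs + 1e-9)
  row <- floor((lat - grid$origin_lat) / cs + 1e-9)
  # closed outer edge: the exact maximum edge folds into the last cell
  max_lon <- grid$origin_lon + grid$n_cols * cs
  max_lat <- grid$origin_lat + grid$n_rows * cs
  col[lon == max_lon] <- grid$n_cols - 1L
  row[lat == max_lat] <- grid$n_rows - 1L
  out <- row * grid$n_cols + col
  bad <- !is.finite(out) | col < 0 | col >= grid$n_cols | row < 0 | row >= grid$n_rows
  out[bad] <- NA
  if (masked) {
    idx <- which(!bad)
    out[idx[!grid$study_mask[out[idx] + 1L]]] <- NA
  }
  as.integer(out)
}

#' Cell centre coordinates
#'
#' @param grid a [grid_domain()].
#' @param cell_id optional integer vector of 0-based cell ids; default all.
#' @return data.frame with `cell_id`, `lon`, `lat` (centres) and `ll_lon`,
#'   `ll_lat` (lower-left corners).
#' @export
cell_centers <- function(grid, cell_id = NULL) {
  if (is.null(cell_id)) cell_id <- seq_len(grid_n_cells(grid)) - 1L
  row <- cell_id %/% grid$n_cols
  col <- cell_id %% grid$n_cols
  cs <- grid$cell_size
  data.frame(cell_id = as.integer(cell_id),
             lon = grid$origin_lon + (col + 0.5) * cs,
             lat = grid$origin_lat + (row + 0.5) * cs,
             ll_lon = grid$origin_lon + col * cs,
             ll_lat = grid$origin_lat + row * cs)
}

#' Refine a grid by an integer factor
#'
#' Produces the finer lattice used for suitability rasters: each coarse cell
#' is split into `factor` x `factor` fine cells; the study mask is replicated
#' blockwise.
#'
#' @param grid a [grid_domain()].
#' @param factor integer refinement factor >= 1.
#' @return a finer [grid_domain()] covering the same extent.
#' @export
refine_grid <- function(grid, factor = 2L) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("refinement factor must be an integer >= 1")
  if (factor == 1L) return(grid)
  fm <- matrix(grid$study_mask, nrow = grid$n_rows, byrow = TRUE)
  fine <- fm[rep(seq_len(grid$n_rows), each = factor),
             rep(seq_len(grid$n_cols), each = factor), drop = FALSE]
  grid_domain(grid$n_rows * factor, grid$n_cols * factor,
              cell_size = grid$cell_size / factor,
              origin_lon = grid$origin_lon, origin_lat = grid$origin_lat,
              study_mask = as.vector(t(fine)))
}

#' Convert between cell-id-ordered vectors and grid matrices
#'
#' Grid rasters are stored as numeric matrices with row 1 = southernmost
#' grid row, matching cell-id order when flattened row-major.
#'
#' @param values numeric vector in cell-id order (length = number of cells).
#' @param grid a [grid_domain()].
#' @return `grid_matrix`: an `n_rows` x `n_cols` matrix; `grid_values`: the
#'   inverse flattening.
#' @export
grid_matrix <- function(values, grid) {
  stopifnot(length(values) == grid_n_cells(grid))
  matrix(values, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}

#' @rdname grid_matrix
#' @param mat a matrix laid out as produced by `grid_matrix`.
#' @export
grid_values <- function(mat, grid) {
  stopifnot(nrow(mat) == grid$n_rows, ncol(mat) == grid$n_cols)
  as.vector(t(mat))
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange format: a 6-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values
#' from the northernmost row down. `NA` is written as the no-data value.
#'
#' @param mat numeric matrix in [grid_matrix()] layout (row 1 = south).
#' @param grid the [grid_domain()] the matrix is aligned to.
#' @param path file path.
#' @param nodata numeric no-data sentinel (default -9999).
#' @return `read_ascii_grid` returns a list with elements `mat` (row 1 =
#'   south) and `grid`.
#' @export
write_ascii_grid <- function(mat, grid, path, nodata = -9999) {
  stopifnot(nrow(mat) == grid$n_rows, ncol(mat) == grid$n_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$n_cols),
               sprintf("nrows %d", grid$n_rows),
               sprintf("xllcorner %.10g", grid$origin_lon),
               sprintf("yllcorner %.10g", grid$origin_lat),
               sprintf("cellsize %.10g", grid$cell_size),
               sprintf("NODATA_value %g", nodata)), con)
  m <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]  # write north first
  m[is.na(m)] <- nodata
  writeLines(apply(m, 1L, function(r) paste(format(r, digits = 10, trim = TRUE,
                                                   scientific = FALSE),
                                            collapse = " ")), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  vals <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                          tolower(vapply(kv, `[`, "", 1L)))
  body <- utils::read.table(path, skip = 6L)
  m <- as.matrix(body)
  dimnames(m) <- NULL
  m[m == vals[["nodata_value"]]] <- NA
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to row 1 = south
  grid <- grid_domain(vals[["nrows"]], vals[["ncols"]],
                      cell_size = vals[["cellsize"]],
                      origin_lon = vals[["xllcorner"]],
                      origin_lat = vals[["yllcorner"]])
  list(mat = m, grid = grid)
}

#' Truncate to one decimal place
#'
#' Floors (never rounds) to one decimal, the reporting convention used for
#' every printed percentage in cohort and assessment summaries, e.g.
#' `100 * 50 / 95` prints as 52.6. A tiny pre-rounding guards against
#' floating-point representation error.
#'
#' @param x numeric vector.
#' @return `x` truncated to one decimal place.
#' @export
truncate1 <- function(x) floor(round(x * 10, 9)) / 10
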