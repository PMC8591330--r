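#' Composite diversity-conservation indicator rasters
#'
#' Raster algebra on the suitability (fine) grid: the predicted-richness
#' stack sum, the ex-situ gap-richness stack sum, bilinear resampling of
#' coarse per-cell metrics to the fine grid, and the max-standardized
#' average that combines a diversity surface with a gap surface into a
#' single 0-1 indicator.
#'
#' @name indicators
NULL

check_aligned <- function(stack) {
  if (length(stack) == 0L) stop("empty raster stack")
  d <- dim(stack[[1L]])
  for (m in stack) if (!identical(dim(m), d)) stop("misaligned rasters in stack")
  invisible(d)
}

#' Predicted species richness raster
#'
#' Cell-wise sum of the binary suitability rasters; integer-valued. Cells
#' that are no-data in any layer are no-data in the sum (all layers share
#' the study-region mask).
#'
#' @param stack named list of aligned binary matrices.
#' @return numeric matrix of per-cell modelled richness.
#' @export
predicted_richness <- function(stack) {
  check_aligned(stack)
  Reduce(`+`, stack)
}

#' Ex-situ gap richness raster
#'
#' For each species, the gap cells are its suitable cells *not* within
#' `buffer_km` of any of its germplasm (G) records — the part of the
#' modelled range collections have not sampled. Gap richness is the
#' cell-wise sum of these per-species gap layers; a species with no
#' germplasm records contributes its whole suitability layer.
#'
#' @param stack named list of binary suitability matrices.
#' @param g_points named list (per species) of data.frames with `lon`,
#'   `lat` of germplasm records; missing names mean no G records.
#' @param fine_grid the [grid_domain()] the stack is aligned to.
#' @param buffer_km germplasm buffer radius in km (default 50).
#' @return numeric matrix of per-cell gap richness (`<=` predicted
#'   richness everywhere).
#' @export
gap_richness <- function(stack, g_points, fine_grid, buffer_km = 50) {
  check_aligned(stack)
  gaps <- lapply(names(stack), function(s) {
    m <- stack[[s]]
    pts <- g_points[[s]]
    if (is.null(pts) || nrow(pts) == 0L) return(m)
    buffered <- grid_matrix(cells_within_km(fine_grid, pts$lon, pts$lat,
                                            buffer_km), fine_grid)
    m * (1 - buffered)
  })
  Reduce(`+`, gaps)
}

#' Bilinear resampling of a coarse raster to a finer grid
#'
#' Interpolates on cell centres: each fine-cell centre takes the bilinear
#' interpolation of the four surrounding coarse-cell centres; fine cells
#' outside the coarse centre lattice take nearest-edge values (clamped
#' coordinates). Exactly reproduces linear fields, and `factor = 1` is the
#' identity.
#'
#' @param mat coarse numeric matrix (row 1 = south).
#' @param factor integer refinement factor >= 1.
#' @return matrix with `factor`-times the rows and columns of `mat`.
#' @export
resample_to_fine <- function(mat, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("refinement factor must be an integer >= 1")
  if (factor == 1L) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  # fine-cell centres in coarse cell-index coordinates (centre of coarse
  # cell i is at i, 1-based)
  fy <- ((seq_len(nr * factor) - 0.5) / factor) + 0.5
  fx <- ((seq_len(nc * factor) - 0.5) / factor) + 0.5
  interp_1d <- function(pos, n) {
    p <- pmin(pmax(pos, 1), n)  # clamp: nearest-edge beyond support
    lo <- pmin(floor(p), n - 1L)
    if (n == 1L) lo <- rep(1L, length(p))
    w <- p - lo
    list(lo = as.integer(lo), w = w)
  }
  iy <- interp_1d(fy, nr); ix <- interp_1d(fx, nc)
  hi_y <- pmin(iy$lo + 1L, nr); hi_x <- pmin(ix$lo + 1L, nc)
  a <- mat[iy$lo, ix$lo, drop = FALSE]; b <- mat[iy$lo, hi_x, drop = FALSE]
  c_ <- mat[hi_y, ix$lo, drop = FALSE]; d <- mat[hi_y, hi_x, drop = FALSE]
  wy <- matrix(iy$w, nrow = nr * factor, ncol = nc * factor)
  wx <- matrix(ix$w, nrow = nr * factor, ncol = nc * factor, byrow = TRUE)
  (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * c_ + wx * d)
}

#' Standardize a raster by its maximum
#'
#' @param mat numeric matrix with a positive maximum.
#' @return `mat / max(mat)`, so the maximum is exactly 1 and the minimum
#'   `>= 0` for non-negative inputs.
#' @export
max_standardize <- function(mat) {
  mx <- max(mat, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("cannot standardize an all-zero raster")
  mat / mx
}

#' Combine two rasters into a composite indicator
#'
#' Each input is standardized by its own maximum and the two are averaged
#' over the common valid mask: `(a / max(a) + b / max(b)) / 2`. The result
#' lies in `[0, 1]`, reaching 1 only where a cell attains both maxima, and
#' is invariant to rescaling either input by a positive constant. Cells
#' missing in either input are missing in the output.
#'
#' @param a,b aligned numeric matrices, each with a positive maximum.
#' @return numeric matrix: the composite indicator.
#' @export
combine_indicator <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("misaligned rasters")
  valid <- !is.na(a) & !is.na(b)
  if (!any(valid)) stop("no common valid cells")
  am <- max(a[valid]); bm <- max(b[valid])
  if (am <= 0 || bm <= 0) stop("cannot standardize an all-zero raster")
  out <- (a / am + b / bm) / 2
  out[!valid] <- NA
  out
}

#' Build the two composite PD indicators
#'
#' Resamples the coarse observed-PD surface to the suitability grid
#' (bilinear), then averages its max-standardized form with (1) the
#' ex-situ gap-richness raster to give the PD conservation gap richness
#' indicator and (2) the predicted species richness raster to give the PD
#' and predicted species richness indicator.
#'
#' @param pd_values named numeric vector of observed PD per occupied
#'   coarse cell (names = cell ids).
#' @param grid coarse [grid_domain()].
#' @param sdms named list of binary suitability matrices.
#' @param g_points per-species germplasm points (see [gap_richness()]).
#' @param fine_grid suitability [grid_domain()].
#' @param buffer_km germplasm buffer radius (default 50).
#' @return list with matrices `pd_fine`, `predicted_richness`,
#'   `gap_richness`, `pd_gap_indicator`, `pd_richness_indicator`.
#' @export
pd_indicators <- function(pd_values, grid, sdms, g_points, fine_grid,
                          buffer_km = 50) {
  factor <- fine_grid$n_cols / grid$n_cols
  stopifnot(factor == round(factor))
  pd_vec <- rep(NA_real_, grid_n_cells(grid))
  pd_vec[as.integer(names(pd_values)) + 1L] <- pd_values
  pd_coarse <- grid_matrix(pd_vec, grid)
  # unoccupied cells are no-data; treat them as 0 contribution for
  # interpolation support, then restore no-data where nothing was near
  filled <- pd_coarse; filled[is.na(filled)] <- 0
  pd_fine <- resample_to_fine(filled, factor)
  support <- resample_to_fine(matrix(as.numeric(!is.na(pd_coarse)),
                                     nrow(pd_coarse)), factor)
  pd_fine[support == 0] <- NA
  pred <- predicted_richness(sdms)
  gap <- gap_richness(sdms, g_points, fine_grid, buffer_km)
  list(pd_fine = pd_fine,
       predicted_richness = pred,
       gap_richness = gap,
       pd_gap_indicator = combine_indicator(pd_fine, gap),
       pd_richness_indicator = combine_indicator(pd_fine, pred))
}
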