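#' Conservation gap analysis of species representativeness
#'
#' Per-species scores (0-100) of how well ex-situ collections and in-situ
#' protection cover the species' sampled records, modelled range, and
#' ecological breadth, following the sampling / geographic / ecological
#' representativeness score family (SRS, GRS, ERS) with final scores (FCS)
#' as their means and a combined FCSc-mean averaging the ex-situ and
#' in-situ final scores. Species are binned into priority categories:
#' high (HP, score < 25), medium (MP, 25-50), low (LP, 50-75) and
#' sufficiently conserved (SC, >= 75); bins are closed on the left of the
#' higher bin, so a score of exactly 25 is MP.
#'
#' @name gap_analysis
NULL

# minimum great-circle distance (km) from each fine-grid cell centre to any
# of the given points; Inf when there are no points
min_dist_km <- function(grid, lon, lat) {
  if (length(lon) == 0L) return(rep(Inf, grid_n_cells(grid)))
  cc <- cell_centers(grid)
  d <- geosphere::distm(cbind(cc$lon, cc$lat), cbind(lon, lat),
                        fun = geosphere::distHaversine)
  apply(d, 1L, min) / 1000
}

#' Cells within a great-circle buffer of a point set
#'
#' @param grid a [grid_domain()].
#' @param lon,lat point coordinates (may be empty).
#' @param radius_km buffer radius in kilometres.
#' @return logical vector over cells (cell-id order): `TRUE` when the cell
#'   centre lies within `radius_km` of any point.
#' @export
cells_within_km <- function(grid, lon, lat, radius_km) {
  min_dist_km(grid, lon, lat) <= radius_km
}

#' Buffer the protected-area mask
#'
#' Refines the coarse protected mask to the suitability grid and extends it
#' by a great-circle buffer (default 5 km) around protected-cell centres.
#'
#' @param protected logical vector over coarse cells (cell-id order).
#' @param grid the coarse [grid_domain()].
#' @param fine_grid the refined grid the suitability rasters live on.
#' @param pa_buffer_km buffer distance in km (default 5).
#' @return logical vector over fine cells.
#' @export
buffer_protected <- function(protected, grid, fine_grid, pa_buffer_km = 5) {
  stopifnot(length(protected) == grid_n_cells(grid))
  f <- fine_grid$n_cols / grid$n_cols
  stopifnot(f == round(f))
  pm <- grid_matrix(protected, grid)
  fine_mat <- pm[rep(seq_len(grid$n_rows), each = f),
                 rep(seq_len(grid$n_cols), each = f), drop = FALSE]
  fine_protected <- grid_values(fine_mat, fine_grid)
  if (pa_buffer_km <= 0 || !any(fine_protected)) return(fine_protected)
  cc <- cell_centers(fine_grid)
  fine_protected | cells_within_km(fine_grid, cc$lon[fine_protected],
                                   cc$lat[fine_protected], pa_buffer_km)
}

#' Ex-situ representativeness scores for one species
#'
#' * SRSex = 100 G / (G + H): share of records that are germplasm
#'   accessions (0 when the species has no records).
#' * GRSex = 100 x (suitable cells within `buffer_km` of any germplasm
#'   point) / (suitable cells): how much of the modelled range collections
#'   already sample.
#' * ERSex = 100 x (ecoregions touched by the buffered suitable area) /
#'   (ecoregions touched by the suitable area).
#' * FCSex = mean of the three, all capped to `[0, 100]`.
#'
#' A species with zero suitable cells gets GRSex = ERSex = 0 and is
#' flagged.
#'
#' @param records the species' cleaned records (`lon`, `lat`, `type`).
#' @param sdm binary suitability matrix on `fine_grid` (`NA` = no data).
#' @param ecoregions integer ecoregion ids over fine cells (cell-id order).
#' @param fine_grid the suitability [grid_domain()].
#' @param buffer_km germplasm collection buffer radius (default 50 km).
#' @return named list: `SRSex`, `GRSex`, `ERSex`, `FCSex`,
#'   `zero_suitable` flag.
#' @export
exsitu_scores <- function(records, sdm, ecoregions, fine_grid, buffer_km = 50) {
  g_pts <- records[records$type == "G", , drop = FALSE]
  n_g <- nrow(g_pts); n_h <- sum(records$type == "H")
  srs <- if (n_g + n_h == 0L) 0 else 100 * n_g / (n_g + n_h)
  suit <- grid_values(sdm, fine_grid) %in% 1
  zero_suitable <- !any(suit)
  if (zero_suitable) {
    grs <- ers <- 0
  } else {
    buffered <- cells_within_km(fine_grid, g_pts$lon, g_pts$lat, buffer_km)
    grs <- 100 * sum(suit & buffered) / sum(suit)
    eco_suit <- unique(ecoregions[suit])
    eco_buf <- unique(ecoregions[suit & buffered])
    ers <- 100 * length(eco_buf) / length(eco_suit)
  }
  scores <- pmin(pmax(c(SRSex = srs, GRSex = grs, ERSex = ers), 0), 100)
  c(as.list(scores), FCSex = mean(scores), zero_suitable = zero_suitable)
}

#' In-situ representativeness scores for one species
#'
#' * SRSin = 100 x (records inside the buffered protected mask) / (all
#'   records).
#' * GRSin = 100 x (suitable cells inside the buffered protected mask) /
#'   (suitable cells).
#' * ERSin = 100 x (ecoregions in the protected suitable area) /
#'   (ecoregions in the suitable area).
#' * FCSin = mean of the three.
#'
#' @param records the species' cleaned records (`lon`, `lat`).
#' @param sdm binary suitability matrix on `fine_grid`.
#' @param protected_fine logical vector over fine cells: the
#'   [buffer_protected()] mask.
#' @param ecoregions integer ecoregion ids over fine cells.
#' @param fine_grid the suitability [grid_domain()].
#' @return named list: `SRSin`, `GRSin`, `ERSin`, `FCSin`, `zero_suitable`.
#' @export
insitu_scores <- function(records, sdm, protected_fine, ecoregions, fine_grid) {
  cell <- assign_cell(records$lon, records$lat, fine_grid, masked = FALSE)
  inside <- !is.na(cell) & protected_fine[cell + 1L]
  srs <- if (nrow(records) == 0L) 0 else 100 * sum(inside) / nrow(records)
  suit <- grid_values(sdm, fine_grid) %in% 1
  zero_suitable <- !any(suit)
  if (zero_suitable) {
    grs <- ers <- 0
  } else {
    grs <- 100 * sum(suit & protected_fine) / sum(suit)
    eco_suit <- unique(ecoregions[suit])
    eco_prot <- unique(ecoregions[suit & protected_fine])
    ers <- 100 * length(eco_prot) / length(eco_suit)
  }
  scores <- pmin(pmax(c(SRSin = srs, GRSin = grs, ERSin = ers), 0), 100)
  c(as.list(scores), FCSin = mean(scores), zero_suitable = zero_suitable)
}

#' Priority category from a conservation score
#'
#' @param score numeric scores in `[0, 100]`.
#' @return factor with levels `HP`, `MP`, `LP`, `SC` (high/medium/low
#'   priority, sufficiently conserved).
#' @export
conservation_category <- function(score) {
  if (any(!is.na(score) & (score < 0 | score > 100)))
    stop("scores must be in [0, 100]")
  cut(score, breaks = c(-0.5, 25, 50, 75, 100.5),
      labels = c("HP", "MP", "LP", "SC"), right = FALSE)
}

#' Combine ex-situ and in-situ final scores
#'
#' @param FCSex,FCSin final scores in `[0, 100]`.
#' @return data.frame with `FCSc_mean = (FCSex + FCSin) / 2` and the three
#'   categories (`category_ex`, `category_in`, `category_combined`).
#' @export
combine_and_categorize <- function(FCSex, FCSin) {
  if (any(!is.na(c(FCSex, FCSin)) & (c(FCSex, FCSin) < 0 | c(FCSex, FCSin) > 100)))
    stop("scores must be in [0, 100]")
  fcsc <- (FCSex + FCSin) / 2
  data.frame(FCSc_mean = fcsc,
             category_ex = conservation_category(FCSex),
             category_in = conservation_category(FCSin),
             category_combined = conservation_category(fcsc))
}

#' Full conservation gap analysis over a species cohort
#'
#' Scores every species that has a suitability model; species without one
#' (insufficient data to model) are assigned high priority in all three
#' categories by rule, with `assessed = FALSE` and no fabricated numeric
#' scores.
#'
#' @param records cleaned occurrence records (all species).
#' @param sdms named list of binary suitability matrices (modelled species
#'   only).
#' @param protected logical protected mask over coarse cells.
#' @param ecoregions integer ecoregion ids over coarse cells.
#' @param grid the coarse [grid_domain()].
#' @param fine_grid the suitability grid (default: inferred from the first
#'   raster's dimensions).
#' @param buffer_km germplasm buffer radius (default 50 km).
#' @param pa_buffer_km protected-area buffer (default 5 km).
#' @param species optional full species list (default: all in `records`).
#' @return data.frame, one row per species, with the eight scores,
#'   `FCSc_mean`, three categories and the `assessed` flag.
#' @export
conservation_gap_analysis <- function(records, sdms, protected, ecoregions,
                                      grid, fine_grid = NULL,
                                      buffer_km = 50, pa_buffer_km = 5,
                                      species = NULL) {
  if (is.null(species)) species <- sort(unique(records$species))
  if (is.null(fine_grid)) {
    if (length(sdms) == 0L) stop("no suitability rasters and no fine_grid given")
    f <- nrow(sdms[[1L]]) / grid$n_rows
    fine_grid <- refine_grid(grid, f)
  }
  eco_fine <- refine_to_fine(ecoregions, grid, fine_grid)
  prot_fine <- buffer_protected(protected, grid, fine_grid, pa_buffer_km)
  rows <- lapply(species, function(s) {
    base <- data.frame(species = s, SRSex = NA_real_, GRSex = NA_real_,
                       ERSex = NA_real_, FCSex = NA_real_, SRSin = NA_real_,
                       GRSin = NA_real_, ERSin = NA_real_, FCSin = NA_real_,
                       FCSc_mean = NA_real_,
                       category_ex = "HP", category_in = "HP",
                       category_combined = "HP", assessed = FALSE,
                       stringsAsFactors = FALSE)
    if (!s %in% names(sdms)) return(base)
    rec <- records[records$species == s, , drop = FALSE]
    ex <- exsitu_scores(rec, sdms[[s]], eco_fine, fine_grid, buffer_km)
    ins <- insitu_scores(rec, sdms[[s]], prot_fine, eco_fine, fine_grid)
    cmb <- combine_and_categorize(ex$FCSex, ins$FCSin)
    data.frame(species = s, SRSex = ex$SRSex, GRSex = ex$GRSex,
               ERSex = ex$ERSex, FCSex = ex$FCSex, SRSin = ins$SRSin,
               GRSin = ins$GRSin, ERSin = ins$ERSin, FCSin = ins$FCSin,
               FCSc_mean = cmb$FCSc_mean,
               category_ex = as.character(cmb$category_ex),
               category_in = as.character(cmb$category_in),
               category_combined = as.character(cmb$category_combined),
               assessed = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# replicate a coarse per-cell vector onto the fine grid (blockwise)
refine_to_fine <- function(values, grid, fine_grid) {
  f <- fine_grid$n_cols / grid$n_cols
  stopifnot(f == round(f), fine_grid$n_rows == grid$n_rows * f)
  m <- grid_matrix(values, grid)
  fm <- m[rep(seq_len(grid$n_rows), each = f),
          rep(seq_len(grid$n_cols), each = f), drop = FALSE]
  grid_values(fm, fine_grid)
}

#' Cohort summary of gap-analysis results
#'
#' Category counts and percentage shares per score type over the full
#' cohort, plus means of each numeric score over assessed species.
#' Percentages are truncated (floored) to one decimal place, the
#' convention used for all reported shares, e.g. 50 of 95 species prints
#' as 52.6.
#'
#' @param scores data.frame from [conservation_gap_analysis()].
#' @param assessed_only if `TRUE` (default) shares are over assessed
#'   species only; otherwise over the full cohort including
#'   assigned-by-rule species.
#' @return list with `counts` (data.frame: `score_type`, `category`,
#'   `count`, `pct`) and `means` (named numeric vector over assessed
#'   species).
#' @export
cohort_summary <- function(scores, assessed_only = TRUE) {
  if (nrow(scores) == 0L) stop("empty cohort")
  pool <- if (assessed_only) scores[scores$assessed, , drop = FALSE] else scores
  cats <- c("HP", "MP", "LP", "SC")
  counts <- do.call(rbind, lapply(
    c("category_ex", "category_in", "category_combined"),
    function(col) {
      tab <- table(factor(pool[[col]], levels = cats))
      data.frame(score_type = col, category = cats,
                 count = as.integer(tab),
                 pct = truncate1(100 * as.integer(tab) / nrow(pool)),
                 stringsAsFactors = FALSE)
    }))
  num_cols <- c("SRSex", "GRSex", "ERSex", "FCSex",
                "SRSin", "GRSin", "ERSin", "FCSin", "FCSc_mean")
  means <- colMeans(scores[scores$assessed, num_cols, drop = FALSE], na.rm = TRUE)
  list(counts = counts, means = means, n = nrow(pool),
       n_assessed = sum(scores$assessed))
}
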