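#' Read an occurrence-record CSV
#'
#' Expected header: `species,lon,lat,type,source` with `type` in `{H, G}`
#' (H = reference/herbarium record, G = germplasm accession). Rows whose
#' coordinates do not parse as numbers are kept with `NA` coordinates and
#' removed (and counted) by [clean_records()].
#'
#' @param path CSV file path.
#' @param delim field delimiter (default comma).
#' @return data.frame with columns `species`, `lon`, `lat`, `type`,
#'   `source`.
#' @export
read_occurrence_csv <- function(path, delim = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, quote = "\"",
                           fill = TRUE, comment.char = "")
  need <- c("species", "lon", "lat", "type", "source")
  if (!all(need %in% names(raw)))
    stop("occurrence file must have columns: ", paste(need, collapse = ", "))
  raw$lon <- suppressWarnings(as.numeric(raw$lon))
  raw$lat <- suppressWarnings(as.numeric(raw$lat))
  raw[need]
}

# exact matching after trimming and collapsing internal whitespace
normalize_species_names <- function(x) gsub("\\s+", " ", trimws(x))

#' Clean occurrence records
#'
#' Applies the record filters in a fixed order, preserving the order of the
#' surviving rows: (1) drop records with missing or non-finite coordinates;
#' (2) drop records whose species (after whitespace normalization) is on
#' the exclusion list; (3) drop records falling outside the study region
#' (outside the grid or in masked-out cells). Cleaning is idempotent.
#'
#' @param records data.frame as from [read_occurrence_csv()].
#' @param grid a [grid_domain()] defining the study region.
#' @param exclude character vector of species names to drop (e.g.
#'   non-native or agricultural taxa).
#' @return list with `records` (cleaned data.frame, `cell` column added)
#'   and `report` (named counts: `n_input`, `missing_coords`,
#'   `excluded_species`, `outside_region`, `n_retained`).
#' @export
clean_records <- function(records, grid, exclude = character()) {
  stopifnot(is.data.frame(records), inherits(grid, "grid_domain"))
  n_input <- nrow(records)
  records$species <- normalize_species_names(records$species)
  ok_coord <- is.finite(records$lon) & is.finite(records$lat)
  r <- records[ok_coord, , drop = FALSE]
  excl <- r$species %in% normalize_species_names(exclude)
  r <- r[!excl, , drop = FALSE]
  cell <- assign_cell(r$lon, r$lat, grid)
  outside <- is.na(cell)
  r <- r[!outside, , drop = FALSE]
  r$cell <- cell[!outside]
  rownames(r) <- NULL
  list(records = r,
       report = c(n_input = n_input,
                  missing_coords = sum(!ok_coord),
                  excluded_species = sum(excl),
                  outside_region = sum(outside),
                  n_retained = nrow(r)))
}

#' Build the cell x species presence matrix
#'
#' Aggregates cleaned records to the analysis grid: incidence is 1 when at
#' least one record of the species falls in the cell; the per-cell sample
#' count `N` counts every record (duplicates included, since redundancy is
#' defined on samples vs species). Cells with no records are simply absent.
#'
#' @param records cleaned records from [clean_records()] (must carry a
#'   `cell` column or valid coordinates).
#' @param grid a [grid_domain()].
#' @return object of class `presence_matrix`: `incidence` (occupied cells x
#'   species 0/1 matrix, rownames = cell ids), `n_samples` (named counts),
#'   `range_size` (occupied cells per species), `species`, `grid`, `cells`
#'   (per-cell coordinate table).
#' @export
build_presence_matrix <- function(records, grid) {
  if (nrow(records) == 0L) stop("empty dataset: no cleaned records to grid")
  if (is.null(records$cell)) records$cell <- assign_cell(records$lon, records$lat, grid)
  if (anyNA(records$cell)) stop("records outside the grid; run clean_records() first")
  cell <- as.character(records$cell)
  species <- normalize_species_names(records$species)
  tab <- table(cell, species)
  inc <- matrix(as.integer(tab > 0), nrow = nrow(tab),
                dimnames = dimnames(tab))
  # order rows by numeric cell id for stable output
  ord <- order(as.integer(rownames(inc)))
  inc <- inc[ord, , drop = FALSE]
  n_samples <- as.integer(table(cell)[rownames(inc)])
  names(n_samples) <- rownames(inc)
  structure(list(incidence = inc,
                 n_samples = n_samples,
                 range_size = colSums(inc),
                 species = colnames(inc),
                 grid = grid,
                 cells = cell_centers(grid, as.integer(rownames(inc)))),
            class = "presence_matrix")
}

#' Assemble a presence matrix from an existing incidence matrix
#'
#' Constructor for workflows that already hold a cells x species incidence
#' matrix (e.g. imported from other gridding software or built in
#' simulation studies). Row names must be 0-based cell ids on `grid`.
#'
#' @param incidence binary matrix, occupied cells x species, with cell-id
#'   rownames and species colnames.
#' @param grid the [grid_domain()] the cell ids refer to.
#' @param n_samples optional named per-cell record counts; defaults to the
#'   cell richness (one record per species present).
#' @return a `presence_matrix` object.
#' @export
as_presence_matrix <- function(incidence, grid, n_samples = NULL) {
  stopifnot(is.matrix(incidence), all(incidence %in% c(0L, 1L)),
            !is.null(rownames(incidence)), !is.null(colnames(incidence)))
  storage.mode(incidence) <- "integer"
  if (is.null(n_samples))
    n_samples <- stats::setNames(as.integer(rowSums(incidence)), rownames(incidence))
  if (any(n_samples < rowSums(incidence)))
    stop("n_samples must be >= cell richness")
  structure(list(incidence = incidence, n_samples = n_samples,
                 range_size = colSums(incidence), species = colnames(incidence),
                 grid = grid,
                 cells = cell_centers(grid, as.integer(rownames(incidence)))),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d occupied cells x %d species, %d records\n",
              nrow(x$incidence), ncol(x$incidence), sum(x$n_samples)))
  invisible(x)
}

#' Match presence-matrix species to tree tips
#'
#' Species names are matched exactly after whitespace normalization; no
#' fuzzy matching. Occurrence species absent from the tree are dropped with
#' a warning (cells left empty by the drop are removed); tree tips without
#' occurrences are retained in the tree, where they still contribute to the
#' comparison-tree branch-length mean.
#'
#' @param pm a [build_presence_matrix()] result.
#' @param tree a `phylo` object.
#' @return the filtered `presence_matrix`.
#' @export
match_presence_to_tree <- function(pm, tree) {
  stopifnot(inherits(pm, "presence_matrix"))
  tips <- normalize_species_names(tree$tip.label)
  keep <- pm$species %in% tips
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " occurrence species not in the tree: ",
            paste(utils::head(pm$species[!keep], 5L), collapse = ", "),
            if (sum(!keep) > 5L) ", ...")
    inc <- pm$incidence[, keep, drop = FALSE]
    occ <- rowSums(inc) > 0
    inc <- inc[occ, , drop = FALSE]
    pm$incidence <- inc
    pm$species <- colnames(inc)
    pm$range_size <- colSums(inc)
    pm$n_samples <- pm$n_samples[rownames(inc)]
    pm$cells <- pm$cells[pm$cells$cell_id %in% as.integer(rownames(inc)), ,
                         drop = FALSE]
  }
  pm
}

#' Export a presence matrix as plain-text tables
#'
#' Writes the incidence structure as a sparse triplet CSV
#' (`cell_id,species,presence`) and the per-cell table
#' (`cell_id,lon,lat,n_samples,richness`), with cell coordinates given as
#' lower-left corners.
#'
#' @param pm a `presence_matrix`.
#' @param triplet_path,cells_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_presence_matrix <- function(pm, triplet_path, cells_path) {
  w <- which(pm$incidence == 1L, arr.ind = TRUE)
  trip <- data.frame(cell_id = as.integer(rownames(pm$incidence)[w[, 1L]]),
                     species = colnames(pm$incidence)[w[, 2L]],
                     presence = 1L)
  trip <- trip[order(trip$cell_id, trip$species), , drop = FALSE]
  utils::write.csv(trip, triplet_path, row.names = FALSE, quote = FALSE)
  cells <- data.frame(cell_id = pm$cells$cell_id,
                      lon = pm$cells$ll_lon, lat = pm$cells$ll_lat,
                      n_samples = as.integer(pm$n_samples),
                      richness = as.integer(rowSums(pm$incidence)))
  utils::write.csv(cells, cells_path, row.names = FALSE, quote = FALSE)
  invisible(c(triplet_path, cells_path))
}
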