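#' Per-cell diversity metrics
#'
#' Species richness (SR), sampling redundancy, Faith's phylogenetic
#' diversity (PD) and relative phylogenetic diversity (RPD) for grid-cell
#' assemblages. PD is the sum of branch lengths in the union of the
#' tip-to-root paths of the species present (incidence only, no abundance
#' weighting); RPD divides observed PD by PD of the same branch union on the
#' comparison tree, so values above 1 indicate an excess of long branches
#' and values below 1 an excess of short branches.
#'
#' @name spatial_phylo
NULL

#' Species richness of an assemblage
#'
#' @param species character vector of species present (duplicates and `NA`
#'   ignored).
#' @return integer count of distinct species.
#' @export
richness <- function(species) length(unique(species[!is.na(species)]))

#' Sampling redundancy of a cell
#'
#' `1 - SR / N`: near 1 the cell is well sampled (many samples per species),
#' near 0 almost every sample added a new species, i.e. poor sample
#' redundancy.
#'
#' @param sr species richness (count of distinct taxa).
#' @param n_samples number of records in the cell; must be >= `sr`.
#' @return redundancy in `[0, 1]`; `NA` for unoccupied cells (`n_samples`
#'   0), which carry no value rather than a spurious zero.
#' @export
redundancy <- function(sr, n_samples) {
  out <- 1 - sr / n_samples
  out[n_samples < 1] <- NA_real_
  out
}

#' Faith's phylogenetic diversity of a species set
#'
#' @param species character vector of tip labels present.
#' @param index a [build_tip_path_index()] for the tree.
#' @return PD: the sum of branch lengths over the union of the species'
#'   tip-to-root paths; 0 for an empty set.
#' @export
pd <- function(species, index) {
  stopifnot(inherits(index, "tip_path_index"))
  species <- unique(species[!is.na(species)])
  if (length(species) == 0L) return(0)
  missing <- setdiff(species, index$tip_labels)
  if (length(missing))
    stop("species not in tree (unmatched names should have been dropped): ",
         paste(missing, collapse = ", "))
  edges <- unique(unlist(index$paths[species], use.names = FALSE))
  sum(index$edge_lengths[edges])
}

#' Relative phylogenetic diversity of a species set
#'
#' @inheritParams pd
#' @param comp_index tip path index of the [comparison_tree()].
#' @return `pd(species, index) / pd(species, comp_index)`.
#' @export
rpd <- function(species, index, comp_index) {
  denom <- pd(species, comp_index)
  if (denom <= 0) stop("comparison-tree PD is zero; cannot form RPD")
  pd(species, index) / denom
}

#' PD for every cell of an incidence matrix at once
#'
#' Vectorized version of [pd()]: reaches each branch through the tips x
#' branches path matrix, so a single matrix product gives the branch union
#' for all cells.
#'
#' @param incidence binary cells x species matrix with species as column
#'   names (all must be tree tips).
#' @param index a [build_tip_path_index()].
#' @return numeric vector of PD values, one per row of `incidence`.
#' @export
pd_cells <- function(incidence, index) {
  stopifnot(inherits(index, "tip_path_index"))
  spp <- colnames(incidence)
  missing <- setdiff(spp, index$tip_labels)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  reach <- incidence %*% index$path_matrix[spp, , drop = FALSE]
  as.vector((reach > 0) %*% index$edge_lengths)
}

#' Compute all per-cell diversity metrics
#'
#' One row per occupied cell: richness, redundancy, observed and
#' comparison-tree PD, RPD, and the fraction of total tree length captured
#' (`PD_frac`). Unoccupied cells are absent (no data), not zero.
#'
#' @param pm a [build_presence_matrix()] result, already matched to the tree
#'   (see [match_presence_to_tree()]).
#' @param tree a validated `phylo` object.
#' @return data.frame with columns `cell_id`, `lon`, `lat` (cell centres),
#'   `n_samples`, `SR`, `redundancy`, `PD_obs`, `PD_comp`, `RPD`, `PD_frac`.
#' @export
compute_cell_diversity <- function(pm, tree) {
  stopifnot(inherits(pm, "presence_matrix"))
  idx <- build_tip_path_index(tree)
  cidx <- build_tip_path_index(comparison_tree(tree))
  inc <- pm$incidence
  sr <- as.integer(rowSums(inc))
  pd_obs <- pd_cells(inc, idx)
  pd_comp <- pd_cells(inc, cidx)
  cc <- cell_centers(pm$grid, as.integer(rownames(inc)))
  data.frame(cell_id = cc$cell_id, lon = cc$lon, lat = cc$lat,
             n_samples = as.integer(pm$n_samples[rownames(inc)]),
             SR = sr,
             redundancy = redundancy(sr, pm$n_samples[rownames(inc)]),
             PD_obs = pd_obs, PD_comp = pd_comp,
             RPD = pd_obs / pd_comp,
             PD_frac = pd_obs / idx$total_length,
             row.names = NULL)
}
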