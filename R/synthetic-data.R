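#' Configuration for the synthetic study system
#'
#' Bundles every knob of the synthetic-data generators. The defaults define
#' the standard synthetic scenario used throughout the package: a 30 x 30
#' grid of 0.1-degree cells, 60 species, 3000 records with spatially biased
#' sampling effort, a quarter of records from germplasm collections, a
#' quarter of the region protected, 8 administrative departments and 6
#' ecoregions. Each generator draws from its own random stream (config seed
#' plus a fixed per-generator offset), so adding one generator call never
#' perturbs another's output and every output is bit-reproducible under a
#' fixed seed.
#'
#' @param seed integer master seed.
#' @param n_species number of species (>= 2).
#' @param n_rows,n_cols,cell_size,origin_lon,origin_lat analysis-grid
#'   geometry (see [grid_domain()]).
#' @param n_records_total total occurrence records (>= `n_species`; every
#'   species receives at least one record).
#' @param range_kernel_sd Gaussian spread (degrees) of each species' range
#'   around its centre.
#' @param effort_bias >= 0; strength of the spatial sampling-effort bias
#'   (0 = uniform effort). Effort is a smooth multiplicative weight
#'   surface, so sampling redundancy varies across the grid.
#' @param germplasm_fraction probability a record is a germplasm (G)
#'   accession rather than a reference (H) record.
#' @param pa_coverage fraction of grid cells protected, grown as contiguous
#'   random blocks.
#' @param n_departments,n_ecoregions number of contiguous administrative
#'   zones / Voronoi ecoregions partitioning the grid.
#' @param tree_model only `"yule"` (pure-birth with exponential waiting
#'   times) is implemented.
#' @param suitability_threshold binarization threshold for suitability
#'   surfaces (default 0.5: values >= 0.5 become 1).
#' @param sdm_factor integer refinement factor of the suitability grid
#'   relative to the analysis grid (default 2, the 10 km to 5 km analogue).
#' @param sdm_fraction fraction of species (ranked by record count) that
#'   receive a suitability model; the rest emulate species with too few
#'   records to model and fall to the assigned-high-priority rule.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_species = 60L,
                         n_rows = 30L, n_cols = 30L, cell_size = 0.1,
                         origin_lon = -75, origin_lat = 0,
                         n_records_total = 3000L,
                         range_kernel_sd = 0.3,
                         effort_bias = 1,
                         germplasm_fraction = 0.25,
                         pa_coverage = 0.25,
                         n_departments = 8L, n_ecoregions = 6L,
                         tree_model = "yule",
                         suitability_threshold = 0.5,
                         sdm_factor = 2L,
                         sdm_fraction = 0.55) {
  cfg <- list(seed = as.integer(seed), n_species = as.integer(n_species),
              n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              cell_size = cell_size, origin_lon = origin_lon,
              origin_lat = origin_lat,
              n_records_total = as.integer(n_records_total),
              range_kernel_sd = range_kernel_sd, effort_bias = effort_bias,
              germplasm_fraction = germplasm_fraction,
              pa_coverage = pa_coverage,
              n_departments = as.integer(n_departments),
              n_ecoregions = as.integer(n_ecoregions),
              tree_model = match.arg(tree_model, "yule"),
              suitability_threshold = suitability_threshold,
              sdm_factor = as.integer(sdm_factor),
              sdm_fraction = sdm_fraction)
  if (cfg$n_species < 2L) stop("invalid config: n_species must be >= 2")
  if (cfg$cell_size <= 0) stop("invalid config: cell_size must be > 0")
  if (cfg$n_records_total < cfg$n_species)
    stop("invalid config: n_records_total must be >= n_species")
  if (cfg$effort_bias < 0) stop("invalid config: effort_bias must be >= 0")
  for (f in c("germplasm_fraction", "pa_coverage", "sdm_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("invalid config: ", f, " must be in [0,1]")
  n_cells <- cfg$n_rows * cfg$n_cols
  if (cfg$n_departments > n_cells || cfg$n_ecoregions > n_cells)
    stop("invalid config: more departments/ecoregions than grid cells")
  if (cfg$n_departments < 1L || cfg$n_ecoregions < 1L)
    stop("invalid config: need at least one department and ecoregion")
  class(cfg) <- "synth_config"
  cfg
}

#' @rdname synth_config
#' @param config a `synth_config`.
#' @export
synth_grid <- function(config) {
  grid_domain(config$n_rows, config$n_cols, cell_size = config$cell_size,
              origin_lon = config$origin_lon, origin_lat = config$origin_lat)
}

synth_species_names <- function(n) sprintf("sp%03d", seq_len(n))

#' Simulate a Yule tree for the synthetic species pool
#'
#' Pure-birth tree: starting from two lineages, waiting times between
#' speciation events are exponential with rate proportional to the number
#' of extant lineages; each event splits a uniformly chosen lineage. The
#' tree is ultrametric with all branch lengths strictly positive and the
#' root has no subtending edge. Tip labels are the synthetic species names.
#'
#' @param config a [synth_config()].
#' @return a rooted binary `phylo` object with `n_species` tips.
#' @export
make_tree <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_species
  set.seed(config$seed + 101L)
  # active lineages carry (parent temp id, start time); root = temp id 0
  parent <- c(0L, 0L)
  start <- c(0, 0)
  # records of finished internal edges: child temp id, parent, length
  int_id <- integer(0); int_parent <- integer(0); int_len <- numeric(0)
  next_id <- 1L
  t <- 0
  while (length(parent) < n) {
    k <- length(parent)
    t <- t + stats::rexp(1L, rate = k)
    pick <- sample.int(k, 1L)
    node <- next_id; next_id <- next_id + 1L
    int_id <- c(int_id, node)
    int_parent <- c(int_parent, parent[pick])
    int_len <- c(int_len, t - start[pick])
    parent <- c(parent[-pick], node, node)
    start <- c(start[-pick], t, t)
  }
  t_end <- t + stats::rexp(1L, rate = n)
  # ape numbering: tips 1..n, root n+1, internals n+2..2n-1
  tip_ape <- seq_len(n)
  internal_map <- c(n + 1L, if (length(int_id)) n + 1L + seq_along(int_id))
  names(internal_map) <- as.character(c(0L, int_id))
  edge <- rbind(cbind(internal_map[as.character(int_parent)],
                      internal_map[as.character(int_id)]),
                cbind(internal_map[as.character(parent)], tip_ape))
  len <- c(int_len, t_end - start)
  phy <- list(edge = unname(edge), edge.length = len,
              tip.label = synth_species_names(n), Nnode = n - 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  validate_tree(phy)
}

# smooth low-frequency effort weight surface: a handful of Gaussian bumps,
# rescaled to [0.2, 1] so no region has zero sampling probability
make_effort_surface <- function(grid, n_bumps = 5L) {
  ext_lon <- grid$n_cols * grid$cell_size
  ext_lat <- grid$n_rows * grid$cell_size
  bumps <- data.frame(
    lon = stats::runif(n_bumps, grid$origin_lon, grid$origin_lon + ext_lon),
    lat = stats::runif(n_bumps, grid$origin_lat, grid$origin_lat + ext_lat),
    sd = stats::runif(n_bumps, 0.15, 0.35) * max(ext_lon, ext_lat),
    w = stats::runif(n_bumps, 0.5, 1))
  function(lon, lat) {
    s <- 0
    for (b in seq_len(n_bumps))
      s <- s + bumps$w[b] * exp(-((lon - bumps$lon[b])^2 + (lat - bumps$lat[b])^2) /
                                  (2 * bumps$sd[b]^2))
    0.2 + 0.8 * s / sum(bumps$w)
  }
}

#' Simulate occurrence records with clustered ranges and biased effort
#'
#' Each species receives a range centre drawn uniformly inside the study
#' region and a record count (at least 1; the remainder allocated by a
#' log-normal abundance multinomial). Record coordinates are drawn from an
#' isotropic Gaussian kernel around the centre and rejection-sampled until
#' inside the study region; when `effort_bias > 0`, candidate points are
#' additionally thinned by a smooth effort weight surface raised to the
#' power `effort_bias`, producing spatially uneven sampling redundancy.
#' Each record is flagged germplasm (`G`) with probability
#' `germplasm_fraction`, reference (`H`) otherwise.
#'
#' @param config a [synth_config()].
#' @param tree the species tree from [make_tree()] (supplies tip labels).
#' @return data.frame `species, lon, lat, type, source` with attributes
#'   `range_centres` (per-species centre coordinates) and `grid`.
#' @export
make_occurrences <- function(config, tree) {
  stopifnot(inherits(config, "synth_config"), inherits(tree, "phylo"))
  grid <- synth_grid(config)
  species <- tree$tip.label
  n <- length(species)
  set.seed(config$seed + 202L)
  ext_lon <- grid$n_cols * grid$cell_size
  ext_lat <- grid$n_rows * grid$cell_size
  inset <- grid$cell_size
  draw_centre <- function() {
    repeat {
      p <- c(stats::runif(1, grid$origin_lon + inset, grid$origin_lon + ext_lon - inset),
             stats::runif(1, grid$origin_lat + inset, grid$origin_lat + ext_lat - inset))
      if (!is.na(assign_cell(p[1], p[2], grid))) return(p)
    }
  }
  centres <- t(vapply(seq_len(n), function(i) draw_centre(), numeric(2)))
  abund <- stats::rlnorm(n, 0, 1)
  extra <- stats::rmultinom(1L, config$n_records_total - n, prob = abund)[, 1L]
  counts <- 1L + extra
  effort <- make_effort_surface(grid)
  sd <- config$range_kernel_sd
  lon <- numeric(0); lat <- numeric(0); spp <- character(0)
  for (i in seq_len(n)) {
    got <- 0L
    while (got < counts[i]) {
      m <- (counts[i] - got) * 4L
      cx <- centres[i, 1L] + stats::rnorm(m, 0, sd)
      cy <- centres[i, 2L] + stats::rnorm(m, 0, sd)
      ok <- !is.na(assign_cell(cx, cy, grid))
      if (config$effort_bias > 0) {
        keep <- stats::runif(m) < effort(cx, cy)^config$effort_bias
        ok <- ok & keep
      }
      take <- which(ok)[seq_len(min(sum(ok), counts[i] - got))]
      lon <- c(lon, cx[take]); lat <- c(lat, cy[take])
      got <- got + length(take)
    }
    spp <- c(spp, rep(species[i], counts[i]))
  }
  type <- ifelse(stats::runif(length(spp)) < config$germplasm_fraction, "G", "H")
  out <- data.frame(species = spp, lon = lon, lat = lat, type = type,
                    source = "synthetic", stringsAsFactors = FALSE)
  attr(out, "range_centres") <- data.frame(species = species,
                                           lon = centres[, 1L],
                                           lat = centres[, 2L])
  attr(out, "grid") <- grid
  out
}

#' Simulate protected areas, departments and ecoregions
#'
#' Protected areas are grown as contiguous random blocks until exactly
#' `round(pa_coverage * n_cells)` cells are protected. Departments are a
#' contiguous, exhaustive, non-overlapping partition obtained by
#' multi-source flood fill from random seed cells. Ecoregions are the
#' Voronoi partition of cell centres around random seed points.
#'
#' @param config a [synth_config()].
#' @return list of class `synthetic_layers` with `protected` (logical),
#'   `departments` and `ecoregions` (integer zone ids), each a vector over
#'   cells in cell-id order, plus the `grid`.
#' @export
make_layers <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  grid <- synth_grid(config)
  n <- grid_n_cells(grid)
  set.seed(config$seed + 303L)
  neighbors <- function(id) {
    r <- id %/% grid$n_cols; c <- id %% grid$n_cols
    out <- c(if (r > 0) id - grid$n_cols,
             if (r < grid$n_rows - 1L) id + grid$n_cols,
             if (c > 0) id - 1L,
             if (c < grid$n_cols - 1L) id + 1L)
    as.integer(out)
  }
  # protected blocks
  target <- round(config$pa_coverage * n)
  protected <- rep(FALSE, n)
  while (sum(protected) < target) {
    free <- which(!protected) - 1L
    block <- min(sample(5:25, 1L), target - sum(protected))
    cur <- free[sample.int(length(free), 1L)]
    protected[cur + 1L] <- TRUE
    frontier <- setdiff(neighbors(cur), which(protected) - 1L)
    added <- 1L
    while (added < block && length(frontier) > 0L) {
      nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
      if (!protected[nxt + 1L]) {
        protected[nxt + 1L] <- TRUE
        added <- added + 1L
        frontier <- union(frontier, neighbors(nxt))
      }
      frontier <- frontier[!protected[frontier + 1L]]
    }
  }
  # departments: multi-source flood fill
  departments <- integer(n)
  seeds <- sample.int(n, config$n_departments) - 1L
  departments[seeds + 1L] <- seq_along(seeds)
  queue <- seeds
  while (length(queue) > 0L) {
    queue <- queue[sample.int(length(queue))]
    nxt_queue <- integer(0)
    for (id in queue) {
      for (nb in neighbors(id)) {
        if (departments[nb + 1L] == 0L) {
          departments[nb + 1L] <- departments[id + 1L]
          nxt_queue <- c(nxt_queue, nb)
        }
      }
    }
    queue <- nxt_queue
  }
  # ecoregions: Voronoi on cell centres
  cc <- cell_centers(grid)
  ext_lon <- grid$n_cols * grid$cell_size
  ext_lat <- grid$n_rows * grid$cell_size
  es <- cbind(stats::runif(config$n_ecoregions, grid$origin_lon, grid$origin_lon + ext_lon),
              stats::runif(config$n_ecoregions, grid$origin_lat, grid$origin_lat + ext_lat))
  d2 <- outer(cc$lon, es[, 1L], "-")^2 + outer(cc$lat, es[, 2L], "-")^2
  ecoregions <- max.col(-d2, ties.method = "first")
  structure(list(protected = protected, departments = departments,
                 ecoregions = as.integer(ecoregions), grid = grid),
            class = "synthetic_layers")
}

#' Simulate binary suitability rasters
#'
#' Stand-ins for species distribution model outputs: for each modelled
#' species, continuous suitability on the refined grid decays as a Gaussian
#' of distance (degrees) from the species' range centre, with a per-species
#' width slightly wider than the occurrence kernel (the potential range
#' exceeds the sampled one). Values are binarized at
#' `suitability_threshold` (>= threshold becomes 1); cells outside the
#' study region are `NA`. When record counts are supplied, only the
#' top `sdm_fraction` of species by record count are modelled, emulating
#' species with too few records to model.
#'
#' @param config a [synth_config()].
#' @param ranges per-species range centres (the `range_centres` attribute
#'   of [make_occurrences()]).
#' @param n_records optional named per-species record counts used to select
#'   the modelled subset; `NULL` models every species.
#' @return named list of binary matrices on the refined grid (attribute
#'   `continuous` holds the underlying surfaces; attribute `fine_grid` the
#'   refined [grid_domain()]).
#' @export
make_suitability <- function(config, ranges, n_records = NULL) {
  stopifnot(inherits(config, "synth_config"), is.data.frame(ranges))
  grid <- synth_grid(config)
  fine <- refine_grid(grid, config$sdm_factor)
  set.seed(config$seed + 404L)
  species <- ranges$species
  if (!is.null(n_records)) {
    n_model <- round(config$sdm_fraction * length(species))
    ord <- order(-n_records[species], species)
    species <- sort(species[ord[seq_len(n_model)]])
  }
  cc <- cell_centers(fine)
  outside <- !fine$study_mask
  sds <- stats::runif(length(species), 1.2, 1.8) * config$range_kernel_sd
  names(sds) <- species
  cont <- list(); bin <- list()
  for (s in species) {
    ctr <- ranges[ranges$species == s, , drop = FALSE]
    d2 <- (cc$lon - ctr$lon)^2 + (cc$lat - ctr$lat)^2
    surf <- exp(-d2 / (2 * sds[[s]]^2))
    surf[outside] <- NA
    b <- ifelse(surf >= config$suitability_threshold, 1, 0)
    cont[[s]] <- grid_matrix(surf, fine)
    bin[[s]] <- grid_matrix(b, fine)
  }
  attr(bin, "continuous") <- cont
  attr(bin, "fine_grid") <- fine
  bin
}

#' Write the full synthetic input bundle to disk
#'
#' Occurrences as CSV, tree as newick, layers and suitability rasters as
#' ASCII grids, and the configuration as YAML.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if absent).
#' @return invisibly, a named list of the generated objects.
#' @export
write_synthetic_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tree <- make_tree(config)
  occ <- make_occurrences(config, tree)
  layers <- make_layers(config)
  grid <- layers$grid
  counts <- table(occ$species)
  sdms <- make_suitability(config, attr(occ, "range_centres"),
                           n_records = stats::setNames(as.integer(counts), names(counts)))
  fine <- attr(sdms, "fine_grid")
  utils::write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE,
                   quote = FALSE)
  write_tree(tree, file.path(dir, "tree.nwk"))
  write_ascii_grid(grid_matrix(as.numeric(layers$protected), grid), grid,
                   file.path(dir, "protected.asc"))
  write_ascii_grid(grid_matrix(as.numeric(layers$departments), grid), grid,
                   file.path(dir, "departments.asc"))
  write_ascii_grid(grid_matrix(as.numeric(layers$ecoregions), grid), grid,
                   file.path(dir, "ecoregions.asc"))
  sdm_dir <- file.path(dir, "sdm")
  dir.create(sdm_dir, showWarnings = FALSE)
  for (s in names(sdms))
    write_ascii_grid(sdms[[s]], fine, file.path(sdm_dir, paste0(s, ".asc")))
  yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  invisible(list(tree = tree, occurrences = occ, layers = layers, sdms = sdms))
}
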