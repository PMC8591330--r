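test_that("config validation rejects impossible study systems", {
  expect_error(synth_config(n_species = 1), "n_species")
  expect_error(synth_config(cell_size = 0), "cell_size")
  expect_error(synth_config(n_records_total = 10, n_species = 20),
               "n_records_total")
  expect_error(synth_config(germplasm_fraction = 1.2), "germplasm_fraction")
  expect_error(quick_config(n_departments = 1000), "departments")
})

test_that("Yule trees are valid, binary, positive and reproducible", {
  cfg <- synth_config(seed = 4, n_species = 2)
  phy <- make_tree(cfg)
  expect_equal(length(phy$tip.label), 2L)
  expect_equal(nrow(phy$edge), 2L)  # root carries no subtending edge
  expect_true(all(phy$edge.length > 0))

  cfg50 <- synth_config(seed = 1, n_species = 50)
  t1 <- make_tree(cfg50)
  t2 <- make_tree(cfg50)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.binary(t1))
  expect_true(ape::is.rooted(t1))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  # total length survives a reparse of the emitted newick
  reparsed <- ape::read.tree(text = ape::write.tree(t1, digits = 12))
  expect_equal(sum(reparsed$edge.length), sum(t1$edge.length),
               tolerance = 1e-9)
})

test_that("occurrences respect the mask, the tree tips, and the germplasm split", {
  cfg <- quick_config(seed = 2, n_records_total = 1000,
                      germplasm_fraction = 0.2)
  tree <- make_tree(cfg)
  occ <- make_occurrences(cfg, tree)
  g <- synth_grid(cfg)
  expect_equal(nrow(occ), 1000L)
  expect_setequal(unique(occ$species), tree$tip.label)   # every species sampled
  expect_false(anyNA(assign_cell(occ$lon, occ$lat, g)))  # all inside the mask
  # germplasm share within the binomial 99% interval around 0.2
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.2)
  expect_true(sum(occ$type == "G") >= bounds[1] &&
              sum(occ$type == "G") <= bounds[2])
  # determinism
  expect_identical(occ, make_occurrences(cfg, tree))
})

test_that("germplasm_fraction = 0 yields no germplasm records", {
  cfg <- quick_config(seed = 3, germplasm_fraction = 0)
  occ <- make_occurrences(cfg, make_tree(cfg))
  expect_equal(sum(occ$type == "G"), 0L)
})

test_that("layers partition the grid and hit the protected coverage", {
  cfg <- quick_config(seed = 6, pa_coverage = 0.3)
  layers <- make_layers(cfg)
  n <- 100
  expect_equal(length(layers$protected), n)
  expect_lte(abs(sum(layers$protected) - 0.3 * n), 1)  # within one cell
  expect_setequal(unique(layers$departments), 1:4)     # exhaustive partition
  expect_equal(length(layers$departments), n)
  expect_setequal(unique(layers$ecoregions), 1:4)
  expect_identical(layers, make_layers(cfg))
  # extremes
  expect_equal(sum(make_layers(quick_config(pa_coverage = 0))$protected), 0)
  expect_equal(sum(make_layers(quick_config(pa_coverage = 1))$protected), n)
})

test_that("departments are contiguous zones", {
  cfg <- quick_config(seed = 9, n_departments = 5)
  layers <- make_layers(cfg)
  g <- synth_grid(cfg)
  # flood fill within one department must reach all its cells
  for (d in unique(layers$departments)) {
    cells <- which(layers$departments == d) - 1L
    reached <- cells[1]
    frontier <- cells[1]
    while (length(frontier) > 0) {
      r <- frontier %/% g$n_cols; c <- frontier %% g$n_cols
      nb <- c(frontier - g$n_cols, frontier + g$n_cols,
              ifelse(c > 0, frontier - 1L, -1L),
              ifelse(c < g$n_cols - 1L, frontier + 1L, -1L))
      nxt <- setdiff(intersect(nb, cells), reached)
      reached <- c(reached, nxt)
      frontier <- nxt
    }
    expect_setequal(reached, cells)
  }
})

test_that("suitability binarization matches the stored continuous surface", {
  cfg <- quick_config(seed = 12)
  tree <- make_tree(cfg)
  occ <- make_occurrences(cfg, tree)
  ranges <- attr(occ, "range_centres")
  sdms <- make_suitability(cfg, ranges)
  cont <- attr(sdms, "continuous")
  fine <- attr(sdms, "fine_grid")
  expect_equal(fine$n_rows, cfg$n_rows * cfg$sdm_factor)
  for (s in names(sdms)[1:3]) {
    recomputed <- ifelse(cont[[s]] >= 0.5, 1, 0)
    expect_equal(sdms[[s]], recomputed)
  }
  # extreme thresholds
  hi <- make_suitability(quick_config(seed = 12, suitability_threshold = 1.1),
                         ranges)
  expect_true(all(unlist(hi) == 0, na.rm = TRUE))
  lo <- make_suitability(quick_config(seed = 12, suitability_threshold = 0),
                         ranges)
  expect_true(all(unlist(lo) == 1, na.rm = TRUE))
})

test_that("record-count ranking selects the modelled species subset", {
  cfg <- quick_config(seed = 13, sdm_fraction = 0.5)
  tree <- make_tree(cfg)
  occ <- make_occurrences(cfg, tree)
  counts <- table(occ$species)
  sdms <- make_suitability(cfg, attr(occ, "range_centres"),
                           n_records = setNames(as.integer(counts),
                                                names(counts)))
  expect_equal(length(sdms), 10L)
  modelled_min <- min(counts[names(sdms)])
  unmodelled_max <- max(counts[setdiff(tree$tip.label, names(sdms))])
  expect_gte(modelled_min, unmodelled_max - 1L)  # top-by-count selection
})

test_that("the synthetic input bundle writes and round-trips from disk", {
  cfg <- quick_config(seed = 14)
  d <- tempfile()
  objs <- write_synthetic_inputs(cfg, d)
  expect_true(all(file.exists(file.path(d, c("occurrences.csv", "tree.nwk",
                                             "protected.asc", "config.yaml")))))
  rt <- read_tree(file.path(d, "tree.nwk"))
  expect_setequal(rt$tip.label, objs$tree$tip.label)
  prot <- read_ascii_grid(file.path(d, "protected.asc"))
  expect_equal(grid_values(prot$mat, prot$grid),
               as.numeric(objs$layers$protected))
  occ <- read_occurrence_csv(file.path(d, "occurrences.csv"))
  expect_equal(nrow(occ), nrow(objs$occurrences))
})
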