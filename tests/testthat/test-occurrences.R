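test_that("assign_cell follows the half-open convention with closed outer edges", {
  g <- grid_domain(10, 10, cell_size = 0.1, origin_lon = -75, origin_lat = 0)
  # interior shared edge belongs to the higher-index cell
  expect_equal(assign_cell(-74.9, 0.05, g), 1L)
  expect_equal(assign_cell(-74.95, 0.1, g), 10L)
  # exact upper-right corner folds into the last cell
  expect_equal(assign_cell(-74, 1, g), 99L)
  # outside the grid
  expect_true(is.na(assign_cell(-75.01, 0.5, g)))
  expect_true(is.na(assign_cell(-74.5, 1.01, g)))
})

test_that("assign_cell matches a floor-division oracle on random points", {
  g <- grid_domain(13, 17, cell_size = 0.05, origin_lon = 3, origin_lat = -2)
  set.seed(42)
  lon <- runif(1000, 2.8, 4.0)
  lat <- runif(1000, -2.2, -1.2)
  oracle <- function(x, y) {
    col <- floor((x - 3) / 0.05); row <- floor((y + 2) / 0.05)
    ifelse(col >= 0 & col < 17 & row >= 0 & row < 13, row * 17 + col, NA)
  }
  expect_equal(assign_cell(lon, lat, g), as.integer(oracle(lon, lat)))
})

test_that("clean_records counts each removal rule and preserves order", {
  g <- grid_domain(10, 10, cell_size = 0.1, origin_lon = 0, origin_lat = 0)
  rec <- data.frame(species = c("a", "b", "c", "d", "e"),
                    lon = c(0.05, NA, 0.15, 0.25, 5),
                    lat = c(0.05, 0.5, 0.15, 0.25, 0.5),
                    type = "H", source = "x")
  out <- clean_records(rec, g)
  expect_equal(unname(out$report["missing_coords"]), 1)
  expect_equal(unname(out$report["outside_region"]), 1)
  expect_equal(out$records$species, c("a", "c", "d"))
})

test_that("records in masked-out cells are removed", {
  mask <- rep(TRUE, 100); mask[1] <- FALSE
  g <- grid_domain(10, 10, cell_size = 0.1, origin_lon = 0, origin_lat = 0,
                   study_mask = mask)
  rec <- data.frame(species = "a", lon = 0.05, lat = 0.05, type = "H",
                    source = "x")
  out <- clean_records(rec, g)
  expect_equal(nrow(out$records), 0L)
  expect_equal(unname(out$report["outside_region"]), 1)
})

test_that("injected invalid records are recovered rule by rule", {
  g <- grid_domain(10, 10, cell_size = 0.1, origin_lon = 0, origin_lat = 0)
  set.seed(7)
  good <- data.frame(species = sample(letters[1:5], 90, replace = TRUE),
                     lon = runif(90, 0, 1), lat = runif(90, 0, 1),
                     type = "H", source = "x")
  bad <- data.frame(
    species = c(rep("a", 4), rep("zz", 3), rep("b", 3)),
    lon = c(rep(NA, 4), runif(3, 0, 1), runif(3, 2, 3)),
    lat = c(runif(4, 0, 1), runif(3, 0, 1), runif(3, 0, 1)),
    type = "H", source = "x")
  mixed <- rbind(good, bad)[sample.int(100), ]
  out <- clean_records(mixed, g, exclude = "zz")
  expect_equal(unname(out$report["missing_coords"]), 4)
  expect_equal(unname(out$report["excluded_species"]), 3)
  expect_equal(unname(out$report["outside_region"]), 3)
  expect_equal(nrow(out$records), 90L)
})

test_that("cleaning is idempotent", {
  g <- grid_domain(5, 5, cell_size = 0.2, origin_lon = 0, origin_lat = 0)
  set.seed(3)
  rec <- data.frame(species = sample(c("a", " b ", "c  d"), 50, replace = TRUE),
                    lon = runif(50, -0.2, 1.2), lat = runif(50, -0.2, 1.2),
                    type = "H", source = "x")
  once <- clean_records(rec, g)
  twice <- clean_records(once$records, g)
  expect_equal(twice$records, once$records)
  expect_equal(unname(twice$report["n_retained"]),
               unname(once$report["n_retained"]))
})

test_that("presence matrix separates incidence from sample counts", {
  g <- grid_domain(5, 5, cell_size = 0.2, origin_lon = 0, origin_lat = 0)
  rec <- data.frame(species = c("A", "A", "B", "C", "D"),
                    lon = c(0.1, 0.15, 0.1, 0.5, 0.9),
                    lat = c(0.1, 0.12, 0.1, 0.5, 0.9),
                    type = "H", source = "x")
  pm <- build_presence_matrix(rec, g)
  expect_equal(nrow(pm$incidence), 3L)  # three occupied cells
  c0 <- pm$incidence["0", ]
  expect_equal(unname(c0[c("A", "B")]), c(1L, 1L))
  expect_equal(unname(pm$n_samples["0"]), 3L)  # duplicates kept in N
  expect_equal(sum(pm$n_samples), nrow(rec))
})

test_that("presence matrix marginals match a tabulation oracle", {
  cfg <- quick_config(seed = 5)
  tree <- make_tree(cfg)
  occ <- make_occurrences(cfg, tree)
  g <- synth_grid(cfg)
  pm <- build_presence_matrix(clean_records(occ, g)$records, g)
  cell <- assign_cell(occ$lon, occ$lat, g)
  oracle_range <- vapply(pm$species, function(s)
    length(unique(cell[occ$species == s])), 0L)
  expect_equal(unname(pm$range_size[pm$species]), unname(oracle_range))
  oracle_rich <- vapply(rownames(pm$incidence), function(cl)
    length(unique(occ$species[cell == as.integer(cl)])), 0L)
  expect_equal(unname(rowSums(pm$incidence)), unname(oracle_rich))
  # total presences = number of distinct (species, cell) pairs
  expect_equal(sum(pm$incidence),
               nrow(unique(data.frame(occ$species, cell))))
})

test_that("empty inputs raise an explicit empty-dataset error", {
  g <- grid_domain(5, 5)
  expect_error(build_presence_matrix(data.frame(species = character(),
                                                lon = numeric(),
                                                lat = numeric()), g),
               "empty dataset")
})

test_that("species unmatched to the tree are dropped with a warning", {
  g <- grid_domain(5, 5, cell_size = 0.2, origin_lon = 0, origin_lat = 0)
  rec <- data.frame(species = c("A", "B", "ghost"),
                    lon = c(0.1, 0.5, 0.9), lat = c(0.1, 0.5, 0.9),
                    type = "H", source = "x")
  pm <- build_presence_matrix(rec, g)
  tree <- ape::read.tree(text = "(A:1,B:1);")
  expect_warning(pm2 <- match_presence_to_tree(pm, tree), "ghost")
  expect_setequal(pm2$species, c("A", "B"))
  expect_equal(nrow(pm2$incidence), 2L)  # ghost's cell dropped
})

test_that("occurrence CSV round-trips through read and export", {
  g <- grid_domain(5, 5, cell_size = 0.2, origin_lon = 0, origin_lat = 0)
  f <- tempfile(fileext = ".csv")
  writeLines(c("species,lon,lat,type,source",
               "A,0.1,0.1,H,x", "A,0.12,0.1,G,x", "B,notanumber,0.5,H,x"), f)
  rec <- read_occurrence_csv(f)
  expect_equal(nrow(rec), 3L)
  out <- clean_records(rec, g)
  expect_equal(unname(out$report["missing_coords"]), 1)
  pm <- build_presence_matrix(out$records, g)
  tf <- tempfile(); cf <- tempfile()
  write_presence_matrix(pm, tf, cf)
  trip <- read.csv(tf)
  expect_equal(nrow(trip), sum(pm$incidence))
  cells <- read.csv(cf)
  expect_equal(cells$n_samples, 2L)
})
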