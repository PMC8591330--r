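# toy geometry: 10x10 grid of 0.1-degree cells at the equator, so cell
# centres in one column are ~11.1 km apart north-south
toy_gap_setup <- function() {
  fine <- grid_domain(10, 10, cell_size = 0.1, origin_lon = 0, origin_lat = 0)
  # 20 suitable cells: 5 in column 5 (rows 3..7), 15 in column 0 (rows 0..9
  # plus 5 in column 1) far from the germplasm point
  suit <- rep(0, 100)
  near <- vapply(3:7, function(r) r * 10L + 5L, 0L)
  far <- c(vapply(0:9, function(r) r * 10L, 0L),
           vapply(0:4, function(r) r * 10L + 1L, 0L))
  suit[c(near, far) + 1L] <- 1
  sdm <- grid_matrix(suit, fine)
  # ecoregion 1 = columns 0..2, ecoregion 2 = columns 3..9
  eco <- vapply(0:99, function(id) if (id %% 10 < 3) 1L else 2L, 0L)
  # one germplasm point at the centre of cell (row 5, col 5)
  g_rec <- data.frame(species = "sp", lon = 0.55, lat = 0.55, type = "G",
                      source = "x")
  list(fine = fine, sdm = sdm, eco = eco, g_rec = g_rec,
       near = near, far = far)
}

test_that("ex-situ scores match the cell-count oracle on toy geometry", {
  s <- toy_gap_setup()
  # buffer 25 km: reaches rows +-2 in the same column, not column 0 (55 km)
  sc <- exsitu_scores(s$g_rec, s$sdm, s$eco, s$fine, buffer_km = 25)
  expect_equal(sc$SRSex, 100)          # all records are germplasm
  expect_equal(sc$GRSex, 25)           # 5 of 20 suitable cells buffered
  expect_equal(sc$ERSex, 50)           # 1 of 2 ecoregions touched
  expect_equal(sc$FCSex, mean(c(100, 25, 50)))
})

test_that("ex-situ scores collapse to zero without germplasm", {
  s <- toy_gap_setup()
  h_only <- transform(s$g_rec, type = "H")
  sc <- exsitu_scores(h_only, s$sdm, s$eco, s$fine, buffer_km = 25)
  expect_equal(c(sc$SRSex, sc$GRSex, sc$ERSex, sc$FCSex), c(0, 0, 0, 0))
  # G = H gives a sampling score of 50
  gh <- rbind(s$g_rec, h_only)
  expect_equal(exsitu_scores(gh, s$sdm, s$eco, s$fine, 25)$SRSex, 50)
})

test_that("zero suitable cells are flagged and scored 0", {
  s <- toy_gap_setup()
  empty <- grid_matrix(rep(0, 100), s$fine)
  sc <- exsitu_scores(s$g_rec, empty, s$eco, s$fine, 25)
  expect_true(sc$zero_suitable)
  expect_equal(c(sc$GRSex, sc$ERSex), c(0, 0))
})

test_that("in-situ scores follow the protected mask", {
  s <- toy_gap_setup()
  all_prot <- rep(TRUE, 100)
  sc <- insitu_scores(s$g_rec, s$sdm, all_prot, s$eco, s$fine)
  expect_equal(c(sc$SRSin, sc$GRSin, sc$ERSin), c(100, 100, 100))
  none <- rep(FALSE, 100)
  sc0 <- insitu_scores(s$g_rec, s$sdm, none, s$eco, s$fine)
  expect_equal(c(sc0$SRSin, sc0$GRSin, sc0$ERSin), c(0, 0, 0))
  # half the suitable cells protected, both ecoregions still represented
  half <- rep(FALSE, 100)
  half[c(s$near, s$far[seq_along(s$near)]) + 1L] <- TRUE  # 5 near + 5 far
  sch <- insitu_scores(s$g_rec, s$sdm, half, s$eco, s$fine)
  expect_equal(sch$GRSin, 50)
  expect_equal(sch$ERSin, 100)
})

test_that("protected-area buffering extends the refined mask by distance", {
  coarse <- grid_domain(5, 5, cell_size = 0.2, origin_lon = 0, origin_lat = 0)
  fine <- refine_grid(coarse, 2)
  prot <- rep(FALSE, 25); prot[13] <- TRUE  # centre cell
  plain <- buffer_protected(prot, coarse, fine, pa_buffer_km = 0)
  expect_equal(sum(plain), 4)  # one coarse cell = 4 fine cells
  buf <- buffer_protected(prot, coarse, fine, pa_buffer_km = 12)
  expect_gt(sum(buf), 4)       # 12 km reaches the neighbouring fine ring
  expect_true(all(plain[buf == FALSE] == FALSE))
})

test_that("categories bin scores with left-closed boundaries", {
  expect_equal(as.character(conservation_category(c(0, 24.9, 25, 49.9, 50,
                                                    74.9, 75, 100))),
               c("HP", "HP", "MP", "MP", "LP", "LP", "SC", "SC"))
  expect_error(conservation_category(101), "0, 100")
})

test_that("combined score averages the final scores and categorizes each", {
  cmb <- combine_and_categorize(33.05, 18.05)
  expect_equal(cmb$FCSc_mean, 25.55)
  expect_equal(as.character(cmb$category_combined), "MP")
  expect_equal(as.character(cmb$category_ex), "MP")
  expect_equal(as.character(cmb$category_in), "HP")
  expect_equal(as.character(combine_and_categorize(80, 80)$category_combined),
               "SC")
  expect_error(combine_and_categorize(120, 10), "0, 100")
})

test_that("the cohort pipeline scores modelled species and assigns the rest HP", {
  cfg <- quick_config(seed = 21)
  tree <- make_tree(cfg)
  occ <- make_occurrences(cfg, tree)
  layers <- make_layers(cfg)
  grid <- synth_grid(cfg)
  counts <- table(occ$species)
  sdms <- make_suitability(cfg, attr(occ, "range_centres"),
                           n_records = setNames(as.integer(counts),
                                                names(counts)))
  cl <- clean_records(occ, grid)
  scores <- conservation_gap_analysis(cl$records, sdms, layers$protected,
                                      layers$ecoregions, grid,
                                      attr(sdms, "fine_grid"),
                                      species = tree$tip.label)
  expect_equal(nrow(scores), 20L)
  expect_equal(sum(scores$assessed), length(sdms))
  un <- scores[!scores$assessed, ]
  expect_true(all(un$category_combined == "HP"))
  expect_true(all(is.na(un$FCSex)))  # no fabricated zeros
  # score algebra on assessed rows
  as_ <- scores[scores$assessed, ]
  expect_equal(as_$FCSex, unname(rowMeans(as_[, c("SRSex", "GRSex", "ERSex")])),
               tolerance = 1e-9)
  expect_equal(as_$FCSin, unname(rowMeans(as_[, c("SRSin", "GRSin", "ERSin")])),
               tolerance = 1e-9)
  expect_equal(as_$FCSc_mean, (as_$FCSex + as_$FCSin) / 2, tolerance = 1e-9)
  expect_true(all(as_[, 2:10] >= 0 & as_[, 2:10] <= 100, na.rm = TRUE))
})

test_that("cohort summary truncates percentage shares", {
  df <- data.frame(species = c("a", "b", "c"),
                   SRSex = 1, GRSex = 1, ERSex = 1, FCSex = 1,
                   SRSin = 1, GRSin = 1, ERSin = 1, FCSin = 1, FCSc_mean = 1,
                   category_ex = c("HP", "MP", "MP"),
                   category_in = c("HP", "HP", "HP"),
                   category_combined = c("HP", "MP", "LP"),
                   assessed = TRUE)
  cs <- cohort_summary(df)
  ex <- cs$counts[cs$counts$score_type == "category_ex", ]
  expect_equal(ex$pct[ex$category == "HP"], 33.3)  # floor(33.33...)
  expect_equal(ex$pct[ex$category == "MP"], 66.6)  # floor(66.66...), not 66.7
  cmb <- cs$counts[cs$counts$score_type == "category_combined", ]
  expect_equal(sum(cmb$count), 3L)
})

test_that("summary bookkeeping separates assessed from assigned species", {
  df <- data.frame(species = letters[1:10],
                   SRSex = c(rep(40, 6), rep(NA, 4)),
                   GRSex = c(rep(40, 6), rep(NA, 4)),
                   ERSex = c(rep(40, 6), rep(NA, 4)),
                   FCSex = c(rep(40, 6), rep(NA, 4)),
                   SRSin = c(rep(20, 6), rep(NA, 4)),
                   GRSin = c(rep(20, 6), rep(NA, 4)),
                   ERSin = c(rep(20, 6), rep(NA, 4)),
                   FCSin = c(rep(20, 6), rep(NA, 4)),
                   FCSc_mean = c(rep(30, 6), rep(NA, 4)),
                   category_ex = c(rep("MP", 6), rep("HP", 4)),
                   category_in = c(rep("HP", 6), rep("HP", 4)),
                   category_combined = c(rep("MP", 6), rep("HP", 4)),
                   assessed = c(rep(TRUE, 6), rep(FALSE, 4)))
  assessed <- cohort_summary(df, assessed_only = TRUE)
  expect_equal(assessed$n, 6L)
  full <- cohort_summary(df, assessed_only = FALSE)
  cmb <- full$counts[full$counts$score_type == "category_combined", ]
  expect_equal(cmb$count[cmb$category == "HP"], 4L)  # injection ledger
  expect_equal(cmb$count[cmb$category == "MP"], 6L)
  expect_equal(unname(full$means["FCSc_mean"]), 30)  # means over assessed only
  # linearity: mean FCSc equals the mean of the two column means
  expect_equal(unname(full$means["FCSc_mean"]),
               mean(c(full$means[["FCSex"]], full$means[["FCSin"]])))
})
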