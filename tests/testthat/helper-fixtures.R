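# shared fixtures and independent oracles

# 4-tip tree used in the worked PD/RPD examples
toy_tree <- function() ape::read.tree(text = "((A:1,B:1):2,(C:3,D:1):1);")

# independent PD oracle: per-tip parent walk on the raw edge table, union of
# visited edges (does not touch tip_path_index or pd_cells)
pd_oracle <- function(species, phy) {
  species <- unique(species)
  if (length(species) == 0L) return(0)
  edges_used <- integer(0)
  for (tp in match(species, phy$tip.label)) {
    node <- tp
    repeat {
      e <- which(phy$edge[, 2L] == node)
      if (length(e) == 0L) break
      edges_used <- c(edges_used, e)
      node <- phy$edge[e, 1L]
    }
  }
  sum(phy$edge.length[unique(edges_used)])
}

# random binary incidence with every cell occupied
random_incidence <- function(n_cells, species, p = 0.15, seed = 1) {
  set.seed(seed)
  inc <- matrix(rbinom(n_cells * length(species), 1L, p),
                nrow = n_cells,
                dimnames = list(as.character(seq_len(n_cells) - 1L), species))
  empty <- rowSums(inc) == 0L
  inc[cbind(which(empty), sample.int(length(species), sum(empty), replace = TRUE))] <- 1L
  storage.mode(inc) <- "integer"
  inc
}

# two-clade tree with a planted set of uniquely long branches
planted_tree <- function(n_short = 34L, n_long = 6L,
                         short_len = 0.1, long_len = 5) {
  short <- paste(sprintf("s%02d:%g", seq_len(n_short), short_len), collapse = ",")
  long <- paste(sprintf("l%02d:%g", seq_len(n_long), long_len), collapse = ",")
  ape::read.tree(text = sprintf("((%s):%g,(%s):%g);",
                                short, short_len, long, long_len))
}

quick_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_species = 20L, n_rows = 10L, n_cols = 10L,
         n_records_total = 400L, n_departments = 4L, n_ecoregions = 4L),
    list(...))
  do.call(synth_config, args)
}
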