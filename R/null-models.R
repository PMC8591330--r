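#' Richness- and range-constrained matrix randomization
#'
#' Randomizes a binary cell x species incidence matrix while holding every
#' cell's richness (row sum) and every species' range size (column sum)
#' exactly constant (a fixed-fixed null), using curveball trades: each
#' trade takes two cells, keeps their shared species, and randomly re-deals
#' the species found in only one of them. The default number of trades is
#' 5 x the number of presences, enough to mix matrices of the sizes used
#' here.
#'
#' @param incidence binary matrix (cells x species).
#' @param n_trades number of curveball trades, or `"auto"` (default,
#'   `5 * sum(incidence)`).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the realization is reproducible.
#' @return a randomized binary matrix with identical row and column sums.
#' @export
randomize_matrix <- function(incidence, n_trades = "auto", seed = NULL) {
  stopifnot(is.matrix(incidence), all(incidence %in% c(0L, 1L)))
  if (identical(n_trades, "auto")) n_trades <- 5L * sum(incidence)
  if (!is.null(seed)) set.seed(seed)
  storage.mode(incidence) <- "integer"
  curveball_trades(incidence, as.integer(n_trades))
}

#' Rank significance of observed metrics against null realizations
#'
#' For each cell, counts realizations at or above (`count_ge`) and at or
#' below (`count_le`) the observed value (ties counted on both sides) and
#' forms rank p values with the +1 correction, `p = (count + 1) /
#' (n_reps + 1)`, so p is never 0. A tail is significant when its p value
#' is `<= alpha_tail`; for a two-tailed test use `alpha / 2` per tail. When
#' both tails tie at significance the high tail wins (documented
#' tie-break; only possible for tiny `n_reps`).
#'
#' @param observed named numeric vector of per-cell observed values.
#' @param nulls matrix of null values, cells x realizations, rows aligned
#'   with `observed`.
#' @param alpha_tail per-tail significance level.
#' @return data.frame with `count_ge`, `count_le`, `p_high`, `p_low`,
#'   `class` (`"sig_high"`, `"sig_low"`, `"ns"`).
#' @export
rank_significance <- function(observed, nulls, alpha_tail = 0.05) {
  if (nrow(nulls) != length(observed)) stop("cell sets of observed and nulls differ")
  tol <- 1e-9 * pmax(1, abs(observed))
  count_ge <- rowSums(nulls >= observed - tol)
  count_le <- rowSums(nulls <= observed + tol)
  n_reps <- ncol(nulls)
  p_high <- (count_ge + 1) / (n_reps + 1)
  p_low <- (count_le + 1) / (n_reps + 1)
  cls <- ifelse(p_high <= alpha_tail, "sig_high",
                ifelse(p_low <= alpha_tail, "sig_low", "ns"))
  data.frame(count_ge = count_ge, count_le = count_le,
             p_high = p_high, p_low = p_low, class = cls,
             row.names = NULL)
}

#' Randomization test for PD and RPD across all cells
#'
#' Runs `n_reps` fixed-fixed randomizations of the incidence matrix,
#' recomputes PD and RPD for every occupied cell on each realization, and
#' classes each cell by rank significance: PD on each tail at `alpha`
#' (both "significantly high" and "significantly low" PD are reported),
#' RPD two-tailed at `alpha / 2` per tail. Realizations are chained (each
#' starts from the previous) with per-realization reseeding
#' (`seed + rep`), so runs are fully reproducible and adding realizations
#' does not perturb earlier ones.
#'
#' @param pm a [build_presence_matrix()] result matched to the tree.
#' @param tree a validated `phylo` object.
#' @param n_reps number of random realizations (default 999).
#' @param seed integer base seed.
#' @param alpha significance level (default 0.05).
#' @param n_trades trades per realization, or `"auto"`.
#' @return data.frame, one row per occupied cell: `cell_id`, observed `SR`,
#'   `PD_obs`, `RPD_obs`, then `p_high_PD`, `p_low_PD`, `class_PD`,
#'   `p_high_RPD`, `p_low_RPD`, `class_RPD`. Attribute `config` records the
#'   randomization settings.
#' @export
run_null_analysis <- function(pm, tree, n_reps = 999L, seed = 1L,
                              alpha = 0.05, n_trades = "auto") {
  stopifnot(inherits(pm, "presence_matrix"), n_reps >= 1L,
            alpha > 0, alpha < 1)
  idx <- build_tip_path_index(tree)
  cidx <- build_tip_path_index(comparison_tree(tree))
  inc <- pm$incidence
  storage.mode(inc) <- "integer"
  if (identical(n_trades, "auto")) n_trades <- 5L * sum(inc)
  pd_obs <- pd_cells(inc, idx)
  rpd_obs <- pd_obs / pd_cells(inc, cidx)
  null_pd <- matrix(0, nrow(inc), n_reps)
  null_rpd <- matrix(0, nrow(inc), n_reps)
  cur <- inc
  for (rep in seq_len(n_reps)) {
    set.seed(seed + rep)
    cur <- curveball_trades(cur, as.integer(n_trades))
    npd <- pd_cells(cur, idx)
    null_pd[, rep] <- npd
    null_rpd[, rep] <- npd / pd_cells(cur, cidx)
  }
  sig_pd <- rank_significance(pd_obs, null_pd, alpha_tail = alpha)
  sig_rpd <- rank_significance(rpd_obs, null_rpd, alpha_tail = alpha / 2)
  out <- data.frame(cell_id = as.integer(rownames(inc)),
                    SR = as.integer(rowSums(inc)),
                    PD_obs = pd_obs, RPD_obs = rpd_obs,
                    count_ge_PD = sig_pd$count_ge, count_le_PD = sig_pd$count_le,
                    p_high_PD = sig_pd$p_high, p_low_PD = sig_pd$p_low,
                    class_PD = sig_pd$class,
                    count_ge_RPD = sig_rpd$count_ge, count_le_RPD = sig_rpd$count_le,
                    p_high_RPD = sig_rpd$p_high, p_low_RPD = sig_rpd$p_low,
                    class_RPD = sig_rpd$class,
                    row.names = NULL)
  attr(out, "config") <- list(n_reps = as.integer(n_reps), seed = as.integer(seed),
                              alpha = alpha, n_trades = as.integer(n_trades))
  out
}
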