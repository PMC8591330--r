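#' Diversity hot-spot cells
#'
#' Cells at or above the `q`-th percentile of the occupied-cell values,
#' using linear interpolation between order statistics (the common
#' "type 7" percentile) and an inclusive `>=` threshold, so ties at the
#' threshold are included. With all values equal every cell is a hot spot
#' (degenerate but well defined); `q = 0` returns all occupied cells. For
#' significance-class metrics the hot spots are instead the cells carrying
#' the class label (see [conservation_assessment()]).
#'
#' @param values named numeric vector (names = cell ids) over occupied
#'   cells.
#' @param q percentile in `[0, 100]` (default 95).
#' @return character vector of hot-spot cell ids.
#' @export
hotspot_cells <- function(values, q = 95) {
  if (length(values) == 0L) return(character(0))
  thr <- stats::quantile(values, q / 100, type = 7, names = FALSE, na.rm = TRUE)
  names(values)[!is.na(values) & values >= thr]
}

#' Percentage of hot-spot cells inside protected areas, per department
#'
#' A hot-spot cell counts as protected when its cell is flagged in the
#' protected mask (cell-level intersection). Departments with no hot-spot
#' cells for the metric yield `NA` ("no data"), not zero, and are excluded
#' from column averages.
#'
#' @param cells character or integer vector of hot-spot cell ids.
#' @param protected logical vector over all cells (cell-id order).
#' @param departments integer department ids over all cells (cell-id
#'   order).
#' @return named numeric vector: per-department percentage (0-100) of
#'   hot-spot cells inside protected areas, `NA` where the department has
#'   none; names `D01`, `D02`, ...
#' @export
percent_protected <- function(cells, protected, departments) {
  ids <- as.integer(cells)
  depts <- sort(unique(departments))
  out <- vapply(depts, function(d) {
    in_d <- ids[departments[ids + 1L] == d]
    if (length(in_d) == 0L) return(NA_real_)
    100 * sum(protected[in_d + 1L]) / length(in_d)
  }, 0)
  names(out) <- sprintf("D%02d", depts)
  out
}

#' Protected-area representativeness table
#'
#' Assembles per-department percentage columns into the summary table:
#' every displayed value is rounded to one decimal place, row averages are
#' means of each department's available (non-missing) displayed columns,
#' column totals are means over departments with data, and the grand
#' average is the mean of the column totals. All aggregation operates on
#' the displayed one-decimal values, so a table rebuilt from its own
#' printed numbers reproduces itself exactly. (Cohort percentage shares
#' use truncation instead; the two reporting conventions are deliberate —
#' see the methods vignette.)
#'
#' @param columns data.frame (or named list of equal-length vectors) of
#'   per-department percentages; row names are department labels, `NA` =
#'   no data.
#' @return object of class `assessment_table`: list with `table` (the
#'   truncated columns plus `row_average`), `column_totals`, and
#'   `grand_average`.
#' @export
assessment_table <- function(columns) {
  df <- as.data.frame(columns)
  if (nrow(df) == 0L) stop("no departments to summarize")
  round1 <- function(x) round(x, 1)
  disp <- as.data.frame(lapply(df, round1))
  rownames(disp) <- rownames(df)
  row_avg <- round1(apply(disp, 1L, function(r)
    if (all(is.na(r))) NA_real_ else mean(r[!is.na(r)])))
  totals <- vapply(disp, function(col) round1(mean(col[!is.na(col)])), 0)
  grand <- round1(mean(totals))
  structure(list(table = cbind(disp, row_average = row_avg),
                 column_totals = totals, grand_average = grand),
            class = "assessment_table")
}

#' @export
print.assessment_table <- function(x, ...) {
  print(x$table)
  cat("Totals:", paste(sprintf("%s=%.1f", names(x$column_totals),
                               x$column_totals), collapse = " "),
      sprintf("| grand average %.1f\n", x$grand_average))
  invisible(x)
}

#' Protected-area representativeness of diversity hot spots
#'
#' Builds the six hot-spot cell sets (observed SR and observed PD at the
#' `q`-th percentile; significantly low/high randomized PD; significantly
#' low/high randomized RPD), intersects each with the protected mask per
#' department, and summarizes with [assessment_table()].
#'
#' @param diversity per-cell table from [compute_cell_diversity()].
#' @param significance per-cell table from [run_null_analysis()].
#' @param protected logical protected mask over all coarse cells.
#' @param departments integer department ids over all coarse cells.
#' @param q hot-spot percentile (default 95).
#' @return an `assessment_table`; attribute `hotspots` holds the six cell
#'   sets.
#' @export
conservation_assessment <- function(diversity, significance, protected,
                                    departments, q = 95) {
  named <- function(v, ids) stats::setNames(v, as.character(ids))
  hs <- list(
    SRob = hotspot_cells(named(diversity$SR, diversity$cell_id), q),
    PDob = hotspot_cells(named(diversity$PD_obs, diversity$cell_id), q),
    PDr_sig_low = as.character(significance$cell_id[significance$class_PD == "sig_low"]),
    PDr_sig_high = as.character(significance$cell_id[significance$class_PD == "sig_high"]),
    RPDr_sig_low = as.character(significance$cell_id[significance$class_RPD == "sig_low"]),
    RPDr_sig_high = as.character(significance$cell_id[significance$class_RPD == "sig_high"]))
  cols <- lapply(hs, percent_protected, protected = protected,
                 departments = departments)
  out <- assessment_table(as.data.frame(cols))
  attr(out, "hotspots") <- hs
  out
}
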