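#' Read and validate a rooted phylogenetic tree
#'
#' Reads newick or nexus trees into an \pkg{ape} `phylo` object and checks
#' the structural assumptions the diversity metrics rely on: a single root,
#' unique tip labels, and finite non-negative branch lengths. Zero-length
#' branches and polytomies are permitted. The root is treated as having no
#' subtending edge: with that convention the phylogenetic diversity of the
#' full taxon set equals the total tree length. Any root edge present in the
#' file is dropped with a warning.
#'
#' @param path path to the tree file.
#' @param format `"newick"`, `"nexus"`, or `"auto"` (default; nexus files
#'   are recognized by their `#NEXUS` header or file extension).
#' @return a validated `phylo` object.
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS") ||
                  grepl("\\.nex(us)?$", path, ignore.case = TRUE)) "nexus" else "newick"
  }
  phy <- if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  if (is.null(phy)) stop("could not parse tree file: ", path)
  validate_tree(phy)
}

#' @rdname read_tree
#' @param phy a `phylo` object.
#' @export
validate_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  if (!is.null(phy$root.edge)) {
    warning("root edge ignored: the root is treated as having no subtending branch")
    phy$root.edge <- NULL
  }
  # exactly one root: one node that never appears as a child
  children <- phy$edge[, 2L]
  parents <- unique(phy$edge[, 1L])
  if (sum(!(parents %in% children)) != 1L) stop("tree must have exactly one root")
  phy
}

#' Comparison tree for relative phylogenetic diversity
#'
#' Returns a tree with identical topology in which every branch length
#' (including originally zero-length branches) is set to the mean of the
#' strictly positive observed branch lengths. PD computed on this tree is
#' the topology-only expectation against which observed PD is compared to
#' form RPD.
#'
#' @param phy a validated `phylo` object with at least one positive branch.
#' @return a `phylo` object with constant branch lengths.
#' @export
comparison_tree <- function(phy) {
  phy <- validate_tree(phy)
  pos <- phy$edge.length > 0
  if (!any(pos)) stop("cannot form comparison tree: all branch lengths are zero")
  phy$edge.length[] <- mean(phy$edge.length[pos])
  phy
}

#' Precompute tip-to-root branch paths
#'
#' Builds, for every tip, the set of branch (edge) indices on its path to
#' the root, plus a tips x branches 0/1 path matrix used to compute PD for
#' many cells at once. The root has no subtending edge, so a tip nested
#' under k clades has k + 1 branches on its path.
#'
#' @param phy a validated `phylo` object.
#' @return an object of class `tip_path_index` with elements `paths` (list
#'   of integer edge-index vectors per tip), `path_matrix` (tips x edges),
#'   `edge_lengths`, `total_length` and `tip_labels`.
#' @export
build_tip_path_index <- function(phy) {
  phy <- validate_tree(phy)
  n_tip <- length(phy$tip.label)
  n_edge <- nrow(phy$edge)
  n_node <- max(phy$edge)
  # edge whose child is a given node (0 = root / absent)
  edge_above <- integer(n_node)
  edge_above[phy$edge[, 2L]] <- seq_len(n_edge)
  parent_of <- integer(n_node)
  parent_of[phy$edge[, 2L]] <- phy$edge[, 1L]
  paths <- vector("list", n_tip)
  pm <- matrix(0L, n_tip, n_edge, dimnames = list(phy$tip.label, NULL))
  for (i in seq_len(n_tip)) {
    node <- i
    p <- integer(0)
    while (edge_above[node] != 0L) {
      p <- c(p, edge_above[node])
      node <- parent_of[node]
    }
    paths[[i]] <- p
    pm[i, p] <- 1L
  }
  structure(list(paths = stats::setNames(paths, phy$tip.label),
                 path_matrix = pm,
                 edge_lengths = phy$edge.length,
                 total_length = sum(phy$edge.length),
                 tip_labels = phy$tip.label),
            class = "tip_path_index")
}

#' @export
print.tip_path_index <- function(x, ...) {
  cat(sprintf("tip_path_index: %d tips, %d branches, total length %.6g\n",
              length(x$tip_labels), length(x$edge_lengths), x$total_length))
  invisible(x)
}

#' Write a tree to newick or nexus
#'
#' Branch lengths are serialized with 10 significant digits.
#'
#' @param phy a `phylo` object.
#' @param path output path.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_tree <- function(phy, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (format == "nexus") ape::write.nexus(phy, file = path)
  else ape::write.tree(phy, file = path, digits = 10)
  invisible(path)
}
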