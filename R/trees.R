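#' Neighbor-joining tree from a K2P distance matrix
#'
#' Standard NJ agglomeration (Q-criterion, via \pkg{ape}), followed by
#' midpoint rooting. Negative branch lengths occasionally produced by NJ
#' are clamped to zero with the deficit moved to the sibling edge, the
#' usual practice, so path lengths through the parent are preserved.
#'
#' @param dm A `k2p_dist` with at least 3 specimens and finite entries.
#' @return A rooted `phylo` tree with branch lengths in
#'   substitutions/site.
#' @export
nj_tree <- function(dm) {
  n <- length(dm$ids)
  if (n < 3) abort("neighbor-joining needs at least 3 specimens",
                   class = "coidelim_size_error")
  if (!all(is.finite(dm$d))) abort("non-finite distances",
                                   class = "coidelim_validation_error")
  tr <- ape::nj(as.dist(dm$d))
  tr <- clamp_negative_edges(tr)
  midpoint_root(tr)
}

clamp_negative_edges <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[e]
      tr$edge.length[sibs[1]] <- max(tr$edge.length[sibs[1]], 0)
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Midpoint-root a tree
#'
#' Places the root halfway along the longest leaf-to-leaf path (via
#' \pkg{phangorn}). A zero-diameter tree (all branch lengths zero) cannot
#' define a midpoint; the tree is returned rooted at its first internal
#' node with a warning.
#'
#' @param tree A `phylo` tree with nonnegative branch lengths.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths",
                                       class = "coidelim_validation_error")
  if (all(tree$edge.length == 0)) {
    warn("zero-diameter tree: rooting at first internal node")
    if (ape::is.rooted(tree)) return(tree)
    return(ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

#' UPGMA chronogram under a strict molecular clock
#'
#' Average-linkage (UPGMA) clustering of the K2P matrix yields an
#' ultrametric tree; node heights are converted to ages in million years
#' by the strict clock `age = pairwise divergence / clock_rate`, with the
#' canonical COI default of 1.2% pairwise divergence per million years.
#' It stands in for a Bayesian relaxed/strict-clock chronogram at desk
#' scale; an externally built chronogram can be supplied to the delimiters
#' instead via Newick.
#'
#' @param dm A `k2p_dist` with at least 2 specimens.
#' @param clock_rate Pairwise divergence per million years (default
#'   0.012).
#' @return An ultrametric rooted `phylo` tree with branch lengths in My
#'   and attribute `clock_rate`.
#' @export
upgma_chronogram <- function(dm, clock_rate = 0.012) {
  n <- length(dm$ids)
  if (n < 2) abort("UPGMA needs at least 2 specimens", class = "coidelim_size_error")
  if (!all(is.finite(dm$d))) abort("non-finite distances",
                                   class = "coidelim_validation_error")
  if (n == 2) {
    age <- dm$d[1, 2] / clock_rate
    tr <- ape::read.tree(text = sprintf("(%s:%.12g,%s:%.12g);",
                                        dm$ids[1], age, dm$ids[2], age))
  } else {
    hc <- hclust(as.dist(dm$d), method = "average")
    tr <- ape::as.phylo(hc)
    # as.phylo(hclust) gives per-lineage node depths of merge-height/2;
    # a merge at pairwise divergence h must sit at age h / clock_rate,
    # so scale all edges by 2 / clock_rate.
    tr$edge.length <- tr$edge.length * 2 / clock_rate
  }
  attr(tr, "clock_rate") <- clock_rate
  tr
}

#' Node ages of an ultrametric tree
#'
#' @param tree An ultrametric rooted `phylo` tree.
#' @param tol Ultrametricity tolerance on root-to-leaf path spread.
#' @return Named numeric vector of internal-node ages (units of the branch
#'   lengths).
#' @export
node_ages <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  h <- max(depths[seq_len(ntip)])
  if (diff(range(depths[seq_len(ntip)])) > tol * max(h, 1)) {
    abort("tree is not ultrametric", class = "coidelim_validation_error")
  }
  ages <- h - depths
  setNames(ages[(ntip + 1):length(ages)], (ntip + 1):length(ages))
}

is_ultrametric_tree <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  diff(range(depths[seq_len(ntip)])) <= tol * max(max(depths), 1)
}

#' Newick input/output
#'
#' Thin wrappers over \pkg{ape}'s Newick reader/writer that validate the
#' result; branch lengths survive a write/read cycle to 1e-9.
#'
#' @param path File path.
#' @param tree A `phylo` tree.
#' @return `read_newick` returns a `phylo`; `write_newick` returns the
#'   tree invisibly.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    abort(sprintf("malformed Newick in '%s'", path), class = "coidelim_parse_error")
  }
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(tree)
}
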