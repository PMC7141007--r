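# Multi-rate Poisson tree process (PTP) delimitation.
#
# The model classifies the branch lengths of a (non-ultrametric) rooted
# tree into one speciation class plus one coalescent class per cut node:
# a cut at internal node v makes all edges below v a "within-species"
# class whose leaves form one OTU; edges above all cuts are speciation
# edges and leaves above all cuts are singleton OTUs. Each class k with m
# edges summing to length L has exponential edge lengths with MLE rate
# m / L and profile log-likelihood m * log(m / L) - m.

# Precompute subtree bookkeeping for a rooted tree.
ptp_setup <- function(tree, min_branch = 1e-9) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths",
                                       class = "coidelim_validation_error")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  # a cherry of two zero-length terminal branches is the signature of
  # identical haplotypes; isolated zero terminals (an NJ clamping artifact)
  # are floored at min_branch instead
  zero_term <- tree$edge[tree$edge.length <= min_branch & tree$edge[, 2] <= ntip, 1]
  if (anyDuplicated(zero_term)) {
    abort(paste0("zero-length terminal cherries: identical haplotypes must be ",
                 "pruned (see deduplicate_haplotypes) before tree delimitation"),
          class = "coidelim_degenerate_error")
  }
  desc <- phangorn::Descendants(tree, seq_len(ntip + nnode), type = "all")
  edge_of_child <- integer(ntip + nnode)
  edge_of_child[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  subtree_edges <- lapply(seq_len(ntip + nnode), function(v) {
    kids <- desc[[v]]
    if (!length(kids)) integer(0) else edge_of_child[kids]
  })
  list(tree = tree, ntip = ntip, root = root, desc = desc,
       edge_len = pmax(tree$edge.length, min_branch),
       subtree_edges = subtree_edges,
       sub_m = vapply(subtree_edges, length, integer(1)),
       sub_L = vapply(subtree_edges, function(e) sum(pmax(tree$edge.length[e], min_branch)),
                      double(1)),
       internal = setdiff(seq(ntip + 1L, ntip + nnode), ntip + 1L))
}

# Validity of a cut set: internal non-root nodes, pairwise non-nested.
ptp_valid_cuts <- function(setup, cut_nodes) {
  if (!length(cut_nodes)) return(TRUE)
  if (any(cut_nodes <= setup$ntip) || any(cut_nodes == setup$root)) return(FALSE)
  if (anyDuplicated(cut_nodes)) return(FALSE)
  for (v in cut_nodes) {
    if (any(setdiff(cut_nodes, v) %in% setup$desc[[v]])) return(FALSE)
  }
  TRUE
}

ptp_score_cuts <- function(setup, cut_nodes, penalty = "aic") {
  m_cut <- setup$sub_m[cut_nodes]
  L_cut <- setup$sub_L[cut_nodes]
  m_spec <- length(setup$edge_len) - sum(m_cut)
  L_spec <- sum(setup$edge_len) - sum(L_cut)
  if (m_spec < 1 || any(m_cut < 1)) return(-Inf)
  class_ll <- function(m, L) m * log(m / L) - m
  ll <- class_ll(m_spec, L_spec) + sum(class_ll(m_cut, L_cut))
  k <- 1 + length(cut_nodes)
  if (penalty == "aic") ll - 2 * k else ll
}

#' Poisson tree process log-likelihood for a given cut set
#'
#' @param tree A rooted `phylo` tree with branch lengths in
#'   substitutions/site, all exceeding `min_branch`.
#' @param cut_nodes Integer vector of internal node numbers (ape
#'   numbering, excluding the root) whose subtrees form the coalescent
#'   classes; no cut may be nested inside another. Empty = single class.
#' @param min_branch Minimum admissible branch length (default 1e-9);
#'   zero-length terminal branches signal unpruned duplicate haplotypes.
#' @return A list with `log_likelihood` and `rates`, a tibble with one
#'   row per class (`class`, `n_edges`, `total_length`, `rate`).
#' @export
ptp_loglik <- function(tree, cut_nodes = integer(0), min_branch = 1e-9) {
  setup <- ptp_setup(tree, min_branch)
  cut_nodes <- as.integer(cut_nodes)
  if (!ptp_valid_cuts(setup, cut_nodes)) {
    abort("invalid cut set: cuts must be distinct non-root internal nodes, not nested",
          class = "coidelim_validation_error")
  }
  m_cut <- setup$sub_m[cut_nodes]
  L_cut <- setup$sub_L[cut_nodes]
  m_spec <- length(setup$edge_len) - sum(m_cut)
  L_spec <- sum(setup$edge_len) - sum(L_cut)
  if (m_spec < 1) {
    abort("speciation class is empty", class = "coidelim_degenerate_error")
  }
  rates <- tibble(
    class = c("speciation", if (length(cut_nodes)) paste0("coalescent_", cut_nodes)),
    n_edges = as.integer(c(m_spec, m_cut)),
    total_length = c(L_spec, L_cut),
    rate = c(m_spec / L_spec, if (length(cut_nodes)) m_cut / L_cut)
  )
  ll <- sum(rates$n_edges * log(rates$rate) - rates$rate * rates$total_length)
  list(log_likelihood = ll, rates = rates)
}

#' Multi-rate PTP delimitation by penalized greedy search
#'
#' The search repeatedly applies the single cut addition or removal that
#' most improves the AIC-penalized profile log-likelihood (2 parameters
#' per class), stopping at a local optimum. The first climb starts from
#' the no-cut model; each further restart climbs from a random valid cut
#' set with shuffled move order, and the best restart wins. Leaves below
#' a cut form one OTU; leaves above all cuts are singletons.
#'
#' @param tree A rooted `phylo` with at least 3 leaves, branch lengths in
#'   substitutions/site, duplicates pruned.
#' @param restarts Number of random restarts (default 10).
#' @param seed RNG seed recorded in the partition parameters (default 42).
#' @param penalty `"aic"` (default) or `"none"` for raw maximum
#'   likelihood.
#' @param min_branch See [ptp_loglik()].
#' @return An [otu_partition()] whose `"model"` attribute is a `ptp_fit`
#'   (cut nodes, rates, log-likelihood); see [tidy.ptp_fit()].
#' @export
delimit_mptp <- function(tree, restarts = 10, seed = 42, penalty = c("aic", "none"),
                         min_branch = 1e-9) {
  penalty <- match.arg(penalty)
  if (length(tree$tip.label) < 3) {
    abort("mPTP needs at least 3 leaves", class = "coidelim_size_error")
  }
  setup <- ptp_setup(tree, min_branch)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  best_cuts <- integer(0)
  best_score <- ptp_score_cuts(setup, integer(0), penalty)
  for (r in seq_len(restarts)) {
    # restart 1 climbs from the null; later restarts from random valid
    # cut sets so the search can cross ridges the single-move
    # neighbourhood cannot
    cuts <- integer(0)
    if (r > 1) {
      for (v in sample(setup$internal)) {
        if (stats::runif(1) < 0.4 && ptp_valid_cuts(setup, c(cuts, v))) {
          cuts <- c(cuts, v)
        }
      }
    }
    score <- ptp_score_cuts(setup, cuts, penalty)
    repeat {
      candidates <- sample(setup$internal)
      improved <- FALSE
      move_best <- NULL
      move_score <- score
      for (v in candidates) {
        new_cuts <- if (v %in% cuts) setdiff(cuts, v) else c(cuts, v)
        if (!ptp_valid_cuts(setup, new_cuts)) next
        s <- ptp_score_cuts(setup, new_cuts, penalty)
        if (s > move_score + 1e-9) {
          move_best <- new_cuts
          move_score <- s
        }
      }
      if (!is.null(move_best)) {
        cuts <- move_best
        score <- move_score
        improved <- TRUE
      }
      if (!improved) break
    }
    if (score > best_score + 1e-12) {
      best_cuts <- cuts
      best_score <- score
    }
  }
  fit <- ptp_loglik(tree, best_cuts, min_branch)
  labels <- ptp_cut_labels(setup, best_cuts)
  part <- otu_partition(tree$tip.label, labels, method = "mPTP-like",
                        params = list(restarts = restarts, seed = seed,
                                      penalty = penalty, n_cuts = length(best_cuts)))
  attr(part, "model") <- structure(
    list(cut_nodes = best_cuts, log_likelihood = fit$log_likelihood,
         rates = fit$rates, score = best_score, penalty = penalty),
    class = "ptp_fit"
  )
  part
}

# OTU labels for the tips given a cut set: tips below a cut share an OTU.
ptp_cut_labels <- function(setup, cut_nodes) {
  ntip <- setup$ntip
  labels <- seq_len(ntip)
  for (v in cut_nodes) {
    tips <- setup$desc[[v]]
    tips <- tips[tips <= ntip]
    labels[tips] <- ntip + v
  }
  dense_labels(labels)
}

#' @export
print.ptp_fit <- function(x, ...) {
  cat(sprintf("<ptp_fit: %d cuts, logL = %.4f (%s-penalized score %.4f)>\n",
              length(x$cut_nodes), x$log_likelihood, x$penalty, x$score))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ptp_fit <- function(x, ...) x$rates

#' @exportS3Method generics::glance
glance.ptp_fit <- function(x, ...) {
  tibble(log_likelihood = x$log_likelihood, n_classes = nrow(x$rates),
         n_cuts = length(x$cut_nodes), score = x$score, penalty = x$penalty)
}
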