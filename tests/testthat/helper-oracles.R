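# Independent oracles and fixture builders. Everything here is written
# against the definitions, not against the package internals, so the two
# code paths can disagree when one of them is wrong.

# --- sequences ------------------------------------------------------------

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# mutate a sequence: n_ts transitions, n_tv transversions, plus optional
# gap/ambiguity contamination
mutate_dna <- function(seq, n_ts = 0, n_tv = 0, n_noise = 0) {
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "T", C = "A", T = "G")
  x <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(x), n_ts + n_tv + n_noise)
  i <- 0
  for (k in seq_len(n_ts)) x[pos[i + k]] <- ts_map[[x[pos[i + k]]]]
  i <- i + n_ts
  for (k in seq_len(n_tv)) x[pos[i + k]] <- tv_map[[x[pos[i + k]]]]
  i <- i + n_tv
  for (k in seq_len(n_noise)) x[pos[i + k]] <- sample(c("-", "N", "R", "Y"), 1)
  paste(x, collapse = "")
}

# closed-form K2P from two character strings, by direct tabulation
oracle_k2p <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  keep <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  va <- va[keep]
  vb <- vb[keep]
  n <- length(va)
  pur <- c("A", "G")
  ts <- sum(va != vb & ((va %in% pur) == (vb %in% pur)))
  tv <- sum(va != vb) - ts
  P <- ts / n
  Q <- tv / n
  list(distance = -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)), sites = n)
}

# a tiny aligned dataset with controlled taxonomy
toy_dataset <- function() {
  base <- random_dna(500)
  far <- mutate_dna(base, n_ts = 30, n_tv = 20)
  vfar <- mutate_dna(base, n_ts = 60, n_tv = 40)
  barcode_dataset(tibble::tibble(
    specimen_id = sprintf("sp%d", 1:6),
    species = c("A1", "A1", "A2", "A2", "B1", "C1"),
    genus = c("GA", "GA", "GA", "GA", "GB", "GC"),
    family = c("F1", "F1", "F1", "F1", "F1", "F2"),
    sequence = c(base, mutate_dna(base, n_ts = 1),
                 far, mutate_dna(far, n_ts = 1, n_tv = 1),
                 vfar, mutate_dna(vfar, n_ts = 25, n_tv = 15))
  ))
}

# --- partitions -----------------------------------------------------------

oracle_ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# brute-force connected components over pairs with d <= t
oracle_single_linkage <- function(d, t) {
  n <- nrow(d)
  labels <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (d[i, j] <= t && labels[i] != labels[j]) {
        labels[labels == labels[j]] <- labels[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(labels, unique(labels))
}

# --- PTP ------------------------------------------------------------------

# all valid cut sets (antichains of non-root internal nodes)
all_cut_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- setdiff(seq(ntip + 1, ntip + tree$Nnode), ntip + 1)
  desc <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), "all")
  sets <- list(integer(0))
  if (length(internal)) {
    for (k in seq_along(internal)) {
      combs <- utils::combn(internal, k, simplify = FALSE)
      ok <- Filter(function(cs) {
        !any(vapply(cs, function(v) any(setdiff(cs, v) %in% desc[[v]]), logical(1)))
      }, combs)
      sets <- c(sets, ok)
    }
  }
  sets
}

# brute-force PTP log-likelihood: per-class exponential densities at the
# per-class MLE rate, classes derived independently by tip descent
oracle_ptp_loglik <- function(tree, cut_nodes) {
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), "all")
  class_of <- rep(0L, nrow(tree$edge))
  for (i in seq_along(cut_nodes)) {
    v <- cut_nodes[i]
    inside <- tree$edge[, 2] %in% desc[[v]]
    class_of[inside] <- i
  }
  ll <- 0
  for (cl in unique(class_of)) {
    len <- tree$edge.length[class_of == cl]
    rate <- length(len) / sum(len)
    ll <- ll + sum(stats::dexp(len, rate, log = TRUE))
  }
  ll
}

# random non-ultrametric tree with exponential branch lengths
random_ptp_tree <- function(ntip, rate_spec = 1, rate_coal = 20) {
  tr <- ape::rtree(ntip)
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate_spec)
  tr
}

# --- GMYC -----------------------------------------------------------------

# fully independent evaluation of the mixed waiting-time log-likelihood at
# FIXED rates: direct per-edge segment bookkeeping, no shared code with
# the package internals
oracle_gmyc_loglik <- function(tree, threshold, p, q, lambda, mu) {
  ntip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  h <- max(depths[seq_len(ntip)])
  ages <- h - depths
  ages[seq_len(ntip)] <- 0
  root <- ntip + 1
  # cluster root of every node: walk up from each node; the cluster root
  # is the shallowest ancestor-or-self with age <= threshold whose parent
  # is older than threshold
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  cluster_root_of <- function(v) {
    if (ages[v] > threshold) return(NA_integer_)
    while (!is.na(parent[v]) && ages[parent[v]] <= threshold) v <- parent[v]
    v
  }
  croots <- unique(stats::na.omit(vapply(seq_len(ntip + tree$Nnode),
                                         cluster_root_of, integer(1))))
  if (ages[root] <= threshold) croots <- root
  internal <- seq(ntip + 1, ntip + tree$Nnode)
  ev_ages <- sort(ages[internal], decreasing = TRUE)
  bounds <- c(ev_ages, 0)
  # crossing counts at an arbitrary time t, split diversification/cluster
  counts_at <- function(t) {
    crossing <- which(!is.na(parent) & ages[parent[seq_len(ntip + tree$Nnode)]] > t &
                        ages[seq_len(ntip + tree$Nnode)] <= t)
    nk <- vapply(croots, function(r) {
      sub <- c(r, phangorn::Descendants(tree, r, "all"))
      sum(crossing %in% setdiff(sub, r))
    }, numeric(1))
    list(b = length(crossing) - sum(nk), nk = nk)
  }
  ll <- 0
  # survival over intervals (midpoints)
  for (i in seq_len(length(bounds) - 1)) {
    x <- bounds[i] - bounds[i + 1]
    if (x <= 0) next
    ct <- counts_at((bounds[i] + bounds[i + 1]) / 2)
    R <- lambda * ct$b^p + sum(mu * (ct$nk * pmax(ct$nk - 1, 0))^q)
    ll <- ll - R * x
  }
  # realized events
  eps <- min(diff(sort(unique(c(ages[internal], 0))))) / 10
  for (v in internal) {
    if (v == root && ages[root] > threshold) next
    above <- counts_at(ages[v] + eps)
    below <- counts_at(ages[v] - eps)
    hazard <- lambda * above$b^p + sum(mu * (below$nk * pmax(below$nk - 1, 0))^q)
    if (hazard <= 0) return(-Inf)
    ll <- ll + log(hazard)
  }
  ll
}

# independent standard Yule log-likelihood (conditioned on the root
# split): events at the end of each interval with n lineages at rate
# lambda * n, survival over every interval
oracle_yule_loglik <- function(tree, lambda) {
  bt <- sort(unname(ape::branching.times(tree)), decreasing = TRUE)
  n <- length(tree$tip.label)
  bounds <- c(bt, 0)
  ll <- 0
  for (i in seq_len(length(bounds) - 1)) {
    lineages <- i + 1
    x <- bounds[i] - bounds[i + 1]
    ll <- ll - lambda * lineages * x
    if (i < length(bounds) - 1) ll <- ll + log(lambda * (lineages + 1 - 1))
  }
  ll
}
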