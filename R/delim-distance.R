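#' Single-linkage OTUs at a distance threshold
#'
#' OTUs are the connected components of the graph linking every specimen
#' pair with K2P distance `<= threshold`. Identical haplotypes (distance
#' 0) therefore always co-cluster at any threshold.
#'
#' @param dm A `k2p_dist`.
#' @param threshold Linking distance (proportion), `>= 0`.
#' @return An [otu_partition()].
#' @export
delimit_single_linkage <- function(dm, threshold) {
  stopifnot(is_scalar_number(threshold), threshold >= 0)
  labels <- single_linkage_labels(dm$d, threshold)
  otu_partition(dm$ids, labels, method = "single_linkage",
                params = list(threshold = threshold))
}

single_linkage_labels <- function(d, threshold) {
  n <- nrow(d)
  if (n == 0) return(integer(0))
  pairs <- which(upper.tri(d) & d <= threshold, arr.ind = TRUE)
  uf_components(n, pairs)
}

#' RESL-like refined single-linkage OTUs
#'
#' A two-stage stand-in for BOLD's Refined Single Linkage (the BIN
#' algorithm): stage 1 links specimens by single linkage at a 2.2% seed
#' threshold; stage 2 re-examines each multi-specimen component in
#' isolation, evaluating single-linkage sub-partitions at every threshold
#' of `refine_grid` and keeping the one with the highest mean silhouette
#' width, provided it exceeds `min_silhouette` (default 0.5, the
#' conventional cutoff for "reasonable" cluster structure); otherwise the
#' component stays whole. The margin stops the refinement from splitting
#' ordinary coalescent variation, where a marginally positive silhouette
#' is always available. BOLD's exact refinement step is unpublished in
#' detail, hence the method label `"RESL-like"`.
#'
#' @param dm A `k2p_dist`.
#' @param seed_threshold Stage-1 linking distance (default 0.022).
#' @param refine_grid Candidate stage-2 thresholds (default 0.005 to 0.04
#'   in steps of 0.0025).
#' @param min_silhouette Minimum mean silhouette a split must reach
#'   (default 0.5).
#' @return An [otu_partition()] refining the stage-1 components.
#' @export
delimit_resl <- function(dm, seed_threshold = 0.022,
                         refine_grid = seq(0.005, 0.04, by = 0.0025),
                         min_silhouette = 0.5) {
  stage1 <- single_linkage_labels(dm$d, seed_threshold)
  labels <- integer(length(stage1))
  next_id <- 0L
  for (comp in unique(stage1)) {
    idx <- which(stage1 == comp)
    if (length(idx) <= 2) {
      sub <- rep(1L, length(idx))
    } else {
      dsub <- dm$d[idx, idx, drop = FALSE]
      best <- rep(1L, length(idx))
      best_score <- min_silhouette
      for (t in sort(refine_grid, decreasing = TRUE)) {
        cand <- single_linkage_labels(dsub, t)
        score <- mean_silhouette(cand, dsub)
        if (score > best_score + 1e-12) {
          best <- cand
          best_score <- score
        }
      }
      sub <- best
    }
    labels[idx] <- next_id + sub
    next_id <- next_id + max(sub)
  }
  otu_partition(dm$ids, labels, method = "RESL-like",
                params = list(seed_threshold = seed_threshold,
                              refine_grid = refine_grid,
                              min_silhouette = min_silhouette))
}

# Mean silhouette width of a labelling on a distance submatrix; the
# trivial one-cluster and all-singleton labellings score 0 by convention.
mean_silhouette <- function(labels, d) {
  k <- length(unique(labels))
  n <- length(labels)
  if (k <= 1 || k >= n) return(0)
  sil <- cluster::silhouette(labels, dmatrix = d)
  mean(sil[, "sil_width"])
}

#' Automatic barcode gap discovery (ABGD-style) OTUs
#'
#' For each prior maximum intraspecific divergence `P` on a log-spaced
#' grid, the ranked pairwise distances are scanned for the first
#' inter-distance interval above `P` whose width exceeds
#' `rel_gap_width_X` times the local slope of the ranked distances below
#' it (mean spacing over a sliding window); specimens are then grouped by
#' single linkage at the gap's lower bound and the scan recurses inside
#' each group until no further gap is found. The primary partition is the
#' modal partition across the prior grid; ties are broken toward the
#' partition holding the longest contiguous plateau of priors, then
#' toward the largest prior, mirroring how an ABGD prior scan is read for
#' its stable partition.
#'
#' @param dm A `k2p_dist`.
#' @param p_min,p_max Prior grid range (proportions), `p_min < p_max`.
#' @param steps Number of priors on the log-spaced grid.
#' @param rel_gap_width_X Gap width multiplier relative to the local
#'   slope (default 1.5).
#' @param slope_window Window (number of ranked spacings) for the local
#'   slope (default 10).
#' @return A list of class `abgd_result`: `by_prior`, a tibble with
#'   columns `prior` and `partition` (list of [otu_partition()]s), and
#'   `primary`, the modal partition.
#' @export
delimit_abgd <- function(dm, p_min = 0.001, p_max = 0.1, steps = 10,
                         rel_gap_width_X = 1.5, slope_window = 10) {
  stopifnot(p_min < p_max, steps >= 1)
  priors <- exp(seq(log(p_min), log(p_max), length.out = steps))
  parts <- map(priors, function(P) {
    labels <- abgd_recurse(dm$d, seq_along(dm$ids), P, rel_gap_width_X, slope_window)
    no_gap <- max(labels) == 1L
    otu_partition(dm$ids, labels, method = "ABGD",
                  params = list(prior = P, X = rel_gap_width_X,
                                slope_window = slope_window, no_gap = no_gap))
  })
  # primary = modal partition across priors; ties go to the signature
  # with the longest contiguous prior plateau, then to the largest prior
  # (the stable coarse reading of an ABGD prior scan)
  sigs <- map_chr(parts, function(p) partition_signature(p$otu_id))
  counts <- table(sigs)
  modal_sig <- names(counts)[counts == max(counts)]
  runs <- rle(sigs)
  plateau <- max(runs$lengths[runs$values %in% modal_sig])
  stable_sig <- runs$values[runs$lengths == plateau & runs$values %in% modal_sig]
  primary_idx <- max(which(sigs %in% stable_sig))
  structure(list(by_prior = tibble(prior = priors, partition = parts),
                 primary = parts[[primary_idx]]),
            class = "abgd_result")
}

#' @export
print.abgd_result <- function(x, ...) {
  cat(sprintf("<abgd_result: %d priors, primary partition has %d OTUs (prior %.4g)>\n",
              nrow(x$by_prior), n_otus(x$primary),
              attr(x$primary, "params")$prior))
  invisible(x)
}

# Recursive gap partitioning on a distance submatrix; returns dense labels.
abgd_recurse <- function(d, idx, P, X, window) {
  n <- length(idx)
  labels <- rep(1L, n)
  if (n < 2) return(labels)
  dsub <- d[idx, idx, drop = FALSE]
  s <- sort(dsub[upper.tri(dsub)])
  cut <- abgd_find_gap(s, P, X, window)
  if (is.na(cut)) return(labels)
  comp <- single_linkage_labels(dsub, cut)
  if (max(comp) == 1L) return(labels)
  out <- integer(n)
  next_id <- 0L
  for (g in unique(comp)) {
    sub_idx <- which(comp == g)
    sub_labels <- abgd_recurse(d, idx[sub_idx], P, X, window)
    out[sub_idx] <- next_id + sub_labels
    next_id <- next_id + max(sub_labels)
  }
  out
}

# First gap in the sorted distance vector above prior P: the spacing
# s[i+1] - s[i] with s[i+1] > P that exceeds X times the mean spacing over
# the preceding `window` ranks. Returns the gap's lower bound, or NA.
abgd_find_gap <- function(s, P, X, window) {
  m <- length(s)
  if (m < 2) return(NA_real_)
  spacings <- diff(s)
  for (i in seq_len(m - 1)) {
    if (s[i + 1] <= P) next
    if (spacings[i] <= 0) next
    lo <- max(1L, i - window)
    local <- if (i > 1) mean(spacings[lo:(i - 1)]) else 0
    if (spacings[i] > X * local) return(s[i])
  }
  NA_real_
}
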