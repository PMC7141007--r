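# General mixed Yule-coalescent (GMYC) delimitation on an ultrametric
# tree. Above a threshold age, branching events follow a Yule
# (diversification) process with hazard lambda * b^p for b diversification
# lineages; below it, each cluster (a subtree crossing its threshold)
# follows its own coalescent with hazard mu_k * (n_k * (n_k - 1))^q_k.
# The model is fit through the waiting times between successive branching
# events on the whole tree: each interval contributes the survival of the
# total intensity and each event the log of the total intensity at its
# age (Yule counts just above the event, coalescent counts just below, so
# the pure-Yule and single-coalescent limits reduce to their standard
# likelihoods). Rates are profiled by an EM fixed point; exponents p and
# q are optimized on a bounded grid.

gmyc_setup <- function(tree, tol = 1e-6) {
  ntip <- length(tree$tip.label)
  if (ntip < 3) abort("GMYC needs at least 3 leaves", class = "coidelim_size_error")
  if (!is_ultrametric_tree(tree, tol)) {
    abort("GMYC needs an ultrametric tree", class = "coidelim_validation_error")
  }
  ages_all <- numeric(ntip + tree$Nnode)
  depths <- ape::node.depth.edgelength(tree)
  h <- max(depths[seq_len(ntip)])
  ages_all <- h - depths
  ages_all[seq_len(ntip)] <- 0
  root <- ntip + 1L
  desc <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), type = "all")
  internal <- seq(ntip + 1L, ntip + tree$Nnode)
  ev_ages <- sort(ages_all[internal], decreasing = TRUE)
  bounds <- c(ev_ages, 0)
  mids <- (bounds[-length(bounds)] + bounds[-1]) / 2
  durations <- bounds[-length(bounds)] - bounds[-1]
  list(tree = tree, ntip = ntip, root = root, ages = ages_all, desc = desc,
       internal = internal, ev_ages = ev_ages, mids = mids, durations = durations,
       root_age = ages_all[root])
}

# Cluster roots implied by a single threshold age T: nodes with age <= T
# whose parent age > T (the root itself when T >= root age).
gmyc_cluster_roots <- function(setup, threshold) {
  tol <- 1e-9 * max(setup$root_age, 1e-12)
  if (threshold >= setup$root_age - tol) return(setup$root)
  edge <- setup$tree$edge
  p_age <- setup$ages[edge[, 1]]
  c_age <- setup$ages[edge[, 2]]
  edge[p_age > threshold + tol & c_age <= threshold + tol, 2]
}

# Core likelihood machinery for a set of cluster roots. The mixed
# process is fit through the waiting times between successive branching
# events on the whole tree: during interval i the total intensity is
# R_i = lambda * b_i^p + sum_k mu_k * (n_ik (n_ik - 1))^q, and each
# observed event contributes the total intensity at its age (Yule counts
# taken just above the event, coalescent counts just below, so the pure
# Yule and pure coalescent limits reduce to their standard likelihoods).
# The root's own split is conditioned on unless the root sits inside a
# cluster. With both processes active the rate MLEs are no longer closed
# form; an EM-style fixed point on the latent event attribution converges
# in a few iterations. `shared_mu` pools one coalescent rate across
# clusters (classic single-threshold GMYC); otherwise each cluster gets
# its own.
gmyc_eval <- function(setup, cluster_roots, p = 1, q = 1,
                      lambda = NULL, mu = NULL, shared_mu = TRUE) {
  ntip <- setup$ntip
  ages <- setup$ages
  mids <- setup$mids
  x <- setup$durations
  clusters <- lapply(cluster_roots, function(r) {
    nodes <- c(r, setup$desc[[r]])
    sort(ages[nodes[nodes > ntip]], decreasing = TRUE)  # internal ages incl. root
  })
  K <- length(clusters)
  # lineage counts per interval (midpoint convention)
  total_cross <- 1 + vapply(mids, function(t) sum(setup$ev_ages > t), double(1))
  n_k <- vapply(clusters, function(ca) {
    out <- numeric(length(mids))
    if (length(ca)) {
      below <- mids < ca[1]
      if (any(below)) {
        out[below] <- 1 + vapply(mids[below], function(t) sum(ca > t), double(1))
      }
    }
    out
  }, double(length(mids)))
  n_k <- matrix(n_k, nrow = length(mids))
  b <- total_cross - rowSums(n_k)
  if (any(b < -1e-9)) abort("inconsistent lineage bookkeeping", class = "coidelim_internal_error")
  b <- pmax(b, 0)
  # events: all internal nodes; the root is conditioned on unless it is
  # a cluster root (single-coalescent null)
  in_cluster <- integer(ntip + setup$tree$Nnode)
  for (i in seq_along(cluster_roots)) {
    r <- cluster_roots[i]
    in_cluster[c(r, setup$desc[[r]])] <- i
  }
  events <- setup$internal
  if (in_cluster[setup$root] == 0L) events <- setdiff(events, setup$root)
  ev_age <- ages[events]
  is_coal <- in_cluster[events] > 0L
  D <- sum(!is_coal)
  C_k <- vapply(seq_len(K), function(i) sum(in_cluster[events] == i), integer(1))
  # per-event bases: Yule count just above the event, per-cluster
  # coalescent pair count just below it
  A <- vapply(seq_along(events), function(j) {
    t_v <- ev_age[j]
    tot <- 1 + sum(setup$ev_ages > t_v)
    nk_above <- vapply(clusters, function(ca) {
      if (!length(ca) || t_v >= ca[1]) 0 else 1 + sum(ca > t_v)
    }, double(1))
    max(tot - sum(nk_above), 0)
  }, double(1))
  B <- vapply(seq_len(K), function(i) {
    ca <- clusters[[i]]
    vapply(ev_age, function(t_v) {
      if (!length(ca) || t_v > ca[1]) return(0)
      n <- 1 + sum(ca >= t_v)
      n * (n - 1)
    }, double(1))
  }, double(length(events)))
  B <- matrix(B, nrow = length(events))
  # survival integrals and event bases at exponents p, q
  Ap <- A^p
  Bq <- B^q
  S_b <- sum(b^p * x)
  S_k <- vapply(seq_len(K), function(i) {
    nk <- n_k[, i]
    sum((nk * pmax(nk - 1, 0))^q * x)
  }, double(1))
  n_rate <- (D > 0) * 2L +
    if (shared_mu) (sum(C_k) > 0) * 2L else 2L * sum(C_k > 0)
  bad <- list(loglik = -Inf, lambda = NA_real_, mu = rep(NA_real_, K),
              D = D, C_k = C_k, n_rate_params = n_rate)
  fixed_rates <- !is.null(lambda) || !is.null(mu)
  if (fixed_rates) {
    lam <- lambda %||% 0
    mu_vec <- rep_len(mu %||% 0, K)
  } else {
    lam <- if (S_b > 0) 0.5 * length(events) / S_b else 0
    mu0 <- if (sum(S_k) > 0) 0.5 * length(events) / sum(S_k) else 0
    mu_vec <- rep(mu0, K)
    for (iter in seq_len(50)) {
      denom <- lam * Ap + Bq %*% mu_vec
      if (any(denom <= 0)) return(bad)
      w_lam <- lam * Ap / denom
      w_mu <- (Bq * rep(mu_vec, each = length(events))) / as.numeric(denom)
      new_lam <- if (S_b > 0) sum(w_lam) / S_b else 0
      new_mu <- if (shared_mu) {
        tot_S <- sum(S_k)
        rep(if (tot_S > 0) sum(w_mu) / tot_S else 0, K)
      } else {
        ifelse(S_k > 0, colSums(w_mu) / pmax(S_k, .Machine$double.xmin), 0)
      }
      moved <- abs(new_lam - lam) + sum(abs(new_mu - mu_vec))
      lam <- new_lam
      mu_vec <- new_mu
      if (moved < 1e-10 * (1 + lam + sum(mu_vec))) break
    }
  }
  hazard_e <- lam * Ap + as.numeric(Bq %*% mu_vec)
  if (any(hazard_e <= 0)) return(bad)
  ll <- sum(log(hazard_e)) - lam * S_b - sum(mu_vec * S_k)
  list(loglik = ll, lambda = lam, mu = mu_vec, D = D, C_k = C_k,
       n_rate_params = n_rate)
}

#' GMYC log-likelihood at a given threshold
#'
#' Evaluates the mixed Yule-coalescent log-likelihood for the clusters
#' implied by a single threshold age, at supplied or profile-MLE rates.
#'
#' @param tree An ultrametric rooted `phylo` (ages in any consistent
#'   unit).
#' @param threshold Threshold age; clusters are the subtrees whose root
#'   age is at most the threshold while their stem parent is older.
#' @param p,q Yule and coalescent scaling exponents (default 1).
#' @param lambda,mu Optional fixed rates; profile MLEs when `NULL`. `mu`
#'   is shared across clusters.
#' @return The log-likelihood (`-Inf` when an observed event has zero
#'   hazard).
#' @export
gmyc_loglik <- function(tree, threshold, p = 1, q = 1, lambda = NULL, mu = NULL) {
  setup <- gmyc_setup(tree)
  roots <- gmyc_cluster_roots(setup, threshold)
  gmyc_eval(setup, roots, p = p, q = q, lambda = lambda, mu = mu,
            shared_mu = TRUE)$loglik
}

#' Multi-rate GMYC delimitation
#'
#' Scans every candidate threshold (the internal node ages, plus zero for
#' the all-singleton solution), maximizing the profile log-likelihood
#' with exponents `p`, `q` optimized on a bounded grid; the winning
#' single-threshold model is then refined greedily, letting individual
#' clusters lower their own threshold (gaining a private coalescent rate)
#' while the AIC improves. A likelihood-ratio test compares the winning
#' single-threshold model against the null single-coalescent model (the
#' whole tree one cluster) with a chi-squared reference.
#'
#' @param tree An ultrametric rooted `phylo` with at least 3 leaves and 3
#'   distinct node ages, duplicates pruned.
#' @param p_grid,q_grid Exponent grids (default 0.5 to 2 by 0.5);
#'   unbounded exponent optimization is numerically fragile at this
#'   scale.
#' @return An [otu_partition()]; its `"model"` attribute is a `gmyc_fit`
#'   with the threshold, exponents, rates, log-likelihoods and the LR
#'   test (`statistic`, `df`, `p_value`).
#' @export
delimit_mgmyc <- function(tree, p_grid = seq(0.5, 2, by = 0.5),
                          q_grid = seq(0.5, 2, by = 0.5)) {
  setup <- gmyc_setup(tree)
  if (length(unique(round(setup$ev_ages, 12))) < 3) {
    abort("fewer than 3 distinct node ages: cannot delimit",
          class = "coidelim_cannot_delimit_error")
  }
  candidates <- c(0, setdiff(sort(unique(setup$ev_ages)), max(setup$ev_ages)))
  best <- NULL
  for (T in candidates) {
    roots <- gmyc_cluster_roots(setup, T)
    for (p in p_grid) for (q in q_grid) {
      fit <- gmyc_eval(setup, roots, p = p, q = q, shared_mu = TRUE)
      if (is.null(best) || fit$loglik > best$loglik + 1e-9) {
        best <- c(fit, list(threshold = T, p = p, q = q, roots = roots))
      }
    }
  }
  # null: single coalescent over the whole tree
  null_best <- NULL
  for (q in q_grid) {
    fit <- gmyc_eval(setup, setup$root, p = 1, q = q, shared_mu = TRUE)
    if (is.null(null_best) || fit$loglik > null_best$loglik) {
      null_best <- c(fit, list(q = q))
    }
  }
  lr_stat <- max(0, 2 * (best$loglik - null_best$loglik))
  lr_df <- max(1L, best$n_rate_params - null_best$n_rate_params)
  lr_p <- pchisq(lr_stat, df = lr_df, lower.tail = FALSE)
  # multi-rate refinement: per-cluster threshold lowering under AIC
  refined <- gmyc_refine(setup, best$roots, best$p, best$q)
  labels <- gmyc_labels(setup, refined$roots)
  part <- otu_partition(tree$tip.label, labels, method = "mGMYC-like",
                        params = list(threshold = best$threshold, p = best$p,
                                      q = best$q))
  attr(part, "model") <- structure(
    list(threshold = best$threshold, p = best$p, q = best$q,
         lambda = best$lambda, mu = best$mu[1],
         log_likelihood = best$loglik, null_log_likelihood = null_best$loglik,
         multi_log_likelihood = refined$loglik,
         cluster_roots = refined$roots,
         lr_test = list(statistic = lr_stat, df = lr_df, p_value = lr_p)),
    class = "gmyc_fit"
  )
  part
}

# Greedy per-cluster threshold refinement with per-cluster rates. The
# penalty is 2 per delimited cluster (as in the PTP search): a split must
# buy its extra entities with real likelihood, otherwise lowering a
# cluster's threshold until it dissolves into singletons would be free.
gmyc_refine <- function(setup, roots, p, q) {
  score_of <- function(rts) {
    fit <- gmyc_eval(setup, rts, p = p, q = q, shared_mu = FALSE)
    list(score = fit$loglik - 2 * length(rts), loglik = fit$loglik)
  }
  cur <- score_of(roots)
  repeat {
    move <- NULL
    for (r in roots) {
      if (r <= setup$ntip) next
      sub_ages <- sort(unique(setup$ages[intersect(c(r, setup$desc[[r]]), setup$internal)]),
                       decreasing = TRUE)
      for (T2 in c(sub_ages[-1], 0)) {  # strictly below the cluster root age
        new_sub <- gmyc_subtree_roots(setup, r, T2)
        cand_roots <- c(setdiff(roots, r), new_sub)
        cand <- score_of(cand_roots)
        if (is.null(move) || cand$score > move$fit$score) {
          move <- list(roots = cand_roots, fit = cand)
        }
      }
    }
    if (!is.null(move) && move$fit$score > cur$score + 1e-9) {
      roots <- move$roots
      cur <- move$fit
    } else break
  }
  list(roots = roots, loglik = cur$loglik, score = cur$score)
}

# Cluster roots within the subtree of `r` at threshold T2.
gmyc_subtree_roots <- function(setup, r, T2) {
  tol <- 1e-9 * max(setup$root_age, 1e-12)
  nodes <- c(r, setup$desc[[r]])
  edge <- setup$tree$edge
  keep <- edge[, 1] %in% nodes & edge[, 2] %in% nodes
  p_age <- setup$ages[edge[keep, 1]]
  c_age <- setup$ages[edge[keep, 2]]
  roots <- edge[keep, 2][p_age > T2 + tol & c_age <= T2 + tol]
  if (setup$ages[r] <= T2 + tol) r else roots
}

gmyc_labels <- function(setup, roots) {
  labels <- seq_len(setup$ntip)
  for (r in roots) {
    tips <- if (r <= setup$ntip) r else {
      d <- setup$desc[[r]]
      d[d <= setup$ntip]
    }
    labels[tips] <- setup$ntip + r
  }
  dense_labels(labels)
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat(sprintf("<gmyc_fit: threshold %.4g, logL %.4f vs null %.4f (LR %.3f, df %d, p %.3g)>\n",
              x$threshold, x$log_likelihood, x$null_log_likelihood,
              x$lr_test$statistic, x$lr_test$df, x$lr_test$p_value))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.gmyc_fit <- function(x, ...) {
  tibble(threshold = x$threshold, p = x$p, q = x$q, lambda = x$lambda,
         mu = x$mu, log_likelihood = x$log_likelihood,
         null_log_likelihood = x$null_log_likelihood,
         lr_statistic = x$lr_test$statistic, lr_df = x$lr_test$df,
         lr_p_value = x$lr_test$p_value)
}
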