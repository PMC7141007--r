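make_dm <- function(d, ids = NULL) {
  n <- nrow(d)
  ids <- ids %||% sprintf("s%02d", seq_len(n))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, sites = matrix(500L, n, n)),
            class = "k2p_dist")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# block-structured matrix: k clusters, within <= w, between >= b
block_dm <- function(sizes, within = 0.005, between = 0.08, seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  grp <- rep(seq_along(sizes), sizes)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <- if (grp[i] == grp[j]) runif(1, 0, within)
    else runif(1, between, between * 1.5)
  }
  list(dm = make_dm(d), truth = grp)
}

test_that("single linkage matches brute-force components and is monotone", {
  set.seed(501)
  n <- 30
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, 0.1)
  d <- d + t(d)
  dm <- make_dm(d)
  for (t in c(0, 0.01, 0.03, 0.06, 0.2)) {
    got <- delimit_single_linkage(dm, t)
    want <- oracle_single_linkage(d, t)
    expect_equal(partition_compare(got, otu_partition(dm$ids, want))$ari, 1)
  }
  counts <- sapply(seq(0, 0.12, by = 0.005),
                   function(t) n_otus(delimit_single_linkage(dm, t)))
  expect_true(all(diff(counts) <= 0))
  # threshold extremes
  expect_equal(n_otus(delimit_single_linkage(dm, 0)), n)
  expect_equal(n_otus(delimit_single_linkage(dm, max(d))), 1L)
})

test_that("RESL-like splits well-separated clusters and keeps tight ones whole", {
  bb <- block_dm(c(6, 6), within = 0.008, between = 0.08, seed = 502)
  p <- delimit_resl(bb$dm)
  expect_equal(n_otus(p), 2L)
  expect_equal(partition_compare(p, otu_partition(bb$dm$ids, bb$truth))$ari, 1)
  tight <- block_dm(c(10), within = 0.004, seed = 503)
  expect_equal(n_otus(delimit_resl(tight$dm)), 1L)
})

test_that("RESL-like refines its own stage-1 single-linkage partition", {
  set.seed(504)
  bb <- block_dm(c(5, 5, 4), within = 0.015, between = 0.05, seed = 504)
  p <- delimit_resl(bb$dm)
  stage1 <- delimit_single_linkage(bb$dm, 0.022)
  # every RESL OTU sits inside one stage-1 component
  tab <- table(p$otu_id, stage1$otu_id)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("ABGD finds a forced gap and degenerates gracefully", {
  # two monomorphic species 5% apart: every prior below 5% must find the gap
  bb <- block_dm(c(4, 5), within = 0, between = 0.05, seed = 505)
  res <- delimit_abgd(bb$dm)
  for (p in res$by_prior$partition) {
    if (attr(p, "params")$prior < 0.05) {
      expect_equal(partition_compare(p, otu_partition(bb$dm$ids, bb$truth))$ari, 1)
    }
  }
  expect_equal(n_otus(res$primary), 2L)
  # with intraspecific noise the primary (modal) partition still recovers it
  noisy <- block_dm(c(4, 5), within = 0.004, between = 0.05, seed = 505)
  expect_equal(partition_compare(delimit_abgd(noisy$dm)$primary,
                                 otu_partition(noisy$dm$ids, noisy$truth))$ari, 1)
  # all identical sequences: one OTU, no-gap flag
  flat <- make_dm(matrix(0, 5, 5))
  res0 <- delimit_abgd(flat)
  expect_equal(n_otus(res0$primary), 1L)
  expect_true(attr(res0$primary, "params")$no_gap)
})

test_that("ABGD partitions nest between single linkage at 0 and at the gap", {
  bb <- block_dm(c(5, 4, 6), within = 0.01, between = 0.07, seed = 506)
  res <- delimit_abgd(bb$dm)
  sl0 <- delimit_single_linkage(bb$dm, 0)
  slmax <- delimit_single_linkage(bb$dm, 0.1)
  for (p in res$by_prior$partition) {
    # coarsening of all-singletons-with-zero-links: distance-0 pairs co-cluster
    zero_pairs <- which(bb$dm$d <= 0 & upper.tri(bb$dm$d), arr.ind = TRUE)
    if (nrow(zero_pairs)) {
      expect_true(all(p$otu_id[zero_pairs[, 1]] == p$otu_id[zero_pairs[, 2]]))
    }
    # refinement of single linkage at p_max: each OTU within one component
    tab <- table(p$otu_id, slmax$otu_id)
    expect_true(all(rowSums(tab > 0) == 1))
  }
  expect_equal(n_otus(res$primary), 3L)
})

test_that("distance delimiters recover a scale-separated truth exactly", {
  # within-species diversity two orders below the species separation, so
  # the coalescent tail cannot reach the refinement grid
  suppressWarnings({
    sim <- simulate_barcodes(sim_config(seed = 507, theta = 2e-4))
  })
  dm <- k2p_distance_matrix(sim$dataset)
  expect_equal(partition_compare(sim$truth$partition, delimit_resl(dm))$ari, 1)
  expect_equal(partition_compare(sim$truth$partition, delimit_abgd(dm)$primary)$ari, 1)
})
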