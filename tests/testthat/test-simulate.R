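test_that("simulation is deterministic in the seed", {
  s1 <- simulate_barcodes(sim_config(seed = 42))
  s2 <- simulate_barcodes(sim_config(seed = 42))
  expect_identical(s1$dataset$sequence, s2$dataset$sequence)
  expect_identical(s1$dataset$specimen_id, s2$dataset$specimen_id)
  s3 <- simulate_barcodes(sim_config(seed = 43))
  expect_false(identical(s1$dataset$sequence, s3$dataset$sequence))
})

test_that("config validation enforces feasibility", {
  expect_error(sim_config(), class = "coidelim_config_error")
  expect_error(sim_config(seed = 1, theta = 0), class = "coidelim_config_error")
  expect_error(sim_config(seed = 1, n_species = 10, introgression_events = 6),
               class = "coidelim_config_error")
})

test_that("summaries of simulated data separate the taxonomic scales", {
  sim <- simulate_barcodes(sim_config(seed = 901))
  ds <- sim$dataset
  expect_equal(length(unique(ds$species)), 20L)
  expect_equal(alignment_length(ds), 652L)
  dm <- k2p_distance_matrix(ds)
  s <- divergence_summary(ds, dm)
  ws <- s$mean[s$level == "within_species"]
  wg <- s$mean[s$level == "within_genus"]
  expect_lt(ws, 0.01)
  if (!is.na(wg)) expect_gt(wg, 10 * ws)
  # within-species scale tracks theta
  expect_lt(abs(ws - 0.003), 0.003)
})

test_that("in the low-diversity limit all delimiters recover the truth", {
  # theta -> 0 with strongly separated species (high speciation rate packs
  # the splits deep, far above the vanishing coalescent scale)
  sim <- simulate_barcodes(sim_config(seed = 902, theta = 1e-5, yule_rate = 3))
  dm <- k2p_distance_matrix(sim$dataset)
  intra <- divergence_summary(sim$dataset, dm)
  # at most stray single-mutation variation within species
  expect_lt(intra$max[intra$level == "within_species"], 0.002)
  pp <- run_pipeline(sim$dataset)
  # the mixed Yule-coalescent needs intraspecific branching to place its
  # threshold; with one haplotype per species it has nothing to fit, so
  # the degenerate-limit recovery claim covers the other three methods
  # and the consensus (which outvotes the undefined case)
  for (m in c("resl", "abgd", "mptp")) {
    expect_equal(partition_compare(sim$truth$partition, pp$partitions[[m]])$ari, 1,
                 tolerance = 1e-12, label = m)
  }
  expect_equal(partition_compare(sim$truth$partition, pp$consensus)$ari, 1,
               tolerance = 1e-12)
})

test_that("expected divergence follows the strict clock and is kappa-invariant", {
  expect_equal(expected_k2p(1, 0.012), 0.012)
  expect_equal(expected_k2p(5, 0.012), 0.06)
  # Monte Carlo: pairs separated 5 My at the default clock
  set.seed(903)
  tr <- ape::read.tree(text = "(x:0.03,y:0.03);")
  dists <- replicate(200, {
    s <- phangorn::simSeq(tr, l = 652, Q = c(1, 4, 1, 1, 4, 1),
                          bf = rep(0.25, 4), type = "DNA")
    m <- toupper(as.character(s))
    k2p_distance(paste(m[1, ], collapse = ""), paste(m[2, ], collapse = ""))$distance
  })
  se <- stats::sd(dists) / sqrt(length(dists))
  expect_lt(abs(mean(dists) - 0.06), 3 * se)
  # kappa does not change the expected total divergence (rate-normalized)
  set.seed(904)
  for (kap in c(2, 8)) {
    d2 <- replicate(60, {
      s <- phangorn::simSeq(tr, l = 652, Q = c(1, kap, 1, 1, kap, 1),
                            bf = rep(0.25, 4), type = "DNA")
      m <- toupper(as.character(s))
      k2p_distance(paste(m[1, ], collapse = ""), paste(m[2, ], collapse = ""))$distance
    })
    expect_lt(abs(mean(d2) - 0.06), 4 * stats::sd(d2) / sqrt(60))
  }
})

test_that("cryptic splits create deep intraspecific structure in the log", {
  sim <- simulate_barcodes(sim_config(seed = 905, cryptic_splits = 2))
  ev <- sim$truth$events
  expect_equal(sum(ev$type == "cryptic_split"), 2L)
  dm <- k2p_distance_matrix(sim$dataset)
  g <- barcode_gap(sim$dataset, dm)
  for (sp in ev$species[ev$type == "cryptic_split"]) {
    row <- g[g$species == sp, ]
    # the split sits well above the coalescent scale
    expect_gt(row$max_intra, 0.01)
  }
})

test_that("introgression moves one haplotype and logs donor and recipient", {
  sim <- simulate_barcodes(sim_config(seed = 906, introgression_events = 2))
  ev <- sim$truth$events[sim$truth$events$type == "introgression", ]
  expect_equal(nrow(ev), 2L)
  ds <- sim$dataset
  for (i in seq_len(nrow(ev))) {
    moved <- ds$sequence[ds$specimen_id == ev$specimen_id[i]]
    donors <- ds$sequence[ds$species == ev$donor[i]]
    expect_true(moved %in% donors)
    expect_equal(ds$species[ds$specimen_id == ev$specimen_id[i]], ev$species[i])
  }
})
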