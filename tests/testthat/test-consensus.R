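ids4 <- sprintf("s%d", 1:4)
part <- function(labels, ids = ids4, method = "m") {
  otu_partition(ids, labels, method = method)
}

test_that("consensus of identical partitions is that partition", {
  p <- part(c(1, 1, 2, 2))
  cons <- consensus_partition(list(p, p, p, p))
  expect_equal(partition_compare(cons, p)$ari, 1)
  # idempotence: consensus of the consensus
  cons2 <- consensus_partition(list(cons, cons))
  expect_equal(partition_compare(cons2, cons)$ari, 1)
})

test_that("quorum arithmetic: 1-of-4 support fails, 2-of-4 ties pass", {
  split3 <- part(c(1, 2, 3, 4))
  merged <- part(c(1, 1, 2, 3))
  # 3 methods split {s1,s2}, 1 merges: support 1/4 < 0.5 -> split
  cons <- consensus_partition(list(split3, split3, split3, merged))
  expect_equal(n_otus(cons), 4L)
  # 2 of 4 merge: tie counts as meeting the 50% quorum -> merged
  cons2 <- consensus_partition(list(split3, split3, merged, merged))
  expect_equal(cons2$otu_id[1], cons2$otu_id[2])
})

test_that("consensus is invariant to input order and specimen order", {
  set.seed(801)
  ps <- list(part(c(1, 1, 2, 2)), part(c(1, 2, 2, 3)),
             part(c(1, 1, 1, 2)), part(c(1, 2, 3, 3)))
  base <- consensus_partition(ps)
  for (i in 1:5) {
    shuf <- consensus_partition(sample(ps))
    expect_equal(partition_compare(base, shuf)$ari, 1)
  }
  # permuting specimen rows of one input changes nothing
  p2 <- ps[[2]][c(3, 1, 4, 2), ]
  attr(p2, "method") <- "m"
  class(p2) <- class(ps[[2]])
  shuf2 <- consensus_partition(list(ps[[1]], p2, ps[[3]], ps[[4]]))
  expect_equal(partition_compare(base, shuf2)$ari, 1)
})

test_that("quorum limits behave as expected", {
  a <- part(c(1, 1, 2, 3))
  b <- part(c(1, 1, 2, 2))
  one <- part(c(1, 1, 1, 1))
  # quorum 1: only the unanimous pair (s1, s2) merges
  cons1 <- consensus_partition(list(a, b), quorum = 1)
  expect_true(cons1$otu_id[1] == cons1$otu_id[2])
  expect_equal(n_otus(cons1), 3L)
  # quorum -> 0: any single merge suffices; with a total merger present,
  # everything collapses
  cons0 <- consensus_partition(list(a, b, one), quorum = 1e-9)
  expect_equal(n_otus(cons0), 1L)
  expect_error(consensus_partition(list(a)), class = "coidelim_validation_error")
  bad <- otu_partition(c("x", "y", "z", "w"), c(1, 1, 2, 2))
  expect_error(consensus_partition(list(a, bad)), class = "coidelim_validation_error")
})

test_that("ARI matches the brute-force contingency formula and mclust", {
  skip_if_not_installed("mclust")
  p1 <- part(c(1, 1, 2, 2))
  expect_equal(partition_compare(p1, p1)$ari, 1)
  n10 <- sprintf("t%d", 1:10)
  singletons <- otu_partition(n10, 1:10)
  lump <- otu_partition(n10, rep(1, 10))
  expect_equal(partition_compare(singletons, lump)$ari, 0)
  set.seed(802)
  for (i in 1:10) {
    ids <- sprintf("u%d", 1:12)
    x <- otu_partition(ids, sample(1:4, 12, replace = TRUE))
    y <- otu_partition(ids, sample(1:3, 12, replace = TRUE))
    got <- partition_compare(x, y)
    expect_equal(got$ari, oracle_ari(x$otu_id, y$otu_id), tolerance = 1e-12)
    # agreement count by explicit pair enumeration
    agree <- 0
    for (a in 1:11) for (b in (a + 1):12) {
      same_x <- x$otu_id[a] == x$otu_id[b]
      same_y <- y$otu_id[a] == y$otu_id[b]
      if (same_x == same_y) agree <- agree + 1
    }
    expect_equal(got$n_agree_pairs, agree)
  }
})

test_that("concordance classifies match, split, merge and mixed correctly", {
  set.seed(803)
  base <- random_dna(500)
  seqs <- c(base, base,                               # A: one OTU
            mutate_dna(base, 40, 20), mutate_dna(mutate_dna(base, 40, 20), 2), # B
            mutate_dna(base, 20, 45), base)           # C: splits, one shares with A
  ds <- barcode_dataset(tibble::tibble(
    specimen_id = sprintf("v%d", 1:6),
    species = c("A", "A", "B", "B", "C", "C"),
    genus = "G", family = "F", sequence = seqs
  ))
  dm <- k2p_distance_matrix(ds)
  cons <- otu_partition(ds$specimen_id, c(1, 1, 2, 2, 3, 1), method = "consensus")
  rep <- concordance_report(ds, cons, dm = dm)
  st <- setNames(rep$per_species$status, rep$per_species$species)
  expect_equal(unname(st["A"]), "MERGE")
  expect_equal(unname(st["B"]), "MATCH")
  expect_equal(unname(st["C"]), "MIXED")
  expect_equal(rep$counts$n_merged_otus, 1L)
  expect_equal(rep$counts$n_split_species, 1L)  # SPLIT + MIXED
  expect_setequal(rep$per_species$species[rep$per_species$haplotype_sharing],
                  c("A", "C"))
  # count identities
  expect_equal(rep$counts$n_match + rep$counts$n_split_species +
                 sum(rep$per_species$status == "MERGE"), rep$counts$n_species)
  expect_equal(rep$counts$n_otus_in_split_species,
               sum(rep$per_species$n_otus[rep$per_species$status %in% c("SPLIT", "MIXED")]))
})

test_that("a one-to-one dataset reports all matches", {
  set.seed(804)
  sim <- simulate_barcodes(sim_config(seed = 804, theta = 0.001))
  pp <- run_pipeline(sim$dataset)
  if (partition_compare(sim$truth$partition, pp$consensus)$ari == 1) {
    expect_true(all(pp$report$per_species$status == "MATCH"))
    expect_equal(pp$report$counts$n_otus, pp$report$counts$n_species)
  }
  expect_equal(pp$report$counts$n_otus, n_otus(pp$consensus))
})

test_that("report rendering writes percent-formatted tables", {
  set.seed(805)
  sim <- simulate_barcodes(sim_config(seed = 805, theta = 0.001))
  pp <- run_pipeline(sim$dataset)
  dir <- withr::local_tempdir()
  paths <- render_reports(pp$report, pp$summaries, dir)
  expect_true(all(file.exists(file.path(dir, c("level_summary.tsv",
                                               "species_concordance.tsv",
                                               "concordance_counts.json")))))
  per <- readr::read_tsv(file.path(dir, "species_concordance.tsv"),
                         show_col_types = FALSE)
  singles <- per$max_intra[per$n == 1]
  if (length(singles)) expect_true(all(singles == "—"))
  js <- jsonlite::read_json(file.path(dir, "concordance_counts.json"))
  expect_equal(js$n_otus, n_otus(pp$consensus))
})
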