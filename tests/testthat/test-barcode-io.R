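test_that("FASTA + metadata round-trips through read and write", {
  set.seed(101)
  ds <- toy_dataset()
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_barcode_dataset(ds, fa, tsv)
  back <- read_barcode_dataset(fa, tsv)
  expect_identical(back$specimen_id, ds$specimen_id)
  expect_identical(back$sequence, ds$sequence)
  expect_identical(back$species, ds$species)
  expect_identical(alignment_length(back), alignment_length(ds))
  # read -> write -> read is the identity
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_barcode_dataset(back, fa2, tsv2)
  expect_identical(read_barcode_dataset(fa2, tsv2)$sequence, ds$sequence)
})

test_that("dataset validation rejects malformed input", {
  df <- tibble::tibble(specimen_id = c("a", "b"), species = "S", genus = "G",
                       family = "F", sequence = c("ACGTACGTAC", "ACGTACGTACG"))
  expect_error(barcode_dataset(df), class = "coidelim_alignment_error")
  df$sequence <- c("ACGTACGTAC", "ACGTACGTAC")
  df$specimen_id <- c("a", "a")
  expect_error(barcode_dataset(df), class = "coidelim_validation_error")
  df$specimen_id <- c("a", "b")
  df$sequence <- c("ACGTACGTAX", "ACGTACGTAC")
  expect_error(barcode_dataset(df), class = "coidelim_validation_error")
})

test_that("FASTA ids must match metadata 1:1", {
  set.seed(102)
  ds <- toy_dataset()
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_barcode_dataset(ds, fa, tsv)
  meta <- readr::read_tsv(tsv, show_col_types = FALSE)
  readr::write_tsv(meta[-1, ], tsv)
  expect_error(read_barcode_dataset(fa, tsv), class = "coidelim_join_error")
})

test_that("haplotype deduplication is idempotent and membership-complete", {
  set.seed(103)
  base <- random_dna(500)
  ds <- barcode_dataset(tibble::tibble(
    specimen_id = sprintf("x%d", 1:5),
    species = c("A", "A", "A", "B", "B"),
    genus = "G", family = "F",
    sequence = c(base, base, mutate_dna(base, n_ts = 2), base,
                 mutate_dna(base, n_tv = 3))
  ))
  dd <- deduplicate_haplotypes(ds)
  # x1, x2, x4 are identical; representative is the first in order
  expect_equal(nrow(dd$dataset), 3)
  expect_setequal(dd$members$specimen_id, ds$specimen_id)
  expect_equal(sum(table(dd$members$haplotype_id)), nrow(ds))
  expect_setequal(dd$members$specimen_id[dd$members$haplotype_id == "x1"],
                  c("x1", "x2", "x4"))
  # shared haplotype carries both species labels in the membership table
  expect_setequal(dd$members$species[dd$members$haplotype_id == "x1"],
                  c("A", "B"))
  # idempotence
  dd2 <- deduplicate_haplotypes(dd$dataset)
  expect_identical(dd2$dataset$specimen_id, dd$dataset$specimen_id)
  # ambiguity codes match any base at shared columns
  amb <- ds
  amb$sequence[2] <- sub("^.", "N", amb$sequence[2])
  amb <- barcode_dataset(amb)
  expect_equal(nrow(deduplicate_haplotypes(amb)$dataset), 3)
})

test_that("deduplication agrees with exhaustive pairwise comparison", {
  set.seed(104)
  base <- random_dna(450)
  seqs <- vapply(1:12, function(i) {
    if (i %% 3 == 0) base else mutate_dna(base, n_ts = sample(0:2, 1))
  }, character(1))
  ds <- barcode_dataset(tibble::tibble(
    specimen_id = sprintf("s%02d", 1:12), species = "A", genus = "G",
    family = "F", sequence = seqs
  ))
  dd <- deduplicate_haplotypes(ds)
  # brute force: i joins the first earlier representative with no
  # conflicting unambiguous site
  reps <- character(0)
  assign <- character(12)
  for (i in 1:12) {
    hit <- NA
    for (r in reps) {
      a <- strsplit(seqs[i], "")[[1]]; b <- strsplit(seqs[match(r, ds$specimen_id)], "")[[1]]
      ok <- a %in% c("A","C","G","T") & b %in% c("A","C","G","T")
      if (!any(a[ok] != b[ok])) { hit <- r; break }
    }
    if (is.na(hit)) { reps <- c(reps, ds$specimen_id[i]); assign[i] <- ds$specimen_id[i] }
    else assign[i] <- hit
  }
  expect_identical(dd$members$haplotype_id, assign)
})

test_that("partition TSV round-trips and empty partitions give a header-only file", {
  p <- otu_partition(c("b", "a", "c"), c(1, 1, 2), method = "demo")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition_tsv(p, f)
  back <- read_partition_tsv(f)
  expect_equal(partition_compare(p, back)$ari, 1)
  expect_identical(attr(back, "method"), "demo")
  empty <- otu_partition(character(0), integer(0), method = "demo")
  write_partition_tsv(empty, f)
  expect_equal(length(readLines(f)), 1L)
})
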