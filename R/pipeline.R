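#' Expand a haplotype-level partition to all specimens
#'
#' Tree delimiters run on deduplicated haplotypes; this maps every
#' specimen to the OTU of its haplotype representative using the
#' membership table from [deduplicate_haplotypes()].
#'
#' @param partition An [otu_partition()] over haplotype representatives.
#' @param members The `members` tibble from [deduplicate_haplotypes()].
#' @return An [otu_partition()] over all specimens.
#' @export
expand_partition <- function(partition, members) {
  idx <- match(members$haplotype_id, partition$specimen_id)
  if (anyNA(idx)) {
    abort("membership table references haplotypes missing from the partition",
          class = "coidelim_validation_error")
  }
  otu_partition(members$specimen_id, partition$otu_id[idx],
                method = attr(partition, "method"),
                params = attr(partition, "params"))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s': %s", stage, conditionMessage(e)),
          class = class(e)[[1]])
  })
}

#' Run the full barcode-library analysis
#'
#' One call from an aligned dataset to the result bundle: K2P distances,
#' taxonomic-level summaries, barcode-gap statistics, duplicate pruning,
#' internal NJ and UPGMA-chronogram trees, the enabled delimiters, their
#' majority-rule consensus and the species-versus-OTU concordance report.
#' Externally built trees (for example maximum-likelihood or Bayesian
#' chronograms) can be injected for the tree delimiters; their tips must
#' be the deduplicated haplotype representatives.
#'
#' @param ds A `barcode_dataset`.
#' @param methods Delimiters to run, a subset of
#'   `c("resl", "abgd", "mptp", "mgmyc")`; the consensus requires at
#'   least two.
#' @param quorum Consensus quorum (see [consensus_partition()]).
#' @param min_overlap Minimum comparable sites per pair.
#' @param clock_rate Pairwise divergence per My for the chronogram.
#' @param seed Seed for the stochastic searches (recorded in
#'   parameters).
#' @param mptp_tree,mgmyc_tree Optional `phylo` trees (or Newick paths)
#'   replacing the internal NJ tree / UPGMA chronogram.
#' @param out_dir Optional directory; when given, partitions, tables and
#'   a `results.json` are written there.
#' @return A `barcode_pipeline` object: list with `summaries`, `gaps`,
#'   `gap_ratio`, `partitions` (named list), `consensus`, `report`,
#'   `dedup`, `results` (the flat result list mirrored to JSON).
#' @export
run_pipeline <- function(ds, methods = c("resl", "abgd", "mptp", "mgmyc"),
                         quorum = 0.5, min_overlap = 400, clock_rate = 0.012,
                         seed = 42, mptp_tree = NULL, mgmyc_tree = NULL,
                         out_dir = NULL) {
  methods <- match.arg(methods, c("resl", "abgd", "mptp", "mgmyc"),
                       several.ok = TRUE)
  if (length(methods) < 2) {
    abort("the consensus needs at least two enabled delimiters",
          class = "coidelim_config_error")
  }
  run_stage("validate", validate_barcode_dataset(ds))
  dm <- run_stage("distances", k2p_distance_matrix(ds, min_overlap))
  summaries <- run_stage("summaries", divergence_summary(ds, dm))
  gaps <- run_stage("gaps", barcode_gap(ds, dm))
  ratio <- tryCatch(gap_ratio(gaps), error = function(e) NA_real_)
  dedup <- run_stage("deduplicate", deduplicate_haplotypes(ds))
  dm_dedup <- subset_k2p(dm, dedup$dataset$specimen_id)
  as_tree <- function(x) if (is.character(x)) read_newick(x) else x

  partitions <- list()
  if ("resl" %in% methods) {
    partitions$resl <- run_stage("resl", delimit_resl(dm))
  }
  if ("abgd" %in% methods) {
    partitions$abgd <- run_stage("abgd", delimit_abgd(dm)$primary)
  }
  if ("mptp" %in% methods) {
    tr <- if (!is.null(mptp_tree)) as_tree(mptp_tree) else {
      run_stage("nj_tree", nj_tree(dm_dedup))
    }
    p <- run_stage("mptp", delimit_mptp(tr, seed = seed))
    partitions$mptp <- expand_partition(p, dedup$members)
    attr(partitions$mptp, "model") <- attr(p, "model")
  }
  if ("mgmyc" %in% methods) {
    tr <- if (!is.null(mgmyc_tree)) as_tree(mgmyc_tree) else {
      run_stage("chronogram", upgma_chronogram(dm_dedup, clock_rate))
    }
    p <- run_stage("mgmyc", delimit_mgmyc(tr))
    partitions$mgmyc <- expand_partition(p, dedup$members)
    attr(partitions$mgmyc, "model") <- attr(p, "model")
  }
  consensus <- run_stage("consensus", consensus_partition(partitions, quorum))
  report <- run_stage("concordance", concordance_report(ds, consensus, gaps, dm))

  results <- list(
    n_specimens = nrow(ds),
    n_haplotypes = nrow(dedup$dataset),
    n_species = length(unique(ds$species)),
    level_summaries = summaries,
    method_n_otus = lapply(partitions, n_otus),
    consensus_n_otus = n_otus(consensus),
    concordance = report$counts,
    gap_ratio = ratio,
    params = list(methods = methods, quorum = quorum, min_overlap = min_overlap,
                  clock_rate = clock_rate, seed = seed)
  )
  out <- structure(
    list(dataset = ds, dm = dm, summaries = summaries, gaps = gaps,
         gap_ratio = ratio, dedup = dedup, partitions = partitions,
         consensus = consensus, report = report, results = results),
    class = "barcode_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (m in names(x$partitions)) {
    p <- file.path(out_dir, paste0("partition_", m, ".tsv"))
    write_partition_tsv(x$partitions[[m]], p, dataset = x$dataset)
    written <- c(written, p)
  }
  p <- file.path(out_dir, "partition_consensus.tsv")
  write_partition_tsv(x$consensus, p, dataset = x$dataset)
  written <- c(written, p)
  written <- c(written, render_reports(x$report, x$summaries, out_dir))
  res <- x$results
  res$level_summaries <- as.data.frame(res$level_summaries)
  p <- file.path(out_dir, "results.json")
  jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, p)
  p <- file.path(out_dir, "manifest.txt")
  writeLines(basename(written), p)
  invisible(c(written, p))
}

#' @export
print.barcode_pipeline <- function(x, ...) {
  cat(sprintf("<barcode_pipeline: %d specimens, %d species, %d haplotypes>\n",
              nrow(x$dataset), length(unique(x$dataset$species)),
              nrow(x$dedup$dataset)))
  counts <- vapply(x$partitions, n_otus, integer(1))
  cat("  OTUs: ", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
      sprintf("; consensus=%d\n", n_otus(x$consensus)), sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.barcode_pipeline <- function(x, ...) {
  counts <- x$report$counts
  tibble(
    n_specimens = counts$n_specimens,
    n_species = counts$n_species,
    n_haplotypes = nrow(x$dedup$dataset),
    consensus_n_otus = counts$n_otus,
    n_match = counts$n_match,
    n_split_species = counts$n_split_species,
    n_merged_otus = counts$n_merged_otus,
    gap_ratio = x$gap_ratio
  )
}
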