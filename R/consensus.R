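#' Majority-rule consensus of OTU partitions
#'
#' Builds a co-clustering graph over specimens: a pair is linked when it
#' shares an OTU in at least `quorum` of the input partitions (ties count
#' as meeting the quorum, so 2-of-4 passes at 50%). Consensus OTUs are
#' the connected components of that graph — majority co-clustering is not
#' transitive, so the component closure is the operational meaning of the
#' consensus.
#'
#' @param partitions A list of at least two [otu_partition()]s over the
#'   same specimen set.
#' @param quorum Fraction of methods that must co-cluster a pair (default
#'   0.5).
#' @return An [otu_partition()] with method `"consensus"`; the
#'   contributing method names are recorded in its parameters.
#' @export
consensus_partition <- function(partitions, quorum = 0.5) {
  if (length(partitions) < 2) {
    abort("consensus needs at least two partitions", class = "coidelim_validation_error")
  }
  ref <- partitions[[1]]
  labels <- vapply(partitions, function(p) align_partitions(ref, p),
                   integer(nrow(ref)))
  n <- nrow(ref)
  support <- matrix(0L, n, n)
  for (m in seq_len(ncol(labels))) {
    same <- outer(labels[, m], labels[, m], `==`)
    support <- support + same
  }
  need <- quorum * length(partitions)
  linked <- which(upper.tri(support) & support >= need - 1e-12, arr.ind = TRUE)
  comp <- uf_components(n, linked)
  otu_partition(ref$specimen_id, comp, method = "consensus",
                params = list(
                  quorum = quorum,
                  methods = vapply(partitions, function(p) attr(p, "method") %||% "?",
                                   character(1))
                ))
}

#' Species-versus-OTU concordance report
#'
#' Classifies every morphological species against the consensus OTUs:
#' `SPLIT` when its specimens fall into several OTUs, none shared with
#' another species (cryptic-lineage candidate); `MERGE` when all its
#' specimens sit in one OTU that also contains other species (haplotype
#' sharing / mixed genealogy); `MIXED` when both happen; `MATCH`
#' otherwise. Haplotype-sharing species are those with a distance-zero
#' heterospecific pair.
#'
#' @param ds A `barcode_dataset`.
#' @param consensus An [otu_partition()] covering all its specimens.
#' @param gaps Optional [barcode_gap()] tibble to merge per-species
#'   distance columns into the report.
#' @param dm Optional `k2p_dist` used to detect haplotype sharing
#'   (distance-zero heterospecific pairs); omit to skip that column.
#' @return A `concordance_report`: list with `consensus`, `per_species`,
#'   `merged_otus` and `counts` (see [glance.concordance_report()]).
#' @export
concordance_report <- function(ds, consensus, gaps = NULL, dm = NULL) {
  if (!setequal(ds$specimen_id, consensus$specimen_id)) {
    abort("consensus partition does not cover the dataset",
          class = "coidelim_validation_error")
  }
  otu <- consensus$otu_id[match(ds$specimen_id, consensus$specimen_id)]
  df <- tibble(specimen_id = ds$specimen_id, species = ds$species, otu_id = otu)
  otu_species <- df |> group_by(.data$otu_id) |>
    summarise(n_species = dplyr::n_distinct(.data$species),
              species_set = list(sort(unique(.data$species))), .groups = "drop")
  shared_otus <- otu_species$otu_id[otu_species$n_species > 1]
  per_species <- df |> group_by(.data$species) |>
    summarise(
      n = n(),
      n_otus = dplyr::n_distinct(.data$otu_id),
      otu_ids = list(sort(unique(.data$otu_id))),
      .groups = "drop"
    )
  per_species$shares_otu <- map_lgl(per_species$otu_ids,
                                    function(o) any(o %in% shared_otus))
  per_species$status <- dplyr::case_when(
    per_species$n_otus > 1 & per_species$shares_otu ~ "MIXED",
    per_species$n_otus > 1 ~ "SPLIT",
    per_species$shares_otu ~ "MERGE",
    TRUE ~ "MATCH"
  )
  if (!is.null(dm)) {
    sharing <- haplotype_sharing_species(ds, dm)
    per_species$haplotype_sharing <- per_species$species %in% sharing
  }
  if (!is.null(gaps)) {
    per_species <- left_join(
      per_species,
      gaps[, c("species", "max_intra", "nn_dist", "nn_taxon")],
      by = "species"
    )
  }
  merged_otus <- otu_species |> filter(.data$n_species > 1) |>
    select("otu_id", "species_set")
  split_like <- per_species$status %in% c("SPLIT", "MIXED")
  counts <- list(
    n_specimens = nrow(ds),
    n_species = nrow(per_species),
    n_otus = n_otus(consensus),
    n_match = sum(per_species$status == "MATCH"),
    n_split_species = sum(split_like),
    n_otus_in_split_species = sum(unlist(per_species$n_otus[split_like])),
    n_merged_otus = nrow(merged_otus),
    n_species_in_merged_otus = length(unique(unlist(merged_otus$species_set))),
    n_haplotype_sharing_species =
      if (!is.null(dm)) sum(per_species$haplotype_sharing) else NA_integer_
  )
  structure(list(consensus = consensus, per_species = per_species,
                 merged_otus = merged_otus, counts = counts),
            class = "concordance_report")
}

# Species involved in at least one distance-zero heterospecific pair.
haplotype_sharing_species <- function(ds, dm) {
  stopifnot(identical(ds$specimen_id, dm$ids))
  zero <- which(upper.tri(dm$d) & dm$d <= 0, arr.ind = TRUE)
  if (!nrow(zero)) return(character(0))
  sp_a <- ds$species[zero[, 1]]
  sp_b <- ds$species[zero[, 2]]
  hetero <- sp_a != sp_b
  sort(unique(c(sp_a[hetero], sp_b[hetero])))
}

#' @export
print.concordance_report <- function(x, ...) {
  c <- x$counts
  cat(sprintf(paste0("<concordance_report: %d species vs %d OTUs; %d match, ",
                     "%d split/mixed species (%d OTUs), %d merged OTUs>\n"),
              c$n_species, c$n_otus, c$n_match, c$n_split_species,
              c$n_otus_in_split_species, c$n_merged_otus))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.concordance_report <- function(x, ...) {
  out <- x$per_species
  out$otu_ids <- map_chr(out$otu_ids, paste, collapse = ",")
  out
}

#' @exportS3Method generics::glance
glance.concordance_report <- function(x, ...) {
  as_tibble(x$counts)
}

#' Write the report tables
#'
#' Emits TSV analogues of the classic barcode-library tables — the
#' taxonomic-level distance summary and the per-species barcode-gap /
#' concordance table (percent, two decimals, singletons' `max_intra`
#' rendered as an em dash) — plus a JSON file with the full counts.
#'
#' @param report A `concordance_report`.
#' @param summaries A `divergence_summary` tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(report, summaries, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lvl <- summaries
  for (col in c("min", "mean", "max")) lvl[[col]] <- fmt_pct(lvl[[col]])
  p1 <- file.path(dir, "level_summary.tsv")
  readr::write_tsv(lvl, p1, progress = FALSE)
  per <- tidy(report)
  for (col in intersect(c("max_intra", "nn_dist"), names(per))) {
    per[[col]] <- fmt_pct(per[[col]])
  }
  p2 <- file.path(dir, "species_concordance.tsv")
  readr::write_tsv(per, p2, progress = FALSE)
  p3 <- file.path(dir, "concordance_counts.json")
  jsonlite::write_json(report$counts, p3, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(p1, p2, p3))
}
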