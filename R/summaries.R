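#' Divergence summaries by taxonomic level
#'
#' Summarises K2P distances over mutually exclusive pair classes:
#' `within_species` (conspecific pairs), `within_genus` (congeneric pairs
#' of different species) and `within_family` (confamilial pairs of
#' different genera). For each level, `n_comparisons` counts the pairs,
#' `n_taxa` the taxa contributing at least one pair, and `n_sequences` the
#' specimens belonging to those taxa. Levels with no pairs report
#' `n_comparisons = 0` and missing `min`/`mean`/`max`.
#'
#' @param ds A `barcode_dataset`.
#' @param dm The matching `k2p_dist`.
#' @return A tibble with one row per level (class `divergence_summary`),
#'   distances in proportions.
#' @export
divergence_summary <- function(ds, dm) {
  stopifnot(identical(ds$specimen_id, dm$ids))
  pairs <- tidy(dm)
  tax <- tibble(specimen_id = ds$specimen_id, species = ds$species,
                genus = ds$genus, family = ds$family)
  pairs <- left_join(pairs, rename(tax, id_a = "specimen_id", sp_a = "species",
                                   ge_a = "genus", fa_a = "family"), by = "id_a")
  pairs <- left_join(pairs, rename(tax, id_b = "specimen_id", sp_b = "species",
                                   ge_b = "genus", fa_b = "family"), by = "id_b")
  pairs$level <- dplyr::case_when(
    pairs$sp_a == pairs$sp_b ~ "within_species",
    pairs$ge_a == pairs$ge_b ~ "within_genus",
    pairs$fa_a == pairs$fa_b ~ "within_family",
    TRUE ~ "between_families"
  )
  level_row <- function(lvl, taxon_col) {
    sub <- pairs[pairs$level == lvl, , drop = FALSE]
    taxa <- unique(c(sub[[paste0(taxon_col, "_a")]], sub[[paste0(taxon_col, "_b")]]))
    full_col <- c(sp = "species", ge = "genus", fa = "family")[[taxon_col]]
    tibble(
      level = lvl,
      n_sequences = sum(ds[[full_col]] %in% taxa),
      n_taxa = length(taxa),
      n_comparisons = nrow(sub),
      min = if (nrow(sub)) min(sub$distance) else NA_real_,
      mean = if (nrow(sub)) mean(sub$distance) else NA_real_,
      max = if (nrow(sub)) max(sub$distance) else NA_real_
    )
  }
  out <- bind_rows(
    level_row("within_species", "sp"),
    level_row("within_genus", "ge"),
    level_row("within_family", "fa")
  )
  class(out) <- c("divergence_summary", class(tibble()))
  out
}

#' Barcode-gap statistics per species
#'
#' For each species: the maximum intraspecific K2P distance (`max_intra`,
#' missing for singletons), the distance to the nearest heterospecific
#' neighbour (`nn_dist`, the minimum over all conspecific-heterospecific
#' specimen pairs), the neighbour's species (`nn_taxon`, ties broken
#' lexicographically) and whether a barcode gap is present
#' (`has_gap = nn_dist > max_intra`, undefined for singletons).
#'
#' @param ds A `barcode_dataset` with at least two species.
#' @param dm The matching `k2p_dist`.
#' @return A tibble with one row per species (class `barcode_gap`),
#'   distances in proportions, ordered by species name.
#' @export
barcode_gap <- function(ds, dm) {
  stopifnot(identical(ds$specimen_id, dm$ids))
  species <- ds$species
  if (length(unique(species)) < 2) {
    abort("barcode-gap statistics need at least two species",
          class = "coidelim_no_neighbor_error")
  }
  sp_levels <- sort(unique(species))
  rows <- map(sp_levels, function(sp) {
    idx <- which(species == sp)
    other <- which(species != sp)
    max_intra <- if (length(idx) > 1) {
      max(dm$d[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))])
    } else NA_real_
    hetero <- dm$d[idx, other, drop = FALSE]
    nn_dist <- min(hetero)
    hit <- which(hetero == nn_dist, arr.ind = TRUE)
    nn_taxon <- min(species[other][hit[, 2]])
    tibble(
      species = sp, n = length(idx), max_intra = max_intra,
      nn_dist = nn_dist, nn_taxon = nn_taxon,
      has_gap = if (is.na(max_intra)) NA else nn_dist > max_intra
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("barcode_gap", class(tibble()))
  out
}

#' Ratio of nearest-neighbour to maximum-intraspecific distances
#'
#' Summarises how far apart the two barcode-gap distributions sit. The
#' default, `ratio_of_means`, is `mean(nn_dist) / mean(max_intra)` over
#' species with a defined `max_intra`; `mean_of_ratios` averages
#' `nn_dist / max_intra` over species with `max_intra > 0` (the per-species
#' ratio is undefined at zero).
#'
#' @param gaps A `barcode_gap` tibble.
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return A single number.
#' @export
gap_ratio <- function(gaps, method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  g <- gaps[!is.na(gaps$max_intra), , drop = FALSE]
  if (!nrow(g)) {
    abort("no species with a defined maximum intraspecific distance",
          class = "coidelim_undefined_ratio_error")
  }
  if (method == "ratio_of_means") {
    denom <- mean(g$max_intra)
    if (denom == 0) {
      abort("all maximum intraspecific distances are zero: ratio undefined",
            class = "coidelim_undefined_ratio_error")
    }
    mean(g$nn_dist) / denom
  } else {
    g <- g[g$max_intra > 0, , drop = FALSE]
    if (!nrow(g)) {
      abort("all maximum intraspecific distances are zero: ratio undefined",
            class = "coidelim_undefined_ratio_error")
    }
    mean(g$nn_dist / g$max_intra)
  }
}
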