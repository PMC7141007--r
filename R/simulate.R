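#' Simulation configuration for synthetic barcode libraries
#'
#' Defaults emulate a local COI reference library: 20 species from a Yule
#' tree deep enough for ~10% mean between-species divergence, 1-7
#' specimens per species (uniform around a mean of 4), within-species
#' coalescent diversity of 0.3% expected pairwise divergence, K80
#' substitution with transition/transversion ratio 4 over 652 aligned
#' sites, and a strict clock of 1.2% pairwise divergence per million
#' years.
#'
#' @param n_species Number of species.
#' @param mean_n_per_species Mean specimens per species; counts are drawn
#'   uniformly on `1..(2*mean - 1)`.
#' @param yule_rate Speciation rate of the Yule species tree (per My).
#' @param species_lag_my Speciation-completion lag (My): every terminal
#'   branch of the species tree is extended by this amount, so no two
#'   species are separated by less than `clock_rate * species_lag_my`
#'   divergence. This emulates the fact that co-occurring, morphologically
#'   diagnosable species are past the earliest (unresolvable) stage of
#'   divergence, as in protracted-speciation models; a pure Yule clade
#'   would otherwise always contain near-zero-age sister species that no
#'   sequence-based method can separate.
#' @param theta Expected within-species pairwise divergence (proportion).
#' @param kappa K80 transition/transversion rate ratio.
#' @param seq_length Alignment columns.
#' @param clock_rate Pairwise divergence per My.
#' @param introgression_events Number of donor-to-recipient haplotype
#'   transfers (at most `n_species / 2`).
#' @param cryptic_splits Number of species given a deep internal split
#'   without a label change.
#' @param seed RNG seed (mandatory: simulations must be reproducible).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 20, mean_n_per_species = 4, yule_rate = 0.4,
                       species_lag_my = 4, theta = 0.003, kappa = 4,
                       seq_length = 652, clock_rate = 0.012,
                       introgression_events = 0, cryptic_splits = 0, seed) {
  if (missing(seed)) abort("sim_config requires an explicit seed",
                           class = "coidelim_config_error")
  cfg <- list(n_species = n_species, mean_n_per_species = mean_n_per_species,
              yule_rate = yule_rate, species_lag_my = species_lag_my,
              theta = theta, kappa = kappa,
              seq_length = seq_length, clock_rate = clock_rate,
              introgression_events = introgression_events,
              cryptic_splits = cryptic_splits, seed = as.integer(seed))
  with(cfg, {
    if (n_species < 2 || mean_n_per_species < 1) {
      abort("need at least 2 species and 1 specimen per species",
            class = "coidelim_config_error")
    }
    if (yule_rate <= 0 || theta <= 0 || kappa <= 0 || clock_rate <= 0) {
      abort("rates must be positive", class = "coidelim_config_error")
    }
    if (species_lag_my < 0) {
      abort("species_lag_my must be nonnegative", class = "coidelim_config_error")
    }
    if (introgression_events > n_species / 2) {
      abort("introgression_events must not exceed n_species / 2",
            class = "coidelim_config_error")
    }
    if (cryptic_splits > n_species) {
      abort("cryptic_splits must not exceed n_species", class = "coidelim_config_error")
    }
  })
  structure(cfg, class = "sim_config")
}

#' Expected K2P divergence under the strict clock
#'
#' Two lineages whose most recent common ancestor sits `t` million years
#' back accumulate an expected pairwise divergence of `clock_rate * t`;
#' within a species the expectation is the coalescent diversity `theta`.
#' The K80 generator is rate-normalized, so `kappa` does not change the
#' expected total divergence.
#'
#' @param t_my Separation time (My).
#' @param clock_rate Pairwise divergence per My.
#' @param kappa Unused beyond rate normalization; accepted for clarity.
#' @return Expected pairwise divergence (proportion).
#' @export
expected_k2p <- function(t_my, clock_rate = 0.012, kappa = 4) {
  stopifnot(t_my >= 0, clock_rate > 0, kappa > 0)
  clock_rate * t_my
}

#' Simulate a barcode library with known truth
#'
#' Draws a Yule species tree, a Kingman coalescent genealogy within each
#' species scaled to `theta`, grafts them into one gene tree in
#' per-lineage divergence units (`clock_rate / 2` per My per branch), and
#' evolves sequences along it under K80. Optional scenarios: cryptic
#' splits give a species two deep subclades (labels unchanged);
#' introgression copies one haplotype from the phylogenetically nearest
#' donor species into a recipient specimen (label unchanged), producing
#' heterospecific haplotype sharing. Genera and families are assigned by
#' cutting the species tree at fixed divergence depths so taxonomic
#' summaries have structure to report.
#'
#' @param config A [sim_config()].
#' @return A list with `dataset` (a [barcode_dataset()]), and `truth`: the
#'   true `partition` ([otu_partition()] by species), `species_tree`
#'   (`phylo`, My), `gene_tree` (`phylo`, per-lineage divergence units)
#'   and `events` (tibble log of cryptic/introgression events).
#' @export
simulate_barcodes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  ns <- config$n_species
  half_clock <- config$clock_rate / 2  # per-lineage divergence per My
  sp_tree <- ape::rphylo(ns, birth = config$yule_rate, death = 0)
  sp_tree$tip.label <- sprintf("Sp%02d", seq_len(ns))
  if (config$species_lag_my > 0) {
    term <- sp_tree$edge[, 2] <= ns
    sp_tree$edge.length[term] <- sp_tree$edge.length[term] + config$species_lag_my
  }
  div_tree <- sp_tree
  div_tree$edge.length <- sp_tree$edge.length * half_clock
  n_per <- sample(seq_len(2 * config$mean_n_per_species - 1), ns, replace = TRUE)
  eligible <- which(n_per >= 2)
  cryptic_sp <- if (config$cryptic_splits > 0) {
    if (length(eligible) < config$cryptic_splits) {
      abort("not enough multi-specimen species for the requested cryptic splits",
            class = "coidelim_config_error")
    }
    sort(sample(eligible, config$cryptic_splits))
  } else integer(0)

  tip_edge <- match(seq_len(ns), div_tree$edge[, 2])
  newick <- ape::write.tree(div_tree, digits = 12)
  events <- list()
  specimen_ids <- character(0)
  specimen_sp <- character(0)
  for (k in seq_len(ns)) {
    sp <- div_tree$tip.label[k]
    ids <- sprintf("%s_%02d", sp, seq_len(n_per[k]))
    specimen_ids <- c(specimen_ids, ids)
    specimen_sp <- c(specimen_sp, rep(sp, n_per[k]))
    L_k <- div_tree$edge.length[tip_edge[k]]
    token <- if (k %in% cryptic_sp) {
      split_at <- sample(seq_len(n_per[k] - 1), 1)
      halves <- list(ids[seq_len(split_at)], ids[-seq_len(split_at)])
      hi <- 0.8 * L_k
      lo <- min(5 * config$theta, 0.5 * hi)
      h_c <- runif(1, lo, hi)
      parts <- vapply(halves, function(h) {
        sub <- coalescent_subtree(h, config$theta, max_height = 0.9 * h_c)
        paste0(sub$core, ":", format(h_c - sub$height, digits = 12))
      }, character(1))
      events[[length(events) + 1]] <- tibble(
        type = "cryptic_split", species = sp, donor = NA_character_,
        specimen_id = paste(halves[[2]], collapse = ","),
        depth = h_c
      )
      paste0("(", parts[1], ",", parts[2], "):", format(L_k - h_c, digits = 12))
    } else {
      sub <- coalescent_subtree(ids, config$theta, max_height = 0.9 * L_k)
      paste0(sub$core, ":", format(L_k - sub$height, digits = 12))
    }
    newick <- sub(sprintf("([(,])%s:[0-9.eE+-]+", sp),
                  paste0("\\1", token), newick)
  }
  gene_tree <- ape::read.tree(text = newick)
  phy <- phangorn::simSeq(gene_tree, l = config$seq_length,
                          Q = c(1, config$kappa, 1, 1, config$kappa, 1),
                          bf = rep(0.25, 4), type = "DNA")
  seq_mat <- toupper(as.character(phy))
  seqs <- setNames(apply(seq_mat, 1, paste, collapse = ""), rownames(seq_mat))

  # introgression: copy a haplotype from the nearest donor species
  if (config$introgression_events > 0) {
    coph <- ape::cophenetic.phylo(sp_tree)
    used <- character(0)
    done <- 0
    recipients <- sample(div_tree$tip.label[n_per >= 2])
    for (rec in recipients) {
      if (done >= config$introgression_events) break
      if (rec %in% used) next
      others <- setdiff(colnames(coph), c(rec, used))
      if (!length(others)) break
      donor <- others[which.min(coph[rec, others])]
      rec_ids <- specimen_ids[specimen_sp == rec]
      don_ids <- specimen_ids[specimen_sp == donor]
      moved <- sample(rec_ids, 1)
      source_id <- sample(don_ids, 1)
      seqs[[moved]] <- seqs[[source_id]]
      events[[length(events) + 1]] <- tibble(
        type = "introgression", species = rec, donor = donor,
        specimen_id = moved, depth = NA_real_
      )
      used <- c(used, rec, donor)
      done <- done + 1
    }
    if (done < config$introgression_events) {
      abort("could not place all requested introgression events",
            class = "coidelim_config_error")
    }
  }

  taxonomy <- assign_taxonomy(sp_tree, config$clock_rate)
  ds <- barcode_dataset(tibble(
    specimen_id = specimen_ids,
    species = specimen_sp,
    genus = taxonomy$genus[match(specimen_sp, taxonomy$species)],
    family = taxonomy$family[match(specimen_sp, taxonomy$species)],
    sequence = unname(seqs[specimen_ids])
  ))
  truth <- list(
    partition = otu_partition(specimen_ids, specimen_sp, method = "truth",
                              params = list(seed = config$seed)),
    species_tree = sp_tree,
    gene_tree = gene_tree,
    events = if (length(events)) bind_rows(events) else
      tibble(type = character(), species = character(), donor = character(),
             specimen_id = character(), depth = double())
  )
  list(dataset = ds, truth = truth)
}

# Kingman coalescent over `ids`, scaled so the expected pairwise path
# length (divergence) equals theta; optionally compressed under
# max_height for very recent species. Returns the rootless Newick core
# and the tree height (per-lineage units).
coalescent_subtree <- function(ids, theta, max_height = Inf) {
  if (length(ids) == 1) return(list(core = ids, height = 0))
  coal <- ape::rcoal(length(ids), tip.label = ids)
  coal$edge.length <- coal$edge.length * theta / 2
  h <- max(ape::node.depth.edgelength(coal))
  if (h > max_height) {
    coal$edge.length <- coal$edge.length * max_height / h
    h <- max_height
  }
  list(core = sub(";$", "", ape::write.tree(coal, digits = 12)), height = h)
}

# Genera and families from fixed-divergence cuts of the species tree.
assign_taxonomy <- function(sp_tree, clock_rate, genus_divergence = 0.10,
                            family_divergence = 0.15) {
  ns <- length(sp_tree$tip.label)
  if (ns == 1) {
    return(tibble(species = sp_tree$tip.label, genus = "Gen01", family = "Fam01"))
  }
  coph <- ape::cophenetic.phylo(sp_tree)  # pairwise time = 2 * TMRCA (My)
  hc <- hclust(as.dist(coph), method = "average")
  genus <- cutree(hc, h = 2 * genus_divergence / clock_rate)
  family <- cutree(hc, h = 2 * family_divergence / clock_rate)
  tibble(
    species = sp_tree$tip.label,
    genus = sprintf("Gen%02d", dense_labels(genus[sp_tree$tip.label])),
    family = sprintf("Fam%02d", dense_labels(family[sp_tree$tip.label]))
  )
}
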