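#' OTU partitions
#'
#' Every delimitation method returns its result as an `otu_partition`: a
#' tibble with columns `specimen_id` and `otu_id` (dense integers
#' `1..n_otus`, numbered by first appearance), carrying the method name and
#' its parameters as attributes.
#'
#' @param specimen_id Character vector of specimen ids (unique).
#' @param otu Cluster labels (any type); relabelled densely unless
#'   `relabel = FALSE`, in which case they must already be dense integers.
#' @param method Method name recorded on the partition.
#' @param params Named list of parameters recorded on the partition.
#' @param relabel Relabel `otu` densely by first appearance?
#' @return An `otu_partition` tibble.
#' @export
otu_partition <- function(specimen_id, otu, method = "manual", params = list(),
                          relabel = TRUE) {
  specimen_id <- as.character(specimen_id)
  if (anyDuplicated(specimen_id)) {
    abort("duplicate specimen_id in partition", class = "coidelim_validation_error")
  }
  if (length(otu) != length(specimen_id)) {
    abort("otu and specimen_id lengths differ", class = "coidelim_validation_error")
  }
  otu_id <- if (relabel) dense_labels(otu) else as.integer(otu)
  if (length(otu_id) && !setequal(unique(otu_id), seq_len(max(otu_id)))) {
    abort("otu ids must be dense 1..n_otus", class = "coidelim_validation_error")
  }
  out <- tibble(specimen_id = specimen_id, otu_id = otu_id)
  attr(out, "method") <- method
  attr(out, "params") <- params
  class(out) <- c("otu_partition", class(tibble()))
  out
}

#' @rdname otu_partition
#' @param x An `otu_partition`.
#' @export
n_otus <- function(x) {
  stopifnot(inherits(x, "otu_partition"))
  if (nrow(x)) max(x$otu_id) else 0L
}

#' @export
print.otu_partition <- function(x, ...) {
  cat(sprintf("<otu_partition: %d specimens, %d OTUs, method = %s>\n",
              nrow(x), n_otus(x), attr(x, "method") %||% "?"))
  NextMethod()
}

# Align partition b onto the specimen order of a; errors if the sets differ.
align_partitions <- function(a, b) {
  if (!setequal(a$specimen_id, b$specimen_id)) {
    abort("partitions cover different specimen sets", class = "coidelim_validation_error")
  }
  b$otu_id[match(a$specimen_id, b$specimen_id)]
}

#' Compare two partitions: adjusted Rand index and pair agreement
#'
#' The adjusted Rand index (ARI) is computed from the contingency table of
#' the two partitions (Hubert & Arabie correction); `n_agree_pairs` counts
#' specimen pairs on which the two partitions agree (co-clustered in both
#' or separated in both). ARI is 1 exactly when the partitions are
#' identical up to labelling.
#'
#' @param a,b `otu_partition` objects over the same specimen set.
#' @return A one-row tibble with columns `ari` and `n_agree_pairs`.
#' @export
partition_compare <- function(a, b) {
  stopifnot(inherits(a, "otu_partition"), inherits(b, "otu_partition"))
  la <- a$otu_id
  lb <- align_partitions(a, b)
  n <- length(la)
  tab <- table(la, lb)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- if (total > 0) sum_a * sum_b / total else 0
  max_index <- (sum_a + sum_b) / 2
  ari <- if (max_index == expected) 1 else (sum_ij - expected) / (max_index - expected)
  # pairs co-clustered in both, plus pairs separated in both
  agree <- sum_ij + (total - sum_a - sum_b + sum_ij)
  tibble(ari = ari, n_agree_pairs = as.integer(round(agree)))
}
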