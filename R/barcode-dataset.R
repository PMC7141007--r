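#' Barcode datasets
#'
#' A barcode dataset is a tibble with one row per specimen and at least the
#' columns `specimen_id`, `species`, `genus`, `family` and `sequence`
#' (uppercase IUPAC DNA, aligned: all sequences the same length, gaps as
#' `-`). Any further metadata columns (locality, accession, ...) are carried
#' along untouched. The alignment length is stored in the
#' `"alignment_length"` attribute.
#'
#' @param x A data frame with the columns listed above.
#' @return A `barcode_dataset` tibble.
#' @export
barcode_dataset <- function(x) {
  x <- as_tibble(x)
  required <- c("specimen_id", "species", "genus", "family", "sequence")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(paste0("missing required columns: ", paste(missing_cols, collapse = ", ")),
          class = "coidelim_validation_error")
  }
  x$specimen_id <- as.character(x$specimen_id)
  x$sequence <- toupper(x$sequence)
  validate_barcode_dataset(x)
  attr(x, "alignment_length") <- if (nrow(x)) nchar(x$sequence[[1]]) else 0L
  class(x) <- c("barcode_dataset", class(tibble()))
  x
}

validate_barcode_dataset <- function(x) {
  if (!nrow(x)) return(invisible(x))
  if (anyDuplicated(x$specimen_id)) {
    abort("duplicate specimen_id values", class = "coidelim_validation_error")
  }
  if (any(!nzchar(x$specimen_id)) || anyNA(x$specimen_id)) {
    abort("specimen_id must be nonempty", class = "coidelim_validation_error")
  }
  len <- nchar(x$sequence)
  if (any(len == 0L)) {
    abort("empty sequence", class = "coidelim_validation_error")
  }
  if (length(unique(len)) > 1L) {
    abort(
      paste0("sequences are not aligned: lengths ", paste(unique(len), collapse = ", ")),
      class = "coidelim_alignment_error"
    )
  }
  bad <- grepl("[^ACGTRYSWKMBDHVN-]", x$sequence)
  if (any(bad)) {
    abort(
      paste0("non-IUPAC characters in sequence of: ",
             paste(head(x$specimen_id[bad], 3), collapse = ", ")),
      class = "coidelim_validation_error"
    )
  }
  invisible(x)
}

#' Alignment length of a barcode dataset
#' @param ds A `barcode_dataset`.
#' @return Integer number of alignment columns.
#' @export
alignment_length <- function(ds) attr(ds, "alignment_length")

#' Read a barcode dataset from FASTA plus a specimen-metadata TSV
#'
#' FASTA headers are specimen ids and must match 1:1 the `specimen_id`
#' column of the metadata table (UTF-8, tab-separated, header row with at
#' least `specimen_id`, `species`, `genus`, `family`; extra columns are
#' preserved). Record order follows the FASTA file; sequences are
#' uppercased on read.
#'
#' @param fasta_path Path to an aligned FASTA file.
#' @param metadata_path Path to the metadata TSV.
#' @return A [barcode_dataset()].
#' @export
read_barcode_dataset <- function(fasta_path, metadata_path) {
  seqs <- ape::read.FASTA(fasta_path)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    abort("FASTA records must carry specimen ids", class = "coidelim_validation_error")
  }
  if (anyDuplicated(ids)) {
    abort("duplicate ids in FASTA", class = "coidelim_validation_error")
  }
  seq_chr <- toupper(vapply(as.character(seqs), paste, character(1), collapse = ""))
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE, progress = FALSE)
  required <- c("specimen_id", "species", "genus", "family")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    abort(paste0("metadata missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "coidelim_validation_error")
  }
  meta$specimen_id <- as.character(meta$specimen_id)
  only_fasta <- setdiff(ids, meta$specimen_id)
  only_meta <- setdiff(meta$specimen_id, ids)
  if (length(only_fasta) || length(only_meta)) {
    abort(
      paste0(
        "FASTA and metadata ids do not match 1:1",
        if (length(only_fasta)) paste0("; FASTA only: ", paste(head(only_fasta, 3), collapse = ", ")),
        if (length(only_meta)) paste0("; metadata only: ", paste(head(only_meta, 3), collapse = ", "))
      ),
      class = "coidelim_join_error"
    )
  }
  df <- tibble(specimen_id = ids, sequence = unname(seq_chr))
  df <- left_join(df, meta, by = "specimen_id")
  barcode_dataset(df[, c("specimen_id", setdiff(names(meta), "specimen_id"), "sequence")])
}

#' Write a barcode dataset as FASTA plus metadata TSV
#'
#' @param ds A `barcode_dataset`.
#' @param fasta_path,metadata_path Output paths.
#' @return `ds`, invisibly.
#' @export
write_barcode_dataset <- function(ds, fasta_path, metadata_path) {
  bin <- ape::as.DNAbin(strsplit(ds$sequence, ""))
  names(bin) <- ds$specimen_id
  ape::write.FASTA(bin, fasta_path)
  meta <- ds[, setdiff(names(ds), "sequence")]
  readr::write_tsv(as_tibble(meta), metadata_path, progress = FALSE)
  invisible(ds)
}

# Integer-coded alignment matrix: rows = specimens, columns = sites;
# A/C/G/T -> 1..4, gaps and ambiguity codes -> NA (pairwise deletion).
seq_code_matrix <- function(ds) {
  codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  m <- matrix(NA_integer_, nrow(ds), alignment_length(ds),
              dimnames = list(ds$specimen_id, NULL))
  for (i in seq_len(nrow(ds))) {
    v <- codes[strsplit(ds$sequence[[i]], "")[[1]]]
    m[i, ] <- unname(v)
  }
  m
}

#' Collapse identical haplotypes to one representative
#'
#' Two sequences are considered the same haplotype when they agree at every
#' alignment column where both carry an unambiguous base (A/C/G/T) and
#' neither is gapped — the same columns pairwise deletion retains, so
#' distance-zero pairs and duplicate pairs coincide. The representative is
#' the first record in dataset order. Tree-based delimiters require this
#' pruning because identical sequences produce zero-length branches.
#'
#' @param ds A `barcode_dataset`.
#' @return A list with `dataset` (the pruned `barcode_dataset`) and
#'   `members`, a tibble with columns `haplotype_id` (the representative's
#'   specimen id), `specimen_id` and `species` reconstituting the full
#'   membership.
#' @export
deduplicate_haplotypes <- function(ds) {
  validate_barcode_dataset(ds)
  n <- nrow(ds)
  if (n == 0L) {
    return(list(dataset = ds,
                members = tibble(haplotype_id = character(), specimen_id = character(),
                                 species = character())))
  }
  m <- seq_code_matrix(ds)
  rep_idx <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    for (r in rep_idx) {
      if (!any(m[i, ] != m[r, ], na.rm = TRUE)) { hit <- r; break }
    }
    if (hit == 0L) {
      rep_idx <- c(rep_idx, i)
      assign[i] <- i
    } else {
      assign[i] <- hit
    }
  }
  members <- tibble(
    haplotype_id = ds$specimen_id[assign],
    specimen_id = ds$specimen_id,
    species = ds$species
  )
  pruned <- ds[rep_idx, , drop = FALSE]
  attr(pruned, "alignment_length") <- alignment_length(ds)
  class(pruned) <- class(ds)
  list(dataset = pruned, members = members)
}

#' Write / read an OTU partition as TSV
#'
#' The file has columns `specimen_id`, `species`, `otu_id`, `method`, rows
#' ordered by `specimen_id`; a write/read cycle is lossless.
#'
#' @param partition An [otu_partition()].
#' @param path Output (input) path.
#' @param dataset Optional `barcode_dataset` supplying species labels; if
#'   absent a `species` column on the partition is used, else `NA`.
#' @return The partition, invisibly (or the re-read partition).
#' @export
write_partition_tsv <- function(partition, path, dataset = NULL) {
  stopifnot(inherits(partition, "otu_partition"))
  species <- if (!is.null(dataset)) {
    dataset$species[match(partition$specimen_id, dataset$specimen_id)]
  } else if ("species" %in% names(partition)) {
    partition$species
  } else {
    rep(NA_character_, nrow(partition))
  }
  out <- tibble(
    specimen_id = partition$specimen_id,
    species = species,
    otu_id = partition$otu_id,
    method = attr(partition, "method") %||% NA_character_
  )
  out <- arrange(out, .data$specimen_id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(partition)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          specimen_id = readr::col_character(),
                          species = readr::col_character(),
                          otu_id = readr::col_integer(),
                          method = readr::col_character()
                        ))
  p <- otu_partition(df$specimen_id, df$otu_id,
                     method = if (nrow(df)) df$method[[1]] else NA_character_)
  p$species <- df$species
  p
}
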