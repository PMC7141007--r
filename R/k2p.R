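#' Kimura 2-parameter distance between two aligned sequences
#'
#' Alignment columns where either sequence is gapped or carries an
#' ambiguity code are dropped (pairwise deletion). Over the retained
#' columns, with transition proportion `P` (A<->G, C<->T) and transversion
#' proportion `Q`, the distance is
#' `-1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`.
#'
#' @param seq_a,seq_b Uppercase IUPAC DNA strings of equal length.
#' @param min_overlap Minimum number of retained columns (default 400, a
#'   conservative floor for ~652 bp COI barcodes trimmed at the ends).
#' @return A list with `distance` (proportion) and `sites` (retained
#'   column count).
#' @section Errors: Fewer than `min_overlap` comparable sites raises an
#'   insufficient-overlap error; a non-positive logarithm argument
#'   (saturated divergence) raises a saturation error rather than clamping,
#'   so summaries are never silently corrupted.
#' @export
k2p_distance <- function(seq_a, seq_b, min_overlap = 400) {
  if (nchar(seq_a) != nchar(seq_b)) {
    abort("sequences differ in length", class = "coidelim_alignment_error")
  }
  codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  a <- unname(codes[strsplit(toupper(seq_a), "")[[1]]])
  b <- unname(codes[strsplit(toupper(seq_b), "")[[1]]])
  k2p_pair(a, b, min_overlap)
}

# Core K2P on integer-coded site vectors (NA = deleted site).
k2p_pair <- function(a, b, min_overlap) {
  keep <- !is.na(a) & !is.na(b)
  n <- sum(keep)
  if (n < min_overlap) {
    abort(
      sprintf("only %d comparable sites (< min_overlap = %d)", n, min_overlap),
      class = "coidelim_overlap_error"
    )
  }
  a <- a[keep]
  b <- b[keep]
  diff <- a != b
  # transitions: A<->G (1,3), C<->T (2,4) -- codes differ by 2
  ts <- sum(diff & (abs(a - b) == 2L))
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    abort(
      sprintf("saturated pair (P = %.4f, Q = %.4f): K2P distance undefined", P, Q),
      class = "coidelim_saturation_error"
    )
  }
  list(distance = -0.5 * log(w1 * sqrt(w2)), sites = as.integer(n))
}

#' Pairwise K2P distance matrix for a barcode dataset
#'
#' @param ds A `barcode_dataset`.
#' @param min_overlap Minimum comparable sites per pair (see
#'   [k2p_distance()]).
#' @return A `k2p_dist` object: a list with `ids`, the symmetric matrix `d`
#'   of distances (proportions) and the matrix `sites` of retained site
#'   counts. Use [tidy()] for a long tibble of pairs.
#' @export
k2p_distance_matrix <- function(ds, min_overlap = 400) {
  validate_barcode_dataset(ds)
  m <- seq_code_matrix(ds)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  s <- matrix(NA_integer_, n, n, dimnames = dimnames(d))
  diag(s) <- as.integer(rowSums(!is.na(m)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        res <- tryCatch(k2p_pair(m[i, ], m[j, ], min_overlap), error = function(e) e)
        if (inherits(res, "error")) {
          abort(
            sprintf("pair (%s, %s): %s", rownames(m)[i], rownames(m)[j],
                    conditionMessage(res)),
            class = class(res)[[1]]
          )
        }
        d[i, j] <- d[j, i] <- res$distance
        s[i, j] <- s[j, i] <- res$sites
      }
    }
  }
  structure(list(ids = rownames(m), d = d, sites = s), class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat(sprintf("<k2p_dist: %d specimens, mean pairwise distance %.4f>\n",
              length(x$ids),
              if (length(x$ids) > 1) mean(x$d[upper.tri(x$d)]) else NA_real_))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.k2p_dist <- function(x, ...) {
  n <- length(x$ids)
  if (n < 2) {
    return(tibble(id_a = character(), id_b = character(),
                  distance = double(), sites = integer()))
  }
  ut <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(
    id_a = x$ids[ut[, 1]],
    id_b = x$ids[ut[, 2]],
    distance = x$d[ut],
    sites = x$sites[ut]
  )
}

# Subset a k2p_dist to a set of ids (dataset order preserved).
subset_k2p <- function(dm, ids) {
  idx <- match(ids, dm$ids)
  structure(
    list(ids = dm$ids[idx], d = dm$d[idx, idx, drop = FALSE],
         sites = dm$sites[idx, idx, drop = FALSE]),
    class = "k2p_dist"
  )
}

#' Export a distance matrix as TSV
#'
#' Writes either a square tab-separated matrix with an `id` column, or a
#' PHYLIP-style lower-triangle file.
#'
#' @param dm A `k2p_dist`.
#' @param path Output path.
#' @param format `"square"` or `"phylip"`.
#' @return `dm`, invisibly.
#' @export
write_distance_tsv <- function(dm, path, format = c("square", "phylip")) {
  format <- match.arg(format)
  if (format == "square") {
    df <- as_tibble(as.data.frame(dm$d))
    names(df) <- dm$ids
    df <- dplyr::bind_cols(tibble(id = dm$ids), df)
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d", length(dm$ids)), con)
    for (i in seq_along(dm$ids)) {
      row <- if (i > 1) paste(sprintf("%.8f", dm$d[i, seq_len(i - 1)]), collapse = "\t") else ""
      writeLines(paste0(dm$ids[i], if (nzchar(row)) "\t", row), con)
    }
  }
  invisible(dm)
}
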