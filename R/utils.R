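# Internal helpers shared across modules.

# Union-find over n items; `pairs` is a 2-column integer matrix of linked
# indices. Returns dense component labels (1..k) in order of first appearance.
uf_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1L])
      b <- find(pairs[r, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Dense relabelling of arbitrary cluster codes, 1..k by first appearance.
dense_labels <- function(x) match(x, unique(x))

# Canonical string signature of a partition given as dense labels in a fixed
# item order; equal signatures <=> equal partitions.
partition_signature <- function(labels) paste(dense_labels(labels), collapse = ".")

# Format a proportion as a percent string with 2 decimals; NA -> em dash,
# matching conventional barcode-gap tables where singletons have no
# intraspecific distance.
fmt_pct <- function(x) ifelse(is.na(x), "—", sprintf("%.2f", 100 * x))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
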