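# Edge subsets are plain integer bitmasks: edge i of the host's canonical
# ordering corresponds to bit i-1.  All helpers are vectorized over subsets.

mask_full <- function(m) {
  if (m >= 31L) stop("bitmask encoding supports at most 30 edges")
  as.integer(bitwShiftL(1L, m) - 1L)
}

#' Edge-subset bitmask helpers
#'
#' Edge subsets of a host graph are encoded as integer bitmasks: bit
#' \eqn{i-1} set means edge \eqn{i} (in the host's canonical order) is
#' present.  `subset_size` is the popcount; `edges_to_subset` converts edge
#' labels or indices to a mask; `subset_edges` lists the member edge labels;
#' `subset_to_bitstring` prints the mask as a 0/1 string whose i-th
#' character (left to right) is edge i, readable alongside the canonical
#' edge list; `bitstring_to_subset` inverts that.
#'
#' @param bits integer vector of bitmasks
#' @param m number of edges (defines the bitstring width)
#' @name edge_subsets
#' @examples
#' h <- fixture_host("p3")
#' edges_to_subset(h, "1--2")             # 1
#' subset_to_bitstring(3L, h$m)           # "11"
#' subset_size(3L)                        # 2
NULL

#' @rdname edge_subsets
#' @export
subset_size <- function(bits) {
  n <- integer(length(bits))
  b <- as.integer(bits)
  while (any(b > 0L)) {
    n <- n + bitwAnd(b, 1L)
    b <- bitwShiftR(b, 1L)
  }
  n
}

#' @rdname edge_subsets
#' @param host a `host_graph`
#' @param edges edge labels (`"u--v"`) or 1-based edge indices
#' @export
edges_to_subset <- function(host, edges) {
  if (length(edges) == 0L) return(0L)
  if (is.character(edges)) {
    idx <- match(edges, host$edge_labels)
    if (anyNA(idx)) stop("unknown edge label: '", edges[which(is.na(idx))[1]], "'")
  } else {
    idx <- as.integer(edges)
    if (any(idx < 1L | idx > host$m)) stop("edge index out of range")
  }
  Reduce(bitwOr, bitwShiftL(1L, unique(idx) - 1L), 0L)
}

#' @rdname edge_subsets
#' @export
subset_edges <- function(host, bits) {
  host$edge_labels[bitwAnd(bitwShiftR(as.integer(bits), seq_len(host$m) - 1L), 1L) == 1L]
}

#' @rdname edge_subsets
#' @export
subset_to_bitstring <- function(bits, m) {
  vapply(as.integer(bits), function(b) {
    paste(bitwAnd(bitwShiftR(b, seq_len(m) - 1L), 1L), collapse = "")
  }, "")
}

#' @rdname edge_subsets
#' @param s character vector of 0/1 bitstrings
#' @export
bitstring_to_subset <- function(s) {
  vapply(s, function(x) {
    d <- as.integer(strsplit(x, "", fixed = TRUE)[[1]])
    if (anyNA(d) || any(d > 1L)) stop("invalid bitstring: '", x, "'")
    sum(bitwShiftL(d, seq_along(d) - 1L))
  }, integer(1), USE.NAMES = FALSE)
}

# 0/1 incidence matrix of states x edges, used by vectorized spectral code.
bits_matrix <- function(states, m) {
  vapply(seq_len(m) - 1L,
         function(j) bitwAnd(bitwShiftR(as.integer(states), j), 1L),
         integer(length(states)))
}

is_submask <- function(a, b) bitwAnd(a, b) == a

check_subset_range <- function(bits, host) {
  bits <- as.integer(bits)
  if (anyNA(bits) || any(bits < 0L) || any(bits > host$full_mask)) {
    stop("edge subset out of range for this host (0 <= bits < 2^m)")
  }
  bits
}
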