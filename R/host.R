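# Host graphs: the fixed vertex/edge universe whose edge subsets form the
# state space of every edit chain.  Edge i <-> bit i-1 of an integer bitmask,
# so the canonical edge ordering must be stable across runs.

label_order <- function(labels) {
  # All-numeric labels compare by value (equivalently, as strings after
  # stripping leading zeros); anything else compares lexicographically in the
  # C locale so the ordering does not depend on the session locale.
  if (all(grepl("^[0-9]+$", labels))) {
    order(as.numeric(labels), labels, method = "radix")
  } else {
    order(labels, method = "radix")
  }
}

as_edge_pairs <- function(edges) {
  if (is.list(edges) && !is.data.frame(edges)) {
    if (!all(lengths(edges) == 2L)) stop("invalid edge: each edge needs exactly two endpoints")
    edges <- do.call(rbind, lapply(edges, function(e) as.character(e)))
  } else if (is.data.frame(edges)) {
    if (ncol(edges) < 2L) stop("invalid edge list: need two endpoint columns")
    edges <- cbind(as.character(edges[[1]]), as.character(edges[[2]]))
  } else if (is.matrix(edges)) {
    if (ncol(edges) < 2L) stop("invalid edge list: need two endpoint columns")
    edges <- cbind(as.character(edges[, 1]), as.character(edges[, 2]))
  } else {
    stop("invalid edge list: expected a list of pairs or a two-column table")
  }
  edges
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a host graph from an edge list
#'
#' Constructs the fixed host graph \eqn{H = (V, E)} whose subgraphs (edge
#' subsets) form the state space of the edit Markov chains.  The vertex and
#' edge orderings are canonical and stable: vertices are sorted by label
#' (numerically when all labels are numeric, lexicographically otherwise) and
#' edge \eqn{i} is sorted by (min endpoint index, max endpoint index).  Edge
#' \eqn{i} corresponds to bit \eqn{i-1} of the integer bitmasks used to
#' encode edge subsets.
#'
#' @param edges a list of length-2 vectors, or a two-column matrix or data
#'   frame, giving the unordered endpoint pairs.  Self-loops and duplicate
#'   edges are rejected.
#' @param p optional numeric vector of per-edge probabilities, one per row of
#'   `edges` (reordered along with the edges), each strictly in (0, 1).
#' @return an object of class `host_graph` with fields `vertices`, `edges`
#'   (two-column matrix of vertex indices), `edge_labels`, `n`, `m`,
#'   `degree`, `nbhd` (per-vertex incident-edge bitmask), `min_degree`,
#'   `full_mask`, and optionally `p`.
#' @examples
#' h <- build_host(list(c(1, 2), c(2, 3)))
#' h$m            # 2
#' h$edge_labels  # "1--2" "2--3"
#' @export
build_host <- function(edges, p = NULL) {
  ep <- as_edge_pairs(edges)
  loops <- ep[, 1] == ep[, 2]
  if (any(loops)) {
    stop("invalid edge: self-loop at vertex '", ep[which(loops)[1], 1], "'")
  }
  vertices <- unique(c(ep[, 1], ep[, 2]))
  vertices <- vertices[label_order(vertices)]
  i1 <- match(ep[, 1], vertices)
  i2 <- match(ep[, 2], vertices)
  lo <- pmin(i1, i2)
  hi <- pmax(i1, i2)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate edge: {", gsub(" ", ", ", d), "}")
  }
  ord <- order(lo, hi)
  lo <- lo[ord]; hi <- hi[ord]
  m <- length(lo)
  if (m < 1L) stop("invalid edge list: no edges")
  if (m > 30L) stop("host too large: bitmask encoding supports at most 30 edges")
  if (!is.null(p)) {
    if (length(p) != m) stop("edge probabilities: need one value per edge")
    p <- as.numeric(p)[ord]
    check_edge_probs(p, m)
  }
  n <- length(vertices)
  nbhd <- integer(n)
  degree <- integer(n)
  for (i in seq_len(m)) {
    b <- bitwShiftL(1L, i - 1L)
    nbhd[lo[i]] <- bitwOr(nbhd[lo[i]], b)
    nbhd[hi[i]] <- bitwOr(nbhd[hi[i]], b)
    degree[lo[i]] <- degree[lo[i]] + 1L
    degree[hi[i]] <- degree[hi[i]] + 1L
  }
  edge_labels <- paste0(vertices[lo], "--", vertices[hi])
  structure(list(
    vertices = vertices,
    edges = cbind(lo = lo, hi = hi),
    edge_labels = edge_labels,
    n = n, m = m,
    degree = degree,
    nbhd = nbhd,
    min_degree = min(degree),
    full_mask = mask_full(m),
    p = p,
    bipartition = NULL,
    key = paste(c(n, m, edge_labels), collapse = ";")
  ), class = "host_graph")
}

check_edge_probs <- function(p, m) {
  if (length(p) != m || anyNA(p) || any(p <= 0) || any(p >= 1)) {
    stop("edge probabilities must lie strictly in (0, 1), one per edge")
  }
  invisible(p)
}

#' @export
print.host_graph <- function(x, ...) {
  cat("host graph: ", x$n, " vertices, ", x$m, " edges",
      if (!is.null(x$bipartition)) " (bipartite)", "\n", sep = "")
  cat("edges: ", paste(x$edge_labels, collapse = ", "), "\n", sep = "")
  if (!is.null(x$p)) cat("edge probabilities: ", paste(signif(x$p, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Named host-graph fixtures
#'
#' Small hosts used throughout the examples and tests: `"p3"` (path on three
#' vertices, two edges), `"c5"` (cycle on five vertices), `"k4"` (complete
#' graph on four vertices), `"kn:n"` (complete graph \eqn{K_n}) and
#' `"knn:n,N"` (complete bipartite graph with parts of size `n` and `N`; the
#' bipartition is recorded on the host and used by the random intersection
#' model).
#'
#' @param name fixture name, e.g. `"p3"`, `"c5"`, `"k4"`, `"kn:5"`,
#'   `"knn:2,3"`.
#' @return a `host_graph`
#' @examples
#' fixture_host("c5")$m   # 5
#' fixture_host("knn:2,3")$m  # 6
#' @export
fixture_host <- function(name) {
  name <- tolower(trimws(name))
  if (name == "p3") return(build_host(list(c(1, 2), c(2, 3))))
  if (name == "c5") {
    return(build_host(lapply(1:5, function(i) c(i, i %% 5 + 1))))
  }
  if (name == "k4") return(fixture_host("kn:4"))
  if (grepl("^kn:[0-9]+$", name)) {
    n <- as.integer(sub("^kn:", "", name))
    if (n < 2L) stop("unknown fixture: kn needs n >= 2")
    pairs <- utils::combn(n, 2)
    return(build_host(lapply(seq_len(ncol(pairs)), function(j) pairs[, j])))
  }
  if (grepl("^knn:[0-9]+,[0-9]+$", name)) {
    nm <- as.integer(strsplit(sub("^knn:", "", name), ",")[[1]])
    n <- nm[1]; N <- nm[2]
    if (n < 1L || N < 1L) stop("unknown fixture: knn needs positive part sizes")
    omega <- paste0("a", seq_len(n))
    omega_prime <- paste0("b", seq_len(N))
    pairs <- expand.grid(omega, omega_prime, stringsAsFactors = FALSE)
    h <- build_host(lapply(seq_len(nrow(pairs)), function(i) c(pairs[i, 1], pairs[i, 2])))
    h$bipartition <- list(omega = omega, omega_prime = omega_prime)
    return(h)
  }
  stop("unknown fixture: '", name, "'")
}

#' Read or write a host graph as edge-list TSV
#'
#' The TSV format has one edge per row with columns `u`, `v` and an optional
#' third column of edge probabilities in (0, 1).  Because the edge ordering
#' is canonical (determined by the labels alone), `read_host(write_host(h))`
#' reproduces `h` including its edge order.
#'
#' @param path file path
#' @return `read_host`: a `host_graph` (with `$p` populated when the third
#'   column is present); `write_host`: the path, invisibly.
#' @export
read_host <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("malformed edge list: empty file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    stop("malformed row at line ", which(nf < 2L)[1], ": need at least two columns")
  }
  u <- vapply(parts, `[[`, "", 1L)
  v <- vapply(parts, `[[`, "", 2L)
  if (any(trimws(u) == trimws(v))) {
    stop("malformed row at line ", which(trimws(u) == trimws(v))[1], ": self-loop")
  }
  p <- NULL
  if (any(nf >= 3L)) {
    if (!all(nf >= 3L)) {
      stop("malformed row at line ", which(nf < 3L)[1],
           ": probability column present on some rows but not all")
    }
    p <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    bad <- is.na(p) | p <= 0 | p >= 1
    if (any(bad)) {
      stop("malformed row at line ", which(bad)[1],
           ": edge probability must lie strictly in (0, 1)")
    }
  }
  build_host(cbind(trimws(u), trimws(v)), p = p)
}

#' @rdname read_host
#' @param host a `host_graph`
#' @export
write_host <- function(host, path) {
  stopifnot(inherits(host, "host_graph"))
  u <- host$vertices[host$edges[, "lo"]]
  v <- host$vertices[host$edges[, "hi"]]
  rows <- if (is.null(host$p)) paste(u, v, sep = "\t") else {
    paste(u, v, format(host$p, digits = 17, trim = TRUE), sep = "\t")
  }
  writeLines(rows, path)
  invisible(path)
}
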