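# Shared fixtures built in code: hosts, full simple-edit generator sets, and
# small random (host, p) instances for property-style checks.

all_simple_edits <- function(host) {
  unlist(lapply(seq_len(host$m), function(i) {
    list(simple_edit(host, i, "+"), simple_edit(host, i, "-"))
  }), recursive = FALSE)
}

# Path host with m edges (vertices 1..m+1); the simple-process spectrum and
# eigenvectors depend only on m, so paths stand in for arbitrary hosts.
path_host <- function(m) {
  build_host(lapply(seq_len(m), function(i) c(i, i + 1)))
}

# Random connected-ish host with m edges on m+1 labeled vertices.
random_host <- function(m, seed) {
  set.seed(seed)
  nv <- m + 1L
  pairs <- utils::combn(nv, 2)
  pick <- sample(ncol(pairs), m)
  build_host(lapply(pick, function(j) pairs[, j]))
}

random_p <- function(m, seed) {
  set.seed(seed)
  stats::runif(m, 0.1, 0.9)
}

worst_tv_at <- function(P, t, pi_vec, rows = seq_len(nrow(P))) {
  Pt <- diag(nrow(P))
  for (i in seq_len(t)) Pt <- Pt %*% P
  max(apply(Pt[rows, , drop = FALSE], 1, tv_distance, pi_vec))
}
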