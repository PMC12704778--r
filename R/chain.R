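# Chain engine: weighted edit families, exact transition matrices,
# stationary distributions, trajectory simulation, total-variation distance
# and mixing-time bounds.

#' Construct a weighted edit family
#'
#' An edit family is a finite set of graph edits together with a probability
#' weight vector; at each step of the compound edit process an edit is drawn
#' from the family and applied.  Duplicate action maps are merged (their
#' weights summed) with a warning.
#'
#' @param edits list of `graph_edit`s over one host
#' @param weights numeric vector of probabilities, summing to 1 (tolerance
#'   1e-12)
#' @return object of class `edit_family` with fields `host`, `edits`,
#'   `weights`, `supports` (per-edit support bitmasks)
#' @export
edit_family <- function(edits, weights) {
  stopifnot(length(edits) >= 1L, all(vapply(edits, inherits, TRUE, "graph_edit")))
  host <- edits[[1]]$host
  if (!all(vapply(edits, function(x) identical(x$host$key, host$key), TRUE))) {
    stop("host mismatch: edits act on different hosts")
  }
  weights <- as.numeric(weights)
  if (length(weights) != length(edits)) stop("need one weight per edit")
  if (anyNA(weights) || any(weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1 (tolerance 1e-12)")
  keys <- vapply(edits, edit_key, "")
  if (anyDuplicated(keys)) {
    warning("duplicate edits in family: weights of identical action maps merged")
    agg <- rowsum(weights, keys)
    keep <- !duplicated(keys)
    edits <- edits[keep]
    weights <- as.numeric(agg[match(keys[keep], rownames(agg)), 1])
  }
  structure(list(host = host, edits = edits, weights = weights,
                 supports = vapply(edits, edit_support, integer(1))),
            class = "edit_family")
}

#' @export
print.edit_family <- function(x, ...) {
  cat("edit family: ", length(x$edits), " edits over ", x$host$m,
      "-edge host\n", sep = "")
  invisible(x)
}

#' The simple edit process as an edit family
#'
#' The single-edge process with edge probabilities `p` — pick an edge
#' uniformly, make it present with probability `p_e`, absent otherwise — is
#' the edit family containing, for each edge `e`, the edit `e+` with weight
#' `p_e / m` and `e-` with weight `(1 - p_e) / m`.  Both descriptions give
#' the same transition matrix.  Edit order is fixed as
#' `e1+, e1-, e2+, e2-, ...` (canonical edge order), which also fixes the
#' inverse-CDF sampling used by [simulate_chain()].
#'
#' @param host a `host_graph`
#' @param p numeric vector of edge probabilities in (0, 1); defaults to
#'   `host$p`
#' @return an `edit_family`
#' @export
simple_family <- function(host, p = NULL) {
  stopifnot(inherits(host, "host_graph"))
  p <- p %||% host$p
  if (is.null(p)) stop("no edge probabilities: supply p or attach host$p")
  if (length(p) == 1L) p <- rep(p, host$m)
  check_edge_probs(p, host$m)
  m <- host$m
  edits <- vector("list", 2L * m)
  w <- numeric(2L * m)
  for (i in seq_len(m)) {
    edits[[2L * i - 1L]] <- simple_edit(host, i, "+")
    edits[[2L * i]] <- simple_edit(host, i, "-")
    w[2L * i - 1L] <- p[i] / m
    w[2L * i] <- (1 - p[i]) / m
  }
  fam <- edit_family(edits, w)
  fam$p <- p
  fam$simple <- TRUE
  fam
}

#' Exact transition matrix of an edit-family chain
#'
#' Builds the row-stochastic matrix `P` over all `2^m` edge-subset states:
#' `P[E, F]` is the total weight of family edits mapping `E` to `F`.  State
#' row `i` corresponds to bitmask `i - 1`.  Dense construction is guarded to
#' hosts with at most 14 edges; simulate larger chains with
#' [simulate_chain()] instead.
#'
#' @param family an `edit_family`
#' @return object of class `transition_data`: list with `P`, `states`
#'   (bitmasks, = `0:(2^m - 1)`), `host`, `family`
#' @export
transition_matrix <- function(family) {
  stopifnot(inherits(family, "edit_family"))
  m <- family$host$m
  if (m > 14L) {
    stop("host too large for a dense transition matrix (m > 14); ",
         "use simulate_chain() instead")
  }
  ns <- 2L^m
  states <- 0:(ns - 1L)
  P <- matrix(0, ns, ns)
  for (i in seq_along(family$edits)) {
    to <- apply_edit(family$edits[[i]], states)
    idx <- cbind(seq_len(ns), to + 1L)
    P[idx] <- P[idx] + family$weights[i]
  }
  structure(list(P = P, states = states, host = family$host, family = family),
            class = "transition_data")
}

#' @export
print.transition_data <- function(x, ...) {
  cat("transition matrix: ", nrow(x$P), " x ", ncol(x$P), " states\n", sep = "")
  invisible(x)
}

#' Product-form stationary distribution of the simple edit process
#'
#' The simple edit process is reversible with stationary law
#' \eqn{\pi(E) = \prod_{e \in E} p_e \prod_{e \notin E} (1 - p_e)}: edges are
#' independently present with probability `p_e`.  This is exactly the
#' edge-independent random graph law with those probabilities.
#'
#' @param host a `host_graph`
#' @param p numeric vector of edge probabilities in (0, 1) (scalar recycled)
#' @return numeric vector of length `2^m` over states `0:(2^m - 1)`
#' @export
stationary_simple <- function(host, p = NULL) {
  stopifnot(inherits(host, "host_graph"))
  p <- p %||% host$p
  if (is.null(p)) stop("no edge probabilities: supply p or attach host$p")
  if (length(p) == 1L) p <- rep(p, host$m)
  check_edge_probs(p, host$m)
  m <- host$m
  B <- bits_matrix(0:(2L^m - 1L), m)
  pi_vec <- rep(1, 2L^m)
  for (j in seq_len(m)) {
    pi_vec <- pi_vec * ifelse(B[, j] == 1L, p[j], 1 - p[j])
  }
  pi_vec
}

#' Recurrent classes of an exact chain
#'
#' Strongly-connected-component analysis of the state digraph (edges where
#' `P > 0`): the recurrent classes are the terminal components.  For the
#' simple process every state is recurrent; for compound families (e.g. the
#' Moran process) transient states are reported rather than silently
#' dropped.
#'
#' @param tmat a `transition_data`
#' @return list of integer vectors of state bitmasks, one per recurrent
#'   class
#' @export
recurrent_classes <- function(tmat) {
  stopifnot(inherits(tmat, "transition_data"))
  g <- igraph::graph_from_adjacency_matrix(tmat$P > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  idx <- which(tmat$P > 0, arr.ind = TRUE)
  crossing <- memb[idx[, 1]] != memb[idx[, 2]]
  nonterminal <- unique(memb[idx[crossing, 1]])
  terminal <- setdiff(seq_len(comp$no), nonterminal)
  lapply(terminal, function(cl) tmat$states[memb == cl])
}

#' Numeric stationary distribution (linear-solver oracle)
#'
#' Solves for the left Perron vector of the chain restricted to its unique
#' recurrent class; the returned distribution has zero mass on transient
#' states.  Errors when the chain has several recurrent classes (e.g. a
#' family consisting only of the identity edit).
#'
#' @param tmat a `transition_data`
#' @return numeric vector of length `2^m`, summing to 1
#' @export
stationary_numeric <- function(tmat) {
  stopifnot(inherits(tmat, "transition_data"))
  classes <- recurrent_classes(tmat)
  if (length(classes) != 1L) {
    stop("not irreducible: ", length(classes), " recurrent classes with sizes ",
         paste(lengths(classes), collapse = ", "))
  }
  R <- match(classes[[1]], tmat$states)
  PR <- tmat$P[R, R, drop = FALSE]
  k <- length(R)
  A <- t(PR) - diag(k)
  A[k, ] <- 1
  b <- c(rep(0, k - 1L), 1)
  piR <- solve(A, b)
  out <- numeric(length(tmat$states))
  out[R] <- piR
  out
}

#' Simulate an edit-family chain
#'
#' Runs the compound edit process: at each step an edit is drawn from the
#' family by inverse-CDF sampling over the fixed edit order (one `runif`
#' per step under `set.seed(seed)`), and applied to the current state.
#' Trajectories are reproducible given (seed, family, E0, steps).
#'
#' @param family an `edit_family`
#' @param E0 initial state bitmask
#' @param steps number of steps (>= 0)
#' @param seed integer RNG seed
#' @return object of class `trajectory`: list with `states` (integer vector
#'   of length `steps + 1`, starting at `E0`), `E0`, `steps`, `seed`
#' @export
simulate_chain <- function(family, E0, steps, seed) {
  stopifnot(inherits(family, "edit_family"), steps >= 0)
  E0 <- check_subset_range(E0, family$host)
  states <- integer(steps + 1L)
  states[1L] <- E0
  if (steps > 0L) {
    set.seed(as.integer(seed))
    cum <- cumsum(family$weights)
    cum[length(cum)] <- 1
    idx <- findInterval(stats::runif(steps), cum) + 1L
    adds <- vapply(family$edits, function(x) x$add, integer(1))
    keep <- bitwXor(family$host$full_mask, family$supports)  # complement of support
    cur <- E0
    for (t in seq_len(steps)) {
      i <- idx[t]
      cur <- bitwOr(bitwAnd(cur, keep[i]), adds[i])
      states[t + 1L] <- cur
    }
  }
  structure(list(states = states, E0 = E0, steps = as.integer(steps),
                 seed = as.integer(seed), host = family$host),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory: ", x$steps, " steps from ",
      subset_to_bitstring(x$E0, x$host$m), " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a trajectory as JSON lines
#'
#' One line per step: `{"t": 0, "state": "10"}` with the state as a
#' bitstring.
#'
#' @param traj a `trajectory`
#' @param path file path
#' @return the path, invisibly
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  bs <- subset_to_bitstring(traj$states, traj$host$m)
  lines <- vapply(seq_along(bs), function(i) {
    as.character(jsonlite::toJSON(list(t = i - 1L, state = bs[i]), auto_unbox = TRUE))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Total variation distance
#'
#' Half the L1 distance between two distributions on the same state index.
#'
#' @param mu,nu numeric probability vectors of equal length
#' @return numeric in [0, 1]
#' @export
tv_distance <- function(mu, nu) {
  if (length(mu) != length(nu)) stop("length mismatch between distributions")
  sum(abs(mu - nu)) / 2
}

#' Spectral upper bound on total-variation decay
#'
#' The chamber-walk bound
#' \eqn{\|P^t(x_0, \cdot) - \pi\|_{TV} \le \sum_X m_X \lambda_X^t}, summed
#' over the non-maximal lattice elements; monotone nonincreasing in `t`.
#' At `t = 0` the bound equals (number of chambers) - 1.
#'
#' @param t nonnegative integer time (vectorized)
#' @param spectrum a `chain_spectrum` (from [chain_spectrum()] or
#'   [simple_spectrum()])
#' @return numeric vector of bounds
#' @export
tv_decay_bound <- function(t, spectrum) {
  stopifnot(inherits(spectrum, "chain_spectrum"))
  lam <- spectrum$lambda[!spectrum$top]
  mult <- spectrum$multiplicity[!spectrum$top]
  vapply(t, function(tt) sum(mult * lam^tt), numeric(1))
}

#' Mixing-time thresholds
#'
#' Integer ceilings of the total-variation mixing thresholds guaranteeing
#' \eqn{\|P^t(x_0,\cdot) - \pi\|_{TV} \le e^{-c}}:
#' \describe{
#'   \item{`simple`}{\eqn{m (c + 2 \ln m)} — the single-edge process on an
#'     m-edge host.}
#'   \item{`compound`}{\eqn{(m \ln 2 + c) / (1 - \lambda^*)} — any edit
#'     family with spectral gap \eqn{1 - \lambda^*}, using the generic
#'     chamber count bound \eqn{2^m}.}
#'   \item{`compound_sharpened`}{\eqn{(\ln M + c) / (1 - \lambda^*)} — when
#'     the number of chambers is known to be at most `M`.}
#' }
#' Logarithms are natural.
#'
#' @param kind one of `"simple"`, `"compound"`, `"compound_sharpened"`
#' @param c positive decay parameter (bound is `exp(-c)`)
#' @param m number of host edges (simple/compound kinds)
#' @param lambda_star second-largest eigenvalue, in [0, 1) (compound kinds)
#' @param M chamber-count bound, >= 1 (sharpened kind)
#' @return integer time threshold
#' @examples
#' mixing_bound("simple", c = 1, m = 5)                      # 22
#' mixing_bound("compound", c = 1, m = 6, lambda_star = 0.5) # 11
#' @export
mixing_bound <- function(kind = c("simple", "compound", "compound_sharpened"),
                         c, m = NULL, lambda_star = NULL, M = NULL) {
  kind <- match.arg(kind)
  stopifnot(c > 0)
  if (kind != "simple") {
    if (is.null(lambda_star)) stop("compound bounds need lambda_star")
    if (lambda_star >= 1) stop("lambda_star must be < 1")
    if (lambda_star < 0) stop("lambda_star must be >= 0")
  }
  val <- switch(kind,
    simple = {
      if (is.null(m)) stop("simple bound needs m")
      m * (c + 2 * log(m))
    },
    compound = {
      if (is.null(m)) stop("compound bound needs m")
      (m * log(2) + c) / (1 - lambda_star)
    },
    compound_sharpened = {
      if (is.null(M) || M < 1) stop("sharpened bound needs a chamber bound M >= 1")
      (log(M) + c) / (1 - lambda_star)
    })
  as.integer(ceiling(val))
}
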