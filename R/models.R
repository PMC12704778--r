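# Model zoo: edge-probability builders whose simple-process stationary laws
# are classical edge-independent random graph models, and the two compound
# showcase processes — the Moran forest and the dynamic random intersection
# graph.

#' Edge-probability builders on a complete host
#'
#' Builds the per-edge probability vector on the complete graph \eqn{K_n}
#' whose simple edit process has, as stationary law, a named
#' edge-independent random graph model:
#' \describe{
#'   \item{`er`}{Erdős–Rényi \eqn{G(n, p)}: every edge probability `p`.}
#'   \item{`chung_lu`}{expected-degree model: \eqn{p_{uv} = k_u k_v / \sum_w
#'     k_w}, requiring \eqn{\max_v k_v \le (\sum_v k_v)^{1/2}}.}
#'   \item{`sbm`}{two-community stochastic block model: probability `p`
#'     within a community, `q` across, with community membership given per
#'     vertex.}
#' }
#'
#' @param model one of `"er"`, `"chung_lu"`, `"sbm"`
#' @param n number of vertices (`er`; inferred from `k` or `membership`
#'   otherwise)
#' @param p within-community / global edge probability
#' @param k positive expected-degree sequence (`chung_lu`)
#' @param membership vector of community labels with exactly two distinct
#'   values (`sbm`)
#' @param q across-community probability (`sbm`)
#' @return a `host_graph` for \eqn{K_n} with `$p` set to the model's edge
#'   probabilities (canonical edge order)
#' @examples
#' h <- edge_probability_model("er", n = 3, p = 0.5)
#' h$p  # 0.5 0.5 0.5
#' @export
edge_probability_model <- function(model = c("er", "chung_lu", "sbm"),
                                   n = NULL, p = NULL, k = NULL,
                                   membership = NULL, q = NULL) {
  model <- match.arg(model)
  if (model == "er") {
    stopifnot(!is.null(n), n >= 2)
    if (is.null(p) || p <= 0 || p >= 1) stop("er model needs 0 < p < 1")
    host <- fixture_host(paste0("kn:", n))
    host$p <- rep(p, host$m)
    return(host)
  }
  if (model == "chung_lu") {
    if (is.null(k) || any(k <= 0)) stop("chung_lu model needs a positive degree sequence k")
    n <- length(k)
    if (n < 2) stop("chung_lu model needs at least two vertices")
    if (max(k) > sqrt(sum(k))) {
      stop("chung_lu degree condition violated: max_v k_v <= (sum_v k_v)^(1/2) required")
    }
    host <- fixture_host(paste0("kn:", n))
    # vertices of kn are labeled 1..n and sorted numerically, so vertex
    # index == label value and k aligns directly
    pe <- k[host$edges[, "lo"]] * k[host$edges[, "hi"]] / sum(k)
    if (any(pe <= 0 | pe >= 1)) {
      stop("chung_lu probabilities must lie strictly in (0, 1); adjust k")
    }
    host$p <- pe
    return(host)
  }
  # sbm
  if (is.null(membership)) stop("sbm model needs a membership vector")
  groups <- unique(membership)
  if (length(groups) != 2L || min(table(membership)) < 1L) {
    stop("sbm model needs two nonempty communities")
  }
  if (is.null(p) || is.null(q) || p <= 0 || p >= 1 || q <= 0 || q >= 1) {
    stop("sbm model needs 0 < p, q < 1")
  }
  n <- length(membership)
  host <- fixture_host(paste0("kn:", n))
  same <- membership[host$edges[, "lo"]] == membership[host$edges[, "hi"]]
  host$p <- ifelse(same, p, q)
  host
}

#' The Moran edit family
#'
#' The Moran process picks an edge \eqn{e = \{u, v\}} uniformly and an
#' endpoint uniformly; the chosen endpoint `u` loses all its edges and is
#' reattached by `e` alone.  As an edit family: one compound edit
#' \eqn{y_{(u,v)}} per oriented edge, with action \"delete every edge
#' incident to `u` except \eqn{\{u,v\}}, which is added\", support
#' \eqn{N(u)} and weight \eqn{1/(2m)}.  Its stationary law on complete
#' hosts is the Moran forest, a random-forest model of the family structure
#' of a Moran-model population.
#'
#' @param host a `host_graph` with no isolated vertices
#' @return an `edit_family` with extra fields `oriented` (data.frame of the
#'   `(u, v)` vertex-index pairs, in edit order) and `moran = TRUE`
#' @export
moran_family <- function(host) {
  stopifnot(inherits(host, "host_graph"))
  if (any(host$degree == 0L)) {
    stop("isolated vertex '", host$vertices[which(host$degree == 0L)[1]],
         "': the Moran process is undefined there")
  }
  m <- host$m
  edits <- vector("list", 2L * m)
  u_idx <- integer(2L * m)
  v_idx <- integer(2L * m)
  for (i in seq_len(m)) {
    lo <- host$edges[i, "lo"]; hi <- host$edges[i, "hi"]
    b <- bitwShiftL(1L, i - 1L)
    # orientation (u, v): u is the endpoint whose neighborhood is reset
    edits[[2L * i - 1L]] <- graph_edit(host, add = b,
                                       del = bitwXor(host$nbhd[lo], b))
    edits[[2L * i]] <- graph_edit(host, add = b,
                                  del = bitwXor(host$nbhd[hi], b))
    u_idx[c(2L * i - 1L, 2L * i)] <- c(lo, hi)
    v_idx[c(2L * i - 1L, 2L * i)] <- c(hi, lo)
  }
  fam <- edit_family(edits, rep(1 / (2 * m), 2L * m))
  fam$oriented <- data.frame(u = u_idx, v = v_idx)
  fam$moran <- TRUE
  fam
}

#' Closed-form Moran eigenvalue
#'
#' \eqn{\lambda_X = \sum_{v : N(v) \subseteq X} d_v / (2m)} over the
#' neighborhood-generated lattice; the second-largest eigenvalue is at most
#' \eqn{1 - \delta(H)/m}.
#'
#' @param host a `host_graph`
#' @param X edge-subset bitmask
#' @return numeric eigenvalue
#' @export
moran_lambda <- function(host, X) {
  stopifnot(inherits(host, "host_graph"))
  X <- check_subset_range(X, host)
  sum(host$degree[is_submask(host$nbhd, X)]) / (2 * host$m)
}

#' Moran spectrum and mixing bounds
#'
#' Computes the full eigenvalue/multiplicity table of the Moran chamber walk
#' (via the generic lattice machinery) and the mixing thresholds
#' guaranteeing total-variation distance at most `exp(-c)`: the general
#' bound \eqn{m (m \ln 2 + c) / \delta(H)}, and for complete hosts
#' \eqn{K_n} the sharpened \eqn{(n^2 \ln n + c n)/2} obtained from the
#' spanning-forest count bound \eqn{F_n \le (n-1)^n}.
#'
#' @param host a `host_graph`
#' @param c positive decay parameter
#' @return list with `spectrum` (a `chain_spectrum`), `lambda_star`,
#'   `lambda_star_bound` (`1 - delta/m`), `t_general`, and `t_kn` (NULL for
#'   non-complete hosts)
#' @export
moran_spectrum_and_bounds <- function(host, c = 1) {
  fam <- moran_family(host)
  spec <- chain_spectrum(fam)
  m <- host$m
  delta <- host$min_degree
  n <- host$n
  complete <- m == n * (n - 1) / 2 && all(host$degree == n - 1L)
  t_kn <- if (complete) as.integer(ceiling((n^2 * log(n) + c * n) / 2)) else NULL
  list(spectrum = spec,
       lambda_star = attr(spec, "lambda_star"),
       lambda_star_bound = 1 - delta / m,
       t_general = as.integer(ceiling(m * (m * log(2) + c) / delta)),
       t_kn = t_kn)
}

#' Recurrent states of the Moran chain
#'
#' The recurrent class of the exact Moran state digraph; it coincides with
#' the chamber images of the semigroup generated by the Moran edits.  On
#' small complete hosts every recurrent state is a forest.
#'
#' @param host a `host_graph` (dense state-space guard: at most 14 edges)
#' @return sorted integer vector of recurrent state bitmasks
#' @export
moran_recurrent_states <- function(host) {
  tm <- transition_matrix(moran_family(host))
  classes <- recurrent_classes(tm)
  if (length(classes) != 1L) {
    stop("unexpected: Moran chain has ", length(classes), " recurrent classes")
  }
  sort(classes[[1]])
}

#' Is an edge subset a forest?
#'
#' Acyclicity check of the subgraph spanned by the edges in `bits`.
#'
#' @param host a `host_graph`
#' @param bits edge-subset bitmask
#' @return logical
#' @export
is_forest_state <- function(host, bits) {
  bits <- check_subset_range(bits, host)
  if (bits == 0L) return(TRUE)
  sel <- bitwAnd(bitwShiftR(bits, seq_len(host$m) - 1L), 1L) == 1L
  g <- igraph::graph_from_edgelist(cbind(host$edges[sel, "lo"],
                                         host$edges[sel, "hi"]),
                                   directed = FALSE)
  igraph::is_forest(g)
}

#' The dynamic random intersection edit family
#'
#' On the complete bipartite host over ground sets \eqn{\Omega} (size `n`)
#' and \eqn{\Omega'} (size `N`), the edit \eqn{y_{v,A}} resets the
#' neighborhood of \eqn{v \in \Omega} to exactly \eqn{A \subseteq \Omega'};
#' its weight is \eqn{w(y_{v,A}) = \mu(|A|) / (n \binom{N}{|A|})}, i.e. a
#' uniform vertex, a neighborhood size drawn from `mu`, and a uniform subset
#' of that size.  The stationary law is the random intersection graph with
#' parameters \eqn{(n, N, \mu)}; the spectral gap is \eqn{1/n} for every
#' `mu`.
#'
#' `mode = "exact"` enumerates all \eqn{n 2^N} edits (guarded to at most
#' `1e5`); `mode = "lazy"` returns a sampler drawing edits on demand,
#' distributionally identical to the exact family.
#'
#' @param n,N sizes of the two ground sets
#' @param mu numeric vector of length `N + 1`: distribution of neighborhood
#'   sizes \eqn{0, \ldots, N}, summing to 1
#' @param mode `"exact"` or `"lazy"`
#' @return exact mode: an `edit_family` with extra field `intersection`
#'   (list with `n`, `N`, `mu`, `edge_index` matrix).  Lazy mode: an object
#'   of class `edit_sampler` for [simulate_sampler()].
#' @export
intersection_family <- function(n, N, mu, mode = c("exact", "lazy")) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, N >= 1)
  mu <- as.numeric(mu)
  if (length(mu) != N + 1L || anyNA(mu) || any(mu < 0) || abs(sum(mu) - 1) > 1e-12) {
    stop("mu must be a probability distribution on {0, ..., N}")
  }
  if (mode == "exact" && n * 2^N > 1e5) {
    stop("exact intersection family too large (n * 2^N > 1e5); use mode = \"lazy\"")
  }
  host <- fixture_host(paste0("knn:", n, ",", N))
  # edge_index[v, u]: canonical edge id of {omega v, omega' u}
  edge_index <- matrix(0L, n, N)
  vi <- match(host$bipartition$omega, host$vertices)
  ui <- match(host$bipartition$omega_prime, host$vertices)
  for (i in seq_len(host$m)) {
    a <- host$edges[i, "lo"]; b <- host$edges[i, "hi"]
    v <- match(a, vi); u <- match(b, ui)
    if (is.na(v)) { v <- match(b, vi); u <- match(a, ui) }
    edge_index[v, u] <- i
  }
  meta <- list(n = n, N = N, mu = mu, edge_index = edge_index, host = host)
  if (mode == "lazy") {
    return(structure(c(meta, list(mode = "lazy")), class = "edit_sampler"))
  }
  edits <- vector("list", n * 2^N)
  w <- numeric(n * 2^N)
  idx <- 0L
  for (v in seq_len(n)) {
    nb_mask <- edges_to_subset(host, edge_index[v, ])
    for (A in 0:(2^N - 1L)) {
      idx <- idx + 1L
      add <- 0L
      for (u in seq_len(N)) {
        if (bitwAnd(bitwShiftR(A, u - 1L), 1L) == 1L) {
          add <- bitwOr(add, bitwShiftL(1L, edge_index[v, u] - 1L))
        }
      }
      edits[[idx]] <- graph_edit(host, add = add, del = bitwXor(nb_mask, add))
      k <- subset_size(A)
      w[idx] <- mu[k + 1L] / (n * choose(N, k))
    }
  }
  fam <- edit_family(edits, w)
  fam$intersection <- meta[c("n", "N", "mu", "edge_index")]
  fam
}

#' Simulate a lazily-sampled edit chain
#'
#' Runs the dynamic random intersection process without enumerating its
#' edit family: each step draws a vertex uniformly, a neighborhood size from
#' `mu`, and a uniform subset of that size, then applies the corresponding
#' neighborhood-reset edit.
#'
#' @param sampler an `edit_sampler` from
#'   `intersection_family(..., mode = "lazy")`
#' @param E0 initial state bitmask
#' @param steps number of steps
#' @param seed integer RNG seed
#' @return a `trajectory`
#' @export
simulate_sampler <- function(sampler, E0, steps, seed) {
  stopifnot(inherits(sampler, "edit_sampler"), steps >= 0)
  host <- sampler$host
  E0 <- check_subset_range(E0, host)
  n <- sampler$n; N <- sampler$N
  nb_mask <- vapply(seq_len(n), function(v) {
    edges_to_subset(host, sampler$edge_index[v, ])
  }, integer(1))
  states <- integer(steps + 1L)
  states[1L] <- E0
  if (steps > 0L) {
    set.seed(as.integer(seed))
    cur <- E0
    for (t in seq_len(steps)) {
      v <- sample.int(n, 1L)
      k <- sample.int(N + 1L, 1L, prob = sampler$mu) - 1L
      A_edges <- if (k > 0L) sample(sampler$edge_index[v, ], k) else integer(0)
      add <- if (k > 0L) edges_to_subset(host, A_edges) else 0L
      cur <- bitwOr(bitwAnd(cur, bitwXor(host$full_mask, nb_mask[v])), add)
      states[t + 1L] <- cur
    }
  }
  structure(list(states = states, E0 = E0, steps = as.integer(steps),
                 seed = as.integer(seed), host = host),
            class = "trajectory")
}
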