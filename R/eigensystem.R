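# Closed-form eigenvectors of the simple edit process, the orthonormal
# symmetrized family, and spectral hitting/commute times with linear-solver
# oracles.
#
# phi_T is the left eigenvector of P with eigenvalue |T|/m; psi_T is its
# normalization to an orthonormal eigenbasis of Q = Pi^{1/2} P Pi^{-1/2};
# the ratio vectors r_T = psi_T / sqrt(pi) drive the hitting/commute sums.

#' Closed-form left eigenvector of the simple edit process
#'
#' For an edge subset `T`, the row vector over states `E`
#' \deqn{\phi_T(E) = (-1)^{|E^c \setminus (E \cup T)|}
#'   \prod_{e \in T \cap E} p_e \prod_{e \in T \setminus E} (1 - p_e)}
#' satisfies \eqn{\phi_T P = (|T|/m) \phi_T}.  For `T` equal to the full
#' edge set, \eqn{\phi_T = \pi}.
#'
#' @param T_bits integer bitmask of the indexing subset
#' @param host a `host_graph`
#' @param p edge probabilities in (0, 1) (scalar recycled)
#' @return numeric vector of length `2^m` over states `0:(2^m - 1)`
#' @examples
#' h <- fixture_host("p3")
#' phi_eigenvector(0L, h, 0.25)  # (1, -1, -1, 1) over states (0, a, b, ab)
#' @export
phi_eigenvector <- function(T_bits, host, p) {
  stopifnot(inherits(host, "host_graph"))
  T_bits <- check_subset_range(T_bits, host)
  if (length(p) == 1L) p <- rep(p, host$m)
  check_edge_probs(p, host$m)
  m <- host$m
  B <- bits_matrix(0:(2L^m - 1L), m)
  v <- rep(1, 2L^m)
  for (j in seq_len(m)) {
    in_T <- bitwAnd(bitwShiftR(T_bits, j - 1L), 1L) == 1L
    v <- v * if (in_T) ifelse(B[, j] == 1L, p[j], 1 - p[j])
    else ifelse(B[, j] == 1L, 1, -1)
  }
  v
}

#' Full eigensystem of the simple edit process
#'
#' Assembles, for every indexing subset `T`, the closed-form eigenvector
#' \eqn{\phi_T}, its normalization
#' \eqn{\psi_T = \sqrt{\prod_{e \notin T} p_e (1 - p_e)}\; \phi_T \Pi^{-1/2}}
#' (an orthonormal left eigenbasis of the symmetrized operator
#' \eqn{Q = \Pi^{1/2} P \Pi^{-1/2}}), and the ratio vectors
#' \eqn{r_T = \psi_T \Pi^{-1/2}} used in the spectral hitting and commute
#' formulas.  Row `t + 1` of each matrix corresponds to subset bitmask `t`;
#' columns are states.
#'
#' @param host a `host_graph`
#' @param p edge probabilities in (0, 1) (scalar recycled)
#' @return object of class `eigensystem`: list with `host`, `p`, `pi`,
#'   `lambda` (per-subset eigenvalues `|T|/m`), `Phi`, `Psi`, `R` (ratio
#'   vectors), `Q`, `P`
#' @export
psi_family <- function(host, p) {
  stopifnot(inherits(host, "host_graph"))
  m <- host$m
  if (m > 12L) stop("host too large for a dense eigensystem (m > 12)")
  if (length(p) == 1L) p <- rep(p, m)
  check_edge_probs(p, m)
  ns <- 2L^m
  subsets <- 0:(ns - 1L)
  pi_vec <- stationary_simple(host, p)
  sq_pi <- sqrt(pi_vec)
  Phi <- t(vapply(subsets, phi_eigenvector, numeric(ns), host = host, p = p))
  q <- p * (1 - p)
  Bt <- bits_matrix(subsets, m)
  # scale_T = sqrt(prod_{e not in T} p_e (1 - p_e))
  scale <- exp(0.5 * as.numeric((1L - Bt) %*% log(q)))
  Psi <- (Phi / rep(sq_pi, each = ns)) * scale
  R <- Psi / rep(sq_pi, each = ns)
  P <- transition_matrix(simple_family(host, p))$P
  Q <- (sq_pi * P) / rep(sq_pi, each = ns)
  structure(list(host = host, p = p, pi = pi_vec,
                 lambda = subset_size(subsets) / m,
                 Phi = Phi, Psi = Psi, R = R, Q = Q, P = P),
            class = "eigensystem")
}

#' @export
print.eigensystem <- function(x, ...) {
  cat("eigensystem: simple edit process on ", x$host$m, " edges (",
      nrow(x$Phi), " eigenvectors)\n", sep = "")
  invisible(x)
}

#' Spectral expected hitting and commute times
#'
#' Hitting times from the spectral representation
#' \deqn{H(x, y) = \sum_{T \ne E} \frac{1}{1 - \lambda_T}
#'   r_T(y) (r_T(y) - r_T(x)),}
#' with the convention \eqn{\tau_y = \inf\{t \ge 0 : X_t = y\}} so that
#' `H[y, y] = 0`.  Commute times are `C = H + t(H)`.  Terms accumulate in
#' descending `|T|` order with compensated (Kahan) summation.
#'
#' @param sys an `eigensystem`
#' @return object of class `hitting_result`: list with matrices `H` and `C`
#'   (states x states, row/column `i` is state bitmask `i - 1`)
#' @export
hitting_times <- function(sys) {
  stopifnot(inherits(sys, "eigensystem"))
  ns <- length(sys$pi)
  ord <- order(-sys$lambda)
  H <- matrix(0, ns, ns)
  comp <- matrix(0, ns, ns)
  ones <- rep(1, ns)
  for (t_idx in ord) {
    lam <- sys$lambda[t_idx]
    if (lam >= 1) next
    r <- sys$R[t_idx, ]
    term <- (outer(ones, r * r) - outer(r, r)) / (1 - lam)
    y <- term - comp
    s <- H + y
    comp <- (s - H) - y
    H <- s
  }
  structure(list(H = H, C = H + t(H)), class = "hitting_result")
}

#' Expected hitting times by fundamental-matrix solve (oracle)
#'
#' Independent linear-algebra route: for each target state `y`, solves
#' \eqn{(I - P_{-y}) h = 1} where \eqn{P_{-y}} deletes row and column `y`,
#' giving the expected hitting times of `y` from every other state.
#'
#' @param P a row-stochastic matrix (or a `transition_data`)
#' @return matrix `H` with `H[x, y]` the expected hitting time of `y` from
#'   `x`
#' @export
hitting_times_solve <- function(P) {
  if (inherits(P, "transition_data")) P <- P$P
  ns <- nrow(P)
  H <- matrix(0, ns, ns)
  I <- diag(ns - 1L)
  for (y in seq_len(ns)) {
    h <- solve(I - P[-y, -y, drop = FALSE], rep(1, ns - 1L))
    H[-y, y] <- h
  }
  H
}

#' Spectral commute time between two subgraph states (restricted sum)
#'
#' The commute time admits the restricted representation
#' \deqn{C(E, F) = \sum_{E \triangle F \not\subseteq T,\, T \ne E}
#'   \frac{m}{m - |T|} \left( r_T(E) - r_T(F) \right)^2,}
#' summing only over indexing subsets `T` that do not contain the symmetric
#' difference of the two states.  When \eqn{E \triangle F \subseteq T}, the
#' ratio identity \eqn{r_T(E) = r_T(F)} holds (every edge outside `T` has
#' the same membership in `E` and `F`, so the edgewise factors of the ratio
#' coincide), and the term vanishes exactly.
#'
#' @param sys an `eigensystem`
#' @param E,F state bitmasks
#' @param restricted if `FALSE`, sum over all `T` except the full set (the
#'   unrestricted representation; equal to the restricted sum)
#' @return numeric commute time
#' @examples
#' sys <- psi_family(fixture_host("p3"), 0.25)
#' commute_time(sys, 1L, 2L)  # 4 / (p (1 - p)) at p = 0.25 -> 21.333...
#' @export
commute_time <- function(sys, E, F, restricted = TRUE) {
  stopifnot(inherits(sys, "eigensystem"))
  E <- check_subset_range(E, sys$host)
  F <- check_subset_range(F, sys$host)
  m <- sys$host$m
  ns <- length(sys$pi)
  subsets <- 0:(ns - 1L)
  sym <- bitwXor(E, F)
  keep <- subsets != sys$host$full_mask
  if (restricted) keep <- keep & !is_submask(sym, subsets)
  tot <- 0
  comp <- 0
  for (t_bits in subsets[keep][order(-subset_size(subsets[keep]))]) {
    r <- sys$R[t_bits + 1L, ]
    k <- subset_size(t_bits)
    term <- (m / (m - k)) * (r[E + 1L] - r[F + 1L])^2
    y <- term - comp
    s <- tot + y
    comp <- (s - tot) - y
    tot <- s
  }
  tot
}

#' Full commute-time matrix
#'
#' @param sys an `eigensystem`
#' @return matrix of commute times over all state pairs (spectral route,
#'   unrestricted sum)
#' @export
commute_times <- function(sys) {
  hitting_times(sys)$C
}

#' Monte-Carlo commute-time estimate
#'
#' Simulates round trips `E -> F -> E` of the edit chain and averages the
#' round-trip lengths; the standard error of the mean accompanies the
#' estimate.
#'
#' @param family an `edit_family`
#' @param E,F state bitmasks
#' @param trips number of round trips
#' @param seed integer RNG seed
#' @return list with `estimate`, `se`, `trips`
#' @export
commute_mc <- function(family, E, F, trips = 1e4, seed = 1L) {
  stopifnot(inherits(family, "edit_family"))
  E <- check_subset_range(E, family$host)
  F <- check_subset_range(F, family$host)
  set.seed(as.integer(seed))
  cum <- cumsum(family$weights)
  cum[length(cum)] <- 1
  adds <- vapply(family$edits, function(x) x$add, integer(1))
  keep <- bitwXor(family$host$full_mask, family$supports)
  draw <- function(k) findInterval(stats::runif(k), cum) + 1L
  buf <- draw(65536L)
  pos <- 1L
  next_edit <- function() {
    if (pos > length(buf)) {
      buf <<- draw(65536L)
      pos <<- 1L
    }
    i <- buf[pos]
    pos <<- pos + 1L
    i
  }
  times <- numeric(trips)
  cur <- E
  for (tr in seq_len(trips)) {
    steps <- 0L
    target <- F
    leg <- 1L
    repeat {
      i <- next_edit()
      cur <- bitwOr(bitwAnd(cur, keep[i]), adds[i])
      steps <- steps + 1L
      if (cur == target) {
        if (leg == 2L) break
        leg <- 2L
        target <- E
      }
    }
    times[tr] <- steps
  }
  list(estimate = mean(times), se = stats::sd(times) / sqrt(trips),
       trips = as.integer(trips))
}

#' Diagonalization of the simple edit process
#'
#' Returns `U` (rows = \eqn{\phi_T}), `Lambda` (diagonal of `|T|/m`), and
#' the reconstruction `solve(U) %*% Lambda %*% U`, which reproduces `P`.
#'
#' @param sys an `eigensystem`
#' @return list with `U`, `Lambda`, `P_reconstructed`
#' @export
diagonalize_simple <- function(sys) {
  stopifnot(inherits(sys, "eigensystem"))
  U <- sys$Phi
  Lambda <- diag(sys$lambda)
  list(U = U, Lambda = Lambda,
       P_reconstructed = solve(U) %*% Lambda %*% U)
}
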