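# Cross-oracle validation harness: binds the closed-form spectral results to
# brute-force numeric oracles (eigendecompositions, matrix powers, linear
# solves) on desk-scale hosts.

#' Numerically computed eigenvalue multiset
#'
#' Real parts of the eigenvalues of a transition matrix (restricted to given
#' states if requested), sorted decreasingly.  Imaginary parts beyond 1e-9
#' raise an error — the chamber walks here are diagonalizable with real
#' spectrum.
#'
#' @param tmat a `transition_data` or a square matrix
#' @param states optional integer vector of state bitmasks to restrict to
#' @return sorted numeric vector
#' @export
numeric_eigenvalues <- function(tmat, states = NULL) {
  P <- if (inherits(tmat, "transition_data")) tmat$P else tmat
  if (!is.null(states)) {
    idx <- states + 1L
    P <- P[idx, idx, drop = FALSE]
  }
  ev <- eigen(P, only.values = TRUE)$values
  if (max(abs(Im(ev))) > 1e-9) stop("unexpectedly complex spectrum")
  sort(Re(ev), decreasing = TRUE)
}

#' Expand a spectrum table into an eigenvalue multiset
#'
#' @param spectrum a `chain_spectrum`
#' @return sorted numeric vector with each eigenvalue repeated by its
#'   multiplicity
#' @export
spectrum_multiset <- function(spectrum) {
  stopifnot(inherits(spectrum, "chain_spectrum"))
  sort(rep(spectrum$lambda, spectrum$multiplicity), decreasing = TRUE)
}

#' Check the spectral total-variation bound against exact matrix powers
#'
#' Verifies, for `t = 0, ..., t_max` and every requested initial state, that
#' the exact total-variation distance `||P^t(x0, .) - pi||` is bounded by
#' the spectral decay bound from `spectrum`.  Returns a falsification with a
#' witness rather than throwing, so corrupted spectra can be detected.
#'
#' @param tmat a `transition_data`
#' @param spectrum a `chain_spectrum`
#' @param pi stationary distribution over all states
#' @param t_max largest time checked
#' @param start_states initial states (bitmasks); default all
#' @return list with `ok`, `witness`
#' @export
check_tv_domination <- function(tmat, spectrum, pi, t_max, start_states = NULL) {
  stopifnot(inherits(tmat, "transition_data"))
  if (is.null(start_states)) start_states <- tmat$states
  rows <- match(start_states, tmat$states)
  Pt <- diag(nrow(tmat$P))
  for (t in 0:t_max) {
    bound <- tv_decay_bound(t, spectrum)
    for (r in rows) {
      tv <- tv_distance(Pt[r, ], pi)
      if (tv > bound + 1e-12) {
        return(list(ok = FALSE, witness = sprintf(
          "TV %.6g exceeds bound %.6g at t = %d from state %s",
          tv, bound, t, subset_to_bitstring(tmat$states[r], tmat$host$m))))
      }
    }
    if (t < t_max) Pt <- Pt %*% tmat$P
  }
  list(ok = TRUE, witness = NULL)
}

run_check <- function(name, suite, tolerance, seed, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fun(), error = function(e) {
    list(ok = FALSE, witness = conditionMessage(e))
  })
  data.frame(check = name, suite = suite,
             status = if (isTRUE(res$ok)) "pass" else "fail",
             witness = if (is.null(res$witness)) "" else res$witness,
             tolerance = tolerance, seed = seed,
             runtime = round(proc.time()[["elapsed"]] - t0, 3),
             stringsAsFactors = FALSE)
}

#' Run the cross-oracle validation suites
#'
#' Each suite binds a family of closed-form results to an independent
#' numeric oracle on small hosts:
#' \describe{
#'   \item{`lrb`}{idempotence and memorylessness of generated semigroups.}
#'   \item{`spectrum`}{closed-form eigenvalues/multiplicities against
#'     numeric eigendecompositions.}
#'   \item{`eigvec`}{closed-form eigenvectors, orthonormality, and
#'     diagonalization.}
#'   \item{`commute`}{restricted spectral commute sums against the
#'     fundamental-matrix solve.}
#'   \item{`mixing`}{spectral decay bounds against exact matrix powers.}
#' }
#'
#' @param suite one of `"all"`, `"lrb"`, `"spectrum"`, `"eigvec"`,
#'   `"commute"`, `"mixing"`
#' @param max_m largest host size used by randomized checks (at most 10)
#' @param seed integer seed for randomized checks
#' @return data.frame report (one row per check) with attribute `ok`;
#'   columns include the tolerance and seed of every check
#' @export
run_validation <- function(suite = c("all", "lrb", "spectrum", "eigvec",
                                     "commute", "mixing"),
                           max_m = 6, seed = 1L) {
  suite <- match.arg(suite)
  stopifnot(max_m <= 10)
  seed <- as.integer(seed)
  reports <- list()
  add <- function(x) reports[[length(reports) + 1L]] <<- x

  if (suite %in% c("all", "lrb")) {
    add(run_check("simple semigroup on p3 is an LRB", "lrb", 0, seed, function() {
      h <- fixture_host("p3")
      gens <- unlist(lapply(seq_len(h$m), function(i) {
        list(simple_edit(h, i, "+"), simple_edit(h, i, "-"))
      }), recursive = FALSE)
      check_lrb(generate_semigroup(gens))
    }))
    add(run_check("Moran semigroup on k4 is an LRB", "lrb", 0, seed, function() {
      check_lrb(generate_semigroup(moran_family(fixture_host("k4"))$edits,
                                   cap = 1e4))
    }))
  }

  if (suite %in% c("all", "spectrum")) {
    add(run_check("simple spectrum matches numeric eigendecomposition", "spectrum",
                  1e-9, seed, function() {
      set.seed(seed)
      for (fx in c("p3", "c5")) {
        h <- fixture_host(fx)
        p <- stats::runif(h$m, 0.1, 0.9)
        ev <- numeric_eigenvalues(transition_matrix(simple_family(h, p)))
        want <- spectrum_multiset(simple_spectrum(h$m))
        if (max(abs(ev - want)) > 1e-9) {
          return(list(ok = FALSE, witness = paste("spectrum mismatch on", fx)))
        }
      }
      list(ok = TRUE, witness = NULL)
    }))
    add(run_check("Moran k3 spectrum matches chamber-block eigenvalues", "spectrum",
                  1e-9, seed, function() {
      h <- fixture_host("kn:3")
      fam <- moran_family(h)
      spec <- chain_spectrum(fam)
      rec <- moran_recurrent_states(h)
      ev <- numeric_eigenvalues(transition_matrix(fam), states = rec)
      want <- spectrum_multiset(spec)
      if (length(ev) != length(want) || max(abs(ev - want)) > 1e-9) {
        return(list(ok = FALSE, witness = "Moran k3 spectrum mismatch"))
      }
      list(ok = TRUE, witness = NULL)
    }))
  }

  if (suite %in% c("all", "eigvec")) {
    add(run_check("closed-form eigenvectors and orthonormal family", "eigvec",
                  1e-10, seed, function() {
      h <- fixture_host("p3")
      sys <- psi_family(h, 0.25)
      ns <- length(sys$pi)
      for (t_bits in 0:(ns - 1L)) {
        resid <- max(abs(sys$Phi[t_bits + 1L, ] %*% sys$P -
                           sys$lambda[t_bits + 1L] * sys$Phi[t_bits + 1L, ]))
        if (resid > 1e-10) {
          return(list(ok = FALSE, witness = paste("phi residual", resid)))
        }
      }
      gram <- sys$Psi %*% t(sys$Psi)
      if (max(abs(gram - diag(ns))) > 1e-10) {
        return(list(ok = FALSE, witness = "Gram matrix is not the identity"))
      }
      dg <- diagonalize_simple(sys)
      if (max(abs(dg$P_reconstructed - sys$P)) > 1e-10) {
        return(list(ok = FALSE, witness = "U^-1 Lambda U does not reproduce P"))
      }
      list(ok = TRUE, witness = NULL)
    }))
  }

  if (suite %in% c("all", "commute")) {
    add(run_check("spectral commute equals fundamental-matrix solve", "commute",
                  1e-8, seed, function() {
      set.seed(seed)
      h <- fixture_host("kn:3")
      p <- stats::runif(h$m, 0.15, 0.85)
      sys <- psi_family(h, p)
      H_solve <- hitting_times_solve(sys$P)
      C_solve <- H_solve + t(H_solve)
      ns <- length(sys$pi)
      for (E in 0:(ns - 1L)) for (F in 0:(ns - 1L)) {
        cr <- commute_time(sys, E, F)
        cf <- commute_time(sys, E, F, restricted = FALSE)
        if (abs(cr - cf) > 1e-10 || abs(cr - C_solve[E + 1L, F + 1L]) > 1e-8) {
          return(list(ok = FALSE, witness = sprintf(
            "commute mismatch at (%d, %d)", E, F)))
        }
      }
      list(ok = TRUE, witness = NULL)
    }))
  }

  if (suite %in% c("all", "mixing")) {
    add(run_check("spectral TV bound dominates exact TV (simple)", "mixing",
                  1e-12, seed, function() {
      h <- fixture_host("p3")
      tm <- transition_matrix(simple_family(h, 0.25))
      check_tv_domination(tm, simple_spectrum(h$m),
                          stationary_simple(h, 0.25), t_max = 25)
    }))
    add(run_check("spectral TV bound dominates exact TV (Moran k3)", "mixing",
                  1e-12, seed, function() {
      h <- fixture_host("kn:3")
      fam <- moran_family(h)
      tm <- transition_matrix(fam)
      spec <- chain_spectrum(fam)
      rec <- moran_recurrent_states(h)
      check_tv_domination(tm, spec, stationary_numeric(tm), t_max = 25,
                          start_states = rec)
    }))
  }

  out <- do.call(rbind, reports)
  attr(out, "ok") <- all(out$status == "pass")
  out
}
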