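# Support semilattice, Moebius function, and closed-form eigenvalues with
# multiplicities for an arbitrary edit family.
#
# The eigenvalues of a chamber walk are indexed by the union-closed family
# generated by the edit supports; the multiplicity of lambda_X follows by
# Moebius inversion of the chamber counts c_X over that lattice.

#' Union-closure of a family of supports
#'
#' Builds the smallest union-closed family of edge subsets containing the
#' empty set and all given supports — the join semilattice indexing the
#' eigenvalues of the corresponding chamber walk.  Elements are sorted by
#' (cardinality, bitmask), so every proper subset of an element precedes it.
#'
#' @param host a `host_graph`
#' @param supports integer vector of support bitmasks
#' @param max_elements refuse lattices larger than this (closure can explode
#'   for adversarial families)
#' @return object of class `support_lattice`: list with `host`, `elements`
#'   (sorted integer bitmasks), `top` (the maximal element, i.e. the union of
#'   all supports).
#' @examples
#' h <- fixture_host("p3")
#' support_semilattice(h, c(1L, 2L))$elements  # 0 1 2 3
#' @export
support_semilattice <- function(host, supports, max_elements = 1e5) {
  stopifnot(inherits(host, "host_graph"))
  supports <- check_subset_range(supports, host)
  els <- unique(c(0L, as.integer(supports)))
  repeat {
    new <- unique(as.integer(outer(els, els, bitwOr)))
    new <- setdiff(new, els)
    if (!length(new)) break
    els <- c(els, new)
    if (length(els) > max_elements) {
      stop("support lattice too large: more than ", max_elements, " elements")
    }
  }
  els <- els[order(subset_size(els), els)]
  structure(list(host = host, elements = els, top = els[length(els)]),
            class = "support_lattice")
}

#' @export
print.support_lattice <- function(x, ...) {
  cat("support semilattice: ", length(x$elements), " elements, top = ",
      subset_to_bitstring(x$top, x$host$m), "\n", sep = "")
  invisible(x)
}

#' Moebius function of a support lattice
#'
#' Computes the Moebius values \eqn{\mu(X, Y)} for all ordered pairs
#' \eqn{X \subseteq Y} of lattice elements by the defining recursion
#' \eqn{\mu(X, X) = 1} and \eqn{\sum_{X \subseteq Z \subseteq Y} \mu(X, Z) = 0}
#' for \eqn{X \subsetneq Y}.
#'
#' @param L a `support_lattice`
#' @return a square numeric matrix with `mu[i, j]` = \eqn{\mu(X_i, X_j)}
#'   when \eqn{X_i \subseteq X_j}, `NA` otherwise; dimnames are the subset
#'   bitstrings.
#' @export
mobius_function <- function(L) {
  stopifnot(inherits(L, "support_lattice"))
  els <- L$elements
  nl <- length(els)
  mu <- matrix(NA_real_, nl, nl)
  bs <- subset_to_bitstring(els, L$host$m)
  dimnames(mu) <- list(bs, bs)
  for (i in seq_len(nl)) {
    mu[i, i] <- 1
    if (i < nl) for (j in (i + 1L):nl) {
      if (is_submask(els[i], els[j])) {
        s <- 0
        for (k in i:(j - 1L)) {
          if (!is.na(mu[i, k]) && is_submask(els[k], els[j])) s <- s + mu[i, k]
        }
        mu[i, j] <- -s
      }
    }
  }
  mu
}

#' Closed-form eigenvalue indexed by a lattice element
#'
#' The eigenvalue indexed by an edge subset `X` is the total weight of the
#' family edits whose support is contained in `X`.  For the single-edge
#' (simple) process this reduces to `|X| / m` independently of the edge
#' probabilities.
#'
#' @param X integer bitmask
#' @param family an `edit_family`
#' @return numeric scalar in [0, 1]
#' @export
family_eigenvalue <- function(X, family) {
  stopifnot(inherits(family, "edit_family"))
  X <- check_subset_range(X, family$host)
  supp <- family$supports
  sum(family$weights[is_submask(supp, X)])
}

# Canonical representative with support X: the product of the
# lexicographically-first (by generator index) greedy set of generators whose
# supports lie in X and union to X.
representative_for <- function(X, generators, supports, host) {
  if (X == 0L) return(identity_edit(host))
  rep_edit <- NULL
  covered <- 0L
  for (i in seq_along(generators)) {
    s <- supports[i]
    if (is_submask(s, X) && bitwAnd(s, bitwXor(X, covered)) != 0L) {
      rep_edit <- if (is.null(rep_edit)) generators[[i]] else compose(generators[[i]], rep_edit)
      covered <- bitwOr(covered, s)
      if (covered == X) return(rep_edit)
    }
  }
  stop("no representative: subset ", subset_to_bitstring(X, host$m),
       " is not a union of generator supports")
}

#' Spectrum of an edit-family chamber walk
#'
#' Computes the full eigenvalue/multiplicity table of the chamber walk driven
#' by an edit family: the support semilattice, the closed-form eigenvalue
#' \eqn{\lambda_X} per lattice element, and the multiplicity \eqn{m_X}
#' obtained by Moebius inversion of the chamber counts \eqn{c_X} (the number
#' of chambers fixed by a canonical representative with support `X`).
#' Consistency is validated: all \eqn{m_X \ge 0} and
#' \eqn{\sum_X m_X} equals the number of chambers; a violation signals a
#' representative-dependence problem and raises an error.
#'
#' @param family an `edit_family`
#' @param semigroup optionally a pre-computed `edit_semigroup` generated by
#'   the family's edits
#' @param cap closure cap passed to [generate_semigroup()]
#' @return object of class `chain_spectrum`: a data.frame with columns
#'   `bits`, `subset` (bitstring), `lambda`, `multiplicity`, `chamber_count`,
#'   `top`; attributes `lambda_star` (largest eigenvalue below 1),
#'   `n_chambers`, and `host`.
#' @export
chain_spectrum <- function(family, semigroup = NULL, cap = NULL) {
  stopifnot(inherits(family, "edit_family"))
  host <- family$host
  L <- support_semilattice(host, family$supports)
  els <- L$elements
  nl <- length(els)
  lambda <- vapply(els, family_eigenvalue, numeric(1), family = family)
  if (is.null(semigroup)) semigroup <- generate_semigroup(family$edits, cap = cap)
  ch <- chambers(semigroup)
  ch_add <- vapply(ch$edits, function(x) x$add, integer(1))
  cX <- vapply(seq_len(nl), function(i) {
    X <- els[i]
    r <- representative_for(X, family$edits, family$supports, host)
    # chambers c with x c = c, i.e. chambers agreeing with the
    # representative's actions on X (r's support is exactly X)
    sum(bitwAnd(ch_add, X) == r$add)
  }, numeric(1))
  mu <- mobius_function(L)
  mX <- vapply(seq_len(nl), function(i) {
    j <- which(!is.na(mu[i, ]))
    sum(mu[i, j] * cX[j])
  }, numeric(1))
  mX <- round(mX)
  if (any(mX < 0)) {
    stop("inconsistent lattice/chambers: negative multiplicity for subset ",
         subset_to_bitstring(els[which(mX < 0)[1]], host$m))
  }
  if (sum(mX) != length(ch$subsets)) {
    stop("inconsistent lattice/chambers: multiplicities sum to ", sum(mX),
         " but the semigroup has ", length(ch$subsets), " chambers")
  }
  out <- data.frame(bits = els,
                    subset = subset_to_bitstring(els, host$m),
                    lambda = lambda,
                    multiplicity = as.integer(mX),
                    chamber_count = as.integer(cX),
                    top = els == L$top,
                    stringsAsFactors = FALSE)
  below <- out$lambda[!out$top]
  attr(out, "lambda_star") <- if (length(below)) max(below) else NA_real_
  attr(out, "n_chambers") <- length(ch$subsets)
  attr(out, "host") <- host
  class(out) <- c("chain_spectrum", "data.frame")
  out
}

#' Spectrum of the simple edit process
#'
#' The simple (single-edge) process on an m-edge host has eigenvalue
#' \eqn{k/m} with multiplicity \eqn{\binom{m}{k}} for \eqn{0 \le k \le m}
#' (one eigenvalue per edge subset `T`, with value `|T|/m`), independent of
#' the edge probabilities.
#'
#' @param m number of host edges
#' @return a `chain_spectrum`-classed data.frame with one row per distinct
#'   eigenvalue: columns `k`, `lambda`, `multiplicity`, `top`.
#' @export
simple_spectrum <- function(m) {
  stopifnot(m >= 1)
  k <- 0:m
  out <- data.frame(k = k, lambda = k / m,
                    multiplicity = choose(m, k),
                    top = k == m)
  attr(out, "lambda_star") <- (m - 1) / m
  attr(out, "n_chambers") <- 2^m
  class(out) <- c("chain_spectrum", "data.frame")
  out
}

#' Export a spectrum as TSV
#'
#' @param spectrum a `chain_spectrum`
#' @param path file path
#' @return the path, invisibly
#' @export
write_spectrum <- function(spectrum, path) {
  df <- as.data.frame(spectrum)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
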