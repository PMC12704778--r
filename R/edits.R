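# Edit algebra: graph edits as canonical idempotent partial maps
# edge -> {add, delete}, the left-regular-band product, supports, semigroup
# closure and chambers.
#
# An edit is stored extensionally as two disjoint bitmasks (add, del); two
# edit words are equal iff they induce the same partial map, which matches
# equality of their action on every edge subset.

#' Construct a graph edit
#'
#' A (compound) graph edit is an idempotent map on edge subsets of a host
#' graph, canonically represented by a partial map from edges to
#' \{add, delete\}: each edge in `add` is forced present, each edge in `del`
#' forced absent, and all other edges are untouched.  The empty map is the
#' identity edit.
#'
#' @param host a `host_graph`
#' @param add,del integer bitmasks (or via [edges_to_subset()]) of edges
#'   forced present / absent; they must be disjoint.
#' @return an object of class `graph_edit`
#' @examples
#' h <- fixture_host("p3")
#' x <- graph_edit(h, add = 1L)          # force edge "1--2" present
#' apply_edit(x, 0L)                     # 1
#' @export
graph_edit <- function(host, add = 0L, del = 0L) {
  stopifnot(inherits(host, "host_graph"))
  add <- check_subset_range(add, host)
  del <- check_subset_range(del, host)
  if (bitwAnd(add, del) != 0L) {
    stop("invalid edit: an edge cannot be both added and deleted")
  }
  structure(list(host = host, add = add, del = del), class = "graph_edit")
}

#' @rdname graph_edit
#' @param edge an edge label or 1-based edge index
#' @param sign `"+"` (force present) or `"-"` (force absent)
#' @export
simple_edit <- function(host, edge, sign = c("+", "-")) {
  sign <- match.arg(sign)
  b <- edges_to_subset(host, edge)
  if (subset_size(b) != 1L) stop("simple edit acts on exactly one edge")
  if (sign == "+") graph_edit(host, add = b) else graph_edit(host, del = b)
}

#' @rdname graph_edit
#' @export
identity_edit <- function(host) graph_edit(host)

edit_key <- function(x) paste(x$add, x$del, sep = ".")

same_host <- function(x, y) identical(x$host$key, y$host$key)

#' @export
print.graph_edit <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.graph_edit <- function(x, ...) {
  if (x$add == 0L && x$del == 0L) return("edit {} (identity)")
  lab <- x$host$edge_labels
  m <- x$host$m
  a <- bitwAnd(bitwShiftR(x$add, seq_len(m) - 1L), 1L) == 1L
  d <- bitwAnd(bitwShiftR(x$del, seq_len(m) - 1L), 1L) == 1L
  parts <- character(0)
  if (any(a)) parts <- c(parts, paste0(lab[a], "+"))
  if (any(d)) parts <- c(parts, paste0(lab[d], "-"))
  paste0("edit {", paste(parts, collapse = " "), "}")
}

#' Apply an edit to an edge subset
#'
#' For each edge in the edit's support the result is determined by the edit
#' (present iff the action is add); every other edge is left unchanged.
#' Applying the same edit twice equals applying it once.
#'
#' @param x a `graph_edit`
#' @param E integer bitmask(s) of edge subsets (vectorized)
#' @return integer bitmask(s) of the edited subset(s)
#' @export
apply_edit <- function(x, E) {
  stopifnot(inherits(x, "graph_edit"))
  E <- check_subset_range(E, x$host)
  supp <- bitwOr(x$add, x$del)
  bitwOr(bitwAnd(E, bitwXor(x$host$full_mask, supp)), x$add)
}

#' Compose two edits (left-regular-band product)
#'
#' Returns the canonical form of the product `later * earlier`, where the
#' rightmost factor acts first:
#' `apply_edit(compose(y, x), E) == apply_edit(y, apply_edit(x, E))` for all
#' subsets `E`.  Per edge, the later edit's action wins; edges touched only
#' by the earlier edit keep its action.  The product satisfies the
#' left-regular-band laws `compose(x, x) == x` and
#' `compose(compose(x, y), x) == compose(x, y)`.
#'
#' @param later,earlier `graph_edit`s over the same host
#' @return a `graph_edit`
#' @examples
#' h <- fixture_host("p3")
#' ep <- simple_edit(h, 1, "+"); em <- simple_edit(h, 1, "-")
#' identical(compose(ep, em), ep)  # e+ e- = e+
#' @export
compose <- function(later, earlier) {
  stopifnot(inherits(later, "graph_edit"), inherits(earlier, "graph_edit"))
  if (!same_host(later, earlier)) stop("host mismatch: edits act on different hosts")
  supp_l <- bitwOr(later$add, later$del)
  not_l <- bitwXor(later$host$full_mask, supp_l)
  graph_edit(later$host,
             add = bitwOr(later$add, bitwAnd(earlier$add, not_l)),
             del = bitwOr(later$del, bitwAnd(earlier$del, not_l)))
}

#' Support of an edit
#'
#' The set of edges on which the edit acts nontrivially, as a bitmask.
#' Supports are union-multiplicative:
#' `edit_support(compose(y, x)) == bitwOr(edit_support(y), edit_support(x))`.
#'
#' @param x a `graph_edit`
#' @return integer bitmask
#' @export
edit_support <- function(x) {
  stopifnot(inherits(x, "graph_edit"))
  bitwOr(x$add, x$del)
}

#' Generate the semigroup closure of a set of edits
#'
#' Worklist breadth-first closure of the generators under the product (in
#' both orders), always including the identity edit.  The full semigroup of
#' all simple edits on an m-edge host has exactly `3^m` elements (each edge
#' independently: untouched, forced present, forced absent), which is the
#' default cap.
#'
#' @param generators list of `graph_edit`s over one host
#' @param cap maximum number of elements before aborting (default `3^m`)
#' @return an object of class `edit_semigroup` with fields `host`,
#'   `elements` (list of `graph_edit`s, identity first), `generators`.
#' @export
generate_semigroup <- function(generators, cap = NULL) {
  if (!length(generators)) stop("need at least one generator")
  stopifnot(all(vapply(generators, inherits, TRUE, "graph_edit")))
  host <- generators[[1]]$host
  if (!all(vapply(generators, function(g) identical(g$host$key, host$key), TRUE))) {
    stop("host mismatch: generators act on different hosts")
  }
  if (is.null(cap)) cap <- 3^host$m
  gkeys <- vapply(generators, edit_key, "")
  generators <- generators[!duplicated(gkeys)]
  elements <- list(identity_edit(host))
  names(elements) <- edit_key(elements[[1]])
  frontier <- list()
  for (g in generators) {
    k <- edit_key(g)
    if (is.null(elements[[k]])) {
      elements[[k]] <- g
      frontier[[k]] <- g
    }
  }
  while (length(frontier)) {
    nxt <- list()
    for (z in frontier) {
      for (g in generators) {
        for (prod in list(compose(z, g), compose(g, z))) {
          k <- edit_key(prod)
          if (is.null(elements[[k]]) && is.null(nxt[[k]])) nxt[[k]] <- prod
        }
      }
    }
    elements <- c(elements, nxt)
    if (length(elements) > cap) {
      stop("semigroup too large: exceeded cap of ", cap, " elements")
    }
    frontier <- nxt
  }
  structure(list(host = host, elements = unname(elements),
                 keys = names_or_keys(elements), generators = generators),
            class = "edit_semigroup")
}

names_or_keys <- function(elements) {
  if (!is.null(names(elements))) names(elements)
  else vapply(elements, edit_key, "")
}

#' @export
print.edit_semigroup <- function(x, ...) {
  cat("edit semigroup: ", length(x$elements), " elements over ",
      x$host$m, "-edge host (", length(x$generators), " generators)\n", sep = "")
  invisible(x)
}

#' Chambers of an edit semigroup
#'
#' Chambers are the elements with full support (every edge acted on); they
#' absorb the semigroup random walk and biject with edge subsets via
#' \"edges the chamber forces present\".
#'
#' @param S an `edit_semigroup`
#' @return list with `edits` (the chamber elements) and `subsets` (integer
#'   bitmasks, the image of each chamber under the bijection)
#' @export
chambers <- function(S) {
  stopifnot(inherits(S, "edit_semigroup"))
  full <- S$host$full_mask
  is_ch <- vapply(S$elements, function(x) edit_support(x) == full, TRUE)
  edits <- S$elements[is_ch]
  subsets <- vapply(edits, function(x) x$add, integer(1))
  if (anyDuplicated(subsets)) stop("internal error: chamber map not injective")
  list(edits = edits, subsets = subsets)
}

#' Check the left-regular-band axioms
#'
#' Verifies idempotence (`x^2 = x`) and the memorylessness identity
#' (`xyx = xy`) over all pairs of elements, or over a fixed-seed uniform
#' sample of pairs when the semigroup is large.  A failed check is returned
#' as a falsification with a witness, not thrown as an error.
#'
#' @param S an `edit_semigroup`
#' @param max_pairs exhaustive when `|S|^2` is at most this, else sampled
#' @param seed RNG seed for the sampled case
#' @return list with `ok` (logical), `exhaustive`, `checked`, and `witness`
#'   (NULL, or a description of the first counterexample)
#' @export
check_lrb <- function(S, max_pairs = 1e4, seed = 1L) {
  stopifnot(inherits(S, "edit_semigroup"))
  els <- S$elements
  n <- length(els)
  for (i in seq_len(n)) {
    x <- els[[i]]
    if (edit_key(compose(x, x)) != edit_key(x)) {
      return(list(ok = FALSE, exhaustive = TRUE, checked = i,
                  witness = paste("idempotence fails:", format(x))))
    }
  }
  exhaustive <- n^2 <= max_pairs
  if (exhaustive) {
    idx <- cbind(rep(seq_len(n), each = n), rep(seq_len(n), n))
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    idx <- cbind(sample.int(n, max_pairs, replace = TRUE),
                 sample.int(n, max_pairs, replace = TRUE))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  for (r in seq_len(nrow(idx))) {
    x <- els[[idx[r, 1]]]; y <- els[[idx[r, 2]]]
    xy <- compose(x, y)
    if (edit_key(compose(xy, x)) != edit_key(xy)) {
      return(list(ok = FALSE, exhaustive = exhaustive, checked = r,
                  witness = paste("xyx != xy for x =", format(x), ", y =", format(y))))
    }
  }
  list(ok = TRUE, exhaustive = exhaustive, checked = nrow(idx), witness = NULL)
}

#' Check the left-regular-band axioms for raw state maps
#'
#' Same checks as [check_lrb()] but for arbitrary maps on the `2^m` subset
#' states, each given as an integer vector of length `2^m` sending state
#' bitmask `b` to `map[b + 1]`.  Used to falsify non-edit dynamics (e.g. an
#' edge toggle, which is not idempotent).
#'
#' @param maps list of integer vectors of equal length `2^m` with values in
#'   `0:(2^m - 1)`
#' @return as [check_lrb()]
#' @export
check_lrb_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  ns <- length(maps[[1]])
  for (i in seq_along(maps)) {
    f <- maps[[i]]
    if (!identical(f[f + 1L], f)) {
      return(list(ok = FALSE, exhaustive = TRUE, checked = i,
                  witness = paste0("idempotence fails for map ", i)))
    }
  }
  for (i in seq_along(maps)) {
    for (j in seq_along(maps)) {
      f <- maps[[i]]; g <- maps[[j]]
      fg <- f[g + 1L]          # apply g then f
      if (!identical(fg[f + 1L], fg)) {  # x y x vs x y (rightmost acts first)
        return(list(ok = FALSE, exhaustive = TRUE, checked = c(i, j),
                    witness = paste0("xyx != xy for maps (", i, ", ", j, ")")))
      }
    }
  }
  list(ok = TRUE, exhaustive = TRUE, checked = length(maps)^2, witness = NULL)
}

#' Serialize a semigroup as a table
#'
#' One row per element: a JSON action map (`{"u--v": "+", ...}`), the support
#' bitstring, and whether the element is a chamber.
#'
#' @param S an `edit_semigroup`
#' @return a data.frame with columns `id`, `actions`, `support`, `is_chamber`
#' @export
semigroup_table <- function(S) {
  stopifnot(inherits(S, "edit_semigroup"))
  m <- S$host$m
  full <- S$host$full_mask
  actions <- vapply(S$elements, function(x) {
    lab <- S$host$edge_labels
    a <- which(bitwAnd(bitwShiftR(x$add, seq_len(m) - 1L), 1L) == 1L)
    d <- which(bitwAnd(bitwShiftR(x$del, seq_len(m) - 1L), 1L) == 1L)
    acts <- c(stats::setNames(rep("+", length(a)), lab[a]),
              stats::setNames(rep("-", length(d)), lab[d]))
    acts <- acts[order(c(a, d))]
    as.character(jsonlite::toJSON(as.list(acts), auto_unbox = TRUE))
  }, "")
  supp <- vapply(S$elements, edit_support, integer(1))
  data.frame(id = seq_along(S$elements) - 1L,
             actions = actions,
             support = subset_to_bitstring(supp, m),
             is_chamber = supp == full,
             stringsAsFactors = FALSE)
}
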