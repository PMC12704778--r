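test_that("applying an edit forces exactly its actions", {
  h <- fixture_host("p3")
  a_minus <- simple_edit(h, "1--2", "-")
  a_plus <- simple_edit(h, "1--2", "+")
  expect_identical(apply_edit(a_minus, 3L), 2L)   # a- on {a,b} -> {b}
  expect_identical(apply_edit(a_plus, 3L), 3L)    # no effect if already present
  expect_identical(apply_edit(a_plus, 0L), 1L)

  # Moran edit y_(1,2) on the full K4 edge set: (E \ N(1)) union {1--2}
  k4 <- fixture_host("k4")
  e12 <- edges_to_subset(k4, "1--2")
  y <- graph_edit(k4, add = e12, del = bitwXor(k4$nbhd[1], e12))
  want <- bitwOr(bitwAnd(k4$full_mask, bitwXor(k4$full_mask, k4$nbhd[1])), e12)
  expect_identical(apply_edit(y, k4$full_mask), want)
})

test_that("the product reduces to a canonical map and is memoryless", {
  h <- fixture_host("p3")
  ep <- simple_edit(h, 1, "+")
  em <- simple_edit(h, 1, "-")
  expect_identical(compose(ep, em), ep)  # e+ e- = e+
  expect_identical(compose(em, ep), em)  # e- e+ = e-

  rand_edit <- function() {
    add <- sample(0:3, 1)
    del_choices <- Filter(function(d) bitwAnd(d, add) == 0L, 0:3)
    graph_edit(h, add = add, del = sample(del_choices, 1))
  }
  set.seed(4)
  for (i in 1:25) {
    x <- rand_edit()
    y <- rand_edit()
    expect_identical(compose(x, x), x)                          # idempotent
    xy <- compose(x, y)
    expect_identical(compose(xy, x), xy)                        # xyx = xy
  }
})

test_that("product semantics match function composition on all subsets", {
  # exhaustive on a 3-edge host: every ordered pair of semigroup elements,
  # every subset
  h <- fixture_host("kn:3")
  S <- generate_semigroup(all_simple_edits(h))
  subsets <- 0:(2^h$m - 1L)
  for (x in S$elements) for (y in S$elements) {
    expect_identical(apply_edit(compose(y, x), subsets),
                     apply_edit(y, apply_edit(x, subsets)))
  }
})

test_that("product semantics hold on sampled pairs of a larger semigroup", {
  h <- fixture_host("k4")
  S <- generate_semigroup(all_simple_edits(h))
  subsets <- 0:(2^h$m - 1L)
  set.seed(11)
  n <- length(S$elements)
  for (r in 1:300) {
    x <- S$elements[[sample.int(n, 1)]]
    y <- S$elements[[sample.int(n, 1)]]
    expect_identical(apply_edit(compose(y, x), subsets),
                     apply_edit(y, apply_edit(x, subsets)))
  }
})

test_that("supports are union-multiplicative", {
  h <- fixture_host("p3")
  expect_identical(edit_support(simple_edit(h, 1, "+")), 1L)
  set.seed(9)
  for (i in 1:30) {
    masks <- sample(0:3, 4)
    x <- graph_edit(h, add = bitwAnd(masks[1], bitwXor(3L, masks[2])), del = bitwAnd(masks[2], bitwXor(3L, masks[1])))
    y <- graph_edit(h, add = bitwAnd(masks[3], bitwXor(3L, masks[4])), del = bitwAnd(masks[4], bitwXor(3L, masks[3])))
    expect_identical(edit_support(compose(x, y)),
                     bitwOr(edit_support(x), edit_support(y)))
  }
  # Moran support is the chosen endpoint's neighborhood
  k4 <- fixture_host("k4")
  fam <- moran_family(k4)
  for (i in seq_along(fam$edits)) {
    u <- fam$oriented$u[i]
    expect_identical(edit_support(fam$edits[[i]]), k4$nbhd[u])
    expect_identical(subset_size(edit_support(fam$edits[[i]])), k4$degree[u])
  }
})

test_that("the full simple semigroup has 3^m elements and 2^m chambers", {
  hosts <- list(build_host(list(c(1, 2))), fixture_host("p3"),
                fixture_host("kn:3"), path_host(4))
  for (h in hosts) {
    S <- generate_semigroup(all_simple_edits(h))
    expect_equal(length(S$elements), 3^h$m, info = paste("m =", h$m))
    ch <- chambers(S)
    expect_equal(length(ch$subsets), 2^h$m)
    expect_setequal(ch$subsets, 0:(2^h$m - 1L))
  }
})

test_that("semigroup closure matches an independent fixpoint oracle", {
  # brute-force closure: repeated pairwise products until no new element
  h <- fixture_host("kn:3")
  gens <- moran_family(h)$edits
  oracle <- gens
  keys <- sapply(oracle, function(x) paste(x$add, x$del))
  repeat {
    added <- FALSE
    for (x in oracle) for (y in oracle) {
      z <- compose(x, y)
      k <- paste(z$add, z$del)
      if (!k %in% keys) {
        oracle <- c(oracle, list(z)); keys <- c(keys, k); added <- TRUE
      }
    }
    if (!added) break
  }
  S <- generate_semigroup(gens, cap = 1e4)
  # generate_semigroup adds the identity by convention
  expect_equal(length(S$elements), length(oracle) + 1L)
})

test_that("the closure cap is enforced with an informative error", {
  h <- fixture_host("p3")
  expect_error(generate_semigroup(all_simple_edits(h), cap = 4),
               "semigroup too large.*4")
})

test_that("chambers are the full-support elements and map to edge subsets", {
  h <- fixture_host("p3")
  S <- generate_semigroup(all_simple_edits(h))
  ch <- chambers(S)
  # chamber (a -> add, b -> delete) corresponds to subset {a}
  i <- which(vapply(ch$edits, function(x) x$add == 1L && x$del == 2L, TRUE))
  expect_length(i, 1)
  expect_identical(ch$subsets[[i]], 1L)
})

test_that("left-regular-band axioms hold for edit semigroups and fail for toggles", {
  h <- fixture_host("p3")
  expect_true(check_lrb(generate_semigroup(all_simple_edits(h)))$ok)
  expect_true(check_lrb(generate_semigroup(moran_family(fixture_host("k4"))$edits,
                                           cap = 1e4))$ok)
  # toggle edge a: an involution, not idempotent
  toggle <- bitwXor(0:3, 1L)
  rep <- check_lrb_maps(list(toggle))
  expect_false(rep$ok)
  expect_match(rep$witness, "idempotence")
})

test_that("the partial order xy = y coincides with action-map containment", {
  h <- fixture_host("p3")
  S <- generate_semigroup(all_simple_edits(h))
  for (x in S$elements) for (y in S$elements) {
    le <- identical(compose(x, y), y)
    submap <- is_submask(x$add, y$add) && is_submask(x$del, y$del)
    expect_identical(le, submap)
  }
})

test_that("the preorder yx = y coincides with support containment", {
  h <- fixture_host("p3")
  S <- generate_semigroup(all_simple_edits(h))
  for (x in S$elements) for (y in S$elements) {
    prec <- identical(compose(y, x), y)
    supp_sub <- is_submask(edit_support(x), edit_support(y))
    expect_identical(prec, supp_sub)
  }
})

test_that("host mismatch is rejected across edit operations", {
  x <- simple_edit(fixture_host("p3"), 1, "+")
  y <- simple_edit(fixture_host("c5"), 1, "+")
  expect_error(compose(x, y), "host mismatch")
  expect_error(apply_edit(y, 200L), "out of range")
})

test_that("semigroup tables serialize action maps, supports and chamber flags", {
  h <- fixture_host("p3")
  tab <- semigroup_table(generate_semigroup(all_simple_edits(h)))
  expect_equal(nrow(tab), 9)
  expect_equal(sum(tab$is_chamber), 4)
  expect_true(any(grepl("\"1--2\":\"\\+\"", tab$actions)))
})
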