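test_that("edge-probability builders produce the named models", {
  er <- edge_probability_model("er", n = 3, p = 0.5)
  expect_equal(er$p, rep(0.5, 3))

  cl <- edge_probability_model("chung_lu", k = c(1, 1, 2))
  # p_uv = k_u k_v / sum(k); edge 1--3 has p = 2/4
  expect_equal(cl$p[cl$edge_labels == "1--3"], 0.5)
  expect_equal(cl$p[cl$edge_labels == "1--2"], 0.25)
  expect_error(edge_probability_model("chung_lu", k = c(1, 1, 9)),
               "degree condition")

  sb <- edge_probability_model("sbm", membership = c(1, 1, 2, 2), p = 0.7, q = 0.1)
  expect_equal(sb$p[sb$edge_labels == "1--2"], 0.7)
  expect_equal(sb$p[sb$edge_labels == "3--4"], 0.7)
  expect_equal(sb$p[sb$edge_labels == "1--3"], 0.1)
  expect_error(edge_probability_model("sbm", membership = rep(1, 4), p = .5, q = .5),
               "two nonempty")
})

test_that("builder stationary laws have exact marginals and pairwise independence", {
  hosts <- list(edge_probability_model("er", n = 4, p = 0.3),
                edge_probability_model("chung_lu", k = c(1, 1.5, 2, 2.5)),
                edge_probability_model("sbm", membership = c(1, 1, 2, 2),
                                       p = 0.6, q = 0.15))
  for (h in hosts) {
    tm <- transition_matrix(simple_family(h))
    piv <- stationary_numeric(tm)
    expect_lt(max(abs(piv - stationary_simple(h))), 1e-12)
    B <- sapply(seq_len(h$m), function(j) bitwAnd(bitwShiftR(tm$states, j - 1L), 1L))
    for (e in seq_len(h$m)) {
      expect_equal(sum(piv[B[, e] == 1]), h$p[e], tolerance = 1e-12)
      for (f in seq_len(h$m)) if (f > e) {
        expect_equal(sum(piv[B[, e] == 1 & B[, f] == 1]), h$p[e] * h$p[f],
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the Moran family has one weight-1/(2m) edit per oriented edge", {
  k4 <- fixture_host("k4")
  fam <- moran_family(k4)
  expect_length(fam$edits, 12)
  expect_equal(fam$weights, rep(1 / 12, 12))
  expect_equal(sum(fam$weights), 1)
  # applying y_(u,v) leaves u with degree exactly one
  set.seed(13)
  for (i in seq_along(fam$edits)) {
    E <- sample(0:(2^6 - 1L), 1)
    out <- apply_edit(fam$edits[[i]], E)
    u <- fam$oriented$u[i]
    expect_equal(subset_size(bitwAnd(out, k4$nbhd[u])), 1L)
  }
  # isolated vertices are rejected
  h_iso <- build_host(list(c(1, 2), c(3, 4)))
  h_iso$degree[1] <- 0L  # simulate an isolated vertex record
  expect_error(moran_family(h_iso), "isolated vertex")
})

test_that("Moran spectrum has the closed-form eigenvalues and gap bound", {
  k4 <- fixture_host("k4")
  res <- moran_spectrum_and_bounds(k4, c = 1)
  spec <- res$spectrum
  # lambda for a union of two neighborhoods: (d_u + d_v)/(2m) = 1/2
  X <- bitwOr(k4$nbhd[1], k4$nbhd[2])
  expect_equal(spec$lambda[spec$bits == X], 0.5)
  expect_equal(moran_lambda(k4, X), 0.5)
  expect_equal(res$lambda_star, 0.5)
  expect_equal(res$lambda_star_bound, 1 - k4$min_degree / k4$m)
  expect_lte(res$lambda_star, res$lambda_star_bound)
  expect_equal(spec$lambda[spec$top], 1)
  expect_equal(res$t_general, ceiling(6 * (6 * log(2) + 1) / 3))
  expect_equal(res$t_kn, ceiling((16 * log(4) + 4) / 2))

  k3 <- fixture_host("kn:3")
  expect_equal(moran_lambda(k3, k3$nbhd[1]), 1 / 3)
  spec3 <- chain_spectrum(moran_family(k3))
  expect_equal(spec3$lambda[spec3$bits == k3$nbhd[1]], 1 / 3)
  # closed form agrees with the generic lattice eigenvalue everywhere
  for (i in seq_len(nrow(spec3))) {
    expect_equal(spec3$lambda[i], moran_lambda(k3, spec3$bits[i]))
  }
})

test_that("Moran recurrent states are the chambers, are forests, exclude K4 itself", {
  k3 <- fixture_host("kn:3")
  rec <- moran_recurrent_states(k3)
  S <- generate_semigroup(moran_family(k3)$edits, cap = 1e4)
  expect_setequal(rec, chambers(S)$subsets)

  k4 <- fixture_host("k4")
  rec4 <- moran_recurrent_states(k4)
  expect_true(all(vapply(rec4, is_forest_state, TRUE, host = k4)))
  expect_false(k4$full_mask %in% rec4)  # the complete graph is transient
  S4 <- generate_semigroup(moran_family(k4)$edits, cap = 1e4)
  expect_setequal(rec4, chambers(S4)$subsets)
})

test_that("Moran K4 long-run state frequencies match the exact stationary law", {
  k4 <- fixture_host("k4")
  fam <- moran_family(k4)
  tm <- transition_matrix(fam)
  piv <- stationary_numeric(tm)
  rec <- moran_recurrent_states(k4)
  tr <- simulate_chain(fam, rec[1], 1e5, seed = 17)
  x <- tr$states[1002:100001]
  # batch-means standard errors absorb the autocorrelation of the chain
  nb <- 100L
  bsize <- length(x) %/% nb
  for (s in rec[1:5]) {
    ind <- as.numeric(x == s)
    bm <- colMeans(matrix(ind[1:(nb * bsize)], nrow = bsize))
    se <- stats::sd(bm) / sqrt(nb)
    expect_lt(abs(mean(ind) - piv[s + 1L]), 4 * se + 1e-4)
  }
})

test_that("the exact intersection family enumerates n 2^N weighted edits", {
  fam <- intersection_family(2, 2, c(0.5, 0.25, 0.25))
  expect_length(fam$edits, 8)
  expect_equal(sum(fam$weights), 1)
  # every edit resets one vertex neighborhood: support is that vertex's star
  expect_setequal(unique(fam$supports), unique(apply(fam$intersection$edge_index, 1,
    function(ix) Reduce(bitwOr, bitwShiftL(1L, ix - 1L)))))
  expect_error(intersection_family(10, 20, rep(1 / 21, 21)), "lazy")
  expect_error(intersection_family(2, 2, c(0.5, 0.5, 0.5)), "probability distribution")
})

test_that("the intersection spectral gap is 1/n independent of mu", {
  for (mu in list(c(0.2, 0.3, 0.5), rep(1 / 3, 3))) {
    fam <- intersection_family(3, 2, mu)
    spec <- chain_spectrum(fam, cap = 200)
    # lambda_B = |B|/n, where |B| = (edges in the mask) / N
    expect_equal(spec$lambda, subset_size(spec$bits) / 2 / 3)
    expect_equal(attr(spec, "lambda_star"), 2 / 3)
    expect_equal(attr(spec, "n_chambers"), 2^6)  # full-support mu: all subsets
    ev <- numeric_eigenvalues(transition_matrix(fam))
    expect_lt(max(abs(ev - spectrum_multiset(spec))), 1e-9)
    gap <- 1 - max(ev[ev < 1 - 1e-12])
    expect_equal(gap, 1 / 3, tolerance = 1e-10)
  }
})

test_that("the lazy sampler is distributionally consistent with the exact family", {
  mu <- c(0.25, 0.5, 0.25)
  fam <- intersection_family(2, 2, mu)
  sam <- intersection_family(2, 2, mu, mode = "lazy")
  tr <- simulate_sampler(sam, 0L, 2e4, seed = 23)
  tr2 <- simulate_sampler(sam, 0L, 100, seed = 23)
  expect_identical(tr$states[1:101], tr2$states)  # reproducible
  piv <- stationary_numeric(transition_matrix(fam))
  x <- tr$states[1001:20001]
  # per-edge presence frequency vs the exact stationary marginal
  B <- bits_matrix(x, sam$host$m)
  marg <- sapply(seq_len(sam$host$m), function(j) {
    sum(piv[bitwAnd(bitwShiftR(0:(2^4 - 1L), j - 1L), 1L) == 1L])
  })
  expect_lt(max(abs(colMeans(B) - marg)), 0.02)
})
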