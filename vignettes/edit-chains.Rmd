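---
title: "Edit-semigroup Markov chains: model, spectra, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edit-semigroup Markov chains: model, spectra, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphedits)
```

## The model

Fix a *host graph* $H = (V, E)$ with $n$ vertices and $m$ edges.  The object
that evolves is not the host but a subgraph of it: the state space is the set
$2^E$ of edge subsets, encoded here as integer bitmasks (edge $i$ of the
canonical ordering is bit $i-1$).

A *graph edit* is an idempotent map on $2^E$.  The package represents every
edit canonically as a partial map from edges to $\{\text{add}, \text{delete}\}$:
each edge in the edit's *support* is forced present or absent, all other
edges are untouched.  The *simple* edits are $e^+$ (force $e$ present) and
$e^-$ (force $e$ absent); compound edits touch several edges in tandem.
Because an edit acts regardless of the current state — "add $e$" does
nothing if $e$ is already there — products of edits satisfy the two *left
regular band* (LRB) laws
$$x^2 = x, \qquad xyx = xy ,$$
which say the process is memoryless: repeating an edit, or re-applying it
after any interleaving, changes nothing.  These two identities are what
make an otherwise unstructured subset-valued chain exactly solvable.

A *chain* is an **edit family**: a finite set of edits with probability
weights.  At each step an edit is drawn from the family and applied.  The
**simple edit process** with edge probabilities $p_e \in (0,1)$ is the
family $\{e^+ \text{ w.p. } p_e/m,\; e^- \text{ w.p. } (1-p_e)/m\}$;
equivalently, pick an edge uniformly and make it present with probability
$p_e$.  Its stationary law is the product measure
$$\pi(E) = \prod_{e \in E} p_e \prod_{e \notin E} (1 - p_e),$$
i.e. the edge-independent random graph with those probabilities — which is
how Erdős–Rényi, Chung–Lu and two-block stochastic block models arise as
stationary laws of `edge_probability_model()` (the chain is also reversible
with respect to $\pi$).

## Spectra by algebra, multiplicities by Möbius inversion

The walk driven by a family $A$ with weights $w$ lives, after at most one
step per edge, on the *chambers* of the semigroup $\langle A \rangle$ — the
elements of full support, which biject with edge subsets.  Its transition
matrix is diagonalizable with eigenvalues indexed by the *support
semilattice* $L$: the union-closure of $\{\mathrm{supp}(x)\}_{x \in A}$
together with $\varnothing$.  For $X \in L$,
$$\lambda_X = \sum_{x \in A,\; \mathrm{supp}(x) \subseteq X} w_x ,$$
implemented in `family_eigenvalue()`.  The multiplicity $m_X$ comes from
the chamber counts $c_X$ (the number of chambers fixed by an element of
support $X$) by Möbius inversion over $L$:
$$\sum_{Y \supseteq X} m_Y = c_X
  \quad\Longleftrightarrow\quad
  m_X = \sum_{Y \supseteq X} \mu(X, Y)\, c_Y .$$
`chain_spectrum()` assembles all of this.  Two validity checks are built in
rather than assumed: every $m_X$ must be a nonnegative integer, and
$\sum_X m_X$ must equal the number of chambers.  Both would fail if the
chamber count depended on which representative of support $X$ was used; the
test suite additionally compares counts across all representatives on small
instances, and they agree.

The canonical representative for $X$ is the product of the greedy
(first-by-index) set of generators whose supports lie in $X$ and union to
$X$ — deterministic, and validated by the checks above.

For the simple process every subset is a flat and every multiplicity is 1,
so the spectrum is $\{k/m \text{ with multiplicity } \binom{m}{k}\}$,
independent of $p$ (`simple_spectrum()`).

```{r spectrum}
k4 <- fixture_host("k4")
spec <- chain_spectrum(moran_family(k4), cap = 1e4)
spec[, c("subset", "lambda", "multiplicity")]
```

Every closed-form spectrum in the package is cross-checked against a
numeric eigendecomposition of the exact transition matrix
(`numeric_eigenvalues()`), with eigenvalues grouped at an absolute
tolerance of `1e-9` — comfortably above the `~1e-13` scatter observed for
these well-conditioned desk-scale matrices and far below the `1/(2m)`
spacing of distinct eigenvalues.

## Eigenvectors, hitting and commute times (simple process)

For the simple process the left eigenvectors are closed-form
(`phi_eigenvector()`):
$$\phi_T(E) = (-1)^{|E^c \setminus (E \cup T)|}
  \prod_{e \in T \cap E} p_e \prod_{e \in T \setminus E} (1 - p_e),
  \qquad \phi_T P = \tfrac{|T|}{m}\, \phi_T .$$
Scaled by $\sqrt{\prod_{e \notin T} p_e(1-p_e)}$ and by $\Pi^{-1/2}$
(where $\Pi = \mathrm{diag}(\pi)$), they become an orthonormal left
eigenbasis $\{\psi_T\}$ of the symmetric operator
$Q = \Pi^{1/2} P \Pi^{-1/2}$ (`psi_family()`).  The printed square roots in
several published accounts of this normalization are typographically
ambiguous; the package fixes the unique scaling under which the Gram matrix
of $\{\psi_T\}$ is exactly the identity — and enforces it with a test.

With the ratio vectors $r_T = \psi_T \Pi^{-1/2}$, expected hitting times of
a reversible chain admit the spectral form
$$H(x, y) = \sum_{T \neq E} \frac{1}{1 - \lambda_T}\,
  r_T(y)\,\bigl(r_T(y) - r_T(x)\bigr),$$
with the convention $\tau_y = \inf\{t \ge 0 : X_t = y\}$, so
$H(y, y) = 0$; commute times are $C = H + H^\top$.  For a pair of subgraph
states, the commute sum can be *restricted*: the ratio
$r_T(E)$ factors over the edges outside $T$, and the factor for edge $e$
depends only on whether $e \in E$ — so $r_T(E) = r_T(F)$, and the $T$-term
vanishes exactly, precisely when every edge of $E \mathbin{\triangle} F$
lies inside $T$.  `commute_time()` therefore sums over
$\{T : E \mathbin{\triangle} F \not\subseteq T,\; T \neq E\}$; the equality
of restricted sum, full sum and the fundamental-matrix linear solve
($(I - P_{-y})h = \mathbf{1}$, `hitting_times_solve()`) is asserted to
`1e-8` over all state pairs in the tests.

Spectral sums accumulate in descending $|T|$ order with compensated (Kahan)
summation; at the sizes involved plain summation would already meet the
`1e-8` budget, but the compensation costs nothing.

```{r commute}
sys <- psi_family(fixture_host("p3"), 0.25)
commute_time(sys, 1L, 2L)   # between the two single-edge states
```

## Mixing bounds

The chamber-walk bound
$\|P^t(x_0,\cdot) - \pi\|_{TV} \le \sum_{X \in L^*} m_X \lambda_X^t$
(`tv_decay_bound()`) yields explicit thresholds for
$\|P^t - \pi\|_{TV} \le e^{-c}$ (`mixing_bound()`):

| kind | threshold | needs |
|---|---|---|
| `simple` | $m(c + 2\ln m)$ | $m$ |
| `compound` | $(m \ln 2 + c)/(1-\lambda^*)$ | $m$, spectral gap |
| `compound_sharpened` | $(\ln M + c)/(1-\lambda^*)$ | chamber bound $M$ |

All logarithms are natural: the derivations pass through
$\log(1+x) \le x$, and the property test that exact total variation at the
returned thresholds is below $e^{-c}$ (run for $c \in \{1,2,3\}$, all
initial states, hosts up to six edges) would fail under a weaker
base-$2$ or base-$10$ reading of the compound bound.  Returned times are
integer ceilings.

## The compound showcases

**Moran forest** (`moran_family()`).  Pick an edge $\{u,v\}$ and an
endpoint $u$ uniformly; $u$ loses all its edges and is reattached by
$\{u,v\}$.  One edit $y_{(u,v)}$ per oriented edge, each of weight
$1/(2m)$, with support $N(u)$, the star of $u$.  The per-edit weight
$1/(2m)$ is forced by the uniform edge-then-endpoint sampling and is
consistent with the closed-form eigenvalues
$$\lambda_X = \sum_{v:\, N(v) \subseteq X} \frac{d_v}{2m},$$
so the spectral gap is at least $\delta(H)/m$.  On $K_4$ the second-largest
eigenvalue is exactly $1 - \delta/m = 1/2$, by both the formula and the
numeric spectrum of the chamber-restricted matrix.  The recurrent states
(computed by strong-component analysis of the exact state digraph,
`moran_recurrent_states()`) coincide with the chamber images of
$\langle B \rangle$ and, on $K_3$ and $K_4$, are all forests — asserted as
a property of the computed states, since whether this holds for arbitrary
hosts is not something the package claims.  On $K_n$ the chamber count is
bounded by the forest count $F_n \le (n-1)^n$, sharpening the mixing
threshold to $(n^2 \ln n + cn)/2$ (`moran_spectrum_and_bounds()`).

**Dynamic random intersection graph** (`intersection_family()`).  On the
complete bipartite host over $\Omega$ ($n$ vertices) and $\Omega'$ ($N$
vertices), the edit $y_{v,A}$ resets the neighborhood of $v \in \Omega$ to
$A \subseteq \Omega'$, with weight $\mu(|A|)/\bigl(n\binom{N}{|A|}\bigr)$
for a user-chosen size law $\mu$ on $\{0,\dots,N\}$.  No default $\mu$ is
provided: the size law *is* the model, and the chamber-count claim
($2^{nN}$, all subsets) holds only for full-support $\mu$, which is why
the spectrum code checks support before asserting it.  Since the vertex
stars are disjoint, the flats are indexed by $B \subseteq \Omega$ with
$\lambda_B = |B|/n$: the spectral gap is $1/n$ whatever $\mu$ is, which
the tests confirm numerically for two different size laws.  Exact
enumeration of the $n 2^N$ edits is guarded at $10^5$; beyond that a lazy
sampler (`simulate_sampler()`) draws vertex, size and subset on the fly —
distributionally identical to the exact family.

## Scale, randomness, degenerate inputs

* **Problem sizes.** Everything exact is desk-scale by design: dense
  transition matrices up to $m = 14$ edges ($2^{14}$ states), dense
  eigensystems up to $m = 12$, closures capped at $3^m$ by default,
  lattices refused beyond $10^5$ elements.  The test and validation suites
  run hosts with $m \le 6$ (up to 64 states), where exact matrix powers,
  eigendecompositions and $3^m$-element closures all complete in seconds;
  these sizes exercise every code path, and the closed forms they certify
  are size-generic.  Larger hosts are the province of `simulate_chain()`.
* **Randomness.** One integer seed per simulation; edits are drawn by
  inverse-CDF over the family's fixed edit order, so trajectories are
  bit-reproducible across platforms given the same generator description.
  Randomized checks (LRB pair sampling, random hosts and probabilities)
  fix their seeds.
* **Degenerate inputs.** Edge probabilities are required to be strictly
  inside $(0,1)$ — at the endpoints the chain loses irreducibility and the
  eigenvector normalizations divide by zero.  A family whose unique edit
  is the identity has every state absorbing; `stationary_numeric()`
  reports the multiple recurrent classes instead of returning one of them.
  Transient states of compound chains are kept in the state space and
  reported, not dropped: the spectrum refers to the chamber-restricted
  block, the stationary law puts zero mass outside it.
* **Ties and orderings.** Vertex order is label order (numeric when all
  labels are numeric); edge order is lexicographic on endpoint index
  pairs; bitstrings read left-to-right as edge 1, 2, ….  These conventions
  make state indices stable across runs and are relied on by the
  round-trip tests.

## What the fixtures do and do not show

The built-in hosts (`p3`, `c5`, `k4`, `kn:n`, `knn:n,N`) and the
seeded random (host, $p$) instances are the *study conditions* of the test
suite: small enough for brute-force oracles, rich enough to cover path,
cycle, complete and bipartite structure.  Passing them certifies the
algebra and the exact linear algebra — eigenvalues, multiplicities,
eigenvectors, commute times, mixing thresholds — which are closed-form in
$m$ and therefore carry to any host size.  What desk scale cannot certify
is statistical behavior on large hosts (e.g. how quickly Monte-Carlo
commute estimates concentrate at $m \gg 6$), nor anything about data:
there is no inference here, only exact models.

## Known limitations

* No sparse or implicit eigensolvers: compound families on hosts beyond
  the dense guards must be simulated, not decomposed.
* Closed-form eigenvectors exist only for the simple process; compound
  families fall back to numeric decomposition of the chamber block.
* Hosts are simple undirected graphs; no multigraphs, no directed edits.
* The bitmask encoding caps hosts at 30 edges even for simulation.
* Commute times relate to effective resistance on the state graph only
  informally here; no resistance computation is provided.
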