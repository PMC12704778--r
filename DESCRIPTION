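Package: graphedits
Title: Edit-Semigroup Markov Chains on Subgraphs of a Host Graph
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Exact construction, simulation and spectral analysis of
    stochastically evolving subgraphs of a fixed host graph.  Edits
    (force an edge present or absent, singly or in tandem) generate a
    left regular band semigroup, which yields closed-form eigenvalues
    indexed by edge subsets, eigenvalue multiplicities via the Moebius
    function of the support semilattice, closed-form eigenvectors for
    the single-edge process, spectral hitting and commute times, and
    rigorous total-variation mixing-time bounds.  Includes the Moran
    forest process and a dynamic random intersection graph process as
    compound-edit models, plus Erdos-Renyi, Chung-Lu and stochastic
    block model edge-probability builders, all verifiable against
    brute-force linear-algebra oracles at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
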