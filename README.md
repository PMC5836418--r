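# rnamibp

Information-theoretic characterization of RNA secondary-structure
Boltzmann ensembles.

An RNA sequence folds into a *distribution* of secondary structures, and
because helices compete for the same bases that distribution is usually
multimodal. `rnamibp` takes a set of structures sampled from the ensemble
(the output of any stochastic sampler, as a multi-structure dot-bracket or
concatenated CT file) and finds the individual basepairs that decide which
conformation a molecule adopts. It is aimed at anyone studying bistable
RNAs, riboSNitch candidates, or the effect of probing data on a predicted
ensemble.

Each candidate pair `{i,j}` is a binary indicator `X_ij` with marginal
`p_ij`, entropy `H[X_ij] = -p log2 p - (1-p) log2(1-p)` (bits), and pairwise
mutual information `I(X_ij; X_kl) = H[X_ij] - H[X_ij | X_kl]`. The **most
informative basepair** (MIBP) maximizes `sum_ij I(X_ij; X_kl)`.
Conditioning on its presence/absence greedily builds a binary tree of
clusters (stopping when cluster mass x MI-sum drops below 2 bits), each
cluster summarized by conditional pair probabilities, remaining entropy,
and the mutually conflicting pairs — pairs that share an endpoint or cross,
so at most one can be present — that explain the split. For conflicting
pairs the mutual information has the closed form
`(1-p-q)log2(1-p-q) - (1-p)log2(1-p) - (1-q)log2(1-q)`, monotone in each
marginal. Near-certain pairs (`H < 0.002` bits) can be frozen and the
surviving pseudoknot-free structure space counted exactly by dynamic
programming in big-integer arithmetic. Results are rendered as a static
HTML tree of circle-chord diagrams (chord opacity = probability; red/blue =
pair constrained present/absent) plus a machine-readable `report.json`.

A built-in toy model (`exact_ensemble()`) enumerates the complete Boltzmann
ensemble of short sequences under additive per-pair energies, providing
exact marginals/MI as a test oracle and a seeded sampler, so nothing
external is needed to try the package.

## Worked example

The 18-nt sequence `GGGGAAAACCCCAAUUUU` can close a left G-C hairpin
(pairs 1-12 … 4-9) or a right A-U hairpin (pairs 5-18 … 8-15), never both:

```r
library(rnamibp)
samples <- tempfile(fileext = ".db")
mibp_simulate("GGGGAAAACCCCAAUUUU", n = 1000, seed = 7, path = samples)
res <- mibp_analyze(samples, out_dir = "mibp-report")
#> [rnamibp] read 1000 sampled structures over 18 nt (seq)
#> [rnamibp] 40 candidate pairs, ensemble entropy 10.763 bits
#> [rnamibp] tree: 2 clusters, conditional entropy 8.083 bits
#> [rnamibp] entropy constraints: 0 forced, 11 forbidden, 1.0000 mass retained
#> [rnamibp] structure space: 10^3.08 -> 10^2.98
print(res$tree)
#> <mibp_tree> 2 leaves (cutoff 2 bits)
#> #1 p=1.0000 H=10.763 split {2,11}
#>   #2 p=0.5990 H=4.980 leaf
#>   #3 p=0.4010 H=12.718 leaf
```

The MIBP is `{2,11}`, a left-helix pair: 59.9% of sampled structures
contain it, and within that cluster only 4.98 bits of basepair uncertainty
remain (versus 10.76 bits overall). The top conflicting pairs recorded at
the root (`res$tree$root$conflicting`) are `{2,12}` (p = 0.158) and
`{2,10}` (p = 0.098) — alternative pairings of the same strand that are
mutually exclusive with the MIBP. Counting the structure space
(`res$counts`) gives 1190 distinct basepair sets unconstrained and 958
after forbidding the 11 near-zero-entropy pairs, with 100% of the sample
mass retained. `mibp-report/report.html` shows the three clusters as
circle diagrams.

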