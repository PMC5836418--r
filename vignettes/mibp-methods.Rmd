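---
title: "Most informative basepairs: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Most informative basepairs: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnamibp)
```

## The problem

An RNA sequence does not fold into a single secondary structure. The
thermodynamic (Boltzmann) ensemble assigns every pseudoknot-free structure a
probability proportional to `exp(-E(x)/kT)`, and because helices compete for
the same bases this distribution is usually multimodal: a handful of
mutually exclusive helices decides which of a few alternative conformations
a molecule adopts. `rnamibp` characterizes such an ensemble — given as a set
of sampled structures from any stochastic sampler — by finding the
individual basepairs that carry the most information about everything else,
and by splitting the ensemble along them.

## Model

Every candidate basepair `{i,j}` defines a binary indicator `X_ij`, equal to
1 in structures that contain the pair. Valid structures obey the standard
model: only A-U, G-C and G-U pairings, no position in two pairs (no
triples), and no crossing pairs (no pseudoknots). Two pairs that can never
coexist — sharing an endpoint or crossing — *conflict*.

From `n` sampled structures we estimate the marginal `p_ij = P(X_ij = 1)`
and score each pair's uncertainty with the binary entropy

    H[X_ij] = -p_ij log2 p_ij - (1 - p_ij) log2 (1 - p_ij)

in bits, with `0 log 0 = 0`. The information one pair carries about another
is the mutual information of the two indicators,
`I(X_ij; X_kl) = H[X_ij] - H[X_ij | X_kl]`, computed from the empirical
2-by-2 joint. The *most informative basepair* (MIBP) maximizes the summed
mutual information with all candidates:

    MIBP = argmax_kl  sum_ij I(X_ij; X_kl)

Knowing whether the MIBP is present tells us the most about the rest of the
structure, so conditioning on it splits the ensemble into the two simplest
halves available from a single pair.

For two conflicting pairs the joint presence probability is exactly zero
and the mutual information collapses to a closed form in the two marginals:

    I = (1-p-q) log2(1-p-q) - (1-p) log2(1-p) - (1-q) log2(1-q)

which, for fixed `p > 0`, increases strictly in `q` (its derivative is
`log2((1-q)/(1-p-q))`). Hence the most probable pair conflicting with an
MIBP is also the conflicting pair sharing the most information with it —
the package reports up to five such pairs per split, chosen greedily so
they are pairwise mutually conflicting.

## The cluster tree

`build_tree()` applies the MIBP search greedily: the root holds all
samples; each node's members are split into those containing the node's
MIBP and those not, which adds one presence/absence constraint per branch.
A node is split only while

    (node probability mass) x (MIBP's summed mutual information)  >=  cutoff

with a default cutoff of 2 bits; leaves form an exhaustive partition of the
samples. Each node records conditional marginals, the conditional ensemble
entropy (the sum of member-restricted pair entropies), its MIBP and the
conflicting pairs. `conditional_entropy_of_tree()` — the leaf-mass-weighted
sum of leaf entropies — measures the uncertainty remaining after learning a
structure's cluster.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `cutoff_bits` | 2 | stop splitting when mass x MI-sum falls below this; smaller values give more clusters with diminishing entropy returns |
| `low_frac`, `high_frac` | 0.01, 0.99 | drop candidates seen in fewer than 1% or more than 99% of samples before the MIBP search; such pairs have near-zero entropy and contribute negligible MI. At 1000 samples this reproduces the absolute 10/990 rule |
| `entropy_threshold` | 0.002 bits | pairs below this entropy are effectively decided; they are constrained to their near-certain state before counting |
| `max_conflicts` | 5 | conflicting pairs reported per split |
| `min_node_samples` | 10 | nodes with fewer members become leaves: sample-based MI on a handful of structures is noise |
| `min_loop` | 3 | minimum unpaired bases in a hairpin, the field-standard sampler convention; structure *validity* only requires `j - i >= 2`, and both the toy model and the counting DP accept other values |

The MIBP sum includes the focal pair's self-term `I(X;X) = H[X]` (the
argmax definition places no restriction on the summation index); since the
self-term is at most 1 bit it rarely changes the winner, and
`include_self = FALSE` switches it off. Ties — exact or within `1e-9` —
are broken toward the smallest `(i, j)`, making every result deterministic
and independent of sample order.

## Counting the structure space

`count_structures()` counts distinct basepair sets compatible with a
constraint set by the interval recursion
`N(i,j) = N(i+1,j) + sum_k [i pairs k] N(i+1,k-1) N(k+1,j)`, with
constraint masking: forbidden pairs and forced-unpaired positions are
removed from the admissible pairing relation, and a forced pair restricts
both its endpoints to each other, which zeroes every branch that crosses or
omits it. Counts grow far beyond `2^53`, so the DP runs in exact
big-integer arithmetic (base-10^4 limb vectors with schoolbook add and
multiply — every intermediate stays well inside the exactly representable
double range); results carry the full decimal string and its `log10`.
These are counts of basepair *sets*: engines that distinguish coaxial
stacking states of one pair set report larger numbers, so absolute counts
are not comparable across conventions, though constrained-to-unconstrained
ratios are.

`entropy_constraints()` turns ensemble statistics into such a constraint
set: every allowed pairing of the sequence with `H < 0.002` bits is forced
present (when `p > 0.5`, in practice `p > 1 - 1.2e-4`) or absent (`p <
0.5`, in practice `p < 1.2e-4`). The candidate universe is all
complementary pairs at minimum separation — pairs never observed in any
sample have `p = 0` and are constrained absent. `retained_mass()` reports
the sample mass the constraints keep; near 1 by construction, since only
near-certain pairs are constrained.

## The toy ensemble: what it emulates and what it does not

Real ensembles come from a thermodynamic sampler and enter through
`read_structures()` (multi-structure dot-bracket or concatenated CT). For
development and testing the package carries its own generator:
`toy_energy_model()` scores a structure as the sum of per-pair-type
energies (defaults G-C -3, A-U -2, G-U -1, `kT = 1`, arbitrary units), and
`exact_ensemble()` enumerates every valid structure of a short sequence
(default cap 30 nt) and normalizes the Boltzmann weights exactly. This
yields three things no external engine provides:

* exact marginals, joints and mutual informations by finite summation — the
  oracle for the estimators;
* an *exact-weights mode*: `exact_weighted_ensemble()` feeds the enumerated
  structures into `build_ensemble()` with their exact probabilities as
  weights (one "sample" per structure), so every downstream statistic takes
  its exact value with no Monte-Carlo error;
* a seeded inverse-CDF sampler (`sample_structures()`), reproducible and
  exact, for convergence checks at chosen `n`.

The toy model has no stacking, loop or dangle terms, so its ensembles are
flatter and less helix-cooperative than nearest-neighbor ensembles; it
emulates the *combinatorial* structure of the problem (competing,
conflicting helices; multimodality) but not folding thermodynamics. Tests
passing on toy data therefore validate the statistics, the tree logic and
the counting — not the realism of any particular RNA's ensemble, which is
inherited from whatever sampler produced the input file.

The bistable design used throughout the tests and the worked examples,
`GGGGAAAACCCCAAUUUU`, lets bases 1-4 pair 9-12 (a G-C hairpin) or bases 5-8
pair 15-18 (an A-U hairpin); every pair of one helix crosses every pair of
the other, so the toy Boltzmann ensemble is genuinely bimodal with an
asymmetry set by the G-C/A-U energy gap. At 1000 samples this gives a
one-split tree whose leaves are the two conformations — a miniature of the
paradigm the method targets.

## Numerical choices

* All logarithms are base 2; all entropies and MI are in bits;
  `0 log 0 = 0` throughout.
* Joints are plug-in (raw weighted frequencies, no pseudocounts); MI is
  computed in the symmetric `sum p log2(p / (p_x p_y))` form, so
  `I(a;b)` and `I(b;a)` agree to machine precision, and values below
  `1e-12` are clamped to zero to absorb floating noise.
* Weighted samples renormalize over cluster members; a cluster carrying no
  mass is an error, not a NaN.
* Degenerate splits (a pair present in all or none of a node's members)
  cannot be selected: the frequency filter removes such candidates, and
  `split_cluster()` refuses them explicitly.
* Enumeration order is lexicographic in the sorted pair list, and sampling
  restores the caller's RNG state, so every output — including the SVG and
  JSON reports, which format numbers with fixed precision — is reproducible
  byte for byte.

## Visual conventions

Each cluster is drawn as a circle-chord diagram: positions run clockwise
from 12 o'clock with ticks every 10 nt, and every basepair above the
plotting floor (default `p < 0.01` omitted) is a straight chord whose
opacity is affine in its node-conditional probability (`0.1 + 0.9 p`, full
opacity at `p = 1`). Chords for the node's path constraints are always
drawn: red for constrained-present MIBPs, blue for constrained-absent. The
HTML report nests the diagrams as a collapsible binary tree using plain
`<details>` elements — fully static, no scripts, no network resources — and
`report.json` carries the complete tree (constraints, probabilities,
entropies, conflicting pairs, per-node marginals) plus the resolved
configuration, and re-renders to byte-identical SVGs.

## Problem sizes

The worked examples and the test suite run on short sequences: exact
enumeration and the oracle comparisons use random sequences up to 16 nt
(hundreds to thousands of structures), counting cross-checks go to 14 nt
against brute force and to 60 nt for exact big-integer digits, and the
end-to-end runs use the 18-nt bistable sequence at 500-10000 samples.
These sizes keep every oracle exact; the pipeline itself is polynomial
(the DP is cubic, the MI matrix quadratic in candidates) and handles the
few-hundred-nt sequences typical of sampler output.

## Known limitations

* Pseudoknots and base triples are outside the structure model, as in the
  samplers whose output is consumed; bracket layers beyond `()` are
  rejected rather than silently dropped.
* Per-cluster marginals come from subsetting the samples. Recomputing them
  with a constrained partition function would be exact but requires the
  external engine; the exact-weights toy mode provides that analogue for
  verification.
* No confidence intervals on MI estimates; the frequency filter plus the
  `min_node_samples` guard are the only small-sample protections.
* Absolute structure counts are convention-dependent (see above).

## Worked example

```{r example, eval = FALSE}
samples <- tempfile(fileext = ".db")
mibp_simulate("GGGGAAAACCCCAAUUUU", n = 1000, seed = 7, path = samples)
res <- mibp_analyze(samples, out_dir = "mibp-report")
print(res$tree)
res$counts
```
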