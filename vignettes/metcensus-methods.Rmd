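---
title: "Methods: a census pipeline for methionine-rich prion-like domains"
author: "metcensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a census pipeline for methionine-rich prion-like domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metcensus)
```

# The problem

Methionine-rich prion-like domains (MR-PrLDs) are low-complexity sequence
stretches, compositionally similar to yeast prion domains but enriched in
methionine, that can act as redox switches for liquid–liquid phase
separation: reversible oxidation of methionine to methionine sulfoxide
changes the side chain's polarity and with it the domain's self-association
behaviour. `metcensus` implements a proteome-wide census of such domains
and the accompanying characterisation analyses: spatial statistics of
methionine placement, domain calling and scoring, structural compactness,
and a GO-similarity network comparison of MR against non-MR prion-like
proteins.

# Spatial statistics of methionine placement

## The transect statistic q

Each protein's effective sequence (the canonical sequence with an
initiator methionine at position 1 removed) is divided into consecutive
transects of 50 residues and the methionines are counted per transect. The
aggregation index is the coefficient of variation of those counts,

$$ q = \frac{\sqrt{N \sum_{i=1}^{N} (x_i - \bar{x})^2}}{\sum_{i=1}^{N} x_i}, $$

the population standard deviation over the mean, with $N$ the number of
segments and $x_i$ the count in segment $i$. The transect length of 50 is
matched to the ~2% average methionine frequency: a random arrangement then
yields Poisson-like counts with expectation 1 per segment, for which the
coefficient of variation is close to 1. Values well above 1 indicate
clustering; values well below 1 indicate dispersion. Note that $q \approx 1$
is specific to that density: at higher methionine frequency the random
expectation of $q$ is $1/\sqrt{\lambda}$ with $\lambda$ the expected count
per segment, which is why significance is never read off $q$ directly but
from a per-protein null.

Two dialects handle a length not divisible by 50: the default `ceil` rule
keeps a final short segment holding the remainder; `merge` folds the
remainder into the last full segment. The published calibration value for
accession O75400 ($q = 1.627$) would adjudicate between the dialects, but
computing it requires the full canonical sequence — an external input the
package does not bundle (`inst/extdata/O75400.fasta` if the user supplies
it). The default therefore remains `ceil`, the rule that discards no
positional information.

## Per-protein empirical nulls and classification

For a protein of effective length $N$ with $m$ methionines, the null
places $m$ ones uniformly without replacement among $N$ positions and
recomputes $q$; the default is $B = 10{,}000$ replicates. Conditioning on
the protein's own $(N, m)$ absorbs the dependence of $q$'s null
distribution on size and abundance. A protein is called `aggregation` when
the fraction of null values at or above the observed $q$ falls below
$\alpha = 10^{-4}$, `dispersion` for the lower tail, otherwise `random`.

Numerical choices:

* Empirical tail fractions use the plug-in estimator $r/B$ rather than
  $(r+1)/(B+1)$, because $\alpha = 10^{-4}$ at $B = 10^4$ is attainable
  only as $r = 0$ (the observed value must fall strictly outside the
  entire null sample). The estimator is documented as anti-conservative.
* Ties count toward both tails (inclusive comparisons), so the two tail
  fractions sum to at least 1.
* Proteins with $m = 0$ or fewer than two segments are `not_evaluable` and
  excluded from category percentages.
* Per-protein seeds derive from a global seed and a polynomial hash of the
  accession (modulo $2^{31}-1$), making proteome-scale runs reproducible
  and independent of input order.

A consequence of fixed transects worth knowing: a planted cluster that
straddles a transect boundary splits its signal between two counts. In
short proteins (few segments) this costs real power — a 10-methionine
cluster in a 30-residue window of a 200-residue protein is recovered far
less often than the same cluster in a 1000-residue host, because a
4-segment count vector simply cannot be extreme enough at
$\alpha = 10^{-4}$ once the cluster is split. The recovery benchmarks in
the test suite therefore plant domains in 1000-residue hosts, the size
scale at which the census's own positives live (aggregation-class proteins
are larger than average).

# MR-PrLD calling

A domain is called when four criteria hold simultaneously:

1. the host protein is in the `aggregation` class;
2. the stretch is a methionine-contributed low-complexity region;
3. the stretch matches a prion-like domain;
4. the stretch contains at least 5 methionines.

## The methionine bias scan (criterion ii)

`metBiasRegions()` is a lowest-probability-subsequence scan: every window
delimited by two methionines is scored by the binomial upper tail
$P[X \ge k]$, $X \sim \mathrm{Bin}(n, p_0)$, with $n$ the window length,
$k$ its methionine count and $p_0$ a background methionine probability
(default: the pooled initiator-stripped frequency of the input proteome;
a per-protein override exists, since bias-scanning tools offer several
baselines and no single one is canonical). The globally most surprising
window is emitted if its tail probability is below $10^{-5}$, its
methionines are masked, and the scan repeats on the flanking stretches.
Window lengths are constrained to $[10, 1000]$; a methionine span shorter
than 10 is scored at $n = 10$, its shortest admissible containing window,
which makes the scan's minimum provably equal to the minimum over all
length-constrained windows (trimming a window to its outermost methionines
never increases the tail probability). Reported coordinates are always
methionine-trimmed, 1-based and inclusive, in canonical full-sequence
numbering.

## The prion-likeness posterior (criterion iii)

`prldPosterior()` is a two-state hidden Markov model (background /
prion-like), each state emitting residues i.i.d. from a bundled
composition table: the background table approximates average proteome
composition (methionine pinned at 0.02); the prion-like table is strongly
Q/N/S/G-enriched with a mild methionine weight. Transitions are
parameterised by expected segment lengths (defaults 1000 residues
background, 100 prion-like; the exit probability of each state is the
reciprocal), the chain starts at its stationary distribution, and
per-residue posteriors come from the scaled forward–backward algorithm.
Ambiguity codes emit uniformly in both states. All emission and transition
parameters are configuration, since no published parameterisation is being
replicated bit-exactly; adapters (`readFlpsRegions()`,
`readPlaacPosterior()`) accept external scan outputs as drop-in
replacements for either internal component.

Prion-like regions are maximal runs of posterior $\ge 0.9$ of at least
`minCore` residues (default 60, the conventional core length for
prion-domain detection). Posterior decoding erodes a few residues at each
boundary of a true segment — the evidence inside the segment must overcome
the transition penalty before the posterior crosses 0.9 — so a detector
whose minimum run length equals the length of the domains being sought is
degenerate by construction. The recovery experiments in the test suite,
which plant 60-residue domains, run this filter at 40 residues and say so;
the default stays 60 for survey use, where domains of interest are
typically longer.

## Calling and scoring (criteria i, iv; the census score)

For every bias-region/prion-region pair with positional overlap, the
emitted domain is their intersection span (`union` and `containment` are
config options; "the LCR must match a PrLD" does not by itself fix the
geometry, and the intersection is the most conservative choice). Spans
with fewer than 5 methionines are dropped; duplicate spans are merged;
multiple domains per protein are allowed. Each domain of length $n$ with
$x$ methionines is scored by the exact binomial upper tail

$$ p\text{-value} = P[X \ge x], \qquad X \sim \mathrm{Bin}(n, p), $$

where $p$ is the whole-protein methionine relative frequency
(initiator-stripped, consistent with the rest of the package), and the
census is ranked by ascending p-value with ties broken by accession and
start coordinate. These p-values order the census; they are not corrected
for the selection of the spans.

# Structural compactness

The compactness index of a chain is $I_c = d / N$: the Euclidean distance
in ångströms between the Cα atoms of the first and last residues that
carry one, divided by the residue count. Lower is more compact. Structures
that cannot provide two terminal Cα atoms are skipped with a logged
reason. Group-level significance uses empirical null distributions of the
group-mean $I_c$: each replicate draws `sampleSize` distinct proteins
(default 49) from a reference pool, in one of three modes — unrestricted;
size-matched (each target protein matched by a pool protein within ±10%
relative length); or methionine-matched (within ±0.005 absolute relative
frequency). The matching tolerances are package choices (no published
values exist); when no unused candidate matches, the tolerance doubles
with a message. The reported p-value is the lower-tail fraction of null
means at or below the observed mean, the directional form of a "more
compact than expected" claim; a two-sided flag exists. A p of 0 at $B$
replicates is reported as "< 1/B".

# The GO-similarity network

Proteins (labelled `MR` / `NonMR`) are nodes; an edge joins two proteins
whose GO term sets have Jaccard similarity $\ge 0.25$ (inclusive). Term
sets are used exactly as annotated — no ancestor propagation, and all
three ontology aspects pooled (an aspect filter exists in `readGaf()`).
The Jaccard of two empty sets is undefined and is taken as 0 (no edge),
with a message.

Mixing is quantified by Newman's nominal assortativity over the edge
mixing matrix,
$r = (\sum_i e_{ii} - \sum_i a_i b_i) / (1 - \sum_i a_i b_i)$,
implemented directly from the formula (the igraph implementation serves as
an independent cross-check in the tests, not as the implementation).
Isolated nodes do not contribute; an edgeless graph is not evaluable. Two
permutation controls give significance, both upper-tailed (positive
assortativity is the claim) with plug-in p-values: `relabelTest()` keeps
the topology and label counts and permutes labels ($10^5$ replicates by
default); `resampleTest()` rebuilds the graph from random samples of an
annotation pool, labels at the observed proportion, and recomputes $r$
($10^3$ replicates), skipping non-evaluable replicates with a message.
Under the relabelling null the expectation of $r$ is not exactly 0 but
carries a small negative $O(1/n)$ bias, which the tests acknowledge.

GO term enrichment is the upper-tail hypergeometric test with Bonferroni
correction over the number of tested terms. Fold enrichment is the ratio
of proportions $(k/n)/(K/N)$; a ratio of raw counts would not be a
dimensionless fold and is not used.

# Synthetic data: what it emulates, what it does not

The generators provide every input the pipeline consumes, deterministically
under a seed (byte-identical files):

* **Proteomes** — lognormal lengths (meanlog 6.1, sdlog 0.6, truncated to
  [100, 5000], roughly human-like), an initiator methionine at position 1,
  i.i.d. 2% methionine elsewhere, other residues from the background
  table. Subpopulations: ~2.5% of proteins with no methionine beyond the
  initiator (the conspicuous zero-Met group, ~500 of ~20,000 in a real
  proteome), and a planted fraction carrying either an exact-count
  methionine cluster in a uniform window (never covering position 1) or a
  60-residue prion-composition segment with methionine weight 1/3 — the
  density of the strongest reported MR-PrLDs (reported domains span
  roughly 19–33% methionine).
* **Structures** — single-chain Cα-only PDB files: collinear chains at
  3.8 Å spacing (terminal distance exactly $3.8(N-1)$) and freely jointed
  random walks (mean squared end-to-end distance $(N-1)\,3.8^2$).
* **GO annotations** — GAF 2.2 plus a label table; two groups draw term
  sets from group pools whose size controls within-group Jaccard and whose
  shared fraction controls between-group Jaccard, so planted assortativity
  is tunable from degenerate (identical within, disjoint between) to none.

What the synthetic data does **not** emulate: real residue correlations
(actual sequences are not i.i.d.), isoforms, genuine protein geometry
(random walks are not folds), the GO DAG (terms are unstructured tokens),
or any particular database release. Green tests on synthetic data
therefore certify the statistical machinery — calibration of the nulls,
recovery of planted signal, exactness of the scores — not agreement with
any specific proteome snapshot, whose published counts (proteins retained,
zero-Met group size, category percentages) depend on the release used.

# Problem sizes and determinism

The test suite runs the null-calibration checks at 2000 proteins of 1000
residues with $B = 10^4$ nulls each, the recovery benchmarks at 100–200
planted proteins, and the end-to-end census at 1000 proteins with 20
plants — sizes at which the Monte Carlo assertions (3-SE bands, >90/95%
recovery rates) are stable across seeds. Every stochastic component takes
an explicit seed and restores the caller's RNG state. Binomial and
hypergeometric tails are delegated to R's `pbinom`/`phyper`; the test
oracles recompute them by log-space term summation, with comparisons
restricted to the normally-representable double range (below ~1e-290,
relative error reflects subnormal granularity rather than arithmetic).

# Known limitations

* The transect statistic is insensitive to clusters split by a segment
  boundary, materially so in proteins under ~300 residues (see above).
* The plug-in empirical p-values are anti-conservative at the extreme
  $\alpha$ used; with $B = 10^4$, `aggregation` means "outside the whole
  null sample".
* Census p-values are selection-unadjusted ranks, not calibrated tail
  probabilities.
* The HMM is a generic two-state compositional model, not a bit-exact
  replication of any published prion-domain predictor; adapters exist for
  ingesting external predictions where exact parity matters.
* Membrane status is an input list; the package does not derive it.
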