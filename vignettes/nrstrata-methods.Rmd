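---
title: "Methods: NR-expression stratification and signed network motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NR-expression stratification and signed network motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrstrata)
```

This vignette is the package's own account of its models and the choices
behind them: what each stage assumes, which knobs matter, what the
synthetic generator does and does not emulate, and where the design was
genuinely open.

## 1. Stratification by Bayesian hierarchical clustering

### Discretisation

Each gene is treated as an independent three-level variable: expression
below the per-gene lower quantile cut (tertiles by default) codes 0
("lower bound"), above the upper cut codes 2 ("upper bound"), and the
band in between codes 1 (the "signal"). The cuts are rank-based, so any
monotone transformation of a gene leaves its codes unchanged — a useful
robustness property for cross-platform expression data. Ties with either
cut fall into the middle bin (the comparisons are strict), and a
constant gene is coded all-middle and flagged rather than dropped, so
the sample space stays rectangular. The quantile positions `lower_q`,
`upper_q` are configuration because nothing forces tertiles; they are
the natural reading of a lower/signal/upper three-way split.

### The clustering model

Samples are clustered by greedy agglomeration under a Dirichlet-process
mixture of per-gene multinomials. For a candidate cluster
$\mathcal{D}_k$ of $n_k$ samples the marginal likelihood is a product
over genes of Dirichlet–multinomial integrals

$$
p(\mathcal{D}_k \mid H_1) \;=\; \prod_g
\frac{\Gamma(\beta_\cdot)}{\Gamma(n_{gk}+\beta_\cdot)}
\prod_{b=0}^{2} \frac{\Gamma(c_{gkb}+\beta_b)}{\Gamma(\beta_b)},
$$

with bin counts $c_{gkb}$, per-bin pseudocounts $\beta_b$ (default 1,
i.e. a uniform prior) and $\beta_\cdot=\sum_b\beta_b$. Genes are assumed
independent given the cluster — the standard naive-Bayes simplification
that makes the integral closed-form.

The tree prior follows the Heller–Ghahramani recursion: with
$d_{\text{leaf}} = \alpha$ and
$d_k = \alpha\,\Gamma(n_k) + d_{\ell}d_{r}$ for a merge of subtrees
$\ell, r$, the prior mass on "these $n_k$ samples are one cluster" is
$\pi_k = \alpha\,\Gamma(n_k)/d_k$, and the subtree evidence is

$$
p(\mathcal{D}_k \mid T_k) \;=\;
\pi_k\, p(\mathcal{D}_k \mid H_1) \;+\;
(1-\pi_k)\, p(\mathcal{D}_\ell \mid T_\ell)\, p(\mathcal{D}_r \mid T_r).
$$

At every step the pair with the highest posterior merge probability
$r_k = \pi_k p(\mathcal{D}_k \mid H_1)/p(\mathcal{D}_k \mid T_k)$ is
merged, and the node stores
$\log\text{odds}_k = \log\frac{\pi_k p(\mathcal{D}_k\mid H_1)}
{(1-\pi_k)p(\mathcal{D}_\ell\mid T_\ell)p(\mathcal{D}_r\mid T_r)}$.
Everything is computed in log space (log-sum-exp for the two-term sums),
so cohorts of several hundred samples pose no under/overflow risk. The
concentration $\alpha$ defaults to 1 and is configuration; the defaults
follow the original Bayesian hierarchical clustering literature rather
than any fit to data. For $n \le 8$ the implementation is tested against
an independent raw-space recursion that recomputes every quantity from
scratch.

Determinism: merge ties are broken by the lexicographically smallest
pair of subtree ids. Samples enter as leaves in input order, but the
test suite asserts that cluster memberships are invariant to permuting
the input columns.

### Clusters, classes, labels

*Clusters* are the maximal subtrees whose internal fusions all have
positive log odds; fusions with non-positive odds live "further up" the
hierarchy and are not applied. Whether to cut strictly at zero or to use
some preferred-merge heuristic was an open choice; the zero cut is
adopted because the log odds is exactly the evidence for merging, and it
is documented here rather than hidden.

*Classes* simplify clusters for small-cohort network inference: starting
from the whole tree, the latest fusions are undone one at a time — never
splitting inside a cluster — until every group is a whole cluster or a
union of clusters, capped at `max_classes`. "Final or penultimate
fusions" does not by itself pin down a class count, so the cap is a
parameter rather than a guess.

*Labels*: with $f$ the largest subtype fraction in a class, the class is
`dominant` at $f \ge 0.85$, `insubstantial_dominant` at
$0.60 \le f < 0.85$, and `ambiguous` below. Published analyses of this
kind state no numeric rule; these two thresholds reproduce the canonical
worked cases (a 97:1 class is dominant, 50:13 is an insubstantial
dominant class, 20:22 is ambiguous) and are exposed as configuration.
No cluster-significance p-values are produced: the hierarchical model
supplies merge odds, not a null distribution against a background
population.

## 2. Shrinkage partial-correlation networks

Within one patient class (often only tens of samples against ~170
genes), the sample correlation matrix is singular, so the package uses
the analytic-shrinkage estimator: shrink toward the identity with

$$
\lambda^* \;=\;
\frac{\sum_{i\ne j}\widehat{\mathrm{Var}}(r_{ij})}{\sum_{i\ne j} r_{ij}^2},
\qquad
\widehat{\mathrm{Var}}(r_{ij}) = \tfrac{n}{(n-1)^3}\sum_k (w_{kij}-\bar w_{ij})^2,
$$

where $w_{kij}$ are products of standardised observations — the
Schäfer–Strimmer intensity, clipped to $[0,1]$. The shrunk matrix is
inverted (Cholesky) and rescaled to partial correlations. Missing values
are handled pairwise-complete with a minimum overlap of 10 samples per
pair (pairs below the floor get correlation 0); zero-variance genes must
be dropped first and the estimator does so with a message. At
$\lambda = 0$ and $n \gg p$ the estimate provably coincides with
regressing each pair of genes on all others and correlating the
residuals; the test suite enforces agreement to $10^{-6}$.

Thresholding ("marginalised thresholding of 1%") is interpreted as a
**rank cut**: all $\binom{p}{2}$ pairs are ordered by
$|r_{ij}|$ (ties broken lexicographically) and the strongest
$\lceil f \binom{p}{2}\rceil$ become edges — the ceiling guarantees at
least one edge for any positive fraction. The phrase could equally be
read as a magnitude cut $|r_{ij}| > 0.01$; both are implemented
(`threshold_edges(mode = "magnitude")`) and the rank cut is the default
because an order-statistics reading matches "reveal the stronger
correlations, eliminate the weaker". No edge-wise significance test is
applied; the ranked list keeps its weights so users can impose their
own cut. Isolated nodes stay in the node set and are reported.

## 3. Hubs and the NPU triad census

Degree counts positive and negative edges alike; total degree sums over
all analysed networks, ranking ties alphabetically. The hub count
defaults to `k = 2`: the motif analysis this package mirrors proceeds
with the top two genes even though its written definition says "top
three" — an internal inconsistency that is surfaced, not resolved, via
the `k` parameter. Ties crossing the boundary expand the returned hub
list rather than being truncated arbitrarily.

The census classifies each unordered gene triple by its NPU code —
(count of Negative, Positive, Un-associated pairs). Exhaustive
enumeration over the $3^3 = 27$ ordered sign assignments gives 10
distinct codes; codes {021, 201, 111} are the 12 linear (two-edge)
configurations when the hub position is distinguished, and
{120, 210, 030, 300} are the $2^3 = 8$ complete sign configurations.
Complete triads are *coherent* iff their edge-sign product is positive
(an even number of negative edges) — the structural-balance convention,
adopted because the published pictures are not formula-defined.

Hub-associated local networks are the induced subgraphs on all nodes
within two edges of a hub. Census tables count only triples that
**contain the hub** and carry at least two edges, over the seven
edge-bearing codes; the no-edge and one-edge codes (003, 012, 102)
remain classifiable but are excluded from tables. A sensitivity flag
(`hub_all_triples = TRUE`) counts every triple in the local network
instead. For linear motifs the centre gene (adjacent to both others) is
recorded as an attribute; motif identity itself is the unordered gene
set, so orderings that differ only in the middle node are one motif with
a centre annotation.

A triple is *conserved* when it occurs as an edge-bearing hub motif in
at least `min_networks` networks spanning at least `min_cohorts` cohort
tags (defaults 6 and 2, reverse-engineered from the "present in six out
of eight networks across both cohorts" convention; both are
configuration since no numeric enrichment criterion is published). The
same triple may legitimately carry different codes in different
networks — an edge near the threshold can flip a 030 to a 021 — and the
report keeps the per-network codes.

## 4. The synthetic-cohort generator

The generator is the package's ground-truth instrument, not a model of
real tumours. It emulates exactly the features the pipeline's claims
rest on:

* two subtypes with configurable arm sizes; latent classes with class 1
  pure one subtype, class 2 pure the other, and any further class a
  50/50 mixture (the minimal structure exercising
  dominant/ambiguous labelling);
* class-specific mean shifts on a random fraction of "informative"
  genes, in units of each gene's residual standard deviation;
* residuals drawn from a Gaussian graphical model whose precision matrix
  carries a planted hub-star and signed-triad support. A requested
  positive partial correlation is encoded as a negative off-diagonal
  precision entry (and vice versa); positive definiteness is restored by
  diagonal loading until the smallest eigenvalue reaches 0.1, which was
  chosen over a Cholesky-based construction because loading the diagonal
  leaves the planted off-diagonal sign pattern untouched. Conflicting
  sign requests for one edge are a configuration error.

The defaults for recovery experiments are the study conditions used
throughout the tests: 50 genes, 60 + 60 samples, a 3-SD shift on 40% of
genes, and 20 seeds per measurement. Deliberately **not** emulated:
cohort-specific marginal distributions, batch or platform effects,
claudin-low/normal-like subtypes, and any dependence between the
discretised clustering view and the Gaussian residual structure beyond
what discretisation itself induces. Passing recovery tests therefore
demonstrates correctness of the machinery under a well-specified
generative model, not performance on real cohorts.

One sizing fact worth recording: precision of the top-1% network against
the planted support is arithmetically capped by
(planted edges)/(retained edges). With 50 genes the 1% cut retains 13 of
1 225 pairs, so recovery experiments plant 17 edges (three degree-5 hub
stars plus two triads, all implied partial correlations above 0.3);
designs that plant fewer edges than the cut retains cannot reach high
precision no matter how strong the signal.

## 5. Numerical choices and degenerate inputs

* Dendrogram evidence in log space; log-sum-exp for all two-term sums.
* Duplicate gene symbols on input: the highest-variance row wins, with a
  warning (the most variable probe is the most informative one).
* Sample matching between expression and clinical tables is exact string
  equality after whitespace trimming — no barcode-truncation heuristics.
* Median-centring ignores missing values, errors on an all-missing gene,
  and is idempotent, so data that arrive pre-centred pass through
  unchanged.
* Edge ranking ties: lexicographically smaller gene pair first. Degree
  ranking ties: alphabetical. Merge-score ties: smallest subtree-id
  pair.
* `ceiling` (never `floor`) for the retained-edge count.
* Fewer than 3 samples per class, an empty gene-list intersection, a hub
  absent from a network, or `min_networks` exceeding the network count
  are hard errors with stage-specific messages; a constant gene is a
  flagged degeneracy, not an error.

## 6. Problem sizes in the shipped tests

The suite runs synthetic cohorts of 30–150 samples over 10–50 genes,
oracle comparisons at 5–10 genes and up to 8 samples (where the slow
reference recursion is exact), exhaustive motif-census checks on graphs
of up to 15 nodes, and 20-seed replications for all stochastic recovery
claims; these sizes were chosen so each property is exercised well above
its smallest non-trivial case while the whole suite stays quick to run.

## 7. Known limitations

* The greedy agglomeration is a point estimate of the hierarchy; no
  merge-order uncertainty or randomised restarts are provided.
* The gene-wise (transposed) clustering strategy is out of scope, as are
  survival analysis and any enrichment testing of motifs against
  degree-preserving null models.
* The class-consolidation rule is one defensible reading of
  "final or penultimate fusions"; alternative readings would shift class
  boundaries on cohorts whose top fusions are nearly tied.
* With very small classes (tens of samples against hundreds of genes)
  the shrinkage intensity approaches 1 and the network degenerates
  toward the strongest marginal correlations; the per-network
  `shrinkage_intensity` is reported precisely so such runs are visible.
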