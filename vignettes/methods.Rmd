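---
title: "Methods: similarity network fusion and miRNA set enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity network fusion and miRNA set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirfuse)
```

## Overview

`mirfuse` implements enrichment analysis of a miRNA list in three
stages: (1) construct miRNA functional similarity networks from
heterogeneous evidence, (2) fuse them and expand the input list by
network diffusion, (3) test the expanded list against a miRNA-set
knowledge base. This vignette documents the model assumptions, the
parameters that matter, the numerical conventions, and the design
choices that were genuinely open — with the reasoning behind each.

## Disease-association similarity (miRSN-DA)

The hierarchical structure of disease vocabularies is exploited by
assigning each disease a decayed contribution profile over its
ancestor closure. The contribution is computed bottom-up over a
topological order of the closure,

$$D_d(d) = 1,\qquad D_d(t) = \max_{t' \in \mathrm{children}(t)} \Delta\, D_d(t'),$$

which equals $\Delta^{h}$ for $h$ the minimum hop count from $d$ up to
$t$: the max rule means the shortest path carries the contribution.
The test suite checks the bottom-up recursion against an independent
breadth-first-search distance oracle on random DAGs. The
"children of $t$" in the recursion are necessarily children within the
closure — the contribution is undefined elsewhere — which is the only
consistent reading of the recursion.

Two diseases are compared by their shared closure,
$S = \sum_{t\in T_i\cap T_j}(D_i(t)+D_j(t)) / (DV_i+DV_j)$, and two
miRNAs by best-match averaging of their associated disease sets
(MISIM). The similarity network is recomputed here from raw
association tables rather than imported from a precomputed similarity
service, so the package has no web dependency and the computation is
auditable end to end.

**Decay $\Delta$** defaults to 0.5, the conventional setting for this
family of semantic similarity measures; it is exposed in the API and
the pipeline config. Associations to diseases absent from the ontology
are dropped with a log message; a miRNA that loses all its diseases is
excluded from the network, because the best-match rule is undefined on
an empty set.

## GO-annotation similarity (miRSN-GOA)

Gene sets are closed over the true-path rule before anything else:
$G_x$ is the set of genes annotated to $x$ *or any descendant*, which
guarantees $G_{\text{child}} \subseteq G_{\text{parent}}$ and hence
monotone information content $IC(x) = -\ln(|G_x|/|G_{\text{root}}|)$.
Terms with no annotated gene are pruned before IC is defined.

Term-pair similarity combines the most informative lowest common
ancestor (LCA) and highest common descendant (HCD):

$$\mathrm{Sim}(x,y) = \min\!\left(1, \frac{IC_L + IC_H}{IC(x) + IC(y)}\right),$$

with $IC_L$ ($IC_H$) the maximum IC over the LCA (HCD) set and
$IC_H = 0$ when no common descendant exists. This form was an open
design point and we fixed it on three grounds: it is symmetric,
self-similarity is exactly 1 for any non-root term, and with an empty
HCD it reduces to a Lin-style shared-ancestor similarity while still
rewarding pairs that share descendants, which is the point of using
the HCD at all. Where the LCA or HCD set has several members we take
the maximum IC — the most informative witness — rather than an
average; both roots (IC sum 0) degenerate to similarity 1 for
identical terms and 0 otherwise.

Each term is weighted per miRNA by its hypergeometric surprise
$w_x = -\ln P(X \ge k)$ (background $N$, annotated $M$, targets $n$,
annotated targets $k$), so uninformative high-level terms that cover
most of the background get weights near zero. miRNA-pair similarity
is a symmetrized, weight-normalized best-match aggregation:

$$s(q\to t) = \sqrt{\frac{\sum_x (\mathrm{Sim}(x, B_t)\, w_x)^2}{\sum_x w_x^2}},
\qquad \mathrm{Sim}_{qt} = \tfrac12\big(s(q\to t) + s(t\to q)\big).$$

The normalization and the extent of the radical were also open; the
chosen form is bounded in $[0,1]$ and equals 1 exactly on identical
annotation profiles, which a fusion by averaging requires. All
logarithms in this module are natural; only ratios of logs enter the
term similarity, so the base only rescales the weights uniformly.

## PPI similarity (miRSN-PPI)

Two miRNAs are similar when their target genes sit close together on
the interaction network: the score is the reciprocal of the mean
shortest-path hop distance over all reachable target pairs, capped at
1 so all three networks share the $[0,1]$ scale that averaging fusion
assumes. Unreachable pairs are excluded from both numerator and
denominator rather than given a penalty distance (a diameter-based
penalty would make scores depend on an arbitrary constant); the
degenerate all-zero-distance case (identical single targets) is
defined as similarity 1, and no reachable pair at all as 0. Edges are
undirected and unweighted, with duplicates and reversals collapsed.

## Fusion

Fusion is a single simultaneous per-pair mean over the networks that
contain both miRNAs. A sequential pairwise description
$((A+B)/2+C)/2$ is order-dependent; the simultaneous mean is its
order-free generalization, and order independence is asserted in the
tests over permutations of three networks. miRNAs known to only one
network keep their similarity information; a pair split across two
networks (each miRNA known to only one) has no evidence in any single
network and gets 0. The default pipeline fuses the disease and GO
networks, the combination that performs best for enrichment; any
subset is selectable.

## Random walk with restart and list expansion

The fused network is thresholded at the similarity coefficient
$\tau = 0.6$ (edges **at or above** $\tau$ are retained — the boundary
case is unstated in prose descriptions of "greater than"/"less than",
and we fix it as inclusive), the diagonal is zeroed, and columns are
normalized to give the walk matrix $W$; dangling columns stay zero.
Edge weights are retained so the walk is biased toward more similar
neighbors rather than binarized.

The walk iterates $r \leftarrow cWr + (1-c)e$ from $r_0 = e$, $e$
uniform over the seeds, to convergence in L1 below `tol = 1e-10`. The
coefficient $c$ multiplies the walk term — so the restart mass is
$1-c$ — and defaults to 0.85, a standard choice for diffusion on
biological networks; it is configurable. Convergence is geometric
with contraction factor at most $c$, and the iterative solution is
tested against the direct linear solve
$(1-c)(I - cW)^{-1}e$ on networks up to 12 nodes.

Candidates for expansion are the non-seed nodes with positive score
(seeds are already in the list); the top
$\lfloor 0.5\,|{\text{candidates}}|\rfloor$ by score are added, with
ties at the cut broken lexicographically by miRNA id so reruns are
byte-identical. Input miRNAs absent from the network cannot seed the
walk but are carried through to the expanded list untouched.

## Enrichment

Each knowledge-base set is tested with the upper-tail hypergeometric
p-value, inclusive of the observed overlap. The universe $N$ is the
union of knowledge-base members: the hypergeometric model requires the
sample to be drawn from the universe, so input miRNAs outside it are
dropped from the effective list size (with a log message).
Benjamini–Hochberg correction is applied jointly across all sets of
all categories (per-category correction is available by subsetting the
knowledge base); significance is FDR < 0.05. Hit rates are reported
as percentages rounded half-up to two decimals, matching the
convention of the published case-study arithmetic the tests reproduce
(91/315 → 28.89, 204/315 → 64.76, and so on).

## Synthetic data

The generators produce every input format from a single integer seed,
with one named pseudo-random stream per generator so adding a
generator never perturbs another's draws. The planted-module scenario
is the end-to-end benchmark: 60 miRNAs of which 20 form a module with
within-module similarity drawn from $[0.8, 0.95]$ in two of the three
networks and background similarity in $[0.05, 0.3]$ elsewhere; the
knowledge base holds the module plus 25 random decoy sets and the
input list is half the module. The effect sizes were chosen once so
that the fused within-module similarity clears the default $\tau=0.6$
while the background does not — the regime the method is designed
for — and are arguments, not constants.

What the generators do *not* emulate: the long-tailed degree and
annotation-size distributions of real association databases,
mature/precursor id ambiguity, annotation bias toward well-studied
miRNAs, or correlated evidence across the three networks. Passing the
planted-module tests therefore demonstrates the machinery — diffusion
recovers held-out module members and the enrichment test ranks the
module first — not performance on any real knowledge base.

## Numerical conventions and degenerate inputs

* Similarity matrices are validated square, symmetric, unit-diagonal,
  finite and non-negative; asymmetry up to `1e-9` (accumulated
  floating-point noise) is symmetrized by averaging with a log
  message, anything larger is an error reporting the worst deviation.
* Matrix TSVs use tab separation, `.` decimal and 12 significant
  digits, making write/read round trips stable below `1e-12`.
* Ontology files are validated acyclic at read time, reporting one
  cycle on failure; self-parent edges are rejected outright.
* Empty disease sets, miRNAs with no usable annotation, and input
  lists disjoint from the knowledge-base universe are errors or
  logged exclusions at the earliest stage that can detect them.

## Problem sizes

The test suite and acceptance script run on deliberately small
problems: oracle enumerations cover all hypergeometric configurations
up to $N = 12$, the random-walk oracle 200 random networks of up to 12
nodes, and the end-to-end benchmark 60 miRNAs. These sizes make every
oracle exhaustive and the whole suite fast; the implementation itself
is vectorized over dense matrices and comfortably handles the
thousand-miRNA scale of real association databases, where the cubic
all-pairs similarity construction dominates runtime.

## Known limitations

* MISIM is recomputed from raw associations; enhancements that
  curated similarity services layer on top of the published recursion
  (expanded association corpora, score recalibration) are not
  reproduced.
* The GO module treats all three GO namespaces as one graph unless the
  caller filters terms beforehand, and ignores evidence codes.
* PPI edges are unweighted; confidence scores are discarded at import.
* The walk supports only a uniform restart vector over seeds.
* Published case-study tables depend on specific database snapshots
  and are not reproducible from the package's inputs; only their
  hit-rate arithmetic is asserted.
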