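# mirfuse

miRNA set enrichment analysis over fused functional similarity
networks.

Plain over-representation analysis of a miRNA list — say, the
differentially expressed miRNAs of a tumor/normal contrast — tests the
list as-is against curated miRNA sets and misses members of the same
functional module that did not pass the differential-expression
filter. `mirfuse` addresses this by *expanding* the list over a
miRNA–miRNA association network before testing it: miRNAs that are
functionally close to the input list are pulled in by network
diffusion, which raises the overlap (hit rate) with the relevant
curated sets and sharpens the enrichment signal.

The package is aimed at computational biologists who have a miRNA list
and tabular association data (miRNA–disease associations, miRNA
target genes, GO annotations, a protein–protein interaction network)
and want a reproducible, scriptable enrichment pipeline.

## Model

Three miRNA functional similarity networks are built from independent
evidence:

* **miRSN-DA** — disease-association similarity. Each disease *d* on a
  MeSH-like DAG gets semantic contributions over its ancestor closure
  T(d): D_d(d) = 1 and D_d(t) = max over children t′ of Δ·D_d(t′),
  with decay Δ = 0.5, so D_d(t) = Δ^(shortest hop distance). Disease
  similarity is S(d_i, d_j) = Σ_{t ∈ T(d_i) ∩ T(d_j)} (D_i(t) + D_j(t))
  / (DV(d_i) + DV(d_j)) with DV(d) = Σ_t D_d(t). Two miRNAs are then
  compared by best-match averaging of their disease sets:
  MISIM(m1, m2) = (Σ_i S(d1i, D2) + Σ_j S(d2j, D1)) / (m + n).
* **miRSN-GOA** — GO-annotation similarity of target genes. Term
  information content is IC(x) = −ln(|G_x| / |G_root|) over
  true-path-closed gene sets; term similarity combines the most
  informative lowest common ancestor and highest common descendant,
  Sim(x, y) = min(1, (IC_L + IC_H) / (IC(x) + IC(y))); each term is
  weighted by its hypergeometric surprise w_x = −ln P(X ≥ k) for the
  miRNA's targets, and miRNA similarity is the symmetrized, weighted
  best-match Euclidean aggregation of term similarities.
* **miRSN-PPI** — shortest-path proximity of target genes on a
  protein–protein interaction network: the reciprocal of the mean
  pairwise distance between the two target sets, capped at 1.

Networks are fused by per-pair averaging over the networks that cover
both miRNAs (single-network information is carried over). The fused
network is thresholded at similarity coefficient τ = 0.6, the input
list seeds a random walk with restart r = cWr + (1 − c)e on the
column-normalized walk matrix W, and the top 50% of positively scored
non-seed nodes join the expanded list. The expanded list is tested per
knowledge-base set with the upper-tail hypergeometric test
p = Σ_{i=m}^{min(n,M)} C(M,i)C(N−M,n−i)/C(N,n) over the knowledge-base
universe N, with Benjamini–Hochberg FDR control at 0.05.

## Worked example

The built-in planted-module benchmark generates a 60-miRNA scenario in
which 20 miRNAs form a functional module with high similarity in two
of the three networks, the knowledge base holds that module plus 25
decoy sets, and the input list is half the module:

```r
library(mirfuse)

sc    <- gen_planted_scenario(seed = 7)   # n = 60, module = 20
fused <- fuse_networks(sc$networks[c("da", "goa")])
res   <- expand_mirna_list(fused, sc$input_list)  # tau = 0.6, c = 0.85

hit_rate(length(intersect(sc$input_list, sc$module)), 20)
#> [1] 50
hit_rate(length(intersect(res$expanded_list, sc$module)), 20)
#> [1] 75

rows <- enrich(res$expanded_list, sc$kb)
head(rows[, c("set_name", "set_size", "overlap", "p_value", "fdr")], 2)
#>         set_name set_size overlap      p_value          fdr
#> 1 planted-module       20      15 2.914610e-10 7.577985e-09
#> 2       decoy-07       11       5 9.229558e-02 8.983804e-01
```

Expansion recovers 5 of the 10 held-out module members, lifting the
module set's hit rate from 50% to 75%, and the planted set ranks first
among the 26 knowledge-base sets with an FDR far below 0.05.

The same analysis runs from the shell on TSV/GMT files:

```sh
Rscript inst/cli/mirfuse.R simulate --out sim/ --seed 7
Rscript inst/cli/mirfuse.R fuse --networks sim/mirsn_da.tsv,sim/mirsn_goa.tsv --out fused.tsv
Rscript inst/cli/mirfuse.R expand --network fused.tsv --list sim/input_list.txt --out exp/
Rscript inst/cli/mirfuse.R enrich --list exp/expanded_list.txt --gmt sim/kb.gmt --out rows.tsv
```

or end to end from a YAML config with `run_pipeline()` /
`mirfuse.R run-all --config config.yaml`, which also writes a
machine-readable manifest of inputs, parameters and per-stage counts.

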