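---
title: "From chromatin contacts to a multimorbidity atlas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From chromatin contacts to a multimorbidity atlas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multimorbid)
```

# The model

Trait-associated variants are overwhelmingly non-coding, and assigning them
to the nearest gene misses regulatory relationships mediated by chromatin
looping. This package identifies a variant's candidate target genes by
physical contact: a SNP and a gene form a *spatial pair* when the
restriction fragment harbouring the SNP is captured, in a Hi-C library, in
contact with any fragment overlapping the gene's composite region. Spatial
pairs with a significant eQTL association are *spatial eQTL–eGene pairs*,
and phenotypes are then related to each other by how many spatial eGenes
they share.

## Fragments, SNPs, genes

The digest cuts at the 5′ start of every occurrence of the recognition
sequence (default `GATC`, the MboI site used by the high-resolution Hi-C
libraries this analysis is designed around). Fragments are 0-based
half-open, tile each chromosome exactly, and carry the per-chromosome
ordinal index that interaction files reference. A zero-length fragment
(site at position 0) is dropped. SNP input positions are 1-based (the
convention of variant and association files) and converted once at ingest;
a SNP maps to exactly one fragment. Gene isoforms are collapsed to their
union span — introns and inter-isoform gaps included — and a gene region
maps to *every* fragment it overlaps by at least one base pair, with no
binning or padding. A SNP landing exactly on a cut site has no
well-defined fragment; the generator never produces one and real input
raises an error naming the record.

## Contact counting

Both ends of an interaction record are treated symmetrically: whichever end
matches a SNP fragment, the other end is tested for gene overlap. A record
whose two ends both hold SNPs contributes to both SNPs, and a partner
fragment overlapping k genes contributes one observation to each of the k
pairs (overlap is defined per composite gene region; there is no
exclusivity rule). Per (SNP, gene) pair we report *fragment interactions*
(distinct contact pairs of fragments) and *supporting interactions*
(replicate-level observations), plus the distinct cell lines and
(cell line, replicate) combinations observing the pair. All pairs with at
least one supporting interaction are retained and the counts carried
forward — support thresholds are an explicit downstream filter
(`min_support`), not a hidden default — because support-stratified
enrichment analysis needs the single-observation pairs. Identical read
names in different replicate files are counted per row; no cross-file
deduplication is attempted.

The enrichment itself is a pooled two-proportions Z-test comparing the
eQTL-significant fraction among pairs with support > 1 against pairs seen
exactly once, with a two-sided normal p-value.

## eQTL calling

Spatial pairs absent from the eQTL table have no test and are excluded
*before* multiple testing, so the Benjamini–Hochberg family consists only
of tested SNP–gene–tissue rows. Adjustment is applied once, jointly, across
all surviving rows — the single-family reading of a pipeline that adjusts
after exclusion — with per-tissue adjustment available via
`per_tissue = TRUE`. Significance is `p_adjusted <= 0.05`; the source
conventions waver between strict and non-strict inequality, we use ≤ and
expose the threshold.

Classification uses a 1 Mb window: same chromosome and distance < 1 Mb is
*cis*, same chromosome at or beyond is *trans_intra*, different chromosomes
*trans_inter*. Distance is zero for a SNP inside the composite region and
otherwise the gap to the nearest region edge, computed as
`max(0, start − pos, pos − end)` with the 1-based SNP position against the
0-based half-open region. This matches the natural "bases between" reading
on the left edge and is one off from it on the right edge; since the
anchor point of the window (TSS versus region edge) is itself a design
choice — we chose the edge because regions are collapsed isoform spans —
the one-base asymmetry is far below any decision boundary of interest.

## Sharing matrices and the permutation null

A phenotype is the trait associated with a SNP; when one study associates a
SNP with several traits simultaneously those traits form a *composite*
phenotype, labelled by the sorted trait names joined with `"|"` (labelling
must be deterministic; the order of traits in the input is not). Each
(SNP, study) group contributes its eGenes to exactly one phenotype. The
sharing ratio

$$a_{ij} = \frac{|S_i \cap S_j|}{|S_i|}$$

is asymmetric; its diagonal is 1 and $a_{ij} n_i = a_{ji} n_j$ recovers the
integer intersection size — an identity the test suite checks on random
sets. Only phenotypes with at least `min_count = 4` eGenes enter the
biclustering; we apply the filter to the phenotype's *own* eGene count
(rather than to pairwise common counts, the other reading the wording
admits) and expose both knobs.

The null pools all eGenes and redraws each phenotype's set uniformly
without replacement, preserving its size, independently across phenotypes
(a gene may serve several null phenotypes, mirroring real sharing). This
choice gives a closed-form expectation,
$E[a_{ij}] = n_j / N$ with $N$ the pool size, which the tests verify to
within three Monte-Carlo standard errors at 1000 replicates. Whether the
original analysis drew with or without replacement within a phenotype is
not stated; without replacement keeps null set sizes exact.

## Convex biclustering

The smoothed matrix at penalty $\gamma$ minimises

$$F_\gamma(U) = \tfrac12\|X - U\|_F^2 +
  \gamma\Big[\sum_{(i,j)} w_{ij}\,\|U_{\cdot i}-U_{\cdot j}\|_2 +
  \sum_{(k,l)} \tilde w_{kl}\,\|U_{k\cdot}-U_{l\cdot}\|_2\Big],$$

a strictly convex problem whose solution path interpolates between the data
($\gamma = 0$) and the grand-mean matrix (fully fused limit, provided both
fusion graphs are connected).

**Weights.** Column weights are a Gaussian kernel
$\exp(-(\phi/m)\,d^2)$ truncated to each column's $k$ nearest neighbours
and symmetrised by union; rows analogously. Kept weights are normalised to
sum to $1/\sqrt{n}$ (columns) and $1/\sqrt{m}$ (rows), the convention of
reference convex-biclustering implementations. The normalisation matters:
it balances the two penalties and puts the informative range of $\gamma$
on the $10^0$–$10^3$ scale that the 100-point log-spaced default grid
covers; with raw kernel weights that whole grid over-smooths a typical
sharing matrix. $\phi = 0.5$ and $k = 5$ are conventional defaults, both
exposed. If truncation disconnects a graph, $k$ is escalated with a
warning — connectivity is required for a unique fused limit.

**Solver.** We minimise $F_\gamma$ by majorisation–minimisation on an
$\varepsilon$-smoothed objective: each norm $\|v\|$ becomes
$\sqrt{\|v\|^2+\delta^2}$ with $\delta = 10^{-8}\,\mathrm{sd}(X)$, and the
resulting quadratic majoriser — a pair of weighted graph Laplacians — is
minimised exactly per step by solving the Sylvester equation
$U + L_r U + U L_c = X$ via eigendecomposition. The objective sequence is
monotone non-increasing (asserted in tests at every $\gamma$, with
floating-point slack), and iteration stops when the relative objective
change falls below `tol` (default `1e-6`; `max_iter` reached returns the
current iterate with a warning). Two numerical guards: an input whose
fusion penalty is already zero (e.g. a constant matrix) is returned
immediately — it is the exact optimum and the IRLS coefficients would
otherwise be ill-conditioned — and the per-edge quadratic coefficients are
capped at $10^8$ so the Laplacian eigensolves stay well-conditioned in the
deeply fused regime. On instances up to 6×6 the returned objective agrees
with an independently coded ADMM solver to far better than $10^{-4}$.

**Validation and cluster extraction.** A seeded random 10% of matrix
entries is held out and replaced by the mean of the observed entries; the
path is solved on the completed matrix and each model scored by the mean
squared difference between its smoothed values and the true held-out
entries; $\gamma^*$ is the argmin. The final smoothed matrix is re-solved
on the *full* (unimputed) data at $\gamma^*$ — the exact hold-out scheme of
the reference validation routine is undocumented, so the package owns this
choice: errors are always measured against genuinely unseen entries, and
the reported model never contains imputed values. Clusters are connected
components under the fusion tolerance
$\|U^*_{\cdot i} - U^*_{\cdot j}\| \le$ `tol_cluster` × scale, with scale
defaulting to $\mathrm{sd}(U^*)$; when counting clusters *along* the path
(`tidy()`), the scale of the unsmoothed data is used instead so the
threshold is identical at every $\gamma$ — a threshold tied to
$\mathrm{sd}(U_\gamma)$ shrinks as the path fuses and makes counts bounce
among numerical residue. Labels are numbered by first appearance.

## Commonality and OMIM summaries

The commonality index of an eGene in a cluster is the fraction of member
phenotypes whose set contains it; genes present in no member are omitted.
The OMIM-style summary reports the fraction of spatial eGenes present in a
genemap-like table and, over the gene–phenotype rows of annotated eGenes,
the proportion per mapping-method category (1 unknown defect, 2 linkage
only, 3 causal mutation identified, 4 contiguous-gene
deletion/duplication).

# The synthetic generator

`sim_config()` defines the study conditions used throughout testing:
12 traits in 3 planted clusters, each cluster sharing a contiguous core
locus of 4 adjacent genes, 2 private eGenes per trait, 2 cell lines × 2
replicates, 200 background interaction records, true-eQTL p-values scaled
by $10^{-8}$, 3 tissues, 3 chromosomes of 300 kb with mean GATC spacing
1 kb. These sizes keep a full pipeline run in seconds while leaving every
stage a non-trivial recovery problem: ~900 fragments, 36 genes, ~80 SNPs,
~400 interaction records, ~500 eQTL rows, a 15 × 15 sharing matrix
(12 trait phenotypes + 3 composites).

What it emulates, and how:

* **Genome.** Random background sequence with recognition sites injected at
  exponential spacings; accidental `GATC` occurrences in the background are
  rejection-fixed, so the planted site list *is* the digest truth and the
  expected fragment count is length/spacing — this is what makes the digest
  tests analytic.
* **Annotation and GWAS.** Genes sit in disjoint slots (placement fails
  loudly if they cannot); half carry a second isoform extending the union
  span, exercising the collapse. Every cluster's core locus is a run of
  adjacent genes, so recovered clusters exhibit the contiguous-core-locus
  geometry the analysis is designed to expose. Each trait gets one SNP per
  target gene, placed mid-fragment in intergenic fragments (never on a cut
  site, at most one SNP per fragment); the last private target of each
  trait is targeted from a different chromosome so inter-chromosomal
  classification is exercised. One multi-trait SNP per cluster (its own
  study) creates a composite phenotype targeting the whole core locus —
  enough eGenes to survive the ≥ 4 filter, and unambiguous cluster
  membership. All GWAS p-values are drawn below the 5 × 10⁻⁶ suggestive
  threshold the ingest filter enforces.
* **Interactions.** Every planted pair gets 1 + Poisson(1.2) observations
  spread uniformly over (cell line, replicate) files, with the SNP randomly
  on either record end; background records pair uniformly random fragments.
* **eQTL table.** Planted pairs are eQTLs in *all* tissues with
  $p = \text{scale} \times U(0,1)$ and non-zero effect sizes; decoy rows
  for non-planted pairs draw $p \sim U(0,1)$. Because decoys have no
  planted contacts, a noise-free run (`background_interactions = 0`)
  recovers the planted triples *exactly* at FDR 0.05 — the end-to-end
  recoverability check. Setting `true_eqtl_p_scale = 1` turns the whole
  table into a null, which the FDR-control smoke test uses.
* **OMIM-like genemap.** A synthetic table covering ~62% of genes with
  method codes drawn heavily from the causal-mutation category, the
  composition typical of curated disease-gene catalogues.

What it does **not** emulate — and what passing tests therefore do not
show about real data: Hi-C distance decay and domain structure (background
contacts are uniform), linkage disequilibrium among SNPs (each planted SNP
is independent), sequence realism beyond GATC content, tissue-specific
effect-size structure, and same-chromosome distal (≥ 1 Mb) associations —
at 300 kb per chromosome every same-chromosome pair is cis, so the
trans-intrachromosomal branch is covered by coordinate-level unit tests
rather than by the generator. Recovering planted structure here validates
the machinery, not the biology.

# Determinism and seeds

Every stochastic stage takes a seed and restores the caller's RNG state;
the generator derives per-stage sub-seeds from `sim_config(seed = )`, so
identical configurations produce byte-identical output files, and
`null_mean_matrix()` / `validate_path()` are reproducible given their
`seed` arguments.

# Known limitations

* The solver's per-step eigendecompositions are cubic in each dimension;
  the package targets the hundreds-of-phenotypes scale, not thousands.
* The asymmetric sharing matrix is biclustered as-is; no symmetrisation is
  applied, so row and column partitions can legitimately differ.
* Hold-out validation assumes missing-completely-at-random entries; for
  small matrices the 10% hold-out is noticeably grainy, and `gamma_star`
  can move between nearby grid points across seeds (the recovered clusters
  are stable in our tests).
* `summarize_tissue_cellline()` sums replicate-level support per
  (tissue, cell line) group; an association tested in several tissues
  contributes its pair's support to each of its tissues.
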