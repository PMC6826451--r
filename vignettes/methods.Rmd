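---
title: "Methods: structure-based clustering of bacterial intergenic sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based clustering of bacterial intergenic sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igsclust)
```

This vignette documents the models, conventions and numerical choices
behind `igsclust`, in the spirit of a methods section: what each stage
assumes, which parameters matter, and where the design was genuinely open.

## 1. From annotation to equal-length intergenic sequences

**Coordinate model.** Internally every position is 0-based on the forward
strand and every span is half-open `[start, end)`. GenBank's 1-based
inclusive coordinates are converted on input and restored on output; all
strand logic is confined to the extraction stage. The translation start
codon (TSC) position is the first base of the start codon: `start` on the
`+` strand, `end − 1` on the `−` strand. Bacterial chromosomes are
circular by default; all windows use modular arithmetic, so an upstream
window always exists on a circular replicon. On linear contigs a unit with
fewer than `L` bp upstream is skipped with a warning — an extension beyond
the circular case, which cannot run out of sequence.

**Start codons.** Annotated starts are accepted as-is by default. Although
the canonical description is an ATG triplet, bacterial annotations
routinely use GTG/TTG starts; `read_genbank(atg_only = TRUE)` restricts to
ATG for users who want the stricter reading.

**Transcription units.** An operon table (DOOR-style,
`gene_id<TAB>operon_id`) groups co-transcribed genes; one upstream region
is attributed to the whole unit at its lead gene — the strand-wise 5′-most
member. Annotated genes missing from the table become singleton units, and
an operon spanning both strands is rejected as a data error.

**Two region families.** The intergenic region (IGR) of a unit runs from
its lead TSC back to the end of the previous coding region *on the same
strand*; the restricted IGR (RIGR) is the strand-agnostic gap between
consecutive coding spans, set to 0 where genes overlap. RIGRs drive the
window-length rule; IGRs are reported for bookkeeping and always bound the
RIGR from above at the same locus.

**Window length.** `choose_window_length()` returns `round(mean − sd)` of
the RIGR lengths, with the *population* standard deviation. The spread
subtracted from the mean is read as a standard deviation, not a variance:
subtracting a quantity in bp² from a length in bp is dimensionally
inconsistent, and the reference arithmetic (≈250 − ≈50 = 200 bp) is
consistent with the sd reading. Pipelines that want the canonical 200 bp
regardless of their genome's RIGR distribution pass
`window_length = 200`, the default config.

**Shine-Dalgarno detection and the TSS anchor.** The 25 bp adjacent to the
TSC are scanned for the consensus `AGGAGG` and its subsequences
(`AGGAG, GGAGG, GGAG, GAGG, AGGA, GGA, GAG, AGG`), in strictly decreasing
length order; the first nucleotide of a hit must lie within the 25-bp
search region. The longest motif wins; among equal-length hits the one
*closest to the TSC* is taken — the tie-break is not specified by the
original description, and the choice matches where ribosome-binding sites
canonically sit (offset peak near 10 bp). The transcription start site
(TSS) is anchored at the motif's **first** nucleotide. One upstream
description places position 0 at the *last* nucleotide of the motif; we
anchor at the first nucleotide everywhere, consistently with how the
offset distribution and the TSS are defined, and note the discrepancy
here.

**The IGS.** The emitted sequence is the `L − 25` bp (175 bp by default)
immediately 5′ of the anchor. Windows are taken even when they cross
coding sequence — truncating them would break the equal-length requirement
of everything downstream — and the per-record `coding_fraction` (overlap
with any CDS on either strand) records the contamination instead.
Ambiguity codes pass through extraction untouched; alignment scores them
via the substitution matrix and base-composition analysis ignores them.

## 2. Pairwise alignment

Scores come from `Biostrings::pairwiseAlignment` under the standard
EDNAFULL nucleotide table (match +5, mismatch −4, IUPAC ambiguity rows),
with affine gaps and, in global mode, free end gaps. Two conventions are
fixed deliberately:

* a gap of length *k* costs `gap_open + (k − 1) · gap_extend` (the EMBOSS
  convention); Biostrings charges `opening + k · extension`, so the
  opening penalty is shifted by one extension internally to reproduce it
  exactly — the test suite pins this bit-for-bit against an independent
  plain-R dynamic-programming implementation;
* defaults `gap_open = 10`, `gap_extend = 0.5`: a high opening and low
  extension cost keeps long gaps cheap, which favors compositionally
  similar sequences and sharpens the downstream eigengap. Scores keep the
  0.5 granularity these penalties induce; no rounding is applied.

Global mode (free end gaps) is the default; local (Smith-Waterman) mode is
retained behind `alignment_params(mode = "local")` — with these penalties
the two give essentially the same similarity structure on equal-length
IGSs. Self-alignments are not computed: the similarity matrix has a zero
diagonal, because a self-score of `5L` on the diagonal would dominate the
`max{w_ij}` normalization and add uninformative self-loops. Alignment is
exact dynamic programming throughout; at 175 bp there is no need for
banded or heuristic acceleration.

## 3. Threshold and adjacency

Even unrelated sequences of similar composition get a sizeable alignment
score, so the similarity graph must be thresholded before clustering. Two
estimators of the threshold *s\** are provided:

* **global shuffle** — shuffle *every* sequence, score all pairs, take the
  mean; iterate (default 5 iterations) and average. Each iteration is
  O(N²) alignments, so a `pair_fraction` config allows unbiased pair
  subsampling for large N (full enumeration is the default up to desk
  scale);
* **self shuffle** (default) — score each sequence against 10 random
  reorderings of *itself* and average over everything. Because each
  sequence is compared only against its own composition, this yields a
  higher, more discriminating threshold for short sequences, and it is
  the estimator the pipeline uses. The acceptance suite checks the
  expected ordering (self > global on average) and that the estimate
  concentrates (sd across seeds below 5% of the mean at N = 100).

Shuffles are plain uniform permutations — composition-matched higher-order
(Markov) shuffles are deliberately out of scope. Thresholding uses the raw
score scale (`s_ij ≥ s*` kept), *then* surviving weights are normalized by
their maximum, preserving the order of operations threshold-first.
Isolated nodes (degree 0 after thresholding) are excluded from clustering
and reported as unclustered, since the normalized Laplacian is undefined
at zero degree. In the global-shuffle estimator all unordered pairs
(shuffled-i vs shuffled-j, i < j) are scored; no other pairing scheme is
applied.

## 4. Spectral clustering

`L_sym = D^{−1/2}(D − W)D^{−1/2}` is symmetrized against floating-point
asymmetry and fully diagonalized (`eigen(symmetric = TRUE)`); eigenvalues
are reported ascending with orthonormal eigenvectors whose sign is
canonicalized (largest-magnitude entry positive), so embeddings are
reproducible up to numerically degenerate subspaces. For a graph of q
disconnected blocks the null eigenvalue has multiplicity q; for mixed
real data the eigengap heuristic applies: `suggest_k()` maximizes
`λ_{k+1} − λ_k` over `2 ≤ k ≤ 20` (k = 1 carries no separation
information; 20 matches the number of leading eigenvalues one usually
inspects). Ties break to the *largest* k with a warning on a perfectly
flat profile. The suggestion is advisory and the full gap table is always
attached: cluster-level evidence can legitimately override it — e.g.
silhouettes may favor k = 2 while the base-composition profiles of three
clusters are clearly distinct — so `k` is never silently final.

The embedding takes the first k eigenvectors as columns and normalizes
rows to unit norm; an all-zero row (possible only in degenerate
spectra) is mapped to the first canonical unit vector and flagged.
k-means is the classical Lloyd iteration with centroids initialized at
sampled points, convergence when the largest centroid displacement drops
below `tol = 1e-8`, an emptied cluster reseeded at the point farthest
from its assigned centroid, and the best of `n_init = 10` restarts by
within-cluster sum of squares (a single run is sensitive to
initialization; restarts remove that without changing the algorithm).
Cluster names `C0, C1, …` are assigned in decreasing size order for
stable reporting.

**Silhouettes.** `s(i) = (b(i) − a(i)) / max(a(i), b(i))` with Euclidean
distances in the embedding. Two intra-cluster normalizations are
implemented: `"paper"` divides the sum over the *other* `N_k − 1` members
by `N_k` (the literal formula this pipeline historically used), and
`"standard"` divides by `N_k − 1` (the textbook definition). The two
differ by a factor `(N_k − 1)/N_k`; the literal form is likely a typo of
the textbook one, but neither is silently "corrected" — the default is
`"paper"` for reproducibility and `"standard"` is one flag away, checked
against an independent reference implementation to 1e-12. Singleton
clusters get `s(i) = 0`.

## 5. Composition profiles and segment statistics

Base composition analysis computes `ρ_x(ℓ)`, the fraction of sequences
with nucleotide x at position ℓ, for `ℓ = −175 … −1` (position 0, the
anchor, is not part of the IGS). Ambiguity codes contribute to no
nucleotide, so the four densities sum to 1 exactly on clean inputs — a
conservation the tests assert at every position. Smoothing averages over
`[ℓ − a, ℓ + a]` with `a = 15` bp by default; at profile ends the window
truncates to the covered positions and renormalizes by the *actual*
width rather than padding, avoiding edge artifacts at the cost of a
slightly noisier boundary estimate.

Homogeneous-segment statistics count maximal runs of three types: pure A,
pure T, and strictly alternating AT (period 2, both letters present, no
two equal adjacent letters — "AT-content-rich" stretches that are not
strictly alternating do not qualify). Types are counted independently,
each by its own maximality, so a homopolymer adjoining an alternating
stretch contributes to both counts; the reported minimum length
(default 6 bp, where run-length distributions of weak nucleotides
typically peak) is configurable.

## 6. Network association and enrichment

Interaction tables (`gene1, gene2, score` with scores 0–1000, as exported
per evidence channel by protein-association databases) are thresholded
*strictly* above 700 — the wording "overtakes" a threshold is read as
strict, and a `strict = FALSE` switch restores ≥ — then stripped of
weights. For a cluster's genes the induced subgraph's largest connected
component gives `N_LCC` (nodes) and `N_link` (edges of that component).
`N_link` is the component's *total* edge count, not a per-node figure: a
reported exemplar (`N_LCC = 62`, `N_link = 707`) is impossible per node,
so the phrase "links per node" is treated as a wording slip. Ties between
equally sized components break by edge count, then by lexicographically
smallest member; an edgeless induced graph reports `(1, 0)`.

The null model redraws `N_IGS` IGSs uniformly without replacement from
the full set, expands them to their member genes — so each draw preserves
operon structure — and recomputes both statistics; 1000 resamples by
default, sample sd with divisor n − 1, and `z = (obs − mean)/sd`. A
degenerate null (sd = 0, e.g. when the cluster is the whole set) flags
the z as undefined rather than dividing by zero.

Category enrichment uses the exact binomial test per category: with k of
the cluster's n annotated genes in a category of background proportion p,
the two-sided p-value is `min(1, 2 · min(P(X ≤ k), P(X ≥ k)))` — the
standard doubling convention, chosen because the sidedness convention was
otherwise unspecified. Benjamini-Hochberg adjusted values are reported
*alongside* the raw ones: the raw p-values are the faithful output, the
adjustment is an addition a modern reader expects.

## 7. The synthetic fixture generator

`simulate_genome()` builds a circular replicon of non-overlapping CDSs
(ATG starts, no internal stops) grouped into operons, and emulates the
study conditions the pipeline targets:

* intergenic gaps from N(250, 50) bp truncated below at 200 bp — the
  truncation guarantees the planted 200-bp upstream window is wholly
  intergenic, at the price of a post-truncation mean of ≈264 bp;
* a Shine-Dalgarno consensus `AGGAGG` planted with probability 0.88 at an
  offset peaked near 10 bp on support 6–25 (at offset 5 the 6-mer would
  overrun the TSC, so the support is clipped to keep the planted motif
  wholly upstream);
* three compositional classes: T-rich (ρ_T ≈ 0.45), A-rich (ρ_A ≈ 0.45)
  and balanced-weak (ρ_A ≈ ρ_T ≈ 0.30, ρ_G ≈ ρ_C ≈ 0.20), each planting
  its *signature* weak-nucleotide patch type — T homopolymers, A
  homopolymers, alternating AT — of length 6 + Geom(0.4) (most frequent
  length six). Rates are Poisson(3)/Poisson(3)/Poisson(6): the balanced
  class, whose composition is closest to uniform, carries the highest
  rate because its real counterpart is the cluster richest in regular
  segments of all three types, and because under a pooled self-shuffle
  threshold a near-uniform class can only cohere through shared patch
  structure — composition alone always scores below the pooled null mean;
* network modules per transcription unit and one planted enriched
  category, emitted in the same TSV dialects the pipeline consumes.

What the generator does **not** emulate: codon usage, GC skew,
replication-strand asymmetry, overlapping genes, pseudogenes/RNA
features, length-175 heterogeneity, or windows crossing coding sequence
(gaps are truncated at 200 bp precisely so the planted class signal is
clean). Passing the planted-recovery tests therefore demonstrates that
the pipeline separates compositional classes *when they exist and are
clean*; on real genomes coding contamination, shared regulons and the
A/T continuum between classes will blur boundaries, which is why
`coding_fraction` is carried on every record and k remains advisory.

## 8. Problem sizes and reproducibility

The test and acceptance workloads are sized for a desk run: alignment
oracle checks on 100 random 20–60-bp pairs; planted-class recovery on
~150 IGSs of 175 bp (≈11k pairwise alignments per seed, five seeds);
threshold-ordering checks across 10 seeds at ~30 sequences; null
calibration across 200 seeded score tables with 200 resamples each. The
full suite and the acceptance script each complete in minutes on one
CPU. All randomness flows from explicit seeds: the simulator is
byte-identical under a fixed seed, k-means restarts and resampling nulls
consume the session RNG, and `run_igs_pipeline()` seeds everything from
its single `seed` key, which the artifact manifest records together with
md5 checksums of every stage output.

## 9. Known limitations

* GenBank parsing is deliberately minimal: single replicon, simple and
  `complement()` CDS locations; compound `join()` locations (rare for
  bacterial CDSs, common for pseudogenes) are rejected.
* The TSS is an operational proxy — the first base of a ribosome-binding
  motif — not a transcriptomics-derived start; promoter elements (−10/−35)
  are out of scope.
* The full similarity matrix is dense O(N²) in memory and alignments; the
  design targets bacterial-scale N (thousands), not eukaryotic promoter
  sets.
* With `k = "auto"` the eigengap can legitimately disagree with
  silhouette-preferred k; the package reports both and leaves the call to
  the analyst.
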