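# igsclust

Structure-based, genome-wide classification of bacterial intergenic
sequences (IGSs).

## The problem

The noncoding DNA immediately upstream of a bacterial transcription unit —
between the translation start codon (TSC) and the previous coding region —
carries the signals that regulate transcription and translation. Unlike
coding sequence, these regions tolerate so much turnover that alignment
against a reference motif often fails even when function is conserved.
`igsclust` takes the opposite, alignment-*within*-genome route: it compares
every upstream sequence of one genome against every other, and groups them
by *global compositional similarity* rather than by shared short motifs.
The resulting clusters can then be characterized structurally (positional
base composition, runs of weak nucleotides) and interrogated functionally
(interaction-network coherence, functional-category enrichment).

The package is aimed at microbial genomics researchers who want a
reproducible, fully offline implementation of this pipeline, runnable on a
single replicon annotation plus an operon table, with optional
interaction-score and category tables.

## The method

For each transcription unit (single gene or operon, from a DOOR-style
operon table) the pipeline:

1. takes the `L = 200` bp upstream of the lead gene's TSC (a common length
   chosen as `round(mean − sd)` of the strand-agnostic intergenic gap
   distribution; 250 − 50 = 200 on the reference genome);
2. scans the 25 bp next to the TSC for a Shine-Dalgarno sequence —
   consensus `AGGAGG` or any of its 3–5-mer subsequences, longest first —
   and anchors the transcription start site (TSS) at the motif's first
   nucleotide (at the TSC when none is found);
3. emits the 175 bp immediately 5′ of that anchor as the IGS, recording
   its coding fraction;
4. scores all IGS pairs with global alignment (EDNAFULL scoring, gap open
   10, gap extend 0.5, free end gaps), giving a similarity matrix *S*;
5. thresholds *S* at *s\**, the mean alignment score of each sequence
   against ten random shuffles of itself, and normalizes surviving weights
   to `w_ij = s_ij / max{s_ij}`;
6. builds the normalized Laplacian `L_sym = D^{−1/2}(D − W)D^{−1/2}`,
   reads the cluster number *k* off the largest eigengap of its ascending
   spectrum, embeds each IGS as the row-normalized first *k* eigenvector
   coordinates, and runs k-means (tolerance 10⁻⁸, 10 restarts);
7. validates clusters with silhouettes `s(i) = (b−a)/max(a,b)` and
   characterizes them by base composition analysis
   `ρ_x(ℓ) = N⁻¹ Σ_i s_i^x(ℓ)` (with 2a+1-bp window smoothing) and by
   counts of homogeneous A-, T- and alternating-AT segments (≥ 6 bp);
8. optionally associates each cluster with an interaction network: the
   largest-connected-component size `N_LCC` and its edge count `N_link`
   over the cluster's genes, compared with a null of 1000 equally sized
   random IGS draws (z-scores), plus exact two-sided binomial tests of
   functional-category enrichment against the genomic background.

A synthetic-genome simulator with planted operons, Shine-Dalgarno motifs,
compositional classes and network modules makes the whole pipeline
testable with no downloads.

## Worked example

```r
library(igsclust)
set.seed(11)
sim <- simulate_genome(fixture_spec(n_genes = 80))
run <- run_igs_pipeline(list(seed = 11, window_length = 200L),
                        annotation = sim$annotation, operons = sim$operons)
#> input: 80 genes, 59 transcription units
#> window length: 200 bp (search region 25 bp)
#> extracted 59 IGSs of 175 bp; SDS found in 84.7%
#> threshold (self_shuffle): s* = 193.58
#> 1 isolated IGS(s) left unclustered
#> clustered into k=3 (eigengap suggested 3); mean silhouette 0.964

glance(run$clustering)
#> # A tibble: 1 × 6
#>       n     k suggested_k mean_silhouette min_cluster_size n_unclustered
#>   <int> <int>       <int>           <dbl>            <int>         <int>
#> 1    58     3           3           0.964                8             1

subset(run$segments, cluster == "C0")
#> # A tibble: 3 × 3
#>   cluster type  count
#>   <chr>   <chr> <int>
#> 1 C0      A         1
#> 2 C0      T         3
#> 3 C0      AT      101
```

Reading the output: 59 upstream windows were extracted, a Shine-Dalgarno
motif anchored the TSS in 84.7% of them, and the self-shuffle threshold
(s\* = 193.6, on the raw score scale where a perfect 175-bp self-match
scores 875) left one IGS with no above-threshold neighbor. The eigengap
of the normalized Laplacian pointed at three clusters, which k-means
recovered with a mean silhouette of 0.96 — here the three planted
compositional classes. The segment table shows C0 is the
alternating-AT-rich class (101 AT-segments ≥ 6 bp versus 1 A- and 3
T-homopolymers).

`autoplot(run$clustering)` draws the clustering space,
`autoplot(run$bca)` the per-cluster smoothed base-composition profiles,
and `plot_spectrum(run)` the Laplacian spectrum with the suggested k.

Real annotations enter through `read_genbank("chromosome.gbk")` (or
`read_fasta_gff()`), `read_operon_table()`, `read_score_table()` and a
gene → category TSV; `run_igs_pipeline()` accepts a YAML config naming
the same inputs (see `default_config()`), and `inst/cli/igsclust` wraps
the simulate / run-all entry points for shell use.

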