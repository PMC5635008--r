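---
title: "Mining and comparing satellitomes from short reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and comparing satellitomes from short reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satellitome)
```

## The model

Satellite DNA occurs as tandem arrays of a monomer of length RUL (here 6 to
~1000 bp). In a shotgun library, reads drawn from an array are near-copies
of one another up to rotation, strand, the intra-family divergence among
copies and sequencing error. Three consequences drive the whole pipeline:

1. **Clustering.** Array-derived reads share most of the monomer's k-mers,
   so in a graph joining reads that share at least `min_shared_kmers`
   canonical k-mers (default k = 17, 5 shared) they form dense connected
   components. Single-copy background reads connect only through genomic
   overlap and form sparse chains.
2. **Periodicity.** A read from an array is self-similar at offset equal to
   the period: the mean per-site identity between positions $i$ and $i+p$
   peaks at the true RUL (and its multiples; the smallest qualifying period
   is taken). A candidate period is accepted at mean identity ≥ 0.8,
   consistent with the 80% family-identity level used downstream.
3. **Abundance.** The fraction of sampled nucleotides assignable to a
   family estimates its genomic fraction, because read start positions are
   uniform.

Monomers are defined only up to rotation and strand; all comparisons use
**rotational identity** — the maximum global-alignment identity over all
rotations of one sequence and both its strands, with gap columns counted as
mismatches — and all reporting uses the **canonical rotation** (the
lexicographically smallest rotation of the monomer or its reverse
complement), which makes deduplication and naming deterministic. Grouping
is single linkage at three nested levels: monomers above 95% identity are
the *same variant*, variants linked above 80% form a *family*, families
linked above 50% a *superfamily*. Identities are rounded to 0.1 percentage
points first and thresholds are inclusive (a pair at exactly 80.0% is one
family); the boundary rule is switchable. Because the identity is a maximum
over ~4·RUL rotation/strand alignments, unrelated *short* monomers can
exceed 50% by chance; a link therefore also requires the Bonferroni-adjusted
binomial tail probability of the observed match count (null: 25% per site)
to fall below 0.01. This mirrors running a homology search first and
applying the thresholds only to detected homologies, and is why a 21-bp and
a 24-bp random monomer do not form a spurious superfamily.

### Divergence

Per-family divergence pools the transitions and transversions of all
assigned read segments against the best-matching variant consensus and
applies the Kimura two-parameter estimator
$d = -\tfrac12\ln[(1-2P-Q)\sqrt{1-2Q}]$ (reported in percent; undefined at
saturation). Pooling across segments (rather than averaging per-variant
estimates) is a declared choice; with substitution-only simulation the
estimate contains the planted intra-family divergence plus the read error.

### The B-chromosome comparison

With abundances $A_{0B}$ and $A_{1B}$ from equal-depth libraries, families
are ranked by $\log_2(A_{1B}/A_{0B})$. Adding one B chromosome of length
fraction $f$ of the haploid A complement to a diploid A set dilutes a
satellite absent from the B by $1/(1+f/2)$, so the largest decrease
explainable by dilution alone is $(f/2)/(1+f/2)$ — 3.85% ("about 4%") at
$f = 0.08$. A family sitting exactly at that bound is classified
`decrease-within-threshold` or `decrease-beyond-threshold` by the sign of
sampling noise; the classification is informative only for decreases well
away from the bound, which is how it is tested. Families with zero
abundance on either side get no log2 ratio; they are assessed by the
two-step structural argument instead: count reads containing ≥ 2
consecutive monomer copies (`multimer_scan`) and recluster up to 2 × 2500
selected homologous read pairs per library (`targeted_recluster`) — a
B-restricted satellite shows tandem structure in the 1B selection only,
even when dispersed single copies give it a tiny non-zero 0B abundance.

### Cytogenetic statistics

Location tables record, per satellite and chromosome, a pattern
(`c` clustered, `nc` non-clustered, `t` telomeric, `ns` no signal scored)
and region tokens `arm:code` with arms p/q and codes pe, i, t, d. The
symmetry index of a B chromosome is the mean over its non-pericentromeric
clustered satellites of the indicator that the p-arm and q-arm region sets
match; pericentromeric clusters are arm-neutral and ignored, and the
terminal/distal codes are one arm-end class for the comparison (the
published scoring treats a p-terminal vs q-distal satellite as symmetric,
and the per-B totals only add up under that rule). The battery around it:

* `mann_whitney()` uses midranks and reports U = min(U₁, U₂); the
  two-sided P is exact by enumerating all arrangements when
  `choose(n+m, min(n,m))` ≤ 2·10⁶, else a tie-corrected normal
  approximation without continuity correction. On the 30-vs-5 RUL
  comparison the exact P is 0.018 while the normal approximation gives the
  historically reported 0.021.
* `fisher_exact_2x2()` sums hypergeometric probabilities; the two-sided P
  follows the probability-mass rule. The published shared-cluster P of
  0.1007 is the one-sided (greater) tail — the two-sided mass P for the
  same table is 0.1446 — so the reproduction uses `alternative =
  "greater"`.
* `levene_test()` is the classic mean-centred Levene (ANOVA F on absolute
  deviations; median centring available), `spearman_test()` is Pearson
  correlation of midranks with the t approximation, and `shapiro_wilk()`
  wraps the standard Royston approximation.

## The synthetic-data generator

`plant_families()` builds a haploid A-complement string of exactly the
requested length (arrays plus i.i.d. background) and a B segment of
`round(f × length)` bp, so the 1B genome literally extends the 0B genome.
Each variant of a family is planted as one contiguous array whose copies
are independently mutated at the family's `intra_divergence`; additional
variants derive from the base monomer at 10% divergence (inside the
80–95% family band), and superfamily partners at an exact target identity
in [0.5, 0.8). `dispersed_0B` plants isolated single copies in the A
complement — the organisation that makes a satellite FISH-invisible yet
detectable in reads. Read simulation uses uniform fragment starts, both
strands, Gaussian insert lengths and independent substitution errors
(default 1%); there are no indels, so read-to-consensus divergence stays
interpretable under the K2P model, and qualities are a fixed Q37
placeholder. By default the 1B library is simulated in *diploid-equivalent*
mode (the A portion duplicated before read generation), making the
dilution factor 1/(1+f/2) as in the comparison above; the haploid mode
(factor 1/(1+f)) is available. An optional per-family lognormal
copy-number jitter between the 0B and 1B individuals models
between-individual abundance differences; no published estimate of its
scale exists, so it defaults to off and is used only to demonstrate that
jitter, not dilution, produces large log2 anomalies.

What the generator does **not** model: indels and array interruption by
transposons, GC/coverage bias, PCR duplicates, quality-score structure,
related-species libraries. Passing tests therefore show the pipeline's
correctness under a clean substitution-only model, not robustness to every
artefact of real libraries.

## Numerical and algorithmic choices

* **k-mers**: canonical (strand-minimum) 2-bit codes, k ≤ 26 so codes are
  exact in doubles; clustering uses k = 17. Pair expansion is bounded: each
  k-mer contributes all-pairs edges for at most 40 of its reads plus a
  connectivity chain for the rest, and expansion proceeds in fixed-size
  chunks — components are preserved while memory stays flat at high
  coverage.
* **Tandem detection**: per-read period votes need ≥ 3 voting reads and at
  least 20 comparable sites, handling periods up to read length − 20.
  Longer periods go through greedy overlap assembly (min overlap 35 bp,
  ≤ 10% mismatch, candidates ranked by shared tail k-mers) seeded from the
  reads whose k-mers are most shared within the cluster; the period is the
  smallest self-alignment offset reaching 0.8 identity on the contig, and
  the folded-contig consensus is refined by two rounds of circular
  realignment of the reads. Clusters whose k-mer sharing never rises above
  background (no k-mer in ≥ max(4, 15% of reads)) are chains of
  overlapping single-copy reads and skip assembly.
* **Consensus calling**: per-column majority over phase-aligned copies,
  ties broken alphabetically; no ambiguity codes.
* **One cluster can hold several satellites** once coverage is high enough
  for boundary reads to chain arrays through flanking sequence; monomers
  are therefore extracted iteratively per cluster, masking each detected
  monomer's reads before re-detection.
* **Masking**: seed-and-extend — reads sharing a canonical 9-mer with the
  doubled consensus are aligned gap-free at every circular offset on both
  strands, and the best-scoring segment (Kadane, +1/−1) is kept if it
  covers ≥ 30 bp at ≥ 70% identity (admitting the most divergent families
  observed in practice, ~26%). Subtraction uses ≥ 80% identity over ≥ 50%
  of the read, aligned with the family threshold; the filtering thresholds
  of the original protocol are not published, so these are declared
  defaults.
* **Stop rule**: mining stops when an iteration yields no monomer that
  fails to group (≥ 80% rotational identity) with an already-known family;
  new *variants* of known families are still catalogued.
* **Determinism**: one master seed; every stage derives child seeds from
  it, read-order never affects masking, and naming is a pure function of
  the ranked abundances and consensus set.

## Problem sizes

The shipped study conditions are desk-scale by design: module tests use
50–200 kb genomes with 5–100 thousand read pairs; the end-to-end recovery
experiment plants ten families spanning RUL 18–365 bp and abundances
halving from 5% to 0.01% in a 4 Mb genome with a 200,000-pair library
(mining samples double from 2000 pairs); the dilution check simulates one
million pairs per genome against a 300 kb complement carrying a 10%
satellite. At these scales the two rarest families (0.02% and 0.01%) sit
below the reliable recovery limit — their arrays are only a few hundred
bases, so the reads that are mostly satellite are too few to vote before
background coverage percolates — which is exactly the regime the recovery
criterion (≥ 8 of 10 families) probes. Sampled coverage matters: the
clustering separates satellites cleanly while background coverage per
mining sample stays below ~1×; beyond that, background reads chain into
giant components and late-appearing rare families are progressively
absorbed. This is a property of overlap-based read clustering generally,
not of this implementation alone, and it is why mining samples start small
and double rather than starting large.

## Known limitations

* Periods are limited to 500 bp by default (configurable); assembly-path
  consensus accuracy degrades for very divergent long monomers.
* Abundance is slightly conservative at array boundaries (segments shorter
  than 30 bp are not assigned) and for families at the masking identity
  floor.
* The superfamily significance guard is deliberately strict for very short
  monomers; genuinely homologous 10–20 bp superfamily partners would need
  the guard relaxed.
* One individual per condition: the log2 comparison inherits any
  between-individual copy-number differences, which is the reason the
  jitter option exists and why classifications at the dilution boundary
  are not over-interpreted.
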