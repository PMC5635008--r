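# satellitome

Satellite DNA (satDNA) consists of long head-to-tail arrays of a short
repeated unit (the monomer), concentrated in heterochromatin. The complete
collection of satDNA families in a genome — its **satellitome** — can be
catalogued from cheap low-coverage short-read data: reads derived from a
tandem array cluster together by sequence similarity, the monomer and its
length (RUL, repeat unit length) can be called from the cluster, and read
counts give each family's genomic abundance. Comparing libraries from a
B-chromosome-carrying individual (1B) and a B-lacking one (0B) then flags
satellites amplified on, or restricted to, the supernumerary B chromosome.

This package implements that workflow end to end for desk-scale, fully
synthetic data, plus the statistics used to analyse cytogenetic (FISH)
satellite location tables:

* **simgen** — paired 0B/1B genome simulator with planted tandem arrays
  (configurable RUL, A+T content, copy number, intra-family divergence,
  sequence variants, superfamily partners, B-restricted families, dispersed
  single copies) and a 2 × 101 bp paired-end read simulator with a
  substitution error model. Every planted array is recorded with exact
  coordinates, so recovery can be scored against ground truth.
* **discovery** — iterative mining: sample reads, build a graph of reads
  sharing canonical k-mers, take connected components, detect tandem
  periodicity (per-read autocorrelation votes for periods up to the read
  length; greedy overlap assembly plus self-alignment offset scoring
  beyond it), call a majority consensus, subtract homologous read pairs,
  double the sample and repeat until no new family appears.
* **catalog** — grouping of monomers into variants / families /
  superfamilies at >95% / >80% / >50% rotational identity (the maximum
  global-alignment identity over all rotations and both strands), and
  naming `<Prefix>Sat<NN>-<RUL>` by decreasing 0B abundance, with a `-tel`
  suffix for the vertebrate telomeric motif.
* **quantify** — read masking against the catalogue (circular, both
  strands) and per-family abundance (% of sampled nucleotides) plus
  Kimura two-parameter divergence,
  `d = -1/2 ln[(1-2P-Q) sqrt(1-2Q)]`,
  with P and Q the transition and transversion proportions.
* **bchrom** — `log2(A1B/A0B)` abundance ratios; the expected maximum
  decrease `(f/2)/(1+f/2)` for a satellite absent from a B chromosome
  whose length is a fraction `f` of the haploid A complement (≈4% at
  f = 0.08); and verification of apparently B-specific satellites by
  scanning 0B reads for monomer multimers and by targeted reclustering.
* **cytostats** — FISH location tables (clustered / non-clustered /
  telomeric patterns; arm and region codes), the B-chromosome symmetry
  index (mean of 0/1 indicators that a satellite occupies matching regions
  on both B arms — the iso-chromosome signature), and the test battery:
  exact Mann-Whitney U, Fisher's exact test, Spearman rank correlation,
  Levene's test and Shapiro-Wilk.

Transcriptions of the published satellitome table and the FISH location
tables for *Astyanax paranae*, *A. fasciatus* and *A. bockmanni* ship under
`inst/extdata/` and drive the statistics reproduction.

## Worked example

```r
library(satellitome)

specs <- list(
  family_spec("satA",   rul = 51, at_frac = 0.55, copies_0B = 200,
              copies_B = 60, intra_divergence = 0.05),
  family_spec("satBsp", rul = 24, copies_0B = 0, copies_B = 80,
              b_restricted = TRUE, dispersed_0B = 3))
pair <- plant_families(specs, background_length = 1e5, f = 0.08, seed = 42)
libs <- simulate_pair_libraries(pair, n_pairs = 20000, seed = 7)

mine <- mine_satellitome(libs$lib_1B, start_pairs = 1000, seed = 9)
mine$log
#>   iteration sampled_pairs clusters new_monomers new_families ...
#> 1         1          1000       36            2            2 ...
#> 2         2          2000       90            0            0 ...

grp  <- group_monomers(mine$monomers)
ab0  <- quantify_library(libs$lib_0B, grp$families, genome = "0B")
fams <- name_families(grp$families,
                      setNames(ab0$abundance_percent, ab0$family), "Sim")
vapply(fams, `[[`, character(1), "name")
#> [1] "SimSat01-51" "SimSat02-24"
```

`SimSat01-51` is the abundant shared family; `SimSat02-24` is the planted
B-restricted satellite: its 0B abundance comes only from dispersed single
copies, so its log2 ratio is strongly positive and
`targeted_recluster(libs$lib_0B, libs$lib_1B, <consensus>)` reports tandem
structure in the 1B library only — the two-step argument used to call a
satellite B-specific.

The numbered scripts under `analysis/` run the same study as a narrative
(simulate → mine → catalogue/quantify → B comparison → cytogenetic
statistics), writing their tables under `results/`. For example,
`analysis/05_cytostats.R` prints, from the shipped fixtures:

```
Clustered vs non-clustered RUL: U = 26, exact P = 0.018
Levene: F = 2.5, df = (1, 33), P = 0.124
Shared clusters A vs B: [[26,4],[12,6]], one-sided Fisher P = 0.1007
BpM: 14 clusters, 13 non-centromeric, SI = 1.00
BfMa: 13 clusters, 11 non-centromeric, SI = 0.45
BbM: 8 clusters, 7 non-centromeric, SI = 1.00
```

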