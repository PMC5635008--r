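# Shared settings for the analysis scripts: a desk-scale satellitome study
# on a synthetic genome pair. The 0B genome carries three satellite families
# (one of them also on the B chromosome); a fourth, B-restricted satellite is
# present in the A complement only as dispersed single copies - the situation
# that makes a satellite FISH-invisible on A chromosomes yet bioinformatically
# detectable at trace abundance.

library(satellitome)

results_dir <- file.path("results")
dir.create(results_dir, showWarnings = FALSE)

study <- list(
  seed = 20170915,
  background_length = 100000,   # haploid A complement, bp
  f = 0.08,                     # B length fraction of the A set
  n_pairs = 20000,              # 2 x 101 bp read pairs per library
  prefix = "Sim",
  families = list(
    family_spec("satA",   rul = 51, at_frac = 0.55, copies_0B = 200,
                copies_B = 60, intra_divergence = 0.05, n_variants = 2),
    family_spec("satB",   rul = 21, at_frac = 0.45, copies_0B = 300,
                copies_B = 0,  intra_divergence = 0.02),
    family_spec("satC",   rul = 86, at_frac = 0.60, copies_0B = 40,
                copies_B = 8,  intra_divergence = 0.08),
    family_spec("satBsp", rul = 24, copies_0B = 0, copies_B = 80,
                b_restricted = TRUE, dispersed_0B = 3))
)
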