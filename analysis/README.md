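# Analysis workflow

Numbered drivers over the package functions; run from the repository root
after installing the package. Each stage writes its tables under `results/`
and the later stages read the earlier stages' text outputs.

    Rscript analysis/01_simulate.R        # genomes + 0B/1B read libraries
    Rscript analysis/02_mine.R            # iterative satellitome mining
    Rscript analysis/03_catalog_quantify.R# families, naming, abundance/divergence
    Rscript analysis/04_bchrom.R          # log2 comparison + B-specificity checks
    Rscript analysis/05_cytostats.R       # FISH location statistics (fixtures)

`analysis/00_config.R` holds the shared study settings (seed, genome and
library sizes, the planted families).
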