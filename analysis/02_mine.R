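#!/usr/bin/env Rscript
# Stage 2: iterative satellitome mining on the 1B library (the genome where
# every planted family is present): sample reads, cluster by shared k-mers,
# detect tandem periodicity, subtract homologous read pairs, double the
# sample, and stop when an iteration adds no new monomer.

source("analysis/00_config.R")

lib_1B <- read_fastq_pair(file.path(results_dir, "reads_1B_1.fastq"),
                          file.path(results_dir, "reads_1B_2.fastq"))

mine <- mine_satellitome(lib_1B, start_pairs = 1000, seed = study$seed + 2)

cat("Per-iteration mining log:\n")
print(mine$log)
cat(sprintf("\n%d monomers mined (periods: %s)\n", length(mine$monomers),
            paste(vapply(mine$monomers, `[[`, numeric(1), "period"),
                  collapse = ", ")))

write_monomers_fasta(mine$monomers,
                     file.path(results_dir, "mined_monomers.fasta"))
write.table(mine$log, file.path(results_dir, "mining_log.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
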