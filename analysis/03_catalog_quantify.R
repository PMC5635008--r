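#!/usr/bin/env Rscript
# Stage 3: group the mined monomers into variants, families and
# superfamilies (95/80/50% rotational identity), name families by decreasing
# 0B abundance, and profile abundance and Kimura divergence of both
# libraries against the catalogue. Writes the satellitome summary table.

source("analysis/00_config.R")

monomers <- as.character(Biostrings::readDNAStringSet(
  file.path(results_dir, "mined_monomers.fasta")))
lib_0B <- read_fastq_pair(file.path(results_dir, "reads_0B_1.fastq"),
                          file.path(results_dir, "reads_0B_2.fastq"))
lib_1B <- read_fastq_pair(file.path(results_dir, "reads_1B_1.fastq"),
                          file.path(results_dir, "reads_1B_2.fastq"))

grp <- group_monomers(monomers)
cat(sprintf("%d families, %d superfamilies\n", length(grp$families),
            length(grp$superfamilies)))

ab0 <- quantify_library(lib_0B, grp$families, seed = study$seed + 3,
                        genome = "0B")
fams <- name_families(grp$families,
                      setNames(ab0$abundance_percent, ab0$family),
                      prefix = study$prefix)
key <- setNames(vapply(fams, `[[`, character(1), "name"),
                vapply(fams, `[[`, character(1), "consensus"))
ab0$family <- unname(key[ab0$family])
ab1 <- quantify_library(lib_1B, fams, seed = study$seed + 4, genome = "1B")

sat <- merge(catalog_table(fams),
             merge(ab0[, c("family", "abundance_percent",
                           "divergence_percent")],
                   ab1[, c("family", "abundance_percent",
                           "divergence_percent")],
                   by = "family", suffixes = c("_0B", "_1B")),
             by.x = "name", by.y = "family")
sat <- sat[order(sat$name), ]
print(sat, digits = 3)

write_catalog_fasta(fams, file.path(results_dir, "catalog.fasta"))
write.table(sat, file.path(results_dir, "satellitome.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rbind(ab0, ab1), file.path(results_dir, "abundance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
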