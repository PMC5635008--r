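#!/usr/bin/env Rscript
# Stage 1: build the paired 0B/1B genomes with planted satellite arrays and
# simulate the two read libraries (diploid-equivalent 1B: reads are drawn
# from a diploid A complement plus one B). Writes genomes, libraries and the
# ground-truth table under results/.

source("analysis/00_config.R")

pair <- plant_families(study$families, study$background_length, study$f,
                       seed = study$seed)
print(pair)
print(pair$truth[, c("family", "rul", "copies_0B", "copies_B",
                     "frac_0B", "frac_1B_diploid")])

libs <- simulate_pair_libraries(pair, n_pairs = study$n_pairs,
                                error_rate = 0.01, seed = study$seed + 1)

write_genome_fasta(pair, file.path(results_dir, "genomes.fasta"))
write_truth_tsv(pair, file.path(results_dir, "truth.tsv"))
write_fastq(libs$lib_0B, file.path(results_dir, "reads_0B"))
write_fastq(libs$lib_1B, file.path(results_dir, "reads_1B"))

cat(sprintf("\nWrote %d + %d read pairs; B segment %d bp (%.1f%% of A)\n",
            libs$lib_0B$n_pairs, libs$lib_1B$n_pairs,
            nchar(pair$seq_1B) - nchar(pair$seq_0B), 100 * study$f))
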