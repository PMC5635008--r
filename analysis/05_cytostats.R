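#!/usr/bin/env Rscript
# Stage 5: the cytogenetic statistics battery on the transcribed FISH
# location tables (three species, A chromosomes and the three metacentric
# B chromosomes): clustered vs non-clustered repeat-unit lengths, the
# shared-cluster contingency comparison, and per-B symmetry indices.

source("analysis/00_config.R")

sat <- read.delim(system.file("extdata", "apa_satellitome.tsv",
                              package = "satellitome"))
locA <- read_location_table(system.file("extdata", "apa_locations_A.tsv",
                                        package = "satellitome"))
locB <- read_location_table(system.file("extdata", "apa_locations_B.tsv",
                                        package = "satellitome"))

report <- c()
say <- function(...) {
  line <- sprintf(...)
  cat(line, "\n")
  report <<- c(report, line)
}

say("Satellitome: %d families, %d variants, median RUL %.0f bp, %d < 100 bp",
    nrow(sat), sum(sat$v), median(sat$rul), sum(sat$rul < 100))
say("Top family is %.0fx more abundant than the second",
    sat$abundance_0B[1] / sat$abundance_0B[2])

sw <- shapiro_wilk(sat$at_percent)
say("A+T content normality: W = %.3f, P = %.2f", sw$value, sw$p_value)
sp <- spearman_test(sat$rul, sat$at_percent)
say("RUL vs A+T: r_S = %.2f, t = %.2f, P = %.3f", sp$value, sp$t,
    sp$p_value)

pa <- locA[locA$species == "paranae", ]
m <- merge(sat, pa[, c("satellite", "pattern")], by.x = "name",
           by.y = "satellite")
cl <- m$rul[m$pattern == "c"]; nc <- m$rul[m$pattern == "nc"]
s <- summarize_rul(c(cl, nc), rep(c("c", "nc"), c(length(cl), length(nc))))
print(s$by_group)
mw <- mann_whitney(cl, nc)
say("Clustered vs non-clustered RUL: U = %g, exact P = %.3f", mw$value,
    mw$p_value)
lv <- levene_test(cl, nc)
say("Levene: F = %.1f, df = (%d, %d), P = %.3f", lv$value, lv$df[1],
    lv$df[2], lv$p_value)

tab <- shared_cluster_table(locA, locB, reference = "paranae")
say("Shared clusters A vs B: [[%d,%d],[%d,%d]], one-sided Fisher P = %.4f",
    tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
    fisher_exact_2x2(tab, "greater")$value)

for (b in unique(locB$chromosome)) {
  si <- symmetry_index(locB[locB$chromosome == b, ])
  say("%s: %d clusters, %d non-centromeric, SI = %.2f", b, si$n_clusters,
      si$n_noncentromeric, si$si)
}

writeLines(report, file.path(results_dir, "cytostats_report.txt"))
stats_tsv <- rbind(
  data.frame(statistic = "mann_whitney_U", value = mw$value,
             p_value = mw$p_value),
  data.frame(statistic = "levene_F", value = lv$value,
             p_value = lv$p_value),
  data.frame(statistic = "fisher_one_sided",
             value = fisher_exact_2x2(tab, "greater")$value,
             p_value = fisher_exact_2x2(tab, "greater")$p_value),
  data.frame(statistic = "spearman_rul_at", value = sp$value,
             p_value = sp$p_value),
  data.frame(statistic = "shapiro_at", value = sw$value,
             p_value = sw$p_value))
write.table(stats_tsv, file.path(results_dir, "cytostats_tests.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(s$by_group, file.path(results_dir, "rul_by_pattern.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
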