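# Paper-table fixtures shipped with the package, plus derived groupings used
# across several test files.

fixture_path <- function(f) {
  system.file("extdata", f, package = "satellitome", mustWork = TRUE)
}

apa_satellitome <- function() {
  read.delim(fixture_path("apa_satellitome.tsv"))
}

apa_locations_A <- function() {
  read_location_table(fixture_path("apa_locations_A.tsv"))
}

apa_locations_B <- function() {
  read_location_table(fixture_path("apa_locations_B.tsv"))
}

# RUL values split by FISH pattern in the reference species; the telomeric
# satellite sits in its own "t" group and is excluded from the c/nc dichotomy
apa_rul_by_pattern <- function() {
  sat <- apa_satellitome()
  locA <- apa_locations_A()
  pa <- locA[locA$species == "paranae", ]
  m <- merge(sat, pa[, c("satellite", "pattern")],
             by.x = "name", by.y = "satellite")
  list(clustered = m$rul[m$pattern == "c"],
       non_clustered = m$rul[m$pattern == "nc"])
}
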