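# Shared synthetic objects, built once per test run and memoised. Sizes are
# chosen so the whole suite stays within a desk-scale run; the methods
# vignette records the reasoning behind the simulation scales.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# Small three-family genome pair (one B-restricted satellite with dispersed
# single copies in the A complement) plus its 0B/1B libraries.
demo_specs <- function() {
  list(
    family_spec("famA", rul = 51, at_frac = 0.55, copies_0B = 200,
                copies_B = 80, intra_divergence = 0.05),
    family_spec("famB", rul = 21, at_frac = 0.45, copies_0B = 300,
                copies_B = 0, intra_divergence = 0.02),
    family_spec("bspec", rul = 24, copies_0B = 0, copies_B = 100,
                b_restricted = TRUE, dispersed_0B = 3))
}

demo_pair <- function() {
  cached("demo_pair",
         plant_families(demo_specs(), background_length = 100000, f = 0.08,
                        seed = 42))
}

demo_libs <- function() {
  cached("demo_libs",
         simulate_pair_libraries(demo_pair(), n_pairs = 5000,
                                 error_rate = 0.01, seed = 7))
}

library_seqs_for_test <- function(lib) c(lib$reads1, lib$reads2)

# The ten-family satellitome used for end-to-end parameter recovery:
# abundances halve from 5% down to 0.01% and repeat unit lengths span
# 18-365 bp.
ten_family_specs <- function(genome_length = 4e6) {
  ab <- c(5, 2.5, 1.2, 0.6, 0.3, 0.15, 0.08, 0.04, 0.02, 0.01) / 100
  rul <- c(51, 21, 151, 365, 86, 59, 112, 33, 180, 18)
  div <- c(0.05, 0.02, 0.05, 0.03, 0.08, 0.05, 0.05, 0.02, 0.02, 0.01)
  lapply(seq_along(ab), function(i)
    family_spec(sprintf("fam%02d", i), rul = rul[i],
                at_frac = 0.45 + 0.02 * i,
                copies_0B = round(ab[i] * genome_length / rul[i]),
                intra_divergence = div[i]))
}

ten_family_run <- function() {
  cached("ten_family_run", {
    G <- 4e6
    pair <- plant_families(ten_family_specs(G), background_length = G,
                           f = 0, seed = 101)
    lib <- simulate_reads(pair$seq_0B, 200000, insert_sd = 30,
                          error_rate = 0.01, seed = 102,
                          genome_label = "0B")
    mine <- mine_satellitome(lib, start_pairs = 2000, seed = 103)
    ## map every mined monomer to its best-matching planted family
    truth <- pair$truth
    map <- lapply(mine$monomers, function(m) {
      ids <- vapply(seq_len(nrow(truth)), function(i) {
        if (abs(truth$rul[i] - m$period) > 0.3 * truth$rul[i] + 10) return(0)
        rotational_identity(m$consensus, truth$monomer[i])
      }, numeric(1))
      data.frame(period = m$period, family = truth$family[which.max(ids)],
                 identity = max(ids))
    })
    list(pair = pair, lib = lib, mine = mine, map = do.call(rbind, map))
  })
}
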