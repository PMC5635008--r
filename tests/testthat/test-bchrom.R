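test_that("log2 ratio matches the printed comparisons and is antisymmetric", {
  expect_equal(log2_ratio(5, 5), 0)
  ## printed-abundance rows: recomputation within rounding slack
  expect_lt(abs(log2_ratio(0.157, 0.084) - 0.91), 0.05)
  expect_lt(abs(log2_ratio(0.041, 0.002) - 4.34), 0.05)
  expect_error(log2_ratio(0, 1), "non-positive")
  expect_error(log2_ratio(1, 0), "non-positive")
  set.seed(15)
  for (i in 1:20) {
    a <- runif(1, 1e-3, 10); b <- runif(1, 1e-3, 10)
    expect_equal(log2_ratio(a, b), -log2_ratio(b, a))
  }
})

test_that("expected maximum decrease follows the diploid dilution argument", {
  expect_equal(expected_max_decrease(0), 0)
  expect_equal(round(100 * expected_max_decrease(0.08), 2), 3.85)
  ## "about 4%" at the printed precision
  expect_equal(round(100 * expected_max_decrease(0.08)), 4)
  expect_error(expected_max_decrease(-0.1), "f must")
})

test_that("classification applies the dilution threshold", {
  rec <- data.frame(family = c("up", "flat", "down", "zero"),
                    a0 = c(0.033, 0.006, 0.049, 0),
                    a1 = c(0.181, 0.006, 0.007, 0.01))
  rec$log2_ratio <- ifelse(rec$a0 > 0 & rec$a1 > 0,
                           log2(rec$a1 / rec$a0), NA)
  rec$expected_max_decrease <- expected_max_decrease(0.08)
  cls <- classify_b(rec)$classification
  expect_equal(cls, c("B-enriched candidate", "decrease-within-threshold",
                      "decrease-beyond-threshold", "undefined"))
})

test_that("multimer scan separates tandem from dispersed organisation", {
  monomer <- build_monomer(24, 0.5, seed = 301)
  ## genome with 4 dispersed single copies only
  bg <- vapply(1:5, function(i) build_monomer(3000, 0.5, seed = 301 + i),
               character(1))
  genome_disp <- paste(c(rbind(bg[1:4], monomer), bg[5]), collapse = "")
  lib_d <- simulate_reads(genome_disp, 2000, error_rate = 0, seed = 307)
  expect_equal(multimer_scan(library_seqs_for_test(lib_d), monomer), 0)
  ## genome with a true tandem array
  genome_tan <- paste0(bg[1], strrep(monomer, 60), bg[2])
  lib_t <- simulate_reads(genome_tan, 2000, error_rate = 0, seed = 308)
  n_multi <- multimer_scan(library_seqs_for_test(lib_t), monomer)
  expect_gt(n_multi, 0)
  ## expectation: reads fully containing >= 2 consecutive copies
  arr_start <- nchar(bg[1]) + 1
  arr_nt <- 60 * 24
  p_window <- (arr_nt - 2 * 24 + 1 - (101 - 2 * 24)) / nchar(genome_tan)
  expected <- 2 * 2000 * (101 - 2 * 24 + 1) / nchar(genome_tan) *
    (arr_nt - 101) / arr_nt
  expect_gt(n_multi, 0.5 * expected)
  ## min_copies = 1 counts any read matching the monomer at all
  n_any <- multimer_scan(library_seqs_for_test(lib_d), monomer,
                         min_copies = 1)
  expect_gt(n_any, 0)
  expect_error(multimer_scan(library_seqs_for_test(lib_d),
                             build_monomer(60, 0.5, seed = 309)),
               "copies")
})

test_that("targeted reclustering verifies B-specificity", {
  pair <- demo_pair()
  libs <- demo_libs()
  mono <- pair$truth$monomer[pair$truth$family == "bspec"]
  tr <- targeted_recluster(libs$lib_0B, libs$lib_1B, mono)
  expect_false(tr$tandem[tr$library == "0B"])
  expect_true(tr$tandem[tr$library == "1B"])
  ## a family planted in both genomes shows tandem structure in both
  mono_a <- pair$truth$monomer[pair$truth$family == "famA"]
  tr2 <- targeted_recluster(libs$lib_0B, libs$lib_1B, mono_a)
  expect_true(all(tr2$tandem))
  ## a monomer absent everywhere is reported absent, not an error
  alien <- build_monomer(40, 0.5, seed = 310)
  tr3 <- targeted_recluster(libs$lib_0B, libs$lib_1B, alien)
  expect_false(any(tr3$tandem))
  expect_equal(tr3$reads_selected, c(0, 0))
})

test_that("b_comparison merges abundance tables and flags families", {
  ab0 <- data.frame(family = c("f1", "f2"), genome = "0B",
                    abundance_percent = c(1, 0),
                    divergence_percent = NA, reads_assigned = 0)
  ab1 <- data.frame(family = c("f1", "f2"), genome = "1B",
                    abundance_percent = c(2, 0.5),
                    divergence_percent = NA, reads_assigned = 0)
  bc <- b_comparison(ab0, ab1, f = 0.08)
  expect_equal(bc$log2_ratio[bc$family == "f1"], 1)
  expect_equal(bc$classification[bc$family == "f2"], "undefined")
  expect_equal(bc$expected_max_decrease,
               rep(expected_max_decrease(0.08), 2))
})

test_that("dilution explains A-only decreases; jitter produces anomalies", {
  ## a family entirely absent from the B sits exactly on the maximum-
  ## decrease bound, so the sound check is convergence of the observed
  ## decrease to the bound, not its classification (which is a coin flip
  ## at the boundary)
  sp <- list(family_spec("s1", rul = 40, copies_0B = 300,
                         intra_divergence = 0.02),
             family_spec("s2", rul = 25, copies_0B = 400,
                         intra_divergence = 0.02))
  pair <- plant_families(sp, background_length = 2e5, f = 0.08, seed = 401)
  libs <- simulate_pair_libraries(pair, n_pairs = 50000, error_rate = 0.01,
                                  seed = 402)
  fams <- setNames(pair$truth$monomer, pair$truth$family)
  bc <- b_comparison(quantify_library(libs$lib_0B, fams, seed = 1),
                     quantify_library(libs$lib_1B, fams, seed = 1), 0.08)
  ## at this depth the sampling s.e. of the decrease is ~2 pp; dilution
  ## keeps deviations small, jitter (below) produces much larger ones
  dec <- 1 - bc$a1 / bc$a0
  expect_true(all(abs(dec - expected_max_decrease(0.08)) < 0.06))

  ## lognormal inter-individual jitter moves abundances far outside the
  ## dilution band, reproducing anomalously large log2 changes
  pairj <- plant_families(sp, background_length = 2e5, f = 0.08, seed = 401,
                          jitter_sdlog = 0.5)
  libsj <- simulate_pair_libraries(pairj, n_pairs = 20000,
                                   error_rate = 0.01, seed = 403)
  famsj <- setNames(pairj$truth$monomer, pairj$truth$family)
  bcj <- b_comparison(quantify_library(libsj$lib_0B, famsj, seed = 1),
                      quantify_library(libsj$lib_1B, famsj, seed = 1), 0.08)
  decj <- 1 - bcj$a1 / bcj$a0
  expect_gt(max(abs(decj - expected_max_decrease(0.08))), 0.06)
})
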