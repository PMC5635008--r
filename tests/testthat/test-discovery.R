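test_that("reads from one perfect tandem form a single cluster", {
  monomer <- build_monomer(40, 0.5, seed = 61)
  genome <- strrep(monomer, 100)  # 4 kb pure array
  lib <- simulate_reads(genome, 200, error_rate = 0, seed = 62)
  cl <- cluster_reads(library_seqs_for_test(lib))
  expect_length(cl, 1)
  expect_equal(cl[[1]]$n_nodes, 400)
})

test_that("unrelated families split into disjoint clusters", {
  m1 <- build_monomer(40, 0.4, seed = 63)
  m2 <- build_monomer(55, 0.6, seed = 64)
  r1 <- library_seqs_for_test(
    simulate_reads(strrep(m1, 80), 120, error_rate = 0, seed = 65))
  r2 <- library_seqs_for_test(
    simulate_reads(strrep(m2, 60), 120, error_rate = 0, seed = 66))
  cl <- cluster_reads(c(r1, r2), min_cluster_size = 10)
  expect_length(cl, 2)
  ## each cluster holds exactly the reads of one family
  member_sets <- lapply(cl, `[[`, "ids")
  expect_setequal(lengths(member_sets), c(240, 240))
  from_m1 <- vapply(member_sets, function(ids) all(ids <= 240), logical(1))
  expect_equal(sort(from_m1), c(FALSE, TRUE))
})

test_that("low-coverage unique sequence yields no cluster", {
  genome <- build_monomer(200000, 0.5, seed = 67)
  lib <- simulate_reads(genome, 150, error_rate = 0, seed = 68)  # ~0.15x
  cl <- cluster_reads(library_seqs_for_test(lib))
  expect_length(cl, 0)
  expect_identical(cluster_reads(character(0)), list())
})

test_that("tandem detection recovers period and consensus exactly", {
  monomer <- build_monomer(51, 0.5, seed = 71)
  genome <- strrep(monomer, 80)
  lib <- simulate_reads(genome, 150, error_rate = 0, seed = 72)
  m <- detect_tandem(library_seqs_for_test(lib))
  expect_equal(m$period, 51)
  expect_identical(m$consensus, canonical_rotation(monomer))
})

test_that("consensus survives 5% divergence among copies", {
  monomer <- build_monomer(21, 0.5, seed = 73)
  arr <- with_seed(74, paste(vapply(1:120, function(i)
    mutate_seq(monomer, 0.05), character(1)), collapse = ""))
  lib <- simulate_reads(arr, 120, error_rate = 0, seed = 75)
  m <- detect_tandem(library_seqs_for_test(lib))
  expect_equal(m$period, 21)
  expect_gte(rotational_identity(m$consensus, monomer), 100 * 19 / 21)
})

test_that("tandem detection is rotation invariant", {
  monomer <- build_monomer(33, 0.5, seed = 76)
  g1 <- strrep(monomer, 60)
  g2 <- substr(paste0(g1, g1), 12, 12 + nchar(g1) - 1)  # rotated array
  m1 <- detect_tandem(library_seqs_for_test(
    simulate_reads(g1, 100, error_rate = 0, seed = 77)))
  m2 <- detect_tandem(library_seqs_for_test(
    simulate_reads(g2, 100, error_rate = 0, seed = 78)))
  expect_identical(m1$consensus, m2$consensus)
})

test_that("non-repetitive clusters yield no monomer", {
  genome <- build_monomer(3000, 0.5, seed = 79)
  lib <- simulate_reads(genome, 300, error_rate = 0, seed = 80)  # 20x
  seqs <- library_seqs_for_test(lib)
  expect_null(detect_tandem(seqs[1:100]))
})

test_that("periods above the read length are found via assembly", {
  monomer <- build_monomer(180, 0.5, seed = 81)
  genome <- strrep(monomer, 30)
  lib <- simulate_reads(genome, 250, error_rate = 0.005, seed = 82)
  m <- detect_tandem(library_seqs_for_test(lib))
  expect_equal(m$period, 180)
  expect_gte(rotational_identity(m$consensus, monomer), 98)
})

test_that("read-vote and assembly paths agree where both apply", {
  monomer <- build_monomer(40, 0.5, seed = 83)
  genome <- strrep(monomer, 80)
  seqs <- library_seqs_for_test(
    simulate_reads(genome, 150, error_rate = 0, seed = 84))
  m_votes <- detect_tandem(seqs)
  ## force the assembly path by disallowing read votes
  m_asm <- detect_tandem(seqs, min_votes = 1e9)
  expect_equal(m_votes$period, m_asm$period)
  expect_identical(m_votes$consensus, m_asm$consensus)
})

test_that("detected period matches a brute-force oracle on toy arrays", {
  ## oracle: smallest period with >= 80% exact self-match on the genome
  brute_period <- function(genome, pmax = 25) {
    n <- nchar(genome)
    ch <- strsplit(genome, "")[[1]]
    for (p in 2:pmax) {
      id <- mean(ch[1:(n - p)] == ch[(p + 1):n])
      if (id >= 0.8) return(p)
    }
    NA_integer_
  }
  for (s in 1:5) {
    rul <- sample(6:25, 1)
    monomer <- build_monomer(rul, 0.5, seed = 900 + s)
    genome <- strrep(monomer, ceiling(8000 / rul))
    truth <- brute_period(genome)
    m <- detect_tandem(library_seqs_for_test(
      simulate_reads(genome, 100, error_rate = 0, seed = 950 + s)))
    expect_equal(m$period, truth)
  }
})

test_that("subtraction removes repeat pairs and keeps background", {
  pair <- demo_pair()
  lib <- simulate_reads(pair$seq_0B, 3000, error_rate = 0, seed = 85,
                        genome_label = "0B")
  monomers <- pair$truth$monomer[pair$truth$family %in% c("famA", "famB")]
  sub <- subtract_reads(lib, monomers)
  ## truth: pairs with >= half a read inside an array should all be gone
  iv <- family_intervals(pair, "0B")
  iv <- iv[iv$family != "bspec", ]
  l <- lib$read_len
  ov_half <- function(s) {
    o <- pmax(0, pmin(iv$end, s + l - 1) - pmax(iv$start, s) + 1)
    max(o) >= l / 2
  }
  s1 <- lib$truth$start
  s2 <- lib$truth$start + lib$truth$insert - l
  repeat_pair <- vapply(seq_len(lib$n_pairs), function(i)
    ov_half(s1[i]) || ov_half(s2[i]), logical(1))
  kept <- sub$library$pair_ids
  expect_length(intersect(kept, which(repeat_pair)), 0)
  ## background-only pairs are retained
  bg_pair <- !vapply(seq_len(lib$n_pairs), function(i) {
    o1 <- pmax(0, pmin(iv$end, s1[i] + l - 1) - pmax(iv$start, s1[i]) + 1)
    o2 <- pmax(0, pmin(iv$end, s2[i] + l - 1) - pmax(iv$start, s2[i]) + 1)
    any(o1 > 0) || any(o2 > 0)
  }, logical(1))
  expect_true(all(which(bg_pair) %in% kept))
  ## empty catalog returns the library unchanged
  sub0 <- subtract_reads(lib, character(0))
  expect_identical(sub0$library$reads1, lib$reads1)
  expect_equal(sub0$removed, 0)
})

test_that("sampling reads is uniform, capped and deterministic", {
  pair <- demo_pair()
  lib <- simulate_reads(pair$seq_0B, 1000, seed = 86)
  expect_error(sample_reads(lib, 1001), "cannot sample")
  full <- sample_reads(lib, 1000)
  expect_identical(full$reads1, lib$reads1)   # whole library, order-stable
  s1 <- sample_reads(lib, 100, seed = 5)
  s2 <- sample_reads(lib, 100, seed = 5)
  expect_identical(s1$pair_ids, s2$pair_ids)
  expect_length(s1$pair_ids, 100)
})

test_that("mining recovers well-separated families and terminates", {
  pair <- demo_pair()
  libs <- demo_libs()
  mine <- mine_satellitome(libs$lib_1B, start_pairs = 500, seed = 9)
  ids <- vapply(mine$monomers, function(m)
    max(vapply(pair$truth$monomer, function(t)
      rotational_identity(m$consensus, t), numeric(1))), numeric(1))
  expect_gte(length(mine$monomers), 3)
  expect_true(all(ids >= 95))
  ## every planted family matched by some monomer
  fam_hit <- vapply(pair$truth$monomer, function(t)
    any(vapply(mine$monomers, function(m)
      rotational_identity(m$consensus, t) >= 95, logical(1))), logical(1))
  expect_true(all(fam_hit))
  ## catalog never shrinks and the log records termination
  expect_equal(tail(mine$log$new_monomers, 1), 0)
})

test_that("a repeat-free genome yields an empty catalog after iteration 1", {
  genome <- build_monomer(150000, 0.5, seed = 87)
  lib <- simulate_reads(genome, 2000, error_rate = 0.01, seed = 88)
  mine <- mine_satellitome(lib, start_pairs = 1000, seed = 89)
  expect_length(mine$monomers, 0)
  expect_equal(nrow(mine$log), 1)
})
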