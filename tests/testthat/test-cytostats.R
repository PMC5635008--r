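test_that("location tables are validated on read", {
  locA <- apa_locations_A()
  expect_equal(nrow(locA), 108)   # 36 satellites x 3 species
  expect_setequal(unique(locA$pattern), c("c", "nc", "t", "ns"))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("satellite\tspecies\tchromosome\tpattern\tregions",
               "S1\tsp\tA\tc\tp:x"), bad)
  expect_error(read_location_table(bad), "region")
  writeLines(c("satellite\tspecies\tchromosome\tpattern\tregions",
               "S1\tsp\tA\tnc\tp:t"), bad)
  expect_error(read_location_table(bad), "non-clustered")
})

test_that("symmetry index reproduces the three B-chromosome values", {
  locB <- apa_locations_B()
  si <- lapply(c("BpM", "BfMa", "BbM"), function(b)
    symmetry_index(locB[locB$chromosome == b, ]))
  names(si) <- c("BpM", "BfMa", "BbM")
  expect_equal(si$BpM$si, 1)
  expect_equal(si$BbM$si, 1)
  expect_equal(si$BfMa$n_noncentromeric, 11)
  expect_equal(si$BfMa$n_symmetric, 5)
  expect_equal(round(si$BfMa$si, 2), 0.45)
})

test_that("symmetry scoring follows the arm-set rule", {
  rec <- function(sat, regions) data.frame(
    satellite = sat, species = "sp", chromosome = "B1", pattern = "c",
    regions = regions, stringsAsFactors = FALSE)
  ## single satellite on one arm only: non-symmetric
  expect_equal(symmetry_index(rec("s1", "p:t"))$si, 0)
  ## pericentromeric-only satellites are excluded
  expect_true(is.na(symmetry_index(rec("s1", "pe"))$si))
  ## pe is arm-neutral; arm sets decide
  expect_equal(symmetry_index(rec("s1", "pe;p:i;q:i"))$si, 1)
  ## terminal and distal are one arm-end class
  expect_equal(symmetry_index(rec("s1", "p:t;q:d"))$si, 1)
  expect_equal(symmetry_index(rec("s1", "p:i;q:t"))$si, 0)
  ## invariant under consistent arm relabelling (p <-> q)
  locB <- apa_locations_B()
  for (b in c("BpM", "BfMa", "BbM")) {
    r <- locB[locB$chromosome == b, ]
    r2 <- r
    r2$regions <- vapply(r$regions, function(x) {
      y <- chartr("pq", "qp", x)
      ## chartr also hits the 'p' in 'pe'; restore it
      gsub("qe", "pe", y)
    }, character(1))
    expect_equal(symmetry_index(r2)$si, symmetry_index(r)$si)
  }
})

test_that("Mann-Whitney reproduces U = 26 on the RUL comparison", {
  g <- apa_rul_by_pattern()
  expect_length(g$clustered, 30)
  expect_length(g$non_clustered, 5)
  mw <- mann_whitney(g$clustered, g$non_clustered)
  expect_equal(mw$value, 26)
  expect_lt(mw$p_value, 0.05)
  ## the tie-corrected normal approximation gives the printed P
  mwn <- mann_whitney(g$clustered, g$non_clustered, method = "normal")
  expect_equal(round(mwn$p_value, 3), 0.021)
})

test_that("Mann-Whitney exact P matches exhaustive enumeration oracles", {
  brute <- function(x, y) {
    n <- length(x); m <- length(y)
    r <- rank(c(x, y))
    U1 <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    Uo <- min(U1, n * m - U1)
    cmb <- combn(n + m, n)
    us <- apply(cmb, 2, function(ix) sum(r[ix])) - n * (n + 1) / 2
    mean(us <= Uo | us >= n * m - Uo)
  }
  set.seed(10)
  for (i in 1:8) {
    x <- sample(1:10, sample(2:4, 1), replace = TRUE)
    y <- sample(1:10, sample(2:4, 1), replace = TRUE)
    mw <- mann_whitney(x, y, method = "exact")
    expect_equal(mw$p_value, brute(x, y))
  }
  ## identical samples: U = n^2/2 and P ~ 1
  x <- c(1, 2, 3, 4)
  mw <- mann_whitney(x, x)
  expect_equal(mw$value, length(x)^2 / 2)
  expect_gt(mw$p_value, 0.99)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney agrees with wilcox.test on tie-free data", {
  set.seed(11)
  x <- rnorm(7); y <- rnorm(6) + 1
  mw <- mann_whitney(x, y, method = "exact")
  wt <- wilcox.test(x, y, exact = TRUE)
  expect_equal(mw$value, min(wt$statistic, length(x) * length(y) -
                               wt$statistic))
  expect_equal(mw$p_value, wt$p.value)
})

test_that("Fisher exact test reproduces the shared-cluster P = 0.1007", {
  tab <- shared_cluster_table(apa_locations_A(), apa_locations_B(),
                              reference = "paranae")
  expect_equal(unname(tab), matrix(c(26, 4, 12, 6), 2, byrow = TRUE))
  ## the printed value is the one-sided tail
  expect_equal(round(fisher_exact_2x2(tab, "greater")$value, 4), 0.1007)
  ## probability-mass two-sided agrees with the base-R implementation
  expect_equal(fisher_exact_2x2(tab)$value,
               fisher.test(tab)$p.value, tolerance = 1e-10)
})

test_that("Fisher exact matches direct enumeration on small tables", {
  brute_two_sided <- function(tab) {
    m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
    xs <- max(0, k - n2):min(k, m)
    probs <- vapply(xs, function(x) {
      choose(m, x) * choose(n2, k - x) / choose(m + n2, k)
    }, numeric(1))
    dob <- probs[xs == tab[1, 1]]
    sum(probs[probs <= dob * (1 + 1e-7)])
  }
  set.seed(12)
  for (i in 1:10) {
    tab <- matrix(sample(1:6, 4, replace = TRUE), 2)
    expect_equal(fisher_exact_2x2(tab)$value, brute_two_sided(tab),
                 tolerance = 1e-12)
  }
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2))$value, 1)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 1, 1), 2)), "margins")
})

test_that("Spearman rank correlation behaves and nears the printed value", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_test(x, x)$value, 1)
  expect_equal(spearman_test(x, rev(x))$value, -1)
  expect_error(spearman_test(x, rep(1, 5)), "constant")

  sat <- apa_satellitome()
  sp <- spearman_test(sat$rul, sat$at_percent)
  ct <- suppressWarnings(cor.test(sat$rul, sat$at_percent,
                                  method = "spearman"))
  expect_equal(sp$value, unname(ct$estimate), tolerance = 1e-10)
  ## printed r_S = 0.34; the transcribed table reproduces it to ~0.01
  expect_lt(abs(sp$value - 0.34), 0.015)
  expect_lt(sp$p_value, 0.05)
})

test_that("Levene's test reproduces F = 2.5 with df = (1, 33)", {
  g <- apa_rul_by_pattern()
  lv <- levene_test(g$clustered, g$non_clustered)
  expect_equal(round(lv$value, 1), 2.5)
  expect_equal(lv$df, c(1, 33))
  expect_equal(round(lv$p_value, 3), 0.124)
})

test_that("Levene's test matches the two-group formula on a toy input", {
  x <- c(1, 4, 7); y <- c(2, 2, 8)
  z <- c(abs(x - mean(x)), abs(y - mean(y)))
  g <- rep(1:2, each = 3)
  zb <- tapply(z, g, mean); n <- 3
  ssb <- sum(n * (zb - mean(z))^2)
  ssw <- sum((z - zb[g])^2)
  f_hand <- (ssb / 1) / (ssw / 4)
  lv <- levene_test(x, y)
  expect_equal(lv$value, f_hand, tolerance = 1e-12)
  ## identical spread pattern in both groups: F = 0
  expect_equal(levene_test(c(1, 2, 3), c(11, 12, 13))$value, 0)
  expect_error(levene_test(c(1, 1), c(2, 2)), "undefined")
})

test_that("Shapiro-Wilk separates normal from heavy-tailed samples", {
  expect_gt(shapiro_wilk(qnorm(ppoints(50)))$value, 0.99)
  set.seed(13)
  mix <- c(rnorm(40, 0, 0.2), rnorm(5, 8, 0.2))
  expect_lt(shapiro_wilk(mix)$p_value, 0.05)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")

  ## A+T content is the one satellitome feature near normality
  sat <- apa_satellitome()
  sw <- shapiro_wilk(sat$at_percent)
  expect_lt(abs(sw$value - 0.978), 0.002)
  expect_gt(sw$p_value, 0.05)
})

test_that("RUL summaries reproduce the printed medians and variances", {
  g <- apa_rul_by_pattern()
  s <- summarize_rul(c(g$clustered, g$non_clustered),
                     rep(c("c", "nc"), c(30, 5)))
  nc <- s$by_group[s$by_group$group == "nc", ]
  cl <- s$by_group[s$by_group$group == "c", ]
  expect_equal(nc$median, 21)
  expect_equal(nc$variance, 1423.5)
  expect_equal(cl$median, 77.5)
  expect_equal(round(cl$variance, 1), 6448.3)
  expect_equal(sum(s$by_group$n), 35)
  ## single-member group: median defined, variance missing
  s1 <- summarize_rul(c(5, 7, 9), c("a", "a", "b"))
  expect_true(is.na(s1$by_group$variance[s1$by_group$group == "b"]))
  expect_equal(s1$by_group$median[s1$by_group$group == "b"], 9)
})
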