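#' Read a satellite chromosomal-location table
#'
#' Expected columns: `satellite`, `species`, `chromosome` (e.g. `A` or a
#' named B such as `BpM`), `pattern` (`c` clustered, `nc` non-clustered,
#' `t` telomeric, `ns` no signal scored), and `regions`: semicolon-separated
#' arm:code tokens (e.g. `p:t;q:t`), with `pe` for the arm-neutral
#' pericentromeric region. Region codes: `pe` pericentromeric, `i`
#' interstitial, `t` terminal, `d` distal; arms `p` (short) and `q` (long).
#'
#' @param path TSV file.
#' @return data frame of location records.
#' @export
read_location_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  need <- c("satellite", "species", "chromosome", "pattern", "regions")
  if (!all(need %in% names(df)))
    stop("location table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$regions[is.na(df$regions)] <- ""
  ok_pat <- df$pattern %in% c("c", "nc", "t", "ns")
  if (!all(ok_pat))
    stop("invalid pattern value(s): ",
         paste(unique(df$pattern[!ok_pat]), collapse = ", "), call. = FALSE)
  bad <- vapply(df$regions, function(r) {
    if (!nzchar(r)) return(FALSE)
    toks <- strsplit(r, ";", fixed = TRUE)[[1]]
    !all(grepl("^(pe|[pq]:(pe|i|t|d))$", toks))
  }, logical(1))
  if (any(bad))
    stop("invalid region token(s) in: ",
         paste(unique(df$regions[bad]), collapse = " | "), call. = FALSE)
  nc_bad <- df$pattern == "nc" & nzchar(df$regions)
  if (any(nc_bad))
    stop("non-clustered records cannot carry regions", call. = FALSE)
  df
}

#' Parse a regions string into per-arm code sets
#' @noRd
parse_regions <- function(r) {
  out <- list(pe = FALSE, p = character(0), q = character(0))
  if (!nzchar(r)) return(out)
  for (tok in strsplit(r, ";", fixed = TRUE)[[1]]) {
    if (tok == "pe") { out$pe <- TRUE; next }
    arm <- substr(tok, 1, 1)
    code <- substr(tok, 3, nchar(tok))
    if (code == "pe") { out$pe <- TRUE; next }
    out[[arm]] <- union(out[[arm]], code)
  }
  out
}

#' Symmetry index of a B chromosome's satellite distribution
#'
#' A satellite clustered on a B chromosome is scored symmetric (1) when its
#' region-code set on the short arm equals its set on the long arm, and
#' non-symmetric (0) otherwise. Pericentromeric clusters are arm-neutral:
#' they are ignored in the comparison, and satellites with only
#' pericentromeric clusters are excluded. Terminal (`t`) and distal (`d`)
#' codes denote the same arm-end class and are merged before comparison
#' (an iso-chromosome-derived B with a cluster at both arm ends is
#' symmetric whether the ends are scored terminal or distal). The symmetry
#' index is the mean indicator over the scored satellites; it is `NA` when
#' no non-pericentromeric satellite is present.
#'
#' @param records location records ([read_location_table()]) for clustered
#'   satellites of a single B chromosome.
#' @param merge_terminal_distal treat `t` and `d` as one class (default).
#' @return list of class `symmetry_record`: B name, n_clusters,
#'   n_noncentromeric, n_symmetric, si, and the per-satellite indicators.
#' @export
symmetry_index <- function(records, merge_terminal_distal = TRUE) {
  b <- unique(records$chromosome)
  if (length(b) != 1)
    stop("records must all belong to one B chromosome", call. = FALSE)
  cl <- records[records$pattern == "c", , drop = FALSE]
  ind <- setNames(rep(NA, nrow(cl)), cl$satellite)
  for (i in seq_len(nrow(cl))) {
    reg <- parse_regions(cl$regions[i])
    p <- reg$p; q <- reg$q
    if (merge_terminal_distal) {
      p[p == "d"] <- "t"; q[q == "d"] <- "t"
    }
    if (length(p) == 0 && length(q) == 0) next  # pericentromeric only
    ind[i] <- as.integer(setequal(p, q))
  }
  scored <- ind[!is.na(ind)]
  structure(list(b = b, n_clusters = nrow(cl),
                 n_noncentromeric = length(scored),
                 n_symmetric = sum(scored),
                 si = if (length(scored)) mean(scored) else NA_real_,
                 indicators = ind),
            class = "symmetry_record")
}

#' @export
print.symmetry_record <- function(x, ...) {
  cat(sprintf("%s: %d clustered satellites, %d non-centromeric, SI = %s\n",
              x$b, x$n_clusters, x$n_noncentromeric,
              if (is.na(x$si)) "undefined" else sprintf("%.2f", x$si)))
  invisible(x)
}

#' @noRd
stat_result <- function(name, value, p_value, ...) {
  structure(c(list(statistic = name, value = value, p_value = p_value),
              list(...)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  extras <- setdiff(names(x), c("statistic", "value", "p_value"))
  cat(sprintf("%s = %.4g", x$statistic, x$value))
  for (e in extras) {
    v <- x[[e]]
    if (is.numeric(v) && length(v) <= 2)
      cat(sprintf(", %s = %s", e, paste(signif(v, 4), collapse = ", ")))
  }
  cat(sprintf(", P = %.4g\n", x$p_value))
  invisible(x)
}

#' Mann-Whitney U test with midranks
#'
#' Reports U = min(U1, U2). The two-sided P value is exact - computed by
#' enumerating all arrangements of the pooled midranks - whenever
#' choose(n + m, min(n, m)) does not exceed `enum_limit`; otherwise (or with
#' `method = "normal"`) the tie-corrected normal approximation without
#' continuity correction is used.
#'
#' @param x,y non-empty numeric vectors.
#' @param method "auto" (exact when feasible), "exact" or "normal".
#' @param enum_limit maximum number of arrangements enumerated.
#' @return `stat_result` with U, z (normal method), and P.
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "normal"),
                         enum_limit = 2e6) {
  method <- match.arg(method)
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U1 <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  U2 <- n * m - U1
  U <- min(U1, U2)
  n_arr <- choose(n + m, min(n, m))
  do_exact <- method == "exact" ||
    (method == "auto" && n_arr <= enum_limit)
  if (do_exact) {
    if (n_arr > enum_limit)
      stop("exact enumeration infeasible: ", format(n_arr), " arrangements",
           call. = FALSE)
    kk <- min(n, m)
    cmb <- combn(n + m, kk)
    usum <- colSums(matrix(r[cmb], nrow = kk)) - kk * (kk + 1) / 2
    ## two-sided: arrangements at least as extreme on either tail
    p <- mean(usum <= U | usum >= n * m - U)
    stat_result("U", U, p, method = "exact")
  } else {
    mu <- n * m / 2
    ties <- table(r)
    sig2 <- n * m / 12 *
      ((n + m + 1) - sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
    z <- (U1 - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    stat_result("U", U, min(1, p), z = z, method = "normal")
  }
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided P sums the hypergeometric probabilities of all tables with the
#' observed margins whose probability does not exceed the observed table's
#' (with a 1e-7 relative slack); one-sided alternatives sum the
#' corresponding tail.
#'
#' @param table 2x2 matrix of non-negative counts with all margins > 0.
#' @param alternative "two.sided", "greater" (association in the direction
#'   of the observed top-left excess) or "less".
#' @return `stat_result` with the odds-ratio-free exact P.
#' @export
fisher_exact_2x2 <- function(table,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table)))
    stop("need a 2x2 table of non-negative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins must be positive", call. = FALSE)
  x <- table[1, 1]
  m <- sum(table[1, ]); n2 <- sum(table[2, ]); k <- sum(table[, 1])
  lo <- max(0, k - n2); hi <- min(k, m)
  d <- dhyper(lo:hi, m, n2, k)
  dob <- dhyper(x, m, n2, k)
  p <- switch(alternative,
    two.sided = sum(d[d <= dob * (1 + 1e-7)]),
    greater = sum(dhyper(x:hi, m, n2, k)),
    less = sum(dhyper(lo:x, m, n2, k)))
  stat_result("P_Fisher", min(1, p), min(1, p), alternative = alternative)
}

#' Spearman rank correlation with the t approximation
#'
#' Pearson correlation of midranks; significance from
#' t = r sqrt((n-2)/(1-r^2)) on n - 2 degrees of freedom (two-sided).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return `stat_result` with r_S, t, df and P.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("correlation undefined for constant input", call. = FALSE)
  n <- length(x)
  r <- cor(rank(x), rank(y))
  t <- r * sqrt((n - 2) / (1 - r^2))
  stat_result("r_S", r, 2 * pt(-abs(t), n - 2), t = t, df = n - 2)
}

#' Levene's test for equality of variances (two groups)
#'
#' Classic Levene: one-way ANOVA F on absolute deviations from the group
#' center (mean by default; `center = "median"` gives the Brown-Forsythe
#' variant), with df = (1, n - 2).
#'
#' @param x,y numeric vectors with >= 2 elements each.
#' @param center "mean" or "median".
#' @return `stat_result` with F, df and P.
#' @export
levene_test <- function(x, y, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(x) < 2 || length(y) < 2)
    stop("both groups need >= 2 observations", call. = FALSE)
  cfun <- if (center == "mean") mean else median
  z <- c(abs(x - cfun(x)), abs(y - cfun(y)))
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  if (all(z == z[1]))
    stop("Levene F undefined: no dispersion in deviations", call. = FALSE)
  a <- anova(lm(z ~ g))
  stat_result("F", a$`F value`[1], a$`Pr(>F)`[1],
              df = c(a$Df[1], a$Df[2]))
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard Royston approximation
#' ([stats::shapiro.test()]) returning the package's `stat_result` shape.
#'
#' @param x numeric vector, 3 <= n <= 5000.
#' @return `stat_result` with W and P.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  s <- shapiro.test(x)
  stat_result("W", unname(s$statistic), s$p.value)
}

#' Repeat-unit-length summary by chromosomal distribution pattern
#'
#' Per pattern group: n, median, sample variance (n - 1 denominator,
#' undefined for single-member groups), min and max; plus the satellitome-
#' wide median RUL and the count of families shorter than 100 bp.
#'
#' @param rul numeric vector of repeat unit lengths.
#' @param group pattern group of each family (e.g. `c` / `nc`; the telomeric
#'   satellite is conventionally excluded from the dichotomy by its own
#'   `t` group).
#' @return list with `by_group` (data frame) and `overall`
#'   (median RUL, n below 100 bp).
#' @export
summarize_rul <- function(rul, group) {
  stopifnot(length(rul) == length(group))
  gs <- split(rul, group)
  by_group <- do.call(rbind, lapply(names(gs), function(g) {
    v <- gs[[g]]
    data.frame(group = g, n = length(v), median = median(v),
               variance = if (length(v) > 1) var(v) else NA_real_,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  list(by_group = by_group,
       overall = list(median_rul = median(rul),
                      n_below_100 = sum(rul < 100),
                      n = length(rul)))
}

#' Shared-cluster 2x2 table for the A- versus B-chromosome comparison
#'
#' Rows: A chromosomes, B chromosomes. Columns: satellites whose clusters
#' are shared with at least one other species, not shared. A satellites are
#' those clustered in the reference species (pattern `c` on chromosome `A`);
#' sharing means a cluster on the A chromosomes of another species.
#' B satellites are those clustered on any of the B chromosomes; sharing
#' means presence on at least two species' Bs.
#'
#' @param loc_A A-chromosome location records for all species (reference
#'   species first in `species_order`).
#' @param loc_B B-chromosome location records (one row per satellite and B).
#' @param reference reference species name.
#' @return 2x2 integer matrix.
#' @export
shared_cluster_table <- function(loc_A, loc_B, reference) {
  ref <- loc_A[loc_A$species == reference & loc_A$chromosome == "A" &
                 loc_A$pattern == "c", "satellite"]
  other <- loc_A[loc_A$species != reference & loc_A$chromosome == "A" &
                   loc_A$pattern == "c", "satellite"]
  a_shared <- sum(ref %in% other)
  b_count <- table(loc_B$satellite[loc_B$pattern == "c"])
  b_total <- length(b_count)
  b_shared <- sum(b_count >= 2)
  matrix(c(a_shared, length(ref) - a_shared,
           b_shared, b_total - b_shared),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("A", "B"), c("shared", "not_shared")))
}
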