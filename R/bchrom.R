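#' log2 abundance ratio between the 1B and 0B genomes
#'
#' @param a1,a0 abundance percentages in the 1B and 0B genomes; both must be
#'   strictly positive (a zero abundance leaves the ratio undefined - such
#'   families are assessed by tandem-structure scanning instead).
#' @return log2(a1/a0), vectorised.
#' @export
log2_ratio <- function(a1, a0) {
  if (any(!is.finite(a1)) || any(!is.finite(a0)) ||
      any(a1 <= 0) || any(a0 <= 0))
    stop("log2 ratio undefined for non-positive abundances", call. = FALSE)
  log2(a1 / a0)
}

#' Expected maximum relative abundance decrease in a 1B genome
#'
#' When one B chromosome of length fraction `f` (relative to the haploid A
#' complement) is added to a diploid A complement, a satellite entirely
#' absent from the B is diluted by 1/(1 + f/2); the largest possible relative
#' decrease of its abundance is therefore (f/2)/(1 + f/2). At f = 0.08 this
#' is 0.0385, i.e. about 4%.
#'
#' @param f B length as a fraction of the haploid A complement, in \[0, 1).
#' @return the maximum relative decrease, as a fraction.
#' @export
expected_max_decrease <- function(f) {
  if (any(f < 0) || any(f >= 1)) stop("f must be in [0, 1)", call. = FALSE)
  (f / 2) / (1 + f / 2)
}

#' Compare per-family abundances between the 0B and 1B genomes
#'
#' Builds one record per family with the log2 ratio and a classification:
#' a positive log2 flags a B-enrichment candidate; a decrease is compared
#' with the maximum decrease expected from pure dilution
#' ([expected_max_decrease()]): within it, absence from the B suffices to
#' explain the loss; beyond it, dilution cannot explain the difference
#' (pointing at between-individual variation). Families with a zero
#' abundance on either side are classified `undefined` and left to the
#' tandem-structure path ([multimer_scan()], [targeted_recluster()]).
#'
#' @param ab_0B,ab_1B per-family abundance tables ([quantify_library()]) for
#'   the 0B and 1B libraries.
#' @param f B length fraction of the haploid A complement.
#' @return data frame: family, a0, a1, log2_ratio, expected_max_decrease,
#'   classification.
#' @export
b_comparison <- function(ab_0B, ab_1B, f) {
  m <- merge(ab_0B[, c("family", "abundance_percent")],
             ab_1B[, c("family", "abundance_percent")],
             by = "family", suffixes = c("_0B", "_1B"), all = TRUE)
  m[is.na(m)] <- 0
  rec <- data.frame(family = m$family,
                    a0 = m$abundance_percent_0B, a1 = m$abundance_percent_1B,
                    log2_ratio = NA_real_,
                    f = f, expected_max_decrease = expected_max_decrease(f),
                    stringsAsFactors = FALSE)
  ok <- rec$a0 > 0 & rec$a1 > 0
  rec$log2_ratio[ok] <- log2(rec$a1[ok] / rec$a0[ok])
  classify_b(rec)
}

#' Classify B-comparison records against the dilution threshold
#'
#' @param records data frame with columns a0, a1, log2_ratio,
#'   expected_max_decrease.
#' @return the records with a `classification` column: one of
#'   `B-enriched candidate`, `decrease-within-threshold`,
#'   `decrease-beyond-threshold`, `undefined`.
#' @export
classify_b <- function(records) {
  cls <- rep("undefined", nrow(records))
  ok <- is.finite(records$log2_ratio)
  dec <- 1 - records$a1 / records$a0
  cls[ok & records$log2_ratio > 0] <- "B-enriched candidate"
  within <- ok & records$log2_ratio <= 0 &
    dec <= records$expected_max_decrease
  cls[within] <- "decrease-within-threshold"
  cls[ok & records$log2_ratio <= 0 & !within] <- "decrease-beyond-threshold"
  records$classification <- cls
  records
}

#' Count reads carrying consecutive monomer copies (multimer scan)
#'
#' Searches reads for at least `min_copies` consecutive, circularly phased
#' copies of the monomer, each at >= `min_identity` identity. A satellite
#' that is genuinely tandem yields many such reads; one present only as
#' dispersed single copies yields none - the criterion used to call a
#' satellite B-specific despite a small read abundance in the 0B library.
#'
#' @param reads character vector or `read_library` (both mates scanned).
#' @param monomer monomer sequence.
#' @param min_copies minimum consecutive copies (default 2 = dimer).
#' @param min_identity per-copy identity threshold.
#' @return number of reads with a qualifying multimer run.
#' @export
multimer_scan <- function(reads, monomer, min_copies = 2,
                          min_identity = 0.8) {
  if (inherits(reads, "read_library")) reads <- library_seqs(reads)
  assert_dna(monomer, "monomer")
  if (!length(reads)) return(0L)
  rl <- nchar(reads[1])
  if (nchar(monomer) * min_copies > rl)
    stop("monomer too long to fit ", min_copies, " copies in a ", rl,
         "-bp read", call. = FALSE)
  ## seed prefilter: only reads sharing a k-mer with the monomer are scanned
  cand <- unique(cpp_mask(reads, monomer, 0.0, 1L, 9L)$read)
  if (!length(cand)) return(0L)
  runs <- cpp_multimer_runs(reads[cand], monomer, min_identity)
  sum(runs >= min_copies)
}

#' Targeted reclustering of reads homologous to one satellite
#'
#' Emulates the B-specificity verification step: from each library
#' separately, select up to `n` read pairs homologous to the monomer, rerun
#' read clustering plus tandem detection on the selection, and report whether
#' tandem structure is present in each library.
#'
#' @param lib_0B,lib_1B the two read libraries.
#' @param monomer satellite monomer sequence.
#' @param n maximum selected pairs per library (default 2500).
#' @param min_identity,min_cov homology thresholds for selecting pairs (the
#'   same thresholds as [subtract_reads()]).
#' @param min_cluster_size,tandem_threshold passed to the clustering and
#'   tandem-detection steps.
#' @return data frame with one row per library: reads selected, tandem
#'   detected, detected period.
#' @export
targeted_recluster <- function(lib_0B, lib_1B, monomer, n = 2500,
                               min_identity = 0.80, min_cov = 0.50,
                               min_cluster_size = 10,
                               tandem_threshold = 0.8) {
  assert_dna(monomer, "monomer")
  one <- function(lib, label) {
    min_len <- as.integer(ceiling(min_cov * lib$read_len))
    h1 <- cpp_mask(lib$reads1, monomer, min_identity, min_len, 9L)$read
    h2 <- cpp_mask(lib$reads2, monomer, min_identity, min_len, 9L)$read
    sel <- sort(union(h1, h2))
    if (length(sel) > n) sel <- sel[seq_len(n)]
    if (!length(sel))
      return(data.frame(library = label, reads_selected = 0L,
                        tandem = FALSE, period = NA_integer_))
    seqs <- c(lib$reads1[sel], lib$reads2[sel])
    clusters <- cluster_reads(seqs, min_cluster_size = min_cluster_size)
    ## tandem structure counts only if a detected monomer is the queried
    ## satellite (mates of selected pairs can drag in neighbouring repeats)
    tandem <- FALSE; period <- NA_integer_
    for (cl in clusters) {
      for (m in detect_tandems_in_cluster(cl, 5, 500, tandem_threshold,
                                          NA)) {
        if (rotational_identity(m$consensus, monomer) >= 80) {
          tandem <- TRUE; period <- m$period; break
        }
      }
      if (tandem) break
    }
    data.frame(library = label, reads_selected = length(sel),
               tandem = tandem, period = period)
  }
  rbind(one(lib_0B, "0B"), one(lib_1B, "1B"))
}
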