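#' Specify a satellite DNA family to plant in a synthetic genome
#'
#' A family is planted as one tandem array per sequence variant, with each
#' monomer copy independently mutated at the family's intra-family divergence.
#' A family can additionally (or, for B-restricted families, exclusively)
#' appear as isolated single monomer copies dispersed through the A complement
#' (`dispersed_0B`), emulating satellites that are genomically present but not
#' tandemly organised outside the B chromosome.
#'
#' @param label unique family label.
#' @param rul repeat unit length in bp (6--1000).
#' @param at_frac target A+T fraction of the base monomer, in \[0, 1\].
#' @param copies_0B tandem monomer copies planted in the A (0B) complement.
#' @param copies_B tandem monomer copies planted in the B segment.
#' @param intra_divergence expected per-site substitution fraction applied
#'   independently to every planted copy, in \[0, 0.3\].
#' @param n_variants number of sequence variants (>= 1). Variants beyond the
#'   first are derived from the base monomer at `variant_divergence` (see
#'   [plant_families()]) so they group as distinct variants of one family.
#' @param superfamily_partner optional label of an earlier family this one is
#'   derived from, at `partner_identity` target identity.
#' @param partner_identity target rotational identity to the partner, in
#'   \[0.5, 0.8) so the pair groups as two families of one superfamily.
#' @param b_restricted if `TRUE` the family has no tandem array in the A
#'   complement (`copies_0B` must be 0); it may still be present as dispersed
#'   single copies.
#' @param dispersed_0B number of isolated, non-tandem single monomer copies
#'   planted in the A complement.
#' @return an object of class `family_spec`.
#' @export
family_spec <- function(label, rul, at_frac = 0.5, copies_0B = 0, copies_B = 0,
                        intra_divergence = 0, n_variants = 1,
                        superfamily_partner = NULL, partner_identity = NULL,
                        b_restricted = FALSE, dispersed_0B = 0) {
  stopifnot(is.character(label), length(label) == 1, nzchar(label))
  if (rul < 6 || rul > 1000)
    stop("rul must be in [6, 1000]", call. = FALSE)
  if (at_frac < 0 || at_frac > 1)
    stop("at_frac must be in [0, 1]", call. = FALSE)
  if (intra_divergence < 0 || intra_divergence > 0.3)
    stop("intra_divergence must be in [0, 0.3]", call. = FALSE)
  if (n_variants < 1) stop("n_variants must be >= 1", call. = FALSE)
  if (b_restricted && copies_0B != 0)
    stop("b_restricted families must have copies_0B = 0", call. = FALSE)
  if (b_restricted && copies_B <= 0)
    stop("b_restricted families must have copies_B > 0", call. = FALSE)
  if (!is.null(superfamily_partner)) {
    if (is.null(partner_identity) ||
        partner_identity < 0.5 || partner_identity >= 0.8)
      stop("partner_identity must lie in [0.5, 0.8)", call. = FALSE)
  }
  structure(list(label = label, rul = as.integer(rul), at_frac = at_frac,
                 copies_0B = as.integer(copies_0B),
                 copies_B = as.integer(copies_B),
                 intra_divergence = intra_divergence,
                 n_variants = as.integer(n_variants),
                 superfamily_partner = superfamily_partner,
                 partner_identity = partner_identity,
                 b_restricted = isTRUE(b_restricted),
                 dispersed_0B = as.integer(dispersed_0B)),
            class = "family_spec")
}

#' Generate a random satellite monomer
#'
#' Bases are drawn i.i.d. with P(A) = P(T) = `at_frac`/2 and
#' P(C) = P(G) = (1 - `at_frac`)/2, so the expected A+T fraction equals
#' `at_frac`.
#'
#' @param rul monomer length in bp (>= 1; satellite monomers use >= 6).
#' @param at_frac target A+T fraction in \[0, 1\].
#' @param seed optional integer seed; the result is deterministic given it.
#' @return a nucleotide string of length `rul`.
#' @export
build_monomer <- function(rul, at_frac = 0.5, seed = NULL) {
  if (!is.numeric(rul) || rul < 1) stop("rul must be >= 1", call. = FALSE)
  if (at_frac < 0 || at_frac > 1)
    stop("at_frac must be in [0, 1]", call. = FALSE)
  p <- c(at_frac / 2, (1 - at_frac) / 2, (1 - at_frac) / 2, at_frac / 2)
  with_seed(seed, paste(sample(DNA_BASES4, rul, replace = TRUE, prob = p),
                        collapse = ""))
}

#' Mutate a sequence by random substitutions
#'
#' @param s nucleotide string.
#' @param divergence per-site substitution probability, or exact fraction when
#'   `exact = TRUE` (then `round(divergence * nchar(s))` distinct sites are
#'   substituted).
#' @param exact hit an exact number of sites rather than a Bernoulli draw.
#' @return mutated string.
#' @export
mutate_seq <- function(s, divergence, exact = FALSE) {
  assert_dna(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  idx <- if (exact) sample.int(n, round(divergence * n))
         else which(runif(n) < divergence)
  if (length(idx)) {
    shift <- sample.int(3, length(idx), replace = TRUE)
    code <- match(ch[idx], DNA_BASES4) - 1L
    ch[idx] <- DNA_BASES4[((code + shift) %% 4L) + 1L]
  }
  paste(ch, collapse = "")
}

#' @noRd
random_dna <- function(n, at_frac = 0.5) {
  p <- c(at_frac / 2, (1 - at_frac) / 2, (1 - at_frac) / 2, at_frac / 2)
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

#' Build a tandem array: head-to-tail copies, each independently mutated
#' @noRd
build_array <- function(monomer, copies, divergence) {
  if (copies == 0) return("")
  copies_v <- vapply(seq_len(copies), function(i)
    if (divergence > 0) mutate_seq(monomer, divergence) else monomer,
    character(1))
  paste(copies_v, collapse = "")
}

#' Split copy numbers among variants with a geometric weighting so the first
#' variant is always the most abundant
#' @noRd
variant_copy_split <- function(copies, v) {
  if (v == 1) return(copies)
  w <- 2^(-(seq_len(v) - 1))
  alloc <- floor(copies * w / sum(w))
  alloc[1] <- alloc[1] + copies - sum(alloc)
  alloc
}

#' Plant satellite families into a paired 0B/1B synthetic genome
#'
#' Builds a haploid A-complement string of exactly `background_length` bp
#' (random background plus the planted arrays) and a B segment of
#' `round(f * background_length)` bp holding the B-located arrays, so that the
#' 1B genome is the 0B genome extended by the B segment. Every planted array
#' and dispersed copy is recorded with exact coordinates in the truth table.
#'
#' @param specs list of [family_spec()] objects with unique labels.
#' @param background_length total length of the A (0B) haploid string, bp.
#' @param f B-segment length as a fraction of the haploid A complement.
#' @param seed integer master seed; all randomness derives from it.
#' @param variant_divergence substitution fraction used to derive additional
#'   variants from a family's base monomer (default 0.10 places variants
#'   between the 95% variant and 80% family identity thresholds).
#' @param background_at A+T fraction of the background sequence.
#' @param jitter_sdlog optional lognormal sdlog for per-family copy-number
#'   jitter between the 0B and 1B individuals' A complements (models
#'   between-individual satellite abundance differences). When > 0 the 1B
#'   genome no longer literally extends the 0B string.
#' @return an object of class `genome_pair` with elements `seq_0B`, `seq_1B`,
#'   `b_fraction`, `truth` (per-family table), `intervals` (exact coordinates),
#'   and `seed`.
#' @export
plant_families <- function(specs, background_length, f = 0.08, seed = 1,
                           variant_divergence = 0.10, background_at = 0.5,
                           jitter_sdlog = 0) {
  if (inherits(specs, "family_spec")) specs <- list(specs)
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("family labels must be unique", call. = FALSE)
  if (f < 0 || f >= 1) stop("f must be in [0, 1)", call. = FALSE)
  with_seed(seed, {
    ## base monomers (partners derived at their target identity)
    monomers <- list()
    for (sp in specs) {
      if (!is.null(sp$superfamily_partner)) {
        if (!sp$superfamily_partner %in% names(monomers))
          stop("superfamily partner '", sp$superfamily_partner,
               "' must be specified before '", sp$label, "'", call. = FALSE)
        base <- monomers[[sp$superfamily_partner]]
        if (nchar(base) != sp$rul)
          base <- substr(paste0(strrep(base, ceiling(sp$rul / nchar(base)))),
                         1, sp$rul)
        monomers[[sp$label]] <- mutate_seq(base, 1 - sp$partner_identity,
                                           exact = TRUE)
      } else {
        monomers[[sp$label]] <- random_dna(sp$rul, sp$at_frac)
      }
    }
    variant_sets <- lapply(specs, function(sp) {
      base <- monomers[[sp$label]]
      c(base, vapply(seq_len(sp$n_variants - 1), function(i)
        mutate_seq(base, variant_divergence, exact = TRUE), character(1)))
    })
    names(variant_sets) <- labels

    build_A <- function(copy_mult) {
      arrays <- list()
      for (si in seq_along(specs)) {
        sp <- specs[[si]]
        copies <- as.integer(round(sp$copies_0B * copy_mult[si]))
        alloc <- variant_copy_split(copies, sp$n_variants)
        for (vi in seq_len(sp$n_variants)) {
          if (sp$n_variants == 1) a <- alloc else a <- alloc[vi]
          if (a > 0)
            arrays[[length(arrays) + 1]] <- list(
              family = sp$label, variant = vi, type = "array",
              seq = build_array(variant_sets[[si]][vi], a, sp$intra_divergence),
              copies = a)
        }
        if (sp$dispersed_0B > 0) {
          for (di in seq_len(sp$dispersed_0B))
            arrays[[length(arrays) + 1]] <- list(
              family = sp$label, variant = 1L, type = "dispersed",
              seq = if (sp$intra_divergence > 0)
                      mutate_seq(variant_sets[[si]][1], sp$intra_divergence)
                    else variant_sets[[si]][1],
              copies = 1L)
        }
      }
      assemble_genome(arrays, background_length, background_at)
    }

    assemble_genome <- function(arrays, total_length, at) {
      arr_nt <- sum(vapply(arrays, function(a) nchar(a$seq), numeric(1)))
      if (arr_nt >= total_length) {
        cum <- cumsum(vapply(arrays, function(a) nchar(a$seq), numeric(1)))
        bad <- arrays[[which(cum >= total_length)[1]]]$family
        stop("planted arrays do not fit: family '", bad,
             "' exceeds the genome capacity", call. = FALSE)
      }
      bg_len <- total_length - arr_nt
      bg <- random_dna(bg_len, at)
      ord <- sample(seq_along(arrays))
      cuts <- sort(sample.int(bg_len + 1, length(arrays), replace = TRUE) - 1L)
      pieces <- character(2 * length(arrays) + 1)
      iv <- vector("list", length(arrays))
      pos <- 0L; prev <- 0L
      for (j in seq_along(arrays)) {
        a <- arrays[[ord[j]]]
        bgpiece <- substr(bg, prev + 1L, cuts[j])
        pieces[2 * j - 1] <- bgpiece
        pos <- pos + nchar(bgpiece)
        pieces[2 * j] <- a$seq
        iv[[j]] <- data.frame(family = a$family, variant = a$variant,
                              type = a$type, start = pos + 1L,
                              end = pos + nchar(a$seq), copies = a$copies,
                              stringsAsFactors = FALSE)
        pos <- pos + nchar(a$seq)
        prev <- cuts[j]
      }
      pieces[2 * length(arrays) + 1] <- substr(bg, prev + 1L, bg_len)
      list(seq = paste(pieces, collapse = ""), intervals = do.call(rbind, iv))
    }

    A0 <- build_A(rep(1, length(specs)))
    mult1 <- if (jitter_sdlog > 0)
      rlnorm(length(specs), 0, jitter_sdlog) else rep(1, length(specs))
    A1 <- if (jitter_sdlog > 0) build_A(mult1) else A0
    LA0 <- nchar(A0$seq); LA1 <- nchar(A1$seq)

    ## B segment
    LB <- as.integer(round(f * background_length))
    Bres <- NULL
    if (LB > 0) {
      b_arrays <- list()
      for (si in seq_along(specs)) {
        sp <- specs[[si]]
        if (sp$copies_B > 0) {
          alloc <- variant_copy_split(sp$copies_B, sp$n_variants)
          for (vi in seq_len(sp$n_variants)) {
            a <- if (sp$n_variants == 1) alloc else alloc[vi]
            if (a > 0)
              b_arrays[[length(b_arrays) + 1]] <- list(
                family = sp$label, variant = vi, type = "array",
                seq = build_array(variant_sets[[si]][vi], a,
                                  sp$intra_divergence),
                copies = a)
          }
        }
      }
      Bres <- assemble_genome(b_arrays, LB, background_at)
    }

    iv0 <- A0$intervals
    if (!is.null(iv0)) iv0 <- cbind(genome = "0B", iv0)
    iv1A <- A1$intervals
    if (!is.null(iv1A)) iv1A <- cbind(genome = "1B", iv1A)
    ivB <- NULL
    if (!is.null(Bres) && !is.null(Bres$intervals)) {
      ivB <- Bres$intervals
      ivB$start <- ivB$start + LA1
      ivB$end <- ivB$end + LA1
      ivB <- cbind(genome = "1B", ivB, segment = "B")
    }
    if (!is.null(iv0)) iv0$segment <- "A"
    if (!is.null(iv1A)) iv1A$segment <- "A"
    intervals <- rbind(iv0, iv1A, ivB)

    seq_1B <- paste0(A1$seq, if (!is.null(Bres)) Bres$seq else "")
    L1 <- nchar(seq_1B)

    nt_in <- function(iv, gen, fam, seg = NULL) {
      sel <- iv$genome == gen & iv$family == fam
      if (!is.null(seg)) sel <- sel & iv$segment == seg
      if (!any(sel)) 0 else sum(iv$end[sel] - iv$start[sel] + 1)
    }
    truth <- do.call(rbind, lapply(seq_along(specs), function(si) {
      sp <- specs[[si]]
      nt0 <- nt_in(intervals, "0B", sp$label)
      nt1A <- nt_in(intervals, "1B", sp$label, "A")
      nt1B <- nt_in(intervals, "1B", sp$label, "B")
      data.frame(family = sp$label, monomer = monomers[[sp$label]],
                 rul = sp$rul, copies_0B = sp$copies_0B,
                 copies_B = sp$copies_B, dispersed_0B = sp$dispersed_0B,
                 b_restricted = sp$b_restricted,
                 frac_0B = nt0 / LA0,
                 frac_1B = (nt1A + nt1B) / L1,
                 frac_1B_diploid = (2 * nt1A + nt1B) / (2 * LA1 + (L1 - LA1)),
                 stringsAsFactors = FALSE)
    }))

    structure(list(seq_0B = A0$seq, seq_1B = seq_1B, b_fraction = f,
                   truth = truth, intervals = intervals, seed = seed,
                   jitter_sdlog = jitter_sdlog,
                   variant_sets = variant_sets),
              class = "genome_pair")
  })
}

#' @export
print.genome_pair <- function(x, ...) {
  cat("genome_pair: |0B| =", nchar(x$seq_0B), "bp, |1B| =", nchar(x$seq_1B),
      "bp, f =", x$b_fraction, "\n")
  cat(nrow(x$truth), "planted families\n")
  invisible(x)
}

#' Simulate a paired-end read library from a genome string
#'
#' Uniform fragment start positions on both strands, Gaussian insert sizes and
#' independent per-base substitution errors (no indels, so divergence of reads
#' to their source stays interpretable as a substitution distance).
#'
#' @param genome nucleotide string.
#' @param n_pairs number of read pairs (> 0).
#' @param read_len read length (default 101, as for 2 x 101 bp paired-end
#'   sequencing).
#' @param insert_mean mean insert (fragment) length.
#' @param insert_sd standard deviation of the insert length (0 = fixed).
#' @param error_rate per-base substitution probability.
#' @param seed optional integer seed; byte-identical output given the seed.
#' @param genome_label label recorded on the library (e.g. "0B").
#' @return an object of class `read_library` with `reads1`, `reads2` and a
#'   per-pair `truth` table (fragment start, insert length, strand).
#' @export
simulate_reads <- function(genome, n_pairs, read_len = 101,
                           insert_mean = 300, insert_sd = 0,
                           error_rate = 0, seed = NULL, genome_label = "") {
  if (!is.numeric(n_pairs) || n_pairs <= 0)
    stop("n_pairs must be a positive integer", call. = FALSE)
  if (read_len > insert_mean || insert_mean > nchar(genome))
    stop("need read_len <= insert_mean <= genome length", call. = FALSE)
  res <- with_seed(seed, cpp_sim_reads(genome, as.integer(n_pairs),
                                       as.integer(read_len),
                                       as.integer(insert_mean), insert_sd,
                                       error_rate))
  structure(list(reads1 = res$reads1, reads2 = res$reads2,
                 read_len = as.integer(read_len),
                 n_pairs = as.integer(n_pairs), error_rate = error_rate,
                 seed = seed, genome = genome_label,
                 genome_len = nchar(genome),
                 truth = data.frame(start = res$start, insert = res$insert,
                                    strand = res$strand),
                 pair_ids = seq_len(n_pairs)),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat("read_library:", x$n_pairs, "pairs of 2 x", x$read_len, "bp",
      if (nzchar(x$genome)) paste0("[", x$genome, "]"), "\n")
  invisible(x)
}

#' Simulate the 0B and 1B read libraries for a genome pair
#'
#' In diploid-equivalent mode (the default) the 1B library is drawn from a
#' diploid A complement plus a single B (the A portion is duplicated before
#' read simulation), so a satellite absent from the B is diluted by
#' 1/(1 + f/2). With `diploid_equivalent = FALSE` both genomes are treated as
#' haploid strings and the dilution factor is 1/(1 + f).
#'
#' @param pair a [plant_families()] result.
#' @param n_pairs read pairs per library.
#' @inheritParams simulate_reads
#' @param diploid_equivalent duplicate the A portion of the 1B genome before
#'   simulating reads.
#' @return list with elements `lib_0B` and `lib_1B`.
#' @export
simulate_pair_libraries <- function(pair, n_pairs, read_len = 101,
                                    insert_mean = 300, insert_sd = 30,
                                    error_rate = 0.01, seed = 1,
                                    diploid_equivalent = TRUE) {
  stopifnot(inherits(pair, "genome_pair"))
  LA1 <- nchar(pair$seq_1B) -
    as.integer(round(pair$b_fraction * nchar(pair$seq_0B)))
  g1 <- if (diploid_equivalent)
    paste0(substr(pair$seq_1B, 1, LA1), pair$seq_1B) else pair$seq_1B
  lib0 <- simulate_reads(pair$seq_0B, n_pairs, read_len, insert_mean,
                         insert_sd, error_rate, seed = child_seed(seed, 1),
                         genome_label = "0B")
  lib1 <- simulate_reads(g1, n_pairs, read_len, insert_mean, insert_sd,
                         error_rate, seed = child_seed(seed, 2),
                         genome_label = if (diploid_equivalent)
                           "1B-diploid" else "1B")
  list(lib_0B = lib0, lib_1B = lib1)
}

#' Planted-family intervals in the coordinates of a simulated genome
#'
#' @param pair a [plant_families()] result.
#' @param genome one of "0B", "1B" (haploid string) or "1B-diploid"
#'   (A duplicated before the B segment, as used by diploid-equivalent read
#'   simulation).
#' @return data frame with columns `family`, `start`, `end`.
#' @export
family_intervals <- function(pair, genome = c("0B", "1B", "1B-diploid")) {
  genome <- match.arg(genome)
  iv <- pair$intervals
  LA1 <- nchar(pair$seq_1B) -
    as.integer(round(pair$b_fraction * nchar(pair$seq_0B)))
  if (genome == "0B") {
    out <- iv[iv$genome == "0B", c("family", "start", "end")]
  } else if (genome == "1B") {
    out <- iv[iv$genome == "1B", c("family", "start", "end")]
  } else {
    a <- iv[iv$genome == "1B" & iv$segment == "A", c("family", "start", "end")]
    b <- iv[iv$genome == "1B" & iv$segment == "B", c("family", "start", "end")]
    a2 <- transform(a, start = start + LA1, end = end + LA1)
    b2 <- transform(b, start = start + LA1, end = end + LA1)
    out <- rbind(a, a2, b2)
  }
  rownames(out) <- NULL
  out
}

#' Fraction of read nucleotides that originate inside a family's intervals
#'
#' Ground-truth abundance of each planted family in a simulated library,
#' computed from the recorded fragment coordinates (independent of any
#' alignment or masking).
#'
#' @param lib a [simulate_reads()] library.
#' @param intervals a [family_intervals()] table for the genome the library
#'   was simulated from.
#' @return named numeric vector: per-family fraction of sampled nucleotides.
#' @export
truth_read_fraction <- function(lib, intervals) {
  l <- lib$read_len
  s1 <- lib$truth$start; e1 <- s1 + l - 1
  s2 <- lib$truth$start + lib$truth$insert - l
  e2 <- lib$truth$start + lib$truth$insert - 1
  fams <- unique(intervals$family)
  total <- 2 * l * lib$n_pairs
  out <- setNames(numeric(length(fams)), fams)
  for (i in seq_len(nrow(intervals))) {
    a <- intervals$start[i]; b <- intervals$end[i]
    ov <- pmax(0, pmin(e1, b) - pmax(s1, a) + 1) +
          pmax(0, pmin(e2, b) - pmax(s2, a) + 1)
    out[intervals$family[i]] <- out[intervals$family[i]] + sum(ov)
  }
  out / total
}

#' Draw a uniform subsample of read pairs
#'
#' @param lib a `read_library`.
#' @param n_pairs pairs to draw (without replacement). Sampling the full
#'   library returns it with pair order preserved.
#' @param seed optional integer seed.
#' @return a `read_library` holding the sampled pairs; `pair_ids` tracks the
#'   identities of the sampled pairs in the parent library.
#' @export
sample_reads <- function(lib, n_pairs, seed = NULL) {
  stopifnot(inherits(lib, "read_library"))
  if (n_pairs > lib$n_pairs)
    stop("cannot sample ", n_pairs, " pairs from a library of ", lib$n_pairs,
         call. = FALSE)
  if (n_pairs == lib$n_pairs) return(lib)
  idx <- sort(with_seed(seed, sample.int(lib$n_pairs, n_pairs)))
  subset_library(lib, idx)
}

#' @noRd
subset_library <- function(lib, idx) {
  out <- lib
  out$reads1 <- lib$reads1[idx]
  out$reads2 <- lib$reads2[idx]
  out$truth <- lib$truth[idx, , drop = FALSE]
  out$pair_ids <- lib$pair_ids[idx]
  out$n_pairs <- length(idx)
  out
}

#' Write a genome (or genome pair) as FASTA
#' @param x a nucleotide string, named character vector, or `genome_pair`.
#' @param path output file.
#' @export
write_genome_fasta <- function(x, path) {
  if (inherits(x, "genome_pair"))
    x <- c(genome_0B = x$seq_0B, genome_1B = x$seq_1B)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path, width = 60)
  invisible(path)
}

#' Write a read library as a pair of FASTQ files
#'
#' Base qualities are a fixed Q37 placeholder ("F"); the substitution error
#' model does not produce calibrated qualities.
#'
#' @param lib a `read_library`.
#' @param prefix output path prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written.
#' @return the two file paths, invisibly.
#' @export
write_fastq <- function(lib, prefix) {
  stopifnot(inherits(lib, "read_library"))
  qual <- strrep("F", lib$read_len)
  ids <- sprintf("pair%d", lib$pair_ids)
  f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
  writeLines(as.vector(rbind(paste0("@", ids, "/1"), lib$reads1, "+", qual)),
             f1)
  writeLines(as.vector(rbind(paste0("@", ids, "/2"), lib$reads2, "+", qual)),
             f2)
  invisible(c(f1, f2))
}

#' Read a paired FASTQ library written by [write_fastq()] (or any 2 x FASTQ)
#' @param file1,file2 FASTQ paths for mates 1 and 2.
#' @return a `read_library`.
#' @export
read_fastq_pair <- function(file1, file2) {
  r1 <- Biostrings::readDNAStringSet(file1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(file2, format = "fastq")
  stopifnot(length(r1) == length(r2))
  structure(list(reads1 = unname(as.character(r1)),
                 reads2 = unname(as.character(r2)),
                 read_len = max(Biostrings::width(r1)),
                 n_pairs = length(r1), error_rate = NA_real_, seed = NULL,
                 genome = "", genome_len = NA_integer_,
                 truth = NULL, pair_ids = seq_along(r1)),
            class = "read_library")
}

#' Write the simulator truth table as TSV
#' @param pair a `genome_pair`.
#' @param path output file.
#' @export
write_truth_tsv <- function(pair, path) {
  write.table(pair$truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
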