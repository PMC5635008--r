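#' All read sequences of a library (both mates)
#' @noRd
library_seqs <- function(lib) {
  c(lib$reads1, lib$reads2)
}

#' Cluster reads by shared canonical k-mers
#'
#' Builds a graph whose nodes are reads and whose edges join reads sharing at
#' least `min_shared_kmers` canonical k-mers, and returns its connected
#' components (largest first). This stands in for graph-layout read clustering:
#' reads drawn from a tandem array share most of the monomer's k-mers and form
#' dense components, while single-copy background reads only connect through
#' genomic overlap.
#'
#' K-mers seen in many reads are themselves strong repeat evidence; to keep
#' the pairwise expansion bounded at high coverage, each k-mer contributes
#' all-pairs edges for at most `pair_cap` of its reads, and reads beyond the
#' cap (or carrying a k-mer seen in more than `max_kmer_reads` reads) are
#' chained directly, which preserves the connected components.
#'
#' @param seqs character vector of read sequences (or a `read_library`, in
#'   which case both mates are used).
#' @param k k-mer size, in \[11, 31\] (<= 26 here so codes stay exact).
#' @param min_shared_kmers minimum shared canonical k-mers for an edge.
#' @param min_cluster_size smallest component reported.
#' @param max_kmer_reads frequency cap above which a k-mer's reads are only
#'   chained, never pair-expanded.
#' @param pair_cap maximum reads per k-mer entering the all-pairs expansion.
#' @return list of clusters, each `read_cluster` with `ids`, `seqs`,
#'   `n_nodes`, `n_edges`, `density`.
#' @export
cluster_reads <- function(seqs, k = 17, min_shared_kmers = 5,
                          min_cluster_size = 10, max_kmer_reads = 3000,
                          pair_cap = 40) {
  if (inherits(seqs, "read_library")) seqs <- library_seqs(seqs)
  if (k < 11 || k > 26) stop("k must be in [11, 26]", call. = FALSE)
  if (length(seqs) == 0) return(list())
  ks <- cpp_kmer_sets(seqs, as.integer(k))
  nk <- lengths(ks)
  dt <- data.table(kmer = unlist(ks), read = rep(seq_along(seqs), nk))
  setkey(dt, kmer)
  cnt <- dt[, .N, by = kmer]
  hot <- cnt[N > max_kmer_reads, kmer]
  ## all-pairs expansion for at most pair_cap reads per k-mer, processed in
  ## bounded chunks so peak memory stays flat at high coverage
  dt_cold <- dt[!kmer %in% hot][, head(.SD, pair_cap), by = kmer]
  edges <- NULL
  if (nrow(dt_cold)) {
    setkey(dt_cold, kmer)
    sizes <- dt_cold[, .N, by = kmer][N > 1]
    if (nrow(sizes)) {
      sizes[, work := as.numeric(N) * (N - 1)]
      sizes[, chunk := cumsum(work) %/% 5e6]
      parts <- list()
      for (ch in unique(sizes$chunk)) {
        sub <- dt_cold[.(sizes[chunk == ch, kmer])]
        m <- merge(sub, sub, by = "kmer", allow.cartesian = TRUE)
        m <- m[read.x < read.y]
        if (nrow(m))
          parts[[length(parts) + 1]] <- m[, .N, by = .(read.x, read.y)]
      }
      if (length(parts)) {
        e <- rbindlist(parts)[, .(N = sum(N)), by = .(read.x, read.y)]
        e <- e[N >= min_shared_kmers]
        if (nrow(e)) edges <- e[, .(from = read.x, to = read.y)]
      }
    }
  }
  ## chain all reads of over-capped or hyper-frequent k-mers (connectivity)
  over <- cnt[N > pair_cap, kmer]
  if (length(over)) {
    dh <- dt[.(over)]
    chains <- dh[, .(from = read[-.N], to = read[-1]), by = kmer]
    if (nrow(chains))
      edges <- rbind(edges, unique(chains[, .(from, to)]))
  }
  if (is.null(edges) || nrow(edges) == 0) return(list())
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(
                                       name = seq_along(seqs)))
  comp <- igraph::components(g)
  keep <- which(comp$csize >= min_cluster_size)
  keep <- keep[order(comp$csize[keep], decreasing = TRUE)]
  ecount_by <- table(comp$membership[edges$from])
  lapply(keep, function(ci) {
    ids <- which(comp$membership == ci)
    n <- length(ids)
    ne <- as.integer(ecount_by[as.character(ci)])
    if (is.na(ne)) ne <- 0L
    structure(list(ids = ids, seqs = seqs[ids], n_nodes = n, n_edges = ne,
                   density = if (n > 1) ne / (n * (n - 1) / 2) else 0),
              class = "read_cluster")
  })
}

#' @export
print.read_cluster <- function(x, ...) {
  cat(sprintf("read_cluster: %d reads, %d edges, density %.3f\n",
              x$n_nodes, x$n_edges, x$density))
  invisible(x)
}

#' Candidate period from per-read autocorrelation votes
#' @noRd
period_votes <- function(seqs, min_period, max_period, threshold,
                         min_sites = 20) {
  votes <- integer(0)
  max_p_read <- min(max_period, nchar(seqs[1]) - min_sites)
  if (max_p_read < min_period) return(votes)
  for (s in seqs) {
    prof <- cpp_period_profile(s, as.integer(min_period),
                               as.integer(max_p_read),
                               as.integer(min_sites))
    ok <- which(!is.na(prof) & prof >= threshold)
    if (length(ok)) votes <- c(votes, ok[1] + min_period - 1L)
  }
  votes
}

#' Greedy overlap assembly of a cluster into a contig
#'
#' Extends a seed read to the right by repeatedly appending the best
#' suffix-overlapping read (overlap >= `min_overlap` bp at <= 10% mismatch);
#' over a tandem array the contig wraps around the monomer, so a few hundred
#' bases suffice to expose periods longer than the read length.
#' @noRd
assemble_contig <- function(seqs, target_len, min_overlap = 35,
                            max_mismatch_frac = 0.10, k = 15) {
  seqs <- unique(c(seqs, revcomp(seqs)))
  ks <- cpp_kmer_sets(seqs, as.integer(k))
  idx <- data.table(kmer = unlist(ks), read = rep(seq_along(seqs), lengths(ks)))
  setkey(idx, kmer)
  contig <- seqs[[1]]
  used <- c(1L)
  rl <- nchar(seqs[[1]])
  repeat {
    if (nchar(contig) >= target_len) break
    tail_seq <- substr(contig, nchar(contig) - rl + 1, nchar(contig))
    tk <- cpp_kmer_sets(tail_seq, as.integer(k))[[1]]
    hits <- idx[.(tk), nomatch = NULL][!read %in% used, .N, by = read]
    if (!nrow(hits)) break
    ## rank candidates by shared tail k-mers: true suffix-overlappers first
    cand <- hits[order(-N), read]
    if (length(cand) > 30) cand <- cand[seq_len(30)]
    best <- NULL; best_new <- 0L
    for (ci in cand) {
      s <- seqs[[ci]]
      ov <- best_suffix_prefix(contig, s, min_overlap, max_mismatch_frac)
      if (!is.null(ov) && ov$new_bases > best_new) {
        best <- list(read = ci, ov = ov); best_new <- ov$new_bases
      }
    }
    if (is.null(best) || best_new == 0L) break
    contig <- paste0(contig,
                     substr(seqs[[best$read]],
                            nchar(seqs[[best$read]]) - best$ov$new_bases + 1,
                            nchar(seqs[[best$read]])))
    used <- c(used, best$read)
  }
  contig
}

#' Best suffix(contig)-prefix(read) overlap
#' @noRd
best_suffix_prefix <- function(contig, s, min_overlap, max_mm) {
  lc <- nchar(contig); ls <- nchar(s)
  cc <- strsplit(substr(contig, max(1, lc - ls + 1), lc), "")[[1]]
  sc <- strsplit(s, "")[[1]]
  nmax <- min(length(cc), ls - 1)
  if (nmax < min_overlap) return(NULL)
  for (ov in seq(nmax, min_overlap)) {
    mism <- sum(cc[(length(cc) - ov + 1):length(cc)] != sc[1:ov])
    if (mism / ov <= max_mm)
      return(list(overlap = ov, new_bases = ls - ov))
  }
  NULL
}

#' Detect tandem structure in a read cluster and call the monomer consensus
#'
#' Two evidence paths are used. For periods not exceeding the read length,
#' each read votes for the smallest period at which its self-comparison
#' identity reaches `threshold`; the modal period wins and the consensus is
#' called by per-column majority over phase-aligned reads. For longer periods
#' the cluster is first assembled into a contig by greedy overlap extension
#' and the period estimated by maximal self-alignment offset scoring on the
#' contig. Returns `NULL` when no periodicity passes the threshold - absence
#' is a valid outcome (e.g. clusters of overlapping single-copy reads).
#'
#' @param cluster a `read_cluster` (or plain character vector of reads).
#' @param min_period,max_period candidate period range, bp.
#' @param threshold minimum mean per-site identity between positions i and
#'   i + p (0.8, consistent with the 80% family-identity level).
#' @param min_votes minimum reads voting for the modal period.
#' @param iteration iteration index recorded on the result.
#' @param assembly_min_density clusters below this edge density skip the
#'   overlap-assembly path: tandem-derived clusters are dense (most read
#'   pairs share monomer k-mers) while chains of overlapping single-copy
#'   background reads are sparse, and assembling them is pointless work.
#'   Plain read vectors (no density information) always attempt assembly.
#' @param max_reads_used per-read period votes and assembly consider at most
#'   this many reads (the consensus still uses the whole cluster).
#' @return a `mined_monomer` (consensus in canonical rotation, period,
#'   supporting read count, iteration) or `NULL`.
#' @export
detect_tandem <- function(cluster, min_period = 5, max_period = 500,
                          threshold = 0.8, min_votes = 3, iteration = NA,
                          assembly_min_density = 0.02, max_reads_used = 200) {
  seqs <- if (inherits(cluster, "read_cluster")) cluster$seqs else cluster
  if (!length(seqs)) return(NULL)
  sub <- if (length(seqs) > max_reads_used)
    seqs[round(seq(1, length(seqs), length.out = max_reads_used))] else seqs
  votes <- period_votes(sub, min_period, max_period, threshold)
  period <- NA_integer_
  consensus <- NULL
  if (length(votes) >= min_votes) {
    tab <- table(votes)
    period <- as.integer(names(tab)[which.max(tab)])
    support <- sum(votes == period)
    cons_reads <- if (length(seqs) > 2 * max_reads_used)
      seqs[round(seq(1, length(seqs), length.out = 2 * max_reads_used))]
    else seqs
    consensus <- consensus_from_reads(cons_reads, period, threshold)
    if (is.null(consensus)) return(NULL)
  } else {
    ## period may exceed the read length: assemble and self-align.
    ## Seed the assembly from reads whose k-mers are widely shared inside
    ## the cluster (repeat-derived reads), with fallback attempts.
    if (inherits(cluster, "read_cluster") &&
        cluster$density < assembly_min_density) return(NULL)
    ks <- cpp_kmer_sets(sub, 15L)
    tab <- table(unlist(ks))
    ## repeat-derived clusters share k-mers across many reads (even highly
    ## divergent families keep conserved stretches); chains of single-copy
    ## reads only pile up to the local coverage, and skip assembly
    if (max(tab) < max(4, ceiling(0.05 * length(sub)))) return(NULL)
    score <- vapply(ks, function(v)
      if (length(v)) mean(tab[as.character(v)]) else 0, numeric(1))
    ord <- order(score, decreasing = TRUE)
    seed_ranks <- unique(pmin(length(ord),
                              c(1L, ceiling(length(ord) * c(0.05, 0.15)))))
    period <- NA_integer_
    for (sr in seed_ranks) {
      reordered <- sub[c(ord[sr], setdiff(seq_along(sub), ord[sr]))]
      contig <- assemble_contig(reordered, target_len = 3 * max_period)
      if (nchar(contig) < 2 * min_period + 30) next
      prof <- cpp_period_profile(contig, as.integer(min_period),
                                 as.integer(min(max_period,
                                                nchar(contig) - 30)),
                                 30L)
      ok <- which(!is.na(prof) & prof >= threshold)
      if (!length(ok)) next
      period <- ok[1] + min_period - 1L
      ## refine the contig-derived consensus by majority over all reads
      ## aligned circularly to it (the contig samples only a few copies)
      init <- consensus_from_contig(contig, period)
      refined <- consensus_from_reads(sub, period, threshold, init = init)
      consensus <- refined %||% init
      break
    }
    if (is.na(period)) return(NULL)
    support <- length(seqs)
  }
  structure(list(consensus = canonical_rotation(consensus),
                 period = nchar(consensus), support = support,
                 iteration = iteration),
            class = "mined_monomer")
}

#' @export
print.mined_monomer <- function(x, ...) {
  cat(sprintf("mined_monomer: period %d bp, %d supporting reads\n",
              x$period, x$support))
  invisible(x)
}

#' Phase-aligned majority consensus from reads at a known period
#' @noRd
consensus_from_reads <- function(seqs, period, threshold, min_member_ident = 0.6,
                                 rounds = 2, init = NULL) {
  if (is.null(init)) {
    ## provisional monomer: fold the best self-periodic read on itself
    best_i <- 1L; best_v <- -1
    for (i in seq_along(seqs)) {
      prof <- cpp_period_profile(seqs[i], as.integer(period),
                                 as.integer(period), 20L)
      if (!is.na(prof[1]) && prof[1] > best_v) { best_v <- prof[1]; best_i <- i }
    }
    if (best_v < 0) return(NULL)
    init <- fold_majority(seqs[best_i], period)
  }
  unit <- init
  for (r in seq_len(rounds)) {
    counts <- matrix(0L, nrow = 4, ncol = period,
                     dimnames = list(DNA_BASES4, NULL))
    for (s in seqs) {
      a <- cpp_circ_align(s, unit)
      ## genuine members align over at least half the read; short chance
      ## segments from foreign reads must not pollute the majority
      if (is.na(a$identity) || a$identity < min_member_ident ||
          a$length < ceiling(0.5 * nchar(s))) next
      oriented <- if (a$strand == 1) s else revcomp(s)
      ch <- strsplit(oriented, "")[[1]]
      pos <- ((a$offset - 1 + seq_along(ch) - 1) %% period) + 1
      for (b in DNA_BASES4) {
        t <- tabulate(pos[ch == b], nbins = period)
        counts[b, ] <- counts[b, ] + t
      }
    }
    if (all(colSums(counts) == 0)) return(NULL)
    unit <- paste(DNA_BASES4[apply(counts, 2, which.max)], collapse = "")
  }
  unit
}

#' Majority-fold a single sequence at period p (ties break alphabetically)
#' @noRd
fold_majority <- function(s, p) {
  ch <- strsplit(s, "")[[1]]
  pos <- ((seq_along(ch) - 1) %% p) + 1
  counts <- vapply(DNA_BASES4, function(b) tabulate(pos[ch == b], nbins = p),
                   integer(p))
  if (p == 1) counts <- matrix(counts, nrow = 1)
  paste(DNA_BASES4[apply(counts, 1, which.max)], collapse = "")
}

#' @noRd
consensus_from_contig <- function(contig, p) {
  fold_majority(contig, p)
}

#' Remove read pairs homologous to catalogued monomers
#'
#' A pair is removed when either mate aligns to any catalogued consensus
#' (treated as circular, both strands) at `min_identity` identity over at
#' least `min_cov` of the read.
#'
#' @param lib a `read_library`.
#' @param catalog list of `mined_monomer` objects (or character monomers).
#' @param min_identity minimum alignment identity (default 0.80, aligned with
#'   the 80% family threshold).
#' @param min_cov minimum fraction of the read covered (default 0.50).
#' @return list with `library` (the filtered library) and `removed` (pairs).
#' @export
subtract_reads <- function(lib, catalog, min_identity = 0.80, min_cov = 0.50) {
  stopifnot(inherits(lib, "read_library"))
  units <- monomer_seqs(catalog)
  if (!length(units)) return(list(library = lib, removed = 0L))
  min_len <- as.integer(ceiling(min_cov * lib$read_len))
  hit1 <- cpp_mask(lib$reads1, units, min_identity, min_len, 9L)$read
  hit2 <- cpp_mask(lib$reads2, units, min_identity, min_len, 9L)$read
  drop <- union(hit1, hit2)
  keep <- setdiff(seq_len(lib$n_pairs), drop)
  list(library = subset_library(lib, keep), removed = length(drop))
}

#' @noRd
monomer_seqs <- function(catalog) {
  if (is.character(catalog)) return(catalog)
  vapply(catalog, function(m)
    if (inherits(m, "mined_monomer")) m$consensus else as.character(m),
    character(1))
}

#' Extract all tandem monomers present in one cluster
#'
#' A cluster can hold more than one satellite (plus chained background) when
#' read coverage is high enough for boundary reads to connect arrays through
#' flanking sequence. Monomers are therefore extracted iteratively: after
#' each detection, reads homologous to the detected monomer are removed from
#' the cluster and detection reruns on the remainder.
#' @noRd
detect_tandems_in_cluster <- function(cluster, min_period, max_period,
                                      threshold, iteration,
                                      mask_identity = 0.75, mask_cov = 0.5,
                                      max_per_cluster = 5) {
  seqs <- if (inherits(cluster, "read_cluster")) cluster$seqs else cluster
  found <- list()
  for (i in seq_len(max_per_cluster)) {
    ## density gate intentionally not inherited: mixed clusters can be
    ## sparse overall, and the k-mer popularity gate inside detect_tandem
    ## already rejects single-copy read chains cheaply
    cl <- structure(list(seqs = seqs, density = 1, n_nodes = length(seqs)),
                    class = "read_cluster")
    m <- detect_tandem(cl, min_period = min_period, max_period = max_period,
                       threshold = threshold, iteration = iteration)
    if (is.null(m)) break
    found[[length(found) + 1]] <- m
    min_len <- as.integer(ceiling(mask_cov * nchar(seqs[1])))
    hit <- cpp_mask(seqs, m$consensus, mask_identity, min_len, 9L)$read
    if (!length(hit) || length(hit) == length(seqs)) break
    seqs <- seqs[-hit]
    if (length(seqs) < 3) break
  }
  found
}

#' Iteratively mine the satellitome of a read library
#'
#' Runs the sample -> cluster -> tandem-detect -> subtract loop, doubling the
#' sample size each iteration, until an iteration yields no monomer that fails
#' to group (at >= `family_threshold` rotational identity) with an already
#' mined one, or the library is exhausted.
#'
#' @param lib a `read_library`.
#' @param start_pairs read pairs sampled in the first iteration (doubled
#'   each subsequent iteration). The default mirrors the full-scale protocol
#'   (2 x 200,000 reads); desk-scale runs on small synthetic genomes should
#'   start far lower so that sampled background coverage stays below ~1x
#'   (see the methods vignette).
#' @param k,min_shared_kmers,min_cluster_size see [cluster_reads()].
#' @param min_period,max_period,tandem_threshold see [detect_tandem()].
#' @param subtract_identity,subtract_cov see [subtract_reads()].
#' @param family_threshold rotational identity (fraction) above which a new
#'   monomer is considered already catalogued.
#' @param max_iterations safety cap.
#' @param seed integer seed driving all per-iteration sampling.
#' @return list with `monomers` (list of `mined_monomer`), `log`
#'   (per-iteration provenance: sample size, clusters, new monomers, pairs
#'   subtracted) and `library` (the remaining, subtracted library).
#' @export
mine_satellitome <- function(lib, start_pairs = 200000, k = 17,
                             min_shared_kmers = 5, min_cluster_size = 10,
                             min_period = 5, max_period = 500,
                             tandem_threshold = 0.8,
                             subtract_identity = 0.80, subtract_cov = 0.50,
                             family_threshold = 0.80, max_iterations = 12,
                             seed = 1) {
  stopifnot(inherits(lib, "read_library"))
  catalog <- list()
  log <- list()
  n <- start_pairs
  for (iter in seq_len(max_iterations)) {
    n_take <- min(n, lib$n_pairs)
    if (n_take == 0) break
    smp <- sample_reads(lib, n_take, seed = child_seed(seed, iter))
    clusters <- cluster_reads(smp, k = k, min_shared_kmers = min_shared_kmers,
                              min_cluster_size = min_cluster_size)
    new_monomers <- list()  # all newly catalogued monomers (incl. variants)
    n_new_families <- 0L    # monomers not grouping with any known family
    for (cl in clusters) {
      for (m in detect_tandems_in_cluster(cl, min_period, max_period,
                                          tandem_threshold, iter)) {
        ids <- vapply(c(catalog, new_monomers), function(x)
          rotational_identity(m$consensus, x$consensus), numeric(1))
        if (length(ids) && max(ids) >= 95) next        # duplicate variant
        if (!length(ids) || max(ids) < 100 * family_threshold)
          n_new_families <- n_new_families + 1L        # new family
        new_monomers[[length(new_monomers) + 1]] <- m  # new variant/family
      }
    }
    removed <- 0L
    if (length(new_monomers)) {
      sub <- subtract_reads(lib, new_monomers, subtract_identity,
                            subtract_cov)
      lib <- sub$library
      removed <- sub$removed
      catalog <- c(catalog, new_monomers)
    }
    log[[iter]] <- data.frame(iteration = iter, sampled_pairs = n_take,
                              clusters = length(clusters),
                              new_monomers = length(new_monomers),
                              new_families = n_new_families,
                              pairs_subtracted = removed,
                              library_remaining = lib$n_pairs)
    ## stop when nothing failed to group with an already-known family
    if (n_new_families == 0) break
    if (n_take == lib$n_pairs && lib$n_pairs == 0) break
    n <- 2 * n
  }
  list(monomers = catalog, log = do.call(rbind, log), library = lib)
}

#' Write mined monomers as FASTA
#' @param monomers list of `mined_monomer`.
#' @param path output file.
#' @export
write_monomers_fasta <- function(monomers, path) {
  seqs <- monomer_seqs(monomers)
  names(seqs) <- vapply(seq_along(monomers), function(i) {
    m <- monomers[[i]]
    sprintf("iter%s_cluster%d_len%d",
            if (inherits(m, "mined_monomer")) m$iteration else NA, i,
            nchar(seqs[i]))
  }, character(1))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60)
  invisible(path)
}
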