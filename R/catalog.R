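#' Rotational sequence identity between two monomers
#'
#' The maximum, over all rotations of `b` and both strands of `b`, of the
#' global-alignment identity with `a`, where identity = matches / alignment
#' length and gap columns count as mismatches. Monomers of equal length are
#' compared gap-free at every rotation offset (exact under a substitution-only
#' model); unequal lengths fall back to a Needleman-Wunsch alignment at each
#' rotation. The value is symmetrised by taking the larger of the two
#' directions.
#'
#' @param a,b non-empty nucleotide strings.
#' @return identity as a percentage in \[0, 100\].
#' @export
rotational_identity <- function(a, b) {
  assert_dna(a); assert_dna(b)
  if (nchar(a) == nchar(b)) {
    100 * max(equal_len_rot_identity(a, b), equal_len_rot_identity(b, a))
  } else {
    100 * max(gapped_rot_identity(a, b), gapped_rot_identity(b, a))
  }
}

#' Best gap-free identity of equal-length monomers over rotations and strands
#' @noRd
equal_len_rot_identity <- function(a, b) {
  best <- 0
  n <- nchar(a)
  ach <- strsplit(a, "")[[1]]
  for (bb in c(b, revcomp(b))) {
    d <- strsplit(paste0(bb, bb), "")[[1]]
    for (o in 0:(n - 1)) {
      m <- sum(ach == d[o + seq_len(n)])
      if (m / n > best) best <- m / n
    }
  }
  best
}

#' Gapped rotational identity for unequal-length monomers
#'
#' A gap-free circular alignment (C++ kernel) locates the best strand and
#' phase cheaply; the gapped global alignment is then evaluated only on a
#' few rotations around that phase. Clearly unrelated pairs are answered by
#' the gap-free bound alone.
#' @noRd
gapped_rot_identity <- function(a, b) {
  nb <- nchar(b); na_ <- nchar(a)
  al <- cpp_circ_align(a, b)
  approx_id <- al$matches / max(na_, nb)
  if (approx_id < 0.40) return(approx_id)
  ## phase of b under a's start: segment start maps to unit offset
  o0 <- (al$offset - 1 - (al$start - 1)) %% nb
  offs <- unique((o0 + c(-3:3)) %% nb)
  best <- approx_id
  strands <- if (al$strand == 1) b else revcomp(b)
  for (bb in unique(c(strands, b, revcomp(b)))) {
    rots <- substring(paste0(bb, bb), offs + 1, offs + nb)
    for (r in rots) {
      id <- global_identity(a, r)
      if (id > best) best <- id
    }
  }
  best
}

#' Global-alignment identity: matches / alignment length (gaps = mismatch)
#' @noRd
global_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 2, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  sum(pa == pb & pa != "-") / length(pa)
}

#' A+T content of a consensus sequence
#' @param x nucleotide string(s), strict ACGT.
#' @return percentage of A and T bases.
#' @export
at_content <- function(x) {
  assert_dna(x)
  vapply(x, function(s) {
    ch <- strsplit(s, "")[[1]]
    100 * sum(ch %in% c("A", "T")) / length(ch)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Group mined monomers into variants, families and superfamilies
#'
#' Single-linkage grouping by rotational identity at three nested levels:
#' monomers at >= `variant` identity are the same sequence variant, variants
#' linked at >= `family` identity form one family, families linked at >=
#' `superfamily` identity form one superfamily. Identities are rounded to
#' 0.1 percentage points before applying the thresholds, so a pair printed as
#' exactly 80.0% joins one family (`boundary = "inclusive"`, the default;
#' `"exclusive"` applies strict >).
#'
#' @param monomers list of `mined_monomer` objects or character vector of
#'   monomer sequences, deduplicated by exact canonical sequence.
#' @param thresholds named numeric vector of identity thresholds (percent).
#' @param boundary how identity exactly at a threshold is treated.
#' @param weights optional per-monomer abundance weights (e.g. supporting
#'   read counts) used to pick each family's representative variant; the
#'   family consensus is its most abundant variant.
#' @param max_chance_p significance guard on every link: because identity is
#'   maximised over all rotations and strands, unrelated short monomers can
#'   exceed 50% identity by chance alone, so a link additionally requires
#'   the Bonferroni-adjusted binomial tail probability of the observed match
#'   count under random 25% matching to fall below this value. This mirrors
#'   running a homology search first and applying the identity thresholds
#'   only to detected homologies. Set to 1 to disable.
#' @return list with `families` (list of `sat_family`: consensus, rul,
#'   at_percent, variants, v, superfamily id) and `superfamilies`.
#' @export
group_monomers <- function(monomers,
                           thresholds = c(variant = 95, family = 80,
                                          superfamily = 50),
                           boundary = c("inclusive", "exclusive"),
                           weights = NULL, max_chance_p = 0.01) {
  boundary <- match.arg(boundary)
  seqs <- canonical_rotation(monomer_seqs(monomers))
  keep <- !duplicated(seqs)
  seqs <- seqs[keep]
  if (is.null(weights)) {
    weights <- if (is.list(monomers) &&
                   all(vapply(monomers, inherits, logical(1), "mined_monomer")))
      vapply(monomers, `[[`, numeric(1), "support")[keep]
    else rep(1, length(seqs))
  } else weights <- weights[keep]
  n <- length(seqs)
  id <- matrix(100, n, n)
  sig <- matrix(TRUE, n, n)
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      v <- round(rotational_identity(seqs[i], seqs[j]), 1)
      id[i, j] <- id[j, i] <- v
      alen <- max(nchar(seqs[i]), nchar(seqs[j]))
      matches <- round(v / 100 * alen)
      trials <- 4 * max(nchar(seqs[i]), nchar(seqs[j]))
      p <- min(1, pbinom(matches - 1, alen, 0.25, lower.tail = FALSE) *
                   trials)
      sig[i, j] <- sig[j, i] <- p < max_chance_p
    }
  link <- function(th) {
    adj <- (if (boundary == "inclusive") id >= th else id > th) & sig
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    igraph::components(g)$membership
  }
  fam_id <- link(thresholds[["family"]])
  var_id <- link(thresholds[["variant"]])
  sf_id <- link(thresholds[["superfamily"]])

  families <- lapply(sort(unique(fam_id)), function(fi) {
    memb <- which(fam_id == fi)
    vgrp <- var_id[memb]
    ## one representative per variant: the highest-weight member
    reps <- vapply(unique(vgrp), function(v) {
      cand <- memb[vgrp == v]
      cand[which.max(weights[cand])]
    }, integer(1))
    vw <- vapply(unique(vgrp), function(v) sum(weights[memb[vgrp == v]]),
                 numeric(1))
    ord <- order(vw, decreasing = TRUE)
    reps <- reps[ord]
    consensus <- seqs[reps[1]]
    structure(list(consensus = consensus, rul = nchar(consensus),
                   at_percent = at_content(consensus),
                   variants = seqs[reps], v = length(reps),
                   weight = sum(weights[memb]),
                   superfamily = NA_integer_,
                   members = memb),
              class = "sat_family")
  })
  ## superfamilies: groups of >= 2 families linked at the superfamily level
  fam_of_sf <- vapply(families, function(f) sf_id[f$members[1]], numeric(1))
  sf_sizes <- table(fam_of_sf)
  sfs <- list()
  next_id <- 1L
  for (s in names(sf_sizes)[sf_sizes >= 2]) {
    memb_f <- which(fam_of_sf == as.numeric(s))
    best_id <- 0
    for (i in memb_f) for (j in memb_f) if (i < j) {
      v <- id[families[[i]]$members[1], families[[j]]$members[1]]
      if (v > best_id) best_id <- v
    }
    for (i in memb_f) families[[i]]$superfamily <- next_id
    sfs[[next_id]] <- list(id = next_id, families = memb_f,
                           defining_identity = best_id)
    next_id <- next_id + 1L
  }
  list(families = families, superfamilies = sfs)
}

#' @export
print.sat_family <- function(x, ...) {
  cat(sprintf("sat_family%s: %d bp, A+T %.1f%%, %d variant(s)%s\n",
              if (!is.null(x$name)) paste0(" ", x$name) else "",
              x$rul, x$at_percent, x$v,
              if (!is.na(x$superfamily)) paste0(", SF", x$superfamily) else ""))
  invisible(x)
}

#' Is a consensus the vertebrate telomeric repeat (or a perfect multimer)?
#' @param consensus nucleotide string.
#' @return logical.
#' @export
is_telomeric <- function(consensus) {
  n <- nchar(consensus)
  if (n %% 6 != 0) return(FALSE)
  canonical_rotation(consensus) ==
    canonical_rotation(strrep("TTAGGG", n / 6))
}

#' Assign catalogue ranks and names to satellite families
#'
#' Ranks are assigned by decreasing abundance in the 0B genome (ties broken
#' by decreasing repeat unit length, then lexicographic consensus), and each
#' family is named `<prefix>Sat<NN>-<RUL>` with the rank zero-padded to two
#' digits. A family whose consensus is the vertebrate telomeric motif (or a
#' perfect multimer of it) receives the suffix `-tel`.
#'
#' @param families list of `sat_family` from [group_monomers()].
#' @param abundance_0B named numeric vector (or plain vector aligned with
#'   `families`) of 0B abundances used for ranking.
#' @param prefix species prefix, e.g. `"Apa"`.
#' @return the families, reordered by rank, with `rank` and `name` set.
#' @export
name_families <- function(families, abundance_0B, prefix = "Sim") {
  n <- length(families)
  ab <- if (!is.null(names(abundance_0B)))
    abundance_0B[vapply(families, `[[`, character(1), "consensus")]
  else abundance_0B
  if (length(ab) != n || any(is.na(ab)))
    stop("abundance must be known for every family", call. = FALSE)
  rul <- vapply(families, `[[`, numeric(1), "rul")
  cons <- vapply(families, `[[`, character(1), "consensus")
  ord <- order(-ab, -rul, cons)
  families <- families[ord]
  for (i in seq_len(n)) {
    families[[i]]$rank <- i
    families[[i]]$abundance_0B <- ab[ord][i]
    families[[i]]$name <- sprintf("%sSat%02d-%d%s", prefix, i,
                                  families[[i]]$rul,
                                  if (is_telomeric(families[[i]]$consensus))
                                    "-tel" else "")
  }
  families
}

#' Write the family catalogue as FASTA (one record per variant)
#' @param families named families from [name_families()].
#' @param path output file.
#' @export
write_catalog_fasta <- function(families, path) {
  seqs <- character(0)
  for (f in families)
    for (k in seq_along(f$variants))
      seqs[sprintf("%s#variant%d", f$name %||% "family", k)] <- f$variants[k]
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60)
  invisible(path)
}

#' Catalogue summary table (one row per family)
#' @param families named families from [name_families()].
#' @return data frame with name, rul, at_percent, v, superfamily.
#' @export
catalog_table <- function(families) {
  data.frame(
    name = vapply(families, function(f) f$name %||% NA_character_,
                  character(1)),
    rul = vapply(families, `[[`, numeric(1), "rul"),
    at_percent = round(vapply(families, `[[`, numeric(1), "at_percent"), 1),
    v = vapply(families, `[[`, numeric(1), "v"),
    superfamily = vapply(families, `[[`, integer(1), "superfamily"),
    stringsAsFactors = FALSE)
}
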