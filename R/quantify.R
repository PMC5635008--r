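#' Kimura two-parameter divergence
#'
#' With P = transitions/sites and Q = transversions/sites, the K2P distance is
#' \deqn{d = -\tfrac12 \ln\left((1-2P-Q)\sqrt{1-2Q}\right)}
#' returned as a percentage. The estimate saturates (log argument <= 0) when
#' the observed substitution load is too high; that raises an error rather
#' than returning a value.
#'
#' @param transitions,transversions,sites non-negative counts with
#'   `transitions + transversions <= sites`, `sites > 0`. Vectorised.
#' @return divergence in percent.
#' @export
kimura_divergence <- function(transitions, transversions, sites) {
  if (any(sites <= 0)) stop("sites must be > 0", call. = FALSE)
  if (any(transitions < 0) || any(transversions < 0) ||
      any(transitions + transversions > sites))
    stop("need transitions + transversions <= sites", call. = FALSE)
  P <- transitions / sites
  Q <- transversions / sites
  if (any(1 - 2 * Q <= 0) || any(1 - 2 * P - Q <= 0))
    stop("Kimura divergence undefined: substitution saturation",
         call. = FALSE)
  arg <- (1 - 2 * P - Q) * sqrt(1 - 2 * Q)
  100 * (-0.5 * log(arg))
}

#' Assign reads to catalogue variants by circular local alignment
#'
#' Each read is aligned against every variant consensus (treated as circular,
#' on both strands); the best-scoring gap-free segment of length >= `min_len`
#' at identity >= `min_identity` assigns the read to that variant (and its
#' family). Assignment is deterministic and independent of read order.
#'
#' @param reads character vector of reads, or a `read_library` (both mates).
#' @param families list of `sat_family` (named or not) whose variants are
#'   masked against; a plain character vector of monomers is also accepted.
#' @param min_identity minimum segment identity (default 0.70, admitting the
#'   most divergent families seen in practice, ~26%).
#' @param min_len minimum aligned segment length, bp.
#' @return data frame: read, family, variant, length, matches, transitions,
#'   transversions, identity.
#' @export
mask_reads <- function(reads, families, min_identity = 0.70, min_len = 30) {
  if (inherits(reads, "read_library")) reads <- library_seqs(reads)
  flat <- flatten_variants(families)
  if (!length(flat$units)) stop("catalogue is empty", call. = FALSE)
  hits <- cpp_mask(reads, flat$units, min_identity, as.integer(min_len), 9L)
  data.frame(read = hits$read,
             family = flat$family[hits$unit],
             variant = flat$variant[hits$unit],
             length = hits$length, matches = hits$matches,
             transitions = hits$transitions,
             transversions = hits$transversions,
             identity = hits$matches / hits$length,
             stringsAsFactors = FALSE)
}

#' @noRd
flatten_variants <- function(families) {
  if (is.character(families))
    return(list(units = families,
                family = names(families) %||% families,
                variant = rep(1L, length(families))))
  units <- character(0); fam <- character(0); var <- integer(0)
  for (i in seq_along(families)) {
    f <- families[[i]]
    if (inherits(f, "mined_monomer")) {
      units <- c(units, f$consensus)
      fam <- c(fam, f$consensus); var <- c(var, 1L)
    } else {
      vs <- f$variants %||% f$consensus
      units <- c(units, vs)
      fam <- c(fam, rep(f$name %||% f$consensus, length(vs)))
      var <- c(var, seq_along(vs))
    }
  }
  list(units = units, family = fam, variant = var)
}

#' Per-family abundance and divergence from read assignments
#'
#' Abundance counts assigned nucleotides (robust to reads partially
#' overlapping array boundaries): by default
#' `abundance_percent = 100 * assigned_nt / total_nt` with `total_nt` the
#' total sampled nucleotides; `denominator = "assigned"` instead normalises
#' by the nucleotides assigned to any family (the "proportion of mapped
#' reads" reading). Divergence pools transitions and transversions across
#' all of a family's assigned segments into one K2P estimate; it is `NA`
#' when no read is assigned or when the estimate saturates.
#'
#' @param assignments a [mask_reads()] table.
#' @param total_nt total nucleotides in the read set that was masked.
#' @param genome label stored on the records (e.g. "0B").
#' @param denominator "total" (sampled nucleotides) or "assigned".
#' @return data frame: family, genome, abundance_percent, divergence_percent,
#'   reads_assigned.
#' @export
abundance <- function(assignments, total_nt, genome = "",
                      denominator = c("total", "assigned")) {
  denominator <- match.arg(denominator)
  if (total_nt <= 0) stop("total_nt must be > 0", call. = FALSE)
  denom <- if (denominator == "total") total_nt
           else sum(assignments$length)
  if (nrow(assignments) == 0)
    return(data.frame(family = character(0), genome = character(0),
                      abundance_percent = numeric(0),
                      divergence_percent = numeric(0),
                      reads_assigned = integer(0)))
  dt <- data.table(assignments)
  agg <- dt[, .(nt = sum(length), ts = sum(transitions),
                tv = sum(transversions), reads = .N), by = family]
  div <- vapply(seq_len(nrow(agg)), function(i) {
    tryCatch(kimura_divergence(agg$ts[i], agg$tv[i], agg$nt[i]),
             error = function(e) NA_real_)
  }, numeric(1))
  data.frame(family = agg$family, genome = genome,
             abundance_percent = 100 * agg$nt / denom,
             divergence_percent = div,
             reads_assigned = agg$reads, stringsAsFactors = FALSE)
}

#' Abundance/divergence profile of a read library against a catalogue
#'
#' Samples up to `max_reads` read pairs (mirroring the fixed-depth masking of
#' full-scale runs), masks them against the catalogue and rolls the
#' assignments up per family. Families with no assigned read get abundance 0
#' and missing divergence.
#'
#' @param lib a `read_library`.
#' @param families catalogue (see [mask_reads()]).
#' @param max_pairs cap on read pairs used.
#' @param seed sampling seed.
#' @inheritParams mask_reads
#' @inheritParams abundance
#' @return per-family `AbundanceRecord` data frame.
#' @export
quantify_library <- function(lib, families, max_pairs = 1e7, seed = 1,
                             min_identity = 0.70, min_len = 30,
                             genome = lib$genome,
                             denominator = c("total", "assigned")) {
  denominator <- match.arg(denominator)
  smp <- if (lib$n_pairs > max_pairs)
    sample_reads(lib, max_pairs, seed = seed) else lib
  asg <- mask_reads(smp, families, min_identity, min_len)
  total_nt <- 2 * smp$read_len * smp$n_pairs
  ab <- abundance(asg, total_nt, genome, denominator)
  fam_names <- unique(flatten_variants(families)$family)
  missing <- setdiff(fam_names, ab$family)
  if (length(missing))
    ab <- rbind(ab, data.frame(family = missing, genome = genome,
                               abundance_percent = 0,
                               divergence_percent = NA_real_,
                               reads_assigned = 0L))
  ab[order(match(ab$family, fam_names)), , drop = FALSE]
}
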