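#' @noRd
DNA_BASES4 <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#' @param x character vector of ACGT strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || any(is.na(x)) || any(nchar(x) == 0))
    stop(what, " must be a non-empty nucleotide string", call. = FALSE)
  if (any(grepl("[^ACGT]", x)))
    stop(what, " contains characters outside the ACGT alphabet", call. = FALSE)
  invisible(x)
}

#' All rotations of a string
#' @noRd
rotations <- function(s) {
  n <- nchar(s)
  d <- paste0(s, s)
  substring(d, seq_len(n), seq_len(n) + n - 1L)
}

#' Canonical rotation of a monomer
#'
#' The lexicographically smallest string among all rotations of the monomer
#' and of its reverse complement. Monomers are defined only up to rotation and
#' strand; the canonical rotation makes naming and deduplication deterministic.
#'
#' @param s a nucleotide string.
#' @return the canonical rotation of `s`.
#' @export
canonical_rotation <- function(s) {
  assert_dna(s, "monomer")
  vapply(s, function(si) min(c(rotations(si), rotations(revcomp(si)))),
         character(1), USE.NAMES = FALSE)
}

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed (keeps results < 2^31)
#' @noRd
child_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 7919) %% 2147483647
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
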