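## Internal sequence helpers. Coordinates throughout the package are 0-based
## half-open [start, end) on the forward strand of the contig; GFF3 emission
## converts to 1-based inclusive.

#' @importFrom methods as is
#' @importFrom stats rbinom rgeom runif setNames
#' @importFrom utils head tail write.table read.delim
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

GC_TABLE <- Biostrings::GENETIC_CODE

## Translate an in-frame nucleotide string; trailing partial codon dropped,
## stop codons rendered "*", codons containing N rendered "X". Plain lookup
## table: called in tight enumeration loops where DNAString overhead counts.
translate_nt <- function(s) {
  n <- nchar(s)
  if (n < 3) return("")
  n <- n - (n %% 3L)
  aa <- GC_TABLE[substring(s, seq(1L, n, 3L), seq(3L, n, 3L))]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## Validate and normalize a DNA sequence: uppercase, alphabet {A,C,G,T,N}.
## IUPAC ambiguity codes beyond N are rejected -- downstream identity and
## translation semantics are undefined for them.
normalize_dna <- function(s, what = "sequence") {
  s <- toupper(s)
  bad <- gsub("[ACGTN]", "", s)
  if (nzchar(bad)) {
    stop(sprintf("invalid character(s) '%s' in %s (allowed: A,C,G,T,N)",
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ","), what),
         call. = FALSE)
  }
  s
}

## Extract [start, end) 0-based from a forward-strand string; strand "-"
## returns the reverse complement of that slice.
subseq0 <- function(seq, start, end, strand = "+") {
  stopifnot(start >= 0, end <= nchar(seq), start <= end)
  s <- substr(seq, start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

## Mirror a 0-based half-open interval onto the reverse complement of a
## contig of length L: [s, e) -> [L - e, L - s).
mirror_interval <- function(start, end, contig_length) {
  c(start = contig_length - end, end = contig_length - start)
}

## Evaluate an expression under a fixed RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Random DNA of length n (i.i.d. uniform).
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Hamming mismatch count between equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## Substitution matrices used across the package.
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

dna_submat <- function(match = 5, mismatch = -4) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE)
}
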