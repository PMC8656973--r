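## Recombination signal sequence (RSS) and splice-site detection. An RSS is
## heptamer + 12- or 23-nt spacer + nonamer, read outward from the coding
## segment; consensus CACAGTG / ACAAAAACC with the first three heptamer
## bases (CAC) required, as is standard in immunogenetics. Spacer tolerance
## is +/- 1 nt.

RSS_HEPTAMER <- "CACAGTG"
RSS_NONAMER <- "ACAAAAACC"

#' Detect recombination signal sequences at a coding boundary
#'
#' Scans a window around the putative coding-segment edge for a heptamer
#' immediately adjacent to the coding end, then for a nonamer at
#' `expected_spacer` +/- 1 nt further out. The motif is read in the
#' orientation pointing away from the coding segment, so a 5' RSS on the
#' plus strand appears reverse-complemented on the forward contig.
#'
#' @param contig_seq forward-strand contig sequence (character scalar).
#' @param boundary 0-based forward-strand position of the coding edge the
#'   RSS abuts (exclusive end for a downstream RSS, start for an upstream
#'   one, before strand mirroring).
#' @param strand `"+"` or `"-"` (transcription strand of the segment).
#' @param side `"three_prime"` (RSS downstream of the coding segment in
#'   transcription direction) or `"five_prime"`.
#' @param expected_spacer 12 or 23.
#' @param window how far (nt) the heptamer start may deviate from
#'   `boundary`.
#' @param max_mismatch per-element mismatch tolerance (heptamer beyond the
#'   fixed CAC, and nonamer).
#' @return list of [rss_motif()] hits sorted by (total mismatches,
#'   spacer deviation, boundary shift); each hit carries an attribute
#'   `boundary` giving the implied coding edge (forward-strand, 0-based).
#'   Empty list when no RSS is found.
#' @export
detect_rss <- function(contig_seq, boundary, strand, side,
                       expected_spacer = 23L, window = 40L,
                       max_mismatch = 3L) {
  s <- contig_seq[[1]]
  L <- nchar(s)
  stopifnot(boundary >= 0, boundary <= L, side %in% c("five_prime", "three_prime"),
            expected_spacer %in% c(12L, 23L))
  if (strand == "-") {
    s_use <- revcomp(s); b <- L - boundary
  } else {
    s_use <- s; b <- boundary
  }
  downstream <- side == "three_prime"
  hits <- list()
  for (shift in -window:window) {
    for (sp in (expected_spacer - 1L):(expected_spacer + 1L)) {
      if (downstream) {
        h0 <- b + shift                        # heptamer start (oriented coords)
        n0 <- h0 + 7L + sp
        if (h0 < 0 || n0 + 9L > L) next
        hept <- substr(s_use, h0 + 1L, h0 + 7L)
        non <- substr(s_use, n0 + 1L, n0 + 9L)
      } else {
        ## upstream: motif reads away from the coding start on the opposite
        ## orientation; take the reverse complement of the outward flank
        h_end <- b - shift                     # heptamer abuts the coding edge
        h0 <- h_end - 7L
        n_end <- h0 - sp
        n0 <- n_end - 9L
        if (n0 < 0 || h_end > L) next
        hept <- revcomp(substr(s_use, h0 + 1L, h_end))
        non <- revcomp(substr(s_use, n0 + 1L, n_end))
      }
      if (substr(hept, 1, 3) != "CAC") next
      hmm <- hamming(hept, RSS_HEPTAMER)
      if (hmm > max_mismatch) next
      nmm <- hamming(non, RSS_NONAMER)
      if (nmm > max_mismatch) next
      ## map oriented offsets back to forward-strand coordinates
      if (strand == "-") {
        h_fwd <- L - (h0 + 7L); n_fwd <- L - (n0 + 9L)
        implied <- L - (if (downstream) h0 else b - shift)
      } else {
        h_fwd <- h0; n_fwd <- n0
        implied <- if (downstream) h0 else b - shift
      }
      m <- rss_motif(heptamer = hept, heptamer_offset = h_fwd,
                     nonamer = non, nonamer_offset = n_fwd,
                     spacer_length = sp, side = side,
                     heptamer_mismatches = hmm, nonamer_mismatches = nmm)
      attr(m, "boundary") <- as.integer(implied)
      attr(m, "shift") <- abs(shift)
      hits[[length(hits) + 1L]] <- m
    }
  }
  if (length(hits) == 0) return(list())
  ord <- order(vapply(hits, function(m) m$heptamer_mismatches + m$nonamer_mismatches, 0L),
               vapply(hits, function(m) abs(m$spacer_length - expected_spacer), 0L),
               vapply(hits, function(m) attr(m, "shift"), 0L))
  hits[ord]
}

#' Check a splice-site dinucleotide at an exon boundary
#'
#' Introns start with GT (donor) and end with AG (acceptor). The donor is
#' the dinucleotide immediately 3' of the exon in transcription direction;
#' the acceptor immediately 5'. Minus-strand boundaries are evaluated on
#' the reverse complement.
#'
#' @param contig_seq forward-strand contig sequence.
#' @param boundary 0-based forward-strand boundary position (exon end for a
#'   donor on `+`, exon start for an acceptor on `+`; mirrored on `-`).
#' @param strand `"+"` or `"-"`.
#' @param kind `"donor"` or `"acceptor"`.
#' @return list with `valid` (logical) and `dinucleotide` (the observed
#'   2-mer in transcription orientation).
#' @export
detect_splice_sites <- function(contig_seq, boundary, strand,
                                kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  s <- contig_seq[[1]]
  L <- nchar(s)
  if (strand == "-") { s <- revcomp(s); boundary <- L - boundary }
  if (kind == "donor") {
    if (boundary + 2L > L) stop("splice boundary at contig edge", call. = FALSE)
    d <- substr(s, boundary + 1L, boundary + 2L)
    list(valid = d == "GT", dinucleotide = d)
  } else {
    if (boundary - 2L < 0) stop("splice boundary at contig edge", call. = FALSE)
    d <- substr(s, boundary - 1L, boundary)
    list(valid = d == "AG", dinucleotide = d)
  }
}
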