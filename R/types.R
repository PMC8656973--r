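## S3 containers for annotation results. These are deliberately light:
## validated lists with class attributes, printable, and convertible to
## data.frames for export.

#' Recombination signal sequence (RSS) motif hit
#'
#' An RSS is a conserved heptamer and nonamer separated by a spacer of about
#' 12 or 23 nt; V(D)J recombination pairs a 12-RSS with a 23-RSS (the 12/23
#' rule). Offsets are 0-based on the forward strand of the contig.
#'
#' @param heptamer,nonamer motif strings (7 and 9 nt).
#' @param heptamer_offset,nonamer_offset 0-based forward-strand offsets.
#' @param spacer_length spacer length in nt; must be within 1 of 12 or 23.
#' @param side `"five_prime"` or `"three_prime"` relative to the coding
#'   segment the RSS flanks.
#' @param heptamer_mismatches,nonamer_mismatches mismatches to the consensus
#'   (CACAGTG / ACAAAAACC).
#' @return an object of class `rss_motif`.
#' @export
rss_motif <- function(heptamer, heptamer_offset, nonamer, nonamer_offset,
                      spacer_length, side,
                      heptamer_mismatches = 0L, nonamer_mismatches = 0L) {
  stopifnot(nchar(heptamer) == 7, nchar(nonamer) == 9,
            spacer_length %in% c(11L, 12L, 13L, 22L, 23L, 24L),
            side %in% c("five_prime", "three_prime"))
  if (abs(nonamer_offset - heptamer_offset) != 7 + spacer_length &&
      abs(heptamer_offset - nonamer_offset) != 9 + spacer_length) {
    stop("RSS offsets inconsistent with spacer length", call. = FALSE)
  }
  structure(list(heptamer = heptamer, heptamer_offset = as.integer(heptamer_offset),
                 nonamer = nonamer, nonamer_offset = as.integer(nonamer_offset),
                 spacer_length = as.integer(spacer_length), side = side,
                 heptamer_mismatches = as.integer(heptamer_mismatches),
                 nonamer_mismatches = as.integer(nonamer_mismatches)),
            class = "rss_motif")
}

#' Annotated TR gene segment
#'
#' @param contig_id contig the segment lies on.
#' @param locus one of `"TRB"`, `"TRAD"`, `"TRG"`.
#' @param segment_type one of `"V"`, `"D"`, `"J"`, `"C"`.
#' @param chain_subtype e.g. `"TRAV"`, `"TRBJ"`; used for naming.
#' @param strand `"+"` or `"-"`; exon intervals are always stored on the
#'   forward strand, sequence extraction reverse-complements for `"-"`.
#' @param exons data.frame with columns `start`, `end` (0-based half-open,
#'   forward strand) and `role` (`"leader"`, `"coding"`, `"constant_exon"`).
#' @param rss list of [rss_motif()] hits.
#' @param functionality `"functional"`, `"ORF"`, `"pseudogene"` or
#'   `"remnant"`.
#' @param name IMGT-style name (assigned by [assign_names()]), or `NA`.
#' @param subgroup integer subgroup number or `NA`.
#' @param order_index 5'-to-3' rank within the subgroup, or `NA`.
#' @param contig_length contig length for bounds checking (optional).
#' @return an object of class `tr_segment`.
#' @export
tr_segment <- function(contig_id, locus, segment_type, chain_subtype, strand,
                       exons, rss = list(),
                       functionality = "functional", name = NA_character_,
                       subgroup = NA_integer_, order_index = NA_integer_,
                       contig_length = NA_integer_) {
  stopifnot(segment_type %in% c("V", "D", "J", "C"),
            strand %in% c("+", "-"),
            functionality %in% c("functional", "ORF", "pseudogene", "remnant"),
            is.data.frame(exons), all(c("start", "end", "role") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$start >= exons$end)) stop("empty or inverted exon interval")
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("overlapping exon intervals")
  }
  if (!is.na(contig_length) && (min(exons$start) < 0 || max(exons$end) > contig_length)) {
    stop("exon interval out of contig bounds")
  }
  structure(list(contig_id = contig_id, locus = locus,
                 segment_type = segment_type, chain_subtype = chain_subtype,
                 strand = strand, exons = exons, rss = rss,
                 functionality = functionality, name = name,
                 subgroup = subgroup, order_index = order_index),
            class = "tr_segment")
}

#' @export
print.tr_segment <- function(x, ...) {
  cat(sprintf("<tr_segment> %s %s [%s] %s:%d-%d(%s) %s\n",
              x$chain_subtype, ifelse(is.na(x$name), "(unnamed)", x$name),
              x$functionality, x$contig_id,
              min(x$exons$start), max(x$exons$end), x$strand,
              paste(x$exons$role, collapse = "+")))
  invisible(x)
}

## Segment span on the forward strand, 0-based half-open.
segment_span <- function(seg) c(start = min(seg$exons$start), end = max(seg$exons$end))

## 5' position in transcription direction (for ordering within the locus).
segment_tx_start <- function(seg) {
  sp <- segment_span(seg)
  if (seg$strand == "+") unname(sp["start"]) else unname(-sp["end"])
}

#' Spliced sequence of a segment in transcription orientation
#'
#' @param seg a [tr_segment()].
#' @param contig_seq forward-strand contig sequence.
#' @param roles which exon roles to include (default all).
#' @return the concatenated exon sequence, reverse-complemented for minus-
#'   strand segments, in transcription order.
#' @export
segment_sequence <- function(seg, contig_seq, roles = NULL) {
  ex <- seg$exons
  if (!is.null(roles)) ex <- ex[ex$role %in% roles, , drop = FALSE]
  pieces <- mapply(function(s, e) substr(contig_seq, s + 1L, e), ex$start, ex$end)
  s <- paste(pieces, collapse = "")
  if (seg$strand == "-") s <- revcomp(s)
  s
}

#' IMGT-trimmed V comparison region
#'
#' The region used for subgroup clustering: 22 codons before CYS23 through
#' 6 nt past CYS104 (codons for positions 1-106 of the IMGT unique
#' numbering).
#'
#' @param gene_id gene label.
#' @param nt_sequence region nucleotide sequence (in frame).
#' @param cys23_codon_index,cys104_codon_index 0-based codon offsets of the
#'   two conserved cysteines within the region.
#' @return an object of class `imgt_region`.
#' @export
imgt_region <- function(gene_id, nt_sequence, cys23_codon_index,
                        cys104_codon_index) {
  aa <- translate_nt(nt_sequence)
  stopifnot(cys23_codon_index == 22L,
            substr(aa, cys23_codon_index + 1L, cys23_codon_index + 1L) == "C",
            substr(aa, cys104_codon_index + 1L, cys104_codon_index + 1L) == "C",
            nchar(nt_sequence) == (cys104_codon_index + 1L) * 3L + 6L)
  structure(list(gene_id = gene_id, nt_sequence = nt_sequence,
                 cys23_codon_index = as.integer(cys23_codon_index),
                 cys104_codon_index = as.integer(cys104_codon_index)),
            class = "imgt_region")
}

#' @export
print.imgt_region <- function(x, ...) {
  cat(sprintf("<imgt_region> %s: %d nt, CYS23 @ codon %d, CYS104 @ codon %d\n",
              x$gene_id, nchar(x$nt_sequence), x$cys23_codon_index,
              x$cys104_codon_index))
  invisible(x)
}
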