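## IMGT-region trimming, pairwise identity, subgroup clustering at >= 75%
## nucleotide identity, and the J-region F-G-X-G motif scan.

#' Trim a V gene to the IMGT comparison region
#'
#' Locates the two conserved cysteines of the V domain and returns the
#' region spanning 22 codons before CYS23 through 6 nt past CYS104 (codons
#' for IMGT positions 1-106). CYS23 is the first cysteine in the 20-30
#' codon window with a downstream tryptophan anchor (IMGT W41); CYS104 is
#' the last cysteine near the 3' end, preferring one with a tyrosine in the
#' two preceding positions (the Y-x-C profile of positions 102-104).
#'
#' @param nt_sequence in-frame V nucleotide sequence (no internal stop in
#'   the chosen frame; all three frames are tried).
#' @param gene_id label carried into the result.
#' @return an [imgt_region()].
#' @export
imgt_trim <- function(nt_sequence, gene_id = "V") {
  nt_sequence <- normalize_dna(nt_sequence)
  best <- NULL
  for (off in 0:2) {
    s <- substr(nt_sequence, off + 1L, nchar(nt_sequence))
    aa <- translate_nt(s)
    core <- substr(aa, 1, nchar(aa) - 1L)   # allow terminal stop only
    if (grepl("*", core, fixed = TRUE)) next
    res <- try(locate_v_anchors(aa), silent = TRUE)
    if (!inherits(res, "try-error")) { best <- list(off = off, anchors = res); break }
    if (is.null(best)) best <- list(off = off, err = attr(res, "condition"))
  }
  if (is.null(best)) {
    stop("no stop-free reading frame in V sequence '", gene_id, "'", call. = FALSE)
  }
  if (is.null(best$anchors)) stop(conditionMessage(best$err), call. = FALSE)
  cys23 <- best$anchors["cys23"]; cys104 <- best$anchors["cys104"]
  start_codon <- cys23 - 22L                      # 22 codons before CYS23
  if (start_codon < 1L) {
    stop("CYS23-failure: fewer than 22 codons precede CYS23 in '", gene_id, "'",
         call. = FALSE)
  }
  nt_start <- best$off + (start_codon - 1L) * 3L  # 0-based
  nt_end <- best$off + cys104 * 3L + 6L           # 6 nt past CYS104
  if (nt_end > nchar(nt_sequence)) {
    stop("CYS104-failure: fewer than 6 nt follow CYS104 in '", gene_id, "'",
         call. = FALSE)
  }
  imgt_region(gene_id = gene_id,
              nt_sequence = substr(nt_sequence, nt_start + 1L, nt_end),
              cys23_codon_index = 22L,
              cys104_codon_index = (cys104 - start_codon))
}

## Anchor location on a translated V: returns 1-based codon positions.
locate_v_anchors <- function(aa) {
  ch <- strsplit(aa, "")[[1]]
  n <- length(ch)
  ## CYS23: first C in the 20-30 codon window with a W within 25 codons after
  win <- 20:min(30, n)
  c23 <- NA_integer_
  for (p in win) {
    if (ch[p] == "C" && any(ch[seq(p + 1L, min(p + 25L, n))] == "W")) {
      c23 <- p; break
    }
  }
  if (is.na(c23)) stop("CYS23-failure: no anchored cysteine in codon window 20-30",
                       call. = FALSE)
  ## CYS104: last C after c23 + 50, preferring the Y-x-C flanking profile
  cand <- which(ch == "C")
  cand <- cand[cand > c23 + 50L & cand + 2L <= n + 2L]
  if (length(cand) == 0) {
    stop("CYS104-failure: no cysteine in the 3' region", call. = FALSE)
  }
  prof <- cand[vapply(cand, function(p) {
    p > 2 && any(ch[c(p - 2L, p - 1L)] == "Y")
  }, logical(1))]
  c104 <- if (length(prof)) max(prof) else max(cand)
  c(cys23 = c23, cys104 = c104)
}

#' Percent identity of two sequences over the longer sequence length
#'
#' Global nucleotide alignment (match +5, mismatch -4, gap open 10, gap
#' extend 0.5); identity is 100 x identical aligned positions / length of
#' the longer input sequence (the SIAS "length of the largest sequence"
#' denominator). Symmetric by construction: the pair is aligned in a
#' canonical order.
#'
#' @param a,b nucleotide strings or [imgt_region()] objects.
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  if (inherits(a, "imgt_region")) a <- a$nt_sequence
  if (inherits(b, "imgt_region")) b <- b$nt_sequence
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  pair <- sort(c(a, b))
  aln <- Biostrings::pairwiseAlignment(pair[1], pair[2], type = "global",
                                       substitutionMatrix = dna_submat(),
                                       gapOpening = 10, gapExtension = 0.5)
  100 * Biostrings::nmatch(aln) / max(nchar(a), nchar(b))
}

#' Build the all-pairs identity matrix
#'
#' @param regions list of [imgt_region()] objects (or named character
#'   vector of nucleotide sequences).
#' @return symmetric matrix of percent identities with 100 on the diagonal,
#'   labelled by gene id.
#' @export
build_identity_matrix <- function(regions) {
  if (length(regions) == 0) stop("no regions supplied", call. = FALSE)
  if (is.character(regions)) {
    labels <- names(regions)
    seqs <- unname(regions)
  } else {
    labels <- vapply(regions, function(r) r$gene_id, character(1))
    seqs <- vapply(regions, function(r) r$nt_sequence, character(1))
  }
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(labels, labels))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      v <- tryCatch(pairwise_identity(seqs[i], seqs[j]), error = function(e) {
        stop("identity failed for pair (", labels[i], ", ", labels[j], "): ",
             conditionMessage(e), call. = FALSE)
      })
      m[i, j] <- m[j, i] <- v
    }
  }
  m
}

#' Write an identity matrix as TSV
#' @param m matrix from [build_identity_matrix()].
#' @param path output path.
#' @export
write_identity_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cluster genes into subgroups at an identity threshold
#'
#' Genes sharing at least `threshold` percent identity are joined; subgroups
#' are the connected components of that graph (single linkage, the IMGT
#' convention that chained membership is tolerated). Components are numbered
#' by the 5'-to-3' position of their first member when `positions` is
#' supplied, else by decreasing size then first label.
#'
#' @param m identity matrix from [build_identity_matrix()].
#' @param threshold percent identity; comparison is inclusive (default 75).
#' @param positions optional named numeric vector of locus positions used
#'   to number subgroups 5' to 3'.
#' @param linkage `"single"` (default) or `"complete"` (every pair within a
#'   subgroup must pass the threshold; computed by repeated splitting of
#'   single-linkage components is not attempted -- complete linkage uses
#'   hclust on 100-identity).
#' @return list with `mapping` (named integer vector gene -> subgroup),
#'   `sizes` (subgroup sizes), `threshold`.
#' @export
cluster_subgroups <- function(m, threshold = 75, positions = NULL,
                              linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  labels <- rownames(m)
  n <- length(labels)
  if (linkage == "single") {
    adj <- m >= threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
  } else {
    if (n == 1) comp <- c(1L) else {
      hc <- stats::hclust(stats::as.dist(100 - m), method = "complete")
      comp <- stats::cutree(hc, h = 100 - threshold)
    }
    names(comp) <- labels
  }
  ## renumber components deterministically
  ids <- unique(comp)
  if (!is.null(positions)) {
    first_pos <- vapply(ids, function(k) min(positions[labels[comp == k]]), numeric(1))
    ord <- order(first_pos)
  } else {
    sz <- vapply(ids, function(k) sum(comp == k), integer(1))
    first_lab <- vapply(ids, function(k) sort(labels[comp == k])[1], character(1))
    ord <- order(-sz, first_lab)
  }
  renum <- setNames(seq_along(ids), ids[ord])
  mapping <- setNames(as.integer(renum[as.character(comp)]), labels)
  list(mapping = mapping,
       sizes = as.integer(table(mapping)),
       threshold = threshold)
}

#' Scan a J gene for the F-G-X-G motif
#'
#' The J region ends in the conserved F-G-X-G motif whose phenylalanine is
#' IMGT position 118 (PHE118, the last CDR3 residue). Non-canonical J genes
#' carry a single substitution at one of the informative positions (1, 2 or
#' 4; position 3 is free), e.g. FAXG or FGXA.
#'
#' @param sequence J gene sequence, nucleotide or amino acid.
#' @param is_aa set `TRUE` if `sequence` is already protein; by default
#'   nucleotide input is assumed and all three frames are tried.
#' @return list of class `j_motif` with `motif_aa` (observed 4-mer),
#'   `canonical`, `variant_class` (masked pattern such as `"FAXG"`, or `NA`
#'   when canonical), `phe118_codon_index` (0-based codon index of the
#'   motif's first residue within the chosen frame) and `frame` (0-2 nt
#'   offset; 0 for protein input).
#' @export
scan_j_motif <- function(sequence, is_aa = FALSE) {
  frames <- if (is_aa) list(list(off = 0L, aa = toupper(sequence))) else {
    lapply(0:2, function(off) {
      list(off = off, aa = translate_nt(substr(sequence, off + 1L, nchar(sequence))))
    })
  }
  best <- NULL
  for (f in frames) {
    hit <- best_j_window(f$aa)
    if (is.null(hit)) next
    if (is.null(best) || hit$mism < best$mism) best <- c(hit, frame = f$off)
  }
  if (is.null(best) || best$mism > 2) {
    stop("motif-failure: no F-G-X-G motif or variant within edit distance 2",
         call. = FALSE)
  }
  obs <- strsplit(best$motif, "")[[1]]
  canonical <- best$mism == 0
  variant <- if (canonical) NA_character_ else {
    paste0(obs[1], obs[2], "X", obs[4])
  }
  structure(list(motif_aa = best$motif, canonical = canonical,
                 variant_class = variant,
                 phe118_codon_index = best$pos - 1L, frame = best$frame),
            class = "j_motif")
}

## Best F-G-X-G window in the 3' portion of a translated J; position 3
## masked. Ties prefer the most 3' window (the motif sits near the segment
## end, with only the short FR4 tail after it).
best_j_window <- function(aa) {
  n <- nchar(aa)
  if (n < 4) return(NULL)
  ch <- strsplit(aa, "")[[1]]
  from <- max(1L, floor(n / 2) - 3L)
  best <- NULL
  for (p in from:(n - 3L)) {
    w <- ch[p:(p + 3L)]
    if (any(w == "*")) next
    mism <- sum(w[c(1, 2, 4)] != c("F", "G", "G"))
    if (is.null(best) || mism <= best$mism) {
      best <- list(pos = p, motif = paste(w, collapse = ""), mism = mism)
    }
  }
  best
}
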