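## Seed-guided discovery of candidate gene segments: exact local alignment
## of protein seeds against six-frame translations (or nucleotide seeds
## against the contig), iterated to closure, plus detection of multi-kb
## duplication blocks (homology units) by k-mer anchored self-comparison.
## Desk-scale loci make exact Smith-Waterman affordable; no word-seeding
## heuristics are used for gene search.

#' Six-frame translation of a contig
#'
#' @param contig a single DNA string (or named character vector of length 1).
#' @return named character vector of 6 protein strings, frames `+1..+3`
#'   from the forward strand and `-1..-3` from the reverse complement.
#'   Stop codons are rendered `*`; trailing partial codons are dropped.
#' @export
six_frame_translate <- function(contig) {
  s <- if (is.null(names(contig))) contig[[1]] else contig[[1]]
  if (nchar(s) == 0) stop("empty contig", call. = FALSE)
  rc <- revcomp(s)
  frames <- c(`+1` = substr(s, 1, nchar(s)), `+2` = substr(s, 2, nchar(s)),
              `+3` = substr(s, 3, nchar(s)),
              `-1` = substr(rc, 1, nchar(rc)), `-2` = substr(rc, 2, nchar(rc)),
              `-3` = substr(rc, 3, nchar(rc)))
  vapply(frames, translate_nt, character(1))
}

## Best local alignments of one seed against one subject string, found
## recursively: take the best alignment, then search the flanking subject
## intervals. Matrix-agnostic (no masking of the subject). Reports
## (start, end) 1-based inclusive in subject units plus score/identity.
local_hits <- function(seed, subject, submat, gap_open, gap_ext,
                       accept, min_span = 5L, max_hits = 200L) {
  out <- list()
  recurse <- function(lo, hi) {
    if (hi - lo + 1L < min_span || length(out) >= max_hits) return()
    sub <- substr(subject, lo, hi)
    aln <- Biostrings::pairwiseAlignment(seed, sub, type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = gap_open,
                                         gapExtension = gap_ext)
    sc <- Biostrings::score(aln)
    if (!is.finite(sc) || sc <= 0) return()
    s <- Biostrings::start(Biostrings::subject(aln)) + lo - 1L
    e <- Biostrings::end(Biostrings::subject(aln)) + lo - 1L
    alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
    pid <- 100 * Biostrings::nmatch(aln) / alen
    span <- e - s + 1L
    if (accept(sc, pid, span)) {
      out[[length(out) + 1L]] <<- list(start = s, end = e, score = sc,
                                       pid = pid, span = span)
      recurse(lo, s - 1L)
      recurse(e + 1L, hi)
    }
  }
  recurse(1L, nchar(subject))
  out
}

#' Search contigs with seed sequences
#'
#' Protein seeds are aligned locally (BLOSUM62, affine gaps) against all six
#' translated frames of each contig; nucleotide seeds are aligned against
#' both strands directly. Hit coordinates are mapped back to 0-based
#' half-open forward-strand contig coordinates. Overlapping hits on the same
#' strand are merged into one candidate interval.
#'
#' @param contigs named character vector of DNA contigs.
#' @param seeds named character vector of seed sequences.
#' @param seed_type `"AA"` or `"DNA"`.
#' @param min_identity minimum percent identity (default 35 for protein,
#'   70 for nucleotide).
#' @param min_length minimum hit length in seed units (aa or nt; default 40
#'   aa / 60 nt).
#' @param min_score alternative acceptance path: report any local alignment
#'   scoring at least this (substitution-matrix units; default 60 for
#'   protein, `Inf` for nucleotide).
#' @param merge collapse overlapping same-strand hits (default `TRUE`).
#' @return data.frame with columns `contig_id`, `start`, `end` (0-based
#'   half-open, forward strand), `strand`, `frame`, `seed_id`, `score`,
#'   `percent_identity`.
#' @export
seed_search <- function(contigs, seeds, seed_type = c("AA", "DNA"),
                        min_identity = NULL, min_length = NULL,
                        min_score = NULL, merge = TRUE) {
  seed_type <- match.arg(seed_type)
  if (length(seeds) == 0) stop("empty seed set", call. = FALSE)
  if (length(contigs) == 0) return(empty_hits())
  if (seed_type == "AA") {
    if (is.null(min_identity)) min_identity <- 35
    if (is.null(min_length)) min_length <- 40L
    if (is.null(min_score)) min_score <- 60
    submat <- blosum62(); gap_open <- 11; gap_ext <- 1
  } else {
    if (is.null(min_identity)) min_identity <- 70
    if (is.null(min_length)) min_length <- 60L
    if (is.null(min_score)) min_score <- Inf
    submat <- dna_submat(); gap_open <- 10; gap_ext <- 0.5
  }
  accept <- function(sc, pid, span) {
    (pid >= min_identity && span >= min_length) || sc >= min_score
  }
  rows <- list()
  for (ci in seq_along(contigs)) {
    cid <- names(contigs)[ci]
    L <- nchar(contigs[[ci]])
    subjects <- if (seed_type == "AA") six_frame_translate(contigs[ci]) else {
      c(`+1` = contigs[[ci]], `-1` = revcomp(contigs[[ci]]))
    }
    for (fr in names(subjects)) {
      unit <- if (seed_type == "AA") 3L else 1L
      off <- if (seed_type == "AA") abs(as.integer(fr)) - 1L else 0L
      minus <- startsWith(fr, "-")
      for (si in seq_along(seeds)) {
        hits <- local_hits(seeds[[si]], subjects[[fr]], submat, gap_open,
                           gap_ext, accept)
        for (h in hits) {
          nt_s <- off + unit * (h$start - 1L)       # 0-based on frame strand
          nt_e <- off + unit * h$end
          if (minus) { tmp <- mirror_interval(nt_s, nt_e, L); nt_s <- tmp[1]; nt_e <- tmp[2] }
          rows[[length(rows) + 1L]] <- data.frame(
            contig_id = cid, start = nt_s, end = nt_e,
            strand = if (minus) "-" else "+", frame = fr,
            seed_id = names(seeds)[si], score = h$score,
            percent_identity = h$pid, stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits()
  if (merge && nrow(hits) > 1) hits <- merge_hits(hits)
  hits[order(hits$contig_id, hits$start), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(contig_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), frame = character(0),
             seed_id = character(0), score = numeric(0),
             percent_identity = numeric(0), stringsAsFactors = FALSE)
}

## Collapse same-contig same-strand hits overlapping by >= 1 nt into their
## union interval, keeping the best-scoring hit's seed/frame/identity.
merge_hits <- function(hits) {
  pieces <- split(hits, paste(hits$contig_id, hits$strand))
  out <- lapply(pieces, function(h) {
    h <- h[order(h$start, -h$score), , drop = FALSE]
    merged <- h[1, , drop = FALSE]
    for (i in seq_len(nrow(h))[-1]) {
      last <- nrow(merged)
      if (h$start[i] < merged$end[last]) {
        if (h$score[i] > merged$score[last]) {
          keep_end <- max(merged$end[last], h$end[i])
          keep_start <- merged$start[last]
          merged[last, ] <- h[i, ]
          merged$start[last] <- keep_start
          merged$end[last] <- keep_end
        } else {
          merged$end[last] <- max(merged$end[last], h$end[i])
        }
      } else {
        merged <- rbind(merged, h[i, ])
      }
    }
    merged
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Iterate seed search to closure
#'
#' Runs [seed_search()], adds each round's novel candidate sequences
#' (translated hit intervals) to the query set, and repeats until a round
#' yields no interval not already covered by an earlier hit.
#'
#' @inheritParams seed_search
#' @param max_rounds round cap; exceeding it is a non-convergence error.
#' @param ... passed through to [seed_search()].
#' @return list with `hits` (merged union across rounds) and `rounds`
#'   (number of search rounds executed, including the final empty one).
#' @export
iterative_closure <- function(contigs, seeds, seed_type = c("AA", "DNA"),
                              max_rounds = 10L, ...) {
  seed_type <- match.arg(seed_type)
  if (length(seeds) == 0) stop("empty seed set", call. = FALSE)
  all_hits <- empty_hits()
  query <- seeds
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    if (rounds > max_rounds) {
      stop("iterative search did not converge within ", max_rounds, " rounds",
           call. = FALSE)
    }
    hits <- seed_search(contigs, query, seed_type = seed_type, ...)
    novel <- hits[!covered_by(hits, all_hits), , drop = FALSE]
    if (nrow(novel) == 0) break
    all_hits <- merge_hits(rbind(all_hits, novel))
    new_seeds <- vapply(seq_len(nrow(novel)), function(i) {
      s <- subseq0(contigs[[novel$contig_id[i]]], novel$start[i], novel$end[i],
                   novel$strand[i])
      if (seed_type == "AA") translate_nt(s) else s
    }, character(1))
    names(new_seeds) <- sprintf("round%d_hit%d", rounds, seq_len(nrow(novel)))
    query <- c(query, new_seeds)
  }
  list(hits = all_hits[order(all_hits$contig_id, all_hits$start), , drop = FALSE],
       rounds = rounds)
}

covered_by <- function(hits, cover) {
  if (nrow(hits) == 0) return(logical(0))
  if (nrow(cover) == 0) return(rep(FALSE, nrow(hits)))
  vapply(seq_len(nrow(hits)), function(i) {
    any(cover$contig_id == hits$contig_id[i] & cover$strand == hits$strand[i] &
          cover$start < hits$end[i] & cover$end > hits$start[i])
  }, logical(1))
}

#' Detect homology units (multi-kb duplication blocks) by self-comparison
#'
#' Anchors exact word matches between a contig and itself (both strands),
#' groups anchors by diagonal, and reports maximal off-diagonal blocks whose
#' ungapped identity and length pass the thresholds. The trivial
#' self-diagonal is excluded. Blocks copied with point substitutions are
#' found reliably; indel-containing duplications may be fragmented across
#' neighboring diagonals.
#'
#' @param contig a single DNA string.
#' @param window word size for anchor matching (nt).
#' @param min_length minimum block length (nt; default 4000).
#' @param min_identity minimum percent identity (default 96).
#' @param max_gap maximum anchor-free stretch allowed inside a block (nt).
#' @return data.frame with one row per block pair: `start1`, `end1`,
#'   `start2`, `end2` (0-based half-open), `strand2`, `length`,
#'   `percent_identity`.
#' @export
find_homology_units <- function(contig, window = 16L, min_length = 4000L,
                                min_identity = 96, max_gap = 250L) {
  s <- contig[[1]]
  L <- nchar(s)
  if (window > L) stop("window exceeds contig length", call. = FALSE)
  res <- rbind(
    diag_blocks(s, s, window, min_length, min_identity, max_gap,
                self = TRUE, strand2 = "+", L = L),
    diag_blocks(s, revcomp(s), window, min_length, min_identity, max_gap,
                self = FALSE, strand2 = "-", L = L))
  rownames(res) <- NULL
  res
}

## Shared worker: anchor word matches of a vs b, cluster by diagonal,
## score candidate blocks. For strand2 == "-", coordinates of the second
## interval are mapped back from the reverse complement.
diag_blocks <- function(a, b, k, min_length, min_identity, max_gap,
                        self, strand2, L) {
  empty <- data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      strand2 = character(0), length = integer(0),
                      percent_identity = numeric(0), stringsAsFactors = FALSE)
  na <- nchar(a) - k + 1L
  if (na < 1) return(empty)
  words_a <- substring(a, 1:na, k:nchar(a))
  words_b <- if (self) words_a else substring(b, 1:na, k:nchar(b))
  pos_b <- split(seq_len(na), words_b)
  shared <- pos_b[names(pos_b) %in% words_a]
  if (length(shared) == 0) return(empty)
  idx_a <- split(seq_len(na), words_a)[names(shared)]
  anchors <- do.call(rbind, lapply(seq_along(shared), function(i) {
    expand.grid(i = idx_a[[i]], j = shared[[i]])
  }))
  if (self) anchors <- anchors[anchors$i < anchors$j, , drop = FALSE]
  if (nrow(anchors) == 0) return(empty)
  anchors$d <- anchors$j - anchors$i
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  out <- list()
  for (d in unique(anchors$d)) {
    ii <- sort(anchors$i[anchors$d == d])
    runs <- cumsum(c(0L, diff(ii) > max_gap))
    for (r in unique(runs)) {
      pos <- ii[runs == r]
      s1 <- min(pos); e1 <- max(pos) + k - 1L     # 1-based inclusive in a
      len <- e1 - s1 + 1L
      if (len < min_length) next
      seg_a <- av[s1:e1]
      seg_b <- bv[(s1 + d):(e1 + d)]
      pid <- 100 * mean(seg_a == seg_b)
      if (pid < min_identity) next
      if (strand2 == "+") {
        st2 <- s1 + d - 1L; en2 <- e1 + d
      } else {
        m <- mirror_interval(s1 + d - 1L, e1 + d, L)
        st2 <- m[1]; en2 <- m[2]
      }
      out[[length(out) + 1L]] <- data.frame(
        start1 = s1 - 1L, end1 = e1, start2 = st2, end2 = en2,
        strand2 = strand2, length = len, percent_identity = pid,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  ## canonical order + dedup mirrored reverse-strand pairs
  flip <- res$start2 < res$start1
  tmp <- res[flip, c("start2", "end2", "start1", "end1")]
  res[flip, c("start1", "end1", "start2", "end2")] <- tmp
  res[!duplicated(res[, c("start1", "start2", "strand2")]), , drop = FALSE]
}
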