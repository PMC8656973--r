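## Repertoire extraction from reads: quality trim, pair merging with
## quality-aware consensus, V/J assignment against a germline database,
## CDR3 extraction (CYS104 codon through PHE118 codon inclusive), and the
## chord-matrix / CDR3-length summaries.

#' Merge a read pair by overlap
#'
#' Finds the best overlap between the 3' end of read 1 and the reverse
#' complement of read 2 within `[min_overlap, max_overlap]`, minimizing the
#' mismatch rate (ties prefer the longer overlap). Disagreeing overlap
#' bases take the higher-quality call.
#'
#' @param r1,r2 lists (or one-row data.frames) with `seq` and `qual`
#'   (Phred+33); `id` optional.
#' @param max_overlap maximum overlap considered (nt; default 90).
#' @param min_overlap minimum overlap (default 10).
#' @param max_mismatch_rate reject overlaps above this mismatch fraction.
#' @return list with `merged` (logical); when merged also `seq`, `qual`,
#'   `overlap_length`; otherwise the original pair.
#' @export
merge_read_pair <- function(r1, r2, max_overlap = 90L, min_overlap = 10L,
                            max_mismatch_rate = 0.25) {
  s1 <- strsplit(r1$seq, "")[[1]]
  q1 <- phred_scores(r1$qual)
  s2 <- rev(strsplit(chartr("ACGT", "TGCA", r2$seq), "")[[1]])  # revcomp
  q2 <- rev(phred_scores(r2$qual))
  n1 <- length(s1); n2 <- length(s2)
  best <- NULL
  for (o in min_overlap:min(max_overlap, n1, n2)) {
    a <- s1[(n1 - o + 1L):n1]
    b <- s2[1:o]
    rate <- mean(a != b)
    if (is.null(best) || rate < best$rate ||
        (rate == best$rate && o > best$o)) best <- list(o = o, rate = rate)
  }
  if (is.null(best) || best$rate > max_mismatch_rate) {
    return(list(merged = FALSE, r1 = r1, r2 = r2))
  }
  o <- best$o
  ia <- (n1 - o + 1L):n1
  a <- s1[ia]; qa <- q1[ia]
  b <- s2[1:o]; qb <- q2[1:o]
  take_b <- a != b & qb > qa
  cons <- a; cons[take_b] <- b[take_b]
  qcons <- pmax(qa, qb)
  tail_s <- if (o < n2) s2[(o + 1L):n2] else character(0)
  tail_q <- if (o < n2) q2[(o + 1L):n2] else integer(0)
  seq <- paste(c(s1[seq_len(n1 - o)], cons, tail_s), collapse = "")
  qual <- intToUtf8(c(q1[seq_len(n1 - o)], qcons, tail_q) + 33L)
  list(merged = TRUE, id = r1$id, seq = seq, qual = qual, overlap_length = o)
}

#' Sliding-window quality trim
#'
#' Cuts each read at the first window whose mean quality drops below the
#' threshold (3' trim, Trimmomatic-style).
#'
#' @param reads data.frame with `seq`, `qual`.
#' @param min_quality mean-quality threshold (default 20).
#' @param window window width (default 4).
#' @return the trimmed reads.
#' @export
trim_reads <- function(reads, min_quality = 20, window = 4L) {
  for (i in seq_len(nrow(reads))) {
    q <- phred_scores(reads$qual[i])
    n <- length(q)
    cut <- n
    if (n >= window) {
      mw <- vapply(seq_len(n - window + 1L), function(p) mean(q[p:(p + window - 1L)]),
                   numeric(1))
      bad <- which(mw < min_quality)
      if (length(bad)) cut <- bad[1] - 1L
    }
    reads$seq[i] <- substr(reads$seq[i], 1, cut)
    reads$qual[i] <- substr(reads$qual[i], 1, cut)
  }
  reads
}

#' Drop reads shorter than a minimum length
#'
#' @param reads data.frame with a `seq` column.
#' @param min_length inclusive minimum (default 100 nt; a 100-nt read is
#'   kept).
#' @return the retained reads, with attribute `n_removed`.
#' @export
filter_reads <- function(reads, min_length = 100L) {
  keep <- nchar(reads$seq) >= min_length
  out <- reads[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

## Map a 1-based pattern position to the subject through a local alignment;
## NA when outside the aligned pattern range.
map_pattern_pos <- function(aln, pos) {
  ps <- Biostrings::start(Biostrings::pattern(aln))
  pe <- Biostrings::end(Biostrings::pattern(aln))
  if (pos < ps || pos > pe) return(NA_integer_)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pi <- ps - 1L
  si <- Biostrings::start(Biostrings::subject(aln)) - 1L
  for (col in seq_along(pa)) {
    if (pa[col] != "-") pi <- pi + 1L
    if (sa[col] != "-") si <- si + 1L
    if (pi == pos && pa[col] != "-") {
      return(if (sa[col] != "-") si else NA_integer_)
    }
  }
  NA_integer_
}

#' Assign V and J genes to a read
#'
#' Aligns the read (both orientations) against every germline V region and
#' J gene; the best-scoring V and J are kept, with co-optimal hits (within
#' `score_tol`) forming the candidate set. With `merge_ambiguous`,
#' co-optimal V genes of a single subgroup collapse to one subgroup-level
#' call; hits spanning several subgroups stay ambiguous.
#'
#' @param read_seq read sequence (merged read).
#' @param db a `germline_db` (see [simulate_germline_db()]): V regions end
#'   6 nt past CYS104 and `j_phe_nt_end` marks the PHE118 codon end.
#' @param merge_ambiguous collapse same-subgroup ties (default `TRUE`).
#' @param score_tol score tolerance for co-optimality (default 0: exact
#'   ties only).
#' @param min_score minimum alignment score to call a segment.
#' @return list with `v_subgroups`, `v_genes`, `j_genes`, `orientation`,
#'   `cys_start`, `phe_end` (1-based read coordinates of the CDR3 span) and
#'   `assigned` (logical).
#' @export
assign_vj <- function(read_seq, db, merge_ambiguous = TRUE, score_tol = 0,
                      min_score = 80) {
  submat <- dna_submat()
  orient <- list(fwd = read_seq, rev = revcomp(read_seq))
  best <- NULL
  for (ori in names(orient)) {
    subj <- orient[[ori]]
    v_set <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(unlist(db$V)), subj, type = "local",
      substitutionMatrix = submat, gapOpening = 10, gapExtension = 0.5)
    j_set <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(unlist(db$J)), subj, type = "local",
      substitutionMatrix = submat, gapOpening = 10, gapExtension = 0.5)
    v_alns <- setNames(lapply(seq_along(db$V), function(i) v_set[i]), names(db$V))
    j_alns <- setNames(lapply(seq_along(db$J), function(i) j_set[i]), names(db$J))
    vs <- setNames(Biostrings::score(v_set), names(db$V))
    js <- setNames(Biostrings::score(j_set), names(db$J))
    tot <- max(vs) + max(js)
    if (is.null(best) || tot > best$tot) {
      best <- list(ori = ori, subj = subj, v_alns = v_alns, j_alns = j_alns,
                   vs = vs, js = js, tot = tot)
    }
  }
  if (max(best$vs) < min_score || max(best$js) < min_score / 2) {
    return(list(assigned = FALSE))
  }
  v_hit <- names(best$vs)[best$vs >= max(best$vs) - score_tol]
  j_hit <- names(best$js)[best$js >= max(best$js) - score_tol]
  v_sub <- sort(unique(unname(db$v_subgroup[v_hit])))
  if (!merge_ambiguous) {
    v_sub <- unname(db$v_subgroup[v_hit])
  }
  ## CDR3 anchors from the top V / top J alignment
  v_top <- v_hit[which.max(best$vs[v_hit])]
  j_top <- j_hit[which.max(best$js[j_hit])]
  vlen <- nchar(db$V[[v_top]])
  cys_start <- map_pattern_pos(best$v_alns[[v_top]], vlen - 8L)
  phe_end <- map_pattern_pos(best$j_alns[[j_top]], db$j_phe_nt_end[[j_top]])
  list(assigned = TRUE, orientation = best$ori, read_oriented = best$subj,
       v_genes = v_hit, v_subgroups = v_sub, j_genes = j_hit,
       cys_start = cys_start, phe_end = phe_end)
}

#' Extract the CDR3 from an assigned read
#'
#' The CDR3 spans the CYS104 codon through the PHE118 codon inclusive.
#' Junctions whose length is not divisible by 3 are flagged non-productive
#' (excluded from amino-acid statistics).
#'
#' @param assignment result of [assign_vj()] (carries the oriented read and
#'   anchor coordinates).
#' @return list with `cdr3_nt`, `cdr3_aa` (`NA` when non-productive) and
#'   `productive`; `NULL` when the anchors are not locatable.
#' @export
extract_cdr3 <- function(assignment) {
  if (!isTRUE(assignment$assigned)) return(NULL)
  cs <- assignment$cys_start; pe <- assignment$phe_end
  if (is.na(cs) || is.na(pe) || pe <= cs) return(NULL)
  nt <- substr(assignment$read_oriented, cs, pe)
  productive <- nchar(nt) %% 3L == 0L
  aa <- if (productive) translate_nt(nt) else NA_character_
  if (productive && grepl("*", aa, fixed = TRUE)) productive <- FALSE
  list(cdr3_nt = nt, cdr3_aa = aa, productive = productive)
}

#' Extract clonotypes from paired-end reads
#'
#' Full pipeline: merge pairs, apply the minimum-length filter, assign V/J,
#' extract CDR3s, and aggregate identical rearrangements. The clonotype
#' identity key is (chain, V subgroup set, J gene set, CDR3 nucleotide
#' sequence) -- subgroup resolution, because 3' V ends are shared within a
#' subgroup.
#'
#' @param r1,r2 data.frames of paired reads (`id`, `seq`, `qual`).
#' @param db a `germline_db`.
#' @param min_read_length minimum merged-read length (inclusive, default
#'   100).
#' @param max_overlap maximum merge overlap (default 90).
#' @param merge_ambiguous,score_tol see [assign_vj()].
#' @param quality_trim apply [trim_reads()] first (default FALSE: useful
#'   for already-clean simulated reads).
#' @return list with `clonotypes` (list of records), `stats` (named counts:
#'   pairs, merged, length_filtered, assigned, ambiguous, unassigned,
#'   no_cdr3) and `table` (the [clonotype_table()]).
#' @export
extract_clonotypes <- function(r1, r2, db, min_read_length = 100L,
                               max_overlap = 90L, merge_ambiguous = TRUE,
                               score_tol = 0, quality_trim = FALSE) {
  if (quality_trim) { r1 <- trim_reads(r1); r2 <- trim_reads(r2) }
  merged <- list()
  n_unmerged <- 0L
  for (i in seq_len(nrow(r1))) {
    m <- merge_read_pair(as.list(r1[i, ]), as.list(r2[i, ]),
                         max_overlap = max_overlap)
    if (m$merged) merged[[length(merged) + 1L]] <- m else n_unmerged <- n_unmerged + 1L
  }
  reads <- if (length(merged)) {
    data.frame(id = vapply(merged, `[[`, "", "id"),
               seq = vapply(merged, `[[`, "", "seq"),
               qual = vapply(merged, `[[`, "", "qual"), stringsAsFactors = FALSE)
  } else data.frame(id = character(0), seq = character(0), qual = character(0))
  reads <- filter_reads(reads, min_read_length)
  n_filtered <- attr(reads, "n_removed")
  agg <- new.env(parent = emptyenv())
  n_unassigned <- 0L; n_nocdr3 <- 0L
  for (i in seq_len(nrow(reads))) {
    asg <- assign_vj(reads$seq[i], db, merge_ambiguous = merge_ambiguous,
                     score_tol = score_tol)
    if (!asg$assigned) { n_unassigned <- n_unassigned + 1L; next }
    cdr3 <- extract_cdr3(asg)
    if (is.null(cdr3)) { n_nocdr3 <- n_nocdr3 + 1L; next }
    key <- paste(db$chain, paste(asg$v_subgroups, collapse = ","),
                 paste(sort(asg$j_genes), collapse = ","), cdr3$cdr3_nt,
                 sep = "|")
    if (is.null(agg[[key]])) {
      agg[[key]] <- list(chain = db$chain, v_subgroups = asg$v_subgroups,
                         j_genes = sort(asg$j_genes), cdr3_nt = cdr3$cdr3_nt,
                         cdr3_aa = cdr3$cdr3_aa, productive = cdr3$productive,
                         read_count = 1L)
    } else {
      agg[[key]]$read_count <- agg[[key]]$read_count + 1L
    }
  }
  keys <- sort(ls(agg))
  clonotypes <- lapply(keys, function(k) agg[[k]])
  stats <- c(pairs = nrow(r1), merged = length(merged),
             unmerged = n_unmerged, length_filtered = n_filtered,
             assigned = nrow(reads) - n_unassigned - n_nocdr3,
             unassigned = n_unassigned, no_cdr3 = n_nocdr3,
             ambiguous = sum(vapply(clonotypes, function(cl) {
               length(cl$v_subgroups) > 1 || length(cl$j_genes) > 1
             }, logical(1))))
  list(clonotypes = clonotypes, stats = stats,
       table = clonotype_table(clonotypes))
}

#' Tally V-subgroup / J-gene associations (chord matrix)
#'
#' Unambiguous clonotypes are tallied by (J gene, V subgroup); clonotypes
#' with an ambiguous V subgroup or J gene are excluded and counted
#' separately (attribute `n_excluded`).
#'
#' @param clonotypes list of clonotype records.
#' @return integer matrix (rows = J genes, cols = V subgroups) of class
#'   `chord_matrix`; the sum of all cells equals the number of unambiguous
#'   clonotypes supplied.
#' @export
build_chord_matrix <- function(clonotypes) {
  unamb <- Filter(function(cl) {
    length(unique(cl$v_subgroups)) == 1 && length(unique(cl$j_genes)) == 1
  }, clonotypes)
  n_excl <- length(clonotypes) - length(unamb)
  if (length(unamb) == 0) {
    m <- matrix(0L, 0, 0)
  } else {
    jl <- vapply(unamb, function(cl) cl$j_genes[1], character(1))
    vl <- vapply(unamb, function(cl) format_v_call(cl$chain, cl$v_subgroups),
                 character(1))
    m <- unclass(table(factor(jl), factor(vl)))
    storage.mode(m) <- "integer"
    names(dimnames(m)) <- NULL
  }
  structure(m, class = c("chord_matrix", class(m)), n_excluded = n_excl)
}

#' @export
print.chord_matrix <- function(x, ...) {
  cat(sprintf("<chord_matrix> %d J gene(s) x %d V subgroup(s), %d association(s), %d ambiguous excluded\n",
              nrow(x), ncol(x), sum(x), attr(x, "n_excluded")))
  m <- unclass(x)
  attr(m, "n_excluded") <- NULL
  if (length(m)) print(m)
  invisible(x)
}

#' Write a chord matrix as TSV
#' @param m a `chord_matrix`.
#' @param path output path.
#' @export
write_chord_matrix <- function(m, path) {
  df <- data.frame(j_gene = rownames(m), unclass(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-chain CDR3 length statistics
#'
#' Lengths are in amino acids, CYS104 through PHE118 inclusive; only
#' productive clonotypes enter.
#'
#' @param clonotypes list of clonotype records.
#' @return named list per chain with `histogram` (table), `min`, `max`,
#'   `mean`, `n`.
#' @export
cdr3_length_stats <- function(clonotypes) {
  prod <- Filter(function(cl) isTRUE(cl$productive), clonotypes)
  if (length(prod) == 0) return(list())
  chains <- vapply(prod, `[[`, "", "chain")
  lens <- vapply(prod, function(cl) nchar(cl$cdr3_aa), numeric(1))
  out <- lapply(split(lens, chains), function(l) {
    list(histogram = table(l), min = min(l), max = max(l), mean = mean(l),
         n = length(l))
  })
  out
}
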