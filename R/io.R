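## Readers and writers for the external formats the pipeline touches:
## FASTA (contigs, seeds, germline databases), FASTQ (reads), GFF3
## (annotations) and TSV (clonotypes, matrices).

#' Read a FASTA file
#'
#' @param path path to a FASTA file.
#' @param type `"DNA"` (default) validates the {A,C,G,T,N} alphabet and
#'   uppercases; `"AA"` reads protein records as-is (uppercased).
#' @return a named character vector, one element per record. Duplicate ids
#'   and empty sequences are rejected.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) return(setNames(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record '", ids[which(empty)[1]], "'", call. = FALSE)
  }
  if (type == "DNA") {
    seqs <- vapply(seq_along(seqs), function(i) {
      normalize_dna(seqs[i], what = sprintf("record '%s'", ids[i]))
    }, character(1))
  }
  setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path path to an (uncompressed or gzipped) FASTQ file.
#' @return a data.frame with columns `id`, `seq`, `qual` (Phred+33 ASCII).
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = unname(sub("\\s.*$", "", names(set))),
             seq = unname(toupper(as.character(set))),
             qual = unname(as.character(S4Vectors::mcols(set)$qualities)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(paste0("@", reads$id[i]), reads$seq[i], "+", reads$qual[i]), con)
  }
  invisible(path)
}

phred_scores <- function(qual) utf8ToInt(qual) - 33L

## ---- GFF3 -----------------------------------------------------------------

gff3_attr <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, function(v) is.null(v) || (length(v) == 1 && is.na(v)), logical(1))]
  paste(vapply(names(kv), function(k) paste0(k, "=", kv[[k]]), character(1)),
        collapse = ";")
}

parse_gff3_attr <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  setNames(vapply(kv, `[`, character(1), 2), vapply(kv, `[`, character(1), 1))
}

#' Write gene segments to GFF3
#'
#' Internal 0-based half-open coordinates are converted to the GFF3
#' convention (1-based, inclusive). Each segment is emitted as a `gene`
#' feature with `exon` and `recombination_signal_sequence` children so the
#' companion reader [read_gff3()] round-trips all fields.
#'
#' @param segments list of [tr_segment()] objects.
#' @param contig a single named contig sequence (named character vector of
#'   length 1) the segments are annotated on.
#' @param path output path.
#' @export
write_gff3 <- function(segments, contig, path) {
  stopifnot(length(contig) == 1, !is.null(names(contig)))
  contig_id <- names(contig)
  L <- nchar(contig[[1]])
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", contig_id, L))
  for (k in seq_along(segments)) {
    seg <- segments[[k]]
    sp <- segment_span(seg)
    if (sp["start"] < 0 || sp["end"] > L) {
      stop(sprintf("segment %d out of contig bounds [0,%d)", k, L), call. = FALSE)
    }
    gid <- sprintf("gene%04d", k)
    lines <- c(lines, paste(
      contig_id, "trlocus", "gene", sp["start"] + 1L, sp["end"], ".",
      seg$strand, ".",
      gff3_attr(ID = gid, Name = seg$name, locus = seg$locus,
                segment_type = seg$segment_type,
                chain_subtype = seg$chain_subtype,
                functionality = seg$functionality,
                subgroup = seg$subgroup, order_index = seg$order_index),
      sep = "\t"))
    for (i in seq_len(nrow(seg$exons))) {
      lines <- c(lines, paste(
        contig_id, "trlocus", "exon",
        seg$exons$start[i] + 1L, seg$exons$end[i], ".", seg$strand, ".",
        gff3_attr(ID = sprintf("%s.exon%d", gid, i), Parent = gid,
                  role = seg$exons$role[i]),
        sep = "\t"))
    }
    for (i in seq_along(seg$rss)) {
      r <- seg$rss[[i]]
      lo <- min(r$heptamer_offset, r$nonamer_offset)
      hi <- max(r$heptamer_offset + 7L, r$nonamer_offset + 9L)
      lines <- c(lines, paste(
        contig_id, "trlocus", "recombination_signal_sequence",
        lo + 1L, hi, ".", seg$strand, ".",
        gff3_attr(ID = sprintf("%s.rss%d", gid, i), Parent = gid,
                  side = r$side, spacer = r$spacer_length,
                  heptamer = r$heptamer, heptamer_offset = r$heptamer_offset,
                  nonamer = r$nonamer, nonamer_offset = r$nonamer_offset,
                  heptamer_mismatches = r$heptamer_mismatches,
                  nonamer_mismatches = r$nonamer_mismatches),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene segments from GFF3 written by [write_gff3()]
#'
#' @param path GFF3 path.
#' @return list of [tr_segment()] objects.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(list())
  f <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(seqid = vapply(f, `[`, "", 1), type = vapply(f, `[`, "", 3),
                   start = as.integer(vapply(f, `[`, "", 4)),
                   end = as.integer(vapply(f, `[`, "", 5)),
                   strand = vapply(f, `[`, "", 7),
                   attrs = vapply(f, `[`, "", 9), stringsAsFactors = FALSE)
  attrs <- lapply(df$attrs, parse_gff3_attr)
  gene_rows <- which(df$type == "gene")
  segs <- lapply(gene_rows, function(gi) {
    a <- attrs[[gi]]
    gid <- a[["ID"]]
    kids <- which(vapply(attrs, function(x) identical(unname(x["Parent"]), gid),
                         logical(1)))
    ex_rows <- kids[df$type[kids] == "exon"]
    exons <- data.frame(start = df$start[ex_rows] - 1L, end = df$end[ex_rows],
                        role = vapply(attrs[ex_rows], `[[`, "", "role"),
                        stringsAsFactors = FALSE)
    rss_rows <- kids[df$type[kids] == "recombination_signal_sequence"]
    rss <- lapply(rss_rows, function(ri) {
      r <- attrs[[ri]]
      rss_motif(heptamer = r[["heptamer"]],
                heptamer_offset = as.integer(r[["heptamer_offset"]]),
                nonamer = r[["nonamer"]],
                nonamer_offset = as.integer(r[["nonamer_offset"]]),
                spacer_length = as.integer(r[["spacer"]]), side = r[["side"]],
                heptamer_mismatches = as.integer(r[["heptamer_mismatches"]]),
                nonamer_mismatches = as.integer(r[["nonamer_mismatches"]]))
    })
    num_or_na <- function(k) if (k %in% names(a)) as.integer(a[[k]]) else NA_integer_
    tr_segment(contig_id = df$seqid[gi], locus = a[["locus"]],
               segment_type = a[["segment_type"]],
               chain_subtype = a[["chain_subtype"]], strand = df$strand[gi],
               exons = exons, rss = rss, functionality = a[["functionality"]],
               name = if ("Name" %in% names(a)) a[["Name"]] else NA_character_,
               subgroup = num_or_na("subgroup"),
               order_index = num_or_na("order_index"))
  })
  segs
}

## ---- clonotype table ------------------------------------------------------

## Format a V call from chain + subgroup set: {1,4} on TRA -> "TRAV1,TRAV4".
format_v_call <- function(chain, v_subgroups) {
  paste0(sub("TRAD", "TRA", chain), "V", sort(unique(v_subgroups)), collapse = ",")
}

#' Convert clonotypes to an AIRR Rearrangement-style data.frame
#'
#' @param clonotypes list of clonotype records (as produced by
#'   [extract_clonotypes()]).
#' @return data.frame with columns `chain`, `v_call`, `j_call`, `junction`,
#'   `junction_aa`, `duplicate_count`, `productive`, `ambiguous`.
#' @export
clonotype_table <- function(clonotypes) {
  if (length(clonotypes) == 0) {
    return(data.frame(chain = character(0), v_call = character(0),
                      j_call = character(0), junction = character(0),
                      junction_aa = character(0), duplicate_count = integer(0),
                      productive = logical(0), ambiguous = logical(0)))
  }
  do.call(rbind, lapply(clonotypes, function(cl) {
    data.frame(chain = cl$chain,
               v_call = format_v_call(cl$chain, cl$v_subgroups),
               j_call = paste(sort(unique(cl$j_genes)), collapse = ","),
               junction = cl$cdr3_nt, junction_aa = cl$cdr3_aa,
               duplicate_count = cl$read_count, productive = cl$productive,
               ambiguous = length(unique(cl$v_subgroups)) > 1 ||
                 length(unique(cl$j_genes)) > 1,
               stringsAsFactors = FALSE)
  }))
}

#' Write clonotypes as a tab-separated AIRR-style table
#'
#' @inheritParams clonotype_table
#' @param path output path.
#' @export
write_clonotype_table <- function(clonotypes, path) {
  write.table(clonotype_table(clonotypes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
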