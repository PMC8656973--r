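## End-to-end locus annotation: iterated seed search, gene-model assembly,
## functionality classification, IMGT trimming, subgroup clustering and
## naming, packaged as one call returning a `tr_annotation`.

#' Annotate a TR locus contig
#'
#' Runs the full discovery-to-naming pipeline: iterated translated seed
#' search for V/J/C candidates, RSS-flank-validated seed matching for D,
#' gene-model assembly, functionality classification, IMGT-region trimming
#' of the V genes, identity-matrix subgroup clustering at `threshold`, and
#' IMGT-style naming.
#'
#' @param contig named character vector of length 1.
#' @param seeds list with protein seed sets `V`, `J`, `C` (named character
#'   vectors; any may be empty) and nucleotide seeds `D`.
#' @param locus `"TRB"`, `"TRAD"` or `"TRG"`. For TRAD, V genes are split
#'   into TRAV/TRDV by leader-exon length (40-43 nt vs 64/67 nt).
#' @param threshold subgroup identity threshold (percent, default 75).
#' @param max_rounds cap for the iterative search.
#' @param v_min_score,j_min_score,c_min_score alignment-score thresholds
#'   (BLOSUM62 units) for calling V/J/C candidates. The pipeline relies on
#'   scores alone (not the generic identity-over-length path of
#'   [seed_search()]): desk-scale loci are searched exhaustively and score
#'   thresholds separate true homologs from the best chance local
#'   alignments far more sharply.
#' @return object of class `tr_annotation`: list with `segments`,
#'   `identity` (V identity matrix), `subgroups`, `v_regions`, `rounds`,
#'   `locus`, `contig_id`, `log` (per-candidate rejection notes).
#' @export
annotate_locus <- function(contig, seeds, locus = c("TRB", "TRAD", "TRG"),
                           threshold = 75, max_rounds = 10L,
                           v_min_score = 150, j_min_score = 65,
                           c_min_score = 120) {
  locus <- match.arg(locus)
  stopifnot(length(contig) == 1, !is.null(names(contig)))
  L <- nchar(contig[[1]])
  hint <- if (locus == "TRAD") "auto" else "generic"
  log <- list()
  segments <- list()

  ## --- V: iterated search + assembly
  if (length(seeds$V) > 0) {
    cl <- iterative_closure(contig, seeds$V, seed_type = "AA",
                            max_rounds = max_rounds, min_identity = 101,
                            min_score = v_min_score)
    vhits <- cl$hits
    rounds <- cl$rounds
    for (i in seq_len(nrow(vhits))) {
      draft <- assemble_gene_model(contig, vhits[i, ], "V",
                                   chain_subtype_hint = hint, locus = locus)
      subtype <- draft$chain_subtype
      if (is.na(subtype)) subtype <- paste0(sub("TRAD", "TRA", locus), "V")
      seg <- draft_to_segment(draft, chain_subtype = subtype, contig_length = L)
      segments[[length(segments) + 1L]] <- seg
    }
  } else rounds <- 0L

  ## --- J
  if (length(seeds$J) > 0) {
    jhits <- seed_search(contig, seeds$J, seed_type = "AA",
                         min_identity = 101, min_score = j_min_score)
    for (i in seq_len(nrow(jhits))) {
      draft <- assemble_gene_model(contig, jhits[i, ], "J", locus = locus)
      seg <- draft_to_segment(draft,
                              chain_subtype = paste0(sub("TRAD", "TRA", locus), "J"),
                              contig_length = L)
      segments[[length(segments) + 1L]] <- seg
    }
  }

  ## --- D (seed + RSS-flank validated)
  if (length(seeds$D) > 0) {
    for (draft in find_d_segments(contig, seeds$D, locus = locus)) {
      seg <- draft_to_segment(draft,
                              chain_subtype = paste0(sub("TRAD", "TRD", locus), "D"),
                              contig_length = L)
      segments[[length(segments) + 1L]] <- seg
    }
  }

  ## --- C (similarity interval)
  if (length(seeds$C) > 0) {
    chits <- seed_search(contig, seeds$C, seed_type = "AA",
                         min_identity = 101, min_score = c_min_score)
    for (i in seq_len(nrow(chits))) {
      draft <- assemble_gene_model(contig, chits[i, ], "C", locus = locus)
      seg <- draft_to_segment(draft,
                              chain_subtype = paste0(sub("TRAD", "TRA", locus), "C"),
                              contig_length = L)
      segments[[length(segments) + 1L]] <- seg
    }
  }

  ## --- IMGT trimming + subgroup clustering of usable V genes
  v_idx <- which(vapply(segments, function(s) s$segment_type == "V" &&
                          s$functionality %in% c("functional", "ORF"), logical(1)))
  v_regions <- list()
  for (i in v_idx) {
    seg <- segments[[i]]
    coding <- segment_sequence(seg, contig[[1]], roles = "coding")
    reg <- tryCatch(imgt_trim(coding, gene_id = as.character(i)),
                    error = function(e) {
                      log[[length(log) + 1L]] <<- sprintf(
                        "segment %d: IMGT trim failed (%s)", i, conditionMessage(e))
                      NULL
                    })
    if (!is.null(reg)) v_regions[[as.character(i)]] <- reg
  }
  identity <- NULL; subgroups <- NULL; subgroup_map <- NULL
  if (length(v_regions) >= 1) {
    identity <- build_identity_matrix(v_regions)
    positions <- vapply(as.integer(names(v_regions)), function(i) {
      segment_tx_start(segments[[i]])
    }, numeric(1))
    names(positions) <- names(v_regions)
    subgroups <- cluster_subgroups(identity, threshold = threshold,
                                   positions = positions)
    subgroup_map <- subgroups$mapping
  }
  segments <- assign_names(segments, subgroup_map)
  structure(list(contig_id = names(contig), locus = locus, segments = segments,
                 identity = identity, subgroups = subgroups,
                 v_regions = v_regions, rounds = rounds,
                 threshold = threshold, log = log),
            class = "tr_annotation")
}

#' @export
print.tr_annotation <- function(x, ...) {
  types <- vapply(x$segments, `[[`, "", "segment_type")
  func <- vapply(x$segments, `[[`, "", "functionality")
  cat(sprintf("<tr_annotation> locus %s on contig '%s': %d segment(s)\n",
              x$locus, x$contig_id, length(x$segments)))
  if (length(x$segments)) {
    tab <- table(type = types, functionality = func)
    print(tab)
  }
  if (!is.null(x$subgroups)) {
    cat(sprintf("V subgroups at >=%g%% identity: %d\n", x$threshold,
                length(unique(x$subgroups$mapping))))
  }
  invisible(x)
}

#' @export
summary.tr_annotation <- function(object, ...) {
  segs <- object$segments
  df <- do.call(rbind, lapply(segs, function(s) {
    sp <- segment_span(s)
    data.frame(name = s$name, type = s$segment_type,
               chain_subtype = s$chain_subtype, strand = s$strand,
               start = sp["start"], end = sp["end"],
               functionality = s$functionality, subgroup = s$subgroup,
               n_rss = length(s$rss), stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df[order(df$start), , drop = FALSE]
}

#' Build a repertoire germline database from an annotation
#'
#' Collects the IMGT-trimmed V regions (ending 6 nt past CYS104), the J
#' gene sequences with their PHE118 positions, and the D cores of an
#' annotated locus into the database format [assign_vj()] consumes.
#'
#' @param annotation a `tr_annotation`.
#' @param contig the annotated contig (named character vector).
#' @param chain chain label for the clonotype records (e.g. `"TRB"`).
#' @return a `germline_db` list.
#' @export
germline_from_annotation <- function(annotation, contig, chain = NULL) {
  if (is.null(chain)) chain <- sub("TRAD", "TRA", annotation$locus)
  segs <- annotation$segments
  V <- character(0); v_subgroup <- integer(0)
  for (k in names(annotation$v_regions)) {
    seg <- segs[[as.integer(k)]]
    if (is.na(seg$name)) next
    V[[seg$name]] <- annotation$v_regions[[k]]$nt_sequence
    v_subgroup[[seg$name]] <- seg$subgroup
  }
  J <- character(0); j_phe <- integer(0)
  for (seg in segs) {
    if (seg$segment_type != "J" || seg$functionality != "functional") next
    nt <- segment_sequence(seg, contig[[1]], roles = "coding")
    jm <- tryCatch(scan_j_motif(nt), error = function(e) NULL)
    if (is.null(jm)) next
    J[[seg$name]] <- substr(nt, jm$frame + 1L, nchar(nt))
    j_phe[[seg$name]] <- 3L * (jm$phe118_codon_index + 1L)
  }
  D <- character(0)
  for (seg in segs) {
    if (seg$segment_type != "D") next
    D[[seg$name]] <- segment_sequence(seg, contig[[1]], roles = "coding")
  }
  structure(list(chain = chain, V = V, v_subgroup = v_subgroup, J = J,
                 j_phe_nt_end = j_phe, D = D, const = ""),
            class = "germline_db")
}
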