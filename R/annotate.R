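## Turning candidate intervals into full gene models: RSS + splice-site
## detection, leader/coding exon assembly, functionality classification and
## IMGT-style naming. All assembly runs in transcription-oriented
## coordinates (the contig is reverse-complemented for minus-strand hits)
## and intervals are mirrored back onto the forward strand at the end.

LEADER_WINDOWS <- list(TRAV = 40:43, TRDV = c(64L, 67L), generic = 36:70)
INTRON_RANGE <- c(70L, 600L)

#' Assemble a gene model from a search hit
#'
#' For V segments: finds the 3' RSS (23-spacer) to fix the coding end, then
#' enumerates acceptor/donor/leader-start combinations upstream (AG...GT
#' splice dinucleotides, intron 70-600 nt, ATG-initiated leader whose
#' length fits the chain-subtype window) and keeps the best-supported
#' structure. For J: the 5' RSS (12-spacer) fixes the coding start and a
#' downstream GT donor the end, with the F-G-X-G motif located in between.
#' For D: RSS on both flanks. For C: the hit interval is kept as a
#' constant-region exon (exon chaining happens in [annotate_locus()]).
#'
#' @param contig named character vector of length 1 (the contig).
#' @param hit one row of a [seed_search()] hit table (or a list with
#'   `start`, `end`, `strand`).
#' @param segment_type `"V"`, `"D"`, `"J"` or `"C"`.
#' @param chain_subtype_hint e.g. `"TRBV"`; `"auto"` (TRAD locus) decides
#'   TRAV vs TRDV from the recovered leader length.
#' @param locus locus label carried into the model.
#' @param min_splice_context minimum splice-context score (of 50: 20 for
#'   the U1-consensus AAGT after the donor, 30 for a clean polypyrimidine
#'   tract before the acceptor) required to believe a candidate leader;
#'   below it the V is treated as leader-absent.
#' @return an object of class `gene_model_draft` whose `diagnostics` are
#'   recomputable from sequence plus exons alone.
#' @export
assemble_gene_model <- function(contig, hit, segment_type,
                                chain_subtype_hint = "generic",
                                locus = "TRB", min_splice_context = 46) {
  stopifnot(length(contig) == 1, !is.null(names(contig)))
  s_fwd <- contig[[1]]
  L <- nchar(s_fwd)
  strand <- hit$strand
  if (strand == "-") {
    s <- revcomp(s_fwd)
    m <- mirror_interval(hit$start, hit$end, L)
    hs <- m[1]; he <- m[2]
  } else {
    s <- s_fwd; hs <- hit$start; he <- hit$end
  }
  draft <- switch(segment_type,
                  V = assemble_v(s, hs, he, chain_subtype_hint,
                                 min_splice_context),
                  J = assemble_j(s, hs, he),
                  D = assemble_d(s, hs, he, locus),
                  C = assemble_c(s, hs, he))
  ## mirror intervals and RSS back onto the forward strand
  if (strand == "-") {
    draft$exons[, c("start", "end")] <- t(apply(draft$exons, 1, function(r) {
      mirror_interval(as.integer(r["start"]), as.integer(r["end"]), L)
    }))
    draft$exons <- draft$exons[order(draft$exons$start), , drop = FALSE]
    draft$rss <- lapply(draft$rss, function(r) {
      r$heptamer_offset <- L - (r$heptamer_offset + 7L)
      r$nonamer_offset <- L - (r$nonamer_offset + 9L)
      r
    })
  }
  draft$contig_id <- names(contig)
  draft$strand <- strand
  draft$locus <- locus
  draft$segment_type <- segment_type
  class(draft) <- "gene_model_draft"
  draft
}

#' @export
print.gene_model_draft <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<gene_model_draft> %s %s:%s [%s] leader=%s cys104=%s stop=%s splice=%s\n",
              x$segment_type, x$contig_id, x$strand,
              paste(sprintf("%d-%d", x$exons$start, x$exons$end), collapse = ","),
              d$leader_present, d$cys104_present, d$internal_stop,
              d$splice_valid))
  invisible(x)
}

## ---- V assembly (oriented coordinates) ------------------------------------

assemble_v <- function(s, hs, he, hint, min_ctx = 46) {
  L <- nchar(s)
  ## 1. 3' RSS fixes the coding end
  rss <- detect_rss(s, he, "+", "three_prime", expected_spacer = 23L)
  if (length(rss) > 0) {
    coding_end <- attr(rss[[1]], "boundary")
    rss <- rss[1]
  } else {
    coding_end <- he
    rss <- list()
  }
  ## 2. enumerate upstream structure; tier 1 requires canonical GT..AG,
  ## tier 2 (run only when tier 1 yields no intact CYS104-bearing frame)
  ## relaxes one splice dinucleotide at a time so splice-broken genes still
  ## assemble on their true structure
  windows <- switch(hint,
                    auto = LEADER_WINDOWS[c("TRAV", "TRDV")],
                    generic = LEADER_WINDOWS["generic"],
                    LEADER_WINDOWS[hint])
  cands <- enumerate_v_structures(s, hs, coding_end, windows,
                                  relaxed = FALSE, min_ctx = min_ctx)
  strong <- vapply(cands, function(cc) {
    isTRUE(cc$diag$cys104_offset == 6L) && cc$context_score >= min_ctx
  }, logical(1))
  if (!any(strong)) {
    cands <- c(cands, enumerate_v_structures(s, hs, coding_end, windows,
                                             relaxed = TRUE,
                                             min_ctx = min_ctx))
  }
  ## 3. rank candidates; a leader is only believed when its splice context
  ## is near-consensus (>= min_ctx of 50), otherwise the candidate structure is
  ## indistinguishable from chance dinucleotides and the gene is treated as
  ## leader-absent
  coding_only <- function() {
    coding_start <- hs
    diag <- list(cys104_present = FALSE, cys104_offset = NA_integer_,
                 internal_stop = FALSE)
    cd <- coding_diag(s, coding_start, coding_end, phase = 0L)
    if (!is.null(cd)) diag <- cd
    list(
      exons = data.frame(start = coding_start, end = coding_end,
                         role = "coding", stringsAsFactors = FALSE),
      rss = rss, chain_subtype = if (hint == "auto") NA_character_ else hint,
      splice = list(donor = NA, acceptor = NA),
      diagnostics = list(leader_present = FALSE, leader_length = NA_integer_,
                         splice_valid = NA,
                         cys104_present = diag$cys104_present,
                         cys104_offset = diag$cys104_offset,
                         internal_stop = diag$internal_stop,
                         frameshift_3prime = FALSE,
                         three_prime_complete = isTRUE(diag$cys104_present) &&
                           length(rss) > 0))
  }
  if (length(cands) == 0 ||
      max(vapply(cands, `[[`, numeric(1), "context_score")) < min_ctx) {
    return(coding_only())
  }
  score <- vapply(cands, function(cc) {
    d <- cc$diag
    in_window <- cc$window != "generic"
    ## splice evidence: the GT/AG dinucleotides are weighted BELOW the
    ## surrounding consensus context (U1 site, polypyrimidine tract) --
    ## chance dinucleotides are common, chance consensus context is not --
    ## and raw context breaks residual ties
    100000 * isTRUE(d$cys104_offset == 6L) +
      10000 * isTRUE(d$cys104_present) +
      100 * (!isTRUE(d$internal_stop)) +
      30 * in_window +
      8 * (cc$donor_dinuc == "GT") + 8 * (cc$acceptor_dinuc == "AG") +
      cc$context_score + cc$context_score / 1000 -
      abs(cc$acceptor - hs) / 100 -
      cc$leader_len / 1e4          # tie-break: shortest consistent leader
  }, numeric(1))
  best <- cands[[which.max(score)]]
  d <- best$diag
  subtype <- if (hint == "auto") {
    if (best$leader_len %in% LEADER_WINDOWS$TRDV) "TRDV"
    else if (best$leader_len %in% LEADER_WINDOWS$TRAV) "TRAV" else "TRAV"
  } else if (hint == "generic") NA_character_ else hint
  list(
    exons = data.frame(start = c(best$leader_start, best$acceptor),
                       end = c(best$donor, coding_end),
                       role = c("leader", "coding"), stringsAsFactors = FALSE),
    rss = rss, chain_subtype = subtype,
    splice = list(donor = list(valid = best$donor_dinuc == "GT",
                               dinucleotide = best$donor_dinuc),
                  acceptor = list(valid = best$acceptor_dinuc == "AG",
                                  dinucleotide = best$acceptor_dinuc)),
    diagnostics = list(leader_present = TRUE, leader_length = best$leader_len,
                       splice_valid = best$splice_valid,
                       cys104_present = d$cys104_present,
                       cys104_offset = d$cys104_offset,
                       internal_stop = d$internal_stop,
                       frameshift_3prime = isTRUE(d$cys104_present) &&
                         !isTRUE(d$cys104_offset == 6L),
                       three_prime_complete = isTRUE(d$cys104_present)))
}

seq_safe <- function(a, b) if (a > b) integer(0) else seq(a, b)

## Enumerate (leader start, donor, acceptor) candidates upstream of the
## coding end. Dinucleotide and ATG positions are precomputed so the
## relaxed tier stays affordable.
enumerate_v_structures <- function(s, hs, coding_end, windows, relaxed,
                                   min_ctx = 46) {
  acc_range <- seq_safe(max(3L, hs - 45L), min(hs + 45L, coding_end - 30L))
  if (length(acc_range) == 0) return(list())
  acc_ok <- substring(s, acc_range - 1L, acc_range) == "AG"
  lmax <- max(unlist(windows))
  cands <- list()
  push <- function(ls, d, cpos, l, wname, don, acc) {
    diag <- v_diagnostics(s, ls, d, cpos, coding_end)
    if (is.null(diag)) return()
    ## splice-context strength: U1-site AAGT after the GT, polypyrimidine
    ## tract before the AG -- disambiguates the true structure from chance
    ## dinucleotides
    don_mm <- if (d + 6L <= nchar(s)) hamming(substr(s, d + 3L, d + 6L), "AAGT") else 4L
    ppt <- if (cpos > 12L) strsplit(substr(s, cpos - 11L, cpos - 2L), "")[[1]] else character(0)
    ppt_bad <- sum(ppt %in% c("A", "G")) + (10L - length(ppt))
    ctx <- 5 * (4 - don_mm) + 3 * (10 - ppt_bad)
    if (relaxed && ctx < min_ctx) return()  # relaxed tier trusts only near-consensus context
    cands[[length(cands) + 1L]] <<- list(
      leader_start = ls, donor = d, acceptor = cpos, leader_len = l,
      window = wname, splice_valid = don == "GT" && acc == "AG",
      donor_dinuc = don, acceptor_dinuc = acc,
      context_score = ctx, diag = diag)
  }
  walk <- function(cpos, acc, require_gt) {
    d_range <- seq_safe(max(3L + lmax, cpos - INTRON_RANGE[2]),
                        cpos - INTRON_RANGE[1])
    if (length(d_range) == 0) return()
    dons <- substring(s, d_range + 1L, d_range + 2L)
    if (require_gt) { keep <- dons == "GT" } else { keep <- rep(TRUE, length(d_range)) }
    d_range <- d_range[keep]; dons <- dons[keep]
    for (k in seq_along(d_range)) {
      d <- d_range[k]
      for (wname in names(windows)) for (l in windows[[wname]]) {
        ls <- d - l
        if (ls < 0 || substr(s, ls + 1L, ls + 3L) != "ATG") next
        if (!require_gt && dons[k] == "GT" && acc == "AG") next  # tier-1 duplicate
        push(ls, d, cpos, l, wname, dons[k], acc)
      }
    }
  }
  if (!relaxed) {
    for (i in which(acc_ok)) walk(acc_range[i], "AG", require_gt = TRUE)
  } else {
    ## donor relaxed (acceptor must be AG), then acceptor relaxed (donor GT)
    for (i in which(acc_ok)) walk(acc_range[i], "AG", require_gt = FALSE)
    for (i in which(!acc_ok)) {
      walk(acc_range[i], substring(s, acc_range[i] - 1L, acc_range[i]),
           require_gt = TRUE)
    }
  }
  cands
}

## Diagnostics of a candidate leader+coding structure; NULL if degenerate.
v_diagnostics <- function(s, ls, d, cpos, coding_end) {
  if (coding_end - cpos < 30) return(NULL)
  phase <- (d - ls) %% 3L
  coding_diag(s, cpos, coding_end, phase,
              spliced = paste0(substr(s, ls + 1L, d), substr(s, cpos + 1L, coding_end)))
}

## CYS104 and stop diagnostics of a coding stretch. The CYS104 codon should
## end 6 nt before the coding end (the V region runs 6 nt past CYS104); an
## offset of 4,5,7 or 8 with an intact frame marks a 3' frameshift that
## preserves CYS104 (the ORF class).
coding_diag <- function(s, cstart, cend, phase, spliced = NULL) {
  if (is.null(spliced)) {
    spliced <- substr(s, cstart + 1L, cend)
    spliced <- substr(spliced, ((3L - phase) %% 3L) + 1L, nchar(spliced))
  }
  if (nchar(spliced) < 30) return(NULL)
  aa <- translate_nt(spliced)
  ch <- strsplit(aa, "")[[1]]
  cys <- which(ch == "C")
  offs <- nchar(spliced) - 3L * cys               # nt after each CYS codon
  ok <- cys[offs >= 3L & offs <= 9L]
  cys104_present <- length(ok) > 0
  cys104_offset <- if (cys104_present) nchar(spliced) - 3L * max(ok) else NA_integer_
  stop_pos <- which(ch == "*")
  internal_stop <- if (cys104_present) any(stop_pos < max(ok)) else length(stop_pos) > 0
  list(cys104_present = cys104_present, cys104_offset = cys104_offset,
       internal_stop = internal_stop)
}

## ---- J assembly -----------------------------------------------------------

assemble_j <- function(s, hs, he) {
  rss <- detect_rss(s, hs, "+", "five_prime", expected_spacer = 12L)
  if (length(rss) > 0) {
    coding_start <- attr(rss[[1]], "boundary")
    rss <- rss[1]
  } else {
    coding_start <- hs
    rss <- list()
  }
  ## donor GT downstream closes the J exon; prefer ends whose exon carries
  ## the F-G-X-G motif and whose donor has U1-consensus context (AAGT)
  best <- NULL
  for (e in seq_safe(max(coding_start + 20L, he - 12L), min(he + 45L, nchar(s) - 6L))) {
    if (substr(s, e + 1L, e + 2L) != "GT") next
    jm <- tryCatch(scan_j_motif(substr(s, coding_start + 1L, e)),
                   error = function(err) NULL)
    sc <- 100 * (!is.null(jm)) + (4 - hamming(substr(s, e + 3L, e + 6L), "AAGT"))
    if (is.null(best) || sc > best$score) {
      best <- list(end = e, motif = jm, donor = "GT", score = sc)
    }
  }
  if (is.null(best)) {
    best <- list(end = he, motif = tryCatch(
      scan_j_motif(substr(s, coding_start + 1L, he)), error = function(err) NULL),
      donor = substr(s, min(he + 1L, nchar(s) - 1L), min(he + 2L, nchar(s))))
  }
  list(exons = data.frame(start = coding_start, end = best$end, role = "coding",
                          stringsAsFactors = FALSE),
       rss = rss, chain_subtype = NA_character_,
       splice = list(donor = list(valid = best$donor == "GT",
                                  dinucleotide = best$donor), acceptor = NA),
       j_motif = best$motif,
       diagnostics = list(leader_present = NA, leader_length = NA_integer_,
                          splice_valid = best$donor == "GT",
                          cys104_present = NA, cys104_offset = NA_integer_,
                          internal_stop = is.null(best$motif),
                          frameshift_3prime = FALSE,
                          three_prime_complete = TRUE,
                          motif_found = !is.null(best$motif),
                          rss_found = length(rss) > 0))
}

## ---- D assembly -----------------------------------------------------------

assemble_d <- function(s, hs, he, locus) {
  spacers <- if (locus == "TRB") c(five = 12L, three = 23L) else c(five = 12L, three = 12L)
  rss5 <- detect_rss(s, hs, "+", "five_prime", expected_spacer = spacers["five"],
                     window = 10L)
  rss3 <- detect_rss(s, he, "+", "three_prime", expected_spacer = spacers["three"],
                     window = 10L)
  cs <- if (length(rss5)) attr(rss5[[1]], "boundary") else hs
  ce <- if (length(rss3)) attr(rss3[[1]], "boundary") else he
  list(exons = data.frame(start = cs, end = ce, role = "coding",
                          stringsAsFactors = FALSE),
       rss = c(rss5[seq_len(min(1, length(rss5)))],
               rss3[seq_len(min(1, length(rss3)))]),
       chain_subtype = NA_character_,
       splice = list(donor = NA, acceptor = NA),
       diagnostics = list(leader_present = NA, leader_length = NA_integer_,
                          splice_valid = NA, cys104_present = NA,
                          cys104_offset = NA_integer_, internal_stop = FALSE,
                          frameshift_3prime = FALSE, three_prime_complete = TRUE,
                          rss_both = length(rss5) > 0 && length(rss3) > 0))
}

## ---- C assembly -----------------------------------------------------------

assemble_c <- function(s, hs, he) {
  list(exons = data.frame(start = hs, end = he, role = "constant_exon",
                          stringsAsFactors = FALSE),
       rss = list(), chain_subtype = NA_character_,
       splice = list(donor = NA, acceptor = NA),
       diagnostics = list(leader_present = NA, leader_length = NA_integer_,
                          splice_valid = NA, cys104_present = NA,
                          cys104_offset = NA_integer_, internal_stop = FALSE,
                          frameshift_3prime = FALSE, three_prime_complete = TRUE))
}

#' Classify the functionality of a gene model
#'
#' Classification rules: a partial V missing the leader or the 3' end
#' (through CYS104) is a remnant; improper splice sites, internal stop
#' codons or a frameshift destroying CYS104 make a pseudogene; a 3'
#' frameshift whose reading frame still encodes CYS104 is an ORF; anything
#' else is functional. Remnant takes precedence over pseudogene when both
#' criteria hold.
#'
#' @param draft a `gene_model_draft` from [assemble_gene_model()].
#' @return one of `"functional"`, `"ORF"`, `"pseudogene"`, `"remnant"`.
#' @export
classify_functionality <- function(draft) {
  d <- draft$diagnostics
  if (draft$segment_type == "V") {
    if (!isTRUE(d$leader_present) || !isTRUE(d$three_prime_complete)) {
      return("remnant")
    }
    if (!isTRUE(d$splice_valid) || isTRUE(d$internal_stop)) return("pseudogene")
    if (isTRUE(d$frameshift_3prime)) return("ORF")
    return("functional")
  }
  if (draft$segment_type == "J") {
    if (!isTRUE(d$rss_found) || !isTRUE(d$splice_valid) || !isTRUE(d$motif_found)) {
      return("pseudogene")
    }
    return("functional")
  }
  if (draft$segment_type == "D") {
    return(if (isTRUE(d$rss_both)) "functional" else "pseudogene")
  }
  "functional"
}

#' Turn a classified draft into a [tr_segment()]
#'
#' @param draft a `gene_model_draft`.
#' @param chain_subtype override the draft's subtype (optional).
#' @param contig_length for bounds validation (optional).
#' @return a [tr_segment()].
#' @export
draft_to_segment <- function(draft, chain_subtype = NULL, contig_length = NA) {
  func <- classify_functionality(draft)
  subtype <- if (!is.null(chain_subtype)) chain_subtype else draft$chain_subtype
  seg <- tr_segment(contig_id = draft$contig_id, locus = draft$locus,
                    segment_type = draft$segment_type,
                    chain_subtype = subtype, strand = draft$strand,
                    exons = draft$exons, rss = draft$rss,
                    functionality = func, contig_length = contig_length)
  seg$diagnostics <- draft$diagnostics
  if (!is.null(draft$j_motif)) seg$j_motif <- draft$j_motif
  seg
}

#' Assign IMGT-style names to gene segments
#'
#' V genes are named subtype + subgroup number + "-" + their 5'-to-3' rank
#' within the subgroup (in locus transcription direction); single-member
#' subgroups omit the rank. J, D and C genes are numbered sequentially 5'
#' to 3'. Pseudogene names are suffixed "P". Remnants are not named.
#'
#' @param segments list of [tr_segment()] objects.
#' @param subgroup_map named integer vector gene-index -> subgroup for V
#'   segments (names are indices into `segments` as character), e.g. built
#'   from [cluster_subgroups()]; segments without an entry keep
#'   `subgroup = NA` and are numbered sequentially.
#' @return the segments, with `name`, `subgroup`, `order_index` filled in.
#' @export
assign_names <- function(segments, subgroup_map = NULL) {
  if (length(segments) == 0) return(segments)
  tx <- vapply(segments, segment_tx_start, numeric(1))
  key <- vapply(segments, function(s) paste(s$chain_subtype, s$segment_type),
                character(1))
  is_remnant <- vapply(segments, function(s) s$functionality == "remnant",
                       logical(1))
  for (k in unique(key)) {
    idx <- which(key == k & !is_remnant)
    if (length(idx) == 0) next
    idx <- idx[order(tx[idx])]
    st <- segments[[idx[1]]]$segment_type
    subtype <- segments[[idx[1]]]$chain_subtype
    if (st == "V" && !is.null(subgroup_map)) {
      sg <- subgroup_map[as.character(idx)]
      sg[is.na(sg)] <- max(c(0L, sg), na.rm = TRUE) + seq_len(sum(is.na(sg)))
      for (g in unique(sg)) {
        members <- idx[sg == g]
        for (r in seq_along(members)) {
          i <- members[r]
          nm <- if (length(members) == 1) paste0(subtype, g)
                else paste0(subtype, g, "-", r)
          if (segments[[i]]$functionality == "pseudogene") nm <- paste0(nm, "P")
          segments[[i]]$name <- nm
          segments[[i]]$subgroup <- as.integer(g)
          segments[[i]]$order_index <- r
        }
      }
    } else {
      for (r in seq_along(idx)) {
        i <- idx[r]
        nm <- if (length(idx) == 1) paste0(subtype, 1) else paste0(subtype, r)
        if (segments[[i]]$functionality == "pseudogene") nm <- paste0(nm, "P")
        segments[[i]]$name <- nm
        segments[[i]]$subgroup <- if (st == "V") 1L else NA_integer_
        segments[[i]]$order_index <- r
      }
    }
  }
  nms <- vapply(segments, function(s) s$name, character(1))
  nms <- nms[!is.na(nms)]
  if (anyDuplicated(nms)) {
    stop("internal error: duplicate segment name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  segments
}

#' Locate D segments by seed match plus RSS-flank validation
#'
#' D segments are too short for translated similarity search; they are
#' located by near-exact nucleotide match to seed D sequences and validated
#' by the presence of RSS on both flanks (12-spacer 5', 23-spacer 3' at
#' TRB; 12/12 elsewhere).
#'
#' @param contig named character vector of length 1.
#' @param d_seeds named character vector of D nucleotide seeds.
#' @param locus locus label (sets the 3' spacer).
#' @param max_mismatch allowed mismatches in the seed match.
#' @return list of `gene_model_draft` objects.
#' @export
find_d_segments <- function(contig, d_seeds, locus = "TRB", max_mismatch = 2L) {
  s <- contig[[1]]
  drafts <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") s else revcomp(s)
    for (di in seq_along(d_seeds)) {
      m <- Biostrings::matchPattern(d_seeds[[di]], Biostrings::DNAString(subj),
                                    max.mismatch = max_mismatch)
      for (k in seq_along(m)) {
        hs <- Biostrings::start(m)[k] - 1L
        he <- Biostrings::end(m)[k]
        hit_fwd <- if (strand == "-") {
          mm <- mirror_interval(hs, he, nchar(s))
          list(start = mm[1], end = mm[2], strand = strand)
        } else list(start = hs, end = he, strand = strand)
        draft <- assemble_gene_model(contig, hit_fwd, "D", locus = locus)
        if (isTRUE(draft$diagnostics$rss_both)) {
          drafts[[length(drafts) + 1L]] <- draft
        }
      }
    }
  }
  ## dedup identical coding intervals found from several seeds/strands
  if (length(drafts) > 1) {
    keys <- vapply(drafts, function(d) paste(d$exons$start[1], d$exons$end[1]),
                   character(1))
    drafts <- drafts[!duplicated(keys)]
  }
  drafts
}
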