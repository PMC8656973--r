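## Synthetic locus and repertoire generator with planted ground truth.
## Gene architecture follows the germline TR canon: V = ATG-initiated
## leader exon + GT..AG intron + coding exon carrying the CYS23/W41 and
## Y-x-CYS104 anchors + 3' 23-spacer RSS; J = 5' 12-spacer RSS + coding
## exon with the F-G-X-G motif + GT donor; D = RSS-flanked core; C = a
## constant-region exon. Intergenic background is i.i.d. uniform sequence.
## Splice sites are planted with canonical context (GTAAGT donor,
## polypyrimidine tract before the acceptor AG) so structure recovery is
## well-posed.

AA_POOL <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], c("C"))
REV_GC <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)

back_translate <- function(aa) {
  ch <- strsplit(aa, "")[[1]]
  paste(vapply(ch, function(a) {
    cods <- REV_GC[[a]]
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
}

random_aa <- function(n, pool = AA_POOL) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

## ---- V region construction ------------------------------------------------

## A founder V comparison region: 106 codons, CYS23, W41, Y102, CYS104,
## no other cysteine in the CYS23 window or 3' of CYS104, and no "AG"
## dinucleotide in the first 45 nt (keeps the acceptor unambiguous).
make_v_region <- function() {
  repeat {
    aa <- c(strsplit(random_aa(22), "")[[1]], "C",
            strsplit(random_aa(17), "")[[1]], "W",
            strsplit(random_aa(60), "")[[1]], "Y",
            sample(AA_POOL, 1), "C",
            sample(setdiff(AA_POOL, "Y"), 2))
    nt <- back_translate(paste(aa, collapse = ""))
    if (!grepl("AG", substr(nt, 1, 45), fixed = TRUE)) return(nt)
  }
}

## Point-mutate a founder region to a target identity, avoiding anchors
## (codons 23, 41, 102, 104), new cysteines near the anchors, stops, and
## new "AG" in the acceptor-proximal prefix.
mutate_v_region <- function(nt, identity) {
  n <- nchar(nt)
  n_mut <- round((1 - identity) * n)
  ch <- strsplit(nt, "")[[1]]
  banned_codons <- c(23L, 41L, 102L, 104L)
  no_c_codons <- c(20:22, 24:30, 105:106)
  done <- 0L; tries <- 0L
  while (done < n_mut && tries < 50L * n_mut) {
    tries <- tries + 1L
    p <- sample.int(n, 1)
    codon_i <- (p - 1L) %/% 3L + 1L
    if (codon_i %in% banned_codons) next
    new <- sample(setdiff(DNA_BASES, ch[p]), 1)
    old <- ch[p]
    ch[p] <- new
    cod <- paste(ch[(codon_i * 3L - 2L):(codon_i * 3L)], collapse = "")
    aa_new <- GC_TABLE[[cod]]
    bad <- aa_new == "*" || (aa_new == "C" && codon_i %in% no_c_codons) ||
      (p <= 46L && (substr(paste(ch[max(1, p - 1L):min(n, p + 1L)], collapse = ""),
                           1, 2) == "AG" ||
                    substr(paste(ch[max(1, p - 1L):min(n, p + 1L)], collapse = ""),
                           2, 3) == "AG"))
    if (bad) { ch[p] <- old; next }
    done <- done + 1L
  }
  paste(ch, collapse = "")
}

## ---- gene cassettes (local coordinates, transcription orientation) --------

rss_seq <- function(spacer) {
  paste0(RSS_HEPTAMER, random_dna(spacer), RSS_NONAMER)
}

rss5_seq <- function(spacer) {
  ## 5' RSS as it appears on the coding strand: revcomp(nonamer spacer heptamer)
  revcomp(paste0(RSS_HEPTAMER, random_dna(spacer), RSS_NONAMER))
}

make_intron <- function(len = NULL) {
  if (is.null(len)) len <- sample(90:200, 1)
  stopifnot(len >= 60)
  repeat {
    body <- random_dna(len - 18L)
    if (grepl("GT", substr(body, 1, 40)) || grepl("AG", substr(body, nchar(body) - 40L, nchar(body)))) next
    intron <- paste0("GTAAGT", body, paste(sample(c("C", "T"), 10, TRUE), collapse = ""), "AG")
    return(intron)
  }
}

## Build one V gene cassette. Returns local 0-based features and sequence.
## Lesions: internal_stop, splice_break, leader_deletion, trunc3, frameshift3.
make_v_cassette <- function(region_nt, leader_len, lesion = "none") {
  phase <- leader_len %% 3L
  filler <- strrep("C", (3L - phase) %% 3L)
  coding <- paste0(filler, region_nt)
  ## leader: ATG + stop-free tail with no internal ATG (the start codon is
  ## then the unique translation start consistent with the leader window)
  repeat {
    leader <- paste0("ATG", random_dna(leader_len - 3L))
    if (grepl("ATG", substr(leader, 2L, leader_len), fixed = TRUE)) next
    spliced_aa <- translate_nt(paste0(leader, coding))
    if (!grepl("*", substr(spliced_aa, 1, nchar(spliced_aa) - 1L), fixed = TRUE)) break
  }
  intron <- make_intron()
  if (lesion == "internal_stop") {
    ## replace codon 60 of the region with TAA
    off <- nchar(filler) + 59L * 3L
    coding <- paste0(substr(coding, 1, off), "TAA",
                     substr(coding, off + 4L, nchar(coding)))
  }
  if (lesion == "frameshift3") {
    ## 1-nt insertion between the CYS104 codon and the final 6 nt
    coding <- paste0(substr(coding, 1, nchar(coding) - 6L), "A",
                     substr(coding, nchar(coding) - 5L, nchar(coding)))
  }
  if (lesion == "splice_break") {
    intron <- paste0("GG", substr(intron, 3, nchar(intron)))
  }
  rss <- rss_seq(23L)
  if (lesion == "leader_deletion") {
    seq <- paste0(coding, rss)
    feats <- list(leader = NULL, coding = c(0L, nchar(coding)),
                  rss_at = nchar(coding))
  } else if (lesion == "trunc3") {
    coding <- substr(coding, 1, 150L)
    seq <- paste0(leader, intron, coding)
    feats <- list(leader = c(0L, nchar(leader)),
                  coding = c(nchar(leader) + nchar(intron),
                             nchar(leader) + nchar(intron) + nchar(coding)),
                  rss_at = NA_integer_)
  } else {
    seq <- paste0(leader, intron, coding, rss)
    feats <- list(leader = c(0L, nchar(leader)),
                  coding = c(nchar(leader) + nchar(intron),
                             nchar(leader) + nchar(intron) + nchar(coding)),
                  rss_at = nchar(leader) + nchar(intron) + nchar(coding))
  }
  expected <- switch(lesion,
                     none = "functional", internal_stop = "pseudogene",
                     splice_break = "pseudogene", leader_deletion = "remnant",
                     trunc3 = "remnant", frameshift3 = "ORF")
  list(seq = seq, feats = feats, lesion = lesion, expected = expected,
       leader_len = if (lesion == "leader_deletion") NA_integer_ else leader_len,
       coding_nt = coding)
}

## J gene: aa = 9 CDR3-side residues + F G x G + 6 FR4 residues, i.e. 19
## codons (real TRAJ genes encode 17-22 aa) with PHE118 at codon 9 -- this
## sizes simulated TRA CDR3s near the published 11-18 aa range. The G-free
## flanks keep the motif window unique. Cassette = 5' 12-RSS + coding +
## GT donor.
make_j_gene <- function(variant = NULL) {
  m <- c("F", "G", sample(AA_POOL, 1), "G")
  if (!is.null(variant)) {
    if (variant == "FAXG") m[2] <- "A"
    if (variant == "FGXA") m[4] <- "A"
  }
  aa <- paste0(random_aa(9, setdiff(AA_POOL, c("F", "G"))),
               paste(m, collapse = ""),
               random_aa(6, setdiff(AA_POOL, "G")))
  nt <- back_translate(aa)
  rss <- rss5_seq(12L)
  list(aa = aa, nt = nt, phe118_codon_index = 9L,
       seq = paste0(rss, nt, "GTAAGT"),
       coding_local = c(nchar(rss), nchar(rss) + nchar(nt)))
}

make_d_gene <- function(core, spacer3 = 23L) {
  rss5 <- rss5_seq(12L)
  list(core = core, seq = paste0(rss5, core, rss_seq(spacer3)),
       coding_local = c(nchar(rss5), nchar(rss5) + nchar(core)))
}

make_c_gene <- function(len_aa = 90L) {
  aa <- random_aa(len_aa)
  list(aa = aa, nt = back_translate(aa))
}

## ---- blueprint ------------------------------------------------------------

#' Blueprint for a synthetic TR locus
#'
#' Presets encode the published catfish locus architectures at 1/10 scale
#' (TRB 112 V / 1 D / 31 J / 2 C; TRAD 140 V on the minus strand / 4 D /
#' 125 + 1 J; TRG V-J-C cassettes), small enough for second-scale tests.
#'
#' @param preset `"trb-like"`, `"trad-like"` or `"trg-like"`.
#' @param n_v,v_subgroups,n_d,n_j,n_c segment counts (override preset).
#' @param within_identity member-to-founder nucleotide identity inside a
#'   subgroup (default 0.94; member pairs then share roughly 88-90%,
#'   comfortably above the 75% subgroup threshold). Founders of different
#'   subgroups are independent, so between-subgroup identity stays far
#'   below it.
#' @param lesion_counts named integer vector; that many V genes receive
#'   each lesion (`internal_stop`, `splice_break`, `leader_deletion`,
#'   `trunc3`, `frameshift3`).
#' @param v_strand strand the V genes are laid on (`"-"` for trad-like:
#'   the V genes of the modeled TRAD locus run opposite to the D/J/C
#'   block).
#' @param duplication `NULL`, or `list(length =, identity =)` to append a
#'   tandem homology-unit pair of that length and identity.
#' @param seed RNG seed; the same blueprint + seed is byte-reproducible.
#' @return object of class `locus_blueprint`.
#' @export
locus_blueprint <- function(preset = c("trb-like", "trad-like", "trg-like"),
                            n_v = NULL, v_subgroups = NULL, n_d = NULL,
                            n_j = NULL, n_c = NULL, within_identity = 0.94,
                            lesion_counts = NULL, v_strand = NULL,
                            duplication = NULL, seed = 1L) {
  preset <- match.arg(preset)
  bp <- switch(preset,
    "trb-like" = list(locus = "TRB", chain = "TRB", n_v = 11L, v_subgroups = 3L,
                      n_d = 1L, n_j = 3L, n_c = 1L, v_strand = "+",
                      leader_lens = 44:52, d_spacer3 = 23L,
                      d_cores = "GGGACAGGGGGC"),
    "trad-like" = list(locus = "TRAD", chain = "TRA", n_v = 14L, v_subgroups = 3L,
                       n_d = 4L, n_j = 6L, n_c = 2L, v_strand = "-",
                       leader_lens = NULL, d_spacer3 = 12L, d_cores = NULL),
    "trg-like" = list(locus = "TRG", chain = "TRG", n_v = 4L, v_subgroups = 2L,
                      n_d = 0L, n_j = 2L, n_c = 2L, v_strand = "+",
                      leader_lens = 44:52, d_spacer3 = 12L, d_cores = NULL))
  for (f in c("n_v", "v_subgroups", "n_d", "n_j", "n_c", "v_strand")) {
    v <- get(f)
    if (!is.null(v)) bp[[f]] <- v
  }
  bp$within_identity <- within_identity
  bp$lesion_counts <- lesion_counts
  bp$duplication <- duplication
  bp$seed <- seed
  bp$preset <- preset
  if (bp$within_identity <= 0.75) {
    stop("within_identity must exceed the 0.75 subgroup threshold", call. = FALSE)
  }
  if (!is.null(duplication) && (duplication$identity > 100 || duplication$identity < 50)) {
    stop("duplication identity must be a percentage in [50, 100]", call. = FALSE)
  }
  structure(bp, class = "locus_blueprint")
}

## ---- locus simulation -----------------------------------------------------

#' Simulate a germline TR locus with planted truth
#'
#' @param blueprint a [locus_blueprint()].
#' @param out_prefix if given, writes `<prefix>.fasta`, `<prefix>.gff3` and
#'   per-type seed files `<prefix>_seeds_v.fasta` (protein), `_seeds_j`,
#'   `_seeds_c` (protein) and `_seeds_d` (nucleotide).
#' @return list with `contig` (named character), `truth` (data.frame of
#'   planted features, forward-strand 0-based half-open coordinates),
#'   `segments` (ground-truth [tr_segment()] list), `seeds` (list of V/J/C
#'   protein and D nucleotide seed sets for the annotator), `v_regions`
#'   (planted IMGT-region nt per V id), `subgroup_truth` (named integer),
#'   and the blueprint.
#' @export
simulate_locus <- function(blueprint, out_prefix = NULL) {
  stopifnot(inherits(blueprint, "locus_blueprint"))
  bp <- blueprint
  with_seed(bp$seed, simulate_locus_impl(bp, out_prefix))
}

simulate_locus_impl <- function(bp, out_prefix) {
  locus <- bp$locus
  ## subgroup plan: founders + member assignment (round-robin)
  founders <- replicate(bp$v_subgroups, make_v_region())
  sg_of <- rep(seq_len(bp$v_subgroups), length.out = bp$n_v)
  sg_of <- sort(sg_of)
  ## subtype + leader window per subgroup
  sg_subtype <- if (locus == "TRAD") {
    c("TRDV", rep("TRAV", max(0, bp$v_subgroups - 1L)))[seq_len(bp$v_subgroups)]
  } else rep(paste0(sub("TRAD", "TRA", locus), "V"), bp$v_subgroups)
  lesions <- rep("none", bp$n_v)
  if (!is.null(bp$lesion_counts)) {
    pool <- sample.int(bp$n_v)
    k <- 0L
    for (nm in names(bp$lesion_counts)) {
      cnt <- bp$lesion_counts[[nm]]
      if (cnt > 0) { lesions[pool[(k + 1L):(k + cnt)]] <- nm; k <- k + cnt }
    }
  }
  ## D cores
  d_cores <- if (bp$n_d > 0) {
    if (!is.null(bp$d_cores)) rep(bp$d_cores, length.out = bp$n_d)
    else replicate(bp$n_d, random_dna(sample(10:16, 1)))
  } else character(0)

  contig <- random_dna(sample(300:600, 1))
  truth <- list(); segments <- list()
  v_regions <- character(0); subgroup_truth <- integer(0)
  seeds_v <- character(0); seeds_j <- character(0); seeds_c <- character(0)
  j_info <- list()

  place <- function(cassette_seq, strand) {
    ## append gap + cassette (revcomp when on "-"), return cassette offset
    gap <- random_dna(sample(300:800, 1))
    piece <- if (strand == "-") revcomp(cassette_seq) else cassette_seq
    off <- nchar(contig) + nchar(gap)
    contig <<- paste0(contig, gap, piece)
    off
  }
  ## map a local [s,e) in cassette coords to forward contig coords
  loc2fwd <- function(off, cas_len, s, e, strand) {
    if (strand == "+") c(off + s, off + e) else c(off + cas_len - e, off + cas_len - s)
  }

  add_v <- function(i) {
    sg <- sg_of[i]
    subtype <- sg_subtype[sg]
    region <- if (sum(sg_of == sg) == 1) founders[sg] else
      mutate_v_region(founders[sg], bp$within_identity)
    leader_len <- if (subtype == "TRDV") sample(c(64L, 67L), 1)
      else if (subtype == "TRAV") sample(40:43, 1)
      else sample(bp$leader_lens, 1)
    cas <- make_v_cassette(region, leader_len, lesions[i])
    off <- place(cas$seq, bp$v_strand)
    id <- sprintf("V%03d", i)
    exr <- list()
    if (!is.null(cas$feats$leader)) {
      le <- loc2fwd(off, nchar(cas$seq), cas$feats$leader[1], cas$feats$leader[2], bp$v_strand)
      exr$leader <- le
    }
    ce <- loc2fwd(off, nchar(cas$seq), cas$feats$coding[1], cas$feats$coding[2], bp$v_strand)
    exons <- data.frame(
      start = c(if (!is.null(exr$leader)) exr$leader[1], ce[1]),
      end = c(if (!is.null(exr$leader)) exr$leader[2], ce[2]),
      role = c(if (!is.null(exr$leader)) "leader", "coding"),
      stringsAsFactors = FALSE)
    seg <- tr_segment(contig_id = "sim", locus = locus, segment_type = "V",
                      chain_subtype = subtype, strand = bp$v_strand,
                      exons = exons, functionality = cas$expected, name = id,
                      subgroup = sg)
    segments[[id]] <<- seg
    truth[[id]] <<- data.frame(
      id = id, segment_type = "V", chain_subtype = subtype, subgroup = sg,
      strand = bp$v_strand, start = min(exons$start), end = max(exons$end),
      coding_start = min(ce), coding_end = max(ce),
      functionality = cas$expected, lesion = cas$lesion,
      leader_len = cas$leader_len, stringsAsFactors = FALSE)
    if (cas$expected %in% c("functional", "ORF")) {
      v_regions[[id]] <<- region
      subgroup_truth[[id]] <<- sg
    }
  }

  add_j <- function(i, variant = NULL) {
    jg <- make_j_gene(variant)
    off <- place(jg$seq, "+")
    id <- sprintf("J%02d", i)
    ce <- c(off + jg$coding_local[1], off + jg$coding_local[2])
    seg <- tr_segment(contig_id = "sim", locus = locus, segment_type = "J",
                      chain_subtype = paste0(sub("TRAD", "TRA", locus), "J"),
                      strand = "+",
                      exons = data.frame(start = ce[1], end = ce[2],
                                         role = "coding", stringsAsFactors = FALSE),
                      functionality = "functional", name = id)
    segments[[id]] <<- seg
    truth[[id]] <<- data.frame(
      id = id, segment_type = "J",
      chain_subtype = paste0(sub("TRAD", "TRA", locus), "J"),
      subgroup = NA_integer_, strand = "+", start = ce[1], end = ce[2],
      coding_start = ce[1], coding_end = ce[2], functionality = "functional",
      lesion = "none", leader_len = NA_integer_, stringsAsFactors = FALSE)
    j_info[[id]] <<- list(nt = jg$nt, aa = jg$aa,
                          phe118_codon_index = jg$phe118_codon_index)
    seeds_j[[id]] <<- jg$aa
  }

  add_d <- function(i) {
    dg <- make_d_gene(d_cores[i], bp$d_spacer3)
    off <- place(dg$seq, "+")
    id <- sprintf("D%02d", i)
    ce <- c(off + dg$coding_local[1], off + dg$coding_local[2])
    seg <- tr_segment(contig_id = "sim", locus = locus, segment_type = "D",
                      chain_subtype = paste0(sub("TRAD", "TRD", sub("TRB", "TRB", locus)), "D"),
                      strand = "+",
                      exons = data.frame(start = ce[1], end = ce[2],
                                         role = "coding", stringsAsFactors = FALSE),
                      functionality = "functional", name = id)
    segments[[id]] <<- seg
    truth[[id]] <<- data.frame(
      id = id, segment_type = "D", chain_subtype = seg$chain_subtype,
      subgroup = NA_integer_, strand = "+", start = ce[1], end = ce[2],
      coding_start = ce[1], coding_end = ce[2], functionality = "functional",
      lesion = "none", leader_len = NA_integer_, stringsAsFactors = FALSE)
  }

  add_c <- function(i) {
    cg <- make_c_gene()
    off <- place(cg$nt, "+")
    id <- sprintf("C%01d", i)
    ce <- c(off, off + nchar(cg$nt))
    seg <- tr_segment(contig_id = "sim", locus = locus, segment_type = "C",
                      chain_subtype = paste0(sub("TRAD", "TRA", locus), "C"),
                      strand = "+",
                      exons = data.frame(start = ce[1], end = ce[2],
                                         role = "constant_exon",
                                         stringsAsFactors = FALSE),
                      functionality = "functional", name = id)
    segments[[id]] <<- seg
    truth[[id]] <<- data.frame(
      id = id, segment_type = "C", chain_subtype = seg$chain_subtype,
      subgroup = NA_integer_, strand = "+", start = ce[1], end = ce[2],
      coding_start = ce[1], coding_end = ce[2], functionality = "functional",
      lesion = "none", leader_len = NA_integer_, stringsAsFactors = FALSE)
    seeds_c[[id]] <<- cg$aa
  }

  ## locus layout: D/J/C block then V block (V possibly on "-")
  for (i in seq_len(bp$n_d)) add_d(i)
  for (i in seq_len(bp$n_j)) add_j(i)
  for (i in seq_len(bp$n_c)) add_c(i)
  for (i in seq_len(bp$n_v)) add_v(i)
  contig <- paste0(contig, random_dna(sample(300:600, 1)))

  ## homology-unit pair: tandem block + mutated copy
  if (!is.null(bp$duplication)) {
    len <- bp$duplication$length
    idn <- bp$duplication$identity
    block <- random_dna(len)
    ch <- strsplit(block, "")[[1]]
    nmut <- round((1 - idn / 100) * len)
    pos <- sample.int(len, nmut)
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA_BASES, b), 1), "")
    contig <- paste0(contig, block, paste(ch, collapse = ""),
                     random_dna(200))
  }

  ## V founders as protein seeds (the annotator's "previously known" set)
  for (sg in seq_len(bp$v_subgroups)) {
    seeds_v[[paste0("Vfounder", sg)]] <- translate_nt(founders[sg])
  }

  contig_v <- setNames(contig, "sim")
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  res <- list(contig = contig_v, truth = truth_df, segments = segments,
              seeds = list(V = unlist(seeds_v), J = unlist(seeds_j),
                           C = unlist(seeds_c), D = d_cores),
              v_regions = v_regions, subgroup_truth = subgroup_truth,
              j_info = j_info, blueprint = bp)
  if (!is.null(out_prefix)) {
    write_fasta(contig_v, paste0(out_prefix, ".fasta"))
    write_gff3(segments, contig_v, paste0(out_prefix, ".gff3"))
    for (ty in c("V", "J", "C", "D")) {
      if (length(res$seeds[[ty]]) > 0) {
        write_fasta(res$seeds[[ty]],
                    paste0(out_prefix, "_seeds_", tolower(ty), ".fasta"))
      }
    }
  }
  res
}

## ---- repertoire simulation ------------------------------------------------

#' Build a compact germline database for repertoire simulation
#'
#' V entries are IMGT-region-like sequences ending 6 nt past CYS104 (so the
#' CYS104 codon is the 3rd-from-last); J entries carry their F-G-X-G
#' (PHE118) position. Subgroup structure mirrors [simulate_locus()]:
#' founders plus mutated members.
#'
#' @param chain `"TRA"`, `"TRB"`, `"TRD"` or `"TRG"`.
#' @param n_subgroups,members_per subgroup plan for V.
#' @param n_j number of J genes.
#' @param n_d number of D genes (default: 1 for TRB, 4 for TRD, else 0).
#' @param within_identity member-to-founder identity.
#' @param seed RNG seed.
#' @return list of class `germline_db` with elements `chain`, `V`,
#'   `v_subgroup`, `J`, `j_phe_nt_end`, `D`, `const`.
#' @export
simulate_germline_db <- function(chain = "TRA", n_subgroups = 3L,
                                 members_per = 2L, n_j = 5L, n_d = NULL,
                                 within_identity = 0.94, seed = 1L) {
  if (is.null(n_d)) n_d <- switch(chain, TRB = 1L, TRD = 4L, 0L)
  with_seed(seed, {
    V <- character(0); v_subgroup <- integer(0)
    for (sg in seq_len(n_subgroups)) {
      founder <- make_v_region()
      for (m in seq_len(members_per)) {
        id <- sprintf("%sV%d-%d", chain, sg, m)
        V[[id]] <- if (m == 1) founder else mutate_v_region(founder, within_identity)
        v_subgroup[[id]] <- sg
      }
    }
    J <- character(0); j_phe <- integer(0)
    for (j in seq_len(n_j)) {
      jg <- make_j_gene()
      id <- sprintf("%sJ%d", chain, j)
      J[[id]] <- jg$nt
      j_phe[[id]] <- 3L * (jg$phe118_codon_index + 1L)  # nt end of PHE codon
    }
    D <- if (n_d > 0) {
      setNames(if (chain == "TRB") rep("GGGACAGGGGGC", n_d)
               else replicate(n_d, random_dna(sample(10:16, 1))),
               sprintf("%sD%d", chain, seq_len(n_d)))
    } else character(0)
    structure(list(chain = chain, V = V, v_subgroup = v_subgroup, J = J,
                   j_phe_nt_end = j_phe, D = D, const = random_dna(80)),
              class = "germline_db")
  })
}

#' Simulate a recombined repertoire as paired-end reads
#'
#' Each read pair derives from one V-(D)n-J junction: uniform V and J
#' choice, chain-specific D usage (up to `max_d` segments for TRD),
#' geometric exonucleolytic trimming, uniform-base N additions, and
#' per-base sequencing errors. TRA defaults emulate minimal TRAJ trimming;
#' TRD defaults emulate heavy junctional diversification. Junctions are
#' resampled to be productive (in frame, stop-free CDR3) unless
#' `productive_only = FALSE`.
#'
#' @param db a `germline_db` from [simulate_germline_db()].
#' @param n_reads number of read pairs.
#' @param read_length read length (nt).
#' @param v_trim_mean,j_trim_mean geometric trim means (nt; capped at 6 so
#'   the CYS104/PHE118 anchors survive). Defaults: 0.5 for TRA, 1.5
#'   otherwise.
#' @param n_mean mean N-addition length per junction boundary (geometric;
#'   default 1 for TRA, 2 for TRB/TRG, 4 for TRD).
#' @param max_d maximum D segments per junction (default 4 for TRD, 1 for
#'   TRB, 0 otherwise).
#' @param error_rate per-base substitution error rate.
#' @param overlap_range range of R1/R2 overlaps (compatible with
#'   [merge_read_pair()] defaults).
#' @param productive_only resample out-of-frame or stopped junctions.
#' @param seed RNG seed.
#' @return list with `r1`, `r2` (data.frames `id`, `seq`, `qual`) and
#'   `truth` (one row per pair: chosen genes, trims, N insertions, CDR3).
#' @export
simulate_repertoire_reads <- function(db, n_reads = 100L, read_length = 120L,
                                      v_trim_mean = NULL, j_trim_mean = NULL,
                                      n_mean = NULL, max_d = NULL,
                                      error_rate = 0, overlap_range = c(40L, 80L),
                                      productive_only = TRUE, seed = 1L) {
  stopifnot(inherits(db, "germline_db"))
  chain <- db$chain
  if (is.null(v_trim_mean)) v_trim_mean <- if (chain == "TRA") 0.5 else 1.5
  if (is.null(j_trim_mean)) j_trim_mean <- if (chain == "TRA") 0.5 else 1.5
  if (is.null(n_mean)) n_mean <- switch(chain, TRA = 1, TRD = 2.5, 2)
  if (is.null(max_d)) max_d <- switch(chain, TRD = 4L, TRB = 1L, 0L)
  if (max_d > 0 && length(db$D) == 0) stop("db has no D segments", call. = FALSE)
  with_seed(seed, {
    rows <- list(); r1 <- list(); r2 <- list()
    rg <- function(mean, cap) min(rgeom(1, 1 / (1 + mean)), cap)
    for (i in seq_len(n_reads)) {
      for (attempt in 1:100) {
        vi <- sample(names(db$V), 1); ji <- sample(names(db$J), 1)
        vseq <- db$V[[vi]]; jseq <- db$J[[ji]]
        vlen <- nchar(vseq)
        v_trim <- rg(v_trim_mean, 6L); j_trim <- rg(j_trim_mean, 6L)
        nd <- if (max_d > 0) sample.int(max_d + 1L, 1) - 1L else 0L
        if (chain == "TRB") nd <- max_d                    # single D, always used
        dis <- if (nd > 0) sample(names(db$D), nd, replace = TRUE) else character(0)
        parts <- character(0); n_ins <- character(0)
        for (d in dis) {
          dcore <- db$D[[d]]
          dl <- min(rg(1, 3L), max(0, nchar(dcore) - 4L))
          dr <- min(rg(1, 3L), max(0, nchar(dcore) - 4L - dl))
          nseq <- random_dna(rg(n_mean, 10L))
          n_ins <- c(n_ins, nseq)
          parts <- c(parts, paste0(nseq, substr(dcore, dl + 1L, nchar(dcore) - dr)))
        }
        n_last <- random_dna(rg(n_mean, 10L))
        cdr3 <- paste0(substr(vseq, vlen - 8L, vlen - v_trim),
                       paste(parts, collapse = ""), n_last,
                       substr(jseq, j_trim + 1L, db$j_phe_nt_end[[ji]]))
        ok <- nchar(cdr3) %% 3L == 0L &&
          !grepl("*", translate_nt(cdr3), fixed = TRUE)
        if (ok || !productive_only) break
      }
      transcript <- paste0(substr(vseq, 1, vlen - 9L), cdr3,
                           substr(jseq, db$j_phe_nt_end[[ji]] + 1L, nchar(jseq)),
                           db$const)
      ov <- sample(overlap_range[1]:overlap_range[2], 1)
      frag <- 2L * read_length - ov
      tl <- nchar(transcript)
      pad <- 0L
      if (tl < frag) {
        pad <- frag - tl
        transcript <- paste0(random_dna(pad), transcript)
        tl <- frag
      }
      center <- pad + (vlen - 9L) + nchar(cdr3) %/% 2L   # middle of the CDR3
      fs <- max(0L, min(tl - frag, center - frag %/% 2L))
      fragment <- substr(transcript, fs + 1L, fs + frag)
      seq1 <- substr(fragment, 1, read_length)
      seq2 <- revcomp(substr(fragment, frag - read_length + 1L, frag))
      if (error_rate > 0) {
        seq1 <- add_errors(seq1, error_rate)
        seq2 <- add_errors(seq2, error_rate)
      }
      id <- sprintf("read%05d", i)
      r1[[i]] <- data.frame(id = id, seq = seq1,
                            qual = strrep("I", read_length), stringsAsFactors = FALSE)
      r2[[i]] <- data.frame(id = id, seq = seq2,
                            qual = strrep("I", read_length), stringsAsFactors = FALSE)
      rows[[i]] <- data.frame(
        id = id, chain = chain, v_gene = vi, v_subgroup = db$v_subgroup[[vi]],
        j_gene = ji, n_d = length(dis),
        d_genes = paste(dis, collapse = ","), v_trim = v_trim, j_trim = j_trim,
        n_insertions = paste(c(n_ins, n_last), collapse = ","),
        cdr3_nt = cdr3, cdr3_aa = translate_nt(cdr3),
        productive = nchar(cdr3) %% 3L == 0L, stringsAsFactors = FALSE)
    }
    list(r1 = do.call(rbind, r1), r2 = do.call(rbind, r2),
         truth = do.call(rbind, rows), db = db)
  })
}

add_errors <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  paste(ch, collapse = "")
}
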