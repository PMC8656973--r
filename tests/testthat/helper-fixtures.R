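## Shared fixtures, built once per test run. Everything is generated in
## code under fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

## Small lesion-free TRB-like locus + its annotation.
fix_trb <- function() memo("trb", {
  bp <- locus_blueprint("trb-like", n_v = 4, v_subgroups = 2, n_j = 2,
                        n_c = 1, seed = 7)
  sim <- simulate_locus(bp)
  ann <- annotate_locus(sim$contig, sim$seeds, locus = "TRB")
  list(sim = sim, ann = ann)
})

## TRAD-like locus (minus-strand V genes) with one of each lesion.
fix_trad_lesions <- function() memo("trad_lesions", {
  bp <- locus_blueprint("trad-like", n_v = 6, v_subgroups = 3, n_j = 3,
                        n_d = 2, n_c = 1,
                        lesion_counts = c(internal_stop = 1, splice_break = 1,
                                          leader_deletion = 1, trunc3 = 1,
                                          frameshift3 = 1),
                        seed = 11)
  sim <- simulate_locus(bp)
  ann <- annotate_locus(sim$contig, sim$seeds, locus = "TRAD")
  list(sim = sim, ann = ann)
})

## TRA germline db + error-free repertoire + clonotype extraction.
fix_tra_rep <- function() memo("tra_rep", {
  db <- simulate_germline_db("TRA", n_subgroups = 3, members_per = 2,
                             n_j = 4, seed = 5)
  rep <- simulate_repertoire_reads(db, n_reads = 30, seed = 9)
  res <- extract_clonotypes(rep$r1, rep$r2, db)
  list(db = db, rep = rep, res = res)
})

## Coding-exon truth vs annotation comparison table.
coding_comparison <- function(sim, ann) {
  segs <- ann$segments
  rec <- do.call(rbind, lapply(segs, function(s) {
    ce <- s$exons[s$exons$role %in% c("coding", "constant_exon"), , drop = FALSE]
    data.frame(type = s$segment_type, start = min(ce$start), end = max(ce$end),
               functionality = s$functionality, subtype = s$chain_subtype,
               subgroup = s$subgroup, stringsAsFactors = FALSE)
  }))
  rec <- rec[order(rec$start), , drop = FALSE]
  tr <- sim$truth[order(sim$truth$coding_start), , drop = FALSE]
  list(truth = tr, rec = rec)
}

with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  expr
}

## Random DNA string helper for tests.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

## Mutate k positions of a DNA string.
mut_dna <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  p <- sample(length(ch), k)
  for (i in p) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

## Exhaustive minimum-evolution oracle: enumerate all unrooted topologies
## (phangorn), fit branch lengths by ordinary least squares on the
## path-indicator system, return the minimum-total-length tree.
brute_force_me <- function(d) {
  labs <- rownames(d)
  n <- length(labs)
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  best <- NULL
  for (ti in seq_along(topos)) {
    tp <- topos[[ti]]
    tp$edge.length <- rep(1, nrow(tp$edge))
    tips <- seq_len(n)
    pairs <- t(combn(tips, 2))
    A <- matrix(0, nrow(pairs), nrow(tp$edge))
    for (r in seq_len(nrow(pairs))) {
      ## edges on the path between the two tips
      p1 <- ape::nodepath(tp, pairs[r, 1], pairs[r, 2])
      for (k in seq_len(length(p1) - 1)) {
        e <- which((tp$edge[, 1] == p1[k] & tp$edge[, 2] == p1[k + 1]) |
                     (tp$edge[, 2] == p1[k] & tp$edge[, 1] == p1[k + 1]))
        A[r, e] <- 1
      }
    }
    b <- d[cbind(match(tp$tip.label[pairs[, 1]], labs),
                 match(tp$tip.label[pairs[, 2]], labs))]
    fit <- qr.coef(qr(A), b)
    fit[is.na(fit)] <- 0
    resid <- sum((A %*% fit - b)^2)
    tot <- sum(fit)
    if (is.null(best) || resid < best$resid - 1e-9 ||
        (abs(resid - best$resid) < 1e-9 && tot < best$tot)) {
      tp$edge.length <- pmax(fit, 0)
      best <- list(tree = tp, tot = tot, resid = resid)
    }
  }
  best$tree
}
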