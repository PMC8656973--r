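## p-distance with pairwise deletion, Saitou-Nei neighbor joining with
## deterministic tie-breaks, and column-resampling bootstrap support.
## Trees are returned as ape "phylo" objects (built via newick text).

#' Pairwise p-distances with pairwise deletion
#'
#' The p-distance is the proportion of differing sites between two aligned
#' sequences. For each pair, sites with a gap or N in either sequence are
#' removed before counting (the pairwise-deletion option).
#'
#' @param aln named character vector of equal-length aligned sequences, or
#'   a character matrix (rows = sequences).
#' @return symmetric numeric matrix of distances in `[0, 1]`.
#' @export
pairwise_p_distance <- function(aln) {
  if (is.matrix(aln)) {
    m <- aln
  } else {
    stopifnot(length(unique(nchar(aln))) == 1)
    m <- do.call(rbind, strsplit(toupper(aln), ""))
    rownames(m) <- names(aln)
  }
  n <- nrow(m)
  stopifnot(n >= 2)
  valid <- matrix(m %in% DNA_BASES, nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    keep <- valid[i, ] & valid[j, ]
    if (!any(keep)) {
      stop(sprintf("no retained sites for pair (%s, %s)",
                   rownames(m)[i], rownames(m)[j]), call. = FALSE)
    }
    d[i, j] <- d[j, i] <- mean(m[i, keep] != m[j, keep])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on the Q criterion. Ties in Q are
#' broken deterministically by the (sorted) label pair. Negative branch
#' lengths are clamped to zero and flagged in the `negative_clamped`
#' attribute.
#'
#' @param d symmetric distance matrix with labelled rows/columns, n >= 2.
#' @return an unrooted `phylo` object (class from ape).
#' @export
nj_tree <- function(d) {
  labels <- rownames(d)
  n <- length(labels)
  stopifnot(n >= 2, identical(labels, colnames(d)),
            max(abs(d - t(d))) < 1e-12, all(diag(d) == 0))
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  fmt <- function(x) sprintf("%.12g", x)
  nodes <- labels                      # newick fragment per active node
  D <- unname(d)
  while (length(nodes) > 3) {
    N <- length(nodes)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- NULL
    for (i in 1:(N - 1)) for (j in (i + 1):N) {
      key <- sort(c(nodes[i], nodes[j]))
      if (is.null(best) || Q[i, j] < best$q - 1e-12 ||
          (abs(Q[i, j] - best$q) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, q = Q[i, j], key = key)
      }
    }
    i <- best$i; j <- best$j
    li <- bl(D[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2)))
    lj <- bl(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))))
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li), nodes[j], fmt(lj))
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    nodes <- c(nodes[keep], new_node)
    D <- D2
  }
  newick <- if (length(nodes) == 2) {
    sprintf("(%s:%s,%s:%s);", nodes[1], fmt(bl(D[1, 2] / 2)),
            nodes[2], fmt(bl(D[1, 2] / 2)))
  } else {
    l1 <- bl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
    l2 <- bl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
    l3 <- bl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt(l1), nodes[2], fmt(l2),
            nodes[3], fmt(l3))
  }
  tree <- ape::read.tree(text = newick)
  attr(tree, "negative_clamped") <- clamped
  tree
}

## Non-trivial bipartitions of an unrooted tree, canonicalized to the side
## not containing the alphabetically first tip; each as a sorted,
## comma-joined label string.
tree_splits <- function(tree) {
  nt <- length(tree$tip.label)
  first <- sort(tree$tip.label)[1]
  tr <- stats::reorder(tree, "postorder")
  desc <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  root <- nt + 1L
  internal <- setdiff(unique(tr$edge[, 1]), root)
  splits <- unique(vapply(internal, function(nd) {
    side <- desc[[nd]]
    if (first %in% side) side <- setdiff(tr$tip.label, side)
    paste(sort(side), collapse = ",")
  }, character(1)))
  sizes <- lengths(strsplit(splits, ","))
  splits[sizes >= 2 & sizes <= nt - 2]
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal bipartition of the full-data
#' tree the percentage of replicates containing it.
#'
#' @param aln named character vector of aligned sequences (see
#'   [pairwise_p_distance()]).
#' @param replicates number of bootstrap replicates (the published analyses
#'   this mirrors used 10,000; desk-scale default 1000).
#' @param seed RNG seed for reproducible resampling.
#' @return the full-data `phylo` tree with `node.label` set to the support
#'   percentages (root label empty) and a `supports` attribute (named by
#'   bipartition).
#' @export
bootstrap_support <- function(aln, replicates = 1000L, seed = 1L) {
  stopifnot(replicates >= 1)
  cols <- nchar(aln[[1]])
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  full <- nj_tree(pairwise_p_distance(m))
  splits <- tree_splits(full)
  counts <- setNames(numeric(length(splits)), splits)
  done <- 0L
  with_seed(seed, {
    for (b in seq_len(replicates)) {
      idx <- sample.int(cols, cols, replace = TRUE)
      tr <- tryCatch(nj_tree(pairwise_p_distance(m[, idx, drop = FALSE])),
                     error = function(e) NULL)
      if (is.null(tr)) next
      done <- done + 1L
      hit <- tree_splits(tr)
      counts[splits %in% hit] <- counts[splits %in% hit] + 1
    }
  })
  supports <- if (done > 0) 100 * counts / done else counts
  ## attach as node labels (ape convention)
  nt <- length(full$tip.label)
  tr2 <- stats::reorder(full, "postorder")
  desc <- vector("list", nt + tr2$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tr2$tip.label[i]
  for (e in seq_len(nrow(tr2$edge))) {
    desc[[tr2$edge[e, 1]]] <- c(desc[[tr2$edge[e, 1]]], desc[[tr2$edge[e, 2]]])
  }
  first <- sort(full$tip.label)[1]
  labs <- vapply((nt + 1L):(nt + full$Nnode), function(nd) {
    side <- desc[[nd]]
    if (first %in% side) side <- setdiff(full$tip.label, side)
    key <- paste(sort(side), collapse = ",")
    if (key %in% names(supports)) sprintf("%g", supports[[key]]) else ""
  }, character(1))
  full$node.label <- labs
  attr(full, "supports") <- supports
  attr(full, "replicates_used") <- done
  full
}

#' Center-star multiple alignment
#'
#' A simple self-contained aligner for sets of homologous gene regions:
#' every sequence is globally aligned to a center sequence (the longest)
#' and the pairwise gap patterns are merged into one set of columns.
#' Adequate for the closely related V-region sets this package compares;
#' it is not a progressive profile aligner.
#'
#' @param seqs named character vector of DNA sequences.
#' @return named character vector of gapped sequences of equal length.
#' @export
align_sequences <- function(seqs) {
  stopifnot(length(seqs) >= 2)
  center_i <- which.max(nchar(seqs))
  center <- seqs[[center_i]]
  m <- nchar(center)
  others <- setdiff(seq_along(seqs), center_i)
  ## per-alignment parse: gaps inserted after center residue i (0..m) and
  ## the subject text in each slot
  parsed <- lapply(others, function(k) {
    aln <- Biostrings::pairwiseAlignment(center, seqs[[k]], type = "global",
                                         substitutionMatrix = dna_submat(),
                                         gapOpening = 10, gapExtension = 0.5)
    pc <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ins <- vector("list", m + 1L)      # subject chars inserted after residue i
    match_ch <- character(m)           # subject char aligned to residue i
    ci <- 0L
    for (col in seq_along(pc)) {
      if (pc[col] == "-") {
        ins[[ci + 1L]] <- c(ins[[ci + 1L]], ps[col])
      } else {
        ci <- ci + 1L
        match_ch[ci] <- ps[col]
      }
    }
    list(ins = ins, match_ch = match_ch)
  })
  gmax <- vapply(seq_len(m + 1L), function(i) {
    max(c(0L, vapply(parsed, function(p) length(p$ins[[i]]), integer(1))))
  }, integer(1))
  build <- function(ins, match_ch) {
    out <- character(0)
    for (i in seq_len(m + 1L)) {
      block <- ins[[i]]
      out <- c(out, block, rep("-", gmax[i] - length(block)))
      if (i <= m) out <- c(out, match_ch[i])
    }
    paste(out, collapse = "")
  }
  res <- character(length(seqs))
  ctr_ch <- strsplit(center, "")[[1]]
  res[center_i] <- build(vector("list", m + 1L), ctr_ch)
  for (t in seq_along(others)) {
    res[others[t]] <- build(parsed[[t]]$ins, parsed[[t]]$match_ch)
  }
  setNames(res, names(seqs))
}

#' Write a tree in newick format
#' @param tree a `phylo` object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
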