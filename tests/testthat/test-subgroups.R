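test_that("IMGT trimming recovers the planted comparison region exactly", {
  set.seed(61)
  for (k in 1:5) {
    region <- trlocus:::make_v_region()
    ## embed in a longer coding sequence with a frame offset and 3' tail
    off <- sample(0:2, 1)
    padded <- paste0(strrep("C", off), region)
    reg <- imgt_trim(padded, gene_id = paste0("g", k))
    expect_equal(reg$nt_sequence, region)
    expect_equal(reg$cys23_codon_index, 22L)
    expect_equal(reg$cys104_codon_index, 103L)
    ## length arithmetic: (cys104 + 1) codons plus 6 nt
    expect_equal(nchar(reg$nt_sequence), (reg$cys104_codon_index + 1L) * 3L + 6L)
  }
})

test_that("anchor failures name the missing anchor", {
  ## polyalanine has no cysteine anywhere
  expect_error(imgt_trim(strrep("GCT", 120)), "CYS23")
  ## TAAT repeats place a stop codon in every reading frame
  expect_error(imgt_trim(strrep("TAAT", 90)), "stop-free")
})

test_that("pairwise identity is symmetric, bounded, and 100 iff identical", {
  set.seed(62)
  a <- rand_dna(300)
  expect_equal(pairwise_identity(a, a), 100)
  b <- mut_dna(a, 30)
  ab <- pairwise_identity(a, b)
  ba <- pairwise_identity(b, a)
  expect_identical(ab, ba)
  expect_lt(ab, 100)
  expect_gt(ab, 80)
  ## denominator is the longer sequence: a prefix of half the length can
  ## never exceed 50%
  half <- substr(a, 1, 150)
  expect_lte(pairwise_identity(a, half), 50)
  expect_error(pairwise_identity("", a), "empty")
})

test_that("identity matrix matches a brute-force pair loop", {
  set.seed(63)
  seqs <- c(g1 = rand_dna(240), g2 = rand_dna(240), g3 = rand_dna(250))
  m <- build_identity_matrix(seqs)
  expect_equal(dim(m), c(3, 3))
  expect_equal(diag(m), c(g1 = 100, g2 = 100, g3 = 100))
  expect_equal(m, t(m))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(m[i, j], pairwise_identity(seqs[[i]], seqs[[j]]))
  }
  m1 <- build_identity_matrix(seqs[1])
  expect_equal(unname(m1), matrix(100))
})

test_that("subgroup clustering is single-linkage transitive closure", {
  m <- matrix(c(100, 80, 60,
                80, 100, 80,
                60, 80, 100), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- cluster_subgroups(m, threshold = 75)
  expect_equal(length(unique(cl$mapping)), 1)   # chained A-B-C
  ## inclusive threshold: exactly 75.0 joins
  m2 <- m; m2["A", "B"] <- m2["B", "A"] <- 75; m2["B", "C"] <- m2["C", "B"] <- 60
  cl2 <- cluster_subgroups(m2, threshold = 75)
  expect_equal(unname(cl2$mapping["A"]), unname(cl2$mapping["B"]))
  expect_false(cl2$mapping["C"] == cl2$mapping["A"])
  ## complete linkage refuses the chain
  cl3 <- cluster_subgroups(m, threshold = 75, linkage = "complete")
  expect_gt(length(unique(cl3$mapping)), 1)
})

test_that("cluster count is monotone non-increasing as threshold drops", {
  set.seed(64)
  founders <- replicate(3, trlocus:::make_v_region())
  seqs <- unlist(lapply(1:3, function(sg) {
    setNames(lapply(1:3, function(m) trlocus:::mutate_v_region(founders[sg], 0.93)),
             paste0("sg", sg, "_", 1:3))
  }))
  m <- build_identity_matrix(seqs)
  counts <- vapply(c(95, 85, 75, 65, 40), function(th) {
    length(unique(cluster_subgroups(m, threshold = th)$mapping))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted subgroup partitions are recovered exactly", {
  set.seed(65)
  founders <- replicate(4, trlocus:::make_v_region())
  truth <- integer(0); seqs <- character(0)
  for (sg in 1:4) for (memb in 1:3) {
    id <- sprintf("V%d_%d", sg, memb)
    seqs[[id]] <- trlocus:::mutate_v_region(founders[sg], 0.93)
    truth[[id]] <- sg
  }
  m <- build_identity_matrix(seqs)
  ## within-subgroup pairs >= 85, between <= 60 under these settings
  for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
    if (i < j) {
      if (truth[i] == truth[j]) expect_gte(m[i, j], 85)
      else expect_lte(m[i, j], 60)
    }
  }
  cl <- cluster_subgroups(m, threshold = 75)
  ## same partition (up to label renumbering)
  expect_equal(length(unique(cl$mapping)), 4)
  for (sg in 1:4) {
    ids <- names(truth)[truth == sg]
    expect_equal(length(unique(cl$mapping[ids])), 1)
  }
})

test_that("J motif scan classifies canonical and variant motifs", {
  j1 <- scan_j_motif("SAFGKGTKLT", is_aa = TRUE)
  expect_true(j1$canonical)
  expect_equal(j1$motif_aa, "FGKG")
  expect_true(is.na(j1$variant_class))

  j2 <- scan_j_motif("SAFAEGTKLT", is_aa = TRUE)
  expect_false(j2$canonical)
  expect_equal(j2$variant_class, "FAXG")

  ## the salmon-type FGKA end masks to the FGXA family
  j3 <- scan_j_motif("SNDSAFGKATKLT", is_aa = TRUE)
  expect_false(j3$canonical)
  expect_equal(j3$variant_class, "FGXA")

  ## PHE118 is the motif's first residue
  expect_equal(j1$phe118_codon_index, 2L)

  ## nucleotide input: frame resolved automatically
  jg <- with_seed_helper(66, trlocus:::make_j_gene())
  jn <- scan_j_motif(jg$nt)
  expect_true(jn$canonical)
  expect_equal(jn$phe118_codon_index, jg$phe118_codon_index)
  expect_equal(jn$frame, 0L)

  ## nothing motif-like within edit distance 2
  expect_error(scan_j_motif("AAAAPPPPWWWW", is_aa = TRUE), "motif-failure")
})
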