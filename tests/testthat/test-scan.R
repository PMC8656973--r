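test_that("six-frame translation follows frame and strand conventions", {
  fr <- six_frame_translate(c(x = "ATGGCC"))
  expect_equal(unname(fr["+1"]), "MA")
  ## revcomp of TTACAT is ATGTAA -> start + stop sentinel
  fr2 <- six_frame_translate(c(x = "TTACAT"))
  expect_equal(unname(fr2["-1"]), "M*")
  ## trailing partial codons dropped: frame f covers floor((7-(f-1))/3) codons
  fr3 <- six_frame_translate(c(x = rand_dna(7)))
  expect_equal(unname(nchar(fr3[c("+1", "+2", "+3")])), c(2L, 2L, 1L))
  expect_error(six_frame_translate(c(x = "")), "empty")
})

test_that("seed_search finds an identical planted protein at 100% identity", {
  set.seed(31)
  seed_aa <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60, TRUE),
                   collapse = "")
  nt <- vapply(strsplit(seed_aa, "")[[1]], function(a) {
    cods <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
    sample(cods, 1)
  }, character(1))
  insert <- paste(nt, collapse = "")
  contig <- c(ctg = paste0(rand_dna(301), insert, rand_dna(200)))
  hits <- seed_search(contig, c(s1 = seed_aa))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$percent_identity, 100)
  expect_equal(hits$start, 301)
  expect_equal(hits$end, 301 + 180)
  expect_equal(hits$strand, "+")
})

test_that("stringent search of random sequence yields no hits", {
  set.seed(32)
  contig <- c(r = rand_dna(30000))
  seeds <- c(a = paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 100,
                              TRUE), collapse = ""))
  hits <- seed_search(contig, seeds, min_identity = 101, min_score = 150)
  expect_equal(nrow(hits), 0)
})

test_that("search hits mirror exactly on the reverse complement", {
  fx <- fix_trb()
  contig <- fx$sim$contig
  rc <- setNames(revcomp(contig[[1]]), names(contig))
  h1 <- seed_search(contig, fx$sim$seeds$V, min_identity = 101, min_score = 150)
  h2 <- seed_search(rc, fx$sim$seeds$V, min_identity = 101, min_score = 150)
  L <- nchar(contig[[1]])
  mirrored <- data.frame(start = L - h2$end, end = L - h2$start,
                         strand = ifelse(h2$strand == "+", "-", "+"),
                         score = h2$score)
  mirrored <- mirrored[order(mirrored$start), ]
  h1o <- h1[order(h1$start), c("start", "end", "strand", "score")]
  expect_equal(h1o, mirrored, ignore_attr = TRUE)
})

test_that("iterative closure converges, is monotone and finds chained homologs", {
  fx <- fix_trb()
  cl <- iterative_closure(fx$sim$contig, fx$sim$seeds$V, min_identity = 101,
                          min_score = 150)
  ## seeds already match every planted gene: round 2 finds nothing new
  expect_equal(cl$rounds, 2L)
  direct <- seed_search(fx$sim$contig, fx$sim$seeds$V, min_identity = 101,
                        min_score = 150)
  expect_true(all(trlocus:::covered_by(direct, cl$hits)))

  ## empty contig set: one round, empty result
  cl0 <- iterative_closure(setNames(character(0), character(0)),
                           fx$sim$seeds$V)
  expect_equal(cl0$rounds, 1L)
  expect_equal(nrow(cl0$hits), 0)
  expect_error(iterative_closure(fx$sim$contig, character(0)), "empty seed")
})

test_that("closure reaches a gene detectable only through an intermediate", {
  ## controlled identity chain: seed S; planted A differs from S in 20
  ## codons; planted B differs from A in 15 further codons, so B is closer
  ## to A than to S. A threshold between score(S, B) and min(score(S, A),
  ## score(A, B)) makes B reachable only through A in round 2.
  set.seed(33)
  swap_codons <- function(nt, k, from = 45L, to = 95L) {
    pool <- setdiff(strsplit("ADEFGHIKLMNPQRSTV", "")[[1]], "")
    pos <- sample(from:to, k)
    for (ci in pos) {
      old <- substr(nt, ci * 3 - 2, ci * 3)
      repeat {
        new <- trlocus:::back_translate(sample(pool, 1))
        if (Biostrings::GENETIC_CODE[[new]] != Biostrings::GENETIC_CODE[[old]]) break
      }
      substr(nt, ci * 3 - 2, ci * 3) <- new
    }
    nt
  }
  s_nt <- trlocus:::make_v_region()
  a_nt <- swap_codons(s_nt, 20)
  b_nt <- swap_codons(a_nt, 15)
  contig <- c(ctg = paste0(rand_dna(400), a_nt, rand_dna(500), b_nt,
                           rand_dna(400)))
  seed <- c(s = trlocus:::translate_nt(s_nt))
  bl <- trlocus:::blosum62()
  sc <- function(p, q) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      trlocus:::translate_nt(p), trlocus:::translate_nt(q), type = "local",
      substitutionMatrix = bl, gapOpening = 11, gapExtension = 1))
  }
  s_a <- sc(s_nt, a_nt); s_b <- sc(s_nt, b_nt); a_b <- sc(a_nt, b_nt)
  expect_gt(min(s_a, a_b), s_b)          # the chain premise holds
  thr <- (s_b + min(s_a, a_b)) / 2
  strict <- seed_search(contig, seed, min_identity = 101, min_score = thr)
  expect_equal(nrow(strict), 1)          # only A directly
  cl <- iterative_closure(contig, seed, min_identity = 101, min_score = thr)
  expect_equal(nrow(cl$hits), 2)         # B reached through A
  expect_gte(cl$rounds, 2L)
})

test_that("homology units: exact tandem duplication found, random clean", {
  set.seed(34)
  X <- rand_dna(5000)
  contig <- paste0(rand_dna(2000), X, X, rand_dna(1500))
  hu <- find_homology_units(contig, min_length = 4000, min_identity = 96)
  expect_equal(nrow(hu), 1)
  expect_equal(hu$percent_identity, 100)
  expect_equal(hu$start1, 2000)
  expect_equal(hu$end1, 7000)
  expect_equal(hu$start2, 7000)
  expect_equal(hu$end2, 12000)
  expect_equal(hu$strand2, "+")

  ## mutated copy at ~96% identity still detected
  contig2 <- paste0(rand_dna(1000), X, mut_dna(X, 200), rand_dna(1000))
  hu2 <- find_homology_units(contig2, min_length = 4000, min_identity = 95)
  expect_equal(nrow(hu2), 1)
  expect_gt(hu2$percent_identity, 95)

  ## i.i.d. random contig: no units, and the self-diagonal is never reported
  r <- rand_dna(50000)
  expect_equal(nrow(find_homology_units(r, min_length = 4000,
                                        min_identity = 96)), 0)
  expect_error(find_homology_units(rand_dna(10), window = 16), "window")
})
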