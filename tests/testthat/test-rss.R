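test_that("a perfect planted 23-RSS is the top hit with zero mismatches", {
  set.seed(41)
  coding <- rand_dna(300)
  spacer <- rand_dna(23)
  contig <- paste0(rand_dna(100), coding, "CACAGTG", spacer, "ACAAAAACC",
                   rand_dna(100))
  hits <- detect_rss(contig, boundary = 400L, strand = "+",
                     side = "three_prime", expected_spacer = 23L)
  expect_gt(length(hits), 0)
  top <- hits[[1]]
  expect_equal(top$heptamer, "CACAGTG")
  expect_equal(top$nonamer, "ACAAAAACC")
  expect_equal(top$spacer_length, 23L)
  expect_equal(top$heptamer_mismatches, 0L)
  expect_equal(top$nonamer_mismatches, 0L)
  expect_equal(top$heptamer_offset, 400L)
  expect_equal(attr(top, "boundary"), 400L)
})

test_that("violating the CAC hard constraint suppresses the hit", {
  set.seed(42)
  contig <- paste0(rand_dna(200), "AACAGTG", rand_dna(23), "ACAAAAACC",
                   rand_dna(50))
  ## no other RSS-like signal in a short random flank
  hits <- detect_rss(contig, boundary = 200L, strand = "+",
                     side = "three_prime", expected_spacer = 23L, window = 5L)
  expect_length(hits, 0)
})

test_that("12-spacer RSS with nonamer mismatches is reported with its count", {
  set.seed(43)
  nonamer <- "ACTAAAACG"            # 2 mismatches to ACAAAAACC
  contig <- paste0(rand_dna(150), "CACAGTG", rand_dna(12), nonamer,
                   rand_dna(60))
  hits <- detect_rss(contig, boundary = 150L, strand = "+",
                     side = "three_prime", expected_spacer = 12L, window = 5L)
  expect_gt(length(hits), 0)
  expect_equal(hits[[1]]$nonamer_mismatches, 2L)
  expect_equal(hits[[1]]$spacer_length, 12L)
})

test_that("five-prime RSS is read in the outward orientation", {
  set.seed(44)
  ## on the coding strand, a 5' RSS upstream of a J gene appears as
  ## revcomp(heptamer..nonamer): nonamer_rc + spacer + heptamer_rc
  rss_fwd <- paste0("CACAGTG", rand_dna(12), "ACAAAAACC")
  upstream <- revcomp(rss_fwd)
  contig <- paste0(rand_dna(120), upstream, rand_dna(200))
  b <- 120L + nchar(upstream)
  hits <- detect_rss(contig, boundary = b, strand = "+", side = "five_prime",
                     expected_spacer = 12L, window = 5L)
  expect_gt(length(hits), 0)
  expect_equal(hits[[1]]$heptamer, "CACAGTG")
  expect_equal(hits[[1]]$heptamer_mismatches, 0L)
  expect_equal(attr(hits[[1]], "boundary"), b)
})

test_that("RSS detection mirrors across strands", {
  set.seed(45)
  coding <- rand_dna(120)
  contig <- paste0(rand_dna(80), coding, "CACAGTG", rand_dna(23),
                   "ACAAAAACC", rand_dna(80))
  L <- nchar(contig)
  plus <- detect_rss(contig, boundary = 200L, strand = "+",
                     side = "three_prime", expected_spacer = 23L)
  minus <- detect_rss(revcomp(contig), boundary = L - 200L, strand = "-",
                      side = "three_prime", expected_spacer = 23L)
  expect_equal(length(plus), length(minus))
  expect_equal(plus[[1]]$heptamer, minus[[1]]$heptamer)
  expect_equal(plus[[1]]$spacer_length, minus[[1]]$spacer_length)
  ## forward offsets mirror: start' = L - (start + len)
  expect_equal(minus[[1]]$heptamer_offset,
               L - (plus[[1]]$heptamer_offset + 7L))
})

test_that("splice dinucleotides follow the GT-AG rule on both strands", {
  contig <- paste0("CCCAAA", "GT", "TTTT", "AG", "GGGCCC")
  ## donor: exon ends at position 6 (0-based), GT follows
  d <- detect_splice_sites(contig, boundary = 6L, strand = "+", kind = "donor")
  expect_true(d$valid)
  expect_equal(d$dinucleotide, "GT")
  ## acceptor: exon starts at position 14, AG precedes
  a <- detect_splice_sites(contig, boundary = 14L, strand = "+",
                           kind = "acceptor")
  expect_true(a$valid)
  ## a CG before the exon is invalid but reported
  contig2 <- paste0("AAAA", "CG", "GGGG")
  a2 <- detect_splice_sites(contig2, boundary = 6L, strand = "+",
                            kind = "acceptor")
  expect_false(a2$valid)
  expect_equal(a2$dinucleotide, "CG")
  ## minus strand: evaluated on the reverse complement
  rc <- revcomp(contig)
  L <- nchar(contig)
  dm <- detect_splice_sites(rc, boundary = L - 6L, strand = "-", kind = "donor")
  expect_true(dm$valid)
  expect_equal(dm$dinucleotide, "GT")
  ## boundary at the contig edge errors
  expect_error(detect_splice_sites(contig, boundary = nchar(contig) - 1L,
                                   strand = "+", kind = "donor"), "edge")
  expect_error(detect_splice_sites(contig, boundary = 1L, strand = "+",
                                   kind = "acceptor"), "edge")
})
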