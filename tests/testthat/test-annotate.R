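test_that("planted functional V genes assemble with exact structure", {
  fx <- fix_trb()
  sim <- fx$sim
  vt <- sim$truth[sim$truth$segment_type == "V", ]
  segs <- Filter(function(s) s$segment_type == "V", fx$ann$segments)
  expect_length(segs, nrow(vt))
  for (s in segs) {
    ce <- s$exons[s$exons$role == "coding", ]
    row <- vt[vt$coding_start == ce$start, ]
    expect_equal(nrow(row), 1)
    expect_equal(ce$end, row$coding_end)
    le <- s$exons[s$exons$role == "leader", ]
    expect_equal(le$end - le$start, row$leader_len)
    expect_true(s$diagnostics$splice_valid)
    expect_length(s$rss, 1)
    expect_equal(s$rss[[1]]$spacer_length, 23L)
    expect_equal(s$functionality, "functional")
  }
})

test_that("the catfish-type TRBD core assembles with both flanking RSS", {
  set.seed(51)
  d <- trlocus:::make_d_gene("GGGACAGGGGGC", spacer3 = 23L)
  contig <- c(ctg = paste0(rand_dna(200), d$seq, rand_dna(200)))
  drafts <- find_d_segments(contig, c(D1 = "GGGACAGGGGGC"), locus = "TRB")
  expect_length(drafts, 1)
  dr <- drafts[[1]]
  expect_equal(dr$exons$start, 200L + d$coding_local[1])
  expect_equal(dr$exons$end, 200L + d$coding_local[2])
  expect_length(dr$rss, 2)
  spacers <- sort(vapply(dr$rss, `[[`, integer(1), "spacer_length"))
  expect_equal(spacers, c(12L, 23L))
  expect_equal(classify_functionality(dr), "functional")
})

test_that("a hit without an upstream leader is flagged leader-absent", {
  set.seed(52)
  region <- trlocus:::make_v_region()
  ## coding exon + RSS but no leader/intron upstream
  contig <- c(ctg = paste0(rand_dna(900), region, "CACAGTG", rand_dna(23),
                           "ACAAAAACC", rand_dna(120)))
  hit <- list(start = 900L, end = 900L + nchar(region), strand = "+")
  draft <- assemble_gene_model(contig, hit, "V", chain_subtype_hint = "TRAV")
  expect_false(draft$diagnostics$leader_present)
  expect_equal(classify_functionality(draft), "remnant")
})

test_that("functionality classes follow the lesion that caused them", {
  fx <- fix_trad_lesions()
  sim <- fx$sim
  segs <- Filter(function(s) s$segment_type == "V", fx$ann$segments)
  vt <- sim$truth[sim$truth$segment_type == "V", ]
  got <- integer(0)
  for (s in segs) {
    sp <- trlocus:::segment_span(s)
    row <- vt[vt$coding_start < sp["end"] & vt$coding_end > sp["start"], ]
    expect_equal(nrow(row), 1)
    expect_equal(s$functionality, row$functionality,
                 info = paste("lesion:", row$lesion))
    got <- c(got, 1L)
  }
  expect_length(got, nrow(vt))
  ## the frameshift case keeps an open frame and its CYS104
  orf <- Filter(function(s) s$functionality == "ORF", segs)
  expect_length(orf, 1)
  expect_true(orf[[1]]$diagnostics$cys104_present)
  expect_true(orf[[1]]$diagnostics$frameshift_3prime)
})

test_that("IMGT-style names encode subgroup, order, and pseudogene status", {
  mk <- function(start, subtype, type = "V", func = "functional", strand = "+") {
    tr_segment(contig_id = "c", locus = "TRB", segment_type = type,
               chain_subtype = subtype, strand = strand,
               exons = data.frame(start = start, end = start + 300L,
                                  role = if (type == "V") "coding" else "coding"),
               functionality = func)
  }
  segs <- list(mk(1000, "TRBV"), mk(2000, "TRBV"), mk(3000, "TRBV"),
               mk(4000, "TRBV", func = "pseudogene"),
               mk(5000, "TRBJ", type = "J"), mk(6000, "TRBJ", type = "J"))
  ## subgroups: genes 1-3 in subgroup 7, gene 4 alone in subgroup 8
  map <- setNames(c(7L, 7L, 7L, 8L), as.character(1:4))
  named <- assign_names(segs, map)
  expect_equal(named[[3]]$name, "TRBV7-3")
  expect_equal(named[[4]]$name, "TRBV8P")   # single-member pseudogene subgroup
  expect_equal(named[[5]]$name, "TRBJ1")
  expect_equal(named[[6]]$name, "TRBJ2")

  ## 5'->3' order respects the minus strand (transcription direction)
  segs2 <- list(mk(1000, "TRAV", strand = "-"), mk(3000, "TRAV", strand = "-"))
  named2 <- assign_names(segs2, setNames(c(1L, 1L), c("1", "2")))
  expect_equal(named2[[2]]$name, "TRAV1-1")  # higher coordinate = 5' on "-"
  expect_equal(named2[[1]]$name, "TRAV1-2")

  ## duplicate names are an invariant breach
  dup <- list(mk(1000, "TRBV"), mk(1000 + 400, "TRBV"))
  expect_error(assign_names(dup, setNames(c(1L, 1L), c("1", "1"))), NA)
})

test_that("TRAD V genes split into TRAV and TRDV by leader length", {
  fx <- fix_trad_lesions()
  segs <- Filter(function(s) s$segment_type == "V" &&
                   s$functionality %in% c("functional", "ORF"),
                 fx$ann$segments)
  vt <- fx$sim$truth
  for (s in segs) {
    ce <- s$exons[s$exons$role == "coding", ]
    row <- vt[vt$coding_start == min(ce$start), ]
    expect_equal(s$chain_subtype, row$chain_subtype)
    le <- s$exons[s$exons$role == "leader", ]
    len <- le$end - le$start
    if (s$chain_subtype == "TRDV") expect_true(len %in% c(64L, 67L))
    if (s$chain_subtype == "TRAV") expect_true(len %in% 40:43)
  }
})
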