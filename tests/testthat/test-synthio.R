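test_that("locus simulation is byte-deterministic under a fixed seed", {
  bp <- locus_blueprint("trb-like", n_v = 3, v_subgroups = 2, n_j = 1,
                        n_c = 1, seed = 91)
  s1 <- simulate_locus(bp)
  s2 <- simulate_locus(bp)
  expect_identical(s1$contig, s2$contig)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$seeds, s2$seeds)
})

test_that("blueprints validate their plans", {
  expect_error(locus_blueprint("trb-like", within_identity = 0.5), "exceed")
  expect_error(locus_blueprint("trb-like",
                               duplication = list(length = 4000, identity = 20)),
               "identity")
})

test_that("forced lesions appear in the truth with matching labels", {
  bp <- locus_blueprint("trb-like", n_v = 5, v_subgroups = 2, n_j = 1,
                        n_c = 1,
                        lesion_counts = c(internal_stop = 1, trunc3 = 1),
                        seed = 92)
  sim <- simulate_locus(bp)
  vt <- sim$truth[sim$truth$segment_type == "V", ]
  expect_equal(sum(vt$lesion == "internal_stop"), 1)
  expect_equal(sum(vt$lesion == "trunc3"), 1)
  expect_equal(vt$functionality[vt$lesion == "internal_stop"], "pseudogene")
  expect_equal(vt$functionality[vt$lesion == "trunc3"], "remnant")
  expect_equal(sum(vt$functionality == "functional"), 3)
})

test_that("planted features lie inside the contig and carry correct sequence", {
  fx <- fix_trb()
  sim <- fx$sim
  L <- nchar(sim$contig[[1]])
  expect_true(all(sim$truth$start >= 0 & sim$truth$end <= L))
  ## planted V region sequence is recoverable from the truth coordinates
  vt <- sim$truth[sim$truth$segment_type == "V" &
                    sim$truth$functionality == "functional", ]
  for (i in seq_len(nrow(vt))) {
    coding <- trlocus:::subseq0(sim$contig[[1]], vt$coding_start[i],
                                vt$coding_end[i], vt$strand[i])
    region <- sim$v_regions[[vt$id[i]]]
    expect_true(grepl(region, coding, fixed = TRUE))
  }
  ## TRBD fixture sequence is planted verbatim
  bp <- locus_blueprint("trb-like", n_v = 2, v_subgroups = 1, n_j = 1,
                        n_c = 1, seed = 93)
  simb <- simulate_locus(bp)
  dt <- simb$truth[simb$truth$segment_type == "D", ]
  expect_equal(substr(simb$contig[[1]], dt$coding_start + 1, dt$coding_end),
               "GGGACAGGGGGC")
})

test_that("duplication plans emit a detectable homology-unit pair", {
  bp <- locus_blueprint("trb-like", n_v = 2, v_subgroups = 1, n_j = 1,
                        n_c = 1, duplication = list(length = 4500, identity = 96),
                        seed = 94)
  sim <- simulate_locus(bp)
  hu <- find_homology_units(sim$contig[[1]], min_length = 4000,
                            min_identity = 94)
  expect_gte(nrow(hu), 1)
  expect_gte(max(hu$percent_identity), 95)
  expect_gte(max(hu$length), 4400)
})

test_that("repertoire simulation is deterministic and records its truth", {
  db <- simulate_germline_db("TRB", n_subgroups = 2, members_per = 2,
                             n_j = 3, seed = 95)
  r1 <- simulate_repertoire_reads(db, n_reads = 10, seed = 96)
  r2 <- simulate_repertoire_reads(db, n_reads = 10, seed = 96)
  expect_identical(r1$r1, r2$r1)
  expect_identical(r1$truth, r2$truth)
  ## every junction reconstructable from its event record: the planted CDR3
  ## appears in the fragment the reads were cut from
  for (i in 1:10) {
    m <- merge_read_pair(as.list(r1$r1[i, ]), as.list(r1$r2[i, ]))
    expect_true(m$merged)
    expect_true(grepl(r1$truth$cdr3_nt[i], m$seq, fixed = TRUE))
  }
  ## TRB junctions always use the single D
  expect_true(all(r1$truth$n_d == 1))
})

test_that("zero trimming and zero N additions give exact V-D-J concatenation", {
  db <- simulate_germline_db("TRB", n_subgroups = 1, members_per = 1,
                             n_j = 1, seed = 97)
  rep <- simulate_repertoire_reads(db, n_reads = 5, v_trim_mean = 0,
                                   j_trim_mean = 0, n_mean = 0,
                                   seed = 98)
  ## geometric with mean 0 is the point mass at 0: junction is pure V+D+J
  v <- db$V[[1]]; j <- db$J[[1]]
  for (i in 1:5) {
    tr <- rep$truth[i, ]
    expect_equal(tr$v_trim, 0L)
    expect_equal(tr$j_trim, 0L)
    expect_true(startsWith(tr$cdr3_nt, substr(v, nchar(v) - 8, nchar(v))))
    expect_true(endsWith(tr$cdr3_nt,
                         substr(j, 1, db$j_phe_nt_end[[names(db$J)[1]]])))
  }
})

test_that("simulated TRD junctions are longer than TRA junctions", {
  dba <- simulate_germline_db("TRA", n_subgroups = 2, members_per = 2,
                              n_j = 3, seed = 99)
  dbd <- simulate_germline_db("TRD", n_subgroups = 2, members_per = 2,
                              n_j = 2, seed = 99)
  ra <- simulate_repertoire_reads(dba, n_reads = 40, seed = 100)
  rd <- simulate_repertoire_reads(dbd, n_reads = 40, seed = 100)
  expect_true(all(rd$truth$n_d <= 4))
  mean_a <- mean(nchar(ra$truth$cdr3_aa))
  mean_d <- mean(nchar(rd$truth$cdr3_aa))
  expect_gt(mean_d, mean_a)
})
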