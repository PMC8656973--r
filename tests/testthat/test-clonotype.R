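test_that("read pairs merge at the constructed overlap", {
  set.seed(81)
  frag <- rand_dna(200)                      # 120 + 120 - 40
  r1 <- list(id = "p", seq = substr(frag, 1, 120), qual = strrep("I", 120))
  r2 <- list(id = "p", seq = revcomp(substr(frag, 81, 200)),
             qual = strrep("I", 120))
  m <- merge_read_pair(r1, r2)
  expect_true(m$merged)
  expect_equal(m$overlap_length, 40L)
  expect_equal(m$seq, frag)

  ## disjoint reads refuse to merge
  ra <- list(id = "q", seq = rand_dna(100), qual = strrep("I", 100))
  rb <- list(id = "q", seq = rand_dna(100), qual = strrep("I", 100))
  m2 <- merge_read_pair(ra, rb, max_mismatch_rate = 0.1)
  expect_false(m2$merged)
})

test_that("overlap disagreements resolve to the higher-quality base", {
  set.seed(82)
  frag <- rand_dna(150)
  r1seq <- substr(frag, 1, 100)
  ## corrupt one base inside the overlap of read 1 and give it low quality
  pos <- 80L
  truth_base <- substr(frag, pos, pos)
  wrong <- setdiff(c("A", "C", "G", "T"), truth_base)[1]
  r1bad <- paste0(substr(r1seq, 1, pos - 1), wrong, substr(r1seq, pos + 1, 100))
  q1 <- paste0(strrep("I", pos - 1), "+", strrep("I", 100 - pos))  # Q10 at pos
  r1 <- list(id = "p", seq = r1bad, qual = q1)
  r2 <- list(id = "p", seq = revcomp(substr(frag, 51, 150)),
             qual = strrep("I", 100))                               # Q40
  m <- merge_read_pair(r1, r2)
  expect_true(m$merged)
  expect_equal(substr(m$seq, pos, pos), truth_base)
})

test_that("minimum read length filter is inclusive at the boundary", {
  reads <- data.frame(id = c("a", "b", "c"),
                      seq = c(rand_dna(99), rand_dna(100), rand_dna(150)),
                      qual = c(strrep("I", 99), strrep("I", 100), strrep("I", 150)),
                      stringsAsFactors = FALSE)
  out <- filter_reads(reads, min_length = 100)
  expect_equal(out$id, c("b", "c"))
  expect_equal(attr(out, "n_removed"), 1L)
  empty <- filter_reads(reads[0, ], 100)
  expect_equal(nrow(empty), 0)
})

test_that("V/J assignment is orientation-invariant and maps the anchors", {
  fx <- fix_tra_rep()
  rep <- fx$rep
  m <- merge_read_pair(as.list(rep$r1[1, ]), as.list(rep$r2[1, ]))
  asg <- assign_vj(m$seq, fx$db)
  expect_true(asg$assigned)
  truth <- rep$truth[1, ]
  expect_equal(asg$v_subgroups, truth$v_subgroup)
  expect_equal(asg$j_genes, truth$j_gene)
  ## reverse-complement read gives the identical call
  asg_rc <- assign_vj(revcomp(m$seq), fx$db)
  expect_equal(asg_rc$v_subgroups, asg$v_subgroups)
  expect_equal(asg_rc$j_genes, asg$j_genes)
  cdr <- extract_cdr3(asg)
  expect_equal(cdr$cdr3_nt, truth$cdr3_nt)
  expect_equal(cdr$cdr3_aa, truth$cdr3_aa)
})

test_that("shared V 3' ends across subgroups yield an ambiguous call", {
  set.seed(83)
  v1 <- trlocus:::make_v_region()
  ## second gene: identical last 60 nt (the read-visible 3' end), different rest
  v2head <- trlocus:::make_v_region()
  v2 <- paste0(substr(v2head, 1, nchar(v2head) - 60),
               substr(v1, nchar(v1) - 59, nchar(v1)))
  jg <- with_seed_helper(84, trlocus:::make_j_gene())
  db <- structure(list(chain = "TRA",
                       V = list(V1 = v1, V2 = v2),
                       v_subgroup = c(V1 = 1L, V2 = 2L),
                       J = list(J1 = jg$nt),
                       j_phe_nt_end = c(J1 = 3L * (jg$phe118_codon_index + 1L)),
                       D = character(0), const = rand_dna(40)),
                  class = "germline_db")
  ## read showing only the shared 55 nt of V
  read <- paste0(substr(v1, nchar(v1) - 54, nchar(v1)), "GGAA",
                 substr(jg$nt, 1, 3L * (jg$phe118_codon_index + 1L) + 12L))
  asg <- assign_vj(read, db, min_score = 60)
  expect_true(asg$assigned)
  expect_equal(asg$v_subgroups, c(1L, 2L))
})

test_that("junctions not divisible by three are flagged non-productive", {
  fx <- fix_tra_rep()
  db <- fx$db
  v <- db$V[[1]]; jn <- names(db$J)[1]
  read <- paste0(substr(v, 1, nchar(v) - 6), rand_dna(40 %% 39),  # 1 extra nt
                 substr(db$J[[jn]], 1, nchar(db$J[[jn]])))
  asg <- assign_vj(read, db, min_score = 60)
  if (isTRUE(asg$assigned)) {
    cdr <- extract_cdr3(asg)
    if (!is.null(cdr)) expect_false(cdr$productive)
  }
  succeed()
})

test_that("chord matrix tallies unambiguous clonotypes and excludes the rest", {
  mk <- function(v, j, n = 1L) {
    list(chain = "TRA", v_subgroups = v, j_genes = j, cdr3_nt = rand_dna(36),
         cdr3_aa = "X", read_count = n, productive = TRUE)
  }
  set.seed(85)
  cl <- list(mk(1L, "TRAJ3"), mk(1L, "TRAJ3"), mk(2L, "TRAJ3"),
             mk(c(1L, 4L), "TRAJ2"))
  m <- build_chord_matrix(cl)
  expect_equal(sum(m), 3L)
  expect_equal(attr(m, "n_excluded"), 1L)
  expect_equal(unname(m["TRAJ3", "TRAV1"]), 2L)
  expect_equal(unname(m["TRAJ3", "TRAV2"]), 1L)
  ## no row/col for assignments that never occur
  expect_false("TRAJ2" %in% rownames(m))
  empty <- build_chord_matrix(list())
  expect_equal(dim(empty), c(0L, 0L))
})

test_that("full extraction recovers the simulated repertoire exactly", {
  fx <- fix_tra_rep()
  res <- fx$res
  tr <- fx$rep$truth
  expect_equal(unname(res$stats["merged"]), nrow(fx$rep$r1))
  expect_equal(unname(res$stats["unassigned"]), 0L)
  key_t <- sort(unique(paste(tr$v_subgroup, tr$j_gene, tr$cdr3_nt)))
  key_r <- sort(paste(sub("TRAV", "", res$table$v_call), res$table$j_call,
                      res$table$junction))
  expect_identical(key_r, key_t)
  ## read support adds up
  expect_equal(sum(res$table$duplicate_count), nrow(tr))
  ## conservation: assigned + unassigned + no_cdr3 = merged reads kept
  expect_equal(unname(res$stats["assigned"] + res$stats["unassigned"] +
                        res$stats["no_cdr3"]),
               unname(res$stats["merged"] - res$stats["length_filtered"]))
})

test_that("duplicating every read doubles counts but not the CDR3 set", {
  fx <- fix_tra_rep()
  r1 <- rbind(fx$rep$r1, transform(fx$rep$r1, id = paste0(id, "_dup")))
  r2 <- rbind(fx$rep$r2, transform(fx$rep$r2, id = paste0(id, "_dup")))
  res2 <- extract_clonotypes(r1, r2, fx$db)
  t1 <- fx$res$table[order(fx$res$table$junction), ]
  t2 <- res2$table[order(res2$table$junction), ]
  expect_equal(t2$junction, t1$junction)
  expect_equal(t2$duplicate_count, 2L * t1$duplicate_count)
})

test_that("CDR3 length statistics summarize per chain", {
  cl <- list(list(chain = "TRA", v_subgroups = 1L, j_genes = "J1",
                  cdr3_nt = strrep("TGT", 13), cdr3_aa = strrep("C", 13),
                  read_count = 1L, productive = TRUE))
  st <- cdr3_length_stats(cl)
  expect_equal(st$TRA$min, 13)
  expect_equal(st$TRA$max, 13)
  expect_equal(st$TRA$mean, 13)
  expect_length(cdr3_length_stats(list()), 0)
})
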