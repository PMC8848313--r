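cfg <- pipeline_config()

test_that("cropping aligns error-free staggered reads to common positions", {
  set.seed(61)
  fx <- two_contig_fixture(n_reads = 4L)
  alns <- filter_reliable(map_reads(fx$reads, contig_seqs(fx$assembly)),
                          mask_track())
  g <- build_graph(fx$assembly, alns)
  pus <- prune_and_collect(g)
  expect_length(pus, 1L)
  pu <- crop_pileup(pus[[1]], fx$reads, contig_seqs(fx$assembly))
  expect_equal(nrow(pu$cropped), 4L)
  # error-free reads cropped at identical reference positions are identical
  expect_length(unique(pu$cropped$seq), 1L)
  # crop positions lie within the flanking contigs
  expect_gte(pu$crop_a, 0L)
  expect_lte(pu$crop_a, nchar(contig_seqs(fx$assembly)[["s1.1"]]))
})

test_that("reads not reaching the crop position are dropped", {
  set.seed(62)
  fx <- two_contig_fixture(n_reads = 3L)
  # add a short read stopping 2 kb before the common crop position
  short <- substr(fx$genome, 1000, 2400)
  reads <- c(fx$reads, short_read = short)
  alns <- filter_reliable(map_reads(reads, contig_seqs(fx$assembly)),
                          mask_track())
  g <- build_graph(fx$assembly, alns)
  pus <- prune_and_collect(g)
  pu <- crop_pileup(pus[[1]], reads, contig_seqs(fx$assembly))
  expect_false("short_read" %in% pu$cropped$read_id)
  expect_equal(sum(pu$cropped$role == "span"), 3L)
})

test_that("intrinsic QVs expose a corrupted read block", {
  set.seed(63)
  truth <- random_seq(1600)
  reads <- setNames(c(truth, truth, truth,
                      paste0(substr(truth, 1, 700), random_seq(100),
                             substr(truth, 801, 1600))),
                    paste0("r", 1:4))
  pu <- cropped_pileup(reads)
  ch <- pileup_chains(pu, cfg)
  qv <- intrinsic_qv(pu, ch)
  expect_equal(length(qv$r1), ceiling(1600 / 100))
  # a pile-up of only identical reads has all-zero QVs
  pu0 <- cropped_pileup(reads[1:3])
  qv0 <- intrinsic_qv(pu0, pileup_chains(pu0, cfg))
  expect_true(all(unlist(qv0) == 0))
  corrupted_windows <- qv$r4[8]
  expect_gt(corrupted_windows, max(qv$r4[-(7:9)]))
})

test_that("reference selection prefers the pristine read", {
  set.seed(64)
  truth <- random_seq(2000)
  reads <- setNames(c(truth,
                      vapply(1:4, function(i) clr_mutate(truth, 0.15), "")),
                    paste0("r", 1:5))
  pu <- cropped_pileup(reads)
  ch <- pileup_chains(pu, cfg)
  qv <- intrinsic_qv(pu, ch)
  expect_equal(select_reference_read(pu, qv), "r1")
  # identical reads tie-break deterministically by id
  pu2 <- cropped_pileup(setNames(rep(truth, 3), c("b", "a", "c")))
  ch2 <- pileup_chains(pu2, cfg)
  expect_equal(select_reference_read(pu2, intrinsic_qv(pu2, ch2)), "a")
})

test_that("consensus is exact on error-free pile-ups", {
  set.seed(65)
  truth <- random_seq(2000)
  pu <- cropped_pileup(setNames(rep(truth, 3), paste0("r", 1:3)))
  ch <- pileup_chains(pu, cfg)
  ref <- select_reference_read(pu, intrinsic_qv(pu, ch))
  expect_identical(pileup_consensus(pu, ref, ch, cfg), truth)
})

test_that("consensus accuracy grows with pile-up depth", {
  set.seed(66)
  truth <- random_seq(2000)
  id_at <- function(n) {
    reads <- setNames(vapply(seq_len(n), function(i)
      clr_mutate(truth, 0.13), ""), paste0("r", seq_len(n)))
    pu <- cropped_pileup(reads)
    ch <- pileup_chains(pu, cfg)
    ref <- select_reference_read(pu, intrinsic_qv(pu, ch))
    gap_identity(pileup_consensus(pu, ref, ch, cfg), truth)
  }
  id5 <- id_at(5L); id12 <- id_at(12L)
  expect_gte(id5, 0.97)
  expect_gte(id12, 0.99)
  expect_gte(id12, id5 - 0.005)  # monotone within noise
})

test_that("a majority preserves homopolymer length against one dropout", {
  set.seed(67)
  left <- random_seq(500); right <- random_seq(500)
  good <- paste0(left, "CCCCCC", right)
  bad <- paste0(left, "CCCCC", right)
  pu <- cropped_pileup(setNames(c(good, good, bad), paste0("r", 1:3)))
  ch <- pileup_chains(pu, cfg)
  ref <- select_reference_read(pu, intrinsic_qv(pu, ch))
  expect_identical(pileup_consensus(pu, ref, ch, cfg), good)
})

test_that("anchoring finds exact insert sites on an error-free pile-up", {
  set.seed(68)
  fx <- two_contig_fixture(n_reads = 3L)
  alns <- filter_reliable(map_reads(fx$reads, contig_seqs(fx$assembly)),
                          mask_track())
  g <- build_graph(fx$assembly, alns)
  pu <- crop_pileup(prune_and_collect(g)[[1]], fx$reads,
                    contig_seqs(fx$assembly))
  ch <- pileup_chains(pu, cfg)
  ref <- select_reference_read(pu, intrinsic_qv(pu, ch))
  cons <- pileup_consensus(pu, ref, ch, cfg)
  ins <- anchor_insertion(cons, pu, cfg)
  expect_equal(ins$validated, "pending")
  # splicing the insertion yields exactly the true genome
  contigs <- contig_seqs(fx$assembly)
  left <- contigs[["s1.1"]]; right <- contigs[["s1.2"]]
  rebuilt <- paste0(substr(left, 1, nchar(left) - ins$trim_a), ins$seq_core,
                    substr(right, ins$trim_b + 1L, nchar(right)))
  expect_identical(rebuilt, fx$genome)
})

test_that("a consensus missing one flank fails anchoring", {
  set.seed(69)
  fx <- two_contig_fixture(n_reads = 3L)
  alns <- filter_reliable(map_reads(fx$reads, contig_seqs(fx$assembly)),
                          mask_track())
  g <- build_graph(fx$assembly, alns)
  pu <- crop_pileup(prune_and_collect(g)[[1]], fx$reads,
                    contig_seqs(fx$assembly))
  cons <- paste0(substr(pu$flank_a, 1, nchar(pu$flank_a)), random_seq(300))
  ins <- anchor_insertion(cons, pu, cfg)
  expect_equal(ins$validated, "fail")
})
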