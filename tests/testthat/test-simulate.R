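test_that("genome simulation is reproducible and base-balanced", {
  g1 <- simulate_genome(50000, seed = 81)
  g2 <- simulate_genome(50000, seed = 81)
  expect_identical(scaffold_seq(g1$assembly[[1]]),
                   scaffold_seq(g2$assembly[[1]]))
  s <- scaffold_seq(g1$assembly[[1]])
  gc <- (lengths(regmatches(s, gregexpr("[GC]", s)))) / nchar(s)
  expect_lt(abs(gc - 0.5), 0.02)
})

test_that("planted repeat copies are alignable at high identity", {
  g <- simulate_genome(80000, list(
    interspersed = data.frame(count = 4, length = 2000, divergence = 0.05)),
    seed = 82)
  expect_equal(nrow(g$repeat_table), 4L)
  s <- scaffold_seq(g$assembly[[1]])
  c1 <- substr(s, g$repeat_table$begin[1] + 1L, g$repeat_table$end[1])
  c2 <- substr(s, g$repeat_table$begin[2] + 1L, g$repeat_table$end[2])
  h <- align_pair(c1, c2, mode = "local", max_err = 0.2)
  expect_gte(nrow(h), 1L)
  expect_gte(max(h$n_match / h$aln_len), 0.88)
})

test_that("simulated reads match the requested length and error profile", {
  set.seed(83)
  g <- simulate_genome(400000, seed = 83)
  sim <- simulate_reads(g$assembly, coverage = 12, mean_len = 3000,
                        len_param = 15000, error = 0.13, seed = 84)
  expect_gte(length(sim$reads), 1000L)
  # mean length within 5% (law of large numbers; truncation shortens a bit)
  expect_lt(abs(mean(nchar(sim$reads)) - 3000) / 3000, 0.05)
  # total coverage within 5%
  expect_lt(abs(sum(nchar(sim$reads)) - 12 * 400000) / (12 * 400000), 0.05)
  # empirical error rate within 10% relative: edit distance to the source
  genome <- scaffold_seq(g$assembly[[1]])
  idx <- order(-nchar(sim$reads))[1:40]
  errs <- vapply(idx, function(i) {
    tr <- sim$truth[i, ]
    src <- substr(genome, tr$begin + 1L, tr$end)
    if (tr$strand == "-") src <- revcomp(src)
    h <- spanweld:::cpp_align_global(sim$reads[[i]], src, 500L)
    h$edit / (tr$end - tr$begin)
  }, 0)
  expect_lt(abs(mean(errs) - 0.13) / 0.13, 0.10)
  # truth intervals reproduce the read (error-free case)
  sim0 <- simulate_reads(g$assembly, coverage = 0.2, error = 0, seed = 85)
  tr <- sim0$truth[1, ]
  src <- substr(genome, tr$begin + 1L, tr$end)
  if (tr$strand == "-") src <- revcomp(src)
  expect_identical(sim0$reads[[1]], src)
})

test_that("test assemblies copy gaps with exact truth bookkeeping", {
  set.seed(86)
  g <- simulate_genome(60000, seed = 86)
  spec <- sample_gap_spec(g$assembly, 5L, c(50L, 800L), seed = 87)
  ta <- make_test_assembly(g$assembly, gap_spec = spec)
  expect_equal(nrow(ta$truth), 5L)
  # introduced gap lengths equal truth lengths exactly
  gt <- gap_table(ta$assembly)
  expect_equal(sort(gt$gap_length), sort(nchar(ta$truth$truth_seq)))
  # reconstructing the non-N sequence from reference + truth is the identity
  genome <- scaffold_seq(g$assembly[[1]])
  rebuilt <- scaffold_seq(ta$assembly[[1]])
  for (i in seq_len(nrow(ta$truth))) {
    b <- ta$truth$begin[i]; e <- ta$truth$end[i]
    rebuilt <- paste0(substr(rebuilt, 1, b), ta$truth$truth_seq[i],
                      substr(rebuilt, e + 1, nchar(rebuilt)))
  }
  expect_identical(rebuilt, genome)
})

test_that("too-small and too-close candidate gaps are rejected", {
  set.seed(88)
  g <- simulate_genome(40000, seed = 88)
  spec <- data.frame(scaffold_id = "chr1",
                     begin = c(10000L, 20000L, 21000L),
                     end = c(10008L, 20500L, 21400L))
  ta <- make_test_assembly(g$assembly, gap_spec = spec, exclusion = 3000L)
  # 8 bp gap dropped (< 10); third gap 500 bp from the second is kept by
  # the builder (exclusion applies to pre-existing reference gaps)
  expect_false(any(ta$truth$end - ta$truth$begin == 8L))
  expect_equal(ta$skipped[["too_small"]], 1L)
  # a reference that already has a gap nearby rejects the candidate
  ref2 <- assembly_from_parts(list(chr1 = list(
    substr(scaffold_seq(g$assembly[[1]]), 1, 20000), 100L,
    substr(scaffold_seq(g$assembly[[1]]), 20101, 40000))))
  ta2 <- make_test_assembly(ref2, gap_spec = data.frame(
    scaffold_id = "chr1", begin = 21000L, end = 21400L))
  expect_equal(nrow(ta2$truth), 0L)
  expect_equal(ta2$skipped[["near_gap"]], 1L)
})

test_that("gap lift-over from a fragmented assembly places gaps correctly", {
  set.seed(89)
  genome <- random_seq(30000)
  reference <- assembly_from_parts(list(chr = list(genome)))
  # fragmented assembly: same genome with one 200 bp stretch replaced by Ns
  frag <- assembly_from_parts(list(f1 = list(
    substr(genome, 1, 12000), 200L, substr(genome, 12201, 30000))))
  ta <- make_test_assembly(reference, fragmented = frag)
  expect_equal(nrow(ta$truth), 1L)
  expect_equal(ta$truth$ref_begin, 12000L)
  expect_equal(ta$truth$ref_end, 12200L)
  expect_identical(ta$truth$truth_seq, substr(genome, 12001, 12200))
})

test_that("closable gaps require spanning reads over both flanks", {
  gaps <- data.frame(gap_id = "g1", contig_id = "c", scaffold_id = "chr",
                     begin = 1000L, end = 1200L, ref_begin = 1000L,
                     ref_end = 1200L, truth_seq = strrep("A", 200))
  mk_truth <- function(spans) do.call(rbind, lapply(seq_along(spans),
    function(i) data.frame(read_id = paste0("r", i), scaffold_id = "chr",
                           begin = spans[[i]][1], end = spans[[i]][2],
                           strand = "+")))
  # three qualifying reads: closable
  t3 <- mk_truth(list(c(400, 1800), c(100, 2000), c(500, 1700)))
  expect_true(find_closable_gaps(t3, gaps)$closable)
  # one read covering only 400 bp of a flank does not qualify
  t2 <- mk_truth(list(c(400, 1800), c(100, 2000), c(700, 1800)))
  r <- find_closable_gaps(t2, gaps)
  expect_equal(r$n_spanning, 2L)
  expect_false(r$closable)
  # zero reads
  t0 <- mk_truth(list(c(5000, 6000)))
  expect_false(find_closable_gaps(t0, gaps)$closable)
  # brute-force containment scan agreement on random fixtures
  set.seed(90)
  for (rep in 1:5) {
    k <- 40L
    b <- sample.int(8000L, k); e <- b + sample(500:3000, k, TRUE)
    tt <- mk_truth(Map(c, b, e))
    gg <- data.frame(gap_id = paste0("g", 1:4), contig_id = "c",
                     scaffold_id = "chr",
                     begin = c(1000L, 3000L, 5000L, 7000L),
                     end = c(1300L, 3400L, 5100L, 7800L),
                     ref_begin = c(1000L, 3000L, 5000L, 7000L),
                     ref_end = c(1300L, 3400L, 5100L, 7800L),
                     truth_seq = "A")
    got <- find_closable_gaps(tt, gg)$n_spanning
    want <- vapply(seq_len(4), function(i)
      sum(b <= gg$ref_begin[i] - 500L & e >= gg$ref_end[i] + 500L), 0L)
    expect_equal(got, want)
  }
})
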