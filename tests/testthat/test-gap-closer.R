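cfg <- pipeline_config()

make_insertion <- function(contig_a = "s1.1", side_a = "end",
                           contig_b = "s1.2", side_b = "begin",
                           core = "TTTT", trim_a = 0L, trim_b = 0L,
                           is_input_gap = TRUE, validated = "pending") {
  structure(list(id = paste0(contig_a, ":", side_a, "--", contig_b, ":",
                             side_b),
                 contig_a = contig_a, side_a = side_a, contig_b = contig_b,
                 side_b = side_b, is_input_gap = is_input_gap,
                 seq_core = core, trim_a = trim_a, trim_b = trim_b,
                 validated = validated, reason = NA_character_),
            class = "spanweld_insertion")
}

test_that("an applied insertion splices left flank, core and right flank", {
  asm <- assembly_from_parts(list(s1 = list("ACGTACGT", 6L, "GGCCGGCC")))
  ins <- make_insertion(core = "TTTT", trim_a = 1L, trim_b = 2L)
  out <- apply_insertions(asm, list(ins))
  expect_equal(scaffold_seq(out$assembly[["s1"]]),
               paste0("ACGTACG", "TTTT", "CCGGCC"))
  expect_equal(out$placements$core_begin, 7L)
  expect_equal(out$placements$core_end, 11L)
})

test_that("no insertions leaves the assembly byte-identical", {
  set.seed(71)
  asm <- assembly_from_parts(list(
    s1 = list(random_seq(500), 40L, random_seq(300)),
    s2 = list(random_seq(200))))
  out <- apply_insertions(asm, list())
  expect_identical(vapply(out$assembly, scaffold_seq, ""),
                   vapply(asm, scaffold_seq, ""))
})

test_that("inter-scaffold insertions are skipped in intra-only mode", {
  set.seed(72)
  asm <- assembly_from_parts(list(s1 = list(random_seq(300)),
                                  s2 = list(random_seq(300))))
  ins <- make_insertion(contig_a = "s1.1", contig_b = "s2.1",
                        is_input_gap = FALSE, core = "AAAA")
  out <- apply_insertions(asm, list(ins), mode = "intra_only")
  expect_equal(length(out$assembly), 2L)
  out2 <- apply_insertions(asm, list(ins), mode = "intra_and_inter")
  expect_equal(length(out2$assembly), 1L)
  expect_equal(names(out2$assembly), "s1+s2")
  expect_true(grepl("AAAA", scaffold_seq(out2$assembly[[1]])))
})

test_that("free scaffolding builds paths from insertion joins alone", {
  set.seed(73)
  a <- random_seq(300); b <- random_seq(300); c <- random_seq(300)
  asm <- assembly_from_parts(list(s1 = list(a, 20L, b), s2 = list(c)))
  # join s1.2:end to s2.1:begin only; the s1 input gap is dropped
  ins <- make_insertion(contig_a = "s1.2", contig_b = "s2.1",
                        is_input_gap = FALSE, core = "GGGG")
  out <- apply_insertions(asm, list(ins), mode = "free_scaffolding")
  seqs <- vapply(out$assembly, scaffold_seq, "")
  expect_true(any(seqs == paste0(b, "GGGG", c)))
  expect_true(any(seqs == a))
})

test_that("conflicting insertions at one contig end are a hard error", {
  asm <- assembly_from_parts(list(s1 = list("ACGT", 4L, "ACGT", 4L, "ACGT")))
  i1 <- make_insertion("s1.1", "end", "s1.2", "begin")
  i2 <- make_insertion("s1.1", "end", "s1.3", "begin")
  expect_error(apply_insertions(asm, list(i1, i2)), "conflicting")
})

test_that("continuous coverage is the sliding-window minimum", {
  one <- aln_row(target_id = "c", tbeg = 0L, tend = 2000L,
                 target_len = 2000L)
  expect_equal(continuous_coverage(one, "c", 0L, 2000L, 500L), 1L)
  # two alignments overlapping 400 bp mid-region: some 500 bp window is
  # covered by neither
  two <- rbind(aln_row(target_id = "c", tbeg = 0L, tend = 1200L),
               aln_row(target_id = "c", tbeg = 800L, tend = 2000L))
  expect_equal(continuous_coverage(two, "c", 0L, 2000L, 500L), 0L)
  # brute-force agreement on random fixtures
  set.seed(74)
  for (rep in 1:10) {
    k <- 12L
    tb <- sample.int(1500L, k)
    te <- pmin(2000L, tb + 300L + sample.int(500L, k))
    alns <- do.call(rbind, lapply(seq_len(k), function(i)
      aln_row(query_id = paste0("r", i), target_id = "c", tbeg = tb[i],
              tend = te[i])))
    w <- 250L
    brute <- min(vapply(0:(2000L - w), function(x)
      sum(tb <= x & te >= x + w), 0L))
    expect_equal(continuous_coverage(alns, "c", 0L, 2000L, w), brute)
  }
  # region shorter than the window: evaluated as one window
  expect_equal(continuous_coverage(one, "c", 100L, 400L, 500L), 1L)
})

test_that("derived validation threshold is half the haploid coverage", {
  expect_equal(min_coverage_threshold(pipeline_config(read_coverage = 40,
                                                      ploidy = 2L)), 10)
  expect_equal(min_coverage_threshold(pipeline_config(read_coverage = 20)),
               10)
  expect_equal(min_coverage_threshold(
    pipeline_config(min_coverage_reads = 7)), 7)
  expect_error(min_coverage_threshold(pipeline_config()))
})

test_that("validation passes a correct insertion and reverts a corrupt one", {
  set.seed(75)
  fx <- two_contig_fixture(n_reads = 20L, read_len = 3500L)
  contigs <- contig_seqs(fx$assembly)
  alns <- filter_reliable(map_reads(fx$reads, contigs), mask_track())
  g <- build_graph(fx$assembly, alns)
  pu <- prune_and_collect(g)[[1]]
  ins <- close_one_gap(pu, fx$reads, contigs, cfg)
  closed <- apply_insertions(fx$assembly, list(ins))
  cfg2 <- pipeline_config(read_coverage = 8)  # threshold 4, matches depth
  v <- validate_gaps(closed, fx$reads, list(ins), cfg2)
  expect_equal(v[[1]]$validated, "pass")
  # corrupt insertion: shuffled core of the same length
  bad <- ins
  bad$seq_core <- random_seq(nchar(ins$seq_core))
  closed_bad <- apply_insertions(fx$assembly, list(bad))
  vb <- validate_gaps(closed_bad, fx$reads, list(bad), cfg2)
  expect_equal(vb[[1]]$validated, "fail")
  # reverting the failed insertion restores the byte-identical input
  reverted <- apply_insertions(fx$assembly, Filter(
    function(x) identical(x$validated, "pass"), vb))
  expect_identical(scaffold_seq(reverted$assembly[["s1"]]),
                   scaffold_seq(fx$assembly[["s1"]]))
})

test_that("adding spanning reads never flips a validation pass to fail", {
  set.seed(76)
  fx <- two_contig_fixture(n_reads = 8L, read_len = 3500L)
  contigs <- contig_seqs(fx$assembly)
  alns <- filter_reliable(map_reads(fx$reads, contigs), mask_track())
  g <- build_graph(fx$assembly, alns)
  pu <- prune_and_collect(g)[[1]]
  ins <- close_one_gap(pu, fx$reads, contigs, cfg)
  closed <- apply_insertions(fx$assembly, list(ins))
  cfg2 <- pipeline_config(read_coverage = 4)
  v1 <- validate_gaps(closed, fx$reads, list(ins), cfg2)[[1]]$validated
  more <- c(fx$reads, setNames(fx$reads, paste0("dup_", names(fx$reads))))
  v2 <- validate_gaps(closed, more, list(ins), cfg2)[[1]]$validated
  if (v1 == "pass") expect_equal(v2, "pass")
  expect_true(v2 %in% c("pass", "fail"))
})
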