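toy_bench <- function(seed = 91, n_gaps = 3L) {
  set.seed(seed)
  g <- simulate_genome(40000, seed = seed)
  spec <- sample_gap_spec(g$assembly, n_gaps, c(60L, 400L),
                          seed = seed + 1L)
  ta <- make_test_assembly(g$assembly, gap_spec = spec)
  list(gen = g, ta = ta)
}

test_that("contigs of an unmodified result are found at their positions", {
  tb <- toy_bench()
  pl <- locate_contigs(tb$ta$assembly, tb$ta$assembly)
  expect_true(all(pl$status == "found"))
  expect_true(all(pl$strand == "+"))
})

test_that("contigs flanking a small inserted patch are still found", {
  tb <- toy_bench(92)
  res_seq <- scaffold_seq(tb$ta$assembly[[1]])
  gt <- gap_table(tb$ta$assembly)[1, ]
  # replace the N-run by 5 arbitrary bases
  res_seq <- paste0(substr(res_seq, 1, gt$begin), "ACGTA",
                    substr(res_seq, gt$end + 1, nchar(res_seq)))
  res <- assembly_from_parts(setNames(list(list(res_seq)),
                                      names(tb$ta$assembly)[1]))
  pl <- locate_contigs(tb$ta$assembly, res)
  ids <- c(gt$left_contig, gt$right_contig)
  expect_true(all(pl$status[pl$contig_id %in% ids] == "found"))
})

test_that("contigs duplicated within the test assembly are excluded", {
  set.seed(93)
  dup <- random_seq(2000)
  asm <- assembly_from_parts(list(s1 = list(dup, 50L, random_seq(2000)),
                                  s2 = list(dup)))
  pl <- locate_contigs(asm, asm, crop_ambiguous = 100L)
  expect_equal(pl$status[pl$contig_id == "s1.1"], "duplicated")
  expect_equal(pl$status[pl$contig_id == "s2.1"], "duplicated")
  expect_equal(pl$status[pl$contig_id == "s1.2"], "found")
})

test_that("imperfect recovery finds contigs modified below the threshold", {
  set.seed(94)
  contig <- random_seq(3000)
  asm <- assembly_from_parts(list(s1 = list(contig)))
  mutated <- contig
  for (p in sample.int(2900, 20)) substr(mutated, p, p) <- "A"
  res <- assembly_from_parts(list(r1 = list(mutated)))
  pl0 <- locate_contigs(asm, res)
  expect_equal(pl0$status, "missing")
  pl1 <- locate_contigs(asm, res, recover_imperfect = TRUE)
  expect_equal(pl1$status, "found")
})

test_that("gap states follow the published rules in order", {
  set.seed(95)
  left <- random_seq(2000); right <- random_seq(2000)
  truth_seq <- random_seq(150)
  ta <- assembly_from_parts(list(t1 = list(left, 150L, right)))
  truth <- data.frame(gap_id = "g1", contig_id = "t1", scaffold_id = "chr",
                      begin = 2000L, end = 2150L, ref_begin = 2000L,
                      ref_end = 2150L, truth_seq = truth_seq,
                      stringsAsFactors = FALSE)
  classify_with <- function(result) {
    pl <- locate_contigs(ta, result)
    classify_gaps(pl, truth, ta, result)
  }
  # closed, exact insert
  closed <- assembly_from_parts(list(r = list(paste0(left, truth_seq,
                                                     right))))
  rec <- classify_with(closed)
  expect_equal(rec$state, "closed")
  expect_equal(rec$identity, 1.0)
  # closed on the reverse strand
  closed_rc <- assembly_from_parts(list(r = list(
    revcomp(paste0(left, truth_seq, right)))))
  rec <- classify_with(closed_rc)
  expect_equal(rec$state, "closed")
  expect_equal(rec$identity, 1.0)
  # unclosed: still an N-run between adjacent result contigs
  rec <- classify_with(ta)
  expect_equal(rec$state, "unclosed")
  # broken: flanks on non-adjacent contigs
  broken <- assembly_from_parts(list(r = list(
    paste0(left, strrep("N", 50), random_seq(3000), strrep("N", 50),
           right))))
  rec <- classify_with(broken)
  expect_equal(rec$state, "broken")
  # unknown: one flank missing entirely
  unknown <- assembly_from_parts(list(r = list(left)))
  rec <- classify_with(unknown)
  expect_equal(rec$state, "unknown")
})

test_that("gap identity is the published alignment-length fraction", {
  set.seed(96)
  truth <- random_seq(20)
  ins <- truth
  substr(ins, 7, 7) <- setdiff(c("A", "C", "G", "T"),
                               substr(truth, 7, 7))[1]
  expect_equal(gap_identity(ins, truth), 0.95)
  expect_equal(gap_identity(truth, truth), 1.0)
  expect_equal(gap_identity("", random_seq(100)), 0)
  expect_equal(gap_identity("", ""), 1)
  # symmetric and equal to 1 - normalized edit distance on fixtures
  a <- random_seq(300); b <- clr_mutate(a, 0.05)
  expect_equal(gap_identity(a, b), gap_identity(b, a))
})

test_that("summaries compute means, weighted means and identity bins", {
  rec <- data.frame(gap_id = c("a", "b"), state = "closed",
                    identity = c(1.0, 0.9), truth_len = c(100L, 900L),
                    inserted_len = c(100L, 900L))
  s <- summarize_gap_records(rec)
  expect_equal(s$mean_id, 0.95)
  expect_equal(s$weighted_id, 0.91)
  expect_equal(sum(s$bins), 2L)
  # bin edges: 0.99 in [0.99, 1), exact 1.0 in {1}
  rec2 <- data.frame(gap_id = c("a", "b"), state = "closed",
                     identity = c(0.99, 1.0), truth_len = 10L,
                     inserted_len = 10L)
  b <- summarize_gap_records(rec2)$bins
  expect_equal(unname(b[["[0.99,1)"]]), 1L)
  expect_equal(unname(b[["{1}"]]), 1L)
  # no closed gaps: NA means
  rec3 <- data.frame(gap_id = "a", state = "unclosed", identity = NA_real_,
                     truth_len = 10L, inserted_len = NA_integer_)
  expect_true(is.na(summarize_gap_records(rec3)$mean_id))
})

test_that("NG statistics match the definition and a sorted-prefix oracle", {
  asm <- assembly_from_parts(list(
    a = list(strrep("A", 50)), b = list(strrep("C", 30)),
    c = list(strrep("G", 20))))
  ng <- ng_stats(asm, 100)
  expect_equal(ng$ng50, 50L)
  one <- assembly_from_parts(list(a = list(strrep("A", 500))))
  ng1 <- ng_stats(one, 500)
  expect_true(all(ng1$ng(c(1, 50, 100)) == 500L))
  # exhausted contigs: NG(x) = 0
  expect_equal(ng_stats(asm, 1000)$ng50, 0L)
  # random oracle
  set.seed(97)
  for (rep in 1:10) {
    lens <- sample(50:5000, 12L)
    asm <- assembly_from_parts(setNames(
      lapply(lens, function(l) list(strrep("A", l))),
      paste0("c", seq_along(lens))))
    G <- sum(lens)
    ng <- ng_stats(asm, G)
    sorted <- sort(lens, decreasing = TRUE)
    want <- sorted[which(cumsum(sorted) >= 0.5 * G)[1]]
    expect_equal(ng$ng50, want)
  }
})

test_that("evaluating the ground truth against its test assembly is exact", {
  tb <- toy_bench(98, n_gaps = 4L)
  ev <- evaluate_gap_closing(tb$ta$assembly, tb$gen$assembly, tb$ta$truth)
  expect_equal(ev$summary$n_closed, nrow(tb$ta$truth))
  expect_true(all(ev$records$identity == 1.0))
  expect_equal(ev$summary$n_broken, 0L)
  G <- sum(contig_table(tb$gen$assembly)$length)
  expect_equal(ev$ng$ng50, ng_stats(tb$gen$assembly, G)$ng50)
})
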