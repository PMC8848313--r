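test_that("dust masking flags low-complexity and spares random sequence", {
  expect_equal(mask_width(dust_mask(c(x = strrep("A", 200)))), 200L)
  set.seed(21)
  r <- random_seq(10000)
  expect_lte(mask_width(dust_mask(c(x = r))), 0.01 * 10000)
  m <- dust_mask(c(x = strrep("ACGT", 50)))
  expect_gte(mask_width(m), 150L)
})

test_that("tandem masking finds period-bounded arrays", {
  set.seed(22)
  unit <- random_seq(17)
  arr <- strrep(unit, 20)
  m <- tandem_mask(c(x = arr))
  expect_gte(mask_width(m, "x"), 0.9 * nchar(arr))
  expect_equal(nrow(tandem_mask(c(x = random_seq(5000)))), 0L)
  expect_gte(mask_width(tandem_mask(c(x = strrep("A", 100)))), 90L)
})

test_that("self-alignment mask equals the per-base depth oracle", {
  # depth profile [3,3,4,5,4,3] over six positions via stacked intervals
  alns <- do.call(rbind, list(
    aln_row(query_id = "q", target_id = "c", tbeg = 0L, tend = 6L),
    aln_row(query_id = "q", target_id = "c", tbeg = 0L, tend = 6L),
    aln_row(query_id = "q", target_id = "c", tbeg = 0L, tend = 6L),
    aln_row(query_id = "q", target_id = "c", tbeg = 2L, tend = 5L),
    aln_row(query_id = "q", target_id = "c", tbeg = 3L, tend = 4L)))
  # count only the target side for a direct depth check
  m <- depth_mask(alns$target_id, alns$tbeg, alns$tend, 4L)
  expect_equal(m$begin, 2L)
  expect_equal(m$end, 5L)
  expect_equal(nrow(self_alignment_mask(empty_alignments())), 0L)
})

test_that("depth masks agree with the boolean-array oracle on random input", {
  set.seed(23)
  for (rep in 1:10) {
    k <- 30L
    b <- sample.int(900L, k)
    e <- pmin(1000L, b + sample.int(200L, k))
    thr <- sample(2:5, 1)
    got <- depth_mask(rep("s", k), b, e, thr, strict = (rep %% 2 == 0))
    want <- depth_oracle(1000L, b, e, thr, strict = (rep %% 2 == 0))
    expect_equal(got$begin, want$begin)
    expect_equal(got$end, want$end)
  }
})

test_that("compute_cmax matches brute-force Poisson tail summation", {
  brute <- function(C, tail_prob = 1e-3) {
    m <- 0L
    # term-by-term pmf summation
    repeat {
      tail <- 1 - sum(dpois(0:m, C))
      if (tail < tail_prob) return(m)
      m <- m + 1L
    }
  }
  for (C in c(1, 5, 10, 25, 50))
    expect_equal(compute_cmax(C), brute(C))
  # monotone in C
  cm <- vapply(c(1, 2, 5, 10, 20, 40, 80), compute_cmax, 0L)
  expect_true(all(diff(cm) >= 0))
  expect_error(compute_cmax(0))
  expect_error(compute_cmax(-3))
})

test_that("read-coverage mask uses a strict depth threshold", {
  alns <- do.call(rbind, lapply(1:4, function(i)
    aln_row(query_id = paste0("r", i), target_id = "c", tbeg = 0L,
            tend = 100L)))
  expect_equal(nrow(read_coverage_mask(alns, 4L)), 0L)  # depth == C_max
  expect_equal(mask_width(read_coverage_mask(alns, 3L)), 100L)
})

test_that("is_proper applies the unaligned-end allowance", {
  ok <- aln_row(query_len = 10000L, qbeg = 50L, qend = 9950L,
                tbeg = 4000L, tend = 9000L, target_len = 20000L)
  expect_true(is_proper(ok))
  bad <- aln_row(query_len = 10000L, qbeg = 500L, qend = 9950L,
                 tbeg = 4000L, tend = 9000L, target_len = 20000L)
  expect_false(is_proper(bad, ignore_boundaries = TRUE))
  expect_false(is_proper(bad))
  # a clipped end that abuts the contig boundary is explained, not improper
  gap_span <- aln_row(query_len = 10000L, qbeg = 4000L, qend = 9950L,
                      tbeg = 0L, tend = 5950L, target_len = 20000L)
  expect_false(is_proper(gap_span, ignore_boundaries = TRUE))
  expect_true(is_proper(gap_span))
})

test_that("improper coverage masks loci attracting partial alignments", {
  proper <- do.call(rbind, lapply(1:6, function(i)
    aln_row(query_id = paste0("p", i), query_len = 1000L, qbeg = 10L,
            qend = 990L, tbeg = 2000L, tend = 2980L, target_len = 10000L)))
  expect_equal(nrow(improper_coverage_mask(proper, 2)), 0L)
  improper <- do.call(rbind, lapply(1:6, function(i)
    aln_row(query_id = paste0("i", i), query_len = 5000L, qbeg = 2000L,
            qend = 3000L, tbeg = 4000L, tend = 5000L, target_len = 10000L)))
  m <- improper_coverage_mask(improper, 2)
  expect_equal(m$begin, 4000L)
  expect_equal(m$end, 5000L)
})

test_that("homogenization spreads masks through read alignments", {
  # no reads: union of inputs
  m1 <- mask_track("c1", 0L, 100L)
  m2 <- mask_track("c1", 300L, 400L)
  expect_equal(as.data.frame(homogenize(list(m1, m2), empty_alignments())),
               as.data.frame(mask_union(m1, m2)))
  # a read aligning repeat copy 1 and copy 2 transfers the mask
  aln <- rbind(
    aln_row(query_id = "r", query_len = 2000L, qbeg = 0L, qend = 1000L,
            target_id = "c1", tbeg = 0L, tend = 1000L, target_len = 1000L),
    aln_row(query_id = "r", query_len = 2000L, qbeg = 0L, qend = 1000L,
            target_id = "c2", tbeg = 500L, tend = 1500L, target_len = 2000L))
  mask <- mask_track("c1", 100L, 400L)
  hm <- homogenize(list(mask), aln)
  d2 <- hm[hm$seq_id == "c2", ]
  expect_equal(nrow(d2), 1L)
  expect_equal(c(d2$begin, d2$end), c(600L, 900L))
  # superset of input union and idempotent
  expect_equal(mask_width(mask_intersect(hm, mask)), mask_width(mask))
  expect_equal(as.data.frame(homogenize(list(hm), aln)), as.data.frame(hm))
})
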