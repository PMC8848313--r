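# Shared fixture builders: everything is generated in code at test time.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

clr_mutate <- function(seq, error) spanweld:::mutate_seq_clr(seq, error)

# Minimal alignment row with sensible defaults.
aln_row <- function(query_id = "r1", query_len = 1000L, qbeg = 0L,
                    qend = 1000L, strand = "+", target_id = "c1",
                    target_len = 10000L, tbeg = 0L, tend = 1000L,
                    n_match = NULL, cigar = NA_character_) {
  if (is.null(n_match)) n_match <- min(qend - qbeg, tend - tbeg)
  spanweld:::as_alignments(data.frame(
    query_id = query_id, query_len = query_len, qbeg = qbeg, qend = qend,
    strand = strand, target_id = target_id, target_len = target_len,
    tbeg = tbeg, tend = tend, n_match = n_match,
    aln_len = max(qend - qbeg, tend - tbeg), mapq = 60L, cigar = cigar,
    chain_id = NA_integer_, stringsAsFactors = FALSE))
}

# A pile-up object holding pre-cropped, co-oriented reads.
cropped_pileup <- function(seqs, roles = rep("span", length(seqs))) {
  ids <- if (is.null(names(seqs))) paste0("r", seq_along(seqs))
         else names(seqs)
  structure(list(id = "test", contig_a = "A", side_a = "end",
                 contig_b = "B", side_b = "begin", span_reads = ids,
                 ext_a = character(), ext_b = character(), reads = ids,
                 is_input_gap = TRUE,
                 cropped = data.frame(read_id = ids, role = roles,
                                      seq = unname(seqs),
                                      stringsAsFactors = FALSE)),
            class = "spanweld_pileup")
}

# Brute-force per-base mask oracle: depth counting on a boolean array.
depth_oracle <- function(seq_len, begins, ends, threshold, strict = FALSE) {
  depth <- integer(seq_len)
  for (i in seq_along(begins)) {
    idx <- seq(begins[i] + 1L, ends[i])
    depth[idx] <- depth[idx] + 1L
  }
  hit <- if (strict) depth > threshold else depth >= threshold
  r <- rle(hit)
  ends_r <- cumsum(r$lengths)
  begins_r <- ends_r - r$lengths
  data.frame(begin = begins_r[r$values], end = ends_r[r$values])
}

# Exhaustive chaining oracle: enumerate every valid chain (all paths in the
# chainability DAG) and return the minimum total weight.
chain_oracle <- function(alns, max_indel = 1000L, max_chain_gap = 10000L,
                         max_relative_overlap = 0.3) {
  n <- nrow(alns)
  t1 <- ifelse(alns$strand == "-", alns$target_len - alns$tend, alns$tbeg)
  t2 <- ifelse(alns$strand == "-", alns$target_len - alns$tbeg, alns$tend)
  node_w <- -((alns$qend - alns$qbeg) + (t2 - t1)) / 2
  ew <- function(i, j) {
    if (alns$strand[i] != alns$strand[j]) return(NA_real_)
    if (!(alns$qbeg[i] < alns$qbeg[j] && t1[i] < t1[j])) return(NA_real_)
    gap_a <- alns$qbeg[j] - alns$qend[i]
    gap_b <- t1[j] - t2[i]
    gsd <- abs(gap_a - gap_b)
    if (gsd >= max_indel) return(NA_real_)
    if (gap_a >= max_chain_gap || gap_b >= max_chain_gap) return(NA_real_)
    len_q <- min(alns$qend[i] - alns$qbeg[i], alns$qend[j] - alns$qbeg[j])
    len_t <- min(t2[i] - t1[i], t2[j] - t1[j])
    rel <- max(max(0, -gap_a) / max(len_q, 1), max(0, -gap_b) / max(len_t, 1))
    if (rel > max_relative_overlap) return(NA_real_)
    gsd + 0.1 * max(abs(gap_a), abs(gap_b))
  }
  best <- Inf
  extend <- function(last, score) {
    best <<- min(best, score)
    for (j in seq_len(n)) {
      w <- ew(last, j)
      if (!is.na(w)) extend(j, score + w + node_w[j])
    }
  }
  for (i in seq_len(n)) extend(i, node_w[i])
  best
}

# Random chaining instance between two pseudo-reads.
random_chain_instance <- function(n) {
  qb <- sort(sample.int(5000, n))
  ql <- sample(100:1200, n, replace = TRUE)
  tb <- pmax(0L, qb + sample(-800:800, n, replace = TRUE))
  tl <- sample(100:1200, n, replace = TRUE)
  spanweld:::as_alignments(data.frame(
    query_id = "A", query_len = 10000L, qbeg = qb, qend = qb + ql,
    strand = sample(c("+", "-"), n, replace = TRUE, prob = c(0.8, 0.2)),
    target_id = "B", target_len = 10000L, tbeg = tb, tend = tb + tl,
    n_match = pmin(ql, tl), aln_len = pmax(ql, tl), mapq = 60L,
    cigar = NA_character_, chain_id = NA_integer_,
    stringsAsFactors = FALSE))
}

# Small two-contig assembly with one gap, error-free spanning reads.
two_contig_fixture <- function(seed = 42, gap_len = 300L, contig_len = 4000L,
                               n_reads = 4L, read_len = 3000L, error = 0) {
  set.seed(seed)
  genome <- random_seq(2L * contig_len + gap_len)
  left <- substr(genome, 1, contig_len)
  gap_truth <- substr(genome, contig_len + 1L, contig_len + gap_len)
  right <- substr(genome, contig_len + gap_len + 1L, nchar(genome))
  assembly <- assembly_from_parts(list(s1 = list(left, gap_len, right)))
  centre <- contig_len + gap_len %/% 2L
  reads <- setNames(vapply(seq_len(n_reads), function(i) {
    start <- centre - read_len %/% 2L - 50L * i
    r <- substr(genome, start + 1L, start + read_len)
    if (error > 0) r <- clr_mutate(r, error)
    r
  }, ""), paste0("read", seq_len(n_reads)))
  list(assembly = assembly, reads = reads, genome = genome,
       gap_truth = gap_truth)
}
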