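#' Crop a pile-up to common reference positions
#'
#' Chooses one cropping position on each flanking contig such that every
#' spanning read's alignment reaches it (keeping as much flank overlap as
#' possible, capped at `flank_cap` to bound downstream work), trims each
#' read via its trace to the read coordinates projecting onto those
#' positions, and reverse-complements reads as needed so all cropped reads
#' share the gap's left-to-right orientation. Extending reads are cropped on
#' their single flank; reads that do not reach the chosen position are
#' dropped.
#'
#' The "gap frame" orients contig A so that its `side_a` end faces right
#' (into the gap) and contig B so that its `side_b` end faces left.
#'
#' @param pileup A `spanweld_pileup` from [prune_and_collect()].
#' @param reads Named character vector of read sequences.
#' @param contigs Named character vector of contig sequences.
#' @param flank_cap Maximum retained flank length in bp (default 3000).
#' @return The pile-up with elements `cropped` (data.frame: `read_id`,
#'   `role`, `seq`), `crop_a`, `crop_b` (contig coordinates), `flank_a`,
#'   `flank_b` (gap-frame flank sequences).
#' @export
crop_pileup <- function(pileup, reads, contigs, flank_cap = 3000L) {
  A <- pileup$contig_a; B <- pileup$contig_b
  lenA <- nchar(contigs[[A]]); lenB <- nchar(contigs[[B]])
  alnA <- pileup$alns[pileup$alns$target_id == A, , drop = FALSE]
  alnB <- pileup$alns[pileup$alns$target_id == B, , drop = FALSE]
  best_aln <- function(d, rid) {
    d <- d[d$query_id == rid, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    d[which.max(d$n_match), , drop = FALSE]
  }
  # crop position on a contig: common position all spanning reads reach
  span_pos <- function(d, side, len) {
    per_read <- vapply(intersect(pileup$span_reads, d$query_id),
                       function(rid) {
      a <- best_aln(d, rid)
      if (side == "end") a$tbeg else a$tend
    }, 0)
    if (side == "end") max(c(per_read, len - flank_cap))
    else min(c(per_read, flank_cap))
  }
  crop_a <- span_pos(alnA, pileup$side_a, lenA)
  crop_b <- span_pos(alnB, pileup$side_b, lenB)
  # A read matches the gap frame when its strand on A is '+' iff side_a is
  # "end" (A kept forward), and on B '+' iff side_b is "begin".
  flip_a <- function(a) xor(a$strand == "-", pileup$side_a == "begin")
  flip_b <- function(a) xor(a$strand == "-", pileup$side_b == "end")
  rows <- list()
  for (rid in pileup$reads) {
    role <- if (rid %in% pileup$span_reads) "span"
            else if (rid %in% pileup$ext_a) "ext_a" else "ext_b"
    aA <- best_aln(alnA, rid); aB <- best_aln(alnB, rid)
    seq <- reads[[rid]]; qlen <- nchar(seq)
    qa <- qb <- NULL; flip <- NA
    if (!is.null(aA)) {
      flip <- flip_a(aA)
      if (crop_a < aA$tbeg || crop_a > aA$tend) { if (role != "ext_b") next }
      else qa <- project_target_pos(aA, crop_a)
    }
    if (!is.null(aB)) {
      if (is.na(flip)) flip <- flip_b(aB)
      if (crop_b < aB$tbeg || crop_b > aB$tend) { if (role != "ext_a") next }
      else qb <- project_target_pos(aB, crop_b)
    }
    if (role == "span" && (is.null(qa) || is.null(qb))) next
    if (role == "ext_a" && is.null(qa)) next
    if (role == "ext_b" && is.null(qb)) next
    pos <- c(if (!is.null(qa)) qa, if (!is.null(qb)) qb)
    if (isTRUE(flip)) pos <- qlen - pos
    lo <- if (role == "ext_b") 0L else min(pos)
    hi <- if (role == "ext_a") qlen else max(pos)
    if (role == "span") { lo <- min(pos); hi <- max(pos) }
    if (hi - lo < 50L) next
    oseq <- if (isTRUE(flip)) revcomp(seq) else seq
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = rid, role = role, seq = substr(oseq, lo + 1L, hi),
      stringsAsFactors = FALSE)
  }
  cropped <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(), role = character(), seq = character())
  pileup$cropped <- cropped
  pileup$crop_a <- crop_a
  pileup$crop_b <- crop_b
  pileup$flank_a <- if (pileup$side_a == "end")
    substr(contigs[[A]], crop_a + 1L, lenA)
  else revcomp(substr(contigs[[A]], 1L, crop_a))
  pileup$flank_b <- if (pileup$side_b == "begin")
    substr(contigs[[B]], 1L, crop_b)
  else revcomp(substr(contigs[[B]], crop_b + 1L, lenB))
  pileup
}

#' Chain local alignments between two reads
#'
#' Reduces alignment chaining to shortest paths on a weighted DAG. Every
#' local alignment is a node with negative weight equal to minus the mean
#' base pairs it covers on the two reads. Two alignments x, y (same
#' orientation, x strictly before y on both reads) are connected when the
#' difference between their unaligned gaps on the two reads,
#' `gapSizeDiff(x,y) = |gap_A - gap_B|`, is below `max_indel`, both gaps are
#' below `max_chain_gap`, and their relative overlap (overlap over the
#' shorter alignment, on either read) is at most `max_relative_overlap`; the
#' edge weight is `gapSizeDiff + 0.1 * max(|gap_A|, |gap_B|)`. The
#' minimum-weight (maximal shortest) path is the best chain; ties are broken
#' toward more aligned bases, then the leftmost start.
#'
#' @param alns Alignment table: all local alignments between one read pair.
#' @param max_indel Maximum `gapSizeDiff` in bp (default 1000).
#' @param max_chain_gap Maximum per-read gap in bp (default 10000).
#' @param max_relative_overlap Maximum relative overlap (default 0.3).
#' @return List with `members` (row indices of the chain, in order),
#'   `score`, `aligned_bp`; or `NULL` for an empty input.
#' @export
chain_alignments <- function(alns, max_indel = 1000L, max_chain_gap = 10000L,
                             max_relative_overlap = 0.3) {
  n <- nrow(alns)
  if (!n) return(NULL)
  # target coordinates in traversal frame (reverse for '-' strand)
  t1 <- ifelse(alns$strand == "-", alns$target_len - alns$tend, alns$tbeg)
  t2 <- ifelse(alns$strand == "-", alns$target_len - alns$tbeg, alns$tend)
  node_w <- -((alns$qend - alns$qbeg) + (t2 - t1)) / 2
  edge_w <- function(i, j) {
    if (alns$strand[i] != alns$strand[j]) return(NA_real_)
    if (!(alns$qbeg[i] < alns$qbeg[j] && t1[i] < t1[j])) return(NA_real_)
    gap_a <- alns$qbeg[j] - alns$qend[i]
    gap_b <- t1[j] - t2[i]
    gsd <- abs(gap_a - gap_b)
    if (gsd >= max_indel) return(NA_real_)
    if (gap_a >= max_chain_gap || gap_b >= max_chain_gap) return(NA_real_)
    len_q <- pmin(alns$qend[i] - alns$qbeg[i], alns$qend[j] - alns$qbeg[j])
    len_t <- pmin(t2[i] - t1[i], t2[j] - t1[j])
    rel <- max(max(0, -gap_a) / max(len_q, 1L),
               max(0, -gap_b) / max(len_t, 1L))
    if (rel > max_relative_overlap) return(NA_real_)
    gsd + 0.1 * max(abs(gap_a), abs(gap_b))
  }
  ord <- order(alns$qbeg, t1)
  best <- node_w
  pred <- rep(NA_integer_, n)
  for (jj in seq_len(n)) {
    j <- ord[jj]
    for (ii in seq_len(jj - 1L)) {
      i <- ord[ii]
      w <- edge_w(i, j)
      if (is.na(w)) next
      cand <- best[i] + w + node_w[j]
      if (cand < best[j] - 1e-9) { best[j] <- cand; pred[j] <- i }
    }
  }
  ends <- which(abs(best - min(best)) < 1e-9)
  trace_chain <- function(j) {
    m <- integer()
    while (!is.na(j)) { m <- c(j, m); j <- pred[j] }
    m
  }
  chains <- lapply(ends, trace_chain)
  bp <- vapply(chains, function(m)
    sum((alns$qend[m] - alns$qbeg[m]) + (t2[m] - t1[m])) / 2, 0)
  starts <- vapply(chains, function(m) min(alns$qbeg[m]), 0)
  pick <- order(-bp, starts)[1]
  list(members = chains[[pick]], score = best[ends[pick]],
       aligned_bp = bp[pick])
}

# Stitch a chain's member alignments into one composite alignment against
# the chain's target; overlaps are trimmed from the later alignment's trace.
stitch_chain <- function(alns, members) {
  d <- alns[members, , drop = FALSE]
  if (any(d$strand == "-")) {
    tb <- d$target_len - d$tend; te <- d$target_len - d$tbeg
    d$tbeg <- tb; d$tend <- te  # traversal frame
  }
  cigar <- d$cigar[1]
  qpos <- d$qend[1]; tpos <- d$tend[1]
  if (nrow(d) > 1) {
    for (i in 2:nrow(d)) {
      gq <- d$qbeg[i] - qpos; gt <- d$tbeg[i] - tpos
      cg <- d$cigar[i]
      if (gq < 0) { cg <- trim_cigar_front(cg, -gq, 0L); gq <- 0L }
      if (gt < 0) { cg <- trim_cigar_front(cg, 0L, -gt); gt <- 0L }
      mid <- paste0(if (gq > 0) paste0(gq, "I"), if (gt > 0) paste0(gt, "D"))
      cigar <- paste0(cigar, mid, cg)
      qpos <- d$qend[i]; tpos <- d$tend[i]
    }
  }
  list(qbeg = d$qbeg[1], qend = qpos, tbeg = d$tbeg[1], tend = tpos,
       strand = d$strand[1], cigar = cigar)
}

trim_cigar_front <- function(cigar, q_trim, t_trim) {
  tt <- cpp_cigar_runs(cigar)
  op <- tt$op; len <- tt$len
  qd <- 0L; td <- 0L; i <- 1L
  while (i <= length(op) && (qd < q_trim || td < t_trim)) {
    cq <- op[i] %in% c("=", "X", "I", "M")
    ct <- op[i] %in% c("=", "X", "D", "M")
    need_q <- if (cq) q_trim - qd else 0L
    need_t <- if (ct) t_trim - td else 0L
    take <- min(len[i], max(need_q, need_t, 0L))
    if (take <= 0L) break
    if (take < len[i]) {
      len[i] <- len[i] - take
      if (cq) qd <- qd + take
      if (ct) td <- td + take
      break
    }
    if (cq) qd <- qd + len[i]
    if (ct) td <- td + len[i]
    op <- op[-i]; len <- len[-i]
  }
  paste0(len, op, collapse = "")
}

#' Pairwise chains among cropped pile-up reads
#'
#' Aligns every pair of cropped reads with the built-in local aligner and
#' chains the resulting local alignments. Returns one composite alignment
#' per pair (query read, target read) for quality estimation and consensus.
#'
#' @param pileup A cropped pile-up ([crop_pileup()]).
#' @param config A [pipeline_config()].
#' @param max_pairs_per_read Bound on alignment partners per read, taken in
#'   a fixed order (default 6) to keep deep pile-ups tractable.
#' @return `data.frame` of composite alignments with the usual columns.
#' @export
pileup_chains <- function(pileup, config = pipeline_config(),
                          max_pairs_per_read = 6L) {
  cr <- pileup$cropped
  n <- nrow(cr)
  if (n < 2) return(empty_alignments())
  rows <- list()
  for (i in seq_len(n - 1)) {
    partners <- seq(i + 1L, min(n, i + max_pairs_per_read))
    for (j in partners) {
      hits <- align_pair(cr$seq[i], cr$seq[j], mode = "local",
                         max_err = config$max_err, min_len = 100L,
                         both_strands = FALSE,
                         query_id = cr$read_id[i], target_id = cr$read_id[j])
      if (!nrow(hits)) next
      ch <- chain_alignments(hits, config$max_indel, config$max_chain_gap,
                             config$max_relative_overlap)
      st <- stitch_chain(hits, ch$members)
      stats <- cigar_stats(st$cigar)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = cr$read_id[i], query_len = nchar(cr$seq[i]),
        qbeg = st$qbeg, qend = st$qend, strand = "+",
        target_id = cr$read_id[j], target_len = nchar(cr$seq[j]),
        tbeg = st$tbeg, tend = st$tend, n_match = stats$n_match,
        aln_len = stats$aln_len, mapq = 60L, cigar = st$cigar,
        chain_id = length(rows) + 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_alignments())
  as_alignments(do.call(rbind, rows))
}

#' Intrinsic quality values from pairwise chains
#'
#' Tiles each cropped read into windows and scores every window by the mean
#' per-base difference rate of the chained alignments covering it, derived
#' from the traces. Windows covered by no alignment get the worst quality
#' (1.0). These intrinsic QVs need no instrument base qualities.
#'
#' @param pileup A cropped pile-up.
#' @param chains Output of [pileup_chains()].
#' @param window Window size in bp (default 100).
#' @return Named list (by read id) of numeric QV vectors, one per window.
#' @export
intrinsic_qv <- function(pileup, chains, window = 100L) {
  cr <- pileup$cropped
  out <- list()
  for (i in seq_len(nrow(cr))) {
    rid <- cr$read_id[i]
    len <- nchar(cr$seq[i])
    nw <- max(1L, as.integer(ceiling(len / window)))
    err <- numeric(nw); cov <- numeric(nw)
    add_side <- function(d, side) {
      for (k in seq_len(nrow(d))) {
        a <- d[k, ]
        prof <- aln_window_profile(a, side, window, len)
        err <<- err + prof$err
        cov <<- cov + prof$cov
      }
    }
    add_side(chains[chains$query_id == rid, , drop = FALSE], "query")
    add_side(chains[chains$target_id == rid, , drop = FALSE], "target")
    qv <- ifelse(cov > 0, err / pmax(cov, 1), 1.0)
    out[[rid]] <- pmin(qv, 1.0)
  }
  out
}

# Per-window error and coverage of one alignment on one of its reads.
aln_window_profile <- function(aln, side, window, read_len) {
  nw <- max(1L, as.integer(ceiling(read_len / window)))
  err <- numeric(nw); cov <- numeric(nw)
  tt <- trace_tables(aln$cigar)
  pos <- if (side == "query") aln$qbeg else aln$tbeg
  for (r in seq_along(tt$op)) {
    adv <- if (side == "query") tt$qadv[r] else tt$tadv[r]
    is_err <- tt$op[r] != "="
    if (adv > 0) {
      p0 <- pos; p1 <- pos + adv
      w0 <- p0 %/% window; w1 <- (p1 - 1L) %/% window
      for (w in w0:w1) {
        lo <- max(p0, w * window); hi <- min(p1, (w + 1L) * window)
        if (w + 1L <= nw) {
          cov[w + 1L] <- cov[w + 1L] + (hi - lo)
          if (is_err) err[w + 1L] <- err[w + 1L] + (hi - lo)
        }
      }
      pos <- p1
    } else if (is_err) {
      w <- min(pos %/% window, nw - 1L)
      err[w + 1L] <- err[w + 1L] + tt$len[r]
    }
  }
  list(err = err, cov = cov)
}

#' Select the reference read of a pile-up
#'
#' A window QV is "bad" when it lies in the worst `bad_fraction` of all
#' window QVs pooled over the pile-up; the spanning read with the fewest bad
#' windows becomes the reference for consensus. Ties go to the longer
#' cropped read, then the lexicographically smaller id.
#'
#' @param pileup A cropped pile-up.
#' @param qvs Output of [intrinsic_qv()].
#' @param bad_fraction Fraction of QVs considered bad (default 0.08).
#' @return Reference read id.
#' @export
select_reference_read <- function(pileup, qvs, bad_fraction = 0.08) {
  cr <- pileup$cropped
  cand <- cr[cr$role == "span", , drop = FALSE]
  if (!nrow(cand)) cand <- cr
  stopifnot(nrow(cand) >= 1)
  all_qv <- unlist(qvs[cand$read_id], use.names = FALSE)
  thr <- stats::quantile(all_qv, 1 - bad_fraction, names = FALSE, type = 7)
  bad <- vapply(cand$read_id, function(rid) sum(qvs[[rid]] > thr), 0)
  lens <- nchar(cand$seq)
  cand$read_id[order(bad, -lens, cand$read_id)[1]]
}

#' Reference-guided pile-up consensus
#'
#' Two-stage consensus. A partial-order alignment (POA) graph is seeded
#' with the reference read; every other cropped read is aligned to the
#' graph (banded around each node's position estimate, shifted by the
#' read's start offset on the reference) and integrated, and the draft is
#' the heaviest edge bundle — matched bases accumulate support across reads
#' independently of any single read's errors. The draft is then polished by
#' deterministic windowed voting: per window (default 100 bp, advancing 50
#' bp) a strict-majority identical realization wins outright, otherwise
#' each position takes the plurality of the aligned read columns (base,
#' deletion, or base plus following insertion), ties resolved toward the
#' draft. Positions no read covers are taken from the reference verbatim.
#'
#' @param pileup A cropped pile-up.
#' @param reference_read Reference read id ([select_reference_read()]).
#' @param chains Output of [pileup_chains()] (re-used for read offsets).
#' @param config A [pipeline_config()].
#' @param window,step Polish window geometry in bp.
#' @param rounds Polish rounds (default 2).
#' @return Consensus DNA string in the gap frame.
#' @export
pileup_consensus <- function(pileup, reference_read, chains = NULL,
                             config = pipeline_config(), window = 100L,
                             step = 50L, rounds = 2L) {
  cr <- pileup$cropped
  ref_seq <- cr$seq[cr$read_id == reference_read]
  stopifnot(length(ref_seq) == 1)
  others <- cr[cr$read_id != reference_read, , drop = FALSE]
  others <- others[order(others$role != "span", -nchar(others$seq)), ,
                   drop = FALSE]
  seqs <- ref_seq
  offs <- 0L
  for (i in seq_len(nrow(others))) {
    st <- composite_to_reference(others$seq[i], others$read_id[i],
                                 reference_read, ref_seq, chains, config)
    if (is.null(st)) next
    seqs <- c(seqs, others$seq[i])
    offs <- c(offs, max(0L, st$tbeg - st$qbeg))
  }
  cons <- cpp_poa_consensus(seqs, as.integer(offs), 150L, 2L, -3L, -2L)
  for (r in seq_len(rounds)) {
    draft <- pileup
    draft$cropped <- rbind(
      data.frame(read_id = ".draft", role = "span", seq = cons,
                 stringsAsFactors = FALSE),
      cr[cr$read_id != ".draft", , drop = FALSE])
    nxt <- consensus_round(draft, ".draft", NULL, config, window, step)
    if (identical(nxt, cons)) break
    cons <- nxt
  }
  cons
}

# Composite (chained) alignment of one read against the reference read.
composite_to_reference <- function(seq, read_id, reference_read, ref_seq,
                                   chains, config) {
  if (!is.null(chains)) {
    d <- chains[chains$query_id == read_id &
                  chains$target_id == reference_read, , drop = FALSE]
    if (nrow(d))
      return(list(qbeg = d$qbeg[1], tbeg = d$tbeg[1], cigar = d$cigar[1]))
    d <- chains[chains$target_id == read_id &
                  chains$query_id == reference_read, , drop = FALSE]
    if (nrow(d))
      return(list(qbeg = d$tbeg[1], tbeg = d$qbeg[1],
                  cigar = flip_cigar(d$cigar[1])))
  }
  hits <- align_pair(seq, ref_seq, mode = "local",
                     max_err = config$max_err, min_len = 100L,
                     both_strands = FALSE)
  if (!nrow(hits)) return(NULL)
  ch <- chain_alignments(hits, config$max_indel, config$max_chain_gap,
                         config$max_relative_overlap)
  stitch_chain(hits, ch$members)
}

consensus_round <- function(pileup, reference_read, chains, config, window,
                            step) {
  cr <- pileup$cropped
  ref_seq <- cr$seq[cr$read_id == reference_read]
  stopifnot(length(ref_seq) == 1)
  ref_len <- nchar(ref_seq)
  seqs <- ref_seq; tbegs <- 0L; qbegs <- 0L
  cigars <- paste0(ref_len, "=")
  for (i in seq_len(nrow(cr))) {
    if (cr$read_id[i] == reference_read) next
    st <- NULL
    if (!is.null(chains)) {
      d <- chains[chains$query_id == cr$read_id[i] &
                    chains$target_id == reference_read, , drop = FALSE]
      if (nrow(d)) {
        st <- list(qbeg = d$qbeg[1], tbeg = d$tbeg[1], cigar = d$cigar[1])
      } else {
        d <- chains[chains$target_id == cr$read_id[i] &
                      chains$query_id == reference_read, , drop = FALSE]
        if (nrow(d)) {
          st <- list(qbeg = d$tbeg[1], tbeg = d$qbeg[1],
                     cigar = flip_cigar(d$cigar[1]))
        }
      }
    }
    if (is.null(st)) {
      hits <- align_pair(cr$seq[i], ref_seq, mode = "local",
                         max_err = config$max_err, min_len = 100L,
                         both_strands = FALSE)
      if (!nrow(hits)) next
      ch <- chain_alignments(hits, config$max_indel, config$max_chain_gap,
                             config$max_relative_overlap)
      st <- stitch_chain(hits, ch$members)
    }
    seqs <- c(seqs, cr$seq[i])
    tbegs <- c(tbegs, st$tbeg)
    qbegs <- c(qbegs, st$qbeg)
    cigars <- c(cigars, st$cigar)
  }
  cpp_consensus(ref_len, seqs, as.integer(tbegs), as.integer(qbegs),
                cigars, as.integer(window), as.integer(step))
}

flip_cigar <- function(cigar) {
  tt <- cpp_cigar_runs(cigar)
  op <- tt$op
  op[op == "I"] <- "d"; op[op == "D"] <- "I"; op[op == "d"] <- "D"
  paste0(tt$len, op, collapse = "")
}

#' Anchor a consensus sequence into its flanking contigs
#'
#' Aligns the consensus ends to the retained flank sequence of each contig
#' (free-end-gap alignment), requires at least 95% identity over at least
#' half the minimum anchor length, and places the insert sites at the
#' innermost exact run of `min_anchor_run` or more matching bases, so the
#' contigs themselves are never modified. Failure on either flank marks the
#' insertion failed and the gap stays open.
#'
#' @param consensus Consensus DNA string in the gap frame.
#' @param pileup The cropped pile-up the consensus came from.
#' @param config A [pipeline_config()].
#' @return A `spanweld_insertion`: gap id, contig ends, `seq_core` (the
#'   bases inserted between the anchors), gap-frame anchor offsets, and
#'   `validated` in `{"pending", "fail"}`.
#' @export
anchor_insertion <- function(consensus, pileup, config = pipeline_config()) {
  fa <- pileup$flank_a; fb <- pileup$flank_b
  min_id <- 0.95
  min_span <- max(50L, config$min_anchor_length %/% 2L)
  fail <- function(reason) {
    structure(list(id = pileup$id, contig_a = pileup$contig_a,
                   side_a = pileup$side_a, contig_b = pileup$contig_b,
                   side_b = pileup$side_b, is_input_gap = pileup$is_input_gap,
                   seq_core = NULL, anchor_a = NA_integer_,
                   anchor_b = NA_integer_, validated = "fail",
                   reason = reason), class = "spanweld_insertion")
  }
  if (is.null(fa) || is.null(fb) || !nchar(fa) || !nchar(fb))
    return(fail("missing flank"))
  la <- nchar(fa); lb <- nchar(fb); lc <- nchar(consensus)
  # left flank: align flank_a inside the consensus head
  head_len <- min(lc, la + max(200L, la %/% 4L))
  ha <- align_pair(fa, substr(consensus, 1L, head_len),
                   mode = "semi_global", max_err = 1, both_strands = FALSE)
  if (!nrow(ha) || ha$n_match / ha$aln_len < min_id ||
      ha$qend - ha$qbeg < min(min_span, la))
    return(fail("left flank alignment failed"))
  anc_a <- last_exact_run(ha$cigar, config$min_anchor_run)
  if (is.null(anc_a)) return(fail("no left anchor run"))
  # anchor: end of the last long exact run, in flank and consensus coords
  a_flank <- ha$qbeg + anc_a$q_end
  a_cons <- ha$tbeg + anc_a$t_end
  # right flank: align flank_b inside the consensus tail
  tail_len <- min(lc, lb + max(200L, lb %/% 4L))
  tail_off <- lc - tail_len
  hb <- align_pair(fb, substr(consensus, tail_off + 1L, lc),
                   mode = "semi_global", max_err = 1, both_strands = FALSE)
  if (!nrow(hb) || hb$n_match / hb$aln_len < min_id ||
      hb$qend - hb$qbeg < min(min_span, lb))
    return(fail("right flank alignment failed"))
  anc_b <- first_exact_run(hb$cigar, config$min_anchor_run)
  if (is.null(anc_b)) return(fail("no right anchor run"))
  b_flank <- hb$qbeg + anc_b$q_beg
  b_cons <- tail_off + hb$tbeg + anc_b$t_beg
  if (b_cons < a_cons) return(fail("anchors cross"))
  structure(list(
    id = pileup$id, contig_a = pileup$contig_a, side_a = pileup$side_a,
    contig_b = pileup$contig_b, side_b = pileup$side_b,
    is_input_gap = pileup$is_input_gap,
    seq_core = substr(consensus, a_cons + 1L, b_cons),
    # bases to trim from each contig's gap-facing end before splicing:
    # the consensus core re-represents the flank inside the anchors
    trim_a = la - a_flank, trim_b = b_flank,
    crop_a = pileup$crop_a, crop_b = pileup$crop_b,
    validated = "pending", reason = NA_character_),
    class = "spanweld_insertion")
}

#' @export
print.spanweld_insertion <- function(x, ...) {
  cat("<insertion ", x$id, ": ", if (is.null(x$seq_core)) "failed" else
    paste0(nchar(x$seq_core), " bp core"), ", ", x$validated, ">\n", sep = "")
  invisible(x)
}

# Last (rightmost) exact run of >= k bases in a cigar; returns boundary
# offsets (q_end, t_end) relative to the alignment start.
last_exact_run <- function(cigar, k) {
  tt <- trace_tables(cigar)
  hits <- which(tt$op == "=" & tt$len >= k)
  if (!length(hits)) return(NULL)
  i <- hits[length(hits)]
  list(q_end = tt$q0[i] + tt$len[i], t_end = tt$t0[i] + tt$len[i])
}

first_exact_run <- function(cigar, k) {
  tt <- trace_tables(cigar)
  hits <- which(tt$op == "=" & tt$len >= k)
  if (!length(hits)) return(NULL)
  i <- hits[1]
  list(q_beg = tt$q0[i], t_beg = tt$t0[i])
}
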