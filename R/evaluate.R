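#' Locate the original test contigs in a gap-closed assembly
#'
#' Searches for exact, unique matches of every test contig in the result
#' assembly (both strands). Contigs are first cropped by `crop_ambiguous`
#' per flank for duplicate detection — contigs with more than one exact
#' match within the test assembly itself are excluded — and by
#' `crop_alignment` before the search, tolerating gap closers that modify
#' contig flanks. Optionally, contigs not found exactly are recovered by
#' alignment allowing up to `max_mismatch` mismatches, accepted only when
#' full-length and unique.
#'
#' @param test_assembly The gap-containing input `spanweld_assembly`.
#' @param result_assembly The gap-closer output `spanweld_assembly`.
#' @param crop_ambiguous Flank crop for duplicate detection (default 300).
#' @param crop_alignment Flank crop for the search (default 0).
#' @param recover_imperfect Also search with mismatches (default FALSE).
#' @param max_mismatch Mismatch fraction for recovery (default 0.015).
#' @return data.frame per test contig: `contig_id`, `status`
#'   (`found`/`ambiguous`/`missing`/`duplicated`), result `scaffold_id`,
#'   `begin`, `end` (of the cropped contig), `strand`, `crop` applied.
#' @export
locate_contigs <- function(test_assembly, result_assembly,
                           crop_ambiguous = 300L, crop_alignment = 0L,
                           recover_imperfect = FALSE, max_mismatch = 0.015) {
  ct <- contig_table(test_assembly)
  res_seqs <- Biostrings::DNAStringSet(
    setNames(vapply(result_assembly, scaffold_seq, ""),
             names(result_assembly)))
  test_seqs <- Biostrings::DNAStringSet(
    setNames(vapply(test_assembly, scaffold_seq, ""), names(test_assembly)))
  crop <- function(seq, by) {
    len <- nchar(seq)
    if (len <= 2 * by + 50L) seq else substr(seq, by + 1L, len - by)
  }
  count_hits <- function(pattern, subjects, max.mismatch = 0L,
                         with.indels = FALSE) {
    hits <- list()
    for (sid in names(subjects)) {
      for (str in c("+", "-")) {
        p <- if (str == "+") pattern else revcomp(pattern)
        if (max.mismatch == 0L) {
          # fixed-string search: no pattern length limit
          m <- gregexpr(p, as.character(subjects[[sid]]),
                        fixed = TRUE)[[1]]
          if (m[1] == -1L) next
          hits[[length(hits) + 1L]] <- data.frame(
            scaffold_id = sid, begin = as.integer(m) - 1L,
            end = as.integer(m) - 1L + nchar(p), strand = str,
            stringsAsFactors = FALSE)
        } else {
          if (nchar(p) > 20000L) next  # algorithm limit; treated as no hit
          m <- Biostrings::matchPattern(Biostrings::DNAString(p),
                                        subjects[[sid]],
                                        max.mismatch = max.mismatch,
                                        with.indels = with.indels)
          if (length(m))
            hits[[length(hits) + 1L]] <- data.frame(
              scaffold_id = sid, begin = Biostrings::start(m) - 1L,
              end = Biostrings::end(m), strand = str,
              stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(hits)) return(NULL)
    unique(do.call(rbind, hits))
  }
  rows <- list()
  for (i in seq_len(nrow(ct))) {
    cid <- ct$contig_id[i]
    dup_pat <- crop(ct$seq[i], crop_ambiguous)
    dup_hits <- count_hits(dup_pat, test_seqs)
    status <- "found"
    placement <- data.frame(scaffold_id = NA_character_, begin = NA_integer_,
                            end = NA_integer_, strand = NA_character_)
    if (!is.null(dup_hits) && nrow(dup_hits) > 1) {
      status <- "duplicated"
    } else {
      pat <- crop(ct$seq[i], crop_alignment)
      hits <- count_hits(pat, res_seqs)
      if (is.null(hits) && recover_imperfect) {
        mm <- ceiling(max_mismatch * nchar(pat))
        hits <- count_hits(pat, res_seqs, max.mismatch = mm,
                           with.indels = TRUE)
      }
      if (is.null(hits)) status <- "missing"
      else if (nrow(hits) > 1) status <- "ambiguous"
      else placement <- hits
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(contig_id = cid, status = status,
                 crop = if (nchar(ct$seq[i]) > 2 * crop_alignment + 50L)
                   crop_alignment else 0L, stringsAsFactors = FALSE),
      placement)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify every introduced gap against the result assembly
#'
#' Applies the published state rules in order: a gap is `closed` when both
#' flanking contigs map to a single contig of the result (same strand,
#' consistent order); `unclosed` when they map to different but adjacent
#' result contigs (consecutive in one result scaffold, separated only by an
#' N-run); `unknown` when a flanking contig is missing or cannot be located
#' uniquely; otherwise `broken` (both located but no longer adjacent — a
#' misassembly). For closed gaps the inserted sequence is extracted between
#' the placements on the placement strand and compared to the truth.
#'
#' @param placements Output of [locate_contigs()] on the test assembly whose
#'   scaffolds are the gap-flanked contig pairs.
#' @param truth Gap truth table from [make_test_assembly()].
#' @param test_assembly The test `spanweld_assembly`.
#' @param result_assembly The gap-closer output.
#' @return data.frame of gap records: `gap_id`, `state`, `identity`,
#'   `truth_len`, `inserted_len`.
#' @export
classify_gaps <- function(placements, truth, test_assembly,
                          result_assembly) {
  tgt <- gap_table(test_assembly)
  res_seqs <- setNames(vapply(result_assembly, scaffold_seq, ""),
                       names(result_assembly))
  res_contigs <- contig_table(result_assembly)
  find_run <- function(sid, pos) {
    d <- res_contigs[res_contigs$scaffold_id == sid &
                       res_contigs$scaffold_offset <= pos &
                       res_contigs$scaffold_offset + res_contigs$length > pos,
                     , drop = FALSE]
    if (nrow(d)) d$contig_id[1] else NA_character_
  }
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    g <- truth[i, ]
    # the introduced gap lives on test scaffold g$contig_id
    tg <- tgt[tgt$scaffold_id == g$contig_id & tgt$begin == g$begin, ,
              drop = FALSE]
    rec <- data.frame(gap_id = g$gap_id, state = "unknown",
                      identity = NA_real_, truth_len = nchar(g$truth_seq),
                      inserted_len = NA_integer_, stringsAsFactors = FALSE)
    if (nrow(tg) == 1) {
      pl <- placements[match(c(tg$left_contig, tg$right_contig),
                             placements$contig_id), , drop = FALSE]
      pL <- pl[1, ]; pR <- pl[2, ]
      if (all(pl$status == "found")) {
        runL <- find_run(pL$scaffold_id, pL$begin)
        runR <- find_run(pR$scaffold_id, pR$begin)
        same_strand <- pL$strand == pR$strand
        ordered <- if (isTRUE(same_strand) && pL$strand == "+")
          pL$end <= pR$begin else if (isTRUE(same_strand))
            pR$end <= pL$begin else FALSE
        if (identical(runL, runR) && !is.na(runL) && same_strand && ordered) {
          rec$state <- "closed"
          seq <- res_seqs[[pL$scaffold_id]]
          if (pL$strand == "+") {
            lo <- pL$end + pL$crop; hi <- pR$begin - pR$crop
          } else {
            lo <- pR$end + pR$crop; hi <- pL$begin - pL$crop
          }
          ins <- if (hi > lo) substr(seq, lo + 1L, hi) else ""
          if (pL$strand == "-" && nchar(ins)) ins <- revcomp(ins)
          rec$inserted_len <- nchar(ins)
          rec$identity <- gap_identity(ins, g$truth_seq)
        } else if (pL$scaffold_id == pR$scaffold_id && same_strand &&
                   ordered && adjacent_runs(res_contigs, runL, runR)) {
          rec$state <- "unclosed"
        } else {
          rec$state <- "broken"
        }
      } else if (any(pl$status %in% c("missing", "ambiguous", "duplicated"))) {
        rec$state <- "unknown"
      }
    }
    rows[[length(rows) + 1L]] <- rec
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# consecutive contig runs of one scaffold, separated only by an N-run
adjacent_runs <- function(res_contigs, runA, runB) {
  if (is.na(runA) || is.na(runB)) return(FALSE)
  a <- res_contigs[res_contigs$contig_id == runA, ]
  b <- res_contigs[res_contigs$contig_id == runB, ]
  a$scaffold_id == b$scaffold_id && abs(a$ordinal - b$ordinal) == 1L
}

#' Sequence identity between inserted and true gap sequence
#'
#' Global edit alignment identity: matches divided by alignment columns
#' (matches + mismatches + indels). Two empty sequences are identical (1);
#' one empty sequence scores 0.
#'
#' @param inserted,truth DNA strings (possibly empty).
#' @return Identity fraction in `[0, 1]`.
#' @export
gap_identity <- function(inserted, truth) {
  n <- nchar(inserted); m <- nchar(truth)
  if (n == 0 && m == 0) return(1)
  if (n == 0 || m == 0) return(0)
  band <- max(64L, abs(n - m) + as.integer(0.5 * max(n, m)))
  h <- cpp_align_global(inserted, truth, band)
  if (!isTRUE(h$ok)) return(0)
  h$nmatch / h$alen
}

#' Summarize gap records
#'
#' Mean identity, identity weighted by true gap length, the 6-bin identity
#' histogram over `[0,0.7) [0.7,0.9) [0.9,0.95) [0.95,0.99) [0.99,1) {1}`,
#' and state counts.
#'
#' @param records Gap records from [classify_gaps()].
#' @return List with `n_closed`, `n_unclosed`, `n_unknown`, `n_broken`,
#'   `mean_id`, `weighted_id`, `bins`.
#' @export
summarize_gap_records <- function(records) {
  closed <- records[records$state == "closed", , drop = FALSE]
  bins <- c("[0,0.7)" = 0L, "[0.7,0.9)" = 0L, "[0.9,0.95)" = 0L,
            "[0.95,0.99)" = 0L, "[0.99,1)" = 0L, "{1}" = 0L)
  if (nrow(closed)) {
    idx <- findInterval(closed$identity, c(0, 0.7, 0.9, 0.95, 0.99, 1 - 1e-12))
    for (k in idx) bins[k] <- bins[k] + 1L
  }
  list(n_closed = nrow(closed),
       n_unclosed = sum(records$state == "unclosed"),
       n_unknown = sum(records$state == "unknown"),
       n_broken = sum(records$state == "broken"),
       mean_id = if (nrow(closed)) mean(closed$identity) else NA_real_,
       weighted_id = if (nrow(closed))
         weighted.mean(closed$identity, pmax(closed$truth_len, 1L))
       else NA_real_,
       bins = bins)
}

#' NG(x) contiguity statistics
#'
#' Contigs are the maximal N-free runs of the assembly; `NG(x)` is the
#' largest length L such that contigs of length at least L sum to at least
#' x percent of the fixed genome size G (the count of A/C/G/T bases in the
#' ground truth). `NG(x) = 0` when the contigs cannot reach x percent.
#'
#' @param assembly A `spanweld_assembly`.
#' @param G Genome size in bp (> 0).
#' @return List with `G`, `ng50`, and `ng`, a function of x in `(0, 100]`.
#' @export
ng_stats <- function(assembly, G) {
  stopifnot(G > 0)
  lens <- sort(contig_table(assembly)$length, decreasing = TRUE)
  csum <- cumsum(as.numeric(lens))
  ng <- function(x) {
    need <- x / 100 * G
    i <- which(csum >= need)
    if (!length(i)) return(0L)
    lens[i[1]]
  }
  list(G = G, ng50 = ng(50), ng = Vectorize(ng))
}

#' Evaluate a gap-closing result end to end
#'
#' Runs [locate_contigs()], [classify_gaps()], [summarize_gap_records()] and
#' [ng_stats()] for one (test assembly, result assembly, truth) triple.
#'
#' @param test_assembly,result_assembly `spanweld_assembly` objects.
#' @param truth Gap truth table from [make_test_assembly()].
#' @param G Genome size for NG statistics; defaults to the summed contig
#'   length of the test assembly plus introduced gap truth.
#' @param ... Passed to [locate_contigs()].
#' @return List with `records`, `summary`, `ng`, `placements`.
#' @export
evaluate_gap_closing <- function(test_assembly, result_assembly, truth,
                                 G = NULL, ...) {
  if (is.null(G))
    G <- sum(contig_table(test_assembly)$length) + sum(nchar(truth$truth_seq))
  placements <- locate_contigs(test_assembly, result_assembly, ...)
  records <- classify_gaps(placements, truth, test_assembly, result_assembly)
  list(records = records, summary = summarize_gap_records(records),
       ng = ng_stats(result_assembly, G), placements = placements)
}
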