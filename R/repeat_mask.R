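#' Low-complexity masking (SDUST-style triplet score)
#'
#' Scores sliding windows by triplet over-representation,
#' \eqn{\sum_t c_t (c_t - 1)/2 / (l - 1)} over the window's triplet counts,
#' and masks windows whose score exceeds the threshold. A substitute for the
#' DUST family of maskers with the published scoring.
#'
#' @param contigs Named character vector of contig sequences.
#' @param window Window size in bp (default 64).
#' @param threshold Score threshold (default 2.0).
#' @return A [mask_track()] in contig coordinates.
#' @export
dust_mask <- function(contigs, window = 64L, threshold = 2.0) {
  rows <- lapply(names(contigs), function(id) {
    m <- cpp_dust(contigs[[id]], as.integer(window), threshold)
    if (!nrow(m)) return(NULL)
    data.frame(seq_id = id, begin = m[, 1], end = m[, 2],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(mask_track())
  normalize_mask(do.call(rbind, rows))
}

#' Tandem-repeat masking by period-bounded self-match
#'
#' Masks intervals where the sequence matches itself at a diagonal offset
#' (period) of at most `max_period` over at least `min_len` bp, tolerating
#' divergence down to a `min_frac` within-window match fraction.
#'
#' @param contigs Named character vector of contig sequences.
#' @param max_period Maximum repeat period in bp (default 100).
#' @param min_len Minimum masked array length in bp (default 60).
#' @param min_frac Minimum match fraction within a window (default 0.8).
#' @return A [mask_track()].
#' @export
tandem_mask <- function(contigs, max_period = 100L, min_len = 60L,
                        min_frac = 0.8) {
  rows <- lapply(names(contigs), function(id) {
    m <- cpp_tandem(contigs[[id]], as.integer(max_period),
                    as.integer(min_len), min_frac)
    if (!nrow(m)) return(NULL)
    data.frame(seq_id = id, begin = m[, 1], end = m[, 2],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(mask_track())
  normalize_mask(do.call(rbind, rows))
}

#' Repeat masking from assembly self-alignment depth
#'
#' Positions covered by at least `max_coverage_self` alignments to other
#' genomic regions are masked. Both intervals of every off-diagonal
#' alignment contribute to the depth.
#'
#' @param self_alns Alignment table from [self_align()] (self-diagonal
#'   records already excluded).
#' @param max_coverage_self Depth threshold (default 4).
#' @return A [mask_track()].
#' @export
self_alignment_mask <- function(self_alns, max_coverage_self = 4L) {
  if (!nrow(self_alns)) return(mask_track())
  depth_mask(c(self_alns$query_id, self_alns$target_id),
             c(self_alns$qbeg, self_alns$tbeg),
             c(self_alns$qend, self_alns$tend),
             max_coverage_self, strict = FALSE)
}

#' Poisson-derived read-coverage ceiling
#'
#' Under uniform read sampling the number of reads over any unique position
#' is Poisson with mean \eqn{C}; \eqn{C_{max}} is the smallest integer m with
#' \eqn{P(X > m) < } `tail_prob`, so that exceeding it is very unlikely
#' outside repeats.
#'
#' @param C Global read coverage (> 0).
#' @param tail_prob Tail probability (default 1e-3).
#' @return Integer \eqn{C_{max}}.
#' @export
compute_cmax <- function(C, tail_prob = 1e-3) {
  if (!is.numeric(C) || C <= 0) stop("read coverage C must be > 0")
  m <- qpois(1 - tail_prob, C)
  # qpois gives smallest m with P(X <= m) >= 1 - tail_prob, i.e.
  # P(X > m) <= tail_prob; enforce the strict inequality
  while (ppois(m, C, lower.tail = FALSE) >= tail_prob) m <- m + 1L
  as.integer(m)
}

#' Repeat masking from read-alignment depth
#'
#' Masks assembly positions covered by more read alignments than expected
#' from the global coverage: depth strictly greater than \eqn{C_{max}}.
#' Every local alignment counts, chained or not.
#'
#' @param read_alns Read-to-assembly alignment table.
#' @param C_max Coverage ceiling, see [compute_cmax()].
#' @return A [mask_track()].
#' @export
read_coverage_mask <- function(read_alns, C_max) {
  if (!nrow(read_alns)) return(mask_track())
  depth_mask(read_alns$target_id, read_alns$tbeg, read_alns$tend,
             C_max, strict = TRUE)
}

#' Is a read alignment proper?
#'
#' An alignment is proper when at most `allowance` bp of the read are
#' unaligned at either read end. A read end whose unaligned tail is explained
#' by a contig boundary (the alignment reaches within `allowance` of the
#' contig end the read continues past) also counts as proper, so that reads
#' reaching into gaps are not mistaken for repeat-induced partial
#' alignments; set `ignore_boundaries = TRUE` for the read-ends-only rule.
#'
#' @param alns Alignment table (vectorized over rows).
#' @param allowance Unaligned-end allowance in bp (default 100).
#' @param ignore_boundaries Do not excuse contig-boundary clipping.
#' @return Logical vector.
#' @export
is_proper <- function(alns, allowance = 100L, ignore_boundaries = FALSE) {
  left_read <- alns$qbeg <= allowance
  right_read <- alns$query_len - alns$qend <= allowance
  if (ignore_boundaries) return(left_read & right_read)
  fwd <- alns$strand == "+"
  # target boundary in the direction the read continues past each read end
  left_tgt <- ifelse(fwd, alns$tbeg <= allowance,
                     alns$target_len - alns$tend <= allowance)
  right_tgt <- ifelse(fwd, alns$target_len - alns$tend <= allowance,
                      alns$tbeg <= allowance)
  (left_read | left_tgt) & (right_read | right_tgt)
}

#' Repeat masking from improper-alignment depth
#'
#' Improper alignments (only a substring of the read aligns, unexplained by
#' contig boundaries) are a repeat signal: positions where their depth
#' exceeds the threshold — by default half the global read coverage — are
#' masked.
#'
#' @param read_alns Read-to-assembly alignment table.
#' @param threshold Depth threshold (default `C/2`).
#' @param allowance Proper-alignment allowance (default 100).
#' @return A [mask_track()].
#' @export
improper_coverage_mask <- function(read_alns, threshold, allowance = 100L) {
  if (!nrow(read_alns)) return(mask_track())
  bad <- read_alns[!is_proper(read_alns, allowance), , drop = FALSE]
  if (!nrow(bad)) return(mask_track())
  depth_mask(bad$target_id, bad$tbeg, bad$tend, threshold, strict = TRUE)
}

#' Homogenize repeat masks through the read alignments
#'
#' Unions the given masks, transfers the masked assembly regions onto each
#' aligned read, and projects every read's masked regions back onto the
#' assembly through all of that read's alignments. A repeat annotated on one
#' copy thereby propagates to every other copy some read aligns to. The
#' output always contains the input union, and the operation is idempotent
#' up to projection granularity.
#'
#' @param masks List of [mask_track()]s in assembly (contig) coordinates.
#' @param read_alns Read-to-assembly alignment table (traces used when
#'   present, else linear interpolation).
#' @return A [mask_track()].
#' @export
homogenize <- function(masks, read_alns) {
  base <- do.call(mask_union, masks)
  if (!nrow(read_alns) || !nrow(base)) return(base)
  # assembly -> read
  read_rows <- list()
  for (i in seq_len(nrow(read_alns))) {
    a <- read_alns[i, ]
    d <- base[base$seq_id == a$target_id &
                base$end > a$tbeg & base$begin < a$tend, , drop = FALSE]
    if (!nrow(d)) next
    for (j in seq_len(nrow(d))) {
      iv <- project_target_interval(a, d$begin[j], d$end[j])
      if (!is.null(iv) && iv[2] > iv[1])
        read_rows[[length(read_rows) + 1L]] <-
          data.frame(seq_id = a$query_id, begin = iv[1], end = iv[2])
    }
  }
  if (!length(read_rows)) return(base)
  read_mask <- normalize_mask(do.call(rbind, read_rows))
  # read -> assembly, through every alignment of each read
  back_rows <- list()
  for (i in seq_len(nrow(read_alns))) {
    a <- read_alns[i, ]
    d <- read_mask[read_mask$seq_id == a$query_id &
                     read_mask$end > a$qbeg & read_mask$begin < a$qend, ,
                   drop = FALSE]
    if (!nrow(d)) next
    for (j in seq_len(nrow(d))) {
      iv <- project_query_interval(a, d$begin[j], d$end[j])
      if (!is.null(iv) && iv[2] > iv[1])
        back_rows[[length(back_rows) + 1L]] <-
          data.frame(seq_id = a$target_id, begin = iv[1], end = iv[2])
    }
  }
  if (!length(back_rows)) return(base)
  mask_union(base, normalize_mask(do.call(rbind, back_rows)))
}

#' Compute all four repeat annotations and homogenize them
#'
#' Convenience driver producing the low-complexity, tandem, self-alignment
#' and read-coverage (depth plus improper-depth) masks and their homogenized
#' union for an assembly.
#'
#' @param assembly A `spanweld_assembly`.
#' @param read_alns Read-to-contig alignments ([map_reads()]).
#' @param config A [pipeline_config()] with `read_coverage` set.
#' @param self_alns Optional precomputed [self_align()] table; computed when
#'   `NULL` and minimap2 is available.
#' @return List of mask tracks: `dust`, `tandem`, `self`, `reads`, `final`.
#' @export
repeat_annotations <- function(assembly, read_alns, config,
                               self_alns = NULL) {
  contigs <- contig_seqs(assembly)
  dust <- dust_mask(contigs)
  tandem <- tandem_mask(contigs)
  if (is.null(self_alns)) {
    self_alns <- if (minimap2_available()) self_align(contigs)
                 else empty_alignments()
  }
  selfm <- self_alignment_mask(self_alns, config$max_coverage_self)
  C <- config$read_coverage
  cmax <- if (!is.null(config$max_coverage_reads)) config$max_coverage_reads
          else compute_cmax(C, config$cmax_tail_prob)
  improper_thr <- if (!is.null(config$max_improper_coverage))
    config$max_improper_coverage else C / 2
  readm <- mask_union(
    read_coverage_mask(read_alns, cmax),
    improper_coverage_mask(read_alns, improper_thr,
                           config$proper_alignment_allowance))
  final <- homogenize(list(dust, tandem, selfm, readm), read_alns)
  list(dust = dust, tandem = tandem, self = selfm, reads = readm,
       final = final)
}
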