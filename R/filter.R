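#' Filter read alignments down to the reliable set
#'
#' Keeps the alignments used for gap closing. An alignment survives when it
#' is (i) proper ([is_proper()]); (ii) strongly anchored: at least
#' `min_anchor` bp of its aligned reference interval are non-repetitive
#' under the homogenized mask; and (iv) not fully contained in a contig
#' (it must reach within `allowance` of a contig end to be able to span or
#' extend into a gap). Additionally (iii), every region of a read may align
#' to at most one assembly region: if two alignments of the same read that
#' pass (i) and (ii) overlap by more than `allowance` bp in read
#' coordinates, the read is ambiguous and all its alignments are discarded.
#'
#' @param read_alns Read-to-contig alignment table.
#' @param final_mask Homogenized repeat [mask_track()].
#' @param min_anchor Minimum unmasked anchor length in bp (default 500).
#' @param allowance Proper-alignment and end-tolerance allowance (default 100).
#' @return Filtered alignment table (subset of the input rows).
#' @export
filter_reliable <- function(read_alns, final_mask, min_anchor = 500L,
                            allowance = 100L) {
  if (!nrow(read_alns)) return(read_alns)
  proper <- is_proper(read_alns, allowance)
  anchored <- vapply(seq_len(nrow(read_alns)), function(i) {
    a <- read_alns[i, ]
    unmasked_bases(final_mask, a$target_id, a$tbeg, a$tend) >= min_anchor
  }, TRUE)
  keep <- proper & anchored
  # rule (iii): unique read regions among retained alignments, per read
  cand <- read_alns[keep, , drop = FALSE]
  bad_reads <- character()
  for (rid in unique(cand$query_id)) {
    d <- cand[cand$query_id == rid, , drop = FALSE]
    if (nrow(d) < 2) next
    o <- order(d$qbeg)
    d <- d[o, ]
    for (i in seq_len(nrow(d) - 1)) {
      if (any(pmin(d$qend[i], d$qend[(i + 1):nrow(d)]) -
              pmax(d$qbeg[i], d$qbeg[(i + 1):nrow(d)]) > allowance)) {
        bad_reads <- c(bad_reads, rid)
        break
      }
    }
  }
  keep <- keep & !(read_alns$query_id %in% bad_reads)
  # rule (iv): drop alignments fully contained in a contig
  contained <- read_alns$tbeg >= allowance &
    read_alns$target_len - read_alns$tend >= allowance
  out <- read_alns[keep & !contained, , drop = FALSE]
  rownames(out) <- NULL
  out
}
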