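#' Mask tracks: per-sequence sorted disjoint interval sets
#'
#' A mask track stores, per sequence, a merged set of 0-based half-open
#' intervals. Used for every repeat annotation. Backed by IRanges for the
#' interval arithmetic.
#'
#' @param seq_id Character vector of sequence ids.
#' @param begin,end Integer vectors, 0-based half-open.
#' @return An object of class `mask_track` (a normalized `data.frame` with
#'   columns `seq_id`, `begin`, `end`).
#' @export
mask_track <- function(seq_id = character(), begin = integer(),
                       end = integer()) {
  df <- data.frame(seq_id = as.character(seq_id), begin = as.integer(begin),
                   end = as.integer(end), stringsAsFactors = FALSE)
  stopifnot(all(df$begin >= 0), all(df$begin <= df$end))
  df <- df[df$end > df$begin, , drop = FALSE]
  normalize_mask(df)
}

normalize_mask <- function(df) {
  if (nrow(df)) {
    parts <- lapply(split(df, df$seq_id), function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(d$begin + 1L, d$end))
      data.frame(seq_id = d$seq_id[1], begin = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, parts)
    df <- df[order(df$seq_id, df$begin), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("mask_track", "data.frame")
  df
}

as_irl <- function(mask, seq_ids = NULL) {
  ids <- if (is.null(seq_ids)) unique(mask$seq_id) else seq_ids
  out <- lapply(setNames(ids, ids), function(id) {
    d <- mask[mask$seq_id == id, , drop = FALSE]
    IRanges::IRanges(d$begin + 1L, d$end)
  })
  out
}

#' Union of mask tracks
#' @param ... `mask_track` objects.
#' @return A `mask_track`.
#' @export
mask_union <- function(...) {
  tracks <- list(...)
  tracks <- tracks[!vapply(tracks, is.null, TRUE)]
  if (!length(tracks)) return(mask_track())
  normalize_mask(do.call(rbind, lapply(tracks, as.data.frame)))
}

#' Intersection of two mask tracks
#' @param a,b `mask_track` objects.
#' @return A `mask_track`.
#' @export
mask_intersect <- function(a, b) {
  ids <- intersect(unique(a$seq_id), unique(b$seq_id))
  rows <- lapply(ids, function(id) {
    ia <- as_irl(a, id)[[1]]; ib <- as_irl(b, id)[[1]]
    ir <- IRanges::intersect(ia, ib)
    if (!length(ir)) return(NULL)
    data.frame(seq_id = id, begin = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(mask_track())
  normalize_mask(do.call(rbind, rows))
}

#' Subtraction of mask tracks (a minus b)
#' @param a,b `mask_track` objects.
#' @return A `mask_track`.
#' @export
mask_subtract <- function(a, b) {
  rows <- lapply(unique(a$seq_id), function(id) {
    ia <- as_irl(a, id)[[1]]
    ib <- if (id %in% b$seq_id) as_irl(b, id)[[1]] else IRanges::IRanges()
    ir <- IRanges::setdiff(ia, ib)
    if (!length(ir)) return(NULL)
    data.frame(seq_id = id, begin = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(mask_track())
  normalize_mask(do.call(rbind, rows))
}

#' Total masked bases, per sequence or overall
#' @param mask A `mask_track`.
#' @param seq_id Optional sequence id to restrict to.
#' @return Integer base count.
#' @export
mask_width <- function(mask, seq_id = NULL) {
  d <- if (is.null(seq_id)) mask else mask[mask$seq_id == seq_id, ]
  sum(d$end - d$begin)
}

#' Unmasked bases within an interval
#'
#' Counts how many bases of `[begin, end)` on `seq_id` fall outside the mask;
#' used for the strong-anchoring filter.
#'
#' @param mask A `mask_track`.
#' @param seq_id Sequence id.
#' @param begin,end 0-based half-open interval.
#' @return Integer count.
#' @export
unmasked_bases <- function(mask, seq_id, begin, end) {
  len <- end - begin
  d <- mask[mask$seq_id == seq_id, , drop = FALSE]
  if (!nrow(d)) return(len)
  ov <- pmin(d$end, end) - pmax(d$begin, begin)
  len - sum(pmax(ov, 0L))
}

#' Positions with interval depth above a threshold
#'
#' Computes the per-base depth of a set of intervals on one coordinate system
#' and returns the mask of positions with `depth >= threshold` (or strictly
#' greater when `strict = TRUE`).
#'
#' @param seq_id,begin,end Parallel vectors of intervals (0-based half-open).
#' @param threshold Depth threshold.
#' @param strict If TRUE mask `depth > threshold` else `depth >= threshold`.
#' @return A `mask_track`.
#' @export
depth_mask <- function(seq_id, begin, end, threshold, strict = FALSE) {
  if (!length(seq_id)) return(mask_track())
  df <- data.frame(seq_id = as.character(seq_id), begin = as.integer(begin),
                   end = as.integer(end))
  rows <- lapply(split(df, df$seq_id), function(d) {
    cov <- IRanges::coverage(IRanges::IRanges(d$begin + 1L, d$end))
    lim <- if (strict) threshold + 1e-9 else threshold - 1e-9
    sl <- IRanges::slice(cov, lower = lim)
    ir <- IRanges::ranges(sl)
    if (!length(ir)) return(NULL)
    data.frame(seq_id = d$seq_id[1], begin = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(mask_track())
  normalize_mask(do.call(rbind, rows))
}

#' Read a BED3 file as a mask track
#' @param path BED file (0-based half-open, as standard).
#' @return A `mask_track`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) return(mask_track())
  d <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  mask_track(d[[1]], d[[2]], d[[3]])
}

#' Write a mask track as BED3
#' @param mask A `mask_track`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(mask, path) {
  write.table(as.data.frame(mask)[, c("seq_id", "begin", "end")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
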