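#' Local alignment tables and PAF I/O
#'
#' Local alignments are kept in a plain `data.frame`, one row per alignment,
#' mirroring PAF: `query_id`, `query_len`, `qbeg`, `qend` (always on the
#' read's forward strand), `strand`, `target_id`, `target_len`, `tbeg`,
#' `tend` (always on the target's forward strand), `n_match`, `aln_len`,
#' `mapq`, `cigar` (`cg:Z`-style, `NA` when absent), `chain_id`.
#'
#' The trace convention follows PAF: the CIGAR aligns the forward query
#' against the target segment, which for `-`-strand alignments is the
#' reverse complement of `target[tbeg, tend)`.
#'
#' @name alignments
NULL

#' Empty alignment table
#' @return Zero-row alignment `data.frame`.
#' @export
empty_alignments <- function() {
  data.frame(query_id = character(), query_len = integer(), qbeg = integer(),
             qend = integer(), strand = character(), target_id = character(),
             target_len = integer(), tbeg = integer(), tend = integer(),
             n_match = integer(), aln_len = integer(), mapq = integer(),
             cigar = character(), chain_id = integer(),
             stringsAsFactors = FALSE)
}

as_alignments <- function(df) {
  tmpl <- empty_alignments()
  for (nm in names(tmpl)) {
    if (is.null(df[[nm]]))
      df[[nm]] <- if (nm == "chain_id") NA_integer_ else tmpl[[nm]][NA_integer_][0]
  }
  if (!nrow(df)) return(tmpl)
  df <- df[, names(tmpl)]
  rownames(df) <- NULL
  df
}

#' Read a PAF file
#'
#' Accepts 12+ column PAF; the `cg:Z` CIGAR tag is parsed when present and
#' cross-checked for interval consistency. Malformed lines raise an error
#' naming the line number.
#'
#' @param path PAF file.
#' @return Alignment `data.frame` (see [empty_alignments()]).
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_alignments())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) stop("malformed PAF line ", i, ": fewer than 12 columns")
    num <- suppressWarnings(as.integer(f[c(2:4, 7:12)]))
    if (anyNA(num) || !f[5] %in% c("+", "-"))
      stop("malformed PAF line ", i)
    tags <- f[-(1:12)]
    cg <- tags[startsWith(tags, "cg:Z:")]
    cigar <- if (length(cg)) sub("^cg:Z:", "", cg[1]) else NA_character_
    ch <- tags[startsWith(tags, "ch:i:")]
    chain <- if (length(ch)) as.integer(sub("^ch:i:", "", ch[1]))
             else NA_integer_
    data.frame(query_id = f[1], query_len = num[1], qbeg = num[2],
               qend = num[3], strand = f[5], target_id = f[6],
               target_len = num[4], tbeg = num[5], tend = num[6],
               n_match = num[7], aln_len = num[8], mapq = num[9],
               cigar = cigar, chain_id = chain,
               stringsAsFactors = FALSE)
  })
  as_alignments(do.call(rbind, rows))
}

#' Write alignments as PAF
#' @param alns Alignment `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(alns, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alns))) {
    a <- alns[i, ]
    line <- paste(a$query_id, a$query_len, a$qbeg, a$qend, a$strand,
                  a$target_id, a$target_len, a$tbeg, a$tend, a$n_match,
                  a$aln_len, a$mapq, sep = "\t")
    if (!is.na(a$cigar)) line <- paste0(line, "\tcg:Z:", a$cigar)
    if (!is.na(a$chain_id)) line <- paste0(line, "\tch:i:", a$chain_id)
    writeLines(line, con)
  }
  invisible(path)
}

#' Summary statistics of a CIGAR string
#' @param cigar CIGAR over `= X I D M`.
#' @return List with `n_match`, `aln_len`, `qlen`, `tlen`, `edit`.
#' @export
cigar_stats <- function(cigar) {
  runs <- cpp_cigar_runs(cigar)
  op <- runs$op; len <- runs$len
  qlen <- sum(len[op %in% c("=", "X", "I", "M")])
  tlen <- sum(len[op %in% c("=", "X", "D", "M")])
  nmatch <- sum(len[op == "="]) + sum(len[op == "M"])
  list(n_match = nmatch, aln_len = sum(len),
       qlen = qlen, tlen = tlen,
       edit = sum(len[op %in% c("X", "I", "D")]))
}

# Per-run cumulative offsets of a trace, in trace frame.
trace_tables <- function(cigar) {
  runs <- cpp_cigar_runs(cigar)
  op <- runs$op; len <- runs$len
  qadv <- ifelse(op %in% c("=", "X", "I", "M"), len, 0L)
  tadv <- ifelse(op %in% c("=", "X", "D", "M"), len, 0L)
  list(op = op, len = len,
       q0 = cumsum(c(0L, qadv))[seq_along(op)],
       t0 = cumsum(c(0L, tadv))[seq_along(op)],
       qadv = qadv, tadv = tadv)
}

# Map trace-frame target boundaries (in [0, tlen]) to trace-frame query
# boundaries. Boundaries before an insertion run map before the insertion.
trace_qboundary_at_t <- function(tt, rt) {
  tends <- tt$t0 + tt$tadv
  vapply(rt, function(x) {
    i <- which(tends >= x)[1]
    if (is.na(i)) return(sum(tt$qadv))
    if (tt$tadv[i] > 0 && tt$qadv[i] > 0) tt$q0[i] + (x - tt$t0[i])
    else tt$q0[i]
  }, 0)
}

trace_tboundary_at_q <- function(tt, rq) {
  qends <- tt$q0 + tt$qadv
  vapply(rq, function(x) {
    i <- which(qends >= x)[1]
    if (is.na(i)) return(sum(tt$tadv))
    if (tt$tadv[i] > 0 && tt$qadv[i] > 0) tt$t0[i] + (x - tt$q0[i])
    else tt$t0[i]
  }, 0)
}

#' Project a target position onto the query through one alignment
#'
#' Maps a boundary position on the forward target to the corresponding
#' boundary on the forward query, using the trace when present and linear
#' interpolation otherwise. `pos` must lie within `[tbeg, tend]`.
#'
#' @param aln One-row alignment `data.frame`.
#' @param pos Target boundary position(s), 0-based.
#' @return Query boundary position(s); `NA` outside the aligned interval.
#' @export
project_target_pos <- function(aln, pos) {
  L <- aln$tend - aln$tbeg
  qspan <- aln$qend - aln$qbeg
  rt <- if (aln$strand == "+") pos - aln$tbeg else aln$tend - pos
  out <- if (is.na(aln$cigar)) {
    aln$qbeg + round(rt / L * qspan)
  } else {
    aln$qbeg + trace_qboundary_at_t(trace_tables(aln$cigar), rt)
  }
  out[pos < aln$tbeg | pos > aln$tend] <- NA
  as.integer(out)
}

#' Project a query position onto the forward target through one alignment
#' @inheritParams project_target_pos
#' @param pos Query boundary position(s) on the forward read, 0-based.
#' @return Target boundary position(s) on the forward target.
#' @export
project_query_pos <- function(aln, pos) {
  L <- aln$tend - aln$tbeg
  qspan <- aln$qend - aln$qbeg
  rq <- pos - aln$qbeg
  t_rel <- if (is.na(aln$cigar)) {
    round(rq / qspan * L)
  } else {
    trace_tboundary_at_q(trace_tables(aln$cigar), rq)
  }
  out <- if (aln$strand == "+") aln$tbeg + t_rel else aln$tend - t_rel
  out[pos < aln$qbeg | pos > aln$qend] <- NA
  as.integer(out)
}

#' Project a target interval onto the query through one alignment
#'
#' The interval is clamped to the aligned region; returns `NULL` when it does
#' not intersect it. Output is on the forward query.
#'
#' @param aln One-row alignment `data.frame`.
#' @param begin,end Target interval, 0-based half-open on the forward target.
#' @return `c(qbeg, qend)` on the forward query, or `NULL`.
#' @export
project_target_interval <- function(aln, begin, end) {
  b <- max(begin, aln$tbeg); e <- min(end, aln$tend)
  if (e <= b) return(NULL)
  q <- sort(project_target_pos(aln, c(b, e)))
  c(q[1], max(q[2], q[1]))
}

#' Project a query interval onto the forward target through one alignment
#' @inheritParams project_target_interval
#' @param begin,end Query interval, 0-based half-open on the forward query.
#' @return `c(tbeg, tend)` on the forward target, or `NULL`.
#' @export
project_query_interval <- function(aln, begin, end) {
  b <- max(begin, aln$qbeg); e <- min(end, aln$qend)
  if (e <= b) return(NULL)
  t <- sort(project_query_pos(aln, c(b, e)))
  c(t[1], max(t[2], t[1]))
}
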