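#' Apply insertions to an assembly
#'
#' Splices validated consensus sequences into the assembly. In mode
#' `intra_only` (the default) only insertions that coincide with an input
#' intra-scaffold gap are applied; `intra_and_inter` additionally joins
#' scaffolds whose terminal contig ends are bridged (new scaffold ids
#' concatenate the constituents); `free_scaffolding` ignores the input
#' scaffold structure and builds scaffolds from the insertion joins alone.
#' Contig bases outside the insertion anchors are never modified; gaps
#' without an applied insertion keep their original N-run.
#'
#' @param assembly A `spanweld_assembly`.
#' @param insertions List of `spanweld_insertion`s ([anchor_insertion()]);
#'   entries with `validated == "fail"` are skipped.
#' @param mode One of `"intra_only"`, `"intra_and_inter"`,
#'   `"free_scaffolding"`.
#' @return List with `assembly` (the gap-closed `spanweld_assembly`) and
#'   `placements`: one row per applied insertion with its id and the
#'   0-based `core_begin`/`core_end` interval of the inserted bases on the
#'   output scaffold.
#' @export
apply_insertions <- function(assembly, insertions,
                             mode = c("intra_only", "intra_and_inter",
                                      "free_scaffolding")) {
  mode <- match.arg(mode)
  ok <- vapply(insertions, function(x)
    !is.null(x$seq_core) && x$validated != "fail", TRUE)
  insertions <- insertions[ok]
  if (mode == "intra_only")
    insertions <- insertions[vapply(insertions, `[[`, TRUE, "is_input_gap")]
  by_key <- list()
  ends_seen <- character()
  for (ins in insertions) {
    key <- edge_key(ins$contig_a, ins$side_a, ins$contig_b, ins$side_b)
    ends <- c(paste0(ins$contig_a, ":", ins$side_a),
              paste0(ins$contig_b, ":", ins$side_b))
    if (any(ends %in% ends_seen))
      stop("conflicting insertions at contig end ",
           ends[ends %in% ends_seen][1])
    ends_seen <- c(ends_seen, ends)
    by_key[[key]] <- ins
  }
  if (mode == "free_scaffolding")
    return(apply_free(assembly, by_key))
  placements <- list()
  scaffolds <- list()
  for (sc in assembly) {
    comps <- sc$components
    out_comps <- list()
    cur <- NULL  # accumulating merged contig sequence
    pend_gap <- NULL
    last_contig <- NULL
    flush <- function() {
      if (!is.null(cur)) out_comps[[length(out_comps) + 1L]] <<- cur
      cur <<- NULL
    }
    for (comp in comps) {
      if (comp$type == "gap") {
        pend_gap <- comp
        next
      }
      if (is.null(cur)) {
        if (!is.null(pend_gap)) {  # leading N-run
          out_comps[[length(out_comps) + 1L]] <- strrep("N", pend_gap$length)
          pend_gap <- NULL
        }
        cur <- comp$seq
        last_contig <- comp$id
        next
      }
      ins <- NULL
      if (!is.null(pend_gap) && !pend_gap$terminal)
        ins <- by_key[[edge_key(last_contig, "end", comp$id, "begin")]]
      if (is.null(ins)) {
        flush()
        if (!is.null(pend_gap))
          out_comps[[length(out_comps) + 1L]] <- strrep("N", pend_gap$length)
        cur <- comp$seq
      } else {
        fwd <- ins$contig_a == last_contig && ins$side_a == "end"
        core <- if (fwd) ins$seq_core else revcomp(ins$seq_core)
        tl <- if (fwd) ins$trim_a else ins$trim_b
        tr <- if (fwd) ins$trim_b else ins$trim_a
        left <- substr(cur, 1L, nchar(cur) - tl)
        right <- substr(comp$seq, tr + 1L, nchar(comp$seq))
        placements[[length(placements) + 1L]] <- data.frame(
          id = ins$id, scaffold_id = sc$id,
          run_index = length(out_comps) + 1L,
          core_begin = nchar(left), core_end = nchar(left) + nchar(core),
          stringsAsFactors = FALSE)
        cur <- paste0(left, core, right)
      }
      last_contig <- comp$id
      pend_gap <- NULL
    }
    flush()
    if (!is.null(pend_gap))
      out_comps[[length(out_comps) + 1L]] <- strrep("N", pend_gap$length)
    scaffolds[[sc$id]] <- out_comps
  }
  # resolve run-local placements to scaffold coordinates
  pl <- resolve_placements(scaffolds, placements)
  out <- new_assembly(lapply(names(scaffolds), function(id)
    scaffold_from_seq(id, paste(unlist(scaffolds[[id]]), collapse = ""))))
  if (mode == "intra_and_inter") {
    joined <- join_scaffolds(out, by_key, pl, assembly)
    out <- joined$assembly; pl <- joined$placements
  }
  list(assembly = out, placements = pl)
}

resolve_placements <- function(scaffolds, placements) {
  if (!length(placements))
    return(data.frame(id = character(), scaffold_id = character(),
                      core_begin = integer(), core_end = integer()))
  pl <- do.call(rbind, placements)
  # count contig runs in the same order they were emitted
  pl$off <- NA_integer_
  for (i in seq_len(nrow(pl))) {
    comps <- scaffolds[[pl$scaffold_id[i]]]
    lens <- vapply(comps, nchar, 0L)
    before <- if (pl$run_index[i] > 1) sum(lens[seq_len(pl$run_index[i] - 1L)])
              else 0L
    pl$off[i] <- before
  }
  pl$core_begin <- pl$core_begin + pl$off
  pl$core_end <- pl$core_end + pl$off
  pl$off <- NULL; pl$run_index <- NULL
  pl
}

# Scaffold-level joins for mode intra_and_inter: terminal contig ends of
# different scaffolds bridged by an insertion are concatenated.
join_scaffolds <- function(assembly, by_key, placements, orig_assembly) {
  # conservative implementation: join pairs of scaffolds end-to-end when an
  # insertion links the last contig of one to the first contig of another
  # (terminal contig ids taken from the input assembly's naming).
  info <- lapply(names(assembly), function(id) {
    ids <- vapply(Filter(function(c) c$type == "contig",
                         orig_assembly[[id]]$components), `[[`, "", "id")
    list(id = id, first = ids[1], last = ids[length(ids)],
         seq = scaffold_seq(assembly[[id]]))
  })
  used <- character()
  merged <- list()
  for (key in names(by_key)) {
    ins <- by_key[[key]]
    if (ins$is_input_gap) next
    from <- NULL; to <- NULL
    for (x in info) if (identical(x$last, ins$contig_a) &&
                        ins$side_a == "end") from <- x
    for (x in info) if (identical(x$first, ins$contig_b) &&
                        ins$side_b == "begin") to <- x
    if (is.null(from) || is.null(to) || from$id == to$id) next
    if (from$id %in% used || to$id %in% used) next
    used <- c(used, from$id, to$id)
    left <- substr(from$seq, 1L, nchar(from$seq) - ins$trim_a)
    right <- substr(to$seq, ins$trim_b + 1L, nchar(to$seq))
    newid <- paste0(from$id, "+", to$id)
    merged[[newid]] <- paste0(left, ins$seq_core, right)
    placements <- rbind(placements, data.frame(
      id = ins$id, scaffold_id = newid, core_begin = nchar(left),
      core_end = nchar(left) + nchar(ins$seq_core)))
    sel <- placements$scaffold_id == from$id
    placements$scaffold_id[sel] <- newid
    sel <- placements$scaffold_id == to$id
    off <- nchar(left) + nchar(ins$seq_core) - ins$trim_b
    placements$core_begin[sel] <- placements$core_begin[sel] + off
    placements$core_end[sel] <- placements$core_end[sel] + off
    placements$scaffold_id[sel] <- newid
  }
  keep <- setdiff(names(assembly), used)
  scaffolds <- c(lapply(keep, function(id)
    scaffold_from_seq(id, scaffold_seq(assembly[[id]]))),
    lapply(names(merged), function(id) scaffold_from_seq(id, merged[[id]])))
  list(assembly = new_assembly(scaffolds), placements = placements)
}

# Free scaffolding: contigs joined by insertions only.
apply_free <- function(assembly, by_key) {
  ct <- contig_table(assembly)
  seqs <- setNames(ct$seq, ct$contig_id)
  nbr <- list()
  for (key in names(by_key)) {
    ins <- by_key[[key]]
    nbr[[paste0(ins$contig_a, ":", ins$side_a)]] <- ins
    nbr[[paste0(ins$contig_b, ":", ins$side_b)]] <- ins
  }
  placements <- list()
  visited <- character()
  scaffolds <- list()
  opposite <- function(s) if (s == "begin") "end" else "begin"
  for (start in ct$contig_id) {
    if (start %in% visited) next
    # walk leftward from `start` to find the path's first contig
    cid <- start; out_side <- "begin"; seen <- start
    repeat {
      ins <- nbr[[paste0(cid, ":", out_side)]]
      if (is.null(ins)) break
      nxt <- if (ins$contig_a == cid && ins$side_a == out_side)
        c(ins$contig_b, ins$side_b) else c(ins$contig_a, ins$side_a)
      if (nxt[1] %in% seen) break  # circular path: cut here
      cid <- nxt[1]; out_side <- opposite(nxt[2]); seen <- c(seen, cid)
    }
    # build forward from the leftmost contig
    path <- character(); orient <- logical()
    fwd <- out_side == "begin"  # path exits via the opposite side
    repeat {
      path <- c(path, cid); orient <- c(orient, fwd)
      visited <- c(visited, cid)
      exit_side <- if (fwd) "end" else "begin"
      ins <- nbr[[paste0(cid, ":", exit_side)]]
      if (is.null(ins)) break
      nxt <- if (ins$contig_a == cid && ins$side_a == exit_side)
        c(ins$contig_b, ins$side_b) else c(ins$contig_a, ins$side_a)
      if (nxt[1] %in% visited) break
      cid <- nxt[1]; fwd <- nxt[2] == "begin"
    }
    scid <- paste(path, collapse = "+")
    seq <- ""
    for (i in seq_along(path)) {
      cseq <- if (orient[i]) seqs[[path[i]]] else revcomp(seqs[[path[i]]])
      if (i == 1) { seq <- cseq; next }
      exit_side <- if (orient[i - 1]) "end" else "begin"
      ins <- nbr[[paste0(path[i - 1], ":", exit_side)]]
      fwd_ins <- ins$contig_a == path[i - 1] && ins$side_a == exit_side
      core <- if (fwd_ins) ins$seq_core else revcomp(ins$seq_core)
      tl <- if (fwd_ins) ins$trim_a else ins$trim_b
      tr <- if (fwd_ins) ins$trim_b else ins$trim_a
      left <- substr(seq, 1L, nchar(seq) - tl)
      placements[[length(placements) + 1L]] <- data.frame(
        id = ins$id, scaffold_id = scid, core_begin = nchar(left),
        core_end = nchar(left) + nchar(core), stringsAsFactors = FALSE)
      seq <- paste0(left, core, substr(cseq, tr + 1L, nchar(cseq)))
    }
    scaffolds[[scid]] <- scaffold_from_seq(scid, seq)
  }
  pl <- if (length(placements)) do.call(rbind, placements) else
    data.frame(id = character(), scaffold_id = character(),
               core_begin = integer(), core_end = integer())
  list(assembly = new_assembly(scaffolds), placements = pl)
}

#' Minimum continuous alignment coverage of a region
#'
#' The continuous alignment coverage at position x with window size w is the
#' number of local alignments (unchained, proper or not) whose target
#' interval completely covers `[x, x + w)`; the minimum is taken by sliding
#' the window across the region. Regions shorter than w are evaluated as a
#' single window.
#'
#' @param alns Alignment table against the gap-closed assembly.
#' @param seq_id Target sequence id.
#' @param begin,end Region, 0-based half-open.
#' @param w Window size in bp (default 500).
#' @return Integer minimum coverage.
#' @export
continuous_coverage <- function(alns, seq_id, begin, end, w = 500L) {
  d <- alns[alns$target_id == seq_id, , drop = FALSE]
  if (end - begin < w) { w <- end - begin }
  if (w <= 0) return(0L)
  # an alignment covers window x iff tbeg <= x and tend >= x + w
  x_lo <- begin; x_hi <- end - w
  iv_lo <- pmax(d$tbeg, x_lo)
  iv_hi <- pmin(d$tend - w, x_hi)
  keep <- iv_hi >= iv_lo
  if (!any(keep)) return(0L)
  cov <- IRanges::coverage(IRanges::IRanges(iv_lo[keep] + 1L, iv_hi[keep] + 1L),
                           width = x_hi + 2L)
  win <- IRanges::Views(cov, start = x_lo + 1L, end = x_hi + 1L)
  as.integer(min(IRanges::viewMins(win)))
}

#' Validate closed gaps by re-mapping the reads
#'
#' Maps the input reads to the gap-closed assembly and inspects the region
#' `region_context` bp up- and downstream of each former gap: the closure
#' passes when at least `min_spanning_reads` alignments each span the whole
#' region and the minimum continuous alignment coverage exceeds the
#' threshold ([min_coverage_threshold()]). Failed insertions are marked so
#' the caller reverts them to the original N-run.
#'
#' @param closed List from [apply_insertions()] (`assembly` + `placements`).
#' @param reads Named character vector of reads, or a precomputed alignment
#'   table via `alns`.
#' @param insertions The insertion list that produced `closed`.
#' @param config A [pipeline_config()].
#' @param alns Optional precomputed read-to-closed-assembly alignments.
#' @return The insertion list with `validated` set to `"pass"`/`"fail"`.
#' @export
validate_gaps <- function(closed, reads, insertions,
                          config = pipeline_config(), alns = NULL) {
  pl <- closed$placements
  if (!nrow(pl)) return(insertions)
  if (is.null(alns))
    # validation counts *local* alignments: a stringent break-on-divergence
    # setting makes alignments split at inserted sequence the reads do not
    # support, instead of plowing through it as mismatches
    alns <- map_reads(reads, contig_seqs(closed$assembly),
                      extra = c("-z", "100,50"))
  thr <- min_coverage_threshold(config)
  ct <- contig_table(closed$assembly)
  names(insertions) <- vapply(insertions, `[[`, "", "id")
  for (i in seq_len(nrow(pl))) {
    ins_id <- pl$id[i]
    # locate the containing contig of the closed gap
    cc <- ct[ct$scaffold_id == pl$scaffold_id[i] &
               ct$scaffold_offset <= pl$core_begin[i] &
               ct$scaffold_offset + ct$length >= pl$core_end[i], , drop = FALSE]
    if (!nrow(cc)) { insertions[[ins_id]]$validated <- "fail"; next }
    cc <- cc[1, ]
    begin <- max(0L, pl$core_begin[i] - cc$scaffold_offset -
                   config$region_context)
    end <- min(cc$length, pl$core_end[i] - cc$scaffold_offset +
                 config$region_context)
    d <- alns[alns$target_id == cc$contig_id, , drop = FALSE]
    spanning <- sum(d$tbeg <= begin & d$tend >= end)
    mincov <- continuous_coverage(d, cc$contig_id, begin, end,
                                  config$weak_coverage_window)
    pass <- spanning >= config$min_spanning_reads && mincov > thr
    insertions[[ins_id]]$validated <- if (pass) "pass" else "fail"
    if (!pass) insertions[[ins_id]]$reason <- "validation"
  }
  insertions
}
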