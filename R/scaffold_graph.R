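#' Scaffold graph: four nodes per contig
#'
#' The graph connects contig ends using the filtered read alignments. Every
#' contig i contributes nodes `pre`, `begin`, `end`, `post`; edge types are
#' `contig` (`begin`--`end` of one contig), `input_gap` (intra-scaffold gap
#' between adjacent contigs of the input assembly), `span` (reads bridging
#' two contig ends) and `extension` (reads running past a contig end).
#' Each span/extension edge carries its supporting read ids.
#'
#' @name scaffold-graph
NULL

edge_key <- function(ca, sa, cb, sb) {
  a <- paste0(ca, ":", sa); b <- paste0(cb, ":", sb)
  if (a <= b) paste(a, b, sep = "--") else paste(b, a, sep = "--")
}

new_graph <- function(edges, alns, contigs, allowance) {
  structure(list(edges = edges, alns = alns, contigs = contigs,
                 allowance = allowance),
            class = "spanweld_graph")
}

#' @export
print.spanweld_graph <- function(x, ...) {
  types <- vapply(x$edges, `[[`, "", "type")
  cat("<scaffold graph: ", sum(types == "contig"), " contigs, ",
      sum(types == "input_gap"), " input gaps, ", sum(types == "span"),
      " span edges, ", sum(types == "extension"), " extension edges>\n",
      sep = "")
  invisible(x)
}

#' Tabular edge list of a scaffold graph
#' @param graph A `spanweld_graph`.
#' @return `data.frame` with node endpoints, type, support and read ids.
#' @export
graph_edges <- function(graph) {
  rows <- lapply(graph$edges, function(e) {
    data.frame(node1 = paste0(e$contig_a, ":", e$side_a),
               node2 = paste0(e$contig_b, ":", e$side_b), type = e$type,
               support = length(e$reads),
               read_ids = paste(e$reads, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame(node1 = character(), node2 = character(),
                                      type = character(), support = integer(),
                                      read_ids = character())
  out
}

# the side of contig through which a read *leaves* (after aligning it)
leave_side <- function(strand) if (strand == "+") "end" else "begin"
# the side through which a read *enters* a contig
enter_side <- function(strand) if (strand == "+") "begin" else "end"

touches_side <- function(aln, side, allowance) {
  if (side == "begin") aln$tbeg <= allowance
  else aln$target_len - aln$tend <= allowance
}

#' Build the scaffold graph from filtered alignments
#'
#' Seeds contig and input-gap edges, then walks every read's alignments in
#' read order: consecutive alignment pairs that are anchored at the facing
#' contig ends become span edges, unaligned read tails running past a contig
#' end become extension edges. Transitive edges (skipping over an aligned
#' intermediate contig) are not added.
#'
#' @param assembly A `spanweld_assembly`.
#' @param filtered_alns Output of [filter_reliable()].
#' @param allowance End-tolerance in bp (default 100).
#' @return A `spanweld_graph`.
#' @export
build_graph <- function(assembly, filtered_alns, allowance = 100L) {
  contigs <- contig_table(assembly)
  edges <- list()
  add_edge <- function(type, ca, sa, cb, sb, read = NULL, alns = NULL) {
    key <- paste0(type, "|", edge_key(ca, sa, cb, sb))
    e <- edges[[key]]
    if (is.null(e)) {
      ord <- order(c(paste0(ca, ":", sa), paste0(cb, ":", sb)))
      ends <- list(c(ca, sa), c(cb, sb))[ord]
      e <- list(type = type, contig_a = ends[[1]][1], side_a = ends[[1]][2],
                contig_b = ends[[2]][1], side_b = ends[[2]][2],
                reads = character())
    }
    if (!is.null(read) && !read %in% e$reads) e$reads <- c(e$reads, read)
    edges[[key]] <<- e
  }
  for (i in seq_len(nrow(contigs)))
    add_edge("contig", contigs$contig_id[i], "begin",
             contigs$contig_id[i], "end")
  gt <- gap_table(assembly)
  for (i in seq_len(nrow(gt)))
    add_edge("input_gap", gt$left_contig[i], "end", gt$right_contig[i], "begin")
  if (nrow(filtered_alns)) {
    for (rid in unique(filtered_alns$query_id)) {
      d <- filtered_alns[filtered_alns$query_id == rid, , drop = FALSE]
      d <- d[order(d$qbeg), , drop = FALSE]
      # span edges between consecutive alignments
      if (nrow(d) > 1) {
        for (i in seq_len(nrow(d) - 1)) {
          a1 <- d[i, ]; a2 <- d[i + 1, ]
          if (a1$target_id == a2$target_id) next
          s1 <- leave_side(a1$strand); s2 <- enter_side(a2$strand)
          if (touches_side(a1, s1, allowance) &&
              touches_side(a2, s2, allowance))
            add_edge("span", a1$target_id, s1, a2$target_id, s2, rid)
        }
      }
      # extension edges at the read's outer ends
      first <- d[1, ]; last <- d[nrow(d), ]
      if (first$qbeg > allowance) {
        s <- enter_side(first$strand)  # boundary the read extends past
        if (touches_side(first, s, allowance)) {
          v <- if (s == "begin") "pre" else "post"
          add_edge("extension", first$target_id, s, first$target_id, v, rid)
        }
      }
      if (last$query_len - last$qend > allowance) {
        s <- leave_side(last$strand)
        if (touches_side(last, s, allowance)) {
          v <- if (s == "begin") "pre" else "post"
          add_edge("extension", last$target_id, s, last$target_id, v, rid)
        }
      }
    }
  }
  new_graph(edges, filtered_alns, contigs, allowance)
}

span_edges <- function(graph) {
  keys <- names(graph$edges)
  keys[vapply(graph$edges, function(e) e$type == "span", TRUE)]
}

# span edges incident to a contig-side node, as keys
incident_span <- function(graph, contig, side) {
  keys <- span_edges(graph)
  keys[vapply(graph$edges[keys], function(e) {
    (e$contig_a == contig && e$side_a == side) ||
      (e$contig_b == contig && e$side_b == side)
  }, TRUE)]
}

other_end <- function(e, contig, side) {
  if (e$contig_a == contig && e$side_a == side) c(e$contig_b, e$side_b)
  else c(e$contig_a, e$side_a)
}

#' Repair small cycles caused by skipped contigs
#'
#' A long low-quality read can fail to align to a small intermediate contig
#' while still aligning to its two neighbours, creating a "skipping" span
#' edge parallel to the stepwise path and hence a small cycle. For each
#' skipping edge parallel to a path of at most `max_skipped` intermediate
#' contigs, the skipping reads are re-aligned to the intermediate contigs
#' with increased sensitivity (error ceiling raised by 5 percentage points,
#' halved seed requirements). On success the read is moved onto the stepwise
#' edges and its new alignments are recorded; on failure it is dropped from
#' the skipping edge. Emptied skipping edges are deleted.
#'
#' @param graph A `spanweld_graph`.
#' @param reads Named character vector of read sequences.
#' @param config A [pipeline_config()].
#' @param max_skipped Maximum intermediate contigs in a repaired cycle
#'   (default 3).
#' @return The repaired `spanweld_graph`.
#' @export
resolve_small_cycles <- function(graph, reads, config = pipeline_config(),
                                 max_skipped = 3L) {
  cseqs <- setNames(graph$contigs$seq, graph$contigs$contig_id)
  repeat {
    changed <- FALSE
    for (key in span_edges(graph)) {
      e <- graph$edges[[key]]
      if (is.null(e)) next
      # search for an alternative stepwise path between the edge's endpoints
      path <- find_stepwise_path(graph, e, max_skipped)
      if (is.null(path)) next
      intermediates <- path$intermediates
      for (rid in e$reads) {
        ok <- TRUE
        new_alns <- list()
        for (cid in intermediates) {
          hit <- align_pair(reads[[rid]], cseqs[[cid]], mode = "local",
                            max_err = config$max_err + 0.05,
                            min_len = max(100L, config$min_anchor_length %/% 2L),
                            k = 9L, min_seeds = 2L,
                            query_id = rid, target_id = cid)
          if (!nrow(hit)) { ok <- FALSE; break }
          best <- hit[which.max(hit$n_match), , drop = FALSE]
          new_alns[[length(new_alns) + 1L]] <- best
        }
        # remove read from the skipping edge either way
        e$reads <- setdiff(e$reads, rid)
        if (ok) {
          graph$alns <- as_alignments(
            rbind(graph$alns, do.call(rbind, new_alns)))
          for (skey in path$span_keys) {
            se <- graph$edges[[skey]]
            if (!rid %in% se$reads) se$reads <- c(se$reads, rid)
            graph$edges[[skey]] <- se
          }
        }
        changed <- TRUE
      }
      if (!length(e$reads)) graph$edges[[key]] <- NULL
      else graph$edges[[key]] <- e
    }
    if (!changed) break
  }
  graph
}

# Find a path from one endpoint of span edge `e` to the other through
# 1..max_skipped intermediate contigs using other span edges; returns the
# intermediate contig ids and the stepwise span edge keys, or NULL.
find_stepwise_path <- function(graph, e, max_skipped) {
  start <- c(e$contig_a, e$side_a)
  goal <- c(e$contig_b, e$side_b)
  e_key <- paste0("span|", edge_key(e$contig_a, e$side_a,
                                    e$contig_b, e$side_b))
  dfs <- function(node, used_contigs, span_keys, depth) {
    if (depth > max_skipped) return(NULL)
    for (key in incident_span(graph, node[1], node[2])) {
      if (key == e_key) next
      se <- graph$edges[[key]]
      nxt <- other_end(se, node[1], node[2])
      if (identical(nxt, goal) && depth >= 1)
        return(list(intermediates = used_contigs,
                    span_keys = c(span_keys, key)))
      if (nxt[1] %in% c(used_contigs, e$contig_a, e$contig_b)) next
      # traverse the intermediate contig to its other side
      far <- c(nxt[1], if (nxt[2] == "begin") "end" else "begin")
      res <- dfs(far, c(used_contigs, nxt[1]), c(span_keys, key), depth + 1)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  dfs(start, character(), character(), 0L)
}

#' Resolve remaining scaffolding conflicts
#'
#' For every contig-end node with more than one incident spanning edge, the
#' edge with the highest effective support is kept only when it has at least
#' `margin` times the effective support of every competitor; otherwise all
#' competing edges are discarded. Effective support is the read count,
#' multiplied by `gap_bonus` for edges that coincide with an intra-scaffold
#' gap of the input assembly.
#'
#' @param graph A `spanweld_graph` (cycles already repaired).
#' @param margin Required superiority factor (default 3).
#' @param gap_bonus Input-gap support multiplier (default 6).
#' @return The conflict-free `spanweld_graph`.
#' @export
resolve_conflicts <- function(graph, margin = 3, gap_bonus = 6) {
  eff_support <- function(key) {
    e <- graph$edges[[key]]
    s <- length(e$reads)
    gap_key <- paste0("input_gap|", edge_key(e$contig_a, e$side_a,
                                             e$contig_b, e$side_b))
    if (!is.null(graph$edges[[gap_key]])) s <- s * gap_bonus
    s
  }
  nodes <- unique(do.call(rbind, lapply(graph$edges[span_edges(graph)],
    function(e) rbind(c(e$contig_a, e$side_a), c(e$contig_b, e$side_b)))))
  to_delete <- character()
  for (i in seq_len(NROW(nodes))) {
    keys <- incident_span(graph, nodes[i, 1], nodes[i, 2])
    if (length(keys) < 2) next
    eff <- vapply(keys, eff_support, 0)
    best <- which.max(eff)
    if (all(eff[best] >= margin * eff[-best])) {
      to_delete <- c(to_delete, keys[-best])
    } else {
      to_delete <- c(to_delete, keys)
    }
  }
  for (key in unique(to_delete)) graph$edges[[key]] <- NULL
  graph
}

#' Prune weak spanning edges and collect pile-ups
#'
#' Removes spanning edges supported by fewer than `min_spanning_reads` reads
#' (no reliable consensus can come from one or two reads), then emits one
#' pile-up per surviving spanning edge, merging in the reads of the
#' extension edges at the two involved contig ends.
#'
#' @param graph A conflict-free `spanweld_graph`.
#' @param min_spanning_reads Minimum spanning reads (default 3).
#' @param allow_single_reads Expert option: keep single-read edges.
#' @return List of `spanweld_pileup` objects.
#' @export
prune_and_collect <- function(graph, min_spanning_reads = 3L,
                              allow_single_reads = FALSE) {
  minr <- if (allow_single_reads) 1L else as.integer(min_spanning_reads)
  pileups <- list()
  for (key in span_edges(graph)) {
    e <- graph$edges[[key]]
    if (length(e$reads) < minr) { graph$edges[[key]] <- NULL; next }
    ext_reads <- function(contig, side) {
      v <- if (side == "begin") "pre" else "post"
      ekey <- paste0("extension|", edge_key(contig, side, contig, v))
      ee <- graph$edges[[ekey]]
      if (is.null(ee)) character() else ee$reads
    }
    ext_a <- setdiff(ext_reads(e$contig_a, e$side_a), e$reads)
    ext_b <- setdiff(ext_reads(e$contig_b, e$side_b), e$reads)
    gap_key <- paste0("input_gap|", edge_key(e$contig_a, e$side_a,
                                             e$contig_b, e$side_b))
    all_reads <- c(e$reads, union(ext_a, ext_b))
    pu <- structure(list(
      id = edge_key(e$contig_a, e$side_a, e$contig_b, e$side_b),
      contig_a = e$contig_a, side_a = e$side_a,
      contig_b = e$contig_b, side_b = e$side_b,
      span_reads = e$reads, ext_a = ext_a, ext_b = ext_b,
      reads = all_reads,
      type = if (length(ext_a) || length(ext_b)) "mixed" else "span",
      is_input_gap = !is.null(graph$edges[[gap_key]]),
      alns = graph$alns[graph$alns$query_id %in% all_reads &
                          graph$alns$target_id %in%
                            c(e$contig_a, e$contig_b), , drop = FALSE]),
      class = "spanweld_pileup")
    pileups[[length(pileups) + 1L]] <- pu
  }
  pileups
}

#' @export
print.spanweld_pileup <- function(x, ...) {
  cat("<pile-up ", x$id, ": ", length(x$span_reads), " spanning + ",
      length(x$ext_a) + length(x$ext_b), " extending reads>\n", sep = "")
  invisible(x)
}
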