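make_span_fixture <- function() {
  set.seed(41)
  fx <- two_contig_fixture(n_reads = 3L)
  alns <- filter_reliable(map_reads(fx$reads, contig_seqs(fx$assembly)),
                          mask_track())
  list(fx = fx, alns = alns)
}

test_that("spanning reads create one span edge with pooled support", {
  sf <- make_span_fixture()
  g <- build_graph(sf$fx$assembly, sf$alns)
  e <- graph_edges(g)
  expect_equal(sum(e$type == "contig"), 2L)
  expect_equal(sum(e$type == "input_gap"), 1L)
  span <- e[e$type == "span", ]
  expect_equal(nrow(span), 1L)
  expect_equal(span$support, 3L)
})

test_that("reads across three contigs add no transitive edges", {
  # one read aligning contigs c1, c2, c3 consecutively
  alns <- do.call(rbind, lapply(1:3, function(i)
    aln_row(query_id = "r", query_len = 3300L,
            qbeg = (i - 1L) * 1100L, qend = (i - 1L) * 1100L + 1000L,
            target_id = paste0("c", i, ".1"), target_len = 1000L,
            tbeg = 0L, tend = 1000L)))
  asm <- assembly_from_parts(list(c1 = list(strrep("A", 1000)),
                                  c2 = list(strrep("C", 1000)),
                                  c3 = list(strrep("G", 1000))))
  g <- build_graph(asm, alns)
  e <- graph_edges(g)
  span <- e[e$type == "span", ]
  expect_equal(nrow(span), 2L)
  expect_false(any(grepl("c1\\.", span$node1) & grepl("c3\\.", span$node2)))
})

test_that("reads running past a contig end create extension edges", {
  aln <- aln_row(query_id = "r", query_len = 3000L, qbeg = 0L, qend = 1000L,
                 target_id = "c1", target_len = 5000L, tbeg = 4000L,
                 tend = 5000L)
  asm <- assembly_from_parts(list(c1 = list(strrep("A", 5000))))
  g <- build_graph(asm, aln)
  e <- graph_edges(g)
  ext <- e[e$type == "extension", ]
  expect_equal(nrow(ext), 1L)
  expect_true(grepl("post", ext$node2))
})

test_that("conflict resolution applies the margin and gap bonus rules", {
  mk_graph <- function(support_x, support_y, y_is_gap = FALSE) {
    set.seed(42)
    L <- random_seq(1000); X <- random_seq(1000); Y <- random_seq(1000)
    if (y_is_gap) {
      asm <- assembly_from_parts(list(s1 = list(L, 50L, Y),
                                      s2 = list(X)))
      y_id <- "s1.2"; x_id <- "s2.1"
    } else {
      asm <- assembly_from_parts(list(s1 = list(L), s2 = list(X),
                                      s3 = list(Y)))
      y_id <- "s3.1"; x_id <- "s2.1"
    }
    rows <- list()
    add_read <- function(rid, to_contig) {
      rows[[length(rows) + 1L]] <<- rbind(
        aln_row(query_id = rid, query_len = 2100L, qbeg = 0L, qend = 1000L,
                target_id = "s1.1", target_len = 1000L, tbeg = 0L,
                tend = 1000L),
        aln_row(query_id = rid, query_len = 2100L, qbeg = 1100L,
                qend = 2100L, target_id = to_contig, target_len = 1000L,
                tbeg = 0L, tend = 1000L))
    }
    # conflicting span edges out of s1.1:end
    for (i in seq_len(support_x)) add_read(sprintf("x%02d", i), x_id)
    for (i in seq_len(support_y)) add_read(sprintf("y%02d", i), y_id)
    build_graph(asm, do.call(rbind, rows))
  }
  # supports {9, 3}: keep 9 (9 >= 3*3)
  g <- resolve_conflicts(mk_graph(9L, 3L))
  span <- graph_edges(g)
  span <- span[span$type == "span", ]
  expect_equal(nrow(span), 1L)
  expect_equal(span$support, 9L)
  # supports {8, 3}: delete both (8 < 9)
  g <- resolve_conflicts(mk_graph(8L, 3L))
  expect_equal(sum(graph_edges(g)$type == "span"), 0L)
  # input-gap bonus: {4, 2*6=12}: keep the bonus edge (12 >= 3*4)
  g <- resolve_conflicts(mk_graph(4L, 2L, y_is_gap = TRUE))
  span <- graph_edges(g)
  span <- span[span$type == "span", ]
  expect_equal(nrow(span), 1L)
  expect_equal(span$support, 2L)
})

test_that("after conflict resolution every contig end has at most one edge", {
  set.seed(43)
  gen <- simulate_genome(60000, seed = 44)
  spec <- sample_gap_spec(gen$assembly, 3L, c(100L, 400L), seed = 45)
  ta <- make_test_assembly(gen$assembly, gap_spec = spec)
  sim <- simulate_reads(gen$assembly, coverage = 15, mean_len = 8000,
                        error = 0, seed = 46)
  alns <- filter_reliable(map_reads(sim$reads, contig_seqs(ta$assembly)),
                          mask_track())
  g <- build_graph(ta$assembly, alns)
  contig_before <- graph_edges(g)
  contig_before <- contig_before[contig_before$type == "contig", ]
  g <- resolve_conflicts(g)
  e <- graph_edges(g)
  span <- e[e$type == "span", ]
  nodes <- c(span$node1, span$node2)
  expect_true(all(table(nodes) <= 1L))
  # contig edges never modified
  after <- e[e$type == "contig", ]
  expect_equal(after$node1, contig_before$node1)
  # error-free conflict-free fixture: surviving edges = true adjacency
  gt <- gap_table(ta$assembly)
  want <- sort(paste0(gt$left_contig, ":end--", gt$right_contig, ":begin"))
  got <- sort(paste0(span$node1, "--", span$node2))
  expect_equal(got, want)
})

test_that("weak spanning edges are pruned and pile-ups merge extensions", {
  sf <- make_span_fixture()
  g <- build_graph(sf$fx$assembly, sf$alns)
  pus <- prune_and_collect(g, min_spanning_reads = 3L)
  expect_length(pus, 1L)
  expect_length(pus[[1]]$span_reads, 3L)
  # with a higher threshold the edge disappears
  expect_length(prune_and_collect(g, min_spanning_reads = 4L), 0L)
  # expert option keeps single-read edges
  expect_length(prune_and_collect(g, min_spanning_reads = 4L,
                                  allow_single_reads = TRUE), 1L)
})

test_that("small cycles are repaired by re-aligning skipping reads", {
  set.seed(47)
  # genome: big contig A, small contig B (800 bp), big contig C
  a <- random_seq(4000); b <- random_seq(800); c <- random_seq(4000)
  genome <- paste0(a, b, c)
  asm <- assembly_from_parts(list(A = list(a), B = list(b), C = list(c)))
  # stepwise reads: align A,B,C -> edges (A,B),(B,C)
  rows <- list(); reads <- character()
  for (i in 1:3) {
    rid <- paste0("s", i)
    reads[[rid]] <- substr(genome, 3001, 5801)  # covers A-end, B, C-begin
    rows[[length(rows) + 1L]] <- rbind(
      aln_row(rid, 2801L, 0L, 1000L, "+", "A.1", 4000L, 3000L, 4000L),
      aln_row(rid, 2801L, 1000L, 1800L, "+", "B.1", 800L, 0L, 800L),
      aln_row(rid, 2801L, 1800L, 2801L, "+", "C.1", 4000L, 0L, 1001L))
  }
  # one skipping read missing the B alignment
  reads[["skip"]] <- substr(genome, 3001, 5801)
  rows[[length(rows) + 1L]] <- rbind(
    aln_row("skip", 2801L, 0L, 1000L, "+", "A.1", 4000L, 3000L, 4000L),
    aln_row("skip", 2801L, 1800L, 2801L, "+", "C.1", 4000L, 0L, 1001L))
  g <- build_graph(asm, do.call(rbind, rows))
  before <- graph_edges(g)
  expect_equal(sum(before$type == "span"), 3L)  # (A,B),(B,C),(A,C)
  g2 <- resolve_small_cycles(g, unlist(reads))
  after <- graph_edges(g2)
  span <- after[after$type == "span", ]
  expect_equal(nrow(span), 2L)  # skipping edge dissolved
  expect_true(all(span$support == 4L))  # read moved onto stepwise edges
  # a graph without cycles is unchanged
  sf <- make_span_fixture()
  g3 <- build_graph(sf$fx$assembly, sf$alns)
  expect_equal(graph_edges(resolve_small_cycles(g3, sf$fx$reads)),
               graph_edges(g3))
})

test_that("re-alignment failure discards the skipping read", {
  set.seed(48)
  a <- random_seq(4000); b <- random_seq(800); c <- random_seq(4000)
  asm <- assembly_from_parts(list(A = list(a), B = list(b), C = list(c)))
  genome <- paste0(a, b, c)
  rows <- list(); reads <- character()
  for (i in 1:3) {
    rid <- paste0("s", i)
    reads[[rid]] <- substr(genome, 3001, 5801)
    rows[[length(rows) + 1L]] <- rbind(
      aln_row(rid, 2801L, 0L, 1000L, "+", "A.1", 4000L, 3000L, 4000L),
      aln_row(rid, 2801L, 1000L, 1800L, "+", "B.1", 800L, 0L, 800L),
      aln_row(rid, 2801L, 1800L, 2801L, "+", "C.1", 4000L, 0L, 1001L))
  }
  # chimeric read joining A and C without any B sequence
  reads[["skip"]] <- paste0(substr(a, 3001, 4000), substr(c, 1, 1001))
  rows[[length(rows) + 1L]] <- rbind(
    aln_row("skip", 2001L, 0L, 1000L, "+", "A.1", 4000L, 3000L, 4000L),
    aln_row("skip", 2001L, 1000L, 2001L, "+", "C.1", 4000L, 0L, 1001L))
  g <- build_graph(asm, do.call(rbind, rows))
  g2 <- resolve_small_cycles(g, unlist(reads))
  span <- graph_edges(g2)
  span <- span[span$type == "span", ]
  expect_equal(nrow(span), 2L)
  expect_false(any(grepl("skip", span$read_ids)))
})
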