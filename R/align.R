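#' Reverse complement
#' @param x Character vector of DNA sequences.
#' @return Character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Pairwise alignment of two sequences
#'
#' The package's reference aligner: a seed-and-extend banded edit-distance
#' search for `mode = "local"` (k-mer seeds, diagonal clustering, banded
#' extension, best-subpath trimming), a free-end-gap ("infix") alignment of
#' the whole of `seq_a` inside `seq_b` for `mode = "semi_global"`, and plain
#' banded global alignment for `mode = "global"`. All modes report a full
#' trace (`=XID` CIGAR) and are deterministic. Adequate for desk-scale
#' genomes; whole-assembly read mapping goes through [map_reads()].
#'
#' @param seq_a,seq_b ACGT sequences (query and target).
#' @param mode `"local"`, `"semi_global"` or `"global"`.
#' @param max_err Maximum error rate (edits / alignment columns) of reported
#'   alignments.
#' @param min_len Minimum alignment length (local mode).
#' @param k Seed k-mer length (local mode).
#' @param min_seeds Minimum seeds per cluster (local mode).
#' @param both_strands Also search the reverse complement of `seq_b`.
#' @param query_id,target_id Ids recorded in the output table.
#' @return Alignment `data.frame` (possibly zero rows), query coordinates on
#'   the forward strand of `seq_a`, target coordinates on the forward strand
#'   of `seq_b`.
#' @export
align_pair <- function(seq_a, seq_b, mode = c("local", "semi_global", "global"),
                       max_err = 0.3, min_len = 100L, k = 11L, min_seeds = 3L,
                       both_strands = TRUE, query_id = "A", target_id = "B") {
  mode <- match.arg(mode)
  n <- nchar(seq_a); m <- nchar(seq_b)
  res <- list()
  run_strand <- function(target, strand) {
    if (mode == "local") {
      hits <- cpp_align_local(seq_a, target, as.integer(k), as.integer(min_len),
                              max_err, as.integer(min_seeds), 64L)
      lapply(hits, function(h) {
        tb <- h$tbeg; te <- h$tend
        if (strand == "-") { tb <- m - h$tend; te <- m - h$tbeg }
        data.frame(query_id = query_id, query_len = n, qbeg = h$qbeg,
                   qend = h$qend, strand = strand, target_id = target_id,
                   target_len = m, tbeg = tb, tend = te, n_match = h$nmatch,
                   aln_len = h$alen, mapq = 60L, cigar = h$cigar,
                   chain_id = NA_integer_, stringsAsFactors = FALSE)
      })
    } else {
      h <- if (mode == "global") cpp_align_global(seq_a, target, 0L)
           else cpp_align_infix(seq_a, target)
      if (!isTRUE(h$ok)) return(list())
      err <- if (h$alen > 0) h$edit / h$alen else 0
      if (err > max_err) return(list())
      tb <- h$tbeg; te <- h$tend
      if (strand == "-") { tb <- m - h$tend; te <- m - h$tbeg }
      list(data.frame(query_id = query_id, query_len = n, qbeg = h$qbeg,
                      qend = h$qend, strand = strand, target_id = target_id,
                      target_len = m, tbeg = tb, tend = te,
                      n_match = h$nmatch, aln_len = h$alen, mapq = 60L,
                      cigar = h$cigar, chain_id = NA_integer_,
                      stringsAsFactors = FALSE))
    }
  }
  res <- run_strand(seq_b, "+")
  if (both_strands && n > 0 && m > 0)
    res <- c(res, run_strand(revcomp(seq_b), "-"))
  if (!length(res)) return(empty_alignments())
  out <- as_alignments(do.call(rbind, res))
  if (mode != "local" && nrow(out) > 1) {
    # keep the better strand only
    err <- (out$aln_len - out$n_match) / pmax(out$aln_len, 1L)
    out <- out[order(err, out$strand), ][1, , drop = FALSE]
  }
  out <- out[order(out$qbeg, out$tbeg, out$strand), , drop = FALSE]
  # drop duplicate intervals from overlapping seed clusters
  key <- paste(out$qbeg, out$qend, out$tbeg, out$tend, out$strand)
  as_alignments(out[!duplicated(key), , drop = FALSE])
}

minimap2_available <- function() nzchar(Sys.which("minimap2"))

write_seqs_tmp <- function(x, prefix) {
  if (length(x) == 1 && is.null(names(x)) && file.exists(x)) return(x)
  path <- tempfile(prefix, fileext = ".fa")
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  write_fasta(x, path)
  path
}

run_minimap2 <- function(args) {
  if (!minimap2_available())
    stop("minimap2 not found on PATH; required for whole-assembly mapping")
  out <- tempfile("mm2", fileext = ".paf")
  err <- system2("minimap2", c(args, "-o", out), stderr = FALSE)
  if (err != 0) stop("minimap2 failed (exit ", err, ")")
  paf <- read_paf(out)
  unlink(out)
  paf
}

#' Map long reads to a target sequence set with minimap2
#'
#' Thin deterministic wrapper (single-threaded, fixed flags) around the
#' standard long-read mapper; emits one local alignment per PAF record with
#' an exact (`=X`) trace for primaries. Secondary alignments are kept: they
#' carry the repeat signal the coverage masks need.
#'
#' @param reads Named character vector of read sequences, or a FASTA path.
#' @param targets Named character vector (e.g. [contig_seqs()]) or FASTA path.
#' @param preset minimap2 preset (`map-pb` for CLR reads).
#' @param extra Extra command-line arguments.
#' @return Alignment `data.frame`, sorted for determinism.
#' @export
map_reads <- function(reads, targets, preset = "map-pb", extra = character()) {
  rf <- write_seqs_tmp(reads, "reads")
  tf <- write_seqs_tmp(targets, "targets")
  paf <- run_minimap2(c("-c", "--eqx", "-t", "1", "-x", preset,
                        "-N", "10", extra, tf, rf))
  paf[order(paf$query_id, paf$target_id, paf$qbeg, paf$tbeg, paf$strand), ,
      drop = FALSE]
}

#' All-vs-all self-alignment of an assembly's contigs
#'
#' Finds alignments between different genomic regions (repeat copies) with
#' minimap2, excluding the trivial self-diagonal; input to
#' [self_alignment_mask()].
#'
#' @param contigs Named character vector of contig sequences or FASTA path.
#' @param preset minimap2 preset; `asm20` tolerates ~20% divergence between
#'   repeat copies.
#' @return Alignment `data.frame`.
#' @export
self_align <- function(contigs, preset = "asm20") {
  cf <- write_seqs_tmp(contigs, "self")
  paf <- run_minimap2(c("-c", "--eqx", "-t", "1", "-X", "-x", preset,
                        "-p", "0.2", "-N", "100", cf, cf))
  # drop residual self-diagonal records
  diag <- paf$query_id == paf$target_id &
    pmax(paf$qbeg, paf$tbeg) < pmin(paf$qend, paf$tend) & paf$strand == "+"
  paf <- paf[!diag, , drop = FALSE]
  paf[order(paf$query_id, paf$target_id, paf$qbeg, paf$tbeg, paf$strand), ,
      drop = FALSE]
}
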