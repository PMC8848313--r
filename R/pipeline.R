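#' Close assembly gaps with long reads
#'
#' Runs the full pipeline: map the reads to the assembly's contigs, build
#' and homogenize the four repeat annotations, filter the alignments down
#' to the reliable set, build the scaffold graph and resolve its conflicts,
#' compute one anchored consensus insertion per surviving pile-up, apply
#' the insertions under the chosen mode, and validate every closed gap by
#' re-mapping the reads; failed closures revert to the original N-run.
#'
#' @param assembly A `spanweld_assembly` (or FASTA path).
#' @param reads Named character vector of reads (or FASTA/FASTQ path).
#' @param config A [pipeline_config()]; when `read_coverage` is unset it is
#'   computed as summed read length over assembly contig length.
#' @param mode Closing mode, see [apply_insertions()].
#' @param validate Run the validation step (default TRUE).
#' @param verbose Print stage progress.
#' @return List with `assembly` (final gap-closed `spanweld_assembly`),
#'   `insertions`, `placements` (applied insertion coordinates), `masks`,
#'   `n_pileups`, `config`.
#' @export
close_gaps <- function(assembly, reads, config = pipeline_config(),
                       mode = c("intra_only", "intra_and_inter",
                                "free_scaffolding"),
                       validate = TRUE, verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.character(assembly) && length(assembly) == 1)
    assembly <- read_fasta(assembly)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads[[1]]) &&
      is.null(names(reads)))
    reads <- read_reads(reads)
  say <- function(...) if (verbose) message(...)
  contigs <- contig_seqs(assembly)
  if (is.null(config$read_coverage))
    config$read_coverage <- sum(nchar(reads)) / sum(nchar(contigs))
  say("mapping ", length(reads), " reads to ", length(contigs), " contigs")
  read_alns <- map_reads(reads, contigs)
  say("computing repeat annotations")
  masks <- repeat_annotations(assembly, read_alns, config)
  say("filtering ", nrow(read_alns), " alignments")
  filtered <- filter_reliable(read_alns, masks$final,
                              config$min_anchor_length,
                              config$proper_alignment_allowance)
  say("building scaffold graph from ", nrow(filtered),
      " reliable alignments")
  graph <- build_graph(assembly, filtered,
                       config$proper_alignment_allowance)
  graph <- resolve_small_cycles(graph, reads, config)
  graph <- resolve_conflicts(graph, config$best_pile_up_margin,
                             config$existing_gap_bonus)
  pileups <- prune_and_collect(graph, config$min_spanning_reads,
                               config$allow_single_reads)
  if (mode == "intra_only")
    pileups <- Filter(function(p) p$is_input_gap, pileups)
  say(length(pileups), " pile-ups")
  insertions <- list()
  for (pu in pileups) {
    ins <- tryCatch(
      close_one_gap(pu, reads, contigs, config),
      error = function(e) NULL)
    if (!is.null(ins)) insertions[[length(insertions) + 1L]] <- ins
  }
  say(sum(vapply(insertions, function(x) x$validated != "fail", TRUE)),
      " candidate insertions")
  closed <- apply_insertions(assembly, insertions, mode)
  if (validate && nrow(closed$placements)) {
    say("validating closed gaps")
    insertions <- validate_gaps(closed, reads, insertions, config)
    passing <- Filter(function(x) identical(x$validated, "pass"), insertions)
    closed <- apply_insertions(assembly, passing, mode)
  }
  say(nrow(closed$placements), " gaps closed")
  list(assembly = closed$assembly, insertions = insertions,
       placements = closed$placements, masks = masks,
       n_pileups = length(pileups), config = config)
}

#' Consensus insertion for a single pile-up
#'
#' Crops the pile-up, computes pairwise chains and intrinsic QVs, selects
#' the reference read, calls the consensus and anchors it into the flanks.
#'
#' @param pileup A `spanweld_pileup`.
#' @param reads,contigs Named sequence vectors.
#' @param config A [pipeline_config()].
#' @param max_depth Pile-ups deeper than this are downsampled (spanning
#'   reads kept preferentially; default 24) — extra depth adds little to
#'   consensus accuracy but scales the pairwise work quadratically.
#' @return A `spanweld_insertion` (possibly with `validated == "fail"`), or
#'   `NULL` when too few spanning reads survive cropping.
#' @export
close_one_gap <- function(pileup, reads, contigs,
                          config = pipeline_config(), max_depth = 24L) {
  pileup <- crop_pileup(pileup, reads, contigs)
  minr <- if (config$allow_single_reads) 1L else config$min_spanning_reads
  if (sum(pileup$cropped$role == "span") < minr) return(NULL)
  if (nrow(pileup$cropped) > max_depth) {
    keep <- order(pileup$cropped$role != "span")[seq_len(max_depth)]
    pileup$cropped <- pileup$cropped[sort(keep), , drop = FALSE]
  }
  chains <- pileup_chains(pileup, config)
  qvs <- intrinsic_qv(pileup, chains)
  ref <- select_reference_read(pileup, qvs, config$bad_fraction)
  cons <- pileup_consensus(pileup, ref, chains, config)
  anchor_insertion(cons, pileup, config)
}

#' Write pipeline outputs
#'
#' Emits the final FASTA and AGP, a closed-gap BED (status column per
#' insertion) and an insertion TSV.
#'
#' @param result Output of [close_gaps()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named vector of written paths, invisibly.
#' @export
write_outputs <- function(result, dir, prefix = "spanweld") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  agp <- file.path(dir, paste0(prefix, ".agp"))
  bed <- file.path(dir, paste0(prefix, ".closed.bed"))
  tsv <- file.path(dir, paste0(prefix, ".insertions.tsv"))
  write_fasta(result$assembly, fa)
  write_agp(result$assembly, agp)
  ins <- result$insertions
  df <- data.frame(
    gap_id = vapply(ins, `[[`, "", "id"),
    contig_a = vapply(ins, `[[`, "", "contig_a"),
    contig_b = vapply(ins, `[[`, "", "contig_b"),
    status = vapply(ins, `[[`, "", "validated"),
    core_len = vapply(ins, function(x)
      if (is.null(x$seq_core)) 0L else nchar(x$seq_core), 0L))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  pl <- result$placements
  if (nrow(pl)) {
    st <- df$status[match(pl$id, df$gap_id)]
    write.table(data.frame(pl$scaffold_id, pl$core_begin, pl$core_end,
                           pl$id, 0L, "+", st),
                bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else file.create(bed)
  invisible(c(fasta = fa, agp = agp, bed = bed, tsv = tsv))
}
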