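#' Pipeline configuration
#'
#' Collects every tunable of the gap-closing pipeline with its default. The
#' defaults are the published operating point of the method; they are
#' deliberately conservative, favouring accuracy over sensitivity.
#'
#' @param read_coverage Global long-read coverage \eqn{C} (summed read length
#'   divided by genome size). Mandatory for the coverage-based repeat masks
#'   and the derived validation threshold.
#' @param ploidy Ploidy of the sequenced organism (default 1 for the haploid
#'   synthetic benchmarks; use 2 for diploid data).
#' @param max_coverage_self Self-alignment depth at or above which an assembly
#'   position is masked as repetitive (default 4).
#' @param proper_alignment_allowance Maximum unaligned read sequence (bp) at
#'   either read end for an alignment to count as proper (default 100).
#' @param min_anchor_length Minimum non-repetitive aligned reference bases for
#'   an alignment to be strongly anchored (default 500).
#' @param best_pile_up_margin Factor by which the best conflicting spanning
#'   edge must outnumber each competitor to be kept (default 3).
#' @param existing_gap_bonus Support multiplier for spanning edges that
#'   coincide with an input intra-scaffold gap (default 6).
#' @param min_spanning_reads Minimum reads on a spanning edge for gap closing,
#'   and minimum spanning alignments for validation (default 3).
#' @param max_indel Maximum absolute difference (bp) between the unaligned
#'   gaps on the two reads for two local alignments to be chainable
#'   (default 1000).
#' @param max_chain_gap Maximum unaligned gap (bp) on either read between two
#'   chainable local alignments (default 10000).
#' @param max_relative_overlap Maximum overlap between chainable alignments,
#'   relative to the shorter alignment (default 0.3).
#' @param bad_fraction Fraction of the worst pile-up quality windows
#'   considered bad when selecting the reference read (default 0.08).
#' @param region_context Validated region extends this many bp up- and
#'   downstream of a closed gap (default 1000).
#' @param weak_coverage_window Window size w (bp) for continuous alignment
#'   coverage during validation (default 500).
#' @param min_coverage_reads Validation coverage threshold; when `NULL` it is
#'   derived as 50% of the haploid read coverage, `0.5 * read_coverage /
#'   ploidy`.
#' @param max_coverage_reads Read-alignment depth above which assembly
#'   positions are masked (\eqn{C_{max}}); when `NULL` it is derived from
#'   `read_coverage` via the Poisson tail (see [compute_cmax()]).
#' @param cmax_tail_prob Poisson tail probability used to derive
#'   `max_coverage_reads` (default 1e-3).
#' @param max_improper_coverage Improper-alignment depth above which positions
#'   are masked; when `NULL` it defaults to `read_coverage / 2`.
#' @param max_err Error-rate ceiling for the built-in aligner (default 0.3,
#'   accommodating two error-prone CLR reads against each other).
#' @param min_anchor_run Minimum exact-match run (bp) defining an insertion
#'   anchor on a flanking contig (default 24).
#' @param allow_single_reads Expert option: close gaps from a single spanning
#'   read by inserting the raw read sequence (default FALSE).
#'
#' @return A list of class `spanweld_config`.
#' @export
pipeline_config <- function(read_coverage = NULL,
                            ploidy = 1L,
                            max_coverage_self = 4L,
                            proper_alignment_allowance = 100L,
                            min_anchor_length = 500L,
                            best_pile_up_margin = 3,
                            existing_gap_bonus = 6,
                            min_spanning_reads = 3L,
                            max_indel = 1000L,
                            max_chain_gap = 10000L,
                            max_relative_overlap = 0.3,
                            bad_fraction = 0.08,
                            region_context = 1000L,
                            weak_coverage_window = 500L,
                            min_coverage_reads = NULL,
                            max_coverage_reads = NULL,
                            cmax_tail_prob = 1e-3,
                            max_improper_coverage = NULL,
                            max_err = 0.3,
                            min_anchor_run = 24L,
                            allow_single_reads = FALSE) {
  cfg <- list(
    read_coverage = read_coverage, ploidy = as.integer(ploidy),
    max_coverage_self = as.integer(max_coverage_self),
    proper_alignment_allowance = as.integer(proper_alignment_allowance),
    min_anchor_length = as.integer(min_anchor_length),
    best_pile_up_margin = best_pile_up_margin,
    existing_gap_bonus = existing_gap_bonus,
    min_spanning_reads = as.integer(min_spanning_reads),
    max_indel = as.integer(max_indel),
    max_chain_gap = as.integer(max_chain_gap),
    max_relative_overlap = max_relative_overlap,
    bad_fraction = bad_fraction,
    region_context = as.integer(region_context),
    weak_coverage_window = as.integer(weak_coverage_window),
    min_coverage_reads = min_coverage_reads,
    max_coverage_reads = max_coverage_reads,
    cmax_tail_prob = cmax_tail_prob,
    max_improper_coverage = max_improper_coverage,
    max_err = max_err,
    min_anchor_run = as.integer(min_anchor_run),
    allow_single_reads = isTRUE(allow_single_reads))
  stopifnot(cfg$max_coverage_self > 0, cfg$proper_alignment_allowance > 0,
            cfg$min_anchor_length > 0, cfg$best_pile_up_margin > 0,
            cfg$existing_gap_bonus > 0, cfg$max_indel > 0,
            cfg$max_chain_gap > 0,
            cfg$max_relative_overlap > 0, cfg$max_relative_overlap <= 1,
            cfg$bad_fraction > 0, cfg$bad_fraction < 1,
            cfg$region_context > 0, cfg$weak_coverage_window > 0)
  class(cfg) <- "spanweld_config"
  cfg
}

#' Derived validation coverage threshold
#'
#' When the user does not give an explicit threshold, the minimum continuous
#' alignment coverage required to validate a closed gap is 50% of the long
#' read coverage expected from a haploid locus: `0.5 * C / ploidy`.
#'
#' @param config A [pipeline_config()].
#' @return Numeric threshold.
#' @export
min_coverage_threshold <- function(config) {
  if (!is.null(config$min_coverage_reads)) return(config$min_coverage_reads)
  if (is.null(config$read_coverage))
    stop("min_coverage_reads must be given, or read_coverage and ploidy ",
         "to derive it")
  0.5 * config$read_coverage / config$ploidy
}
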