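#' Simulate a genome with planted repeats
#'
#' Draws a uniform-base background sequence and plants interspersed repeat
#' families (each family one master sequence copied with per-copy
#' substitution divergence) and tandem arrays at random non-overlapping
#' loci. The planted repeats are the ground-truth repeat annotation.
#'
#' @param length Genome length in bp.
#' @param repeat_spec List with optional elements `interspersed` (data.frame
#'   with `count`, `length`, `divergence` per family) and `tandem`
#'   (data.frame with `unit_len`, `copies`, `count` per array family).
#' @param seed Integer seed; the genome is reproducible given it.
#' @param scaffold_id Name of the single emitted scaffold.
#' @return List with `assembly` (one gap-free scaffold), `repeats`
#'   (ground-truth [mask_track()] in scaffold coordinates) and
#'   `repeat_table` (one row per planted element).
#' @export
simulate_genome <- function(length, repeat_spec = list(), seed = 1L,
                            scaffold_id = "chr1") {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  geno <- sample(bases, length, replace = TRUE)
  occupied <- logical(length)
  placed <- list()
  place_element <- function(el_seq, label) {
    len <- nchar(el_seq)
    for (try in 1:200) {
      pos <- sample.int(length - len, 1L)  # 1-based start
      if (!any(occupied[pos:(pos + len - 1L)])) {
        geno[pos:(pos + len - 1L)] <<- strsplit(el_seq, "")[[1]]
        occupied[pos:(pos + len - 1L)] <<- TRUE
        placed[[length(placed) + 1L]] <<- data.frame(
          label = label, begin = pos - 1L, end = pos - 1L + len,
          stringsAsFactors = FALSE)
        return(TRUE)
      }
    }
    FALSE
  }
  isp <- repeat_spec$interspersed
  if (!is.null(isp)) {
    for (f in seq_len(nrow(isp))) {
      master <- paste(sample(bases, isp$length[f], replace = TRUE),
                      collapse = "")
      for (cp in seq_len(isp$count[f])) {
        copy <- mutate_seq_subs(master, isp$divergence[f])
        place_element(copy, sprintf("interspersed%d.%d", f, cp))
      }
    }
  }
  tnd <- repeat_spec$tandem
  if (!is.null(tnd)) {
    for (f in seq_len(nrow(tnd))) {
      for (cp in seq_len(tnd$count[f])) {
        unit <- paste(sample(bases, tnd$unit_len[f], replace = TRUE),
                      collapse = "")
        place_element(strrep(unit, tnd$copies[f]),
                      sprintf("tandem%d.%d", f, cp))
      }
    }
  }
  rep_table <- if (length(placed)) do.call(rbind, placed) else
    data.frame(label = character(), begin = integer(), end = integer())
  mask <- if (nrow(rep_table))
    mask_track(rep(scaffold_id, nrow(rep_table)), rep_table$begin,
               rep_table$end) else mask_track()
  assembly <- new_assembly(list(scaffold_from_seq(
    scaffold_id, paste(geno, collapse = ""))))
  list(assembly = assembly, repeats = mask, repeat_table = rep_table)
}

mutate_seq_subs <- function(seq, rate) {
  if (rate <= 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(s)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    s[hit] <- vapply(s[hit], function(b)
      sample(setdiff(bases, b), 1L), "")
  }
  paste(s, collapse = "")
}

# CLR-like per-base corruption: indel-dominant error profile.
mutate_seq_clr <- function(seq, error, ins_frac = 0.55, del_frac = 0.25) {
  if (error <= 0) return(seq)
  code <- utf8ToInt(seq)
  n <- length(code)
  u <- runif(n)
  etype <- integer(n)  # 0 none, 1 sub, 2 del, 3 ins(before)
  etype[u < error * (1 - ins_frac - del_frac)] <- 1L
  etype[u >= error * (1 - ins_frac - del_frac) &
          u < error * (1 - ins_frac)] <- 2L
  etype[u >= error * (1 - ins_frac) & u < error] <- 3L
  bases_int <- utf8ToInt("ACGT")
  expand <- rep(1L, n); expand[etype == 3L] <- 2L
  map <- rep(seq_len(n), expand)
  out <- code[map]
  first <- !duplicated(map)
  ins_slot <- first & etype[map] == 3L
  out[ins_slot] <- sample(bases_int, sum(ins_slot), replace = TRUE)
  orig_slot <- !ins_slot
  sub_here <- orig_slot & etype[map] == 1L
  if (any(sub_here)) {
    shift <- sample.int(3L, sum(sub_here), replace = TRUE)
    cur <- match(out[sub_here], bases_int)
    out[sub_here] <- bases_int[((cur - 1L + shift) %% 4L) + 1L]
  }
  del_here <- orig_slot & etype[map] == 2L
  intToUtf8(out[!del_here])
}

#' Simulate CLR-like long reads from a genome
#'
#' Read start positions are uniform over the genome's contigs; lengths come
#' from a long-tailed log-normal distribution with the given mean, truncated
#' at contig ends; each read is corrupted with i.i.d. per-base errors at
#' rate `error`, split 55% insertions / 25% deletions / 20% substitutions
#' (the indel-dominant continuous-long-read profile), and reverse
#' complemented with probability one half. A truth table records every
#' read's source interval and strand.
#'
#' @param genome A `spanweld_assembly` (typically the ground truth).
#' @param coverage Target mean coverage (summed read length over genome
#'   size).
#' @param mean_len Mean read length in bp (default 25000).
#' @param len_param Spread parameter in bp; the length standard deviation is
#'   `len_param / 5` (default 125000, i.e. sd = mean).
#' @param error Per-base error rate (default 0.13).
#' @param seed Integer seed.
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame `read_id`, `scaffold_id`, `begin`, `end`, `strand`).
#' @export
simulate_reads <- function(genome, coverage, mean_len = 25000,
                           len_param = 125000, error = 0.13, seed = 1L) {
  set.seed(seed)
  ct <- contig_table(genome)
  gsize <- sum(ct$length)
  target <- coverage * gsize
  sdlen <- len_param / 5
  sigma2 <- log(1 + (sdlen / mean_len)^2)
  mu <- log(mean_len) - sigma2 / 2
  reads <- character(); truth <- list()
  total <- 0; i <- 0L
  while (total < target) {
    i <- i + 1L
    ci <- sample.int(nrow(ct), 1L, prob = ct$length)
    start <- sample.int(ct$length[ci], 1L) - 1L
    len <- max(200L, round(rlnorm(1, mu, sqrt(sigma2))))
    len <- min(len, ct$length[ci] - start)
    if (len < 200L) next
    src <- substr(ct$seq[ci], start + 1L, start + len)
    strand <- if (runif(1) < 0.5) "+" else "-"
    if (strand == "-") src <- revcomp(src)
    rid <- sprintf("read%06d", i)
    reads[[rid]] <- mutate_seq_clr(src, error)
    truth[[length(truth) + 1L]] <- data.frame(
      read_id = rid, scaffold_id = ct$scaffold_id[ci],
      begin = ct$scaffold_offset[ci] + start,
      end = ct$scaffold_offset[ci] + start + len, strand = strand,
      stringsAsFactors = FALSE)
    total <- total + len
  }
  list(reads = unlist(reads), truth = do.call(rbind, truth))
}

#' Draw a synthetic gap specification over a reference
#'
#' Samples `n` non-overlapping gap intervals with lengths uniform in
#' `len_range`, biased toward repeat loci when a repeat mask is given (each
#' gap is placed adjacent to or overlapping a repeat with probability
#' `repeat_bias`), respecting the exclusion distance between gaps and to
#' contig ends.
#'
#' @param reference A `spanweld_assembly`.
#' @param n Number of gaps.
#' @param len_range Two-element vector of gap lengths in bp.
#' @param repeats Optional [mask_track()] of repeat loci.
#' @param repeat_bias Probability of placing near a repeat (default 0.5).
#' @param exclusion Minimum distance between gaps and to sequence ends
#'   (default 3000).
#' @param seed Integer seed.
#' @return data.frame `scaffold_id`, `begin`, `end`.
#' @export
sample_gap_spec <- function(reference, n, len_range = c(50L, 5000L),
                            repeats = NULL, repeat_bias = 0.5,
                            exclusion = 3000L, seed = 1L) {
  set.seed(seed)
  sc <- reference[[1]]
  gsize <- nchar(scaffold_seq(sc))
  chosen <- list()
  too_close <- function(b, e) {
    if (!length(chosen)) return(FALSE)
    any(vapply(chosen, function(g)
      b < g$end + exclusion && e > g$begin - exclusion, TRUE))
  }
  reps <- if (!is.null(repeats)) repeats[repeats$seq_id == sc$id, ] else NULL
  tries <- 0L
  while (length(chosen) < n && tries < 2000L) {
    tries <- tries + 1L
    len <- sample(seq(len_range[1], len_range[2]), 1L)
    near_repeat <- !is.null(reps) && nrow(reps) && runif(1) < repeat_bias
    if (near_repeat) {
      r <- reps[sample.int(nrow(reps), 1L), ]
      anchor <- sample(seq(max(0L, r$begin - 500L), r$end + 500L), 1L)
      begin <- anchor - len %/% 2L
    } else {
      begin <- sample.int(gsize - len, 1L) - 1L
    }
    begin <- max(exclusion, begin)
    end <- begin + len
    if (end > gsize - exclusion) next
    if (too_close(begin, end)) next
    chosen[[length(chosen) + 1L]] <- list(begin = begin, end = end)
  }
  df <- data.frame(scaffold_id = sc$id,
                   begin = vapply(chosen, `[[`, 0L, "begin"),
                   end = vapply(chosen, `[[`, 0L, "end"))
  df[order(df$begin), , drop = FALSE]
}

#' Build a test assembly by introducing gaps into a reference
#'
#' Replaces true sequence with N-runs of identical length, either at
#' explicitly given positions (`gap_spec`) or at positions lifted over from
#' a fragmented assembly of the same genome (`fragmented`): the 500 bp
#' flanks of each gap in the fragmented assembly are mapped to the
#' reference, requiring a unique placement with at least 80% of flank bases
#' matching; a flank pair mapping adjacently yields an introduced gap. A gap
#' is only introduced when the enclosed length is at least `min_gap` bp and
#' no pre-existing reference gap lies within `exclusion` bp. The reference
#' is first disassembled into its contigs so every introduced gap has known
#' ground truth.
#'
#' @param reference Ground-truth `spanweld_assembly`.
#' @param gap_spec data.frame `scaffold_id`, `begin`, `end`
#'   ([sample_gap_spec()]); mutually exclusive with `fragmented`.
#' @param fragmented A fragmented `spanweld_assembly` of the same genome.
#' @param min_gap Minimum introduced gap size in bp (default 10).
#' @param exclusion Exclusion distance to pre-existing gaps in bp
#'   (default 3000).
#' @param flank Flank length used for lift-over in bp (default 500).
#' @param min_match Minimum fraction of flank bases matching (default 0.8).
#' @return List with `assembly` (test assembly), `truth` (data.frame
#'   `gap_id`, `scaffold_id`, `begin`, `end`, `truth_seq`) and `skipped`
#'   (counts of rejected candidate gaps by reason).
#' @export
make_test_assembly <- function(reference, gap_spec = NULL, fragmented = NULL,
                               min_gap = 10L, exclusion = 3000L,
                               flank = 500L, min_match = 0.8) {
  stopifnot(xor(is.null(gap_spec), is.null(fragmented)))
  # disassemble the reference into contigs: gaps only where truth is known
  ct <- contig_table(reference)
  contig_assembly <- new_assembly(lapply(seq_len(nrow(ct)), function(i)
    scaffold_from_seq(ct$contig_id[i], ct$seq[i])))
  skipped <- c(too_small = 0L, near_gap = 0L, ambiguous = 0L,
               overlapping = 0L)
  if (is.null(gap_spec))
    gap_spec <- liftover_gaps(reference, fragmented, flank, min_match,
                              environment())
  # gap coordinates are in reference scaffold space; transfer to contigs
  rows <- list()
  for (i in seq_len(nrow(gap_spec))) {
    b <- gap_spec$begin[i]; e <- gap_spec$end[i]
    sc_id <- gap_spec$scaffold_id[i]
    if (e - b < min_gap) { skipped["too_small"] <- skipped["too_small"] + 1L; next }
    cc <- ct[ct$scaffold_id == sc_id & ct$scaffold_offset <= b &
               ct$scaffold_offset + ct$length >= e, , drop = FALSE]
    if (!nrow(cc)) { skipped["near_gap"] <- skipped["near_gap"] + 1L; next }
    cc <- cc[1, ]
    cb <- b - cc$scaffold_offset; ce <- e - cc$scaffold_offset
    # pre-existing reference gaps sit at contig boundaries
    if (cb < exclusion && cc$ordinal > 1L ||
        cc$length - ce < exclusion &&
          cc$ordinal < max(ct$ordinal[ct$scaffold_id == sc_id])) {
      skipped["near_gap"] <- skipped["near_gap"] + 1L; next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gap_id = sprintf("gap%03d", length(rows) + 1L),
      contig_id = cc$contig_id, scaffold_id = sc_id,
      begin = cb, end = ce,
      ref_begin = b, ref_end = e,
      truth_seq = substr(cc$seq, cb + 1L, ce), stringsAsFactors = FALSE)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gap_id = character(), contig_id = character(),
               scaffold_id = character(), begin = integer(), end = integer(),
               ref_begin = integer(), ref_end = integer(),
               truth_seq = character())
  # apply the N replacements per contig-scaffold
  test_scaffolds <- lapply(names(contig_assembly), function(cid) {
    seq <- scaffold_seq(contig_assembly[[cid]])
    d <- truth[truth$contig_id == cid, , drop = FALSE]
    if (nrow(d)) {
      for (j in order(-d$begin)) {
        seq <- paste0(substr(seq, 1L, d$begin[j]),
                      strrep("N", d$end[j] - d$begin[j]),
                      substr(seq, d$end[j] + 1L, nchar(seq)))
      }
    }
    scaffold_from_seq(cid, seq)
  })
  list(assembly = new_assembly(test_scaffolds), truth = truth,
       skipped = skipped)
}

# Map gap flanks of a fragmented assembly onto the reference.
liftover_gaps <- function(reference, fragmented, flank, min_match, env) {
  gt <- gap_table(fragmented)
  ref_seqs <- setNames(vapply(reference, scaffold_seq, ""), names(reference))
  place_flank <- function(fseq) {
    hits <- list()
    for (sid in names(ref_seqs)) {
      h <- align_pair(fseq, ref_seqs[[sid]], mode = "local",
                      max_err = 0.25, min_len = as.integer(flank * 0.6),
                      target_id = sid)
      h <- h[h$n_match >= min_match * nchar(fseq), , drop = FALSE]
      if (nrow(h)) hits[[length(hits) + 1L]] <- h
    }
    if (!length(hits)) return(NULL)
    hits <- do.call(rbind, hits)
    if (nrow(hits) > 1) return("ambiguous")
    hits
  }
  rows <- list()
  for (i in seq_len(nrow(gt))) {
    fs <- scaffold_seq(fragmented[[gt$scaffold_id[i]]])
    lf <- substr(fs, gt$begin[i] - flank + 1L, gt$begin[i])
    rf <- substr(fs, gt$end[i] + 1L, gt$end[i] + flank)
    if (nchar(lf) < flank || nchar(rf) < flank) next
    hl <- place_flank(lf); hr <- place_flank(rf)
    if (is.null(hl) || is.null(hr) ||
        identical(hl, "ambiguous") || identical(hr, "ambiguous")) {
      env$skipped["ambiguous"] <- env$skipped["ambiguous"] + 1L
      next
    }
    if (hl$target_id != hr$target_id || hl$strand != hr$strand ||
        hl$strand != "+") {
      env$skipped["ambiguous"] <- env$skipped["ambiguous"] + 1L
      next
    }
    b <- hl$tend; e <- hr$tbeg
    if (e <= b) { env$skipped["overlapping"] <- env$skipped["overlapping"] + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold_id = hl$target_id, begin = b, end = e,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(scaffold_id = character(), begin = integer(),
                      end = integer()))
  do.call(rbind, rows)
}

#' Flag closable gaps from the read truth table
#'
#' A gap is closable if and only if at least `min_reads` simulated reads
#' span the gap plus `flank` bp on either side — the sensitivity ceiling of
#' any gap closer on that read set. Requires simulated reads (known source
#' intervals).
#'
#' @param truth Read truth table from [simulate_reads()] (reference
#'   coordinates).
#' @param gaps Gap truth table from [make_test_assembly()].
#' @param min_reads Minimum spanning reads (default 3).
#' @param flank Required flank span in bp (default 500).
#' @return The gap table with a logical `closable` column and the spanning
#'   read count `n_spanning`.
#' @export
find_closable_gaps <- function(truth, gaps, min_reads = 3L, flank = 500L) {
  gaps$n_spanning <- vapply(seq_len(nrow(gaps)), function(i) {
    d <- truth[truth$scaffold_id == gaps$scaffold_id[i], , drop = FALSE]
    sum(d$begin <= gaps$ref_begin[i] - flank &
          d$end >= gaps$ref_end[i] + flank)
  }, 0L)
  gaps$closable <- gaps$n_spanning >= min_reads
  gaps
}
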