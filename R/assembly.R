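#' @title Assembly data model
#'
#' @description An assembly is a named list of scaffolds; each scaffold is an
#' ordered list of components: contigs (gap-free ACGT sequence) and gaps
#' (N-runs of known length). Contigs are named `<scaffold>.<ordinal>`. All
#' coordinates in the package are 0-based, half-open; AGP output uses the
#' standard 1-based inclusive convention.
#'
#' @name assembly-model
NULL

new_scaffold <- function(id, components) {
  structure(list(id = id, components = components),
            class = "spanweld_scaffold")
}

new_assembly <- function(scaffolds) {
  names(scaffolds) <- vapply(scaffolds, `[[`, "", "id")
  structure(scaffolds, class = "spanweld_assembly")
}

#' Build a scaffold from a raw sequence string
#'
#' Splits a sequence over `{A,C,G,T,N}` into contig and gap components.
#' Terminal N-runs are preserved (they round-trip to FASTA) but flagged so
#' that they are never treated as closable gaps.
#'
#' @param id Scaffold identifier.
#' @param seq Character scalar over ACGTN (lowercase tolerated).
#' @return A `spanweld_scaffold`.
#' @export
scaffold_from_seq <- function(id, seq) {
  seq <- toupper(seq)
  seq <- gsub("[^ACGTN]", "N", seq)
  runs <- gregexpr("N+", seq)[[1]]
  comps <- list()
  ord <- 0L
  pos <- 1L
  n <- nchar(seq)
  add_contig <- function(comps, from, to) {
    if (to < from) return(comps)
    ord <<- ord + 1L
    c(comps, list(list(type = "contig", id = paste0(id, ".", ord),
                       seq = substr(seq, from, to))))
  }
  if (runs[1] == -1L) {
    comps <- add_contig(comps, 1L, n)
  } else {
    lens <- attr(runs, "match.length")
    for (i in seq_along(runs)) {
      comps <- add_contig(comps, pos, runs[i] - 1L)
      terminal <- runs[i] == 1L || runs[i] + lens[i] - 1L == n
      comps <- c(comps, list(list(type = "gap", length = lens[i],
                                  terminal = terminal)))
      pos <- runs[i] + lens[i]
    }
    comps <- add_contig(comps, pos, n)
  }
  new_scaffold(id, comps)
}

#' @export
print.spanweld_scaffold <- function(x, ...) {
  k <- vapply(x$components, `[[`, "", "type")
  cat("<scaffold ", x$id, ": ", sum(k == "contig"), " contigs, ",
      sum(k == "gap"), " gaps, ", nchar(scaffold_seq(x)), " bp>\n", sep = "")
  invisible(x)
}

#' @export
print.spanweld_assembly <- function(x, ...) {
  ct <- contig_table(x)
  cat("<assembly: ", length(x), " scaffolds, ", nrow(ct), " contigs, ",
      sum(ct$length), " contig bp>\n", sep = "")
  invisible(x)
}

#' Full sequence of a scaffold (contigs plus N-runs)
#' @param scaffold A `spanweld_scaffold`.
#' @return Character scalar.
#' @export
scaffold_seq <- function(scaffold) {
  paste(vapply(scaffold$components, function(comp) {
    if (comp$type == "gap") strrep("N", comp$length) else comp$seq
  }, ""), collapse = "")
}

#' Table of all contigs in an assembly
#'
#' @param assembly A `spanweld_assembly`.
#' @return `data.frame` with columns `contig_id`, `scaffold_id`, `ordinal`,
#'   `scaffold_offset` (0-based), `length`, `seq`.
#' @export
contig_table <- function(assembly) {
  rows <- list()
  for (sc in assembly) {
    off <- 0L
    ord <- 0L
    for (comp in sc$components) {
      if (comp$type == "gap") {
        off <- off + comp$length
      } else {
        ord <- ord + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = comp$id, scaffold_id = sc$id, ordinal = ord,
          scaffold_offset = off, length = nchar(comp$seq),
          seq = comp$seq, stringsAsFactors = FALSE)
        off <- off + nchar(comp$seq)
      }
    }
  }
  if (!length(rows))
    return(data.frame(contig_id = character(), scaffold_id = character(),
                      ordinal = integer(), scaffold_offset = integer(),
                      length = integer(), seq = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Named character vector of contig sequences
#' @param assembly A `spanweld_assembly`.
#' @return Named character vector keyed by contig id.
#' @export
contig_seqs <- function(assembly) {
  ct <- contig_table(assembly)
  setNames(ct$seq, ct$contig_id)
}

#' Intra-scaffold gap table
#'
#' Lists gaps between adjacent contigs (terminal N-runs excluded): these are
#' the closable candidates of the default mode.
#'
#' @param assembly A `spanweld_assembly`.
#' @return `data.frame` with `scaffold_id`, `left_contig`, `right_contig`,
#'   `gap_length`, and the gap's 0-based scaffold interval.
#' @export
gap_table <- function(assembly) {
  rows <- list()
  for (sc in assembly) {
    off <- 0L
    last_contig <- NULL
    pending_gap <- NULL
    for (comp in sc$components) {
      if (comp$type == "gap") {
        if (!is.null(last_contig) && !comp$terminal)
          pending_gap <- list(begin = off, length = comp$length)
        off <- off + comp$length
      } else {
        if (!is.null(pending_gap)) {
          rows[[length(rows) + 1L]] <- data.frame(
            scaffold_id = sc$id, left_contig = last_contig$id,
            right_contig = comp$id, gap_length = pending_gap$length,
            begin = pending_gap$begin,
            end = pending_gap$begin + pending_gap$length,
            stringsAsFactors = FALSE)
        }
        pending_gap <- NULL
        last_contig <- comp
        off <- off + nchar(comp$seq)
      }
    }
  }
  if (!length(rows))
    return(data.frame(scaffold_id = character(), left_contig = character(),
                      right_contig = character(), gap_length = integer(),
                      begin = integer(), end = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an assembly from FASTA
#'
#' N-runs become gap components; IUPAC ambiguity codes other than ACGTN are
#' uppercased and treated as N; soft-masking (lowercase) is ignored.
#'
#' @param path FASTA file.
#' @return A `spanweld_assembly`.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate scaffold ids in ", path)
  scaffolds <- lapply(seq_along(seqs), function(i)
    scaffold_from_seq(ids[i], as.character(seqs[[i]])))
  new_assembly(scaffolds)
}

#' Read long reads from FASTA or FASTQ
#' @param path FASTA or FASTQ file (extension .fq/.fastq selects FASTQ).
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  setNames(toupper(as.character(seqs)), sub("\\s.*$", "", names(seqs)))
}

#' Write an assembly (or named sequences) to FASTA
#' @param x A `spanweld_assembly` or a named character vector of sequences.
#' @param path Output file.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  seqs <- if (inherits(x, "spanweld_assembly")) {
    setNames(vapply(x, scaffold_seq, ""), names(x))
  } else x
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write assembly structure as AGP v2.1
#'
#' One `W` row per contig and one `N` row (gap type "scaffold") per gap,
#' 1-based inclusive coordinates.
#'
#' @param assembly A `spanweld_assembly`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_agp <- function(assembly, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (sc in assembly) {
    pos <- 0L
    part <- 0L
    for (comp in sc$components) {
      part <- part + 1L
      if (comp$type == "gap") {
        writeLines(paste(sc$id, pos + 1L, pos + comp$length, part, "N",
                         comp$length, "scaffold", "yes", "na",
                         sep = "\t"), con)
        pos <- pos + comp$length
      } else {
        len <- nchar(comp$seq)
        writeLines(paste(sc$id, pos + 1L, pos + len, part, "W",
                         comp$id, 1L, len, "+", sep = "\t"), con)
        pos <- pos + len
      }
    }
  }
  invisible(path)
}

#' Assemble scaffolds from contig sequences and explicit gap structure
#'
#' Convenience constructor used by the benchmark builders: `parts` is a list
#' with one element per scaffold, each an alternating list of contig sequence
#' strings and integer gap lengths.
#'
#' @param parts Named list; see details.
#' @return A `spanweld_assembly`.
#' @export
assembly_from_parts <- function(parts) {
  scaffolds <- lapply(names(parts), function(id) {
    seq <- paste(vapply(parts[[id]], function(p) {
      if (is.numeric(p)) strrep("N", p) else p
    }, ""), collapse = "")
    scaffold_from_seq(id, seq)
  })
  new_assembly(scaffolds)
}
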