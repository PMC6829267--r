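# Promoter extraction and degenerate motif scanning. The promoter window is
# the 1000 bp immediately upstream of the start codon on the gene's strand
# (measured from the CDS start; transcription start sites are not used).
# Degenerate matching is IUPAC-consensus matching: a pattern position with
# code R matches A or G in the promoter; N in the promoter matches nothing.

#' Extract upstream promoter windows
#'
#' For a plus-strand gene the promoter is the `length` genomic bases ending
#' just before the CDS start, reported as-is; for a minus-strand gene it is
#' the `length` bases following the CDS end, reverse-complemented so the
#' reported sequence is gene-strand oriented and ends just before the start
#' codon. Windows are clipped at contig edges and flagged `truncated`;
#' zero-length windows are dropped with a warning.
#'
#' @param genes Gene-model data frame from [read_gff3()].
#' @param genome Named character vector of contig sequences.
#' @param length Promoter length in bp (default 1000).
#' @return Data frame: `gene_id`, `sequence`, `window_start`, `window_end`
#'   (0-based half-open genome coordinates), `truncated`.
#' @export
extract_promoters <- function(genes, genome, length = 1000L) {
  stopifnot(length >= 1L)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    contig <- if (g$contig_id %in% names(genome)) genome[[g$contig_id]] else NULL
    if (is.null(contig)) {
      stop("contig '", g$contig_id, "' missing for gene '", g$gene_id, "'",
           call. = FALSE)
    }
    clen <- nchar(contig)
    if (g$strand == "+") {
      from <- max(1L, g$cds_start - length)
      to <- g$cds_start - 1L
      if (to < from) {
        warning("gene '", g$gene_id, "' starts at the contig edge; ",
                "empty promoter excluded", call. = FALSE)
        return(NULL)
      }
      seq <- substr(contig, from, to)
    } else {
      from <- g$cds_end + 1L
      to <- min(clen, g$cds_end + length)
      if (to < from) {
        warning("gene '", g$gene_id, "' ends at the contig edge; ",
                "empty promoter excluded", call. = FALSE)
        return(NULL)
      }
      seq <- reverse_complement(substr(contig, from, to))
    }
    data.frame(gene_id = g$gene_id, sequence = seq,
               window_start = from - 1L, window_end = to,
               truncated = (to - from + 1L) < length,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no non-empty promoter windows could be extracted", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

validate_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- !chars %in% names(IUPAC_CODES)
  if (any(bad)) {
    stop("invalid IUPAC code '", chars[bad][1], "' in pattern", call. = FALSE)
  }
  if (all(chars == "N")) stop("N-only patterns are not allowed", call. = FALSE)
  if (length(chars) < 4L) stop("motif patterns must have length >= 4",
                               call. = FALSE)
  toupper(pattern)
}

#' Scan one sequence for a degenerate motif
#'
#' Reports every (possibly overlapping) window of `sequence` matching the
#' IUPAC pattern on the given strand(s). Minus-strand hits are windows
#' matching the reverse complement of the pattern, reported at their
#' position on the scanned sequence with `strand = "-"`. `N` in the
#' scanned sequence matches nothing.
#'
#' @param sequence A nucleotide string (e.g. one promoter).
#' @param pattern IUPAC degenerate pattern (length >= 4, not all N).
#' @param name Motif name carried into the result.
#' @param both_strands Scan the reverse complement of the pattern too.
#' @return Data frame `motif`, `start` (1-based), `strand`, sorted by
#'   start then strand.
#' @export
#' @examples
#' scan_motif("TTACCGACTT", "RCCGAC", name = "CRT/DRE")
scan_motif <- function(sequence, pattern, name = pattern,
                       both_strands = TRUE) {
  pattern <- validate_iupac(pattern)
  subj <- Biostrings::DNAString(toupper(sequence))
  hit_starts <- function(pat) {
    if (nchar(pat) > nchar(sequence)) return(integer(0))
    Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(pat), subj, fixed = "subject"))
  }
  out <- data.frame(motif = character(0), start = integer(0),
                    strand = character(0))
  fwd <- hit_starts(pattern)
  if (length(fwd) > 0L) {
    out <- rbind(out, data.frame(motif = name, start = fwd, strand = "+"))
  }
  if (both_strands) {
    rev <- hit_starts(reverse_complement(pattern))
    if (length(rev) > 0L) {
      out <- rbind(out, data.frame(motif = name, start = rev, strand = "-"))
    }
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of promoters for one motif
#'
#' @param promoters Promoter data frame from [extract_promoters()] (or any
#'   data frame with `gene_id` and `sequence` columns).
#' @inheritParams scan_motif
#' @return Data frame `gene_id`, `motif`, `start`, `strand`.
#' @export
scan_promoters <- function(promoters, pattern, name = pattern,
                           both_strands = TRUE) {
  rows <- lapply(seq_len(nrow(promoters)), function(i) {
    h <- scan_motif(promoters$sequence[i], pattern, name, both_strands)
    if (nrow(h) == 0L) return(NULL)
    cbind(gene_id = promoters$gene_id[i], h)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), motif = character(0),
                      start = integer(0), strand = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Per-gene motif hit counts
#'
#' @inheritParams scan_promoters
#' @return Named integer vector of hit counts, one per promoter row (zeros
#'   retained).
#' @export
count_motif_hits <- function(promoters, pattern, both_strands = TRUE) {
  hits <- scan_promoters(promoters, pattern, both_strands = both_strands)
  counts <- table(factor(hits$gene_id, levels = promoters$gene_id))
  stats::setNames(as.integer(counts), promoters$gene_id)
}

#' Scan promoters against a cis-element catalogue
#'
#' Counts hits of every catalogue element in every promoter, producing the
#' gene-by-element grid familiar from promoter cis-element figures. Zero
#' cells are retained.
#'
#' @inheritParams scan_promoters
#' @param catalogue Data frame with columns `name` and `iupac`; defaults to
#'   the built-in [default_cis_elements()] table.
#' @return Integer matrix, genes as rows and elements as columns.
#' @export
scan_catalogue <- function(promoters, catalogue = default_cis_elements(),
                           both_strands = TRUE) {
  if (nrow(catalogue) == 0L) {
    return(matrix(integer(0), nrow = nrow(promoters), ncol = 0L,
                  dimnames = list(promoters$gene_id, NULL)))
  }
  if (anyDuplicated(catalogue$name)) {
    stop("duplicate catalogue element name '",
         catalogue$name[duplicated(catalogue$name)][1], "'", call. = FALSE)
  }
  grid <- vapply(seq_len(nrow(catalogue)), function(k) {
    count_motif_hits(promoters, catalogue$iupac[k], both_strands)
  }, integer(nrow(promoters)))
  if (nrow(promoters) == 1L) grid <- matrix(grid, nrow = 1L)
  dimnames(grid) <- list(promoters$gene_id, catalogue$name)
  grid
}
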