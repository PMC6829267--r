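# Candidate CBF identification: a protein-level local-alignment homology
# screen combined with verification of the two CBF signature sequences that
# flank the AP2 DNA-binding domain (PKK/RPAGRxKFxETRHP upstream, DSAWR
# downstream). Alignment goes through Biostrings; signature matching and the
# acceptance rule are implemented here.

#' Build a degenerate protein signature pattern
#'
#' Patterns are written with one element per position: a plain residue
#' letter, a bracketed residue class such as `[KR]`, or `x` for a wildcard
#' that never counts as a mismatch.
#'
#' @param name Pattern name.
#' @param pattern Pattern string, e.g. `"PK[KR]PAGRxKFxETRHP"`.
#' @param max_mismatches Number of non-wildcard mismatches tolerated.
#' @return An object of class `signature_pattern`.
#' @export
#' @examples
#' signature_pattern("S2", "DSAWR", max_mismatches = 0)
signature_pattern <- function(name, pattern, max_mismatches = 0L) {
  stopifnot(is.character(pattern), length(pattern) == 1L, max_mismatches >= 0L)
  elements <- list()
  chars <- strsplit(pattern, "")[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("unterminated residue class in pattern",
                                  call. = FALSE)
      cls <- chars[(i + 1L):(j - 1L)]
      if (!all(cls %in% AMINO_ACIDS)) stop("invalid residue in class",
                                           call. = FALSE)
      elements[[length(elements) + 1L]] <- cls
      i <- j + 1L
    } else if (ch %in% c("x", "X", ".")) {
      elements[[length(elements) + 1L]] <- AMINO_ACIDS
      i <- i + 1L
    } else if (ch %in% AMINO_ACIDS) {
      elements[[length(elements) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("invalid character '", ch, "' in signature pattern", call. = FALSE)
    }
  }
  if (length(elements) < 3L) stop("signature patterns must have length >= 3",
                                  call. = FALSE)
  structure(list(name = name, elements = elements,
                 max_mismatches = as.integer(max_mismatches)),
            class = "signature_pattern")
}

#' @rdname signature_pattern
#' @export
cbf_signature_s1 <- function(max_mismatches = 2L) {
  signature_pattern("S1", "PK[KR]PAGRxKFxETRHP", max_mismatches)
}

#' @rdname signature_pattern
#' @export
cbf_signature_s2 <- function(max_mismatches = 0L) {
  signature_pattern("S2", "DSAWR", max_mismatches)
}

#' Match a signature pattern against a protein
#'
#' Slides the pattern along the protein and reports every window whose
#' number of mismatches at non-wildcard positions is at most the pattern's
#' `max_mismatches`.
#'
#' @param protein A protein sequence string.
#' @param pattern A [signature_pattern()].
#' @return Data frame with columns `start` (1-based) and `mismatches`,
#'   sorted by start; zero rows when there is no hit.
#' @export
match_signature <- function(protein, pattern) {
  stopifnot(inherits(pattern, "signature_pattern"))
  res <- strsplit(toupper(protein), "")[[1]]
  k <- length(pattern$elements)
  n <- length(res)
  empty <- data.frame(start = integer(0), mismatches = integer(0))
  if (n < k) return(empty)
  # per-position indicator of "residue allowed here", as a k x n logical
  allowed <- vapply(pattern$elements, function(cls) res %in% cls,
                    logical(n))
  if (n == 1L) allowed <- matrix(allowed, nrow = 1L)
  starts <- seq_len(n - k + 1L)
  mm <- vapply(starts, function(s) {
    sum(!allowed[cbind(s + seq_len(k) - 1L, seq_len(k))])
  }, integer(1))
  keep <- mm <= pattern$max_mismatches
  data.frame(start = starts[keep], mismatches = mm[keep])
}

#' Local (Smith-Waterman) protein alignment score
#'
#' Affine-gap local alignment via [Biostrings::pairwiseAlignment()]. A gap
#' of length L costs `gap_open + L * gap_extend`.
#'
#' @param query,subject Protein sequence strings.
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @param matrix Substitution matrix name (default BLOSUM62).
#' @return List with `score` and the aligned `query`/`subject` substrings.
#' @export
sw_align <- function(query, subject, gap_open = 11, gap_extend = 1,
                     matrix = "BLOSUM62") {
  stopifnot(nchar(query) > 0L, nchar(subject) > 0L,
            gap_open >= gap_extend, gap_extend > 0)
  validate_alphabet(c(q = toupper(query), s = toupper(subject)),
                    AMINO_ACIDS, "protein")
  submat <- get_submatrix(matrix)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(query)), Biostrings::AAString(toupper(subject)),
    type = "local", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(al)
  if (sc <= 0) {
    return(list(score = 0, query = "", subject = ""))
  }
  list(score = sc,
       query = as.character(Biostrings::alignedPattern(al)),
       subject = as.character(Biostrings::alignedSubject(al)))
}

get_submatrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Self-score of a protein under a substitution matrix
#'
#' The score of aligning a sequence to itself without gaps; used to set the
#' relative homology threshold of the family screen.
#'
#' @inheritParams sw_align
#' @param protein Protein sequence string.
#' @return Numeric score.
#' @export
self_score <- function(protein, matrix = "BLOSUM62") {
  submat <- get_submatrix(matrix)
  res <- strsplit(toupper(protein), "")[[1]]
  sum(submat[cbind(res, res)])
}

#' Verify one candidate CBF protein
#'
#' A candidate is accepted when its homology score reaches the threshold
#' and both signature sequences occur in order (S1 before S2) with a
#' separation, measured from the end of S1 to the start of S2, inside the
#' configured window -- the interval in which the AP2 DNA-binding domain
#' sits.
#'
#' @param protein Protein sequence string.
#' @param sw_score Homology score of this protein against the query set.
#' @param min_score Minimum acceptable `sw_score`.
#' @param s1,s2 The two [signature_pattern()]s.
#' @param sep_window Length-2 numeric, allowed separation in residues.
#' @param protein_id Optional id carried into the result.
#' @return One-row data frame: `protein_id`, `sw_score`, `s1_start`,
#'   `s2_start` (1-based; NA when absent), `separation`, `accepted`.
#' @export
verify_candidate <- function(protein, sw_score, min_score,
                             s1 = cbf_signature_s1(), s2 = cbf_signature_s2(),
                             sep_window = c(40, 120), protein_id = NA_character_) {
  h1 <- match_signature(protein, s1)
  h2 <- match_signature(protein, s2)
  s1_start <- NA_integer_; s2_start <- NA_integer_; separation <- NA_integer_
  ok <- FALSE
  if (nrow(h1) > 0L && nrow(h2) > 0L) {
    # best-supported (fewest-mismatch, then leftmost) S1; first S2 after it
    h1 <- h1[order(h1$mismatches, h1$start), , drop = FALSE]
    for (i in seq_len(nrow(h1))) {
      s1_end <- h1$start[i] + length(s1$elements) - 1L
      after <- h2[h2$start > s1_end, , drop = FALSE]
      if (nrow(after) == 0L) next
      sep <- after$start - s1_end - 1L
      j <- which(sep >= sep_window[1] & sep <= sep_window[2])
      if (length(j) > 0L) {
        s1_start <- h1$start[i]; s2_start <- after$start[j[1]]
        separation <- sep[j[1]]; ok <- TRUE
        break
      }
    }
    if (!ok) {  # record the leftmost in-order pair even if out of window
      s1_start <- h1$start[1]
      after <- h2[h2$start > s1_start + length(s1$elements) - 1L, , drop = FALSE]
      if (nrow(after) > 0L) {
        s2_start <- after$start[1]
        separation <- s2_start - (s1_start + length(s1$elements) - 1L) - 1L
      }
    }
  }
  data.frame(protein_id = protein_id, sw_score = sw_score,
             s1_start = s1_start, s2_start = s2_start,
             separation = separation,
             accepted = ok && sw_score >= min_score)
}

#' Screen a proteome for CBF-family candidates
#'
#' Every subject protein is scored against each query by local alignment;
#' the best score is compared to `min_score_frac` times the query
#' self-score, and the two signature sequences are verified in order with
#' their separation inside `sep_window`.
#'
#' @param queries Named character vector of seed CBF proteins.
#' @param subjects Named character vector of proteins to screen.
#' @param min_score_frac Homology threshold as a fraction of the best
#'   query's self-score.
#' @param s1,s2 Signature patterns, see [signature_pattern()].
#' @param sep_window Allowed S1-to-S2 separation (residues).
#' @param gap_open,gap_extend,matrix Alignment parameters, see [sw_align()].
#' @return Data frame with one row per subject in input order, columns as
#'   in [verify_candidate()].
#' @export
identify_family <- function(queries, subjects, min_score_frac = 0.4,
                            s1 = cbf_signature_s1(), s2 = cbf_signature_s2(),
                            sep_window = c(40, 120),
                            gap_open = 11, gap_extend = 1, matrix = "BLOSUM62") {
  stopifnot(length(queries) > 0L, length(subjects) > 0L,
            min_score_frac > 0, min_score_frac <= 1)
  rows <- lapply(seq_along(subjects), function(i) {
    scores <- vapply(seq_along(queries), function(q) {
      thr <- min_score_frac * self_score(queries[[q]], matrix)
      sw <- sw_align(queries[[q]], subjects[[i]], gap_open, gap_extend, matrix)
      c(sw$score, thr)
    }, numeric(2))
    best <- which.max(scores[1, ])
    verify_candidate(subjects[[i]], sw_score = scores[1, best],
                     min_score = scores[2, best], s1 = s1, s2 = s2,
                     sep_window = sep_window,
                     protein_id = names(subjects)[i] %||% as.character(i))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Six-frame translations of a nucleotide sequence
#'
#' Helper for screening genomic (nucleotide) input: translates all six
#' reading frames permissively and, per frame, returns the longest open
#' reading frame between stops.
#'
#' @param seq Nucleotide sequence string.
#' @return Named character vector of six longest-ORF translations
#'   (`F1..F3`, `R1..R3`).
#' @export
six_frame_orfs <- function(seq) {
  seq <- toupper(seq)
  frames <- c(lapply(0:2, function(o) substr(seq, 1L + o, nchar(seq))),
              lapply(0:2, function(o) {
                rc <- reverse_complement(seq)
                substr(rc, 1L + o, nchar(rc))
              }))
  names(frames) <- c("F1", "F2", "F3", "R1", "R2", "R3")
  vapply(frames, function(f) {
    f <- substr(f, 1L, nchar(f) - nchar(f) %% 3L)
    if (nchar(f) < 3L) return("")
    aa <- suppressWarnings(
      as.character(Biostrings::translate(Biostrings::DNAString(f),
                                         if.fuzzy.codon = "X")))
    parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
    if (length(parts) == 0L) "" else parts[which.max(nchar(parts))]
  }, character(1))
}
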