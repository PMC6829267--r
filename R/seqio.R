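# Sequence IO and primitives. Parsing is delegated to Biostrings/rtracklayer;
# the validation contracts (alphabets, duplicate ids, malformed gene models)
# are enforced here so downstream modules can assume clean input.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

validate_alphabet <- function(seqs, alphabet, what) {
  pat <- sprintf("[^%s]", paste(alphabet, collapse = ""))
  bad <- grepl(pat, seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- regmatches(seqs[i], regexpr(pat, seqs[i]))
    stop(sprintf("record '%s' contains non-%s character '%s'",
                 names(seqs)[i] %||% i, what, ch), call. = FALSE)
  }
  invisible(seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file into a named character vector.
#' The id of each record is the header token before the first whitespace.
#' Lowercase (softmasked) letters are normalized to uppercase.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` (letters A, C, G, T, N) or `"protein"` (the 20
#'   standard residues, `*` permitted as a stop).
#' @return Named character vector of sequences, in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 descr", "ACGT", "ACGT"), f)
#' read_fasta(f)
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id '", ids[duplicated(ids)][1], "' in ", path,
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  ab <- if (alphabet == "dna") DNA_ALPHABET else c(AMINO_ACIDS, "*")
  validate_alphabet(seqs, ab, alphabet)
  seqs
}

#' Write a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  con <- file(path, open = "wb")  # LF line endings on every platform
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con, sep = "\n")
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses a GFF3 file and groups CDS features by their parent gene
#' (resolving one level of mRNA parentage where present). Coordinates are
#' 1-based inclusive, as on disk.
#'
#' @param path Path to a GFF3 file.
#' @return A data frame with one row per gene: `gene_id`, `contig_id`,
#'   `strand`, `cds_start`, `cds_end` (1-based inclusive extremes over all
#'   segments) and a list column `cds_segments` of two-column matrices of
#'   segment starts/ends sorted in genome order.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gff <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")))
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("no CDS features in ", path, call. = FALSE)
  parent_of <- function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p)[1]
  }
  cds$parent <- vapply(cds$Parent, parent_of, character(1))
  if (anyNA(cds$parent)) {
    stop("CDS feature without Parent attribute at ", path, " line for ",
         cds$seqid[is.na(cds$parent)][1], call. = FALSE)
  }
  # resolve mRNA -> gene one level where the parent is itself a feature
  id2parent <- stats::setNames(
    vapply(gff$Parent, parent_of, character(1)),
    vapply(gff$ID, function(x) as.character(x)[1] %||% NA_character_,
           character(1)))
  up <- id2parent[cds$parent]
  cds$gene <- ifelse(!is.na(up), up, cds$parent)
  if (any(cds$start > cds$end)) {
    bad <- cds[cds$start > cds$end, ][1, ]
    stop(sprintf("CDS with start > end (%d > %d) for gene '%s'",
                 bad$start, bad$end, bad$gene), call. = FALSE)
  }
  if (any(!cds$strand %in% c("+", "-"))) {
    stop("CDS with unknown strand for gene '",
         cds$gene[!cds$strand %in% c("+", "-")][1], "'", call. = FALSE)
  }
  out <- lapply(split(cds, cds$gene), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    if (length(unique(g$seqid)) != 1L || length(unique(g$strand)) != 1L) {
      stop("CDS segments of gene '", g$gene[1],
           "' span multiple contigs or strands", call. = FALSE)
    }
    if (nrow(g) > 1L && any(g$start[-1] <= g$end[-nrow(g)])) {
      stop("overlapping CDS segments for gene '", g$gene[1], "'",
           call. = FALSE)
    }
    data.frame(gene_id = g$gene[1], contig_id = as.character(g$seqid[1]),
               strand = as.character(g$strand[1]),
               cds_start = min(g$start), cds_end = max(g$end),
               cds_segments = I(list(cbind(start = g$start, end = g$end))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$contig_id, out$cds_start), , drop = FALSE]
}

#' Write gene models to a GFF3 file
#'
#' Emits one `gene` line and one `CDS` line per segment for each gene
#' model, with `ID`/`Parent` attributes and LF line endings. Coordinates
#' are written 1-based inclusive.
#'
#' @param genes Gene-model data frame as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(paste(g$contig_id, "cbfsurvey", "gene", g$cds_start,
                     g$cds_end, ".", g$strand, ".",
                     paste0("ID=", g$gene_id), sep = "\t"), con, sep = "\n")
    segs <- g$cds_segments[[1]]
    for (s in seq_len(nrow(segs))) {
      writeLines(paste(g$contig_id, "cbfsurvey", "CDS", segs[s, "start"],
                       segs[s, "end"], ".", g$strand, "0",
                       paste0("ID=", g$gene_id, ".cds", s, ";Parent=",
                              g$gene_id), sep = "\t"), con, sep = "\n")
    }
  }
  invisible(path)
}

#' Reverse complement of a nucleotide sequence
#'
#' Accepts any IUPAC degenerate code (so motif patterns can be
#' strand-flipped too); `N` maps to `N`.
#'
#' @param seq A single nucleotide string.
#' @return The reverse complement as a character string.
#' @export
#' @examples
#' reverse_complement("ACCGAC")
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl(sprintf("[^%s]", paste(names(IUPAC_CODES), collapse = "")),
            toupper(seq))) {
    stop("non-nucleotide character in sequence", call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Translate a coding sequence
#'
#' Translates a CDS under the standard genetic code. A single terminal stop
#' is excluded from the returned protein. An internal stop is an error
#' unless `permissive = TRUE`, in which case the translation is truncated
#' at the first stop with a warning.
#'
#' @param cds A nucleotide string whose length is divisible by 3.
#' @param permissive Truncate at internal stops instead of erroring.
#' @return The protein sequence as a character string (stop excluded).
#' @export
#' @examples
#' translate_cds("ATGGGTTAA")
translate_cds <- function(cds, permissive = FALSE) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not divisible by 3", call. = FALSE)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  n <- nchar(aa)
  if (substr(aa, n, n) == "*") aa <- substr(aa, 1L, n - 1L)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    if (!permissive) {
      stop("internal stop codon at residue ", stop_at, call. = FALSE)
    }
    warning("internal stop codon at residue ", stop_at,
            "; translation truncated", call. = FALSE)
    aa <- substr(aa, 1L, stop_at - 1L)
  }
  aa
}

#' Spliced coding sequence of a gene model
#'
#' Concatenates the CDS segments of a gene model in 5'-to-3' transcript
#' order (reverse-complementing minus-strand genes).
#'
#' @param gene One row of the data frame returned by [read_gff3()].
#' @param genome Named character vector of contig sequences.
#' @return The spliced CDS as a character string.
#' @export
spliced_cds <- function(gene, genome) {
  if (!gene$contig_id %in% names(genome)) {
    stop("contig '", gene$contig_id, "' not in genome", call. = FALSE)
  }
  contig <- genome[[gene$contig_id]]
  segs <- gene$cds_segments[[1]]
  parts <- substring(contig, segs[, "start"], segs[, "end"])
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") s <- reverse_complement(s)
  s
}
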