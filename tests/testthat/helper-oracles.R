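# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
rand_protein <- function(n) paste(sample(AAS, n, TRUE), collapse = "")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# full affine-gap local-alignment DP (Gotoh); a gap of length L costs
# open + L * extend, matching the package's alignment convention
sw_score_oracle <- function(a, b, open = 11, ext = 1, S = blosum62) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      M[i, j] <- max(0, S[a[i - 1], b[j - 1]] +
                        max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]))
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

iupac_regex <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                 S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
                 B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
                 N = "[ACGT]")

# overlapping degenerate-motif hits by regex expansion; N in the scanned
# sequence matches nothing because the classes never contain N
motif_hits_oracle <- function(seq, pattern, both_strands = TRUE) {
  expand <- function(p) {
    paste(iupac_regex[strsplit(p, "")[[1]]], collapse = "")
  }
  find <- function(p) {
    m <- gregexpr(paste0("(?=", expand(p), ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
              N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  fwd <- find(pattern)
  out <- data.frame(start = fwd, strand = rep("+", length(fwd)))
  if (both_strands) {
    rev <- find(revcomp(pattern))
    out <- rbind(out, data.frame(start = rev,
                                 strand = rep("-", length(rev))))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# naive character-class matcher for signature patterns with mismatches
signature_hits_oracle <- function(protein, classes, max_mm) {
  res <- strsplit(protein, "")[[1]]
  k <- length(classes)
  hits <- integer(0)
  if (length(res) < k) return(hits)
  for (s in seq_len(length(res) - k + 1)) {
    mm <- 0
    for (p in seq_len(k)) {
      if (!res[s + p - 1] %in% classes[[p]]) mm <- mm + 1
    }
    if (mm <= max_mm) hits <- c(hits, s)
  }
  hits
}

# random unrooted tree with strictly positive internal branches and its
# additive (path-length) distance matrix
random_additive_case <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
  list(tree = tr, d = cbfsurvey::path_length_matrix(tr))
}
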