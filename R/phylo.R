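# Distance-based phylogeny: pairwise-alignment p-distances, a deterministic
# neighbor-joining implementation (Saitou-Nei agglomeration with the
# Studier-Keppler Q criterion, lowest-index tie-breaking and clamping of
# negative branch estimates), and bootstrap support by joint resampling of
# pairwise-alignment columns. Trees are ape "phylo" objects throughout.

# Per-pair column states: FALSE = match, TRUE = mismatch, NA = gap column
# (excluded from distances). For aligned input the sequences are compared
# site by site; otherwise each pair is globally aligned (Needleman-Wunsch,
# affine gaps).
pairwise_columns <- function(seqs, aligned = FALSE, gap_open = 11,
                             gap_extend = 1, matrix = "BLOSUM62",
                             type = c("protein", "dna")) {
  type <- match.arg(type)
  n <- length(seqs)
  if (n < 3L) stop("at least 3 sequences are required", call. = FALSE)
  if (any(nchar(seqs) == 0L)) stop("empty sequence", call. = FALSE)
  taxa <- names(seqs) %||% as.character(seq_len(n))
  states <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (aligned) {
        if (nchar(seqs[[i]]) != nchar(seqs[[j]])) {
          stop("aligned = TRUE requires equal-length sequences", call. = FALSE)
        }
        a <- strsplit(toupper(seqs[[i]]), "")[[1]]
        b <- strsplit(toupper(seqs[[j]]), "")[[1]]
      } else {
        submat <- if (type == "protein") get_submatrix(matrix) else NULL
        al <- if (type == "protein") {
          Biostrings::pairwiseAlignment(
            Biostrings::AAString(toupper(seqs[[i]])),
            Biostrings::AAString(toupper(seqs[[j]])),
            type = "global", substitutionMatrix = submat,
            gapOpening = gap_open, gapExtension = gap_extend)
        } else {
          Biostrings::pairwiseAlignment(
            Biostrings::DNAString(toupper(seqs[[i]])),
            Biostrings::DNAString(toupper(seqs[[j]])),
            type = "global", gapOpening = gap_open, gapExtension = gap_extend)
        }
        a <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
        b <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
      }
      st <- a != b
      st[a == "-" | b == "-"] <- NA
      states[[paste(i, j)]] <- st
    }
  }
  list(taxa = taxa, states = states, n = n)
}

dist_from_columns <- function(cols, model = c("p", "poisson"),
                              index = NULL) {
  model <- match.arg(model)
  n <- cols$n
  d <- matrix(0, n, n, dimnames = list(cols$taxa, cols$taxa))
  for (key in names(cols$states)) {
    ij <- as.integer(strsplit(key, " ")[[1]])
    st <- cols$states[[key]]
    if (!is.null(index)) {
      idx <- pmax(1L, ceiling(index * length(st)))
      st <- st[idx]
    }
    p <- mean(st, na.rm = TRUE)
    if (is.nan(p)) p <- 0
    if (model == "poisson") p <- -log(1 - min(p, 0.999999))
    d[ij[1], ij[2]] <- d[ij[2], ij[1]] <- p
  }
  d
}

#' Pairwise distance matrix from sequences
#'
#' For protein input each pair is globally aligned (Needleman-Wunsch,
#' BLOSUM62, affine gaps) and the p-distance is the fraction of mismatched
#' positions among aligned non-gap columns. Already-aligned (equal-length)
#' sequences can skip alignment with `aligned = TRUE`.
#'
#' @param seqs Named character vector of at least 3 sequences.
#' @param model `"p"` for p-distance, `"poisson"` for Poisson-corrected
#'   distance `-log(1 - p)`.
#' @param aligned Compare site-by-site without aligning.
#' @param type `"protein"` or `"dna"` (only used when aligning).
#' @param gap_open,gap_extend,matrix Alignment parameters.
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
pairwise_distance <- function(seqs, model = c("p", "poisson"),
                              aligned = FALSE, type = c("protein", "dna"),
                              gap_open = 11, gap_extend = 1,
                              matrix = "BLOSUM62") {
  cols <- pairwise_columns(seqs, aligned = aligned, gap_open = gap_open,
                           gap_extend = gap_extend, matrix = matrix,
                           type = match.arg(type))
  dist_from_columns(cols, model = match.arg(model))
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler selection criterion
#' `Q(i, j) = (n - 2) d(i, j) - r_i - r_j`. Ties in the Q minimization are
#' broken by the lowest `(i, j)` index pair for determinism. Negative
#' branch-length estimates are clamped to zero with the deficit moved to
#' the sibling branch; clamping is reported via the `"clamped"` attribute.
#'
#' @param d Symmetric distance matrix (zero diagonal, taxa as dimnames),
#'   at least 3 taxa.
#' @return An unrooted [ape] `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining requires at least 3 taxa", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12 || any(abs(diag(d)) > 1e-12) || any(d < 0)) {
    stop("distance matrix must be symmetric, nonnegative, zero-diagonal",
         call. = FALSE)
  }
  taxa <- rownames(d) %||% as.character(seq_len(n))
  ids <- seq_len(n)              # node ids of active rows; tips are 1..n
  next_id <- n + 1L
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  clamped <- 0L
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, len)
  }
  # clamp a negative branch estimate to 0, moving the deficit to its
  # sibling so the pair's total length is preserved
  clamp_pair <- function(vi, vj) {
    if (vi < 0) { vj <- vj + vi; vi <- 0; clamped <<- clamped + 1L }
    if (vj < 0) { vi <- vi + vj; vj <- 0; clamped <<- clamped + 1L }
    c(max(vi, 0), max(vj, 0))
  }
  D <- d
  while (length(ids) > 3L) {
    m <- length(ids)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest (i, j) pair among minima, i < j
    qmin <- min(Q)
    hit <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    v <- clamp_pair(vi, D[i, j] - vi)
    u <- next_id; next_id <- next_id + 1L
    add_edge(u, ids[i], v[1])
    add_edge(u, ids[j], v[2])
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
               c(duk[keep], 0))
    ids <- c(ids[keep], u)
    rownames(D) <- colnames(D) <- NULL
  }
  # final three nodes join at the central vertex
  center <- next_id
  x <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  y <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  z <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (any(c(x, y, z) < 0)) clamped <- clamped + sum(c(x, y, z) < 0)
  add_edge(center, ids[1], max(x, 0))
  add_edge(center, ids[2], max(y, 0))
  add_edge(center, ids[3], max(z, 0))
  # renumber into ape convention: tips 1..n, root n+1, internals n+2..
  n_internal <- center - n
  map <- integer(center)
  map[seq_len(n)] <- seq_len(n)
  map[center] <- n + 1L
  others <- setdiff((n + 1L):center, center)
  map[others] <- n + 1L + seq_along(others)
  edge <- cbind(map[edges[, 1]], map[edges[, 2]])
  ord <- order(edge[, 1], edge[, 2])
  tree <- structure(list(edge = edge[ord, , drop = FALSE],
                         edge.length = lens[ord],
                         tip.label = taxa, Nnode = n_internal),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "clamped") <- clamped
  tree
}

#' Internal bipartitions of an unrooted tree
#'
#' One entry per internal edge: the canonical form of the tip-label split
#' the edge induces (the side not containing the alphabetically smallest
#' tip, as a sorted, pipe-joined string).
#'
#' @param tree An ape `phylo` object.
#' @return Character vector of canonical split keys.
#' @export
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  internal_child <- tree$edge[, 2] > n
  anchor <- sort(tree$tip.label)[1]
  keys <- vapply(which(internal_child), function(e) {
    side <- tree$tip.label[desc[[tree$edge[e, 2]]]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  keys[!is.na(keys)]
}

descendant_tips <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- i
  tree <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the tree from all columns, then resamples alignment columns with
#' replacement `reps` times and rebuilds; the support of each internal edge
#' is 100 times the fraction of replicate trees containing its bipartition.
#' For unaligned input the per-pair alignments are computed once and their
#' columns are resampled jointly through one master coordinate vector per
#' replicate.
#'
#' @inheritParams pairwise_distance
#' @param reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; resampling is fully reproducible.
#' @return List with `tree` (node labels carry integer supports), and
#'   `support`, a data frame of bipartition keys and supports in `[0, 100]`.
#' @export
bootstrap_support <- function(seqs, reps = 1000L, seed = 20191017L,
                              model = c("p", "poisson"), aligned = FALSE,
                              type = c("protein", "dna"),
                              gap_open = 11, gap_extend = 1,
                              matrix = "BLOSUM62") {
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  model <- match.arg(model)
  cols <- pairwise_columns(seqs, aligned = aligned, gap_open = gap_open,
                           gap_extend = gap_extend, matrix = matrix,
                           type = match.arg(type))
  tree <- neighbor_joining(dist_from_columns(cols, model = model))
  keys <- tree_bipartitions(tree)
  hits <- stats::setNames(numeric(length(keys)), keys)
  withr::with_seed(seed, {
    for (b in seq_len(reps)) {
      u <- stats::runif(round(stats::median(lengths(cols$states))))
      bt <- neighbor_joining(dist_from_columns(cols, model = model, index = u))
      bk <- tree_bipartitions(bt)
      hits[keys %in% bk] <- hits[keys %in% bk] + 1
    }
  })
  support <- round(100 * hits / reps)
  list(tree = annotate_support(tree, support),
       support = data.frame(bipartition = keys, support = unname(support)))
}

annotate_support <- function(tree, support) {
  n <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  anchor <- sort(tree$tip.label)[1]
  labels <- rep("", tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= n) next
    side <- tree$tip.label[desc[[ch]]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      labels[ch - n] <- as.character(as.integer(support[[key]]))
    }
  }
  tree$node.label <- labels
  tree
}

#' Write a tree in Newick format
#'
#' Branch lengths are always written; integer bootstrap supports, when
#' present as node labels, appear as internal labels. Reading the string
#' back reproduces topology, lengths and supports.
#'
#' @param tree An ape `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read a Newick tree
#'
#' @param text Newick string (or use `file`).
#' @param file Optional path to read from.
#' @return An ape `phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text)
}

#' Path-length (patristic) distance matrix of a tree
#'
#' @param tree An ape `phylo` object with branch lengths.
#' @return Symmetric matrix of tip-to-tip path lengths.
#' @export
path_length_matrix <- function(tree) {
  n <- length(tree$tip.label)
  d <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}
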