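# Seeded generators with planted ground truth. Every generator is a pure
# function of its arguments (seed included): reruns are byte-identical, and
# the returned truth tables are sufficient to compute the expected output
# of every downstream stage without rerunning the generator.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a valid CDS: ATG + random non-stop codons + TAA, total length nt
random_cds <- function(nt) {
  stopifnot(nt %% 3L == 0L, nt >= 9L)
  codons <- c()
  stops <- c("TAA", "TAG", "TGA")
  while (length(codons) < nt / 3L - 2L) {
    cand <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                  collapse = "")
    if (!cand %in% stops) codons <- c(codons, cand)
  }
  paste(c("ATG", codons, "TAA"), collapse = "")
}

plant_motifs <- function(promoter, k, motif = crt_dre_motif()) {
  L <- nchar(promoter)
  w <- nchar(motif)
  if (k == 0L) return(list(promoter = promoter, offsets = integer(0)))
  if (k * (w + 2L) > L) stop("infeasible motif packing", call. = FALSE)
  # non-overlapping placement by slotting
  offsets <- integer(0)
  avail <- seq_len(L - w + 1L)
  for (i in seq_len(k)) {
    if (length(avail) == 0L) stop("infeasible motif packing", call. = FALSE)
    o <- if (length(avail) == 1L) avail else sample(avail, 1L)
    offsets <- c(offsets, o)
    avail <- avail[abs(avail - o) >= w]
  }
  offsets <- sort(offsets)
  expand <- function(pat) {
    paste(vapply(strsplit(pat, "")[[1]], function(ch) {
      opts <- IUPAC_CODES[[ch]]
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, character(1)), collapse = "")
  }
  for (o in offsets) {
    substr(promoter, o, o + w - 1L) <- expand(motif)
  }
  list(promoter = promoter, offsets = offsets)
}

# mutate chance hits (not overlapping planted windows) until only the
# planted copies match, so exact-count recovery tests are well defined
scrub_chance_hits <- function(promoter, offsets, motif = crt_dre_motif()) {
  w <- nchar(motif)
  planted <- unlist(lapply(offsets, function(o) o:(o + w - 1L)))
  for (iter in 1:50) {
    hits <- scan_motif(promoter, motif, both_strands = TRUE)
    chance <- hits[!(hits$start %in% offsets & hits$strand == "+"), ,
                   drop = FALSE]
    if (nrow(chance) == 0L) return(promoter)
    for (r in seq_len(nrow(chance))) {
      win <- chance$start[r]:(chance$start[r] + w - 1L)
      free <- setdiff(win, planted)
      if (length(free) == 0L) next
      pos <- free[1]
      old <- substr(promoter, pos, pos)
      substr(promoter, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                                   old), 1L)
    }
  }
  promoter
}

#' Generate a synthetic genome with planted promoter motifs
#'
#' Builds uniform-random contigs carrying stranded single-CDS gene models,
#' each with a promoter of `promoter_len` bp immediately upstream of its
#' start codon into which a controlled number of CRT/DRE copies is planted
#' at recorded offsets. By default chance (unplanted) motif occurrences in
#' the promoters are scrubbed so the planted count is the exact total.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param n_contigs Number of contigs to spread the genes over.
#' @param strand_mix Fraction of genes placed on the minus strand.
#' @param promoter_len Promoter window length (default 1000 bp).
#' @param motif_copies Planted CRT/DRE copies per gene; scalar or length
#'   `n_genes` vector.
#' @param cds_len CDS length in bp (divisible by 3).
#' @param spacer Intergenic spacer length.
#' @param motif The motif to plant (IUPAC; default [crt_dre_motif()]).
#' @param scrub Remove chance motif occurrences from promoters.
#' @return List with `genome` (named contig sequences), `genes` (gene-model
#'   data frame as from [read_gff3()]) and `truth` (per gene: planted copy
#'   count and 1-based promoter offsets).
#' @export
make_genome <- function(n_genes, seed = 1L, n_contigs = 2L, strand_mix = 0.5,
                        promoter_len = 1000L, motif_copies = 1L,
                        cds_len = 300L, spacer = 50L,
                        motif = crt_dre_motif(), scrub = TRUE) {
  stopifnot(n_genes >= 1L, n_contigs >= 1L, promoter_len >= nchar(motif))
  copies <- rep_len(as.integer(motif_copies), n_genes)
  withr::with_seed(seed, {
    contig_of <- sort(rep_len(seq_len(n_contigs), n_genes))
    strands <- ifelse(stats::runif(n_genes) < strand_mix, "-", "+")
    parts <- vector("list", n_contigs)
    offset <- integer(n_contigs)
    genes <- list(); truth <- list()
    for (i in seq_len(n_genes)) {
      ci <- contig_of[i]
      gid <- sprintf("gene%03d", i)
      cds <- random_cds(cds_len)
      pm <- plant_motifs(random_dna(promoter_len), copies[i], motif)
      promoter <- pm$promoter
      if (scrub) promoter <- scrub_chance_hits(promoter, pm$offsets, motif)
      if (strands[i] == "+") {
        segment <- paste0(promoter, cds)
        cds_start <- offset[ci] + promoter_len + 1L
      } else {
        segment <- paste0(reverse_complement(cds),
                          reverse_complement(promoter))
        cds_start <- offset[ci] + 1L
      }
      segment <- paste0(segment, random_dna(spacer))
      cds_end <- cds_start + cds_len - 1L
      parts[[ci]] <- c(parts[[ci]], segment)
      offset[ci] <- offset[ci] + nchar(segment)
      genes[[i]] <- data.frame(
        gene_id = gid, contig_id = sprintf("contig%02d", ci),
        strand = strands[i], cds_start = cds_start, cds_end = cds_end,
        cds_segments = I(list(cbind(start = cds_start, end = cds_end))),
        stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(gene_id = gid, strand = strands[i],
                               n_planted = copies[i],
                               offsets = I(list(pm$offsets)))
    }
    genome <- stats::setNames(
      vapply(parts, paste, character(1), collapse = ""),
      sprintf("contig%02d", seq_len(n_contigs)))
    list(genome = genome,
         genes = do.call(rbind, genes),
         truth = do.call(rbind, truth))
  })
}

#' Generate a count table with planted differential effects
#'
#' Per-gene baseline FPKM is drawn log-normally and shared by both
#' conditions; planted genes are shifted by `effect_log2fc` log2 units in
#' the first condition (up or down), decoys drift by a fold change drawn
#' strictly inside (0.6, 1.7) to keep a margin from the 2-fold boundary,
#' and fragment counts are Poisson-sampled around the FPKM-implied means.
#'
#' @param gene_ids Character vector of gene ids.
#' @param n_up,n_down,n_decoy Planted structure; must sum to at most the
#'   number of genes (the rest are unchanged).
#' @param effect_log2fc Planted effect size in log2 units (>= 1).
#' @param noise_sd Standard deviation (log2 units) of the per-gene
#'   baseline spread.
#' @param base_fpkm Median baseline FPKM.
#' @param gene_length Exonic length in bp; scalar or per-gene vector.
#' @param totals Length-2 vector of library totals (mapped fragments).
#' @param conditions Length-2 condition labels, effect applied to the first.
#' @param seed Integer seed.
#' @return List with `counts` (data frame: `gene_id`, `length`, one column
#'   per condition), `totals` (named vector) and `truth` (per gene `role`
#'   and intended `direction`).
#' @export
make_counts <- function(gene_ids, n_up, n_down, n_decoy,
                        effect_log2fc = 3, noise_sd = 0.1, base_fpkm = 20,
                        gene_length = 1000L, totals = c(2e7, 2e7),
                        conditions = c("winter_mature_leaf",
                                       "summer_mature_leaf"),
                        seed = 1L) {
  n <- length(gene_ids)
  if (n_up + n_down + n_decoy > n) stop("planted structure exceeds gene count",
                                        call. = FALSE)
  if (min(n_up, n_down, n_decoy, effect_log2fc, noise_sd) < 0) {
    stop("negative parameters", call. = FALSE)
  }
  lens <- rep_len(as.integer(gene_length), n)
  withr::with_seed(seed, {
    role <- rep("null", n)
    role[seq_len(n_up)] <- "up"
    role[n_up + seq_len(n_down)] <- "down"
    role[n_up + n_down + seq_len(n_decoy)] <- "decoy"
    baseline <- base_fpkm * 2^stats::rnorm(n, 0, noise_sd)
    shift <- numeric(n)
    shift[role == "up"] <- effect_log2fc
    shift[role == "down"] <- -effect_log2fc
    shift[role == "decoy"] <- log2(stats::runif(sum(role == "decoy"),
                                                0.62, 1.65))
    fpkm_a <- baseline * 2^shift
    fpkm_b <- baseline
    counts <- data.frame(
      gene_id = gene_ids, length = lens,
      a = stats::rpois(n, fpkm_a * lens * totals[1] / 1e9),
      b = stats::rpois(n, fpkm_b * lens * totals[2] / 1e9))
    colnames(counts)[3:4] <- conditions
    list(counts = counts,
         totals = stats::setNames(totals, conditions),
         truth = data.frame(gene_id = gene_ids, role = role,
                            direction = ifelse(role %in% c("up", "down"),
                                               role, "unchanged")))
  })
}

random_protein <- function(n) {
  paste(sample(AMINO_ACIDS, n, replace = TRUE), collapse = "")
}

instantiate_signature <- function(pattern) {
  paste(vapply(pattern$elements, function(cls) {
    if (length(cls) == 1L) cls else sample(cls, 1L)
  }, character(1)), collapse = "")
}

#' Generate a protein family with planted signature sequences
#'
#' Family members are point-mutated copies of a common ancestor carrying
#' the two CBF signature sequences at recorded offsets with an S1-to-S2
#' separation inside `sep_window`; the signature windows themselves are not
#' mutated. Background proteins are uniform-random and rejection-sampled to
#' be free of both signatures at the patterns' own mismatch tolerances.
#'
#' @param n_members,n_background Family and background sizes.
#' @param length Protein length in residues.
#' @param sep_window Allowed S1-to-S2 separation (residues).
#' @param mut_rate Per-residue substitution rate outside the signatures.
#' @param s1,s2 Signature patterns (see [signature_pattern()]).
#' @param seed Integer seed.
#' @return List with `proteins` (named vector, members first) and `truth`
#'   (member ids with `s1_start`, `s2_start`, `separation`).
#' @export
make_family <- function(n_members = 5L, n_background = 50L, length = 250L,
                        sep_window = c(40, 120), mut_rate = 0.08,
                        s1 = cbf_signature_s1(), s2 = cbf_signature_s2(),
                        seed = 1L) {
  k1 <- length(s1$elements); k2 <- length(s2$elements)
  stopifnot(length >= k1 + k2 + sep_window[1] + 2L)
  withr::with_seed(seed, {
    sep <- sample(seq(sep_window[1], min(sep_window[2],
                                         length - k1 - k2 - 2L)), 1L)
    s1_start <- sample(seq(2L, length - k1 - sep - k2), 1L)
    s2_start <- s1_start + k1 + sep
    ancestor <- random_protein(length)
    substr(ancestor, s1_start, s1_start + k1 - 1L) <- instantiate_signature(s1)
    substr(ancestor, s2_start, s2_start + k2 - 1L) <- instantiate_signature(s2)
    sig_pos <- c(s1_start:(s1_start + k1 - 1L), s2_start:(s2_start + k2 - 1L))
    members <- vapply(seq_len(n_members), function(i) {
      res <- strsplit(ancestor, "")[[1]]
      mut <- which(stats::runif(length) < mut_rate)
      mut <- setdiff(mut, sig_pos)
      res[mut] <- vapply(res[mut], function(r) {
        sample(setdiff(AMINO_ACIDS, r), 1L)
      }, character(1))
      paste(res, collapse = "")
    }, character(1))
    background <- character(n_background)
    for (i in seq_len(n_background)) {
      repeat {
        cand <- random_protein(length)
        if (nrow(match_signature(cand, s1)) == 0L &&
            nrow(match_signature(cand, s2)) == 0L) break
      }
      background[i] <- cand
    }
    proteins <- stats::setNames(
      c(members, background),
      c(sprintf("member%02d", seq_len(n_members)),
        sprintf("bg%03d", seq_len(n_background))))
    list(proteins = proteins,
         truth = data.frame(protein_id = names(proteins)[seq_len(n_members)],
                            s1_start = s1_start, s2_start = s2_start,
                            separation = sep))
  })
}

#' Evolve sequences along a tree
#'
#' Independent-site substitution down a tree: on each branch, every site is
#' hit by a substitution event with probability `1 - exp(-rate * branch)`;
#' a hit site is redrawn uniformly from the four bases (a Jukes-Cantor-style
#' process whose expected observable difference saturates at 3/4).
#'
#' @param tree A rooted or trifurcating ape `phylo` tree with branch
#'   lengths.
#' @param root_seq Root nucleotide sequence; random of `root_len` when
#'   `NULL`.
#' @param rate Substitution rate per site per unit branch length (> 0).
#' @param seed Integer seed.
#' @param root_len Length of the random root sequence.
#' @return Named character vector of leaf sequences (tip labels as names).
#' @export
evolve_sequences <- function(tree, root_seq = NULL, rate = 1, seed = 1L,
                             root_len = 1000L) {
  stopifnot(inherits(tree, "phylo"), rate > 0)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  withr::with_seed(seed, {
    if (is.null(root_seq)) root_seq <- random_dna(root_len)
    n <- length(tree$tip.label)
    seqs <- vector("list", n + tree$Nnode)
    root <- n + 1L
    seqs[[root]] <- strsplit(toupper(root_seq), "")[[1]]
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
      s <- seqs[[p]]
      hit <- which(stats::runif(length(s)) < 1 - exp(-rate * ord$edge.length[e]))
      if (length(hit) > 0L) {
        s[hit] <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
      }
      seqs[[ch]] <- s
    }
    stats::setNames(vapply(seqs[seq_len(n)], paste, character(1),
                           collapse = ""),
                    tree$tip.label)
  })
}
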