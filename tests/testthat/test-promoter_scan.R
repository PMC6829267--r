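toy_genome <- function(contig) c(c1 = contig)
toy_gene <- function(strand, s, e) {
  data.frame(gene_id = "g1", contig_id = "c1", strand = strand,
             cds_start = s, cds_end = e,
             cds_segments = I(list(cbind(start = s, end = e))))
}

test_that("promoter windows sit immediately upstream of the start codon", {
  set.seed(81)
  contig <- rand_dna(5000)
  # plus strand, CDS starting at 2001: bases 1001..2000
  p <- extract_promoters(toy_gene("+", 2001, 2300), toy_genome(contig))
  expect_equal(p$sequence, substr(contig, 1001, 2000))
  expect_equal(c(p$window_start, p$window_end), c(1000, 2000))
  expect_false(p$truncated)
  # minus strand, CDS ending at 3000: revcomp of bases 3001..4000
  m <- extract_promoters(toy_gene("-", 2701, 3000), toy_genome(contig))
  expect_equal(m$sequence, reverse_complement(substr(contig, 3001, 4000)))
  # plus-strand gene starting at 501 gives a 500-bp truncated window
  tr <- extract_promoters(toy_gene("+", 501, 800), toy_genome(contig))
  expect_equal(nchar(tr$sequence), 500)
  expect_true(tr$truncated)
  # gene at the contig edge is excluded with a warning
  expect_warning(
    expect_error(extract_promoters(toy_gene("+", 1, 300), toy_genome(contig)),
                 "no non-empty"),
    "contig edge")
  expect_error(
    extract_promoters(toy_gene("+", 2001, 2300), c(other = contig)),
    "missing")
})

test_that("a plus gene and its coordinate-mirrored minus twin share a promoter", {
  set.seed(82)
  contig <- rand_dna(4000)
  plus <- extract_promoters(toy_gene("+", 1501, 1800), toy_genome(contig),
                            length = 700)
  mirror <- reverse_complement(contig)
  # the mirrored gene occupies positions 4000-1800+1 .. 4000-1501+1
  minus <- extract_promoters(toy_gene("-", 2201, 2500), toy_genome(mirror),
                             length = 700)
  expect_identical(plus$sequence, minus$sequence)
})

test_that("degenerate scanning honors IUPAC classes on both strands", {
  h <- scan_motif("TTACCGACTT", "RCCGAC", name = "CRT/DRE")
  expect_equal(h[h$strand == "+", "start"], 3)
  expect_equal(nrow(scan_motif("TTGCCGACTT", "RCCGAC",
                               both_strands = FALSE)), 1)
  expect_equal(nrow(scan_motif("TTCCCGACTT", "RCCGAC",
                               both_strands = FALSE)), 0)
  # GTCGGT is the reverse complement of ACCGAC
  h2 <- scan_motif("AAGTCGGTAA", "RCCGAC")
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 3)
  # N in the scanned sequence matches nothing
  expect_equal(nrow(scan_motif("TTNCCGACTT", "RCCGAC")), 0)
  expect_error(scan_motif("ACGT", "RCJGAC"), "IUPAC")
  expect_error(scan_motif("ACGT", "NNNN"), "N-only")
})

test_that("hit lists equal the regex-expansion oracle, overlaps included", {
  set.seed(83)
  pats <- c("RCCGAC", "CACGTG", "WWCGNR", "YYYY", "AGGAGG")
  for (i in 1:30) {
    s <- rand_dna(300)
    for (pat in pats) {
      got <- scan_motif(s, pat)
      want <- motif_hits_oracle(s, pat)
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
    }
  }
  # overlapping palindromic matches are all reported
  got <- scan_motif(strrep("CACGTG", 3), "CACGTG", both_strands = FALSE)
  expect_equal(got$start, c(1, 7, 13))
})

test_that("strand-pair symmetry: a sequence and its revcomp give equal counts", {
  set.seed(84)
  for (i in 1:15) {
    s <- rand_dna(250)
    expect_equal(nrow(scan_motif(s, "RCCGAC")),
                 nrow(scan_motif(reverse_complement(s), "RCCGAC")))
  }
})

test_that("planted CRT/DRE copies are recovered exactly", {
  copies <- c(0, 1, 2, 3, 1, 0, 2, 1)
  g <- make_genome(8, seed = 85, motif_copies = copies)
  p <- extract_promoters(g$genes, g$genome)
  p <- p[match(g$genes$gene_id, p$gene_id), ]
  hits <- scan_promoters(p, "RCCGAC")
  plus <- hits[hits$strand == "+", ]
  counts <- table(factor(plus$gene_id, levels = g$genes$gene_id))
  expect_equal(as.integer(counts), copies)
  # the planted offsets themselves are reported
  for (i in seq_len(nrow(g$truth))) {
    expect_setequal(plus$start[plus$gene_id == g$truth$gene_id[i]],
                    g$truth$offsets[[i]])
  }
})

test_that("the catalogue grid retains zeros and conserves per-gene totals", {
  set.seed(86)
  proms <- data.frame(gene_id = c("gA", "gB"),
                      sequence = c(paste0(rand_dna(40), "CACGTG",
                                          rand_dna(40), "CACGTG"),
                                   rand_dna(100)))
  cat2 <- data.frame(name = c("G-box", "MBS"),
                     iupac = c("CACGTG", "CAACTG"))
  grid <- scan_catalogue(proms, cat2)
  expect_equal(dim(grid), c(2, 2))
  expect_gte(grid["gA", "G-box"], 2)
  for (g in rownames(grid)) {
    total <- sum(vapply(cat2$iupac, function(p) {
      nrow(scan_motif(proms$sequence[proms$gene_id == g], p))
    }, numeric(1)))
    expect_equal(sum(grid[g, ]), total)
  }
  empty <- scan_catalogue(proms, data.frame(name = character(0),
                                            iupac = character(0)))
  expect_equal(ncol(empty), 0)
  expect_error(scan_catalogue(proms, data.frame(name = c("a", "a"),
                                                iupac = c("ACGT", "AAAA"))),
               "duplicate")
})
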