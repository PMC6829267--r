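test_that("FASTA reading concatenates multi-line records and keeps order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1 some description", "ACGT", "ACGT", ">g2", "TTTT"), f)
  seqs <- read_fasta(f)
  expect_identical(seqs, c(g1 = "ACGTACGT", g2 = "TTTT"))
})

test_that("FASTA reader rejects empty files, duplicate ids and bad letters", {
  f <- withr::local_tempfile(fileext = ".fa")
  file.create(f)
  expect_error(read_fasta(f), "empty|malformed")
  writeLines(c(">a", "ACGT", ">a", "TTTT"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">a", "ACXT"), f)
  expect_error(read_fasta(f), "'X'")
})

test_that("FASTA round-trip reproduces ids and sequences exactly", {
  set.seed(41)
  for (rep in 1:5) {
    seqs <- setNames(vapply(1:8, function(i) rand_dna(sample(1:200, 1)),
                            character(1)),
                     paste0("seq", 1:8))
    f <- withr::local_tempfile(fileext = ".fa")
    write_fasta(seqs, f, width = 37)
    expect_identical(read_fasta(f), seqs)
  }
})

test_that("GFF3 gene models group CDS segments under their parent gene", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t101\t400\t.\t+\t.\tID=gA",
    "c1\tsrc\tCDS\t101\t400\t.\t+\t0\tID=gA.c1;Parent=gA",
    "c1\tsrc\tgene\t1001\t1400\t.\t-\t.\tID=gB",
    "c1\tsrc\tmRNA\t1001\t1400\t.\t-\t.\tID=gB.t1;Parent=gB",
    "c1\tsrc\tCDS\t1001\t1100\t.\t-\t0\tID=gB.c1;Parent=gB.t1",
    "c1\tsrc\tCDS\t1301\t1400\t.\t-\t0\tID=gB.c2;Parent=gB.t1"), f)
  g <- read_gff3(f)
  expect_setequal(g$gene_id, c("gA", "gB"))
  a <- g[g$gene_id == "gA", ]
  expect_equal(c(a$cds_start, a$cds_end, a$strand), c("101", "400", "+"),
               ignore_attr = TRUE)
  b <- g[g$gene_id == "gB", ]
  segs <- b$cds_segments[[1]]
  expect_equal(unname(segs), cbind(c(1001, 1301), c(1100, 1400)),
               ignore_attr = TRUE)
  expect_equal(sum(segs[, "end"] - segs[, "start"] + 1), 200)
})

test_that("GFF3 reader rejects orphaned, inverted and strandless CDS", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("c1\tsrc\tCDS\t400\t101\t.\t+\t0\tID=x;Parent=g"), f)
  expect_error(read_gff3(f), "start > end")
  writeLines(c("c1\tsrc\tCDS\t101\t400\t.\t+\t0\tID=x"), f)
  expect_error(read_gff3(f), "Parent")
})

test_that("GFF3 writer round-trips through the reader", {
  g <- make_genome(6, seed = 20, n_contigs = 2)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g$genes, f)
  back <- read_gff3(f)
  back <- back[match(g$genes$gene_id, back$gene_id), ]
  expect_equal(as.integer(back$cds_start), g$genes$cds_start)
  expect_equal(as.integer(back$cds_end), g$genes$cds_end)
  expect_equal(back$strand, g$genes$strand)
})

test_that("reverse_complement is an involution that preserves N", {
  expect_identical(reverse_complement("ACCGAC"), "GTCGGT")
  expect_identical(reverse_complement("N"), "N")
  expect_error(reverse_complement("ACGU"), "non-nucleotide")
  set.seed(7)
  for (i in 1:20) {
    s <- rand_dna(sample(1:100, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
  s <- "ANNGT"
  rc <- reverse_complement(s)
  expect_equal(which(strsplit(rc, "")[[1]] == "N"),
               rev(6 - which(strsplit(s, "")[[1]] == "N")))
})

test_that("translation excludes the terminal stop and flags internal stops", {
  expect_identical(translate_cds("ATGGGTTAA"), "MG")
  expect_error(translate_cds("ATGTAAATG"), "internal stop")
  expect_warning(p <- translate_cds("ATGTAAATG", permissive = TRUE),
                 "truncated")
  expect_identical(p, "M")
  expect_error(translate_cds("ATGG"), "divisible by 3")
  # a 720-nt CDS with one terminal stop yields 239 residues
  set.seed(3)
  cds <- local({
    stops <- c("TAA", "TAG", "TGA")
    cod <- character(0)
    while (length(cod) < 238) {
      c3 <- rand_dna(3)
      if (!c3 %in% stops) cod <- c(cod, c3)
    }
    paste(c("ATG", cod[1:238], "TAA"), collapse = "")
  })
  expect_equal(nchar(cds), 720)
  expect_equal(nchar(translate_cds(cds)), 239)
})

test_that("coding-complete gene models translate to (CDS length)/3 - 1 residues", {
  g <- make_genome(8, seed = 9, cds_len = 300)
  for (i in seq_len(nrow(g$genes))) {
    cds <- spliced_cds(g$genes[i, ], g$genome)
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_equal(nchar(translate_cds(cds)), nchar(cds) / 3 - 1)
  }
})
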