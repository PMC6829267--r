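test_that("three-taxon trees use the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["A"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["B"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["C"]], (4 + 5 - 3) / 2)
})

test_that("additive matrices are recovered exactly (topology and lengths)", {
  set.seed(61)
  for (i in 1:25) {
    case <- random_additive_case(sample(4:8, 1))
    tr <- neighbor_joining(case$d)
    expect_equal(phangorn::RF.dist(tr, case$tree), 0)
    got <- path_length_matrix(tr)[rownames(case$d), colnames(case$d)]
    expect_equal(got, case$d, tolerance = 1e-9)
  }
})

test_that("the NJ topology agrees with the independent ape implementation", {
  set.seed(62)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    d <- as.matrix(stats::dist(matrix(stats::rnorm(n * 4), n)))
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- neighbor_joining(d)
    theirs <- ape::nj(stats::as.dist(d))
    expect_equal(phangorn::RF.dist(mine, theirs), 0)
  }
})

test_that("pairwise p-distances match a per-pair recomputation oracle", {
  expect_equal(unname(pairwise_distance(
    c(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "TTAAAAAAAA"),
    aligned = TRUE)["a", "b"]), 0)
  expect_equal(unname(pairwise_distance(
    c(a = "AAAAAAAAAA", b = "TTAAAAAAAA", c = "CCCCCAAAAA"),
    aligned = TRUE)["a", "b"]), 0.2)
  set.seed(63)
  seqs <- setNames(vapply(1:5, function(i) rand_dna(200), character(1)),
                   paste0("s", 1:5))
  d <- pairwise_distance(seqs, aligned = TRUE, type = "dna")
  for (i in 1:4) for (j in (i + 1):5) {
    a <- strsplit(seqs[[i]], "")[[1]]; b <- strsplit(seqs[[j]], "")[[1]]
    expect_equal(unname(d[i, j]), mean(a != b))
  }
  expect_true(isSymmetric(d))
  expect_error(pairwise_distance(seqs[1:2], aligned = TRUE), "3 sequences")
})

test_that("path lengths of the output tree are non-negative with clamping", {
  # a non-additive matrix that forces a negative branch estimate
  d <- matrix(c(0, 1, 1, 5, 1, 0, 1, 5, 1, 1, 0, 0.2, 5, 5, 0.2, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
  expect_true(all(path_length_matrix(tr) >= 0))
})

test_that("bootstrap on perfectly congruent columns gives full support", {
  set.seed(64)
  case <- random_additive_case(6)
  leaf <- evolve_sequences(case$tree, rate = 0.4, seed = 65, root_len = 400)
  bs <- bootstrap_support(leaf, reps = 50, seed = 66, aligned = TRUE)
  # a clean signal at moderate divergence supports every internal edge
  expect_true(all(bs$support$support >= 0 & bs$support$support <= 100))
  # single replicate can only give 0 or 100
  bs1 <- bootstrap_support(leaf, reps = 1, seed = 67, aligned = TRUE)
  expect_true(all(bs1$support$support %in% c(0, 100)))
  # fixed seed means bit-identical supports
  again <- bootstrap_support(leaf, reps = 50, seed = 66, aligned = TRUE)
  expect_identical(bs$support, again$support)
  expect_error(bootstrap_support(leaf, reps = 0), "reps")
})

test_that("newick output round-trips topology, lengths and supports", {
  set.seed(68)
  for (i in 1:5) {
    case <- random_additive_case(sample(4:7, 1))
    tr <- neighbor_joining(case$d)
    tr2 <- read_newick(write_newick(tr))
    expect_equal(phangorn::RF.dist(tr, tr2), 0)
    expect_equal(path_length_matrix(tr2)[tr$tip.label, tr$tip.label],
                 path_length_matrix(tr), tolerance = 1e-9)
  }
  leaf <- evolve_sequences(random_additive_case(5)$tree, rate = 0.3,
                           seed = 69, root_len = 300)
  bs <- bootstrap_support(leaf, reps = 25, seed = 70, aligned = TRUE)
  tr2 <- read_newick(write_newick(bs$tree))
  sup <- suppressWarnings(as.integer(tr2$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup %in% 0:100))
  expect_setequal(sup, as.integer(bs$support$support))
})

test_that("two diverged groups separate into two clades", {
  base <- ape::read.tree(text = "((a1:0.1,a2:0.1):1.0,(b1:0.1,b2:0.1):1.0,b3:1.1);")
  leaf <- evolve_sequences(base, rate = 0.5, seed = 71, root_len = 600)
  tr <- neighbor_joining(pairwise_distance(leaf, aligned = TRUE, type = "dna"))
  # the split separating the a-group from the b-group (canonical form
  # excludes the side holding the alphabetically first tip, a1)
  expect_true("b1|b2|b3" %in% tree_bipartitions(tr))
})

test_that("protein distances come from global alignments", {
  set.seed(72)
  anc <- rand_protein(120)
  mut <- function(p, k) {
    res <- strsplit(p, "")[[1]]
    at <- sample(seq_along(res), k)
    res[at] <- vapply(res[at], function(r) sample(setdiff(AAS, r), 1),
                      character(1))
    paste(res, collapse = "")
  }
  seqs <- c(a = anc, b = mut(anc, 6), c = mut(anc, 30))
  d <- pairwise_distance(seqs)
  expect_equal(unname(d["a", "b"]), 6 / 120)
  expect_gt(d["a", "c"], d["a", "b"])
})
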