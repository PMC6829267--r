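test_that("FPKM follows c * 1e9 / (N * L) and scales as expected", {
  expect_equal(fpkm(10, 1000, 1e6), 10)
  expect_equal(fpkm(0, 1000, 1e6), 0)
  expect_equal(fpkm(7, 500, 2e7), 2 * fpkm(7, 500, 4e7))
  expect_error(fpkm(1, 0, 1e6), "length")
  expect_error(fpkm(1, 100, 0), "total")
  expect_error(fpkm(-1, 100, 1e6), "non-negative")
})

test_that("fold change is boundary-inclusive and floor-guarded", {
  fc <- fold_change(c(20, 10, 5), c(10, 20, 0))
  expect_equal(fc$fc, c(2, 0.5, 50))
  expect_equal(fc$direction, c("up", "down", "up"))
  expect_equal(fc$log2fc, log2(fc$fc))
  mid <- fold_change(15, 10)
  expect_equal(mid$direction, "unchanged")
  # reciprocal symmetry away from the floor
  set.seed(91)
  a <- runif(20, 1, 50); b <- runif(20, 1, 50)
  expect_equal(fold_change(a, b)$fc * fold_change(b, a)$fc, rep(1, 20))
  expect_error(fold_change(-1, 2), "negative")
})

test_that("the FPKM matrix equals a per-cell oracle", {
  set.seed(92)
  counts <- data.frame(gene_id = paste0("g", 1:6),
                       length = sample(300:3000, 6),
                       s1 = rpois(6, 200), s2 = rpois(6, 400))
  totals <- c(s1 = 1.5e6, s2 = 3.2e6)
  m <- expression_matrix(counts, totals)
  for (i in 1:6) for (s in c("s1", "s2")) {
    expect_equal(m[i, s], counts[[s]][i] * 1e9 / (totals[[s]] * counts$length[i]))
  }
  # all-zero column stays zero
  counts$s1 <- 0L
  expect_true(all(expression_matrix(counts, totals)[, "s1"] == 0))
  expect_error(expression_matrix(counts, c(s1 = 1e6)), "missing")
})

test_that("normalization centers per gene and leaves flat genes at zero", {
  m <- matrix(c(1, 1, 1, 2, 4, 8), 2, byrow = TRUE,
              dimnames = list(c("flat", "var"), c("a", "b", "c")))
  z <- normalize_expression(m, log2 = FALSE, zscale = TRUE)
  expect_equal(unname(z["flat", ]), c(0, 0, 0))
  expect_equal(mean(z["var", ]), 0)
  expect_equal(sd(z["var", ]), 1)
})

test_that("2^-ddCt matches a hand-computed oracle", {
  q <- data.frame(sample = rep(c("0h", "6h"), each = 3), replicate = rep(1:3, 2),
                  ct_target = c(25.0, 25.2, 24.8, 23.0, 23.1, 22.9),
                  ct_reference = c(20.0, 20.1, 19.9, 20.0, 20.05, 19.95))
  r <- ddct(q, "0h")
  # spreadsheet-style recomputation
  dct <- q$ct_target - q$ct_reference
  cal_mean <- mean(dct[1:3])
  rq6 <- 2^(-(dct[4:6] - cal_mean))
  expect_equal(r$replicates$rq[4:6], rq6, tolerance = 1e-12)
  expect_equal(r$summary$rq[r$summary$sample == "6h"],
               2^(-mean(dct[4:6] - cal_mean)), tolerance = 1e-12)
  p_or <- t.test(dct[4:6], dct[1:3])$p.value
  expect_equal(r$summary$p_value[r$summary$sample == "6h"], p_or)
  expect_true(r$summary$significant[r$summary$sample == "6h"])
})

test_that("the calibrator's own RQ is identically 1", {
  for (n in c(2, 3, 5)) {
    set.seed(100 + n)
    q <- data.frame(sample = "0h", replicate = 1:n,
                    ct_target = 25 + rnorm(n, 0, 0.3),
                    ct_reference = 20 + rnorm(n, 0, 0.2))
    r <- ddct(q, "0h")
    expect_equal(r$summary$rq, 1)
    expect_false(r$summary$significant)
  }
})

test_that("a uniform ddCt shift of -1 doubles the relative quantity", {
  q <- data.frame(sample = rep(c("cal", "trt"), each = 2), replicate = rep(1:2, 2),
                  ct_target = c(25, 25, 24, 24), ct_reference = c(20, 20, 20, 20))
  r <- ddct(q, "cal")
  expect_equal(r$replicates$rq[r$replicates$sample == "trt"], c(2, 2))
  expect_equal(r$summary$rq[r$summary$sample == "trt"], 2)
})

test_that("qPCR input validation catches bad tables", {
  q <- data.frame(sample = "a", replicate = 1, ct_target = 50,
                  ct_reference = 20)
  expect_error(ddct(q, "a"), "Ct values")
  q2 <- data.frame(sample = c("a", "a", "b"), replicate = c(1, 2, 1),
                   ct_target = c(25, 25, 24), ct_reference = c(20, 20, 20))
  expect_error(ddct(q2, "a"), "replicates")
  expect_error(ddct(q2, "zz"), "calibrator")
})

test_that("planted winter effects pass the 2-fold rule with high winter FPKM", {
  # 4 of 5 family genes planted winter-high, the 5th left unchanged
  mc <- make_counts(paste0("CBF", 1:5), n_up = 4, n_down = 0, n_decoy = 0,
                    effect_log2fc = 3, noise_sd = 0.1, seed = 95)
  m <- expression_matrix(mc$counts, mc$totals)
  fc <- fold_change(m[, "winter_mature_leaf"], m[, "summer_mature_leaf"])
  expect_equal(fc$direction, c(rep("up", 4), "unchanged"))
  expect_true(all(m[1:4, "winter_mature_leaf"] > 10))
})
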