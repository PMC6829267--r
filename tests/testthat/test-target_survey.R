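expr_of <- function(w, s) {
  m <- cbind(winter = w, summer = s)
  rownames(m) <- paste0("g", seq_along(w))
  m
}

# independent naive implementation of the two-criterion selection
survey_oracle <- function(w, s, hits, floor = 0.1) {
  genes <- paste0("g", seq_along(w))
  lfc <- log2(pmax(w, floor) / pmax(s, floor))
  sel <- abs(lfc) >= 1 & hits[genes] >= 1
  genes[!is.na(sel) & sel]
}

test_that("both criteria are required, at the inclusive 2-fold boundary", {
  m <- expr_of(c(30, 30, 15, 20), c(10, 10, 10, 10))
  hits <- c(g1 = 1, g2 = 0, g3 = 2, g4 = 1)
  sv <- survey_targets(m, hits, "winter", "summer")
  # g1: fc 3 with a hit -> in; g2: no hit -> out; g3: fc 1.5 -> out;
  # g4: fc exactly 2 -> in ("at least 2-fold" is inclusive)
  expect_equal(sv$gene_id, c("g1", "g4"))
  expect_equal(sv$direction, c("up", "up"))
  expect_error(survey_targets(m, hits, "autumn", "summer"), "unknown condition")
})

test_that("survey equals the brute-force intersection oracle on random fixtures", {
  set.seed(111)
  for (i in 1:40) {
    n <- sample(5:120, 1)
    w <- round(2^rnorm(n, 3, 2), 2)
    s <- round(2^rnorm(n, 3, 2), 2)
    w[sample(n, n %/% 10 + 1)] <- 0
    hits <- setNames(rpois(n, 0.8), paste0("g", 1:n))
    sv <- survey_targets(expr_of(w, s), hits, "winter", "summer")
    expect_setequal(sv$gene_id, survey_oracle(w, s, hits))
  }
})

test_that("up plus down always equals the survey total", {
  set.seed(112)
  for (i in 1:10) {
    n <- 50
    w <- 2^rnorm(n, 3, 2); s <- 2^rnorm(n, 3, 2)
    hits <- setNames(rpois(n, 1), paste0("g", 1:n))
    sv <- survey_targets(expr_of(w, s), hits, "winter", "summer")
    tot <- survey_summary(sv)
    expect_equal(tot$up + tot$down, tot$total)
    expect_equal(tot$total, nrow(sv))
  }
})

test_that("classification maps annotations to categories by keyword", {
  recs <- data.frame(gene_id = c("g1", "g2", "g3"),
                     direction = c("up", "down", "up"),
                     annotation = c("galactinol synthase GOLS3",
                                    "hypothetical protein",
                                    "calcium-transporting ATPase"))
  cl <- classify_targets(recs)
  expect_equal(cl$categories[[1]], "carbohydrate metabolism")
  expect_equal(cl$categories[[2]], "other")
  # one annotation can land in several categories, in stable map order
  expect_equal(cl$categories[[3]], c("calcium signaling", "transporter"))
  expect_error(classify_targets(recs, data.frame(category = character(0),
                                                 keyword = character(0))),
               "empty")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  bg <- paste0("g", 1:10)
  tm <- rbind(data.frame(term = "T1", gene_id = paste0("g", 1:5)),
              data.frame(term = "all", gene_id = bg))
  e <- enrich_terms(paste0("g", 1:4), bg, tm)
  # all 4 draws inside the 5-gene term: C(5,4)C(5,0)/C(10,4) = 5/210
  expect_equal(e$p[e$term == "T1"], 5 / 210)
  expect_equal(e$p[e$term == "all"], 1)
  expect_true(all(e$p_adj >= e$p))
  expect_error(enrich_terms("gX", bg, tm), "absent from background")
})

test_that("closed-form enrichment p agrees with Monte-Carlo resampling", {
  set.seed(113)
  bg <- paste0("g", 1:40)
  term <- paste0("g", 1:12)
  drawn <- paste0("g", c(1:6, 30:35))  # k = 6 of n = 12 in the term
  tm <- rbind(data.frame(term = "T", gene_id = term),
              data.frame(term = "bgterm", gene_id = bg))
  p <- enrich_terms(drawn, bg, tm)
  p <- p$p[p$term == "T"]
  B <- 1e5
  k_sim <- vapply(seq_len(B), function(b) {
    length(intersect(sample(bg, length(drawn)), term))
  }, numeric(1))
  p_mc <- mean(k_sim >= 6)
  se <- sqrt(p_mc * (1 - p_mc) / B)
  expect_lt(abs(p - p_mc), 3 * se + 1e-6)
})

test_that("enrichment p-values are invariant to gene relabeling", {
  set.seed(114)
  bg <- paste0("g", 1:30)
  tm <- data.frame(term = rep(c("A", "B"), c(8, 10)),
                   gene_id = c(paste0("g", 1:8), paste0("g", 11:20)))
  drawn <- paste0("g", c(1:5, 12, 13, 25))
  e1 <- enrich_terms(drawn, bg, tm)
  relabel <- setNames(paste0("x", 1:30), bg)
  tm2 <- transform(tm, gene_id = relabel[gene_id])
  e2 <- enrich_terms(unname(relabel[drawn]), unname(relabel), tm2)
  expect_equal(e1[c("term", "k", "K", "p", "p_adj")],
               e2[c("term", "k", "K", "p", "p_adj")])
})

test_that("the survey report conserves counts and isolates hormone genes", {
  recs <- data.frame(
    gene_id = paste0("g", 1:4), fc = c(4, 0.2, 8, 3),
    log2fc = log2(c(4, 0.2, 8, 3)),
    direction = c("up", "down", "up", "up"), n_crtdre = 1L,
    annotation = c("auxin response factor", "protein kinase",
                   "receptor kinase", "JAZ protein"))
  attr(recs, "summary") <- list(total = 4L, up = 3L, down = 1L)
  recs <- classify_targets(recs)
  rep <- survey_report(recs)
  expect_equal(rep$totals$total, 4)
  expect_true(all(rep$categories$up + rep$categories$down ==
                  rep$categories$total))
  expect_setequal(rep$hormone_signaling$gene_id, c("g1", "g4"))
  empty <- survey_report(recs[0, ])
  expect_equal(empty$totals$total, 0)
  expect_equal(nrow(empty$enrichment), 0)
})
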