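# Expression analysis: FPKM from fragment counts, winter/summer fold
# changes with a ratio floor, and relative qPCR quantification by the
# 2^-ddCt method with Welch significance on delta-Ct.

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = c * 1e9 / (N * L)` for count `c`, exonic gene length `L` in bp
#' and library total `N` mapped fragments. Vectorized over all arguments.
#'
#' @param counts Non-negative fragment counts.
#' @param lengths Gene lengths in bp (> 0).
#' @param totals Total mapped fragments per library (> 0).
#' @return Numeric FPKM values.
#' @export
#' @examples
#' fpkm(10, 1000, 1e6)  # 10
fpkm <- function(counts, lengths, totals) {
  if (any(lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(totals <= 0)) stop("library totals must be positive", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  counts * 1e9 / (totals * lengths)
}

#' Fold change between two conditions with a ratio floor
#'
#' `fc = max(a, floor) / max(b, floor)`; the floor guards ratios against
#' zero expression without modifying the FPKM values themselves. Direction
#' is `up` when `fc >= threshold`, `down` when `fc <= 1/threshold`, else
#' `unchanged` ("at least `threshold`-fold" is boundary-inclusive).
#'
#' @param a,b FPKM in the numerator (e.g. winter) and denominator (e.g.
#'   summer) condition; vectorized.
#' @param floor Positive ratio floor (default 0.1 FPKM).
#' @param threshold Fold threshold (default 2).
#' @return Data frame with columns `fc`, `log2fc`, `direction`.
#' @export
#' @examples
#' fold_change(c(20, 10, 5), c(10, 20, 0))
fold_change <- function(a, b, floor = 0.1, threshold = 2) {
  stopifnot(floor > 0, threshold > 1)
  if (any(a < 0) || any(b < 0)) stop("negative FPKM", call. = FALSE)
  fc <- pmax(a, floor) / pmax(b, floor)
  direction <- ifelse(fc >= threshold, "up",
                      ifelse(fc <= 1 / threshold, "down", "unchanged"))
  data.frame(fc = fc, log2fc = log2(fc), direction = direction)
}

#' FPKM expression matrix from a count table
#'
#' @param counts Data frame with columns `gene_id`, `length`, then one
#'   integer column per sample.
#' @param totals Named numeric vector of total mapped fragments, one entry
#'   per sample column.
#' @return Numeric matrix of FPKM, genes as rows, samples as columns.
#' @export
expression_matrix <- function(counts, totals) {
  samples <- setdiff(colnames(counts), c("gene_id", "length"))
  if (!all(samples %in% names(totals))) {
    stop("missing library totals for: ",
         paste(setdiff(samples, names(totals)), collapse = ", "),
         call. = FALSE)
  }
  m <- vapply(samples, function(s) {
    fpkm(counts[[s]], counts$length, totals[[s]])
  }, numeric(nrow(counts)))
  if (nrow(counts) == 1L) m <- matrix(m, nrow = 1L)
  dimnames(m) <- list(counts$gene_id, samples)
  m
}

#' Normalize an expression matrix for heat-map display
#'
#' Optional `log2(FPKM + 1)` transform and per-gene z-scaling (genes with
#' zero variance are left at 0).
#'
#' @param mat FPKM matrix from [expression_matrix()].
#' @param log2 Apply `log2(x + 1)`.
#' @param zscale Center and scale each gene row.
#' @return Transformed numeric matrix.
#' @export
normalize_expression <- function(mat, log2 = TRUE, zscale = TRUE) {
  if (log2) mat <- log2(mat + 1)
  if (zscale) {
    mat <- t(apply(mat, 1, function(x) {
      s <- stats::sd(x)
      if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }))
  }
  mat
}

#' Relative qPCR expression by the 2^-ddCt method
#'
#' Per biological replicate, `dCt = Ct_target - Ct_reference`; `ddCt` is
#' the replicate dCt minus the mean dCt of the calibrator sample, and the
#' relative quantity is `RQ = 2^-ddCt`. The summary RQ is `2^-mean(ddCt)`
#' (the geometric mean of the replicate RQs), so the calibrator's own RQ is
#' identically 1. Significance per sample is a two-sided Welch t-test of
#' the replicate dCt values against the calibrator's dCt values at
#' `p < 0.05` (replicate counts may differ).
#'
#' @param qpcr Data frame with columns `sample`, `replicate`, `ct_target`,
#'   `ct_reference`; Ct values must lie in (0, 45).
#' @param calibrator Name of the calibrator sample (e.g. `"0h"`).
#' @param alpha Significance level for the Welch test.
#' @return List with `replicates` (per-replicate `dct`, `ddct`, `rq`) and
#'   `summary` (per-sample `rq`, `se` of the replicate RQs, `p_value`,
#'   `significant`).
#' @export
ddct <- function(qpcr, calibrator, alpha = 0.05) {
  needed <- c("sample", "replicate", "ct_target", "ct_reference")
  if (!all(needed %in% colnames(qpcr))) {
    stop("qpcr table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  ct <- c(qpcr$ct_target, qpcr$ct_reference)
  if (any(ct <= 0 | ct >= 45)) stop("Ct values must lie in (0, 45)",
                                    call. = FALSE)
  if (!calibrator %in% qpcr$sample) {
    stop("calibrator sample '", calibrator, "' not present", call. = FALSE)
  }
  qpcr$dct <- qpcr$ct_target - qpcr$ct_reference
  cal_dct <- qpcr$dct[qpcr$sample == calibrator]
  qpcr$ddct <- qpcr$dct - mean(cal_dct)
  qpcr$rq <- 2^(-qpcr$ddct)
  summaries <- lapply(split(qpcr, qpcr$sample), function(g) {
    n <- nrow(g)
    p <- NA_real_
    if (g$sample[1] != calibrator) {
      if (n < 2L || length(cal_dct) < 2L) {
        stop("significance testing needs >= 2 replicates per sample",
             call. = FALSE)
      }
      # degenerate (zero-variance) inputs: equal means are a clear null,
      # unequal means a clear difference
      p <- tryCatch(stats::t.test(g$dct, cal_dct)$p.value,
                    error = function(e) {
                      if (isTRUE(all.equal(mean(g$dct), mean(cal_dct)))) 1
                      else 0
                    })
    }
    data.frame(sample = g$sample[1], n = n,
               rq = 2^(-mean(g$ddct)),
               se = if (n > 1L) stats::sd(g$rq) / sqrt(n) else NA_real_,
               p_value = p,
               significant = !is.na(p) & p < alpha)
  })
  summary <- do.call(rbind, summaries[unique(qpcr$sample)])
  rownames(summary) <- NULL
  list(replicates = qpcr, summary = summary)
}
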