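# The headline procedure: intersect the set of genes changing at least
# 2-fold between two conditions with the set whose promoters carry at least
# one CRT/DRE motif, then classify the survivors into functional categories
# and test term enrichment with the hypergeometric distribution.

#' Survey candidate CBF target genes
#'
#' Applies the two selection criteria: (1) the gene is up- or downregulated
#' at least `fold_threshold`-fold in `cond_a` relative to `cond_b`; (2) its
#' promoter carries at least `min_hits` CRT/DRE motifs. Both are required.
#'
#' @param expr FPKM matrix (genes x conditions) from [expression_matrix()].
#' @param hits Named integer vector of per-gene CRT/DRE hit counts, e.g.
#'   from [count_motif_hits()]. Genes absent from `hits` count as 0.
#' @param cond_a,cond_b Column names of the contrasted conditions (e.g.
#'   winter and summer mature leaf).
#' @param fold_threshold Fold-change criterion (boundary inclusive).
#' @param floor Ratio floor passed to [fold_change()].
#' @param min_hits Minimum number of motif hits (default 1).
#' @param annotations Optional named character vector of free-text gene
#'   annotations carried into the records.
#' @return Data frame of surviving genes: `gene_id`, `fc`, `log2fc`,
#'   `direction`, `n_crtdre`, `annotation`; the totals block (`total`,
#'   `up`, `down`) is attached as attribute `"summary"`.
#' @export
survey_targets <- function(expr, hits, cond_a, cond_b, fold_threshold = 2,
                           floor = 0.1, min_hits = 1L, annotations = NULL) {
  for (cond in c(cond_a, cond_b)) {
    if (!cond %in% colnames(expr)) {
      stop("unknown condition label '", cond, "'", call. = FALSE)
    }
  }
  genes <- rownames(expr)
  fc <- fold_change(expr[, cond_a], expr[, cond_b], floor = floor,
                    threshold = fold_threshold)
  n_crtdre <- ifelse(genes %in% names(hits), hits[genes], 0L)
  keep <- fc$direction != "unchanged" & n_crtdre >= min_hits
  out <- data.frame(gene_id = genes[keep], fc = fc$fc[keep],
                    log2fc = fc$log2fc[keep],
                    direction = fc$direction[keep],
                    n_crtdre = as.integer(n_crtdre[keep]),
                    annotation = if (is.null(annotations)) {
                      rep(NA_character_, sum(keep))
                    } else {
                      unname(annotations[genes[keep]])
                    },
                    row.names = NULL)
  attr(out, "summary") <- list(total = nrow(out),
                               up = sum(out$direction == "up"),
                               down = sum(out$direction == "down"))
  out
}

#' Totals block of a survey
#'
#' @param records Survey data frame from [survey_targets()].
#' @return List with `total`, `up` and `down` gene counts.
#' @export
survey_summary <- function(records) {
  list(total = nrow(records), up = sum(records$direction == "up"),
       down = sum(records$direction == "down"))
}

#' Classify surveyed genes into functional categories
#'
#' Case-insensitive substring matching of each record's annotation against
#' a keyword map. A gene may fall into several categories (kept in the
#' keyword map's category order); genes matching nothing are assigned
#' `"other"`.
#'
#' @param records Survey data frame with an `annotation` column.
#' @param keyword_map Data frame with columns `category` and `keyword`;
#'   defaults to the built-in eleven-category map,
#'   [default_category_keywords()].
#' @return `records` with a list column `categories` added.
#' @export
classify_targets <- function(records, keyword_map = default_category_keywords()) {
  if (nrow(keyword_map) == 0L) stop("empty keyword map", call. = FALSE)
  cat_order <- unique(keyword_map$category)
  records$categories <- lapply(records$annotation, function(ann) {
    if (is.na(ann) || !nzchar(ann)) return("other")
    ann <- tolower(ann)
    hit <- vapply(seq_len(nrow(keyword_map)), function(k) {
      grepl(tolower(keyword_map$keyword[k]), ann, fixed = TRUE)
    }, logical(1))
    cats <- intersect(cat_order, unique(keyword_map$category[hit]))
    if (length(cats) == 0L) "other" else cats
  })
  records
}

#' Hypergeometric term enrichment
#'
#' For each term, `p` is the upper-tail hypergeometric probability of
#' drawing at least `k` term genes when `n` annotated survey genes are
#' drawn from `M` annotated background genes of which `K` are in the term.
#' Benjamini-Hochberg adjusted p-values are reported alongside.
#'
#' @param survey_genes Character vector of surveyed gene ids (must be a
#'   subset of `background`).
#' @param background Character vector of background gene ids.
#' @param term_map Data frame with columns `term` and `gene_id`.
#' @return Data frame `term`, `k`, `n`, `K`, `M`, `p`, `p_adj`, sorted by
#'   increasing `p`.
#' @export
enrich_terms <- function(survey_genes, background, term_map) {
  if (!all(survey_genes %in% background)) {
    stop("survey gene '", setdiff(survey_genes, background)[1],
         "' absent from background", call. = FALSE)
  }
  term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  annotated_bg <- unique(term_map$gene_id)
  annotated_sv <- intersect(survey_genes, annotated_bg)
  M <- length(annotated_bg)
  n <- length(annotated_sv)
  terms <- split(term_map$gene_id, term_map$term)
  rows <- lapply(names(terms), function(t) {
    K <- length(unique(terms[[t]]))
    k <- length(intersect(annotated_sv, terms[[t]]))
    p <- stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(term = t, k = k, n = n, K = K, M = M, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Machine-readable survey report
#'
#' Assembles the totals block, per-category counts with up/down splits, a
#' hormone-signaling subtable and the enrichment table into one
#' JSON-serializable list.
#'
#' @param records Classified survey data frame (see [classify_targets()]).
#' @param enrichments Optional enrichment data frame from [enrich_terms()].
#' @param top Number of top enrichment rows to retain (default 20).
#' @return A named list with elements `totals`, `categories`,
#'   `hormone_signaling`, `enrichment`.
#' @export
survey_report <- function(records, enrichments = NULL, top = 20L) {
  totals <- survey_summary(records)
  cats <- if (nrow(records) > 0L && !is.null(records$categories)) {
    long <- data.frame(
      category = unlist(records$categories),
      direction = rep(records$direction, lengths(records$categories)))
    agg <- lapply(split(long, long$category), function(g) {
      data.frame(category = g$category[1], total = nrow(g),
                 up = sum(g$direction == "up"),
                 down = sum(g$direction == "down"))
    })
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
    out[order(-out$total, out$category), , drop = FALSE]
  } else {
    data.frame(category = character(0), total = integer(0),
               up = integer(0), down = integer(0))
  }
  hormone <- if (nrow(records) > 0L && !is.null(records$categories)) {
    keep <- vapply(records$categories, function(x) "hormone signaling" %in% x,
                   logical(1))
    records[keep, setdiff(colnames(records), "categories"), drop = FALSE]
  } else {
    records[0, , drop = FALSE]
  }
  enr <- if (is.null(enrichments)) {
    data.frame()
  } else {
    utils::head(enrichments, top)
  }
  list(totals = totals, categories = cats,
       hormone_signaling = hormone, enrichment = enr)
}
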