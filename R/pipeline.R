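# End-to-end pipeline: identify -> props -> tree -> promoters -> scan ->
# fpkm -> survey on a config-declared input set, with a validated config
# object, per-stage structured logging and deterministic, seeded outputs.
# The effective configuration is always echoed into the output directory.

pipeline_defaults <- function() {
  list(promoter_len = 1000L, fold_threshold = 2, motif = crt_dre_motif(),
       bootstrap_reps = 1000L, seed = 20191017L, fpkm_floor = 0.1,
       min_score_frac = 0.4, sep_window = c(40, 120),
       s1_max_mismatches = 2L, s2_max_mismatches = 0L,
       gap_open = 11, gap_extend = 1, both_strands = TRUE,
       min_hits = 1L,
       cond_a = "winter_mature_leaf", cond_b = "summer_mature_leaf")
}

#' Build and validate a pipeline configuration
#'
#' Named overrides of the defaults: `promoter_len` (1000 bp),
#' `fold_threshold` (2), `motif` (`RCCGAC`), `bootstrap_reps` (1000),
#' `seed` (20191017), `fpkm_floor` (0.1), `min_score_frac` (0.4),
#' `sep_window` (40-120 residues), signature mismatch tolerances, gap
#' penalties, strand handling, and the contrasted condition labels.
#' Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults above.
#' @return A validated `pipeline_config` list.
#' @export
#' @examples
#' pipeline_config(fold_threshold = 2, seed = 42)
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over) > 0L && (is.null(names(over)) || any(names(over) == ""))) {
    stop("all config overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot(promoter_len >= 1, fold_threshold > 1, fpkm_floor > 0,
              bootstrap_reps >= 1, min_score_frac > 0, min_score_frac <= 1,
              length(sep_window) == 2, sep_window[1] <= sep_window[2],
              min_hits >= 1)
  })
  validate_iupac(cfg$motif)
  structure(cfg, class = "pipeline_config")
}

stage <- function(name, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  res
}

write_tsv <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Run the full survey pipeline
#'
#' Chains the stages in dependency order on in-memory inputs: family
#' identification (homology + signatures), protein property profiling,
#' neighbor-joining tree with bootstrap, promoter extraction, CRT/DRE and
#' cis-element scanning, FPKM computation, and the two-criterion target
#' survey with classification. All outputs are deterministic given the
#' config (the bootstrap seed comes from `config$seed`) and are written as
#' TSV/Newick/JSON under `out_dir` together with the effective config and
#' a per-stage log.
#'
#' @param config A [pipeline_config()].
#' @param genome Named character vector of contig sequences.
#' @param genes Gene-model data frame (see [read_gff3()]).
#' @param queries Named character vector of seed CBF proteins.
#' @param proteins Named character vector of proteins to screen (the
#'   accepted ones are profiled and put on the tree).
#' @param counts,totals Count table and library totals (see
#'   [expression_matrix()]).
#' @param annotations Optional named character vector of gene annotations.
#' @param catalogue Optional cis-element catalogue for the grid scan.
#' @param keyword_map Keyword map for classification.
#' @param term_map Optional term-to-gene map for enrichment.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all stage results (`family`, `props`,
#'   `tree`, `promoters`, `crtdre_hits`, `element_grid`, `fpkm`, `survey`,
#'   `report`, `log`).
#' @export
run_pipeline <- function(config, genome, genes, queries, proteins,
                         counts, totals, annotations = NULL,
                         catalogue = default_cis_elements(),
                         keyword_map = default_category_keywords(),
                         term_map = NULL, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  note <- function(stage_name, n_in, n_out) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage_name,
                                           n_in = n_in, n_out = n_out)
    message(sprintf("[%s] in=%d out=%d", stage_name, n_in, n_out))
  }
  s1 <- cbf_signature_s1(config$s1_max_mismatches)
  s2 <- cbf_signature_s2(config$s2_max_mismatches)

  family <- stage("identify", identify_family(
    queries, proteins, min_score_frac = config$min_score_frac,
    s1 = s1, s2 = s2, sep_window = config$sep_window,
    gap_open = config$gap_open, gap_extend = config$gap_extend))
  note("identify", length(proteins), sum(family$accepted))
  accepted <- proteins[family$protein_id[family$accepted]]

  props <- stage("props", protein_properties(accepted))
  note("props", length(accepted), nrow(props))

  tree_res <- if (length(accepted) >= 3L) {
    stage("tree", bootstrap_support(
      accepted, reps = config$bootstrap_reps, seed = config$seed,
      gap_open = config$gap_open, gap_extend = config$gap_extend))
  } else NULL
  note("tree", length(accepted), if (is.null(tree_res)) 0L else 1L)

  promoters <- stage("promoters",
                     extract_promoters(genes, genome, config$promoter_len))
  note("promoters", nrow(genes), nrow(promoters))

  crtdre <- stage("scan", count_motif_hits(
    promoters, config$motif, both_strands = config$both_strands))
  grid <- stage("scan", scan_catalogue(promoters, catalogue,
                                            both_strands = config$both_strands))
  note("scan", nrow(promoters), sum(crtdre))

  expr <- stage("fpkm", expression_matrix(counts, totals))
  note("fpkm", nrow(counts), nrow(expr))

  survey <- stage("survey", survey_targets(
    expr, crtdre, config$cond_a, config$cond_b,
    fold_threshold = config$fold_threshold, floor = config$fpkm_floor,
    min_hits = config$min_hits, annotations = annotations))
  survey <- stage("survey", classify_targets(survey, keyword_map))
  note("survey", nrow(expr), nrow(survey))

  enr <- if (!is.null(term_map)) {
    stage("enrich", enrich_terms(survey$gene_id, rownames(expr),
                                      term_map))
  } else NULL
  report <- stage("report", survey_report(survey, enr))

  # deterministic output bundle
  write_tsv(family, file.path(out_dir, "family.tsv"))
  write_tsv(props, file.path(out_dir, "protein_properties.tsv"))
  if (!is.null(tree_res)) {
    write_newick(tree_res$tree, file.path(out_dir, "tree.nwk"))
    write_tsv(tree_res$support, file.path(out_dir, "tree_support.tsv"))
  }
  write_fasta(stats::setNames(promoters$sequence, promoters$gene_id),
              file.path(out_dir, "promoters.fa"))
  write_tsv(data.frame(gene_id = names(crtdre), n_crtdre = crtdre),
            file.path(out_dir, "crtdre_counts.tsv"))
  write_tsv(cbind(gene_id = rownames(grid), as.data.frame(grid)),
            file.path(out_dir, "element_grid.tsv"))
  write_tsv(cbind(gene_id = rownames(expr), as.data.frame(expr)),
            file.path(out_dir, "fpkm.tsv"))
  flat <- survey
  flat$categories <- vapply(flat$categories, paste, character(1),
                            collapse = ";")
  write_tsv(flat, file.path(out_dir, "survey.tsv"))
  if (!is.null(enr)) write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "effective_config.yaml"))
  log_df <- do.call(rbind, log)
  write_tsv(log_df, file.path(out_dir, "pipeline_log.tsv"))

  invisible(list(family = family, props = props, tree = tree_res,
                 promoters = promoters, crtdre_hits = crtdre,
                 element_grid = grid, fpkm = expr, survey = survey,
                 enrichment = enr, report = report, log = log_df))
}
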