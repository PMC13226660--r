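#' Run the full synthetic-data discovery pipeline
#'
#' Generates the four synthetic datasets from one [sim_config()], runs the
#' four analysis stages in order — anchor co-expression screen,
#' tissue-distribution clustering, single-cell cluster summary + gene-set
#' scoring, and the fasting/refeeding response classifier with
#' over-representation testing — writes every intermediate artifact under
#' `outdir`, and joins the per-gene evidence into one candidate report. A gene
#' is a final hit when it passes the screen AND sits in the anchors' tissue
#' module AND is cluster-restricted in the single-cell data (the evidence
#' chain used to prioritize a tissue-specific secretory candidate).
#'
#' The run is deterministic given `config`: artifacts of two runs with the
#' same configuration are byte-identical.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing).
#' @param threshold,transform screen parameters (see
#'   [candidate_intersection()], [anchor_correlations()]).
#' @param n_modules modules to cut in the tissue clustering; default 3, the
#'   number of planted profile blocks.
#' @param top_fraction,min_cells single-cell scoring parameters.
#' @param pseudocount,resp_thresh,diff_thresh classifier parameters.
#' @return Invisibly, a list: `report` (per-gene evidence data.frame),
#'   `screen`, `modules`, `anchor_mod`, `summary_sc`, `score`,
#'   `classification`, `enrichment`, `provenance`.
#' @examples
#' \donttest{
#' res <- run_pipeline(sim_config(seed = 1, n_genes = 300,
#'                                n_samples_per_tissue = 30,
#'                                module_size = 10, n_responsive = 30),
#'                     outdir = tempfile())
#' head(res$report)
#' }
#' @export
run_pipeline <- function(config, outdir,
                         threshold = 0.6,
                         transform = c("log2p1", "identity"),
                         n_modules = 3L,
                         top_fraction = 0.05, min_cells = 10L,
                         pseudocount = 1.0, resp_thresh = 1.0,
                         diff_thresh = 1.0) {
  stopifnot(inherits(config, "sim_config"))
  transform <- match.arg(transform)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  pth <- function(...) file.path(outdir, ...)

  # --- stage 0: simulate -----------------------------------------------
  co <- sim_coexpression(config)
  tp <- sim_tissue_profiles(config)
  sc <- sim_single_cell(config)
  rs <- sim_response(config)
  anchors <- attr(co$truth, "anchor_ids")
  write_expression_tsv(co$tissue_a, pth("bulk_liver.tsv"))
  write_expression_tsv(co$tissue_b, pth("bulk_intestine.tsv"))
  write_expression_tsv(tp$profile, pth("tissue_profile.tsv"))
  write_single_cell(sc$counts, sc$cells, pth("single_cell"))
  write_expression_tsv(rs$values, pth("response.tsv"))
  write_gmt(rs$gene_sets, pth("gene_sets.gmt"))
  write_truth_tsv(co$truth, pth("truth_coexpression.tsv"))
  write_truth_tsv(tp$truth, pth("truth_tissue.tsv"))
  write_truth_tsv(sc$truth, pth("truth_single_cell.tsv"))
  write_truth_tsv(rs$truth, pth("truth_response.tsv"))

  # --- stage 1: anchor screen ------------------------------------------
  screen <- screen_anchors(list(liver = co$tissue_a, intestine = co$tissue_b),
                           anchors = anchors, threshold = threshold,
                           transform = transform)
  utils::write.table(within(screen$candidates, min_r <- signif(min_r, 6)),
                     pth("screen_candidates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(screen$venn, pth("screen_venn.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- stage 2: tissue clustering --------------------------------------
  scaled <- minmax_scale(tp$profile)
  keep <- setdiff(rownames(scaled), attr(scaled, "constant_rows"))
  corr <- pairwise_gene_correlation(scaled[keep, , drop = FALSE])
  modules <- hierarchical_modules(corr, n_modules = n_modules)
  anchor_mod <- anchor_module(modules, anchors)
  utils::write.table(
    data.frame(gene_id = names(modules$membership),
               module = as.integer(modules$membership),
               in_anchor_module = names(modules$membership) %in%
                 anchor_mod$members),
    pth("tissue_modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 3: single-cell summary + signature score ------------------
  summary_sc <- cluster_summary(sc$counts, sc$cells$cluster,
                                min_cells = min_cells)
  restricted <- restricted_genes(summary_sc)
  score <- score_cells(sc$counts, sc$cells$cluster,
                       gene_set = anchor_mod$members,
                       top_fraction = top_fraction,
                       gene_set_id = "anchor_module")
  utils::write.table(
    data.frame(cluster = names(score$cluster_mean),
               mean_auc = signif(as.numeric(score$cluster_mean), 6)),
    pth("celltype_score.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 4: response classification + enrichment -------------------
  classification <- classify_dataset(rs$values, rs$samples,
                                     pseudocount = pseudocount,
                                     resp_thresh = resp_thresh,
                                     diff_thresh = diff_thresh)
  expressed <- rownames(rs$values)[rowSums(rs$values) > 0]
  blunted <- classification$gene_id[classification$status == "blunted"]
  enrichment <- enrich_gene_sets(blunted, rs$gene_sets, expressed)
  utils::write.table(
    within(as.data.frame(classification),
           {log2fc_ctl <- signif(log2fc_ctl, 6)
            log2fc_ko <- signif(log2fc_ko, 6)
            delta <- signif(delta, 6)
            mean_fast_ctl <- signif(mean_fast_ctl, 6)
            mean_refed_ctl <- signif(mean_refed_ctl, 6)
            mean_fast_ko <- signif(mean_fast_ko, 6)
            mean_refed_ko <- signif(mean_refed_ko, 6)}),
    pth("response_classification.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(within(enrichment,
                            {p_value <- signif(p_value, 6)
                             p_adjusted <- signif(p_adjusted, 6)}),
                     pth("enrichment.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- join: candidate report ------------------------------------------
  genes <- screen$universe
  idx <- match(genes, classification$gene_id)
  r_by_gene <- {
    full <- as.data.frame(matrix(NA_real_, length(genes),
                                 length(screen$sets),
                                 dimnames = list(genes, screen$sets)))
    hit <- match(screen$candidates$gene_id, genes)
    full[hit, ] <- screen$candidates[, screen$sets]
    full
  }
  report <- data.frame(
    gene_id = genes,
    r_by_gene,
    min_r = NA_real_,
    screen_candidate = genes %in% screen$candidate_set,
    tissue_module = modules$membership[match(genes, names(modules$membership))],
    in_anchor_module = genes %in% anchor_mod$members,
    celltype_restricted = genes %in% restricted,
    hepatocyte_auc = signif(rep(score$cluster_mean[[1]], length(genes)), 6),
    response_status = as.character(classification$status[idx]),
    check.names = FALSE, stringsAsFactors = FALSE)
  report$min_r[match(screen$candidates$gene_id, genes)] <-
    screen$candidates$min_r
  report$final_hit <- report$screen_candidate & report$in_anchor_module &
    report$celltype_restricted
  report[screen$sets] <- lapply(report[screen$sets], signif, 6)
  report$min_r <- signif(report$min_r, 6)

  provenance <- list(package = "anchorscreen",
                     version = as.character(utils::packageVersion("anchorscreen")),
                     seed = config$seed,
                     config_hash = config_hash(unclass(config)),
                     parameters = list(threshold = threshold,
                                       transform = transform,
                                       n_modules = n_modules,
                                       top_fraction = top_fraction,
                                       min_cells = min_cells,
                                       pseudocount = pseudocount,
                                       resp_thresh = resp_thresh,
                                       diff_thresh = diff_thresh))
  write_report(report, pth("candidate_report.tsv"), provenance = provenance)

  invisible(list(report = report, screen = screen, modules = modules,
                 anchor_mod = anchor_mod, summary_sc = summary_sc,
                 score = score, classification = classification,
                 enrichment = enrichment, provenance = provenance,
                 truth = list(coexpression = co$truth, tissue = tp$truth,
                              single_cell = sc$truth, response = rs$truth)))
}

#' Write / read a candidate report (TSV + JSON provenance sidecar)
#'
#' @param report per-gene evidence data.frame.
#' @param path TSV path; the sidecar is written next to it with extension
#'   `.json`.
#' @param provenance named list recorded alongside the report.
#' @return `read_report` returns `list(report, provenance)`; the writer
#'   returns `path` invisibly.
#' @export
write_report <- function(report, path, provenance = list()) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(provenance, paste0(tools::file_path_sans_ext(path),
                                          ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  report <- utils::read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  provenance <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  list(report = report, provenance = provenance)
}
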