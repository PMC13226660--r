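#' Per-gene condition means of a response dataset
#'
#' Arithmetic mean over replicates in each genotype x condition cell. Every
#' cell must be present; cells with a single replicate are accepted with a
#' warning.
#'
#' @param values gene x sample numeric matrix.
#' @param samples data.frame with columns `sample`, `genotype`, `condition`
#'   (and optionally `replicate`) matching the columns of `values`.
#' @return A list with `means` (gene x cell matrix, columns
#'   `genotype.condition`) and `n_replicates` (named counts).
#' @export
condition_means <- function(values, samples) {
  check_matrix(values, "values")
  if (!all(c("sample", "genotype", "condition") %in% colnames(samples)))
    stop_input("'samples' needs columns sample, genotype, condition")
  if (!setequal(samples$sample, colnames(values)) ||
      nrow(samples) != ncol(values))
    stop_input("'samples' rows must match the columns of 'values' one-to-one")
  samples <- samples[match(colnames(values), samples$sample), ]
  cell <- paste(samples$genotype, samples$condition, sep = ".")
  expected <- as.vector(outer(unique(samples$genotype),
                              unique(samples$condition), paste, sep = "."))
  missing_cell <- setdiff(expected, unique(cell))
  if (length(missing_cell))
    stop_input(sprintf("no replicate for cell(s): %s",
                       paste(missing_cell, collapse = ", ")))
  n_rep <- table(cell)
  if (any(n_rep == 1L))
    warning(sprintf("single-replicate cell(s): %s",
                    paste(names(n_rep)[n_rep == 1L], collapse = ", ")))
  cells <- sort(unique(cell))
  means <- vapply(cells, function(cc)
    rowMeans(values[, cell == cc, drop = FALSE]), numeric(nrow(values)))
  dimnames(means) <- list(rownames(values), cells)
  list(means = means,
       n_replicates = stats::setNames(as.integer(n_rep[cells]), cells))
}

#' Log2 refeeding/fasting response per genotype
#'
#' `log2((mean_refed + c) / (mean_fast + c))` with a pseudocount `c` guarding
#' zero means (FPKM-like values can be exactly 0).
#'
#' @param means gene x cell matrix from [condition_means()] (columns
#'   `genotype.condition` with conditions `fasting` and `refeeding`).
#' @param pseudocount positive pseudocount, default 1.
#' @return Gene x genotype matrix of log2 fold changes.
#' @export
log2_response <- function(means, pseudocount = 1.0) {
  check_scalar_number(pseudocount, "pseudocount", lower = 0,
                      strict_lower = TRUE)
  cn <- strsplit(colnames(means), ".", fixed = TRUE)
  genotype <- vapply(cn, `[`, "", 1L)
  condition <- vapply(cn, `[`, "", 2L)
  if (!all(c("fasting", "refeeding") %in% condition))
    stop_input("means must cover conditions 'fasting' and 'refeeding'")
  genos <- unique(genotype)
  out <- vapply(genos, function(g) {
    refed <- means[, genotype == g & condition == "refeeding"]
    fast <- means[, genotype == g & condition == "fasting"]
    log2((refed + pseudocount) / (fast + pseudocount))
  }, numeric(nrow(means)))
  dimnames(out) <- list(rownames(means), genos)
  out
}

#' Classify the knockout response relative to control
#'
#' Implements the fold-change-of-fold-change geometry of a CTL-vs-KO response
#' scatter plot. A gene is responsive when its control response exceeds the
#' twofold gate (`|log2FC_CTL| > resp_thresh`, both thresholds in log2 units
#' and strict). For responsive genes, the KO response is projected onto the
#' control direction (`p = sign(log2FC_CTL) * log2FC_KO`) and compared with
#' the control magnitude: `delta = p - |log2FC_CTL|`. The gene is `blunted`
#' when `delta < -diff_thresh` (the KO response falls more than twofold short
#' of control, crossing the lower diagonal), `enhanced` when
#' `delta > diff_thresh`, and `concordant` otherwise. `reversed` flags blunted
#' genes whose KO response runs opposite to control (`p < 0`).
#'
#' @param log2fc_ctl,log2fc_ko numeric vectors of per-gene log2 responses
#'   (finite, equal length).
#' @param resp_thresh responsiveness gate in log2, default 1 (twofold).
#' @param diff_thresh genotype-difference gate in log2, default 1 (twofold).
#' @return data.frame with `status` (factor: not_responsive, concordant,
#'   blunted, enhanced), `delta`, `reversed`.
#' @examples
#' classify_response(c(2, 2, -2, 0.58), c(2, 0, -4, 0.58))$status
#' @export
classify_response <- function(log2fc_ctl, log2fc_ko, resp_thresh = 1.0,
                              diff_thresh = 1.0) {
  if (length(log2fc_ctl) != length(log2fc_ko))
    stop_input("log2FC vectors must have equal length")
  if (any(!is.finite(log2fc_ctl)) || any(!is.finite(log2fc_ko)))
    stop_input("log2 fold changes must be finite")
  check_scalar_number(resp_thresh, "resp_thresh", lower = 0, strict_lower = TRUE)
  check_scalar_number(diff_thresh, "diff_thresh", lower = 0, strict_lower = TRUE)
  responsive <- abs(log2fc_ctl) > resp_thresh
  direction <- sign(log2fc_ctl)
  p <- direction * log2fc_ko
  delta <- p - abs(log2fc_ctl)
  status <- rep("not_responsive", length(log2fc_ctl))
  status[responsive & abs(delta) <= diff_thresh] <- "concordant"
  status[responsive & delta < -diff_thresh] <- "blunted"
  status[responsive & delta > diff_thresh] <- "enhanced"
  delta[!responsive] <- NA_real_
  data.frame(
    status = factor(status, levels = c("not_responsive", "concordant",
                                       "blunted", "enhanced")),
    delta = delta,
    reversed = responsive & p < 0,
    stringsAsFactors = FALSE)
}

#' Classify every gene of a response dataset
#'
#' Convenience wrapper chaining [condition_means()], [log2_response()] and
#' [classify_response()] into a per-gene classification table.
#'
#' @inheritParams condition_means
#' @inheritParams log2_response
#' @inheritParams classify_response
#' @param control,knockout genotype labels of `samples` playing the control
#'   and knockout roles (defaults `"CTL"`, `"KO"`).
#' @return Object of class `response_classification`: data.frame with the four
#'   cell means, `log2fc_ctl`, `log2fc_ko`, `delta`, `status`, `reversed`;
#'   thresholds and pseudocount in attributes.
#' @examples
#' sim <- sim_response(sim_config(seed = 11, n_genes = 300, n_responsive = 30))
#' cls <- classify_dataset(sim$values, sim$samples)
#' summary(cls)
#' @export
classify_dataset <- function(values, samples, pseudocount = 1.0,
                             resp_thresh = 1.0, diff_thresh = 1.0,
                             control = "CTL", knockout = "KO") {
  cm <- condition_means(values, samples)
  fc <- log2_response(cm$means, pseudocount)
  if (!all(c(control, knockout) %in% colnames(fc)))
    stop_input(sprintf("genotypes '%s' and '%s' not found in the dataset",
                       control, knockout))
  cls <- classify_response(fc[, control], fc[, knockout],
                           resp_thresh, diff_thresh)
  out <- data.frame(
    gene_id = rownames(values),
    mean_fast_ctl = cm$means[, paste(control, "fasting", sep = ".")],
    mean_refed_ctl = cm$means[, paste(control, "refeeding", sep = ".")],
    mean_fast_ko = cm$means[, paste(knockout, "fasting", sep = ".")],
    mean_refed_ko = cm$means[, paste(knockout, "refeeding", sep = ".")],
    log2fc_ctl = fc[, control], log2fc_ko = fc[, knockout],
    delta = cls$delta, status = cls$status, reversed = cls$reversed,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(resp_thresh = resp_thresh,
                               diff_thresh = diff_thresh,
                               pseudocount = pseudocount)
  class(out) <- c("response_classification", "data.frame")
  out
}

#' Summarize a response classification
#'
#' Counts per status, the number of genotype-altered genes
#' (blunted + enhanced) and the blunted fraction among them (reported as `NA`
#' when no gene is altered).
#'
#' @param classification a [classify_dataset()] table (or any data.frame with
#'   a `status` column using the same levels).
#' @return A list: `counts` (named integer), `n_altered`, `blunted_fraction`.
#' @export
summarize_classes <- function(classification) {
  if (!("status" %in% colnames(classification)) ||
      nrow(classification) == 0L)
    stop_input("'classification' must be a non-empty table with a status column")
  counts <- table(factor(classification$status,
                         levels = c("not_responsive", "concordant",
                                    "blunted", "enhanced")))
  altered <- counts[["blunted"]] + counts[["enhanced"]]
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       n_altered = as.integer(altered),
       blunted_fraction = if (altered > 0) counts[["blunted"]] / altered
                          else NA_real_)
}

#' @export
summary.response_classification <- function(object, ...) {
  s <- summarize_classes(object)
  cat("Fasting/refeeding response classification\n")
  for (nm in names(s$counts)) cat(sprintf("  %s: %d\n", nm, s$counts[[nm]]))
  cat(sprintf("  altered: %d | blunted fraction: %s\n", s$n_altered,
              ifelse(is.na(s$blunted_fraction), "NA",
                     sprintf("%.3f", s$blunted_fraction))))
  invisible(s)
}

#' Hypergeometric over-representation of one gene set
#'
#' Exact upper-tail probability that a selected gene list contains at least
#' the observed number of gene-set members when drawn without replacement
#' from the universe: `p = P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`, `N` the universe size, `K` the set size in
#' the universe, `n` the selection size, `k` the overlap.
#'
#' @param selected character vector of selected gene ids (must lie in
#'   `universe`).
#' @param gene_set character vector of set member ids (intersected with the
#'   universe).
#' @param universe character vector of all eligible gene ids (non-empty).
#' @return One-row data.frame: `k`, `n`, `K`, `N`, `p_value`.
#' @examples
#' hypergeometric_enrichment(paste0("g", 1:4), paste0("g", 1:5),
#'                           paste0("g", 1:10))$p_value # 5/210
#' @export
hypergeometric_enrichment <- function(selected, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_input("the universe is empty")
  selected <- unique(selected)
  if (length(setdiff(selected, universe)))
    stop_input("'selected' must be a subset of 'universe'")
  K <- length(intersect(unique(gene_set), universe))
  n <- length(selected)
  k <- length(intersect(selected, gene_set))
  N <- length(universe)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(k = k, n = n, K = K, N = N, p_value = min(1, p))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment; input order is preserved and every
#' adjusted value is at least the raw one.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop_input("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation of multiple gene sets with FDR control
#'
#' @param selected,universe see [hypergeometric_enrichment()].
#' @param gene_sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @return data.frame with one row per set (`set_id`, `k`, `n`, `K`, `N`,
#'   `p_value`, `p_adjusted`), ordered by adjusted then raw p-value.
#' @export
enrich_gene_sets <- function(selected, gene_sets, universe) {
  if (length(gene_sets) == 0L) stop_input("no gene sets supplied")
  rows <- lapply(names(gene_sets), function(nm) {
    cbind(set_id = nm,
          hypergeometric_enrichment(selected, gene_sets[[nm]], universe))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out <- out[order(out$p_adjusted, out$p_value, out$set_id), ]
  rownames(out) <- NULL
  out
}
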