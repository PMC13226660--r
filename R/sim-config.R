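#' Configuration for the synthetic-data generators
#'
#' Collects every knob shared by the four generators ([sim_coexpression()],
#' [sim_tissue_profiles()], [sim_single_cell()], [sim_response()]) into a
#' single validated object. The defaults describe the study conditions the
#' generators emulate: two GTEx-like bulk tissues with a planted anchor
#' co-expression module, an HPA-like gene-by-tissue consensus profile, a
#' labelled liver single-cell count matrix with one undersized cluster, and a
#' two-genotype fasting/refeeding experiment in which most genotype-altered
#' genes have a blunted refeeding response.
#'
#' @param seed integer RNG seed; a fixed config yields bit-identical outputs.
#' @param n_genes number of genes in the bulk, single-cell and response
#'   universes.
#' @param n_samples_per_tissue bulk samples per tissue.
#' @param n_tissues tissues in the consensus profile (>= 3).
#' @param n_cells_per_cluster integer vector of cells per single-cell cluster;
#'   exactly one entry must be below 10 so the small-cluster exclusion filter
#'   is exercised.
#' @param module_size genes per planted module (>= 3; the first two members of
#'   the both-tissue module are the anchors).
#' @param module_loading loading of module genes on the shared latent factor,
#'   in (0, 1]. The planted within-module Pearson correlation is
#'   `module_loading^2 / (module_loading^2 + noise_sd^2)`.
#' @param noise_sd standard deviation of the gene-level residual in the
#'   one-factor model (> 0). The default 0.4 puts the planted correlation at
#'   0.835 for the default loading 0.9, comfortably above the screen cutoff.
#' @param n_responsive number of fasting/refeeding responsive genes.
#' @param blunted_fraction,enhanced_fraction fractions of the responsive genes
#'   whose knockout response is planted as blunted resp. enhanced; their sum
#'   must not exceed 1 (the remainder respond concordantly in both genotypes).
#' @param nb_dispersion negative-binomial size parameter shared by all
#'   single-cell genes (variance = mu + mu^2 / size).
#' @param base_expression_scale median baseline expression of the bulk
#'   matrices (TPM-like units).
#' @param n_replicates replicates per genotype x condition cell (>= 2).
#' @param replicate_cv lognormal sdlog of replicate-level noise in the
#'   response dataset.
#' @param tissue_noise relative noise of the tissue consensus profile; 0 gives
#'   the exact noise-free patterns.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 200, module_size = 10)
#' cfg$module_loading^2 / (cfg$module_loading^2 + cfg$noise_sd^2)
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_samples_per_tissue = 60L,
                       n_tissues = 30L,
                       n_cells_per_cluster = c(300L, 150L, 100L, 60L, 9L),
                       module_size = 40L,
                       module_loading = 0.9,
                       noise_sd = 0.4,
                       n_responsive = 200L,
                       blunted_fraction = 0.85,
                       enhanced_fraction = 0.15,
                       nb_dispersion = 2,
                       base_expression_scale = 100,
                       n_replicates = 4L,
                       replicate_cv = 0.2,
                       tissue_noise = 0.1) {
  check_scalar_number(seed, "seed", lower = 0, upper = .Machine$integer.max)
  check_scalar_number(n_genes, "n_genes", lower = 1)
  check_scalar_number(n_samples_per_tissue, "n_samples_per_tissue", lower = 3)
  check_scalar_number(n_tissues, "n_tissues", lower = 1)
  check_scalar_number(module_size, "module_size", lower = 3)
  check_scalar_number(module_loading, "module_loading",
                      lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  check_scalar_number(n_responsive, "n_responsive", lower = 0)
  check_scalar_number(blunted_fraction, "blunted_fraction", lower = 0, upper = 1)
  check_scalar_number(enhanced_fraction, "enhanced_fraction", lower = 0, upper = 1)
  if (blunted_fraction + enhanced_fraction > 1 + 1e-12)
    stop_input("blunted_fraction + enhanced_fraction must not exceed 1")
  check_scalar_number(nb_dispersion, "nb_dispersion", lower = 0, strict_lower = TRUE)
  check_scalar_number(base_expression_scale, "base_expression_scale",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(n_replicates, "n_replicates", lower = 2)
  check_scalar_number(replicate_cv, "replicate_cv", lower = 0)
  check_scalar_number(tissue_noise, "tissue_noise", lower = 0)
  if (module_size > n_genes)
    stop_input("module_size must not exceed n_genes")
  if (n_responsive > n_genes)
    stop_input("n_responsive must not exceed n_genes")
  if (length(n_cells_per_cluster) < 1L || any(n_cells_per_cluster < 1))
    stop_input("n_cells_per_cluster must be a non-empty vector of counts >= 1")

  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_samples_per_tissue = as.integer(n_samples_per_tissue),
    n_tissues = as.integer(n_tissues),
    n_cells_per_cluster = as.integer(n_cells_per_cluster),
    module_size = as.integer(module_size),
    module_loading = module_loading,
    noise_sd = noise_sd,
    n_responsive = as.integer(n_responsive),
    blunted_fraction = blunted_fraction,
    enhanced_fraction = enhanced_fraction,
    nb_dispersion = nb_dispersion,
    base_expression_scale = base_expression_scale,
    n_replicates = as.integer(n_replicates),
    replicate_cv = replicate_cv,
    tissue_noise = tissue_noise
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-data configuration (sim_config)\n")
  cat(sprintf("  seed: %d | genes: %d | samples/tissue: %d | tissues: %d\n",
              x$seed, x$n_genes, x$n_samples_per_tissue, x$n_tissues))
  cat(sprintf("  module: %d genes, loading %.2f, noise sd %.2f (planted r = %.3f)\n",
              x$module_size, x$module_loading, x$noise_sd,
              x$module_loading^2 / (x$module_loading^2 + x$noise_sd^2)))
  cat(sprintf("  cells/cluster: %s | NB dispersion: %.2f\n",
              paste(x$n_cells_per_cluster, collapse = ", "), x$nb_dispersion))
  cat(sprintf("  responsive: %d (blunted %.2f, enhanced %.2f) | replicates: %d\n",
              x$n_responsive, x$blunted_fraction, x$enhanced_fraction,
              x$n_replicates))
  invisible(x)
}

gene_ids <- function(n) sprintf("gene%05d", seq_len(n))

# Assemble a planted-truth table: one row per gene, one class per gene.
make_truth <- function(gene_id, planted_class, anchors, config,
                       module_id = NULL) {
  stopifnot(length(gene_id) == length(planted_class))
  truth <- data.frame(gene_id = gene_id, planted_class = planted_class,
                      stringsAsFactors = FALSE)
  if (!is.null(module_id)) truth$module_id <- module_id
  attr(truth, "anchor_ids") <- anchors
  attr(truth, "config") <- config
  class(truth) <- c("synthetic_truth", "data.frame")
  truth
}
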