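#' Simulate two bulk expression matrices with a planted anchor module
#'
#' One-factor Gaussian latent model per tissue. Each tissue draws one latent
#' factor per sample; a gene in a planted module has (on the latent scale)
#' `module_loading * factor + noise_sd * residual`, so the within-module
#' Pearson correlation is `loading^2 / (loading^2 + noise_sd^2)` in
#' expectation. The latent signal is mapped to TPM-like units per gene as
#' `baseline * (1 + 0.2 * latent)` with a lognormal baseline; correlation is
#' invariant to this per-gene affine map, so the closed form holds exactly on
#' the raw scale and, because the fluctuations are small relative to the
#' baseline, is nearly unchanged under `log2(x + 1)`. Values are clipped at 0.
#'
#' Planted structure: genes 1..`module_size` form the both-tissue module (its
#' first two members are the anchor genes, co-expressed in both tissues, the
#' APOB/MTTP analogues); the next `module_size` genes load on the factor in
#' tissue A only; all remaining genes are independent background.
#'
#' @param config a [sim_config()].
#' @return A list with elements `tissue_a` and `tissue_b` (gene x sample
#'   matrices with a `tissue` attribute, labelled "liver" and "intestine"),
#'   and `truth`, the planted-class table with the anchor ids in
#'   `attr(, "anchor_ids")`.
#' @examples
#' sim <- sim_coexpression(sim_config(seed = 1, n_genes = 100,
#'                                    n_samples_per_tissue = 20,
#'                                    module_size = 10))
#' table(sim$truth$planted_class)
#' @export
sim_coexpression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  m <- config$module_size
  if (2L * m > n)
    stop_input("n_genes must accommodate two disjoint modules (n_genes >= 2 * module_size)")
  ids <- gene_ids(n)
  anchors <- ids[1:2]
  cls <- rep("background", n)
  cls[seq_len(m)] <- "both_tissue_module"
  cls[m + seq_len(m)] <- "single_tissue_module"

  with_seed(offset_seed(config$seed, 0L), {
    baseline <- config$base_expression_scale * stats::rlnorm(n, 0, 1)
    total_sd <- sqrt(config$module_loading^2 + config$noise_sd^2)
    make_tissue <- function(loads_factor, tissue) {
      ns <- config$n_samples_per_tissue
      f <- stats::rnorm(ns)
      latent <- matrix(stats::rnorm(n * ns, sd = config$noise_sd), n, ns)
      latent[loads_factor, ] <- config$module_loading *
        matrix(f, sum(loads_factor), ns, byrow = TRUE) + latent[loads_factor, ]
      # background rows get matched marginal variance so the screen cannot
      # separate classes on spread alone
      latent[!loads_factor, ] <- latent[!loads_factor, ] *
        (total_sd / config$noise_sd)
      x <- baseline * (1 + 0.2 * latent)
      x[x < 0] <- 0
      dimnames(x) <- list(ids, sprintf("%s_s%03d", tissue, seq_len(ns)))
      attr(x, "tissue") <- tissue
      x
    }
    tissue_a <- make_tissue(cls %in% c("both_tissue_module", "single_tissue_module"),
                            "liver")
    tissue_b <- make_tissue(cls == "both_tissue_module", "intestine")
    list(tissue_a = tissue_a, tissue_b = tissue_b,
         truth = make_truth(ids, cls, anchors, config))
  })
}
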