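#' Simulate a two-genotype fasting/refeeding expression table
#'
#' Emulates an FPKM-like RNA-seq experiment with genotypes CTL and KO, each
#' measured fasting and refeeding with `n_replicates` replicates. The first
#' `n_responsive` genes are responsive in the control genotype: their planted
#' control response `|log2(refed / fasted)|` is drawn uniformly from
#' \[1.5, 3\] with random sign, keeping a margin above the twofold gate.
#' Among the responsive genes, `blunted_fraction` are planted as blunted and
#' `enhanced_fraction` as enhanced: the KO response along the control
#' direction is shifted by d ~ U\[1.2, 3\] below resp. above the control
#' magnitude, so the planted genotype difference always exceeds the twofold
#' (log2 = 1) rule with margin; the rest of the responsive genes respond
#' identically in both genotypes (concordant). All other genes are null.
#' Replicate values are `mean * exp(rnorm(sd = replicate_cv))`.
#'
#' Emitted gene sets (GMT-ready): `lipid_biosynthesis`, composed of 80%
#' planted-blunted genes and 20% null genes (the set that should come out
#' over-represented among blunted genes), plus four decoy sets drawn
#' uniformly from null genes.
#'
#' @param config a [sim_config()].
#' @param set_size number of genes per emitted gene set.
#' @return A list with `values` (gene x sample matrix, columns named
#'   `genotype_condition_rep`), `samples` (data.frame of sample, genotype,
#'   condition, replicate), `gene_sets` (named list of gene-id vectors) and
#'   `truth` (classes `responsive_concordant`, `responsive_blunted`,
#'   `responsive_enhanced`, `null`; planted log2 responses in
#'   `attr(, "planted_log2fc")`).
#' @examples
#' sim <- sim_response(sim_config(seed = 11, n_genes = 500, n_responsive = 40))
#' table(sim$truth$planted_class)
#' @export
sim_response <- function(config, set_size = 50L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  nr <- config$n_responsive
  n_blunt <- as.integer(round(config$blunted_fraction * nr))
  n_enh <- as.integer(round(config$enhanced_fraction * nr))
  if (n_blunt + n_enh > nr)
    stop_input("blunted_fraction + enhanced_fraction exceed the responsive set")
  ids <- gene_ids(n)
  cls <- rep("null", n)
  cls[seq_len(nr)] <- "responsive_concordant"
  cls[seq_len(n_blunt)] <- "responsive_blunted"
  if (n_enh > 0) cls[n_blunt + seq_len(n_enh)] <- "responsive_enhanced"

  with_seed(offset_seed(config$seed, 3L), {
    baseline <- config$base_expression_scale * stats::rlnorm(n, -1, 1)
    ctl_fc <- rep(0, n)
    resp <- seq_len(nr)
    ctl_fc[resp] <- sample(c(-1, 1), nr, replace = TRUE) *
      stats::runif(nr, 1.5, 3)
    ko_fc <- ctl_fc
    shift <- function(rows, dir) {
      d <- stats::runif(length(rows), 1.2, 3)
      ko_fc[rows] <<- sign(ctl_fc[rows]) * (abs(ctl_fc[rows]) + dir * d)
    }
    if (n_blunt > 0) shift(which(cls == "responsive_blunted"), -1)
    if (n_enh > 0) shift(which(cls == "responsive_enhanced"), +1)

    reps <- config$n_replicates
    grid <- expand.grid(replicate = seq_len(reps),
                        condition = c("fasting", "refeeding"),
                        genotype = c("CTL", "KO"),
                        stringsAsFactors = FALSE)[, 3:1]
    sample_id <- sprintf("%s_%s_%d", grid$genotype, grid$condition,
                         grid$replicate)
    mean_for <- function(genotype, condition) {
      fc <- if (genotype == "CTL") ctl_fc else ko_fc
      if (condition == "fasting") baseline else baseline * 2^fc
    }
    values <- vapply(seq_len(nrow(grid)), function(j) {
      mu <- mean_for(grid$genotype[j], grid$condition[j])
      mu * exp(stats::rnorm(n, sd = config$replicate_cv))
    }, numeric(n))
    dimnames(values) <- list(ids, sample_id)

    null_ids <- ids[cls == "null"]
    blunted_ids <- ids[cls == "responsive_blunted"]
    n_from_blunt <- min(length(blunted_ids), as.integer(round(0.8 * set_size)))
    enriched <- c(sample(blunted_ids, n_from_blunt),
                  sample(null_ids, set_size - n_from_blunt))
    decoys <- lapply(1:4, function(i) sample(null_ids, min(set_size, length(null_ids))))
    names(decoys) <- sprintf("decoy_pathway_%d", 1:4)
    gene_sets <- c(list(lipid_biosynthesis = enriched), decoys)

    truth <- make_truth(ids, cls, character(0), config)
    attr(truth, "planted_log2fc") <- data.frame(
      gene_id = ids, log2fc_ctl = ctl_fc, log2fc_ko = ko_fc,
      stringsAsFactors = FALSE)
    list(values = values,
         samples = data.frame(sample = sample_id, genotype = grid$genotype,
                              condition = grid$condition,
                              replicate = grid$replicate,
                              stringsAsFactors = FALSE),
         gene_sets = gene_sets, truth = truth)
  })
}
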