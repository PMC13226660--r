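# Independent oracles used across the suite. Each is a naive, direct
# transcription of the defining formula, kept free of any package internals.

# Two-pass sample Pearson coefficient.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Recovery-curve AUC by direct enumeration of the staircase: walk ranks
# 1..T, count set members recovered at each step, normalize by the maximal
# staircase.
auc_oracle <- function(ranking, gene_set, top_fraction) {
  G <- length(ranking)
  T_top <- ceiling(top_fraction * G)
  set_ranks <- ranking[names(ranking) %in% gene_set]
  S <- length(set_ranks)
  if (S == 0L) return(0)
  raw <- 0
  max_raw <- 0
  for (x in seq_len(T_top)) {
    raw <- raw + sum(set_ranks <= x)
    max_raw <- max_raw + min(x, S)
  }
  raw / max_raw
}

# Hypergeometric upper tail by exhaustive enumeration of all n-subsets of an
# N-element universe with K marked elements (feasible for N <= 12).
hyper_oracle <- function(N, K, n, k) {
  universe <- seq_len(N)
  marked <- seq_len(K)
  subsets <- utils::combn(universe, n)
  hits <- apply(subsets, 2L, function(s) sum(s %in% marked))
  mean(hits >= k)
}

# Benjamini-Hochberg step-up by hand.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(seq_len(m) >= i)
    q[i] <- min(pmin(p[o][js] * m / js, 1))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

f1_score <- function(called, truth) {
  tp <- length(intersect(called, truth))
  if (tp == 0) return(0)
  prec <- tp / length(called)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}

# Best-match Jaccard of each planted block against the recovered partition.
block_jaccards <- function(membership, blocks) {
  vapply(blocks, function(b) {
    max(vapply(unique(membership), function(k)
      jaccard(names(membership)[membership == k], b), numeric(1)))
  }, numeric(1))
}

small_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_genes = 200, n_samples_per_tissue = 30,
                   module_size = 10, n_tissues = 12,
                   n_cells_per_cluster = c(60, 40, 25, 8),
                   n_responsive = 40)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
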