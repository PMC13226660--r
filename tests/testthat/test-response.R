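make_response_fixture <- function(genes = 6, reps = 3, seed = 5) {
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(reps),
                      condition = c("fasting", "refeeding"),
                      genotype = c("CTL", "KO"), stringsAsFactors = FALSE)
  samples <- data.frame(sample = sprintf("%s_%s_%d", grid$genotype,
                                         grid$condition, grid$replicate),
                        genotype = grid$genotype, condition = grid$condition,
                        replicate = grid$replicate, stringsAsFactors = FALSE)
  values <- matrix(rlnorm(genes * nrow(grid), 3, 0.4), genes, nrow(grid),
                   dimnames = list(sprintf("g%02d", seq_len(genes)),
                                   samples$sample))
  list(values = values, samples = samples)
}

test_that("condition means equal a brute-force group-by mean", {
  fx <- make_response_fixture()
  cm <- condition_means(fx$values, fx$samples)
  for (g in rownames(fx$values)) {
    for (geno in c("CTL", "KO")) for (cond in c("fasting", "refeeding")) {
      cols <- fx$samples$sample[fx$samples$genotype == geno &
                                  fx$samples$condition == cond]
      expect_equal(cm$means[g, paste(geno, cond, sep = ".")],
                   mean(fx$values[g, cols]))
    }
  }
  expect_equal(unname(cm$n_replicates), rep(3L, 4))
})

test_that("missing cells error and single replicates warn", {
  fx <- make_response_fixture()
  drop <- fx$samples$sample[fx$samples$genotype == "KO" &
                              fx$samples$condition == "refeeding"]
  expect_error(condition_means(fx$values[, setdiff(colnames(fx$values), drop)],
                               fx$samples[!fx$samples$sample %in% drop, ]),
               "KO.refeeding")
  keep <- drop[1]
  single <- setdiff(colnames(fx$values), drop[-1])
  expect_warning(condition_means(fx$values[, single],
                                 fx$samples[fx$samples$sample %in% single, ]),
                 "single-replicate")
})

test_that("log2 response follows the pseudocounted formula", {
  means <- cbind("CTL.fasting" = c(g1 = 5, g2 = 0),
                 "CTL.refeeding" = c(5, 3),
                 "KO.fasting" = c(2, 1), "KO.refeeding" = c(2, 1))
  fc <- log2_response(means, pseudocount = 1)
  expect_equal(unname(fc["g1", ]), c(0, 0))
  expect_equal(fc[["g2", "CTL"]], 2.0) # log2((3+1)/(0+1))
  set.seed(9)
  m2 <- matrix(rlnorm(40, 2, 1), 10, 4,
               dimnames = list(sprintf("g%02d", 1:10), colnames(means)))
  fc2 <- log2_response(m2, pseudocount = 0.5)
  expect_equal(fc2[, "KO"],
               log2((m2[, "KO.refeeding"] + 0.5) / (m2[, "KO.fasting"] + 0.5)),
               tolerance = 1e-12)
  expect_error(log2_response(means, pseudocount = 0), "pseudocount")
})

test_that("the response geometry classifies the worked cases", {
  cls <- classify_response(c(2, 2, -2, 0.58), c(2, 0, -4, 0.58))
  expect_equal(as.character(cls$status),
               c("concordant", "blunted", "enhanced", "not_responsive"))
  expect_equal(cls$delta[2], -2)
  expect_equal(cls$delta[3], 2)
  expect_false(any(cls$reversed))
  # reversed KO response co-occurs with blunted
  rev <- classify_response(2, -0.5)
  expect_equal(as.character(rev$status), "blunted")
  expect_true(rev$reversed)
  expect_error(classify_response(Inf, 1), "finite")
  expect_error(classify_response(1, 2, resp_thresh = 0), "resp_thresh")
})

test_that("classification is symmetric under joint negation and partitions genes", {
  set.seed(13)
  ctl <- rnorm(300, 0, 2)
  ko <- rnorm(300, 0, 2)
  a <- classify_response(ctl, ko)
  b <- classify_response(-ctl, -ko)
  expect_identical(a$status, b$status)
  expect_equal(a$delta, b$delta)
  expect_equal(sum(table(a$status)), 300)
  # shrinking |KO| toward zero never moves blunted toward enhanced
  shrunk <- classify_response(ctl, ko * 0.5)
  worse <- a$status == "blunted" & shrunk$status == "enhanced"
  expect_false(any(worse))
  expect_true(all(shrunk$delta[abs(ctl) > 1] <= a$delta[abs(ctl) > 1] |
                    sign(ctl[abs(ctl) > 1]) * ko[abs(ctl) > 1] < 0))
})

test_that("summarize_classes reports counts, altered and the blunted fraction", {
  df <- data.frame(status = factor(
    c(rep("blunted", 17), rep("enhanced", 3), rep("concordant", 5),
      rep("not_responsive", 10)),
    levels = c("not_responsive", "concordant", "blunted", "enhanced")))
  s <- summarize_classes(df)
  expect_equal(s$n_altered, 20L)
  expect_equal(s$blunted_fraction, 0.85)
  all_conc <- data.frame(status = factor(rep("concordant", 4),
                                         levels = levels(df$status)))
  s2 <- summarize_classes(all_conc)
  expect_equal(s2$n_altered, 0L)
  expect_true(is.na(s2$blunted_fraction))
})

test_that("hypergeometric p equals exhaustive enumeration for small universes", {
  expect_equal(hypergeometric_enrichment(paste0("g", 1:4), paste0("g", 1:5),
                                         paste0("g", 1:10))$p_value,
               5 / 210, tolerance = 1e-12)
  # selected = universe -> certain event
  u <- paste0("g", 1:8)
  expect_equal(hypergeometric_enrichment(u, u[1:3], u)$p_value, 1.0)
  # zero overlap -> P(X >= 0) = 1
  expect_equal(hypergeometric_enrichment(u[4:6], u[1:3], u)$p_value,
               hyper_oracle(8, 3, 3, 0), tolerance = 1e-12)
  set.seed(17)
  for (i in 1:25) {
    N <- sample(4:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    universe <- sprintf("u%02d", 1:N)
    gene_set <- universe[seq_len(K)]
    selected <- sample(universe, n)
    res <- hypergeometric_enrichment(selected, gene_set, universe)
    expect_equal(res$p_value, hyper_oracle(N, K, n, res$k), tolerance = 1e-12)
    expect_lte(res$k, min(res$n, res$K))
  }
  expect_error(hypergeometric_enrichment("g1", "g1", character(0)), "empty")
  expect_error(hypergeometric_enrichment("zz", "g1", u), "subset")
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(23)
  for (i in 1:20) {
    p <- runif(sample(1:15, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("enrichment over gene sets orders by adjusted significance", {
  universe <- sprintf("g%03d", 1:100)
  selected <- universe[1:20]
  sets <- list(hit = universe[1:15], miss = universe[60:80],
               part = universe[c(1:5, 50:59)])
  res <- enrich_gene_sets(selected, sets, universe)
  expect_equal(res$set_id[1], "hit")
  expect_true(all(diff(res$p_adjusted) >= 0))
  expect_true(all(res$p_adjusted >= res$p_value))
})
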