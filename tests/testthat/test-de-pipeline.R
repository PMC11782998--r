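test_that("top-N roll-up sums the same top peptides in every sample", {
  mat <- rbind(
    pA_1 = c(12, 8),  pA_2 = c(9, 7), pA_3 = c(5, 7), pA_4 = c(4, 4),
    pB_1 = c(3, 1))
  map <- c(pA_1 = "A", pA_2 = "A", pA_3 = "A", pA_4 = "A", pB_1 = "B")
  colnames(mat) <- c("s1", "s2")
  q <- topn_protein_quant(mat, map, n = 3)
  # peptide means are (10, 8, 6, 4): top-3 are pA_1..pA_3 in both samples
  expect_equal(q["A", ], c(s1 = 12 + 9 + 5, s2 = 8 + 7 + 7))
  expect_equal(q["B", ], c(s1 = 3, s2 = 1))           # single peptide
  q4 <- topn_protein_quant(mat, map, n = 4)           # n = all peptides
  expect_equal(q4["A", ], colSums(mat[1:4, ]))
  expect_error(topn_protein_quant(mat, character()), "empty")
  expect_error(topn_protein_quant(unname(mat), map), "named")
})

test_that("filtering removes uninformative rows and keeps one-condition signal", {
  cond <- rep(c("KO", "WT"), each = 3)
  mat <- rbind(
    allzero  = rep(0, 6),
    constant = rep(5, 6),
    ko_only  = c(0, 0, 0, 8, 9, 10),   # zero in KO, present in WT
    normal   = c(1, 2, 3, 4, 5, 6))
  out <- filter_uninformative(mat, cond)
  expect_setequal(rownames(out), c("ko_only", "normal"))
  expect_equal(attr(out, "removed_condition_mean"), 1)
  expect_equal(attr(out, "removed_nzv"), 1)
  expect_error(filter_uninformative(mat[1, , drop = FALSE], cond), "removed")
  expect_error(filter_uninformative(mat, c("KO", rep("WT", 5))), "2 samples")
})

test_that("near-zero-variance rule agrees with the caret implementation", {
  set.seed(4)
  mat <- matrix(rlnorm(50 * 20), 50, 20)
  # plant near-constant rows
  mat[1, ] <- c(rep(7, 19), 8)
  mat[2, ] <- c(rep(7, 18), 8, 9)
  rownames(mat) <- paste0("p", 1:50)
  out <- filter_uninformative(mat, rep(c("KO", "WT"), each = 10))
  caret_flag <- caret::nearZeroVar(t(mat), freqCut = 95 / 5, uniqueCut = 10)
  kept_caret <- setdiff(rownames(mat), rownames(mat)[caret_flag])
  expect_setequal(rownames(out), kept_caret)
})

test_that("midpoint imputation halves the row minimum into zeros", {
  mat <- rbind(a = c(0, 4, 8), b = c(1, 2, 3), c = c(0, 0, 6))
  out <- impute_zeros_midpoint(mat)
  expect_equal(unname(out["a", ]), c(2, 4, 8))
  expect_equal(unname(out["b", ]), c(1, 2, 3))   # untouched
  expect_equal(unname(out["c", ]), c(3, 3, 6))
  expect_error(impute_zeros_midpoint(rbind(c(0, 0))), "filter")
})

test_that("TMM factors: identity, known scaling, and scale invariance", {
  set.seed(2)
  base <- rlnorm(300, 10, 1)
  mat <- cbind(s1 = base, s2 = base, s3 = base)
  f <- tmm_factors(mat)
  expect_equal(f$factor, rep(1, 3), tolerance = 1e-9)

  mat2 <- cbind(s1 = base, s2 = 2 * base)
  f2 <- tmm_factors(mat2)
  expect_equal(f2$effective_size[2] / f2$effective_size[1], 2,
               tolerance = 1e-6)

  f3 <- tmm_factors(mat2 * 17)
  expect_equal(f3$factor, f2$factor, tolerance = 1e-9)
  expect_error(tmm_factors(cbind(c(0, 1), c(1, 1))), "positive")
})

test_that("TMM factors agree with the edgeR reference implementation", {
  set.seed(8)
  counts <- matrix(rpois(200 * 6, lambda = rlnorm(200, 5, 1)), 200, 6) + 1
  ours <- tmm_factors(counts)
  theirs <- edgeR::calcNormFactors(counts, method = "TMM",
                                   logratioTrim = 0.3, sumTrim = 0.05)
  expect_equal(ours$factor, theirs, tolerance = 0.02)
})

test_that("TMM normalisation equalises a pure scaling difference", {
  set.seed(3)
  base <- rlnorm(500, 10, 1)
  mat <- cbind(s1 = base, s2 = 2 * base, s3 = 0.5 * base)
  norm <- normalize_tmm(mat)
  expect_equal(norm[, "s1"] / norm[, "s2"], rep(1, 500), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("batch removal: no-op on batch-free data, rejects bad designs", {
  cond <- rep(c("KO", "WT"), each = 4)
  batch <- rep(1:2, 4)
  means <- rlnorm(50, 10, 1)
  mat <- outer(means, ifelse(cond == "KO", 2, 1))  # pure condition effect
  colnames(mat) <- paste0("s", 1:8)
  out <- remove_batch_arsyn(mat, batch, cond)
  expect_equal(unname(out), unname(mat), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(attr(out, "components_removed"), 0L)
  expect_error(remove_batch_arsyn(mat, rep(1, 8), cond), "2 batch")
  expect_error(remove_batch_arsyn(mat, as.integer(cond == "KO"), cond),
               "confounded")
})

test_that("batch removal strips a planted block offset, sparing the contrast", {
  sim <- simulate_abundance_matrix(n_proteins = 800, de_fraction = 0.1,
                                   noise_sd = 0.3, zero_threshold = 0,
                                   n_batches = 3, batch_offsets = c(0, 1, 0),
                                   seed = 13)
  md <- sim$metadata
  blocks <- mrmlfq:::run_order_blocks(md$run_order, 3)
  corrected <- remove_batch_arsyn(sim$matrix, blocks, md$genotype)
  # block offset before vs after
  col_means <- function(m) tapply(colMeans(log2(m)), blocks, mean)
  before <- col_means(sim$matrix); after <- col_means(corrected)
  expect_gt(max(before) - min(before), 0.9)
  expect_lt(max(after) - min(after), 0.05)       # >= 95% of delta removed
  # the planted genotype effect survives correction within 5%
  ko <- md$genotype == "KO"
  lfc <- rowMeans(log2(corrected[, ko])) - rowMeans(log2(corrected[, !ko]))
  up <- sim$truth$is_de & sim$truth$true_logfc > 0
  dn <- sim$truth$is_de & sim$truth$true_logfc < 0
  expect_lt(abs(median(lfc[up]) - 1.5) / 1.5, 0.05)
  expect_lt(abs(median(lfc[dn]) + 1.5) / 1.5, 0.05)
})

test_that("precision weights are positive, flat when variance is flat", {
  set.seed(42)
  n <- 1000; ns <- 12
  mu <- runif(n, 18, 22)   # even coverage keeps the lowess trend stable
  mat <- 2^(matrix(mu, n, ns) + matrix(rnorm(n * ns, 0, 0.3), n, ns))
  design <- cbind(Intercept = 1, group = rep(0:1, each = ns / 2))
  v <- voom_weights(mat, design)
  expect_true(all(is.finite(v$weights)) && all(v$weights > 0))
  expect_lt(max(abs(v$weights / median(v$weights) - 1)), 0.10)

  # variance decreasing with mean: weights rise with fitted intensity
  sdv <- seq(0.6, 0.1, length.out = n)[rank(mu)]
  mat2 <- 2^(matrix(mu, n, ns) + matrix(rnorm(n * ns), n, ns) * sdv)
  v2 <- voom_weights(mat2, design)
  expect_gt(cor(rowMeans(v2$E), rowMeans(v2$weights), method = "spearman"),
            0.9)
  expect_error(voom_weights(mat[, 1:3], design[1:3, ][, c(1, 2, 1, 2)]),
               "fewer samples")
})

test_that("moderated t has the ordinary-t and complete-pooling limits", {
  set.seed(5)
  mat <- matrix(rnorm(100 * 8, 10), 100, 8)
  rownames(mat) <- paste0("p", 1:100)
  design <- cbind(1, rep(0:1, each = 4))
  mt0 <- moderated_t(mat, design, coef = 2, params = list(d0 = 0))
  fit <- limma::lmFit(mat, design)
  ordinary_t <- fit$coefficients[, 2] / (fit$stdev.unscaled[, 2] * fit$sigma)
  expect_equal(mt0$t, unname(ordinary_t), tolerance = 1e-9)

  mtInf <- moderated_t(mat, design, coef = 2,
                       params = list(d0 = Inf, s02 = 2))
  pooled_t <- fit$coefficients[, 2] / (fit$stdev.unscaled[, 2] * sqrt(2))
  expect_equal(mtInf$t, unname(pooled_t), tolerance = 1e-9)
})

test_that("moderated t matches the limma empirical-Bayes reference", {
  set.seed(6)
  mat <- matrix(rnorm(200 * 10, 8, 1), 200, 10)
  design <- cbind(1, rep(0:1, each = 5))
  mt <- moderated_t(mat, design, coef = 2)
  eb <- limma::eBayes(limma::lmFit(mat, design))
  expect_equal(mt$t, unname(eb$t[, 2]), tolerance = 1e-8)
  expect_equal(mt$p.value, unname(eb$p.value[, 2]), tolerance = 1e-8)
})

test_that("moderated t holds its type-I error on null data", {
  sim <- simulate_abundance_matrix(n_proteins = 2000, de_fraction = 0,
                                   noise_sd = 0.3, batch_offsets = 0,
                                   zero_threshold = 0, seed = 19)
  md <- sim$metadata
  md$genotype <- factor(md$genotype, levels = c("WT", "KO"))
  design <- model.matrix(~ genotype + age + sex, md)
  mt <- moderated_t(log2(sim$matrix), design, coef = "genotypeKO")
  expect_lt(abs(mean(mt$p.value < 0.05) - 0.05), 0.01)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(2:20, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
    expect_true(all(bh_adjust(p) >= p))
    ps <- sort(p)
    expect_true(all(diff(bh_adjust(ps)) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("significance calling applies strict FC and FDR thresholds", {
  res <- data.frame(protein = c("a", "b", "c"),
                    logFC = c(0.6, log2(1.4), 0.6),
                    p.value = c(0.04, 0.001, 0.05))
  # single-protein frames keep BH = raw p, so boundary cases are exact
  one <- call_de(data.frame(logFC = 0.6, p.value = 0.04))
  expect_true(one$significant)          # FC 1.52, adj p 0.04
  expect_equal(one$direction, "up")
  low_fc <- call_de(data.frame(logFC = log2(1.4), p.value = 1e-6))
  expect_false(low_fc$significant)      # below the FC cut at any p
  boundary <- call_de(data.frame(logFC = 2, p.value = 0.05))
  expect_false(boundary$significant)    # adj p exactly 0.05 is not < 0.05
  down <- call_de(data.frame(logFC = -0.7, p.value = 0.01))
  expect_equal(down$direction, "down")
  expect_equal(unname(attr(down, "summary")), c(1, 0, 1))
  expect_error(call_de(res, fc_cut = 0), "positive")
})

test_that("PCA scores: duplicates coincide, groups separate, shares bounded", {
  set.seed(30)
  mat <- matrix(rlnorm(200 * 6, 10, 1), 200, 6)
  mat[, 2] <- mat[, 1]                        # duplicated sample
  colnames(mat) <- paste0("s", 1:6)
  pc <- pca_scores(mat, k = 2)
  expect_equal(pc$scores[1, ], pc$scores[2, ], tolerance = 1e-9)
  expect_lte(sum(pc$variance_share), 1)
  expect_error(pca_scores(mat, k = 10), "rank")

  sim <- simulate_abundance_matrix(n_proteins = 500, de_fraction = 0.3,
                                   logfc_effect = 3, noise_sd = 0.2,
                                   batch_offsets = 0, zero_threshold = 0,
                                   seed = 31)
  pcs <- pca_scores(sim$matrix, k = 2)
  expect_gt(silhouette_mean(pcs$scores, sim$metadata$genotype), 0.5)
})

test_that("the pipeline runs stage-ordered with dimension logging", {
  sim <- simulate_abundance_matrix(n_proteins = 300, seed = 41)
  res <- run_de_pipeline(sim$matrix, sim$metadata)
  expect_named(res$log, c("input", "filtered", "imputed", "normalised",
                          "batch_corrected", "tested"))
  expect_equal(unname(res$log$input), c(300, 18))
  expect_true(all(c("total", "up", "down") %in% names(res$summary)))
  expect_s3_class(res$results, "data.frame")
  expect_true(all(res$results$adj.p.value >= res$results$p.value - 1e-12))

  bad_md <- sim$metadata
  bad_md$sample[1] <- "nope"
  expect_error(run_de_pipeline(sim$matrix, bad_md), "do not match")
})
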