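#' Top-N protein roll-up from peptide intensities
#'
#' Protein abundance per sample is the sum of the protein's N most
#' abundant peptides, ranked once by mean intensity across samples so
#' the same peptides contribute in every sample. Proteins with fewer
#' than N peptides use all available.
#'
#' @param peptide_intensities Peptide x sample numeric matrix with
#'   peptide ids as row names.
#' @param protein_map Named character vector or data frame
#'   (`peptide`, `protein`) mapping every peptide to one protein.
#' @param n Number of top peptides (default 3).
#' @return Protein x sample matrix.
#' @export
topn_protein_quant <- function(peptide_intensities, protein_map, n = 3) {
  if (n < 1) stop("n must be >= 1")
  if (is.data.frame(protein_map)) {
    protein_map <- stats::setNames(protein_map$protein, protein_map$peptide)
  }
  if (!length(protein_map)) stop("empty peptide-to-protein mapping")
  peps <- rownames(peptide_intensities)
  if (is.null(peps) || !all(peps %in% names(protein_map))) {
    stop("every peptide row must be named and mapped to a protein")
  }
  prot <- protein_map[peps]
  means <- rowMeans(peptide_intensities)
  out <- t(vapply(split(seq_along(peps), prot), function(idx) {
    top <- idx[order(means[idx], decreasing = TRUE)][seq_len(min(n, length(idx)))]
    colSums(peptide_intensities[top, , drop = FALSE])
  }, numeric(ncol(peptide_intensities))))
  colnames(out) <- colnames(peptide_intensities)
  out
}

#' Filter statistically uninformative proteins
#'
#' Two rules, applied in order: (1) remove proteins whose mean
#' intensity is <= 0 in every condition (a protein present in only one
#' genotype is retained — that is exactly the biology sought); then
#' (2) remove near-zero-variance proteins, those whose most frequent
#' value accounts for at least `percent_cut`% of samples and whose
#' ratio of most-frequent to second-most-frequent value count exceeds
#' `freq_cut`.
#'
#' @param mat Protein x sample matrix.
#' @param condition Factor/character of per-sample conditions.
#' @param percent_cut Most-frequent-value percentage threshold
#'   (default 90).
#' @param freq_cut Frequency-ratio threshold (default 95/5).
#' @return Filtered matrix; attributes `removed_condition_mean` and
#'   `removed_nzv` report counts removed by each rule.
#' @export
filter_uninformative <- function(mat, condition, percent_cut = 90,
                                 freq_cut = 95 / 5) {
  stopifnot(ncol(mat) == length(condition))
  if (any(table(condition) < 2)) stop("need >= 2 samples per condition")
  cond_means <- vapply(unique(condition), function(g) {
    rowMeans(mat[, condition == g, drop = FALSE])
  }, numeric(nrow(mat)))
  cond_means <- matrix(cond_means, nrow = nrow(mat))
  keep1 <- apply(cond_means > 0, 1, any)
  m1 <- mat[keep1, , drop = FALSE]

  nzv <- apply(m1, 1, function(x) {
    tab <- sort(table(x), decreasing = TRUE)
    pct_most <- tab[1] / length(x) * 100
    ratio <- if (length(tab) > 1) tab[1] / tab[2] else Inf
    pct_most >= percent_cut && ratio > freq_cut
  })
  out <- m1[!nzv, , drop = FALSE]
  if (!nrow(out)) stop("all proteins removed by filtering")
  attr(out, "removed_condition_mean") <- sum(!keep1)
  attr(out, "removed_nzv") <- sum(nzv)
  out
}

#' Midpoint imputation of zero intensities
#'
#' Every zero in a protein row is replaced by the midpoint between it
#' and the row's smallest non-zero value, i.e. `min(x[x > 0]) / 2`.
#' Applied within protein so the result does not depend on sample
#' ordering. Rows that are entirely zero are rejected — filtering must
#' run first.
#'
#' @param mat Protein x sample matrix with no all-zero rows.
#' @return Matrix with all entries strictly positive.
#' @export
impute_zeros_midpoint <- function(mat) {
  all_zero <- rowSums(mat > 0) == 0
  if (any(all_zero)) {
    stop(sum(all_zero), " all-zero protein row(s); apply ",
         "filter_uninformative() before imputation")
  }
  t(apply(mat, 1, function(x) {
    if (any(x == 0)) x[x == 0] <- min(x[x > 0]) / 2
    x
  }))
}

#' Trimmed mean of M-values scaling factors
#'
#' Per sample, the weighted trimmed mean of log2 ratios (M) against a
#' reference sample, trimming 30% of M-values and 5% of A-values
#' two-sided, with inverse-asymptotic-variance weights. The reference
#' is the sample whose upper-quartile (of library-size-scaled
#' intensities) is closest to the mean upper-quartile. TMM factors are
#' scaled so their product is 1; `effective_size = lib_size x factor`
#' is the overall per-sample scale.
#'
#' @param mat Strictly positive protein x sample matrix
#'   (post-imputation).
#' @param logratio_trim,sum_trim Two-sided trim fractions for M and A.
#' @return Data frame: `sample`, `lib_size`, `factor` (product 1),
#'   `effective_size`; attribute `"ref"` names the reference sample.
#' @export
tmm_factors <- function(mat, logratio_trim = 0.3, sum_trim = 0.05) {
  if (any(mat <= 0)) {
    stop("TMM requires strictly positive intensities; impute zeros first")
  }
  lib <- colSums(mat)
  uq <- apply(sweep(mat, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  r <- mat[, ref] / lib[ref]
  f <- vapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j] / lib[j]
    M <- log2(x / r)
    A <- 0.5 * log2(x * r)
    w <- (lib[j] - mat[, j]) / (lib[j] * mat[, j]) +
      (lib[ref] - mat[, ref]) / (lib[ref] * mat[, ref])
    ok <- is.finite(M) & is.finite(A) & is.finite(w) & w > 0
    M <- M[ok]; A <- A[ok]; w <- w[ok]
    if (!length(M) || max(abs(M)) < 1e-10) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1;      hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  out <- data.frame(
    sample = if (is.null(colnames(mat))) as.character(seq_along(f))
             else colnames(mat),
    lib_size = lib, factor = f, effective_size = lib * f,
    row.names = NULL)
  attr(out, "ref") <- out$sample[ref]
  out
}

#' @rdname tmm_factors
#' @description `normalize_tmm()` divides each sample by its effective
#'   size rescaled to geometric mean 1, so intensities keep their
#'   original magnitude.
#' @export
normalize_tmm <- function(mat, logratio_trim = 0.3, sum_trim = 0.05) {
  fac <- tmm_factors(mat, logratio_trim, sum_trim)
  eff <- fac$effective_size / exp(mean(log(fac$effective_size)))
  out <- sweep(mat, 2, eff, "/")
  attr(out, "tmm") <- fac
  out
}

#' ANOVA-component removal of run-order batch effects
#'
#' Per-protein two-way ANOVA decomposition of the log2 matrix into
#' condition effects, batch effects, and residuals (both factors
#' estimated jointly, so the batch estimate is not contaminated by the
#' case/control contrast even in unbalanced designs). The principal
#' components of the fitted batch submodel that cumulatively explain at
#' least `variance_threshold` of its variance are subtracted.
#' Condition effects stay in the matrix, preserving case/control
#' differences.
#'
#' @param mat Strictly positive protein x sample matrix.
#' @param batch Per-sample batch labels (>= 2 distinct blocks).
#' @param condition Per-sample condition labels.
#' @param variance_threshold Cumulative variance cut (default 0.95).
#' @return Corrected matrix on the intensity scale; attribute
#'   `"components_removed"`.
#' @export
remove_batch_arsyn <- function(mat, batch, condition,
                               variance_threshold = 0.95) {
  stopifnot(ncol(mat) == length(batch), ncol(mat) == length(condition))
  batch <- factor(batch)
  condition <- factor(condition)
  if (nlevels(batch) < 2) stop("need >= 2 batch blocks")
  design <- stats::model.matrix(~ condition + batch)
  if (qr(design)$rank < ncol(design)) {
    stop("batch is confounded with condition: the batch effect is ",
         "not separable from the case/control contrast")
  }
  X <- log2(mat)
  bcols <- grep("^batch", colnames(design))
  coefs <- stats::lm.fit(design, t(X))$coefficients
  B <- t(design[, bcols, drop = FALSE] %*% coefs[bcols, , drop = FALSE])
  # centre the batch submodel across samples so only contrasts are removed
  B <- B - rowMeans(B)
  tot <- sum(B^2)
  if (tot < 1e-12) {
    attr(mat, "components_removed") <- 0L
    return(mat)
  }
  s <- svd(B)
  cumvar <- cumsum(s$d^2) / sum(s$d^2)
  k <- which(cumvar >= variance_threshold)[1]
  Bhat <- s$u[, seq_len(k), drop = FALSE] %*%
    diag(s$d[seq_len(k)], k) %*% t(s$v[, seq_len(k), drop = FALSE])
  out <- 2^(X - Bhat)
  dimnames(out) <- dimnames(mat)
  attr(out, "components_removed") <- k
  out
}

#' Log transformation with precision weights
#'
#' Mean-variance modelling of log2 intensities: a lowess trend of
#' residual standard deviation against mean log intensity from a
#' preliminary fit yields per-observation inverse-variance weights
#' (the voom transformation, applied here to label-free protein
#' intensities treated as count-like with a 0.5 offset and column
#' totals as library sizes).
#'
#' @param mat Strictly positive protein x sample matrix.
#' @param design Model matrix (samples x coefficients).
#' @param lib_size Library sizes handed to the transformation. The
#'   matrix arrives already between-sample normalised (TMM), so the
#'   default uses one shared size for every sample; re-normalising by
#'   raw column totals would re-inject noise from the few
#'   highest-abundance proteins that dominate them.
#' @return A `limma::EList` with `E` (log2 values) and `weights`.
#' @export
voom_weights <- function(mat, design,
                         lib_size = rep(mean(colSums(mat)), ncol(mat))) {
  if (nrow(design) != ncol(mat)) {
    stop("design rows must match the number of samples")
  }
  if (ncol(design) >= ncol(mat)) {
    stop("fewer samples than design columns; model not estimable")
  }
  limma::voom(mat, design = design, lib.size = lib_size, plot = FALSE)
}

#' Empirical-Bayes moderated t-test
#'
#' Per-protein weighted least squares under the design, then variance
#' moderation: hyperparameters (prior df d0, prior variance s0^2) are
#' estimated by moment matching of the scaled-F distribution of
#' residual variances; the posterior variance
#' `(d0 s0^2 + dg sg^2) / (d0 + dg)` replaces `sg^2` in the t
#' statistic, with p-values on `d0 + dg` degrees of freedom. Supplying
#' `params` overrides estimation: `d0 = 0` recovers the ordinary t,
#' `d0 = Inf` complete pooling at `s0^2`.
#'
#' @param object Matrix of log2 values or an `EList` from
#'   [voom_weights()].
#' @param design Model matrix; the tested coefficient defaults to the
#'   second column.
#' @param coef Column name or index of the coefficient of interest.
#' @param params Optional `list(d0 = , s02 = )`.
#' @return Data frame `protein`, `logFC`, `t`, `p.value`, `df.total`;
#'   attribute `"params"` holds the moderation hyperparameters.
#' @export
moderated_t <- function(object, design, coef = 2, params = NULL) {
  fit <- limma::lmFit(object, design)
  dg <- fit$df.residual
  if (all(dg <= 0)) stop("no residual degrees of freedom under this design")
  sg2 <- fit$sigma^2
  if (is.null(params)) {
    sq <- limma::squeezeVar(sg2, dg)
    d0 <- sq$df.prior
    s02 <- sq$var.prior
  } else {
    d0 <- params$d0
    s02 <- params$s02
    if (is.null(s02) && is.finite(d0) && d0 > 0) {
      stop("params must supply s02 when d0 > 0")
    }
  }
  s2post <- if (is.infinite(d0)) rep(s02, length(sg2))
            else if (d0 == 0) sg2
            else (d0 * s02 + dg * sg2) / (d0 + dg)
  beta <- fit$coefficients[, coef]
  su <- fit$stdev.unscaled[, coef]
  tval <- beta / (su * sqrt(s2post))
  df_total <- pmin(dg + d0, sum(dg))
  pval <- 2 * stats::pt(-abs(tval), df = df_total)
  out <- data.frame(
    protein = if (is.null(rownames(fit$coefficients)))
      as.character(seq_along(tval)) else rownames(fit$coefficients),
    logFC = beta, t = tval, p.value = pval, df.total = df_total,
    row.names = NULL)
  attr(out, "params") <- list(d0 = d0, s02 = if (is.null(params)) s02
                              else params$s02)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values; inputs outside [0, 1] are rejected.
#'
#' @param p Raw p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Significance calling at fold-change and FDR thresholds
#'
#' A protein is significant when its BH-adjusted p is strictly below
#' `fdr_cut` and its absolute linear fold change strictly exceeds
#' `fc_cut` (i.e. |log2FC| > log2(fc_cut)). Direction follows the sign
#' of log2FC.
#'
#' @param results Data frame with `logFC` and `p.value` (and optionally
#'   `protein`).
#' @param fc_cut Linear fold-change threshold (default 1.5).
#' @param fdr_cut FDR threshold (default 0.05).
#' @return The input with `adj.p.value`, `significant`, `direction`
#'   columns; attribute `"summary"` gives total/up/down counts.
#' @export
call_de <- function(results, fc_cut = 1.5, fdr_cut = 0.05) {
  if (fc_cut <= 0 || fdr_cut <= 0) stop("thresholds must be positive")
  results$adj.p.value <- bh_adjust(results$p.value)
  sig <- results$adj.p.value < fdr_cut &
    abs(results$logFC) > log2(fc_cut)
  results$significant <- sig
  results$direction <- ifelse(!sig, "ns",
                              ifelse(results$logFC > 0, "up", "down"))
  attr(results, "summary") <- c(total = sum(sig),
                                up = sum(sig & results$logFC > 0),
                                down = sum(sig & results$logFC < 0))
  results
}

#' Principal-component scores of samples
#'
#' PCA of centred (optionally unit-scaled) log2 intensities; returns
#' the top-k sample scores and per-component variance shares.
#'
#' @param mat Strictly positive protein x sample matrix.
#' @param k Number of components (at most `min(dim) - 1`).
#' @param scale. Unit-scale proteins before PCA.
#' @return List with `scores` (samples x k) and `variance_share`.
#' @export
pca_scores <- function(mat, k = 3, scale. = FALSE) {
  maxk <- min(ncol(mat) - 1, nrow(mat))
  if (k > maxk) stop("k exceeds the matrix rank (max ", maxk, ")")
  pc <- stats::prcomp(t(log2(mat)), center = TRUE, scale. = scale.)
  share <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       variance_share = share[seq_len(k)])
}

# equal-sized consecutive run-order blocks
run_order_blocks <- function(run_order, n_batches) {
  ceiling(rank(run_order, ties.method = "first") * n_batches /
            length(run_order))
}

#' Run the full label-free differential-expression pipeline
#'
#' Stage order: filtering, midpoint zero imputation, TMM
#' normalisation, ANOVA-component batch removal over run-order blocks,
#' voom precision weights under the covariate design, moderated
#' t-test for the genotype coefficient, BH adjustment, and
#' significance calling. Each stage logs input/output dimensions.
#'
#' @param mat Protein x sample intensity matrix.
#' @param metadata Data frame with `sample`, `genotype` ("KO"/"WT"),
#'   `age`, `sex`, `run_order` matching the matrix columns.
#' @param covariates Metadata columns adjusted for in the linear model.
#' @param n_batches Number of run-order blocks.
#' @param variance_threshold Batch-removal cumulative variance cut.
#' @param fc_cut,fdr_cut Significance thresholds.
#' @param pca_k Components reported.
#' @return List: `results` (per-protein table), `summary`, `pca`,
#'   `log` (per-stage dimensions), `corrected` (post-batch matrix).
#' @export
run_de_pipeline <- function(mat, metadata, covariates = c("age", "sex"),
                            n_batches = 3, variance_threshold = 0.95,
                            fc_cut = 1.5, fdr_cut = 0.05, pca_k = 3) {
  if (is.null(colnames(mat))) colnames(mat) <- metadata$sample
  unmatched <- setdiff(colnames(mat), metadata$sample)
  if (length(unmatched) ||
      length(setdiff(metadata$sample, colnames(mat)))) {
    stop("sample ids in matrix and metadata do not match: ",
         paste(c(unmatched, setdiff(metadata$sample, colnames(mat))),
               collapse = ", "))
  }
  metadata <- metadata[match(colnames(mat), metadata$sample), ]
  log <- list(input = dim(mat))

  filt <- filter_uninformative(mat, metadata$genotype)
  log$filtered <- c(dim(filt),
                    removed_condition_mean = attr(filt, "removed_condition_mean"),
                    removed_nzv = attr(filt, "removed_nzv"))

  imp <- impute_zeros_midpoint(filt)
  log$imputed <- dim(imp)

  norm <- normalize_tmm(imp)
  log$normalised <- dim(norm)

  blocks <- run_order_blocks(metadata$run_order, n_batches)
  corrected <- remove_batch_arsyn(norm, blocks, metadata$genotype,
                                  variance_threshold)
  log$batch_corrected <- c(dim(corrected),
                           components = attr(corrected, "components_removed"))

  metadata$genotype <- factor(metadata$genotype, levels = c("WT", "KO"))
  form <- stats::reformulate(c("genotype", covariates))
  design <- stats::model.matrix(form, data = metadata)
  v <- voom_weights(corrected, design)
  mt <- moderated_t(v, design, coef = "genotypeKO")
  called <- call_de(mt, fc_cut = fc_cut, fdr_cut = fdr_cut)
  log$tested <- nrow(called)

  list(results = called,
       summary = attr(called, "summary"),
       pca = pca_scores(corrected, k = min(pca_k, ncol(corrected) - 1)),
       log = log,
       corrected = corrected)
}
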