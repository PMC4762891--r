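#' Impute missing sample covariates from subject averages
#'
#' Missing PMI/pH values are replaced by the subject's mean over its
#' non-missing samples; subjects with no observed value at all fall back to
#' the cohort mean. Imputations are recorded in the `"imputed"` attribute of
#' the returned table.
#'
#' @param samples Sample table.
#' @param covariates Covariate columns eligible for imputation.
#' @return The sample table with gaps filled; attribute `"imputed"` is a
#'   data.frame listing each imputed cell and the source of its value
#'   (`subject_mean` or `cohort_mean`).
#' @export
impute_missing_covariates <- function(samples, covariates = c("PMI", "pH")) {
  .check_sample_table(samples)
  report <- list()
  for (cv in intersect(covariates, colnames(samples))) {
    v <- samples[[cv]]
    if (!anyNA(v)) next
    if (all(is.na(v)))
      .sd_stop("covariate '", cv, "' is missing for the entire cohort")
    cohort_mean <- mean(v, na.rm = TRUE)
    for (subj in unique(samples$subject_id[is.na(v)])) {
      rows <- which(samples$subject_id == subj & is.na(v))
      have <- v[samples$subject_id == subj]
      if (all(is.na(have))) {
        fill <- cohort_mean; src <- "cohort_mean"
      } else {
        fill <- mean(have, na.rm = TRUE); src <- "subject_mean"
      }
      v[rows] <- fill
      report[[length(report) + 1L]] <- data.frame(
        sample_id = samples$sample_id[rows], covariate = cv,
        value = fill, source = src, stringsAsFactors = FALSE)
    }
    samples[[cv]] <- v
  }
  attr(samples, "imputed") <- if (length(report)) do.call(rbind, report) else
    data.frame(sample_id = character(), covariate = character(),
               value = numeric(), source = character(), stringsAsFactors = FALSE)
  samples
}

# internal: build the fixed-effect design matrix.
# Column "sexmale" is the contrast of interest (male - female on log2 scale).
.build_design <- function(samples, covariates = character()) {
  .check_sample_table(samples)
  sex <- factor(samples$sex, levels = c("female", "male"))
  df <- data.frame(sex = sex)
  for (cv in covariates) {
    if (!cv %in% colnames(samples))
      .sd_stop("covariate '", cv, "' not present in sample table")
    if (anyNA(samples[[cv]]))
      .sd_stop("covariate '", cv, "' has missing values; impute first")
    df[[cv]] <- if (cv == "lobe") factor(samples[[cv]]) else
      as.numeric(samples[[cv]])
  }
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    .sd_stop("design matrix is rank deficient; collinear column(s): ",
             paste(bad, collapse = ", "))
  }
  X
}

# internal: orthonormal Helmert-style basis with constant first row
.helmert_orth <- function(m) {
  H <- matrix(0, m, m)
  H[1L, ] <- 1 / sqrt(m)
  if (m > 1L) for (r in 2:m) {
    H[r, 1:(r - 1L)] <- 1 / sqrt(r * (r - 1))
    H[r, r] <- -(r - 1) / sqrt(r * (r - 1))
  }
  H
}

# internal: whitening matrix W with W %*% R(rho) %*% t(W) = I for the
# block compound-symmetry correlation R (blocks = subjects), plus log|R|.
.cs_whitener <- function(subject, rho) {
  n <- length(subject)
  W <- matrix(0, n, n)
  logdet <- 0
  for (ids in split(seq_len(n), subject)) {
    m <- length(ids)
    if (m == 1L) { W[ids, ids] <- 1; next }
    d <- c(1 + (m - 1) * rho, rep(1 - rho, m - 1L))
    if (any(d <= 0)) .sd_stop("rho = ", rho, " infeasible for block size ", m)
    W[ids, ids] <- .helmert_orth(m) / sqrt(d)
    logdet <- logdet + sum(log(d))
  }
  list(W = W, logdet = logdet)
}

#' Estimate the consensus intra-subject correlation
#'
#' Samples from the same subject (different cortical regions of one brain)
#' are not independent. Per gene, the intra-subject correlation of a
#' compound-symmetry model with the given fixed-effect design is estimated
#' by restricted maximum likelihood (profiled over the residual variance and
#' maximized on a grid with parabolic refinement). The consensus value is
#' the hyperbolic tangent of the 15%-trimmed mean of the per-gene
#' atanh-transformed estimates, clamped to (-0.99, 0.99).
#'
#' @param mat Expression matrix.
#' @param samples Sample table covering the matrix columns.
#' @param covariates Fixed-effect covariate columns (subset of
#'   `RIN`, `age`, `PMI`, `lobe`, `pH`).
#' @param grid_points Resolution of the correlation grid.
#' @return Scalar consensus correlation. If no subject contributes more than
#'   one sample, 0 is returned with a warning.
#' @export
estimate_consensus_correlation <- function(mat, samples,
                                           covariates = character(),
                                           grid_points = 31L) {
  .check_expression(mat)
  samples <- .align_samples(samples, mat)
  subject <- samples$subject_id
  block_sizes <- table(subject)
  if (max(block_sizes) < 2L) {
    warning("no subject contributes repeated samples; returning rho = 0")
    return(0)
  }
  X <- .build_design(samples, covariates)
  n <- nrow(X); p <- ncol(X)
  lo <- max(-0.9, -1 / (max(block_sizes) - 1) + 0.02)
  grid <- seq(lo, 0.97, length.out = grid_points)

  keep <- apply(mat, 1L, stats::sd) > 1e-10
  Y <- mat[keep, , drop = FALSE]
  G <- nrow(Y)
  if (G == 0L) .sd_stop("no genes with positive variance")

  crit <- matrix(NA_real_, G, length(grid))  # -2 REML (up to constants)
  for (k in seq_along(grid)) {
    wh <- .cs_whitener(subject, grid[k])
    Xt <- wh$W %*% X
    qrX <- qr(Xt)
    Q <- qr.Q(qrX)
    logdet_xtx <- 2 * sum(log(abs(diag(qr.R(qrX)))))
    Yt <- Y %*% t(wh$W)
    E <- Yt - (Yt %*% Q) %*% t(Q)
    rss <- pmax(rowSums(E * E), 1e-300)
    crit[, k] <- (n - p) * log(rss) + wh$logdet + logdet_xtx
  }

  # per-gene grid argmin with parabolic refinement between neighbours
  idx <- max.col(-crit, ties.method = "first")
  step <- grid[2L] - grid[1L]
  rho_g <- grid[idx]
  interior <- idx > 1L & idx < length(grid)
  if (any(interior)) {
    i <- idx[interior]
    y0 <- crit[cbind(which(interior), i - 1L)]
    y1 <- crit[cbind(which(interior), i)]
    y2 <- crit[cbind(which(interior), i + 1L)]
    denom <- y0 - 2 * y1 + y2
    off <- ifelse(denom > 0, 0.5 * (y0 - y2) / denom, 0)
    off <- pmin(pmax(off, -1), 1)
    rho_g[interior] <- grid[i] + off * step
  }
  rho_g <- pmin(pmax(rho_g, -0.98), 0.98)
  consensus <- tanh(mean(atanh(rho_g), trim = 0.15))
  min(max(consensus, -0.99), 0.99)
}

#' Fit per-gene sex-contrast models by generalized least squares
#'
#' Every gene is fit with the same fixed-effect design (sex contrast plus
#' covariates) under a block compound-symmetry covariance: samples from the
#' same subject share the consensus correlation `rho`. The model is solved
#' by whitening, so with `rho = 0` the fit collapses to ordinary least
#' squares.
#'
#' @param mat Expression matrix (log2 scale).
#' @param samples Sample table covering the matrix columns.
#' @param covariates Fixed-effect covariate columns.
#' @param rho Consensus intra-subject correlation, typically from
#'   [estimate_consensus_correlation()].
#' @return Data.frame with one row per gene: `gene`, `log2FD`
#'   (male - female), `stderr`, `s2` (residual variance), `df` (residual
#'   degrees of freedom), `stdev_unscaled` and `mean_expr`. The correlation
#'   used is stored in attribute `"rho"`.
#' @export
fit_gene_models <- function(mat, samples, covariates = character(), rho = 0) {
  .check_expression(mat)
  samples <- .align_samples(samples, mat)
  if (!.is_num1(rho) || rho <= -1 || rho >= 1)
    .sd_stop("rho must lie in (-1, 1)")
  X <- .build_design(samples, covariates)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) .sd_stop("fewer samples than design columns")
  sex_col <- match("sexmale", colnames(X))

  wh <- .cs_whitener(samples$subject_id, rho)
  Xt <- wh$W %*% X
  Yt <- mat %*% t(wh$W)            # genes x samples, whitened
  xtx_inv <- solve(crossprod(Xt))
  coef <- Yt %*% Xt %*% xtx_inv     # genes x p
  resid <- Yt - coef %*% t(Xt)
  s2 <- rowSums(resid * resid) / (n - p)
  v_ss <- xtx_inv[sex_col, sex_col]

  out <- data.frame(
    gene = rownames(mat),
    log2FD = coef[, sex_col],
    stderr = sqrt(s2 * v_ss),
    s2 = s2,
    df = n - p,
    stdev_unscaled = sqrt(v_ss),
    mean_expr = rowMeans(mat),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "rho") <- rho
  out
}

# internal: Newton solve of trigamma(y) = x (x > 0)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

# internal: method-of-moments hyperparameters (d0, s0_sq) of the scaled
# inverse-chi-square variance prior, matched on log variances.
.estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10L)
    .sd_stop("need at least 10 genes with positive residual variance")
  z <- log(s2[ok])
  dfo <- rep_len(df, length(s2))[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(dfo / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderate per-gene variances and compute moderated t-statistics
#'
#' Empirical-Bayes variance moderation: the per-gene residual variances are
#' assumed to follow a scaled inverse-chi-square prior with hyperparameters
#' `(d0, s0_sq)`, estimated by the closed-form method of moments on log
#' variances (digamma/trigamma matching). Each gene's posterior variance is
#' `(d0*s0_sq + df*s2) / (d0 + df)`; the moderated t-statistic uses it in
#' place of `s2` and gains `d0` degrees of freedom. Two-sided p-values are
#' adjusted by Benjamini-Hochberg across all genes.
#'
#' @param fits Output of [fit_gene_models()].
#' @param d0,s0_sq Optional hyperparameter overrides (e.g. `d0 = 0` for no
#'   moderation, `d0 = Inf` for complete shrinkage to `s0_sq`); by default
#'   both are estimated from the data.
#' @return List with `table` (data.frame: `gene`, `log2FD`, `FD`, `t`, `p`,
#'   `p_bh`, `mean_expr`) and `params` (list `d0`, `s0_sq`, `rho`).
#' @export
ebayes_moderate <- function(fits, d0 = NULL, s0_sq = NULL) {
  need <- c("gene", "log2FD", "s2", "df", "stdev_unscaled")
  if (!all(need %in% colnames(fits)))
    .sd_stop("fits must come from fit_gene_models()")
  if (is.null(d0) || is.null(s0_sq)) {
    prior <- .estimate_variance_prior(fits$s2, fits$df)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s0_sq)) s0_sq <- prior$s0_sq
  }
  if (d0 < 0 || s0_sq <= 0) .sd_stop("invalid hyperparameters")

  stilde2 <- if (is.infinite(d0)) rep(s0_sq, nrow(fits)) else
    (d0 * s0_sq + fits$df * fits$s2) / (d0 + fits$df)
  df_total <- if (is.infinite(d0)) Inf else d0 + fits$df
  tmod <- fits$log2FD / (fits$stdev_unscaled * sqrt(stilde2))
  p <- 2 * stats::pt(-abs(tmod), df = df_total)

  table <- data.frame(
    gene = fits$gene,
    log2FD = fits$log2FD,
    FD = 2^fits$log2FD,
    t = tmod,
    p = p,
    p_bh = stats::p.adjust(p, method = "BH"),
    mean_expr = fits$mean_expr,
    stringsAsFactors = FALSE, row.names = NULL)
  list(table = table,
       params = list(d0 = d0, s0_sq = s0_sq, rho = attr(fits, "rho")))
}

#' Call sex-differentially expressed genes at threshold tiers
#'
#' A gene is male-DE at tier `alpha` when its fold difference (male/female)
#' is at least `fd_threshold` and its unadjusted p-value is at most `alpha`;
#' female-DE when the fold difference is at most `1/fd_threshold`. Every
#' gene is also labelled by threshold-free direction: male-higher
#' (`log2FD > 0`) or female-higher (`log2FD < 0`); genes with `log2FD`
#' exactly 0 belong to neither category.
#'
#' @param table DE table from [ebayes_moderate()].
#' @param fd_threshold Minimum fold-difference magnitude (default 1.2).
#' @param p_tiers Unadjusted p-value tiers (default 0.005, 0.01, 0.05).
#' @return The table with a `direction` column and one `de_p<tier>` column
#'   per tier (values `male-DE`, `female-DE`, `ns`).
#' @export
call_sex_de <- function(table, fd_threshold = 1.2,
                        p_tiers = c(0.005, 0.01, 0.05)) {
  if (!all(c("gene", "log2FD", "p") %in% colnames(table)))
    .sd_stop("table must carry gene, log2FD and p columns")
  if (!.is_num1(fd_threshold) || fd_threshold <= 1)
    .sd_stop("fd_threshold must exceed 1")
  fd <- 2^table$log2FD
  table$direction <- ifelse(table$log2FD > 0, "male-higher",
                            ifelse(table$log2FD < 0, "female-higher", "none"))
  for (alpha in sort(p_tiers)) {
    lab <- rep("ns", nrow(table))
    lab[fd >= fd_threshold & table$p <= alpha] <- "male-DE"
    lab[fd <= 1 / fd_threshold & table$p <= alpha] <- "female-DE"
    table[[.tier_col(alpha)]] <- lab
  }
  attr(table, "fd_threshold") <- fd_threshold
  attr(table, "p_tiers") <- sort(p_tiers)
  table
}

# internal: column name for a p-value tier (0.05 -> "de_p0.05")
.tier_col <- function(alpha) paste0("de_p", format(alpha, drop0trailing = TRUE))

#' Run the full sex-differential expression analysis
#'
#' Convenience wrapper: impute missing covariates, estimate the consensus
#' intra-subject correlation, fit gene-wise GLS models, moderate variances
#' and call sex-DE genes.
#'
#' @param mat Preprocessed expression matrix.
#' @param samples Sample table.
#' @param covariates Fixed-effect covariates (default: all of RIN, age, PMI,
#'   lobe, pH that are present in the table).
#' @param fd_threshold,p_tiers Passed to [call_sex_de()].
#' @return List with `table` (labelled DE table) and `params`
#'   (`d0`, `s0_sq`, `rho`).
#' @export
run_sex_de <- function(mat, samples,
                       covariates = intersect(c("RIN", "age", "PMI", "lobe", "pH"),
                                              colnames(samples)),
                       fd_threshold = 1.2, p_tiers = c(0.005, 0.01, 0.05)) {
  samples <- impute_missing_covariates(samples)
  rho <- estimate_consensus_correlation(mat, samples, covariates)
  fits <- fit_gene_models(mat, samples, covariates, rho = rho)
  mod <- ebayes_moderate(fits)
  list(table = call_sex_de(mod$table, fd_threshold, p_tiers),
       params = mod$params)
}

#' Write a DE table to TSV
#'
#' @param table Labelled DE table from [call_sex_de()] or [run_sex_de()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a DE table written by [write_de_table()]
#'
#' @param path Path to the TSV file.
#' @return Data.frame with the DE-table columns.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene", "log2FD", "p") %in% colnames(df)))
    .sd_stop("not a DE table (needs gene, log2FD, p): ", path)
  df
}
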