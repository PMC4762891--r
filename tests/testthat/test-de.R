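test_that("missing PMI/pH are imputed from subject then cohort means", {
  st <- data.frame(
    sample_id = paste0("x", 1:5),
    sex = c("male", "male", "male", "female", "female"),
    subject_id = c("s1", "s1", "s1", "s2", "s2"),
    PMI = c(10, NA, 14, 20, 22),
    pH = c(NA, NA, NA, 6.4, 6.6),
    stringsAsFactors = FALSE)
  out <- impute_missing_covariates(st)
  expect_equal(out$PMI[2], 12)                 # subject mean of {10, 14}
  expect_equal(out$pH[1:3], rep(6.5, 3))        # cohort mean fallback
  rep <- attr(out, "imputed")
  expect_true(all(rep$source[rep$covariate == "pH"] == "cohort_mean"))

  # no missing values: identity
  expect_equal(impute_missing_covariates(out)$PMI, out$PMI)

  st$PMI <- NA_real_
  expect_error(impute_missing_covariates(st), "entire cohort")
})

test_that("consensus correlation recovers the generative rho", {
  co0 <- generate_cohort(sim_config(
    n_subjects_per_sex = 10, n_regions_per_subject = 3, n_genes = 1500,
    rho_subject = 0, covariate_effect_scale = 0, seed = 31))
  rho0 <- estimate_consensus_correlation(co0$expression, co0$samples)
  expect_lt(abs(rho0), 0.05)

  co5 <- generate_cohort(sim_config(
    n_subjects_per_sex = 10, n_regions_per_subject = 4, n_genes = 1500,
    rho_subject = 0.5, covariate_effect_scale = 0, seed = 32))
  rho5 <- estimate_consensus_correlation(co5$expression, co5$samples)
  expect_lt(abs(rho5 - 0.5), 0.1)

  # every subject contributes one sample: rho = 0 with a warning
  one <- generate_cohort(sim_config(
    n_subjects_per_sex = 4, n_regions_per_subject = 1, n_genes = 50, seed = 1))
  expect_warning(r <- estimate_consensus_correlation(one$expression, one$samples),
                 "repeated")
  expect_equal(r, 0)
})

test_that("consensus correlation agrees with the limma estimator", {
  skip_if_not_installed("limma")
  co <- generate_cohort(sim_config(
    n_subjects_per_sex = 8, n_regions_per_subject = 3, n_genes = 400,
    rho_subject = 0.4, covariate_effect_scale = 0, seed = 33))
  rho <- estimate_consensus_correlation(co$expression, co$samples)
  design <- model.matrix(~ factor(co$samples$sex, c("female", "male")))
  dc <- limma::duplicateCorrelation(co$expression, design,
                                    block = co$samples$subject_id)
  expect_lt(abs(rho - dc$consensus.correlation), 0.05)
})

test_that("GLS with rho = 0 collapses to ordinary least squares", {
  co <- null_cohort(seed = 17, n_genes = 30, n_subjects = 4, rho = 0)
  fits <- fit_gene_models(co$expression, co$samples,
                          covariates = c("age", "RIN"), rho = 0)
  for (g in c(1, 15, 30)) {
    df <- data.frame(y = co$expression[g, ],
                     sex = factor(co$samples$sex, c("female", "male")),
                     age = co$samples$age, RIN = co$samples$RIN)
    fit <- lm(y ~ sex + age + RIN, data = df)
    expect_equal(fits$log2FD[g], unname(coef(fit)[["sexmale"]]),
                 tolerance = 1e-8)
    expect_equal(fits$stderr[g],
                 unname(sqrt(diag(vcov(fit)))[["sexmale"]]), tolerance = 1e-8)
  }
})

test_that("a gene equal to the sex indicator fits perfectly", {
  st <- toy_samples(4)
  y <- matrix(as.numeric(st$sex == "male"), 1,
              dimnames = list("g1", st$sample_id))
  fits <- fit_gene_models(y, st, rho = 0)
  expect_equal(fits$log2FD, 1, tolerance = 1e-10)
  expect_equal(fits$s2, 0, tolerance = 1e-12)
})

test_that("GLS matches the explicit whitening oracle at rho = 0.5", {
  set.seed(9)
  st <- data.frame(
    sample_id = paste0("x", 1:6),
    sex = rep(c("female", "male"), each = 3),
    subject_id = c("a", "a", "b", "c", "c", "d"),
    stringsAsFactors = FALSE)
  y <- matrix(rnorm(6), 1, dimnames = list("g1", st$sample_id))
  rho <- 0.5
  # hand-built block compound-symmetry covariance and direct GLS solve
  V <- diag(6)
  same <- outer(st$subject_id, st$subject_id, "==")
  V[same & !diag(6)] <- rho
  X <- cbind(1, as.numeric(st$sex == "male"))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% t(y))
  fits <- fit_gene_models(y, st, rho = rho)
  expect_equal(fits$log2FD, unname(beta[2, 1]), tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with the offending column", {
  st <- toy_samples(4)
  st$PMI <- st$age * 2  # exactly collinear with age
  y <- matrix(rnorm(8 * 5), 5,
              dimnames = list(paste0("g", 1:5), st$sample_id))
  expect_error(fit_gene_models(y, st, covariates = c("age", "PMI")),
               "collinear.*PMI|collinear.*age")
})

test_that("moderation limits behave as expected", {
  co <- null_cohort(seed = 19, n_genes = 200, n_subjects = 4)
  fits <- fit_gene_models(co$expression, co$samples, rho = 0)

  # d0 = 0: moderated t equals ordinary t on d_g dof
  m0 <- ebayes_moderate(fits, d0 = 0, s0_sq = 1)
  t_ord <- fits$log2FD / fits$stderr
  expect_equal(m0$table$t, t_ord, tolerance = 1e-10)
  expect_equal(m0$table$p, 2 * pt(-abs(t_ord), fits$df), tolerance = 1e-12)

  # d0 = Inf: posterior variance is s0_sq everywhere
  mi <- ebayes_moderate(fits, d0 = Inf, s0_sq = 0.05)
  expect_equal(mi$table$t, fits$log2FD / (fits$stdev_unscaled * sqrt(0.05)),
               tolerance = 1e-10)

  # estimated case: posterior variance strictly between s2 and s0_sq
  mm <- ebayes_moderate(fits)
  d0 <- mm$params$d0; s0 <- mm$params$s0_sq
  stilde2 <- (d0 * s0 + fits$df * fits$s2) / (d0 + fits$df)
  inside <- fits$s2 != s0
  expect_true(all(stilde2[inside] > pmin(fits$s2, s0)[inside]))
  expect_true(all(stilde2[inside] < pmax(fits$s2, s0)[inside]))

  # BH column obeys p_bh >= p and the step-up oracle
  expect_true(all(mm$table$p_bh >= mm$table$p - 1e-15))
  expect_equal(mm$table$p_bh, oracle_bh(mm$table$p), tolerance = 1e-12)
})

test_that("variance-prior hyperparameters are recovered from simulation", {
  set.seed(44)
  sigma2 <- sample_gene_variances(5000, d0 = 4, s0_sq = 0.05)
  df <- 20
  s2 <- sigma2 * rchisq(5000, df) / df
  fits <- data.frame(gene = paste0("g", 1:5000), log2FD = 0, s2 = s2,
                     df = df, stdev_unscaled = 1, mean_expr = 0)
  params <- ebayes_moderate(fits)$params
  expect_gt(params$d0, 3); expect_lt(params$d0, 5.5)
  expect_gt(params$s0_sq, 0.04); expect_lt(params$s0_sq, 0.06)
})

test_that("moderated fit agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  co <- null_cohort(seed = 23, n_genes = 300, n_subjects = 5, rho = 0.3,
                    cov_scale = 0)
  rho <- estimate_consensus_correlation(co$expression, co$samples)
  fits <- fit_gene_models(co$expression, co$samples, rho = rho)
  mod <- ebayes_moderate(fits)

  design <- model.matrix(~ factor(co$samples$sex, c("female", "male")))
  lf <- limma::lmFit(co$expression, design, block = co$samples$subject_id,
                     correlation = rho)
  eb <- limma::eBayes(lf)
  expect_equal(unname(fits$log2FD), unname(lf$coefficients[, 2]),
               tolerance = 1e-6)
  expect_equal(unname(fits$s2), unname(lf$sigma^2), tolerance = 1e-6)
  expect_equal(mod$params$d0, eb$df.prior, tolerance = 0.05)
  expect_equal(mod$params$s0_sq, eb$s2.prior, tolerance = 1e-3)
  expect_gt(cor(mod$table$t, eb$t[, 2]), 0.9999)
})

test_that("sex-DE calling applies the FD and p thresholds strictly", {
  tb <- data.frame(
    gene = c("a", "b", "c", "d"),
    log2FD = c(log2(1.25), log2(1.19), 0, -log2(1.3)),
    p = c(0.03, 1e-10, 0.001, 0.004))
  out <- call_sex_de(tb)
  expect_equal(out$de_p0.05[1], "male-DE")
  expect_equal(out$de_p0.01[1], "ns")       # p = 0.03 misses the 0.01 tier
  expect_equal(out$de_p0.05[2], "ns")       # FD 1.19 never qualifies
  expect_equal(out$direction[3], "none")    # log2FD exactly 0
  expect_equal(out$de_p0.005[4], "female-DE")
  # tiers are nested
  called05 <- out$de_p0.05 != "ns"
  called005 <- out$de_p0.005 != "ns"
  expect_true(all(!called005 | called05))
  expect_error(call_sex_de(tb, fd_threshold = 0.9), "exceed 1")
})

test_that("null cohorts give calibrated type-I error and uniform p-values", {
  co <- generate_cohort(sim_config(
    n_subjects_per_sex = 5, n_regions_per_subject = 3, n_genes = 2000,
    rho_subject = 0.3, seed = 77))
  res <- run_sex_de(co$expression, co$samples)
  auto <- co$truth$sexchrom_class == "autosomal"
  p <- res$table$p[match(co$truth$gene_id[auto], res$table$gene)]
  frac <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / length(p))
  expect_lt(abs(frac - 0.05), 3 * se + 0.01)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("planted effects are recovered with the right sign convention", {
  co <- planted_cohort(seed = 55, n_genes = 2000, set_size = 200,
                       log2fd = 0.4, n_subjects = 10)
  res <- run_sex_de(co$expression, co$samples)
  planted <- co$sets$sets$planted$genes
  est <- res$table$log2FD[match(planted, res$table$gene)]
  expect_gt(median(est), 0)
  expect_lt(abs(median(est) - 0.4), 0.05)
})
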