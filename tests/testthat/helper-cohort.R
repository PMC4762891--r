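# Shared fixture builders. Everything is generated in code at test time.

# small cohort with no planted effects
null_cohort <- function(seed = 1, n_genes = 500, n_subjects = 5, n_regions = 3,
                        rho = 0.3, cov_scale = 0.1) {
  generate_cohort(sim_config(
    n_subjects_per_sex = n_subjects, n_regions_per_subject = n_regions,
    n_genes = n_genes, rho_subject = rho,
    covariate_effect_scale = cov_scale, seed = seed))
}

# cohort with one planted male-higher set plus its control
planted_cohort <- function(seed = 1, n_genes = 1000, set_size = 100,
                           log2fd = 0.4, n_subjects = 10, n_regions = 3,
                           rho = 0.3) {
  generate_cohort(sim_config(
    n_subjects_per_sex = n_subjects, n_regions_per_subject = n_regions,
    n_genes = n_genes, rho_subject = rho,
    planted_sets = list(planted = list(n_genes = set_size, log2fd = log2fd)),
    seed = seed))
}

# minimal hand-built sample table
toy_samples <- function(n_per_sex = 3, region = "A") {
  data.frame(
    sample_id = c(sprintf("f%d", seq_len(n_per_sex)),
                  sprintf("m%d", seq_len(n_per_sex))),
    sex = rep(c("female", "male"), each = n_per_sex),
    subject_id = c(sprintf("sf%d", seq_len(n_per_sex)),
                   sprintf("sm%d", seq_len(n_per_sex))),
    region = region,
    age = 30,
    stringsAsFactors = FALSE)
}

# independent brute-force two-sided Fisher p (direct lchoose arithmetic)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; K <- a + c; N <- a + b + c + d
  supp <- max(0, K - (N - m)):min(K, m)
  lp <- lchoose(m, supp) + lchoose(N - m, K - supp) - lchoose(N, K)
  probs <- exp(lp)
  p_obs <- probs[supp == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# independent brute-force BH step-up adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}
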