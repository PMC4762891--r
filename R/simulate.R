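#' Configuration for the synthetic-cohort generator
#'
#' Describes a balanced repeated-measures brain expression cohort: each
#' subject contributes one sample per cortical region, sexes are balanced,
#' and per-gene residual variances follow a scaled inverse-chi-square
#' hyperprior so the moderated-t machinery downstream sees exactly the
#' variance structure it assumes.
#'
#' @param n_subjects_per_sex Subjects per sex (default 5, a small post-mortem
#'   cohort).
#' @param n_regions_per_subject Cortical regions sampled per subject
#'   (default 3: frontal, temporal, parietal).
#' @param n_genes Total genes simulated.
#' @param d0 Prior degrees of freedom of the variance hyperprior; must
#'   exceed 2 so the prior mean is finite.
#' @param s0_sq Prior variance scale, in squared log2 units.
#' @param rho_subject Intra-subject correlation of samples from the same
#'   brain, in `[0, 1)`.
#' @param planted_sets Named list describing autosomal gene sets carrying a
#'   true sex effect; each element is `list(n_genes =, log2fd =)` with
#'   positive `log2fd` meaning male-higher.
#' @param n_sexchrom_female_marker Number of female-only marker genes
#'   (XIST-like).
#' @param n_sexchrom_male_marker Number of male-only marker genes (Y-like).
#' @param covariate_effect_scale Standard deviation of per-gene fixed
#'   covariate effects (log2 units per SD of the covariate).
#' @param baseline_mean_range Length-2 interval for baseline log2 expression.
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects_per_sex = 5,
                       n_regions_per_subject = 3,
                       n_genes = 2000,
                       d0 = 4,
                       s0_sq = 0.05,
                       rho_subject = 0.3,
                       planted_sets = list(),
                       n_sexchrom_female_marker = 1,
                       n_sexchrom_male_marker = 6,
                       covariate_effect_scale = 0.1,
                       baseline_mean_range = c(2, 10),
                       seed = 1L) {
  cfg <- list(n_subjects_per_sex = n_subjects_per_sex,
              n_regions_per_subject = n_regions_per_subject,
              n_genes = n_genes, d0 = d0, s0_sq = s0_sq,
              rho_subject = rho_subject, planted_sets = planted_sets,
              n_sexchrom_female_marker = n_sexchrom_female_marker,
              n_sexchrom_male_marker = n_sexchrom_male_marker,
              covariate_effect_scale = covariate_effect_scale,
              baseline_mean_range = baseline_mean_range, seed = seed)
  for (f in c("n_subjects_per_sex", "n_regions_per_subject", "n_genes"))
    if (!.is_count(cfg[[f]])) .sd_stop(f, " must be a positive integer")
  if (!.is_num1(cfg$d0) || cfg$d0 <= 2)
    .sd_stop("d0 must exceed 2 (finite prior variance mean)")
  if (!.is_num1(cfg$s0_sq) || cfg$s0_sq <= 0) .sd_stop("s0_sq must be positive")
  if (!.is_num1(cfg$rho_subject) || cfg$rho_subject < 0 || cfg$rho_subject >= 1)
    .sd_stop("rho_subject must lie in [0, 1)")
  if (!.is_num1(cfg$covariate_effect_scale) || cfg$covariate_effect_scale < 0)
    .sd_stop("covariate_effect_scale must be nonnegative")
  if (length(cfg$baseline_mean_range) != 2L ||
      !all(is.finite(cfg$baseline_mean_range)) ||
      diff(cfg$baseline_mean_range) < 0)
    .sd_stop("baseline_mean_range must be an increasing length-2 interval")
  for (f in c("n_sexchrom_female_marker", "n_sexchrom_male_marker"))
    if (!.is_num1(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      .sd_stop(f, " must be a nonnegative integer")
  if (length(cfg$planted_sets)) {
    if (is.null(names(cfg$planted_sets)) || anyDuplicated(names(cfg$planted_sets)))
      .sd_stop("planted_sets must be uniquely named")
    for (nm in names(cfg$planted_sets)) {
      ps <- cfg$planted_sets[[nm]]
      if (!.is_count(ps$n_genes) || !.is_num1(ps$log2fd))
        .sd_stop("planted set '", nm, "' needs n_genes (count) and log2fd (number)")
    }
  }
  n_marker <- cfg$n_sexchrom_female_marker + cfg$n_sexchrom_male_marker
  n_planted <- sum(vapply(cfg$planted_sets, function(p) p$n_genes, numeric(1)))
  # controls mirror planted sets one-for-one, so reserve space for both
  if (n_marker + 2 * n_planted > cfg$n_genes)
    .sd_stop("planted sets (plus matched controls) and markers exceed n_genes")
  if (!.is_num1(cfg$seed) || cfg$seed != round(cfg$seed))
    .sd_stop("seed must be an integer")
  class(cfg) <- "sim_config"
  cfg
}

#' Draw per-gene residual variances from a scaled inverse-chi-square prior
#'
#' Each variance is `d0 * s0_sq / chisq(d0)`, the conjugate hyperprior
#' assumed by the empirical-Bayes moderated t-test, so hyperparameter
#' recovery can be checked exactly.
#'
#' @param n_genes Number of variances to draw.
#' @param d0 Prior degrees of freedom (> 0).
#' @param s0_sq Prior scale (> 0).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of strictly positive variances.
#' @export
sample_gene_variances <- function(n_genes, d0, s0_sq, seed = NULL) {
  if (!.is_count(n_genes)) .sd_stop("n_genes must be a positive integer")
  if (!.is_num1(d0) || d0 <= 0) .sd_stop("d0 must be positive")
  if (!.is_num1(s0_sq) || s0_sq <= 0) .sd_stop("s0_sq must be positive")
  if (!is.null(seed)) set.seed(seed)
  d0 * s0_sq / stats::rchisq(n_genes, df = d0)
}

#' Generate a synthetic repeated-measures expression cohort
#'
#' Builds a balanced two-sex cohort on the log2 scale. Per gene g and sample
#' i the simulated value is
#' `baseline_g + sign(sex_i) * log2FD_g / 2 + covariate effects +
#'  subject intercept + noise`,
#' where the subject-intercept variance is `rho/(1-rho)` times the gene's
#' noise variance so the intra-subject correlation equals `rho_subject`.
#' Sex-chromosome markers are encoded as an extreme fold difference around a
#' mid-baseline (6.0 in the expressing sex, 0.05 in the other), reproducing
#' the XIST/Y-gene wings of a sex volcano plot without modelling copy number.
#' For every planted set an unplanted control set of the same size is also
#' emitted as a negative-control surface for enrichment tests.
#'
#' @param config A [sim_config()].
#' @param truth Optional truth table from a previous cohort; when supplied,
#'   gene identities, true effects and set memberships are reused and only
#'   baselines, covariates, variances and noise are redrawn, emulating an
#'   independent replication cohort measuring the same biology.
#' @return List with components `expression` (matrix), `samples`
#'   (data.frame), `sets` ([gene_set_collection()]) and `truth` (data.frame
#'   with `gene_id`, `true_log2fd`, `sexchrom_class`, `sets`).
#' @export
generate_cohort <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n_g <- config$n_genes
  n_f <- config$n_sexchrom_female_marker
  n_m <- config$n_sexchrom_male_marker

  if (is.null(truth)) {
    gene_ids <- character(n_g)
    fclass <- rep("autosomal", n_g)
    idx <- 1L
    if (n_f > 0) {
      gene_ids[idx:(idx + n_f - 1L)] <- sprintf("xf_%03d", seq_len(n_f))
      fclass[idx:(idx + n_f - 1L)] <- "X-marker"
      idx <- idx + n_f
    }
    if (n_m > 0) {
      gene_ids[idx:(idx + n_m - 1L)] <- sprintf("ym_%03d", seq_len(n_m))
      fclass[idx:(idx + n_m - 1L)] <- "Y-marker"
      idx <- idx + n_m
    }
    n_auto <- n_g - n_f - n_m
    gene_ids[idx:n_g] <- sprintf("g_%06d", seq_len(n_auto))

    true_fd <- numeric(n_g)
    # extreme marker fold differences: 6.0 vs 0.05 in/out of expressing sex
    true_fd[fclass == "X-marker"] <- -(6.0 - 0.05)
    true_fd[fclass == "Y-marker"] <- +(6.0 - 0.05)

    auto_pool <- gene_ids[fclass == "autosomal"]
    membership <- stats::setNames(vector("list", n_g), gene_ids)
    set_defs <- list()
    take <- function(n) {
      picked <- sample(auto_pool, n)
      auto_pool <<- setdiff(auto_pool, picked)
      picked
    }
    if (length(config$planted_sets)) {
      for (nm in names(config$planted_sets)) {
        ps <- config$planted_sets[[nm]]
        genes <- take(ps$n_genes)
        true_fd[match(genes, gene_ids)] <- ps$log2fd
        set_defs[[nm]] <- genes
        set_defs[[paste0("ctrl_", nm)]] <- take(ps$n_genes)
      }
    } else {
      set_defs[["ctrl_null"]] <- take(max(1L, min(100L, floor(n_auto / 10))))
    }
    for (nm in names(set_defs))
      for (g in set_defs[[nm]])
        membership[[g]] <- c(membership[[g]], nm)

    truth <- data.frame(
      gene_id = gene_ids,
      true_log2fd = true_fd,
      sexchrom_class = fclass,
      sets = vapply(membership, function(x)
        if (is.null(x)) "" else paste(x, collapse = ","), character(1L)),
      stringsAsFactors = FALSE)
  } else {
    if (!all(c("gene_id", "true_log2fd", "sexchrom_class", "sets") %in%
             colnames(truth)))
      .sd_stop("truth table must have gene_id, true_log2fd, sexchrom_class, sets")
    if (nrow(truth) != n_g)
      .sd_stop("truth table has ", nrow(truth), " genes but config expects ", n_g)
    gene_ids <- truth$gene_id
    fclass <- truth$sexchrom_class
    true_fd <- truth$true_log2fd
    memb <- strsplit(truth$sets, ",", fixed = TRUE)
    all_sets <- unique(unlist(memb))
    all_sets <- all_sets[nzchar(all_sets)]
    set_defs <- lapply(stats::setNames(all_sets, all_sets), function(nm)
      gene_ids[vapply(memb, function(m) nm %in% m, logical(1L))])
  }

  # sample layout: balanced, one sample per subject x region
  n_s <- config$n_subjects_per_sex
  n_r <- config$n_regions_per_subject
  subjects <- c(sprintf("f%02d", seq_len(n_s)), sprintf("m%02d", seq_len(n_s)))
  subj_sex <- rep(c("female", "male"), each = n_s)
  regions <- sprintf("R%d", seq_len(n_r))
  lobes <- rep_len(c("frontal", "temporal", "parietal"), n_r)
  samples <- data.frame(
    sample_id = paste(rep(subjects, each = n_r), rep(regions, 2 * n_s), sep = "_"),
    sex = rep(subj_sex, each = n_r),
    subject_id = rep(subjects, each = n_r),
    region = rep(regions, 2 * n_s),
    lobe = rep(lobes, 2 * n_s),
    stringsAsFactors = FALSE)
  n_samp <- nrow(samples)

  # covariates: age/PMI/pH vary by subject, RIN by sample
  age <- stats::setNames(stats::runif(2 * n_s, 13, 40), subjects)
  pmi <- stats::setNames(stats::runif(2 * n_s, 5, 30), subjects)
  ph <- stats::setNames(stats::runif(2 * n_s, 6.0, 7.0), subjects)
  samples$age <- unname(age[samples$subject_id])
  samples$RIN <- stats::runif(n_samp, 7, 10)
  samples$PMI <- unname(pmi[samples$subject_id])
  samples$pH <- unname(ph[samples$subject_id])

  sex_sign <- ifelse(samples$sex == "male", +0.5, -0.5)
  baseline <- stats::runif(n_g, config$baseline_mean_range[1L],
                           config$baseline_mean_range[2L])
  baseline[fclass != "autosomal"] <- (6.0 + 0.05) / 2

  s2 <- sample_gene_variances(n_g, config$d0, config$s0_sq)
  rho <- config$rho_subject
  tau2 <- rho / (1 - rho) * s2  # subject-intercept variance per gene

  y <- outer(baseline, rep(1, n_samp)) + outer(true_fd, sex_sign)

  cs <- config$covariate_effect_scale
  if (cs > 0) {
    num_cov <- cbind(age = samples$age, RIN = samples$RIN,
                     PMI = samples$PMI, pH = samples$pH)
    num_cov <- scale(num_cov)
    lobe_levels <- unique(lobes)
    lobe_ind <- vapply(lobe_levels, function(l) as.numeric(samples$lobe == l),
                       numeric(n_samp))
    if (is.null(dim(lobe_ind))) lobe_ind <- matrix(lobe_ind, nrow = n_samp)
    num_cov[is.nan(num_cov)] <- 0  # constant covariate in tiny cohorts
    covmat <- cbind(num_cov, lobe_ind)
    coefs <- matrix(stats::rnorm(n_g * ncol(covmat), 0, cs), nrow = n_g)
    y <- y + coefs %*% t(covmat)
  }

  subj_idx <- match(samples$subject_id, subjects)
  subj_int <- matrix(stats::rnorm(n_g * length(subjects)), nrow = n_g) * sqrt(tau2)
  y <- y + subj_int[, subj_idx]
  y <- y + matrix(stats::rnorm(n_g * n_samp), nrow = n_g) * sqrt(s2)
  dimnames(y) <- list(gene_ids, samples$sample_id)

  sets <- lapply(set_defs, function(g)
    list(genes = g, background_category = "protein_coding"))
  collection <- gene_set_collection(
    sets = sets, backgrounds = list(protein_coding = gene_ids))

  list(expression = y, samples = samples, sets = collection, truth = truth)
}

#' Write a cohort to disk as a plain-text fixture bundle
#'
#' Emits `expression.tsv`, `samples.tsv`, `sets.gmt` and `truth.tsv` in
#' `dir`, all round-trippable through the package readers.
#'
#' @param cohort List as returned by [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture_bundle <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             sets = file.path(dir, "sets.gmt"),
             truth = file.path(dir, "truth.tsv"))
  write_expression(cohort$expression, paths[["expression"]])
  write_sample_table(cohort$samples, paths[["samples"]])
  write_gmt(cohort$sets, paths[["sets"]])
  utils::write.table(cohort$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(paths)
}

#' Read a cohort truth table written by [write_fixture_bundle()]
#'
#' @param path Path to `truth.tsv`.
#' @return Data.frame with columns `gene_id`, `true_log2fd`,
#'   `sexchrom_class`, `sets`.
#' @export
read_truth_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, na.strings = NULL)
  need <- c("gene_id", "true_log2fd", "sexchrom_class", "sets")
  if (!all(need %in% colnames(df)))
    .sd_stop("truth table missing columns: ",
             paste(setdiff(need, colnames(df)), collapse = ", "))
  df$sets[is.na(df$sets)] <- ""
  df
}
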