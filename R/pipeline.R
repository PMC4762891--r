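#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent named list), fills in
#' the reference defaults (fold-difference threshold 1.2; p-value tiers
#' 0.005 / 0.01 / 0.05; outlier z 2.5) and collects every violation before
#' reporting, so a bad file yields one complete error list. Unknown keys
#' warn but do not fail.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A resolved configuration list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) .sd_stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) .sd_stop("config must be a file path or a named list")

  defaults <- list(
    stages = c("simulate", "preprocess", "de", "enrich", "concord"),
    out_dir = "sexdimorph_out",
    seed = 1L,
    expression = NULL, samples = NULL, gmt = NULL,
    simulate = list(),
    preprocess = list(mode = "rnaseq", z_threshold = 2.5, match = TRUE),
    de = list(covariates = NULL, fd_threshold = 1.2,
              p_tiers = c(0.005, 0.01, 0.05)),
    enrich = list(n_fisher_tests = NULL, n_binom_tests = NULL))

  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config[intersect(names(config), names(defaults))])

  errors <- character()
  bad_stage <- setdiff(cfg$stages, defaults$stages)
  if (length(bad_stage))
    errors <- c(errors, paste0("unknown stage(s): ", paste(bad_stage, collapse = ", ")))
  if (!.is_num1(cfg$seed) || cfg$seed != round(cfg$seed))
    errors <- c(errors, "seed must be an integer")
  fd <- cfg$de$fd_threshold
  if (!.is_num1(fd) || fd <= 1)
    errors <- c(errors, "de.fd_threshold must exceed 1")
  tiers <- cfg$de$p_tiers
  if (!is.numeric(tiers) || !length(tiers) || any(tiers <= 0 | tiers >= 1))
    errors <- c(errors, "de.p_tiers must lie in (0, 1)")
  z <- cfg$preprocess$z_threshold
  if (!.is_num1(z) || z <= 0)
    errors <- c(errors, "preprocess.z_threshold must be positive")

  # without the simulate stage, the inputs must exist up front
  if (!"simulate" %in% cfg$stages) {
    for (key in c("expression", "samples")) {
      if (is.null(cfg[[key]]))
        errors <- c(errors, paste0("config requires '", key, "' when simulate is not run"))
      else if (!file.exists(cfg[[key]]))
        errors <- c(errors, paste0(key, " file not found: ", cfg[[key]]))
    }
    if ("enrich" %in% cfg$stages) {
      if (is.null(cfg$gmt))
        errors <- c(errors, "config requires 'gmt' when enrich runs without simulate")
      else if (!file.exists(cfg$gmt))
        errors <- c(errors, paste0("gmt file not found: ", cfg$gmt))
    }
  }
  if (length(errors))
    .sd_stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}

# internal: write a TSV deterministically (fixed column order, full precision)
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  path
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes the selected stages in fixed order — simulate, preprocess,
#' differential expression, enrichment, concordance — writing each stage's
#' outputs under `out_dir` and finishing with a manifest
#' (`manifest.tsv`) that lists every artifact with its MD5 checksum.
#' Identical configuration and seed give byte-identical artifacts, hence
#' identical checksums. When the concordance stage is selected together
#' with simulation, a replication cohort is drawn from the same ground
#' truth (seed offset by 1000) and analysed in parallel.
#'
#' @param config Path to a YAML file or a named list; see
#'   [validate_config()].
#' @return Invisibly, the manifest data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  emit <- function(path) artifacts <<- c(artifacts, path)
  stage <- function(name) message("[sexdimorph] stage: ", name)

  expr <- samples <- collection <- truth <- NULL
  if ("simulate" %in% cfg$stages) {
    stage("simulate")
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    if (!is.null(sim_args$planted_sets))
      sim_args$planted_sets <- lapply(sim_args$planted_sets, as.list)
    scfg <- do.call(sim_config, sim_args)
    cohort <- generate_cohort(scfg)
    expr <- cohort$expression; samples <- cohort$samples
    collection <- cohort$sets; truth <- cohort$truth
    paths <- write_fixture_bundle(cohort, file.path(cfg$out_dir, "cohort"))
    for (p in paths) emit(p)
  } else {
    expr <- read_expression(cfg$expression)
    samples <- read_sample_table(cfg$samples)
    if (!is.null(cfg$gmt)) {
      collection <- read_gmt(cfg$gmt)
      # default background: every gene in the matrix
      if (!length(collection$backgrounds))
        collection <- gene_set_collection(
          sets = collection$sets,
          backgrounds = list(protein_coding = rownames(expr)))
    }
  }

  if ("preprocess" %in% cfg$stages) {
    stage("preprocess")
    pp <- preprocess_pipeline(
      expr, samples,
      filter = filter_spec(mode = cfg$preprocess$mode),
      outliers = outlier_spec(z_threshold = cfg$preprocess$z_threshold),
      match = isTRUE(cfg$preprocess$match))
    expr <- pp$matrix
    samples <- pp$samples
    emit(write_expression(expr, file.path(cfg$out_dir, "expression_preprocessed.tsv")))
    emit(.write_tsv(pp$removed_outliers, file.path(cfg$out_dir, "removed_outliers.tsv")))
    writeLines(pp$log, file.path(cfg$out_dir, "preprocess_log.txt"))
    emit(file.path(cfg$out_dir, "preprocess_log.txt"))
  }

  de_res <- NULL
  if ("de" %in% cfg$stages) {
    stage("de")
    covars <- cfg$de$covariates %||%
      intersect(c("RIN", "age", "PMI", "lobe", "pH"), colnames(samples))
    de_res <- run_sex_de(expr, samples, covariates = covars,
                         fd_threshold = cfg$de$fd_threshold,
                         p_tiers = cfg$de$p_tiers)
    emit(write_de_table(de_res$table, file.path(cfg$out_dir, "de_table.tsv")))
    params <- data.frame(param = c("d0", "s0_sq", "rho", "seed"),
                         value = c(de_res$params$d0, de_res$params$s0_sq,
                                   de_res$params$rho, cfg$seed))
    emit(.write_tsv(params, file.path(cfg$out_dir, "de_params.tsv")))
  }

  if ("enrich" %in% cfg$stages) {
    stage("enrich")
    if (is.null(de_res)) .sd_stop("enrich stage requires the de stage")
    if (is.null(collection)) .sd_stop("enrich stage requires gene sets")
    report <- run_enrichment_suite(
      de_res$table, collection,
      p_tiers = cfg$de$p_tiers,
      n_fisher_tests = cfg$enrich$n_fisher_tests,
      n_binom_tests = cfg$enrich$n_binom_tests)
    emit(write_enrichment_report(report, file.path(cfg$out_dir, "enrichment.tsv")))
  }

  if ("concord" %in% cfg$stages) {
    stage("concord")
    if (is.null(de_res)) .sd_stop("concord stage requires the de stage")
    if (is.null(truth)) {
      message("[sexdimorph] concord skipped: needs a simulated truth to replicate")
    } else {
      sim_args <- cfg$simulate
      sim_args$seed <- cfg$seed + 1000L
      if (!is.null(sim_args$planted_sets))
        sim_args$planted_sets <- lapply(sim_args$planted_sets, as.list)
      rep_cohort <- generate_cohort(do.call(sim_config, sim_args), truth = truth)
      rep_de <- run_sex_de(rep_cohort$expression, rep_cohort$samples,
                           fd_threshold = cfg$de$fd_threshold,
                           p_tiers = cfg$de$p_tiers)
      cs <- concordance_summary(de_res$table, rep_de$table,
                                collection = collection,
                                fd_threshold = cfg$de$fd_threshold)
      summary_df <- data.frame(
        metric = c("fd_r", "fd_p", "n_shared", "n_overlap_male", "n_overlap_female"),
        value = c(cs$fd_correlation$r, cs$fd_correlation$p,
                  cs$fd_correlation$n, length(cs$overlap_male),
                  length(cs$overlap_female)))
      emit(.write_tsv(summary_df, file.path(cfg$out_dir, "concordance.tsv")))
      if (!is.null(cs$set_enrichment))
        emit(.write_tsv(cs$set_enrichment,
                        file.path(cfg$out_dir, "concordance_sets.tsv")))
    }
  }

  manifest <- data.frame(
    file = vapply(artifacts, function(p)
      sub(paste0("^", cfg$out_dir, "/?"), "", p), character(1L)),
    md5 = unname(tools::md5sum(artifacts)),
    stringsAsFactors = FALSE, row.names = NULL)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  .write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  invisible(manifest)
}
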