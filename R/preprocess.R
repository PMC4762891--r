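#' Expression-filter specification
#'
#' A gene is dropped when the fraction of samples expressing it below
#' `level_threshold` exceeds `fraction`, evaluated within each sex when
#' `per_sex` is set (drop if either sex fails). Defaults follow the two
#' platform conventions: RNA-seq (log2 value < 1 in more than 50% of male or
#' female samples) and expression array (log2 intensity < 6 in more than 80%).
#'
#' @param mode `"rnaseq"` or `"array"`; sets the default threshold/fraction.
#' @param level_threshold Log2 expression cutoff; overrides the mode default.
#' @param fraction Proportion of samples, in (0, 1]; strict `>` comparison.
#' @param per_sex Evaluate the rule within each sex separately.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(mode = c("rnaseq", "array"), level_threshold = NULL,
                        fraction = NULL, per_sex = TRUE) {
  mode <- match.arg(mode)
  level_threshold <- level_threshold %||% switch(mode, rnaseq = 1, array = 6)
  fraction <- fraction %||% switch(mode, rnaseq = 0.5, array = 0.8)
  if (!.is_num1(level_threshold)) .sd_stop("level_threshold must be finite")
  if (!.is_num1(fraction) || fraction <= 0 || fraction > 1)
    .sd_stop("fraction must lie in (0, 1]")
  structure(list(mode = mode, level_threshold = level_threshold,
                 fraction = fraction, per_sex = isTRUE(per_sex)),
            class = "filter_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Outlier-removal specification
#'
#' Samples whose mean inter-sample correlation falls more than `z_threshold`
#' standard deviations below the group mean are removed, in one or more
#' passes over different groupings (within each sex, then all samples
#' together), recomputing correlations after each pass.
#'
#' @param z_threshold Positive number of standard deviations (default 2.5).
#' @param passes Character vector of pass schemes, each `"within_sex"` or
#'   `"all"`, applied in order.
#' @return A list of class `outlier_spec`.
#' @export
outlier_spec <- function(z_threshold = 2.5, passes = c("within_sex", "all")) {
  if (!is.numeric(z_threshold) || length(z_threshold) != 1L ||
      is.na(z_threshold) || z_threshold <= 0)
    .sd_stop("z_threshold must be positive")
  if (!all(passes %in% c("within_sex", "all")))
    .sd_stop("passes must be 'within_sex' or 'all'")
  structure(list(z_threshold = z_threshold, passes = passes),
            class = "outlier_spec")
}

#' Remove non-expressed genes
#'
#' @param mat Expression matrix (genes x samples, log2 scale).
#' @param samples Sample table covering the matrix columns.
#' @param spec A [filter_spec()].
#' @return The matrix restricted to retained genes, original order kept.
#' @export
filter_nonexpressed <- function(mat, samples, spec = filter_spec()) {
  .check_expression(mat)
  stopifnot(inherits(spec, "filter_spec"))
  samples <- .align_samples(samples, mat)
  groups <- if (spec$per_sex) split(samples$sample_id, samples$sex) else
    list(all = samples$sample_id)
  if (spec$per_sex && length(groups) < 2L)
    .sd_stop("per-sex filtering needs both sexes present")
  if (any(lengths(groups) == 0L)) .sd_stop("empty sex stratum")
  drop <- rep(FALSE, nrow(mat))
  for (ids in groups) {
    frac_low <- rowMeans(mat[, ids, drop = FALSE] < spec$level_threshold)
    drop <- drop | (frac_low > spec$fraction)  # strict: exactly at cutoff kept
  }
  mat[!drop, , drop = FALSE]
}

# internal: subset/validate sample table against matrix columns
.align_samples <- function(samples, mat) {
  .check_sample_table(samples)
  miss <- setdiff(colnames(mat), samples$sample_id)
  if (length(miss))
    .sd_stop("samples missing from sample table: ", paste(miss, collapse = ", "))
  samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
}

#' Remove low-correlation outlier samples
#'
#' For each pass, every sample's mean product-moment correlation with the
#' other samples in its group is computed; samples falling more than
#' `z_threshold` standard deviations below the group mean of these means are
#' removed. Only the low side is flagged: an unusually high mean correlation
#' cannot indicate a degraded sample.
#'
#' @param mat Expression matrix.
#' @param samples Sample table covering the matrix columns.
#' @param spec An [outlier_spec()].
#' @return List with `matrix` (outliers dropped) and `removed`, a data.frame
#'   of `sample_id` and the `pass` that removed it.
#' @export
remove_outliers <- function(mat, samples, spec = outlier_spec()) {
  .check_expression(mat)
  stopifnot(inherits(spec, "outlier_spec"))
  removed <- list()
  for (p in seq_along(spec$passes)) {
    scheme <- spec$passes[[p]]
    st <- .align_samples(samples, mat)
    groups <- if (scheme == "within_sex") split(st$sample_id, st$sex) else
      list(all = st$sample_id)
    drop_ids <- character()
    for (ids in groups) {
      if (length(ids) < 3L)
        .sd_stop("outlier pass '", scheme, "' needs at least 3 samples per group")
      cm <- stats::cor(mat[, ids, drop = FALSE])
      mean_cor <- (rowSums(cm) - 1) / (length(ids) - 1)
      s <- stats::sd(mean_cor)
      if (!is.finite(s) || s == 0) next  # all samples identical
      z <- (mean_cor - mean(mean_cor)) / s
      drop_ids <- c(drop_ids, ids[z < -spec$z_threshold])
    }
    if (length(drop_ids)) {
      removed[[length(removed) + 1L]] <- data.frame(
        sample_id = drop_ids,
        pass = paste0(p, ":", scheme), stringsAsFactors = FALSE)
      mat <- mat[, setdiff(colnames(mat), drop_ids), drop = FALSE]
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(sample_id = character(), pass = character(),
               stringsAsFactors = FALSE)
  list(matrix = mat, removed = removed)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample onto the common reference distribution given by the
#' per-rank mean of the sorted columns. Tied values within a sample receive
#' the mean of the reference values over their tied ranks, so the operation
#' is deterministic and idempotent.
#'
#' @param mat Expression matrix with at least 2 samples.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  .check_expression(mat)
  if (ncol(mat) < 2L) .sd_stop("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(mat, 2L, sort))
  out <- mat
  n <- nrow(mat)
  for (j in seq_len(ncol(mat))) {
    o <- order(mat[, j])
    sx <- mat[o, j]
    col <- numeric(n)
    i <- 1L
    while (i <= n) {
      k <- i
      while (k < n && sx[k + 1L] == sx[i]) k <- k + 1L
      col[o[i:k]] <- mean(ref[i:k])
      i <- k + 1L
    }
    out[, j] <- col
  }
  out
}

#' Match samples across sexes by region and age
#'
#' Balances the cohort by pairing every sample of the minority sex with one
#' unused sample of the majority sex from the same region, greedily in
#' ascending order of absolute age difference (ties broken by sample ID so
#' the pairing is deterministic). Minority samples with no region-compatible
#' partner left are dropped and reported.
#'
#' @param samples Sample table with `sex`, `region` and `age` columns.
#' @return List with `selected` (character vector of retained sample IDs,
#'   equal counts per sex), `pairs` (data.frame of matched pairs with age
#'   difference) and `dropped` (minority sample IDs left unmatched).
#' @export
match_samples <- function(samples) {
  .check_sample_table(samples)
  if (!all(c("region", "age") %in% colnames(samples)))
    .sd_stop("match_samples needs region and age columns")
  counts <- table(samples$sex)
  if (length(counts) < 2L) .sd_stop("both sexes must be present")
  # reference sex = the smaller side (ties: male, the side females are matched to)
  minority <- if (counts[["male"]] <= counts[["female"]]) "male" else "female"
  minor <- samples[samples$sex == minority, , drop = FALSE]
  major <- samples[samples$sex != minority, , drop = FALSE]

  cand <- merge(minor[, c("sample_id", "region", "age")],
                major[, c("sample_id", "region", "age")],
                by = "region", suffixes = c("_minor", "_major"))
  if (nrow(cand)) {
    cand$age_diff <- abs(cand$age_minor - cand$age_major)
    cand <- cand[order(cand$age_diff, cand$sample_id_minor,
                       cand$sample_id_major), , drop = FALSE]
  }
  used_minor <- character(); used_major <- character()
  pairs <- list()
  for (i in seq_len(nrow(cand))) {
    a <- cand$sample_id_minor[i]; b <- cand$sample_id_major[i]
    if (a %in% used_minor || b %in% used_major) next
    used_minor <- c(used_minor, a); used_major <- c(used_major, b)
    pairs[[length(pairs) + 1L]] <- data.frame(
      minority = a, majority = b, region = cand$region[i],
      age_diff = cand$age_diff[i], stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(minority = character(), majority = character(),
               region = character(), age_diff = numeric(),
               stringsAsFactors = FALSE)
  dropped <- setdiff(minor$sample_id, used_minor)
  list(selected = sort(c(used_minor, used_major)),
       pairs = pairs, dropped = dropped)
}

#' Run the full preprocessing pipeline
#'
#' Fixed stage order: expression filter, outlier passes, quantile
#' normalization, sex-balanced sample matching, then a second expression
#' filter on the matched cohort (matching changes the sample set, so the
#' expressed-gene universe is re-derived).
#'
#' @param mat Expression matrix.
#' @param samples Sample table.
#' @param filter A [filter_spec()].
#' @param outliers An [outlier_spec()], or `NULL` to skip outlier removal.
#' @param match Logical; balance the sexes by region/age matching.
#' @return List with `matrix`, `samples` (rows for retained samples),
#'   `removed_outliers`, `dropped_unmatched` and `log` (character vector of
#'   stage summaries).
#' @export
preprocess_pipeline <- function(mat, samples, filter = filter_spec(),
                                outliers = outlier_spec(), match = TRUE) {
  log <- character()
  n0 <- nrow(mat)
  mat <- filter_nonexpressed(mat, samples, filter)
  log <- c(log, sprintf("filter: %d of %d genes retained", nrow(mat), n0))

  removed <- data.frame(sample_id = character(), pass = character())
  if (!is.null(outliers)) {
    out <- remove_outliers(mat, samples, outliers)
    mat <- out$matrix
    removed <- out$removed
    log <- c(log, sprintf("outliers: %d sample(s) removed", nrow(removed)))
  }

  mat <- quantile_normalize(mat)
  log <- c(log, "quantile normalization applied")

  dropped <- character()
  if (isTRUE(match)) {
    st <- .align_samples(samples, mat)
    m <- match_samples(st)
    dropped <- m$dropped
    mat <- mat[, intersect(colnames(mat), m$selected), drop = FALSE]
    log <- c(log, sprintf("matching: %d samples retained (%d unmatched dropped)",
                          ncol(mat), length(dropped)))
    n1 <- nrow(mat)
    mat <- filter_nonexpressed(mat, .align_samples(samples, mat), filter)
    log <- c(log, sprintf("re-filter: %d of %d genes retained", nrow(mat), n1))
  }

  list(matrix = mat,
       samples = .align_samples(samples, mat),
       removed_outliers = removed,
       dropped_unmatched = dropped,
       log = log)
}
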