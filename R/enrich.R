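#' Resolve the background gene universe for a category
#'
#' Expression-dependent categories (`protein_coding` and any
#' `source_publication:<tag>`) are intersected with the expressed-gene
#' universe; the genome-wide one-to-one orthologue category
#' (`orthologue_1to1`) is returned as-is, since it is defined independently
#' of what is expressed in the data set at hand.
#'
#' @param category Background category name registered in the collection.
#' @param collection A [gene_set_collection()] with backgrounds.
#' @param expressed_genes Character vector of expressed gene IDs.
#' @return Character vector of background gene IDs.
#' @export
build_background <- function(category, collection, expressed_genes) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!category %in% names(collection$backgrounds))
    .sd_stop("unknown background category: ", category)
  bg <- collection$backgrounds[[category]]
  if (category != "orthologue_1to1") {
    bg <- intersect(bg, expressed_genes)
    if (length(bg) == 0L)
      .sd_stop("background '", category, "' is empty after intersection with expressed genes")
  }
  bg
}

# internal: exact two-sided hypergeometric p for a 2x2 table.
# Sums all point probabilities not exceeding that of the observed table,
# with a 1e-7 relative tolerance on the comparison.
.fisher_p_twosided <- function(a, b, c, d) {
  m <- a + b          # set size within background
  K <- a + c          # DE genes within background
  N <- a + b + c + d
  supp <- max(0L, K - (N - m)):min(K, m)
  probs <- stats::dhyper(supp, m, N - m, K)
  p_obs <- probs[supp == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Two-sided Fisher's exact test of set / DE-gene overlap
#'
#' Counts are formed entirely within the background universe:
#' `a` = set and DE, `b` = set not DE, `c` = DE not in set, `d` = neither.
#' Reports both the sample odds ratio `a*d/(b*c)` and the fold of expected
#' `(a/(a+b)) / ((a+c)/N)`, alongside the exact two-sided p-value under the
#' hypergeometric null.
#'
#' @param set_genes Genes of the annotation set.
#' @param de_genes DE genes (one direction, one tier).
#' @param background Background gene universe.
#' @param set_name Label used in errors and the result.
#' @return One-row data.frame: `set`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `fold_of_expected`, `p`.
#' @export
fisher_enrichment <- function(set_genes, de_genes, background,
                              set_name = "set") {
  if (length(background) == 0L) .sd_stop("empty background")
  set_bg <- intersect(set_genes, background)
  if (length(set_bg) == 0L)
    .sd_stop("set '", set_name, "' is disjoint from its background")
  de_bg <- intersect(de_genes, background)
  a <- length(intersect(set_bg, de_bg))
  b <- length(set_bg) - a
  c <- length(de_bg) - a
  d <- length(background) - a - b - c
  num <- as.numeric(a) * d
  den <- as.numeric(b) * c
  odds <- if (den > 0) num / den else if (num > 0) Inf else NaN
  N <- a + b + c + d
  fold <- if (a + c == 0L) NaN else (a / (a + b)) / ((a + c) / N)
  data.frame(set = set_name, a = a, b = b, c = c, d = d,
             odds_ratio = odds, fold_of_expected = fold,
             p = .fisher_p_twosided(a, b, c, d),
             stringsAsFactors = FALSE)
}

#' Bonferroni-adjust Fisher enrichment results
#'
#' The two directions tested against each annotation set share one
#' correction: `n_tests` defaults to twice the number of distinct sets, and
#' the adjustment is applied within each p-value tier.
#'
#' @param results Data.frame of Fisher results with columns `p` and
#'   (optionally) `tier`.
#' @param n_tests Number of tests to correct for within each tier.
#' @return `results` with a `p_adj` column (`min(1, p * n_tests)`).
#' @export
adjust_fisher <- function(results, n_tests = NULL) {
  if (is.null(n_tests))
    n_tests <- 2L * length(unique(results$set))
  if (!.is_count(n_tests)) .sd_stop("n_tests must be a positive integer")
  results$p_adj <- .bonf(results$p, n_tests)
  results
}

# internal: exact two-sided binomial p by summing outcome probabilities
# not exceeding that of the observed count (1e-7 relative tolerance).
.binom_p_twosided <- function(k, n, prob) {
  probs <- stats::dbinom(0:n, n, prob)
  min(1, sum(probs[probs <= probs[k + 1L] * (1 + 1e-7)]))
}

# internal: exact Clopper-Pearson 95% CI for a proportion
.clopper_pearson <- function(k, n, conf = 0.95) {
  alpha <- 1 - conf
  lo <- if (k == 0L) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo, hi)
}

#' Threshold-free directional binomial shift test
#'
#' Classifies every gene of a set (restricted to its background, excluding
#' genes with `log2FD` exactly 0) as male-higher or female-higher at any
#' p-value, and tests the male-higher count against the background's
#' male-higher proportion with an exact two-sided binomial test. The shift
#' is the set's male-higher proportion minus the background's, and an exact
#' Clopper-Pearson 95% CI accompanies the set proportion.
#'
#' @param set_genes Genes of the annotation set.
#' @param de_table DE table with `gene` and `log2FD` columns (any p-value;
#'   no thresholding is applied).
#' @param background Background gene universe.
#' @param set_name Label used in errors and the result.
#' @param exclude_set_from_background Drop the set's own genes from the
#'   background proportion; off by default (the curated backgrounds contain
#'   their sets).
#' @return One-row data.frame: `set`, `n_set`, `k_male`, `prop`, `p_bg`,
#'   `shift`, `ci_lo`, `ci_hi`, `p`.
#' @export
binomial_shift <- function(set_genes, de_table, background,
                           set_name = "set",
                           exclude_set_from_background = FALSE) {
  if (length(background) == 0L) .sd_stop("empty background")
  fd <- de_table$log2FD[match(background, de_table$gene)]
  informative <- !is.na(fd) & fd != 0
  bg_genes <- background[informative]
  bg_fd <- fd[informative]

  in_set <- bg_genes %in% set_genes
  n_set <- sum(in_set)
  if (n_set == 0L)
    .sd_stop("set '", set_name, "' has no informative genes in its background")
  k_male <- sum(bg_fd[in_set] > 0)

  bg_mask <- if (exclude_set_from_background) !in_set else rep(TRUE, length(bg_genes))
  if (!any(bg_mask)) .sd_stop("background empty after excluding set '", set_name, "'")
  p_bg <- mean(bg_fd[bg_mask] > 0)

  ci <- .clopper_pearson(k_male, n_set)
  data.frame(set = set_name, n_set = n_set, k_male = k_male,
             prop = k_male / n_set, p_bg = p_bg,
             shift = k_male / n_set - p_bg,
             ci_lo = ci[1L], ci_hi = ci[2L],
             p = .binom_p_twosided(k_male, n_set, p_bg),
             stringsAsFactors = FALSE)
}

#' Bonferroni-adjust binomial shift results
#'
#' @param results Data.frame of shift results with a `p` column.
#' @param n_sets Number of sets tested; defaults to the number of rows.
#' @return `results` with a `p_adj` column.
#' @export
adjust_binomial <- function(results, n_sets = NULL) {
  if (is.null(n_sets)) n_sets <- nrow(results)
  if (!.is_count(n_sets)) .sd_stop("n_sets must be a positive integer")
  results$p_adj <- .bonf(results$p, n_sets)
  results
}

#' Run the dual over-representation analysis over a collection
#'
#' For every set in the collection: two-sided Fisher tests of overlap with
#' male-DE and female-DE genes at each p-value tier (Bonferroni-adjusted for
#' sets x 2 directions within each tier), plus one threshold-free binomial
#' shift test (Bonferroni-adjusted for the number of sets). Backgrounds are
#' resolved per set category via [build_background()].
#'
#' @param de_table Labelled DE table from [call_sex_de()] / [run_sex_de()].
#' @param collection A [gene_set_collection()] with backgrounds.
#' @param expressed_genes Expressed-gene universe (default: all genes in the
#'   DE table).
#' @param p_tiers Tiers to test; must match columns present in `de_table`.
#' @param n_fisher_tests,n_binom_tests Optional overrides of the Bonferroni
#'   denominators (defaults: 2 x number of sets, and number of sets).
#' @param alpha Adjusted significance cutoff for the `significant` flags.
#' @return List of class `enrichment_report` with data.frames `fisher`
#'   (set x direction x tier rows) and `shift` (one row per set).
#' @export
run_enrichment_suite <- function(de_table, collection,
                                 expressed_genes = de_table$gene,
                                 p_tiers = c(0.005, 0.01, 0.05),
                                 n_fisher_tests = NULL,
                                 n_binom_tests = NULL,
                                 alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  set_names <- names(collection$sets)
  if (!length(set_names)) .sd_stop("collection has no sets")
  n_fisher_tests <- n_fisher_tests %||% (2L * length(set_names))
  n_binom_tests <- n_binom_tests %||% length(set_names)

  fisher_rows <- list(); shift_rows <- list()
  for (nm in set_names) {
    s <- collection$sets[[nm]]
    bg <- build_background(s$background_category, collection, expressed_genes)
    for (alpha_tier in sort(p_tiers)) {
      col <- .tier_col(alpha_tier)
      if (!col %in% colnames(de_table))
        .sd_stop("DE table lacks tier column ", col, " (set '", nm, "')")
      for (dir in c("male-DE", "female-DE")) {
        de_genes <- de_table$gene[de_table[[col]] == dir]
        row <- fisher_enrichment(s$genes, de_genes, bg, set_name = nm)
        row$direction <- dir
        row$tier <- alpha_tier
        fisher_rows[[length(fisher_rows) + 1L]] <- row
      }
    }
    shift_rows[[length(shift_rows) + 1L]] <-
      binomial_shift(s$genes, de_table, bg, set_name = nm)
  }

  fisher <- do.call(rbind, fisher_rows)
  fisher <- do.call(rbind, lapply(split(fisher, fisher$tier),
                                  adjust_fisher, n_tests = n_fisher_tests))
  rownames(fisher) <- NULL
  fisher <- fisher[order(fisher$set, fisher$tier, fisher$direction), ,
                   drop = FALSE]
  fisher$significant <- fisher$p_adj < alpha

  shift <- adjust_binomial(do.call(rbind, shift_rows), n_sets = n_binom_tests)
  shift$significant <- shift$p_adj < alpha
  rownames(shift) <- NULL

  structure(list(fisher = fisher, shift = shift), class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("enrichment_report:", nrow(x$fisher), "Fisher rows,",
      nrow(x$shift), "shift rows\n")
  cat("  significant Fisher overlaps:", sum(x$fisher$significant), "\n")
  cat("  significant shifts:", sum(x$shift$significant), "\n")
  invisible(x)
}

#' Write an enrichment report as one long TSV
#'
#' Fisher and shift rows are stacked with a `test` discriminator column;
#' columns not applicable to a test are `NA`.
#'
#' @param report An `enrichment_report` from [run_enrichment_suite()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(report, path) {
  stopifnot(inherits(report, "enrichment_report"))
  f <- report$fisher
  f$test <- "fisher"
  s <- report$shift
  s$test <- "binomial_shift"
  cols <- c("set", "test", "direction", "tier", "a", "b", "c", "d",
            "odds_ratio", "fold_of_expected", "n_set", "k_male", "prop",
            "p_bg", "shift", "ci_lo", "ci_hi", "p", "p_adj", "significant")
  for (col in setdiff(cols, colnames(f))) f[[col]] <- NA
  for (col in setdiff(cols, colnames(s))) s[[col]] <- NA
  long <- rbind(f[, cols], s[, cols])
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
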