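#' Correlate fold differences (or expression levels) across two analyses
#'
#' Product-moment correlation of per-gene `log2FD` (or mean expression)
#' between two DE tables over their shared genes, optionally restricted to
#' a subset; the p-value comes from the usual t transform with `n - 2`
#' degrees of freedom.
#'
#' @param tableA,tableB DE tables with `gene` and `log2FD` columns.
#' @param genes Optional gene subset (e.g. the sex-DE genes of one
#'   analysis); default uses all shared genes.
#' @param value Column to correlate: `"log2FD"` (default) or `"mean_expr"`.
#' @return List with `r`, `p`, `n` and `excluded` (genes requested but
#'   missing from either table).
#' @export
correlate_fd <- function(tableA, tableB, genes = NULL, value = "log2FD") {
  for (tb in list(tableA, tableB))
    if (!all(c("gene", value) %in% colnames(tb)))
      .sd_stop("both tables need columns gene and ", value)
  want <- genes %||% intersect(tableA$gene, tableB$gene)
  shared <- intersect(intersect(want, tableA$gene), tableB$gene)
  excluded <- setdiff(want, shared)
  if (length(shared) < 3L)
    .sd_stop("need at least 3 shared genes (have ", length(shared), ")")
  a <- tableA[[value]][match(shared, tableA$gene)]
  b <- tableB[[value]][match(shared, tableB$gene)]
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared),
       excluded = excluded)
}

#' Genes replicating a directional fold difference in two analyses
#'
#' Returns the genes whose fold difference passes the threshold in the
#' stated direction in BOTH tables (male-higher: `FD >= fd_threshold`;
#' female-higher: `FD <= 1/fd_threshold`), in deterministic gene-ID order.
#'
#' @param tableA,tableB DE tables with `gene` and `log2FD` columns.
#' @param fd_threshold Fold-difference threshold (default 1.2).
#' @param direction `"male-higher"` or `"female-higher"`.
#' @return Sorted character vector of gene IDs.
#' @export
replication_overlap <- function(tableA, tableB, fd_threshold = 1.2,
                                direction = c("male-higher", "female-higher")) {
  direction <- match.arg(direction)
  if (!.is_num1(fd_threshold) || fd_threshold <= 1)
    .sd_stop("fd_threshold must exceed 1")
  pass <- function(tb) {
    fd <- 2^tb$log2FD
    if (direction == "male-higher") tb$gene[fd >= fd_threshold]
    else tb$gene[fd <= 1 / fd_threshold]
  }
  sort(intersect(pass(tableA), pass(tableB)))
}

#' Fold enrichment of an annotation set within a gene list
#'
#' Fold enrichment is the set's frequency in the list over its frequency in
#' the background, with a hypergeometric upper-tail p-value; both the list
#' and the set are restricted to the background first.
#'
#' @param gene_list Gene list of interest (must lie within the background).
#' @param set_genes Annotation set.
#' @param background Background gene universe.
#' @return List with `overlap`, `fold` and `p`.
#' @export
fold_enrichment_in_list <- function(gene_list, set_genes, background) {
  gene_list <- intersect(gene_list, background)
  if (length(gene_list) == 0L) .sd_stop("gene list empty (within background)")
  set_bg <- intersect(set_genes, background)
  if (length(set_bg) == 0L) .sd_stop("set has no genes in the background")
  overlap <- length(intersect(gene_list, set_bg))
  fold <- (overlap / length(gene_list)) / (length(set_bg) / length(background))
  p <- stats::phyper(overlap - 1, length(set_bg),
                     length(background) - length(set_bg),
                     length(gene_list), lower.tail = FALSE)
  list(overlap = overlap, fold = fold, p = p)
}

#' Cross-dataset concordance summary
#'
#' Bundles the standard replication comparisons between two DE analyses:
#' fold-difference and expression-level correlations over shared genes, the
#' directional replication overlaps at a fold threshold, and per-set fold
#' enrichment of each annotation set within the male-higher overlap list
#' (background: genes tested in both analyses).
#'
#' @param tableA,tableB DE tables.
#' @param collection Optional [gene_set_collection()] whose sets are scored
#'   against the male-higher overlap.
#' @param fd_threshold Fold threshold for the overlap lists.
#' @return List with `fd_correlation`, `expr_correlation`, `overlap_male`,
#'   `overlap_female` and `set_enrichment` (data.frame or `NULL`).
#' @export
concordance_summary <- function(tableA, tableB, collection = NULL,
                                fd_threshold = 1.2) {
  fd_cor <- correlate_fd(tableA, tableB)
  expr_cor <- if (all(c("mean_expr") %in% colnames(tableA)) &&
                  "mean_expr" %in% colnames(tableB))
    correlate_fd(tableA, tableB, value = "mean_expr") else NULL
  ov_m <- replication_overlap(tableA, tableB, fd_threshold, "male-higher")
  ov_f <- replication_overlap(tableA, tableB, fd_threshold, "female-higher")

  set_enr <- NULL
  if (!is.null(collection) && length(ov_m)) {
    background <- intersect(tableA$gene, tableB$gene)
    rows <- list()
    for (nm in names(collection$sets)) {
      sg <- collection$sets[[nm]]$genes
      if (!length(intersect(sg, background))) next
      fe <- fold_enrichment_in_list(ov_m, sg, background)
      rows[[length(rows) + 1L]] <- data.frame(
        set = nm, overlap = fe$overlap, fold = fe$fold, p = fe$p,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) set_enr <- do.call(rbind, rows)
  }
  list(fd_correlation = fd_cor, expr_correlation = expr_cor,
       overlap_male = ov_m, overlap_female = ov_f,
       set_enrichment = set_enr)
}
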