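#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-separated file whose header row carries sample identifiers
#' (first field names the gene-ID column) and whose first column carries gene
#' identifiers. All body cells must be finite numbers on the log2 scale.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with gene IDs as rownames and sample IDs as
#'   colnames.
#' @export
#' @examples
#' d <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t1.5\t2", "g2\t0\t3.25"), d)
#' read_expression(d)
read_expression <- function(path) {
  if (!file.exists(path)) .sd_stop("expression file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           fill = FALSE, na.strings = NULL)
  if (ncol(tab) < 2L) .sd_stop("expression file needs a gene-ID column plus at least one sample: ", path)
  gene_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  if (anyDuplicated(gene_ids))
    .sd_stop("duplicate gene IDs in ", path, ": ",
             paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    .sd_stop("duplicate sample IDs in ", path, ": ",
             paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    .sd_stop("non-numeric expression value at gene '", gene_ids[bad[1L, 1L]],
             "', sample '", sample_ids[bad[1L, 2L]], "' in ", path)
  dimnames(vals) <- list(gene_ids, sample_ids)
  vals
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]; values are written with full precision so
#' the round trip is lossless to within 1e-9.
#'
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  .check_expression(mat)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

# internal: validate expression-matrix invariants
.check_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    .sd_stop("expression data must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    .sd_stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(mat))) .sd_stop("duplicate gene IDs")
  if (anyDuplicated(colnames(mat))) .sd_stop("duplicate sample IDs")
  if (!all(is.finite(mat))) .sd_stop("expression values must be finite")
  invisible(mat)
}

#' Read a per-sample metadata table from TSV
#'
#' Required columns: `sample_id`, `sex` (values `male`/`female`) and
#' `subject_id`; recognised optional columns are `region`, `lobe`, `age`,
#' `RIN`, `PMI` and `pH` (numeric except region/lobe; missing values are the
#' literal `NA`).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with one row per sample.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) .sd_stop("sample table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  .check_sample_table(df)
  for (col in intersect(c("age", "RIN", "PMI", "pH"), colnames(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]])))
      .sd_stop("non-numeric value in column '", col, "' of ", path)
    df[[col]] <- v
  }
  df
}

# internal: validate sample-table invariants
.check_sample_table <- function(df) {
  need <- c("sample_id", "sex", "subject_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) .sd_stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) .sd_stop("duplicate sample IDs in sample table")
  if (any(is.na(df$sex)) || any(is.na(df$subject_id)))
    .sd_stop("sex and subject_id may not be missing")
  if (!all(df$sex %in% c("male", "female")))
    .sd_stop("sex must be 'male' or 'female'")
  invisible(df)
}

#' Write a sample metadata table to TSV
#'
#' @param samples Data.frame as returned by [read_sample_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  .check_sample_table(samples)
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

# background categories the GMT description field is allowed to carry
.known_bg_categories <- function(extra = character()) {
  c("protein_coding", "orthologue_1to1", extra)
}

#' Construct a gene-set collection
#'
#' A collection holds named gene sets, each tagged with the background
#' category its enrichment should be judged against, plus the background
#' gene lists themselves (category name to gene-ID vector).
#'
#' @param sets Named list; each element a list with fields `genes`
#'   (character vector) and `background_category` (scalar string).
#' @param backgrounds Named list of character vectors, one per category
#'   referenced by the sets. May be empty at construction and filled later.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets = list(), backgrounds = list()) {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(names(sets) == ""))
      .sd_stop("gene set names must be unique and non-empty")
    for (nm in names(sets)) {
      s <- sets[[nm]]
      if (!is.list(s) || is.null(s$genes) || is.null(s$background_category))
        .sd_stop("set '", nm, "' needs fields 'genes' and 'background_category'")
      sets[[nm]]$genes <- unique(as.character(s$genes))
    }
  }
  if (length(backgrounds)) {
    if (is.null(names(backgrounds)) || anyDuplicated(names(backgrounds)))
      .sd_stop("background categories must be uniquely named")
    empty <- names(backgrounds)[lengths(backgrounds) == 0L]
    if (length(empty)) .sd_stop("empty background list: ", paste(empty, collapse = ", "))
    backgrounds <- lapply(backgrounds, function(g) unique(as.character(g)))
  }
  structure(list(sets = sets, backgrounds = backgrounds),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "set(s),",
      length(x$backgrounds), "background list(s)\n")
  for (nm in utils::head(names(x$sets), 10L))
    cat("  ", nm, ": ", length(x$sets[[nm]]$genes), " genes [",
        x$sets[[nm]]$background_category, "]\n", sep = "")
  if (length(x$sets) > 10L) cat("  ...\n")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, `name<TAB>description<TAB>gene1...`.
#' The description field is interpreted as the set's background category when
#' it matches a known tag (`protein_coding`, `orthologue_1to1`, or any
#' `source_publication:<tag>`); otherwise the default `protein_coding` is
#' assigned. Duplicated genes within a line are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()] carrying sets only (no backgrounds).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .sd_stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      .sd_stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    nm <- fields[[1L]]
    desc <- fields[[2L]]
    cat_ok <- desc %in% .known_bg_categories() ||
      startsWith(desc, "source_publication:")
    sets[[nm]] <- list(genes = unique(fields[-(1:2)]),
                       background_category = if (cat_ok) desc else "protein_coding")
  }
  gene_set_collection(sets = sets)
}

#' Write gene sets to a GMT file
#'
#' The description column carries each set's background category so a
#' collection round-trips through [read_gmt()].
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    paste(c(nm, s$background_category, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a static gene-ID mapping table
#'
#' Two-column TSV (`source_id`, `target_id`), the offline replacement for a
#' live annotation lookup.
#'
#' @param path Path to the TSV file.
#' @return Data.frame with columns `source_id`, `target_id`.
#' @export
read_id_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("source_id", "target_id") %in% colnames(df)))
    .sd_stop("ID map needs columns source_id and target_id: ", path)
  df
}

#' Translate gene identifiers in a collection through a static map
#'
#' Applies a source-to-target ID map to every set and background list.
#' The applied mapping is strictly one-to-one: sources listed more than once
#' and groups of sources that collide on one target are removed from the map
#' entirely, and any gene they would have translated is dropped and reported.
#' Genes with no mapping at all are likewise dropped and reported. Dropping
#' rather than merging keeps cross-source gene comparisons unambiguous.
#'
#' @param collection A [gene_set_collection()].
#' @param map Data.frame with columns `source_id`, `target_id`.
#' @return List with `collection` (translated) and `report`, a data.frame of
#'   dropped genes with columns `gene`, `where`, `reason`
#'   (`unmapped` or `collision`).
#' @export
map_ids <- function(collection, map) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!all(c("source_id", "target_id") %in% colnames(map)))
    .sd_stop("ID map needs columns source_id and target_id")
  src <- as.character(map$source_id)
  tgt <- as.character(map$target_id)
  dup_src <- src %in% src[duplicated(src)]
  multi_tgt <- tgt %in% tgt[duplicated(tgt)]
  collided <- unique(src[dup_src | multi_tgt])
  keep <- !(dup_src | multi_tgt)
  lookup <- stats::setNames(tgt[keep], src[keep])

  report <- list()
  translate <- function(genes, where) {
    hit <- genes %in% names(lookup)
    coll <- genes %in% collided
    unmapped <- !hit & !coll
    if (any(coll))
      report[[length(report) + 1L]] <<- data.frame(
        gene = genes[coll], where = where, reason = "collision",
        stringsAsFactors = FALSE)
    if (any(unmapped))
      report[[length(report) + 1L]] <<- data.frame(
        gene = genes[unmapped], where = where, reason = "unmapped",
        stringsAsFactors = FALSE)
    unique(unname(lookup[genes[hit]]))
  }

  sets <- collection$sets
  for (nm in names(sets)) sets[[nm]]$genes <- translate(sets[[nm]]$genes, nm)
  bgs <- collection$backgrounds
  for (nm in names(bgs)) bgs[[nm]] <- translate(bgs[[nm]], paste0("background:", nm))
  bgs <- bgs[lengths(bgs) > 0L]

  report <- if (length(report)) do.call(rbind, report) else
    data.frame(gene = character(), where = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(collection = gene_set_collection(sets = sets, backgrounds = bgs),
       report = report)
}
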