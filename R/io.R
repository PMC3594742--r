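# Expression matrix input, gene pre-filters, and tabular writers/readers.
# The universal container is a plain numeric matrix, genes in rows, with
# rownames = gene IDs and colnames = sample IDs.

#' Validate an expression matrix
#'
#' Checks the container convention used throughout the package: a finite
#' numeric matrix with unique, non-missing gene rownames and sample colnames,
#' and at least two samples.
#'
#' @param expr numeric matrix, genes x samples.
#' @return `expr`, invisibly, after validation.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    stop("duplicated gene IDs: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", "))
  if (anyDuplicated(colnames(expr)))
    stop("duplicated sample IDs: ",
         paste(unique(colnames(expr)[duplicated(colnames(expr))]), collapse = ", "))
  if (ncol(expr) < 2) stop("at least 2 samples are required")
  if (!all(is.finite(expr))) stop("expression values must be finite")
  invisible(expr)
}

#' Load an expression matrix from delimited text
#'
#' Reads a genes x samples (or transposed) table with a header row and a
#' leading label column. Duplicate IDs and non-numeric cells are reported as
#' errors naming the offenders.
#'
#' @param path file to read.
#' @param delimiter field separator (default tab).
#' @param genes_in_rows if `FALSE`, the file stores samples in rows and is
#'   transposed on load.
#' @return numeric matrix, genes x samples, IDs in file order.
#' @export
load_expression <- function(path, delimiter = "\t", genes_in_rows = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, sep = delimiter, header = TRUE, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicated IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("non-numeric value at row ", bad[1], ", column '",
             colnames(vals)[j], "': '", v[bad[1]], "'")
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (!genes_in_rows) m <- t(m)
  validate_expression(m)
  m
}

#' Filter genes on mean intensity and coefficient of variation
#'
#' Keeps genes whose mean intensity is strictly above the grand mean of
#' per-gene means (when `use_intensity_filter`), then genes whose coefficient
#' of variation sd/|mean| is strictly above `cv_min`. Genes with mean 0 are
#' excluded from the CV step (CV undefined) with a warning; negative means are
#' allowed (log-scale data) and CV uses |mean|.
#'
#' @param expr genes x samples matrix.
#' @param cv_min minimum coefficient of variation (default 0.05).
#' @param use_intensity_filter apply the above-average-intensity step first.
#' @return list with `expr` (filtered matrix) and `report`, a
#'   `gene_filter_report` with counts at each stage.
#' @export
filter_genes <- function(expr, cv_min = 0.05, use_intensity_filter = TRUE) {
  validate_expression(expr)
  stopifnot(cv_min >= 0)
  n_input <- nrow(expr)
  means <- rowMeans(expr)
  keep1 <- if (use_intensity_filter) means > mean(means) else rep(TRUE, n_input)
  e1 <- expr[keep1, , drop = FALSE]
  m1 <- means[keep1]
  n_after_intensity <- nrow(e1)

  zero <- m1 == 0
  if (any(zero))
    warning(sum(zero), " gene(s) with mean 0 excluded (CV undefined)")
  if (any(m1 < 0))
    warning("negative mean intensities present; CV computed on |mean|")
  sds <- apply(e1, 1, sd)
  cv <- ifelse(zero, NA_real_, sds / abs(m1))
  keep2 <- !zero & cv > cv_min
  e2 <- e1[keep2, , drop = FALSE]

  report <- structure(list(n_input = n_input,
                           n_after_intensity = n_after_intensity,
                           n_after_cv = nrow(e2),
                           kept_gene_ids = rownames(e2)),
                      class = "gene_filter_report")
  list(expr = e2, report = report)
}

#' @export
print.gene_filter_report <- function(x, ...) {
  cat("Gene filter:", x$n_input, "->", x$n_after_intensity,
      "(intensity) ->", x$n_after_cv, "(CV)\n")
  invisible(x)
}

#' Select the k most variable genes
#'
#' Top-k companion to [filter_genes()] for datasets curated by variability.
#'
#' @param expr genes x samples matrix.
#' @param k number of genes to keep.
#' @return filtered matrix, original gene order preserved.
#' @export
select_top_variable <- function(expr, k) {
  validate_expression(expr)
  k <- min(k, nrow(expr))
  v <- apply(expr, 1, var)
  keep <- rank(-v, ties.method = "first") <= k
  expr[keep, , drop = FALSE]
}

#' Select the k most highly expressed genes
#'
#' Top-k companion to [filter_genes()] for datasets curated by expression level.
#'
#' @inheritParams select_top_variable
#' @return filtered matrix, original gene order preserved.
#' @export
select_top_expressed <- function(expr, k) {
  validate_expression(expr)
  k <- min(k, nrow(expr))
  m <- rowMeans(expr)
  keep <- rank(-m, ties.method = "first") <= k
  expr[keep, , drop = FALSE]
}

#' Write a labelled matrix or partition as TSV
#'
#' Matrices (association, membership, expression) are written with a leading
#' label column and header row, values at 12 significant digits so a reload
#' reproduces them to at least 1e-12 relative accuracy. Module partitions are
#' written as two columns (gene, module), unplaced genes labelled "unplaced".
#'
#' @param obj numeric matrix with dimnames, or a `module_partition`.
#' @param path output file.
#' @export
write_matrix <- function(obj, path) {
  if (inherits(obj, "module_partition")) {
    df <- data.frame(gene = obj$gene_ids,
                     module = vapply(obj$gene_ids, function(g) {
                       mods <- obj$modules[[g]]
                       if (length(mods) == 0) "unplaced"
                       else paste(mods, collapse = ",")
                     }, character(1)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  stopifnot(is.matrix(obj), !is.null(rownames(obj)), !is.null(colnames(obj)))
  df <- data.frame(id = rownames(obj),
                   signif(obj, 12),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a matrix written by [write_matrix()]
#'
#' @param path file to read.
#' @return numeric matrix with row and column labels.
#' @export
read_matrix <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read back a partition written by [write_matrix()]
#'
#' @param path file to read.
#' @return a `module_partition`.
#' @export
read_partition <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  mods <- lapply(as.character(tab$module), function(s) {
    if (identical(s, "unplaced")) character(0) else strsplit(s, ",")[[1]]
  })
  new_partition(as.character(tab$gene), mods)
}
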