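# Shared small containers and helpers.

#' Construct a module partition
#'
#' A partition maps every gene to zero (unplaced), one, or several module
#' labels; multi-assignment arises from membership thresholding.
#'
#' @param gene_ids character vector of gene IDs.
#' @param modules list parallel to `gene_ids`; each element a character vector
#'   of module labels (length 0 = unplaced).
#' @return object of class `module_partition`.
#' @export
new_partition <- function(gene_ids, modules) {
  stopifnot(length(gene_ids) == length(modules))
  modules <- lapply(modules, as.character)
  names(modules) <- gene_ids
  structure(list(gene_ids = as.character(gene_ids),
                 modules = modules,
                 n_modules = length(unique(unlist(modules)))),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  unpl <- sum(vapply(x$modules, length, 1L) == 0)
  cat("Module partition:", length(x$gene_ids), "genes,",
      x$n_modules, "modules,", unpl, "unplaced\n")
  invisible(x)
}

#' Single-label view of a partition
#'
#' @param part a `module_partition`.
#' @return named character vector, first module per gene, `NA` when unplaced.
#' @export
partition_labels <- function(part) {
  vapply(part$modules, function(m) if (length(m)) m[[1]] else NA_character_,
         character(1))
}

#' Genes assigned to each module
#'
#' @param part a `module_partition`.
#' @return named list: module label -> character vector of gene IDs.
#' @export
module_gene_sets <- function(part) {
  labs <- sort(unique(unlist(part$modules)))
  out <- lapply(labs, function(l) {
    part$gene_ids[vapply(part$modules, function(m) l %in% m, logical(1))]
  })
  names(out) <- labs
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two hard clusterings; 1 for identical
#' partitions (up to relabeling), about 0 for independent ones.
#'
#' @param a,b label vectors of equal length (factors, characters or integers).
#' @return adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- as.integer(factor(a[keep])); b <- as.integer(factor(b[keep]))
  n <- length(a)
  if (n < 2) return(NA_real_)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Pairwise co-placement rate of a gene set
#'
#' Fraction of gene pairs from `genes` that share at least one module of the
#' partition: 1 when the whole set sits in one module, about 0.5 when it is
#' split into two equal halves, 0 when scattered singly or unplaced. The
#' statistic used to ask whether a method holds a planted gene set together.
#'
#' @param part a `module_partition`.
#' @param genes gene IDs to score (>= 2 of them must be in the partition).
#' @return fraction in \[0, 1\].
#' @export
pair_coplacement <- function(part, genes) {
  genes <- intersect(genes, part$gene_ids)
  if (length(genes) < 2) stop("need at least 2 genes present in the partition")
  mods <- part$modules[genes]
  n <- length(genes)
  hits <- 0L
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      if (length(intersect(mods[[i]], mods[[j]])) > 0) hits <- hits + 1L
  hits / (n * (n - 1) / 2)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
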