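# Simplified correlation-network baseline: soft-power adjacency, topological
# overlap, average-linkage clustering to a requested module count, and
# eigengene-based merging.

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij)` with the
#' u-sum over all other genes, k_i the row sums off-diagonal, diagonal TOM set
#' to 1 by convention; `dist = 1 - TOM` is the clustering dissimilarity.
#'
#' @param adj adjacency matrix with entries in \[0, 1\] and gene dimnames.
#' @return object of class `tom_matrix`: list with `tom` and `dist`.
#' @export
tom <- function(adj) {
  stopifnot(is.matrix(adj), all(adj >= 0), all(adj <= 1))
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a # u-sum; diag(a)=0 removes u in {i, j}
  kmin <- outer(k, k, pmin)
  t <- (shared + a) / (kmin + 1 - a)
  diag(t) <- 1
  dimnames(t) <- dimnames(adj)
  structure(list(tom = t, dist = 1 - t), class = "tom_matrix")
}

#' Cluster a TOM dissimilarity into a fixed number of modules
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut to `n_modules`
#' groups; groups smaller than `min_size` are reassigned to unplaced. A
#' static cut stands in for dynamic tree cutting: the baseline's role is
#' comparative and the fuzzy method inherits its module count from here.
#'
#' @param tomm a `tom_matrix`.
#' @param n_modules number of clusters to cut (>= 2).
#' @param min_size smallest retained module (default 20).
#' @return a `module_partition` with contiguous labels "B1", "B2", ...
#' @export
cluster_to_modules <- function(tomm, n_modules, min_size = 20) {
  stopifnot(inherits(tomm, "tom_matrix"), n_modules >= 2)
  d <- tomm$dist
  if (n_modules > nrow(d)) stop("more modules requested than genes")
  hc <- hclust(as.dist(d), method = "average")
  cl <- cutree(hc, k = n_modules)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  labmap <- setNames(paste0("B", seq_along(keep)), keep)
  mods <- lapply(as.character(cl), function(g) {
    if (g %in% keep) labmap[[g]] else character(0)
  })
  new_partition(rownames(d), mods)
}

baseline_eigengenes <- function(part, expr) {
  sets <- module_gene_sets(part)
  sets <- sets[vapply(sets, length, 1L) >= 2]
  vapply(names(sets), function(l) {
    g <- intersect(sets[[l]], rownames(expr))
    weighted_eigengene(expr[g, , drop = FALSE], rep(1, length(g)), l)$values
  }, numeric(ncol(expr)))
}

#' Merge modules with near-identical eigengenes
#'
#' Iteratively merges the module pair with the highest eigengene Pearson
#' correlation above `r_min`, recomputing eigengenes after each merge, until
#' no pair exceeds the threshold.
#'
#' @param part a `module_partition`.
#' @param expr genes x samples matrix.
#' @param r_min merge threshold on eigengene correlation (default 0.8).
#' @return a `module_partition` with merged, relabelled modules.
#' @export
merge_close_modules <- function(part, expr, r_min = 0.8) {
  labels <- partition_labels(part)
  repeat {
    labs <- sort(unique(labels[!is.na(labels)]))
    if (length(labs) < 2) break
    eg <- baseline_eigengenes(new_partition(names(labels),
                                            lapply(labels, function(l)
                                              if (is.na(l)) character(0) else l)),
                              expr)
    cc <- cor(eg)
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] <= r_min) break
    a <- colnames(cc)[mx[2]]; b <- rownames(cc)[mx[1]]
    labels[labels == b] <- a
  }
  labs <- sort(unique(labels[!is.na(labels)]))
  labmap <- setNames(paste0("B", seq_along(labs)), labs)
  new_partition(part$gene_ids, lapply(labels, function(l) {
    if (is.na(l)) character(0) else labmap[[l]]
  }))
}

#' Correlation/TOM baseline pipeline
#'
#' Pearson |r| -> soft-power scan -> adjacency |r|^power -> TOM ->
#' average-linkage cut to `n_modules` -> eigengene merging. When no power
#' passes the scale-free threshold, the power with the best signed fit is
#' used and reported.
#'
#' @param expr genes x samples matrix.
#' @param n_modules modules to cut.
#' @param r2_min scale-free fit threshold (default 0.9).
#' @param min_size smallest retained module (default 20).
#' @param r_min eigengene merge threshold (default 0.8).
#' @param powers soft powers to scan (default 1:20).
#' @return list of class `baseline_fit`: `partition`, `power`, `sft`.
#' @export
run_baseline <- function(expr, n_modules, r2_min = 0.9, min_size = 20,
                         r_min = 0.8, powers = 1:20) {
  validate_expression(expr)
  r <- pearson_matrix(expr, absolute = TRUE)
  fit <- suppressWarnings(sft_fit(r, powers))
  power <- pick_soft_power(fit, r2_min)
  if (is.na(power)) {
    power <- fit$powers[which.max(fit$r2_signed)]
    message("using power with best signed fit: ", power)
  }
  adj <- r^power
  part <- cluster_to_modules(tom(adj), n_modules, min_size)
  part <- merge_close_modules(part, expr, r_min)
  structure(list(partition = part, power = power, sft = fit),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat("Correlation/TOM baseline (soft power", x$power, ")\n")
  print(x$partition)
  invisible(x)
}
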