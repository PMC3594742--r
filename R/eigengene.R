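# Eigengenes: weighted and cutoff-thresholded first principal components of
# module expression, and their stability across membership cutoffs.

#' Weighted first-principal-component module summary
#'
#' Gene profiles are standardized (mean 0, sd 1); the eigengene is the leading
#' eigenvector of the weighted sample covariance
#' `C = t(X) \%*\% diag(w) \%*\% X / sum(w)`, a convention that reduces exactly
#' to the unweighted PCA at uniform weights. The sign is oriented so the
#' eigengene correlates non-negatively with the weighted mean module profile.
#'
#' @param expr genes x samples matrix.
#' @param weights nonnegative per-gene weights (e.g. a membership column).
#' @param module_id label carried through to the result.
#' @return object of class `eigengene`: `values` (unit-norm, one per sample),
#'   `sample_ids`, `module_id`, `variance_explained`.
#' @export
weighted_eigengene <- function(expr, weights, module_id = "module") {
  validate_expression(expr)
  stopifnot(length(weights) == nrow(expr), all(weights >= 0))
  const <- apply(expr, 1, sd) == 0
  if (any(const & weights > 0)) {
    warning(sum(const & weights > 0),
            " constant gene(s); weight forced to 0")
    weights[const] <- 0
  }
  if (sum(weights) == 0) stop("all weights are zero")
  X <- expr[weights > 0, , drop = FALSE]
  w <- weights[weights > 0]
  X <- (X - rowMeans(X)) / apply(X, 1, sd)
  Cw <- crossprod(X * w, X) / sum(w) # t(X) W X / sum(w)
  eg <- eigen(Cw, symmetric = TRUE)
  v <- eg$vectors[, 1]
  ref <- colSums(X * w) / sum(w)
  if (sum(v * ref) < 0) v <- -v
  structure(list(module_id = module_id,
                 sample_ids = colnames(expr),
                 values = setNames(v, colnames(expr)),
                 variance_explained = eg$values[1] / sum(pmax(eg$values, 0))),
            class = "eigengene")
}

#' @export
print.eigengene <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("Undefined eigengene for", x$module_id, "(", x$n_genes, "genes )\n")
  } else {
    cat(sprintf("Eigengene %s: %d samples, %.1f%% variance\n", x$module_id,
                length(x$values), 100 * x$variance_explained))
  }
  invisible(x)
}

#' Unweighted eigengene of the genes passing a membership cutoff
#'
#' @param expr genes x samples matrix.
#' @param mm a `membership_matrix` over (a superset of) the genes in `expr`.
#' @param module_id column of `mm` to summarize.
#' @param cutoff membership cutoff; genes with `mm >= cutoff` are included.
#' @return an `eigengene`, or an undefined-eigengene stub (class `eigengene`,
#'   `undefined = TRUE`, carrying `n_genes`) when fewer than 2 genes pass.
#' @export
eigengene_at_cutoff <- function(expr, mm, module_id, cutoff) {
  genes <- intersect(rownames(expr), rownames(mm))
  sel <- genes[mm[genes, module_id] >= cutoff]
  if (length(sel) < 2) {
    return(structure(list(module_id = module_id, undefined = TRUE,
                          n_genes = length(sel)),
                     class = "eigengene"))
  }
  weighted_eigengene(expr[sel, , drop = FALSE],
                     rep(1, length(sel)), module_id)
}

#' Eigengene stability across membership cutoffs
#'
#' For each module and cutoff, computes the unweighted eigengene of the genes
#' passing the cutoff, plus the weighted eigengene using the membership
#' column as weights. Stability between two cutoffs is the mean over modules
#' of |cor| between their eigengenes (absolute value, since a principal
#' component's sign is arbitrary); undefined eigengenes are dropped from the
#' means and counted.
#'
#' @param expr genes x samples matrix.
#' @param mm a `membership_matrix`.
#' @param cutoffs membership cutoffs (default 0.10 to 0.90 by 0.05).
#' @return object of class `stability_profile`: `cutoffs`, `pairwise_corr`
#'   (cutoff x cutoff), `corr_to_weighted` (per cutoff), `n_undefined`.
#' @export
stability_profile <- function(expr, mm, cutoffs = seq(0.10, 0.90, by = 0.05)) {
  mods <- colnames(mm)
  nc <- length(cutoffs)
  # eigengene value matrix per cutoff: samples x modules (NA when undefined)
  egs <- vector("list", nc)
  n_undef <- 0L
  for (a in seq_len(nc)) {
    m <- matrix(NA_real_, ncol(expr), length(mods),
                dimnames = list(colnames(expr), mods))
    for (md in mods) {
      e <- eigengene_at_cutoff(expr, mm, md, cutoffs[a])
      if (isTRUE(e$undefined)) n_undef <- n_undef + 1L else m[, md] <- e$values
    }
    egs[[a]] <- m
  }
  wg <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), mods))
  for (md in mods)
    wg[, md] <- weighted_eigengene(expr, mm[rownames(expr), md], md)$values

  mean_abs_cor <- function(A, B) {
    v <- vapply(seq_along(mods), function(j) {
      if (anyNA(A[, j]) || anyNA(B[, j])) NA_real_
      else abs(cor(A[, j], B[, j]))
    }, numeric(1))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  pc <- matrix(NA_real_, nc, nc, dimnames = list(cutoffs, cutoffs))
  for (a in seq_len(nc))
    for (b in a:nc) {
      pc[a, b] <- pc[b, a] <- mean_abs_cor(egs[[a]], egs[[b]])
    }
  ctw <- vapply(seq_len(nc), function(a) mean_abs_cor(egs[[a]], wg), numeric(1))
  if (n_undef > 0)
    message(n_undef, " undefined module x cutoff eigengene(s) excluded")
  structure(list(cutoffs = cutoffs, pairwise_corr = pc,
                 corr_to_weighted = setNames(ctw, cutoffs),
                 n_undefined = n_undef),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("Eigengene stability over", length(x$cutoffs), "cutoffs; mean |cor| to",
      "weighted PCA:\n")
  print(round(x$corr_to_weighted, 3))
  invisible(x)
}
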