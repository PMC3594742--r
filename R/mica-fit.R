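# The central fit: MIC association matrix -> hard threshold chosen by
# scale-free fit -> ICMg link-community sampling -> fuzzy memberships,
# hardened partition, and weighted eigengenes.

#' Fit a maximal-information component decomposition
#'
#' Runs the full pipeline on an expression matrix: (1) all-pairs MIC
#' association scores; (2) the lowest hard threshold whose binarized degree
#' distribution passes the scale-free criterion (falling back to the
#' best-fitting scanned cutoff when none passes); (3) collapsed Gibbs
#' sampling of link-community assignments, giving each gene a fuzzy
#' membership across `n_modules` components; (4) a hardened partition and a
#' weighted-PCA eigengene per module.
#'
#' The number of modules is a free parameter of the model; fixing it to the
#' module count of a correlation baseline (see [run_baseline()]) makes the
#' two decompositions directly comparable.
#'
#' @param expr genes x samples numeric matrix (rownames = genes).
#' @param n_modules number of latent components C.
#' @param exponent MIC resolution exponent (default 0.6).
#' @param mode MIC search mode, `"heuristic"` or `"exhaustive"`.
#' @param hard_threshold fixed edge cutoff; when NULL (default) the lowest
#'   scale-free-passing cutoff is scanned with [pick_hard_threshold()].
#' @param threshold_step,r2_min hard-threshold scan parameters.
#' @param alpha,beta,burn_in,thin,sampling_iters,seed sampler controls, see
#'   [icmg_config()].
#' @param assoc optional precomputed association matrix (skips step 1).
#' @return object of class `mica`: list with `assoc`, `cutoff`, `edges`,
#'   `membership` (gene x module matrix, rows sum to 1), `partition`,
#'   `eigengenes` (sample x module matrix), `variance_explained`, `config`,
#'   `call`.
#' @seealso [run_baseline()] for the correlation/TOM comparison pipeline,
#'   [optimal_cutoff_scan()] for choosing a membership cutoff.
#' @examples
#' sim <- simulate_expression(simulation_design(
#'   n_samples = 60,
#'   modules = list(module_spec(15, "linear"), module_spec(15, "linear")),
#'   seed = 7))
#' fit <- mica(sim$expr, n_modules = 2, burn_in = 200, sampling_iters = 200,
#'             seed = 7)
#' summary(fit)
#' @export
mica <- function(expr, n_modules, exponent = 0.6,
                 mode = c("heuristic", "exhaustive"),
                 hard_threshold = NULL, threshold_step = 0.05, r2_min = 0.9,
                 alpha = 10, beta = 0.1, burn_in = 40000, thin = 10,
                 sampling_iters = 10000, seed = 1, assoc = NULL) {
  mode <- match.arg(mode)
  validate_expression(expr)
  if (is.null(assoc)) assoc <- mic_matrix(expr, exponent, mode)

  cutoff <- hard_threshold
  if (is.null(cutoff)) {
    cutoff <- suppressWarnings(pick_hard_threshold(assoc, threshold_step, r2_min))
    if (is.na(cutoff)) {
      scan <- attr(cutoff, "scan")
      ok <- !is.na(scan$r2_signed)
      cutoff <- scan$cutoff[ok][which.max(scan$r2_signed[ok])]
      message("no cutoff passes signed R^2 >= ", r2_min,
              "; using best-fitting cutoff ", cutoff)
    }
    cutoff <- as.numeric(cutoff)
  }
  edges <- binarize(assoc, cutoff)
  if (nrow(edges$edges) == 0) stop("hard threshold leaves no edges")

  config <- icmg_config(n_modules, alpha = alpha, beta = beta,
                        burn_in = burn_in, thin = thin,
                        sampling_iters = sampling_iters, seed = seed)
  mm <- run_icmg(edges, config)
  part <- harden(mm)

  genes <- rownames(expr)
  eg <- matrix(NA_real_, ncol(expr), n_modules,
               dimnames = list(colnames(expr), colnames(mm)))
  ve <- setNames(rep(NA_real_, n_modules), colnames(mm))
  for (md in colnames(mm)) {
    w <- mm[genes, md]
    if (sum(w) == 0) next
    e <- suppressWarnings(weighted_eigengene(expr, w, md))
    eg[, md] <- e$values
    ve[md] <- e$variance_explained
  }

  structure(list(call = match.call(), assoc = assoc, cutoff = cutoff,
                 edges = edges, membership = mm, partition = part,
                 eigengenes = eg, variance_explained = ve, config = config),
            class = "mica")
}

#' @export
print.mica <- function(x, ...) {
  cat("Maximal information component decomposition\n")
  cat("  genes:", length(x$edges$nodes),
      " links:", nrow(x$edges$edges),
      " (hard threshold", format(x$cutoff), ")\n")
  cat("  components:", x$config$n_components,
      " sampler: burn-in", x$config$burn_in, "/",
      x$config$sampling_iters, "sweeps, thin", x$config$thin, "\n")
  invisible(x)
}

#' @export
summary.mica <- function(object, ...) {
  labs <- partition_labels(object$partition)
  sizes <- table(factor(labs, levels = colnames(object$membership)))
  out <- list(cutoff = object$cutoff,
              n_links = nrow(object$edges$edges),
              module_sizes = sizes,
              n_unplaced = sum(is.na(labs)),
              mean_max_membership = mean(apply(object$membership, 1, max)),
              variance_explained = object$variance_explained)
  class(out) <- "summary.mica"
  out
}

#' @export
print.summary.mica <- function(x, ...) {
  cat("MICA fit: ", x$n_links, " links at hard threshold ",
      format(x$cutoff), "\n", sep = "")
  cat("Hardened module sizes (", x$n_unplaced, " unplaced):\n", sep = "")
  print(x$module_sizes)
  cat(sprintf("Mean max membership: %.3f\n", x$mean_max_membership))
  cat("Eigengene variance explained:\n")
  print(round(x$variance_explained, 3))
  invisible(x)
}

#' @export
coef.mica <- function(object, ...) object$membership

#' Membership heatmap of a fitted decomposition
#'
#' @param x a `mica` fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.mica <- function(x, ...) {
  mm <- x$membership
  ord <- order(apply(mm, 1, which.max), -apply(mm, 1, max))
  graphics::image(seq_len(ncol(mm)), seq_len(nrow(mm)), t(mm[ord, ]),
                  xlab = "module", ylab = "gene (sorted)", axes = FALSE,
                  main = "Fuzzy module membership", ...)
  graphics::axis(1, at = seq_len(ncol(mm)), labels = colnames(mm))
  graphics::box()
  invisible(x)
}
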