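# Maximal information coefficient (MIC): grid-search normalized mutual
# information on ranks, and assembly of gene x gene association matrices.

#' Maximal information coefficient of a variable pair
#'
#' Searches axis-aligned grids on the rank-ordered data, subject to the
#' resolution bound `x_bins * y_bins < n^exponent` (the minimal 2x2 grid is
#' always admitted so the statistic stays defined at small n). Mutual
#' information is computed in bits on empirical cell frequencies and each
#' grid's MI is divided by `log2(min(x_bins, y_bins))`; MIC is the maximum
#' over the search. Cuts are placed only at boundaries between distinct
#' values, so ties are never split.
#'
#' `mode = "exhaustive"` enumerates every admissible grid (feasible for small
#' n). `mode = "heuristic"` equipartitions one axis and finds the exactly
#' optimal partition of the other by dynamic programming over clump
#' boundaries, in both orientations; for `n <= exact_limit` the admissible
#' grid space is tiny and the heuristic falls through to full enumeration, so
#' the two modes coincide there.
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @param exponent resolution exponent in (0, 1], default 0.6.
#' @param mode `"heuristic"` (default) or `"exhaustive"`.
#' @param exact_limit sample size at or below which the heuristic enumerates
#'   exhaustively (default 25).
#' @param clump_factor superclump multiplier bounding dynamic-programming
#'   candidate cuts (default 15).
#' @return object of class `mic_result`: list with `mic` in \[0, 1\],
#'   `best_grid` (`x_bins`, `y_bins`, and rank-threshold cut positions),
#'   `n`, and `exponent`.
#' @examples
#' x <- 1:16
#' mic_score(x, x)$mic # exactly 1 for a noiseless monotone pair
#' @export
mic_score <- function(x, y, exponent = 0.6, mode = c("heuristic", "exhaustive"),
                      exact_limit = 25, clump_factor = 15) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("n >= 4 observations are required")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (exponent <= 0 || exponent > 1) stop("exponent must be in (0, 1]")
  res <- cpp_mic(x, y, exponent, mode, as.integer(exact_limit),
                 as.integer(clump_factor))
  structure(list(mic = res$mic,
                 best_grid = list(x_bins = res$x_bins, y_bins = res$y_bins,
                                  x_cuts = res$x_cuts, y_cuts = res$y_cuts),
                 n = n, exponent = exponent),
            class = "mic_result")
}

#' @export
print.mic_result <- function(x, ...) {
  cat(sprintf("MIC = %.4f (n = %d, best grid %d x %d)\n",
              x$mic, x$n, x$best_grid$x_bins, x$best_grid$y_bins))
  invisible(x)
}

new_assoc <- function(scores, gene_ids, measure) {
  dimnames(scores) <- list(gene_ids, gene_ids)
  structure(scores, measure = measure, class = c("association_matrix", "matrix"))
}

#' All-pairs MIC association matrix
#'
#' Computes [mic_score()] for every gene pair of an expression matrix. Pair
#' computations are independent; the result does not depend on evaluation
#' order, and permuting gene order permutes the matrix accordingly.
#'
#' @param expr genes x samples matrix.
#' @inheritParams mic_score
#' @return symmetric numeric matrix in \[0, 1\] with unit diagonal, gene IDs
#'   as dimnames, attribute `measure = "mic"`.
#' @export
mic_matrix <- function(expr, exponent = 0.6, mode = c("heuristic", "exhaustive"),
                       exact_limit = 25, clump_factor = 15) {
  mode <- match.arg(mode)
  validate_expression(expr)
  if (nrow(expr) < 2) stop("at least 2 genes are required")
  if (ncol(expr) < 4) stop("n >= 4 samples are required for MIC")
  scores <- cpp_mic_matrix(expr, exponent, mode, as.integer(exact_limit),
                           as.integer(clump_factor))
  new_assoc(scores, rownames(expr), "mic")
}

#' Pearson correlation association matrix
#'
#' @param expr genes x samples matrix (>= 3 samples).
#' @param absolute return |r| (default) rather than signed r.
#' @return symmetric gene x gene matrix; constant genes get correlation 0
#'   with a warning.
#' @export
pearson_matrix <- function(expr, absolute = TRUE) {
  validate_expression(expr)
  if (nrow(expr) < 2) stop("at least 2 genes are required")
  if (ncol(expr) < 3) stop("at least 3 samples are required")
  const <- apply(expr, 1, sd) == 0
  r <- suppressWarnings(cor(t(expr)))
  if (any(const)) {
    warning(sum(const), " constant gene(s); correlations set to 0")
    r[const, ] <- 0
    r[, const] <- 0
  }
  diag(r) <- 1
  if (absolute) r <- abs(r)
  new_assoc(r, rownames(expr), if (absolute) "pearson_abs" else "pearson")
}
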