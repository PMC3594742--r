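# ICMg: collapsed Gibbs sampling of link-community assignments, yielding
# fuzzy per-gene module memberships.

#' Sampler configuration for ICMg
#'
#' Defaults follow the method's published schedule: Dirichlet concentration
#' alpha = 10 on component sizes, beta = 0.1 on node co-occurrences, 40,000
#' burn-in sweeps, then 10,000 sweeps sampled every 10. A sweep is one pass
#' over all links in fixed input order.
#'
#' @param n_components number of components C (>= 2).
#' @param alpha,beta positive Dirichlet control parameters.
#' @param burn_in burn-in sweeps.
#' @param thin record every `thin`-th sweep.
#' @param sampling_iters post-burn-in sweeps.
#' @param seed integer seed governing the whole run.
#' @return list of class `icmg_config`.
#' @export
icmg_config <- function(n_components, alpha = 10, beta = 0.1,
                        burn_in = 40000, thin = 10, sampling_iters = 10000,
                        seed = 1) {
  stopifnot(n_components >= 2, alpha > 0, beta > 0,
            burn_in >= 0, thin >= 1, sampling_iters >= thin)
  structure(list(n_components = as.integer(n_components), alpha = alpha,
                 beta = beta, burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 sampling_iters = as.integer(sampling_iters),
                 seed = as.integer(seed)),
            class = "icmg_config")
}

#' Collapsed Gibbs conditional for one link
#'
#' Unnormalized weight of component z for a link with endpoints i0, j0, given
#' counts from which the interrogated link has been removed:
#' `(n_z + alpha) / (N + C alpha) * (q_zi + beta)(q_zj + beta) /
#'  ((2 n_z + 1 + M beta)(2 n_z + M beta))`, normalized to sum 1.
#'
#' @param n_z links-per-component counts (length C), link removed.
#' @param q component x node co-occurrence count matrix (C x M), link removed.
#' @param i0,j0 endpoint node indices (1-based columns of `q`).
#' @param alpha,beta control parameters.
#' @return probability vector of length C.
#' @export
gibbs_conditional <- function(n_z, q, i0, j0, alpha = 10, beta = 0.1) {
  C <- length(n_z)
  M <- ncol(q)
  stopifnot(nrow(q) == C, i0 >= 1, i0 <= M, j0 >= 1, j0 <= M, i0 != j0)
  N <- sum(n_z)
  w <- (n_z + alpha) / (N + C * alpha) *
    (q[, i0] + beta) * (q[, j0] + beta) /
    ((2 * n_z + 1 + M * beta) * (2 * n_z + M * beta))
  w / sum(w)
}

#' Run the ICMg sampler on an edge list
#'
#' Initializes link labels from a single global Dirichlet(alpha) component-
#' probability draw, runs `burn_in` sweeps of single-link collapsed Gibbs
#' updates, then accumulates component-node co-occurrences every `thin`
#' sweeps for `sampling_iters` sweeps. A gene's membership in component z is
#' its share of accumulated co-occurrences. Deterministic given
#' `config$seed`.
#'
#' @param edges an `edge_list` (see [binarize()]).
#' @param config an [icmg_config()].
#' @param keep_draws also return the retained link-label samples.
#' @param check_counts verify count invariants after every sweep (slow;
#'   for validation).
#' @return object of class `membership_matrix`: gene x component numeric
#'   matrix (rows sum to 1) with attributes `n_samples_used`, `unsupported`
#'   (zero-degree genes given uniform rows), and optionally `draws`.
#' @export
run_icmg <- function(edges, config, keep_draws = FALSE, check_counts = FALSE) {
  stopifnot(inherits(edges, "edge_list"), inherits(config, "icmg_config"))
  if (nrow(edges$edges) == 0) stop("edge list is empty")
  nodes <- edges$nodes
  M <- length(nodes)
  C <- config$n_components
  if (C > nrow(edges$edges))
    warning("more components than links; some components may starve")
  from <- match(edges$edges[, 1], nodes) - 1L
  to <- match(edges$edges[, 2], nodes) - 1L
  if (anyNA(from) || anyNA(to)) stop("edge endpoints missing from node set")

  set.seed(config$seed)
  res <- cpp_icmg(from, to, M, C, config$alpha, config$beta,
                  config$burn_in, config$thin, config$sampling_iters,
                  keep_draws, check_counts)

  acc <- t(res$acc_q) # gene x component
  tot <- rowSums(acc)
  unsupported <- tot == 0
  mm <- acc
  mm[unsupported, ] <- 1 / C
  mm[!unsupported, ] <- acc[!unsupported, , drop = FALSE] / tot[!unsupported]
  dimnames(mm) <- list(nodes, paste0("M", seq_len(C)))
  structure(mm,
            n_samples_used = res$n_samples,
            unsupported = nodes[unsupported],
            draws = if (keep_draws) res$draws else NULL,
            class = c("membership_matrix", "matrix"))
}

#' Harden fuzzy memberships into a partition
#'
#' Each gene goes to its argmax component; ties break to the lowest module
#' index; genes with no link support (uniform flagged rows) go unplaced.
#'
#' @param mm a `membership_matrix`.
#' @return a `module_partition`.
#' @export
harden <- function(mm) {
  unsupported <- attr(mm, "unsupported") %||% character(0)
  labs <- colnames(mm)
  mods <- lapply(seq_len(nrow(mm)), function(i) {
    if (rownames(mm)[i] %in% unsupported) return(character(0))
    labs[which.max(mm[i, ])]
  })
  new_partition(rownames(mm), mods)
}

#' Threshold memberships into a (multi-assignment) partition
#'
#' A gene belongs to every module where its membership is >= `cutoff`; genes
#' passing nowhere are unplaced.
#'
#' @param mm a `membership_matrix`.
#' @param cutoff membership cutoff in (0, 1).
#' @return a `module_partition` (possibly multi-assigned).
#' @export
threshold_membership <- function(mm, cutoff) {
  stopifnot(cutoff > 0, cutoff < 1)
  labs <- colnames(mm)
  mods <- lapply(seq_len(nrow(mm)), function(i) labs[mm[i, ] >= cutoff])
  new_partition(rownames(mm), mods)
}
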