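# Synthetic data with the statistical structure the method assumes: planted
# (possibly overlapping) modules driven by latent factors, the relationship
# archetypes seen in strain-panel expression data (linear, high-threshold,
# logarithmic, quadratic, and two-condition gene-by-environment mixtures),
# preferential-attachment graphs, and toy ontologies.

#' Specify one planted module
#'
#' @param size number of member genes (>= 2).
#' @param type relationship between members and the latent factor:
#'   `"linear"`, `"threshold"` (sharp step at the factor median),
#'   `"logarithmic"`, `"quadratic"`, or `"gxe"`. In a gxe module the
#'   treatment both shifts the latent pathway activity (by
#'   `condition_shift` standard deviations) and flips the response sign of
#'   the sensitive half of the members, so a stable-vs-sensitive pair pooled
#'   over conditions traces a parabola-like "complex" curve: near-zero
#'   Pearson correlation but near-perfect mutual information.
#' @param loading signal amplitude relative to unit noise (default 1).
#' @param noise_sd additive Gaussian noise sd (default 0.1).
#' @param condition_shift latent-activity shift between conditions in factor
#'   sd units (gxe modules only, default 1.2).
#' @return list of class `module_spec`.
#' @export
module_spec <- function(size, type = c("linear", "threshold", "logarithmic",
                                       "quadratic", "gxe"),
                        loading = 1, noise_sd = 0.1, condition_shift = 1.2) {
  type <- match.arg(type)
  stopifnot(size >= 2, noise_sd >= 0, loading > 0, condition_shift >= 0)
  structure(list(size = as.integer(size), type = type, loading = loading,
                 noise_sd = noise_sd, condition_shift = condition_shift),
            class = "module_spec")
}

#' Specify a simulation design
#'
#' @param n_samples number of samples (strains/arrays).
#' @param modules list of [module_spec()]s.
#' @param n_overlap_genes genes loading on the first two module factors at
#'   once (requires >= 2 modules).
#' @param n_background_genes independent-noise genes.
#' @param condition_split fraction of samples in condition A (for gxe).
#' @param seed integer seed; the generator is a pure function of design+seed.
#' @return list of class `simulation_design`.
#' @export
simulation_design <- function(n_samples = 100, modules,
                              n_overlap_genes = 0, n_background_genes = 0,
                              condition_split = 0.5, seed = 1) {
  stopifnot(n_samples >= 4, length(modules) >= 1,
            all(vapply(modules, inherits, TRUE, "module_spec")),
            condition_split > 0, condition_split < 1,
            n_overlap_genes == 0 || length(modules) >= 2)
  structure(list(n_samples = as.integer(n_samples), modules = modules,
                 n_overlap_genes = as.integer(n_overlap_genes),
                 n_background_genes = as.integer(n_background_genes),
                 condition_split = condition_split, seed = as.integer(seed)),
            class = "simulation_design")
}

std1 <- function(v) (v - mean(v)) / sd(v)

#' Simulate strain-panel expression with planted modules
#'
#' Every module is driven by its own latent factor (standard normal across
#' samples); members are `loading * f(factor) + noise` with `f` set by the
#' module type. In a gxe module the treatment shifts the latent activity by
#' `condition_shift` sd and the sensitive half of the members flip their
#' response sign in condition B, so a stable-vs-sensitive pair pooled over
#' conditions is parabola-like ("complex"): near-zero correlation, high
#' mutual information. Overlap genes mix the first two module factors
#' equally. Deterministic given the design seed.
#'
#' @param design a [simulation_design()].
#' @return list with `expr` (genes x samples matrix) and `truth`
#'   (`ground_truth`: per-gene module sets, per-module type, per-gene gxe
#'   sensitivity, condition labels, latent factors).
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  n <- design$n_samples
  nA <- round(design$condition_split * n)
  cond <- rep(c("A", "B"), c(nA, n - nA))
  csign <- ifelse(cond == "A", 1, -1)

  nmod <- length(design$modules)
  factors <- matrix(rnorm(n * nmod), n, nmod,
                    dimnames = list(NULL, paste0("P", seq_len(nmod))))

  rows <- list(); gene_mods <- list(); sens <- numeric(0)
  gid <- 0
  nextid <- function() sprintf("G%04d", gid)
  for (m in seq_len(nmod)) {
    sp <- design$modules[[m]]
    f <- factors[, m]
    if (sp$type == "gxe") f <- f + sp$condition_shift * csign
    base <- switch(sp$type,
                   linear = f,
                   threshold = plogis((f - median(f)) / 0.1),
                   logarithmic = log(f - min(f) + 1),
                   quadratic = f^2,
                   gxe = f)
    for (g in seq_len(sp$size)) {
      gid <- gid + 1
      s <- if (sp$type == "gxe" && g > sp$size / 2) -1 else 1
      sig <- if (sp$type == "gxe" && s < 0) base * csign else base
      rows[[nextid()]] <- sp$loading * std1(sig) + rnorm(n, 0, sp$noise_sd)
      gene_mods[[nextid()]] <- paste0("P", m)
      if (sp$type == "gxe") sens[nextid()] <- s
    }
  }
  if (design$n_overlap_genes > 0) {
    sp1 <- design$modules[[1]]
    mix <- std1(factors[, 1] + factors[, 2])
    for (g in seq_len(design$n_overlap_genes)) {
      gid <- gid + 1
      rows[[nextid()]] <- sp1$loading * mix + rnorm(n, 0, sp1$noise_sd)
      gene_mods[[nextid()]] <- c("P1", "P2")
    }
  }
  for (g in seq_len(design$n_background_genes)) {
    gid <- gid + 1
    rows[[nextid()]] <- rnorm(n)
    gene_mods[[nextid()]] <- character(0)
  }

  expr <- do.call(rbind, rows)
  colnames(expr) <- sprintf("S%03d", seq_len(n))
  truth <- structure(list(
    modules = gene_mods,
    module_type = setNames(vapply(design$modules, `[[`, "", "type"),
                           paste0("P", seq_len(nmod))),
    gxe_sensitivity = sens,
    conditions = setNames(cond, colnames(expr)),
    factors = factors),
    class = "ground_truth")
  list(expr = expr, truth = truth)
}

#' Planted gene-by-environment pairs of a ground truth
#'
#' Pairs of genes in the same gxe module with opposite condition sensitivity:
#' the relationships that are X-shaped when conditions are pooled.
#'
#' @param truth a `ground_truth`.
#' @return data.frame with columns `gene1`, `gene2`.
#' @export
gxe_pairs <- function(truth) {
  out <- list()
  for (m in names(truth$module_type)[truth$module_type == "gxe"]) {
    genes <- names(truth$modules)[vapply(truth$modules, function(x)
      m %in% x, logical(1))]
    s <- truth$gxe_sensitivity[genes]
    pos <- genes[s > 0]; neg <- genes[s < 0]
    if (length(pos) && length(neg))
      out[[m]] <- expand.grid(gene1 = pos, gene2 = neg,
                              stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(data.frame(gene1 = character(0),
                                          gene2 = character(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Simulate a scale-free graph by preferential attachment
#'
#' @param n_nodes number of nodes.
#' @param edges_per_node edges added with each new node.
#' @param seed integer seed.
#' @return an `edge_list` with nodes "N1", "N2", ...
#' @export
simulate_scale_free <- function(n_nodes, edges_per_node, seed = 1) {
  stopifnot(n_nodes > edges_per_node, edges_per_node >= 1)
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, m = edges_per_node, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  nodes <- paste0("N", seq_len(n_nodes))
  edges <- cbind(from = nodes[el[, 1]], to = nodes[el[, 2]])
  structure(list(nodes = nodes, edges = edges, cutoff_used = NA_real_),
            class = "edge_list")
}

#' Simulate a toy rooted annotation DAG
#'
#' Builds a random rooted DAG of `n_terms` terms over `depth` levels and
#' annotates genes to terms (propagated child -> parent). When enough genes
#' are supplied (about 400+), the construction guarantees at least one term
#' with fewer than 30 and one with more than 300 annotated genes, so both
#' rules of [standard_gene_classes()] can fire.
#'
#' @param n_terms number of terms (>= depth).
#' @param depth number of levels including the root (>= 2).
#' @param genes gene IDs to annotate.
#' @param seed integer seed.
#' @return an `annotation_set`.
#' @export
simulate_ontology <- function(n_terms, depth, genes, seed = 1) {
  stopifnot(n_terms >= depth, depth >= 2)
  set.seed(seed)
  ids <- paste0("T", seq_len(n_terms))
  level <- integer(n_terms); level[1] <- 1
  parents <- setNames(vector("list", n_terms), ids)
  parents[[1]] <- character(0)
  # guarantee one chain reaching full depth, then attach the rest randomly
  for (i in 2:min(depth, n_terms)) {
    level[i] <- i
    parents[[i]] <- ids[i - 1]
  }
  if (n_terms > depth) {
    for (i in (depth + 1):n_terms) {
      lv <- sample(2:depth, 1)
      cand <- which(level == lv - 1)
      parents[[i]] <- ids[sample(cand, 1)]
      if (lv < depth && runif(1) < 0.2) { # occasional second parent (DAG)
        cand2 <- setdiff(which(level == lv - 1), match(parents[[i]], ids))
        if (length(cand2)) parents[[i]] <- c(parents[[i]], ids[sample(cand2, 1)])
      }
      level[i] <- lv
    }
  }
  # direct annotations: one guaranteed small leaf-like term, one large term,
  # the rest random chunks
  pool <- sample(genes)
  gene_sets <- setNames(vector("list", n_terms), ids)
  is_parent <- ids %in% unlist(parents)
  leaves <- which(!is_parent & level > 1)
  small_term <- if (length(leaves)) leaves[1] else n_terms
  take <- function(k) {
    k <- min(k, length(pool))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  gene_sets[[small_term]] <- take(10)
  big_term <- if (n_terms >= 3) setdiff(2:n_terms, small_term)[1] else 1
  gene_sets[[big_term]] <- take(320)
  targets <- setdiff(2:n_terms, c(small_term, big_term))
  while (length(pool) > 0 && length(targets) > 0) {
    tt <- if (length(targets) == 1) targets else sample(targets, 1)
    gene_sets[[tt]] <- c(gene_sets[[tt]], take(sample(15:80, 1)))
  }
  annotation_set(parents, gene_sets)
}
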