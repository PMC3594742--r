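# Network-fitness statistics: ontology-derived standard gene classes,
# perplexity, hypergeometric enrichment, usefulness, Fisher-exact module
# stability, and the MIC-vs-Pearson non-linearity census.

#' Construct an annotation set
#'
#' A rooted DAG of terms plus per-term gene sets. Annotations are propagated
#' child -> parent (a gene annotated to a term belongs to all its ancestors),
#' the convention of ontology enrichment analysis.
#'
#' @param parents named list: term -> character vector of parent terms
#'   (empty for roots). Every term must appear as a name.
#' @param gene_sets named list: term -> character vector of gene IDs
#'   (direct annotations; ancestors are filled in unless `propagate = FALSE`).
#' @param propagate propagate annotations to ancestors (default TRUE).
#' @return object of class `annotation_set` with `term_ids`, `parents`,
#'   `children`, `gene_sets`, `roots`.
#' @export
annotation_set <- function(parents, gene_sets, propagate = TRUE) {
  term_ids <- names(parents)
  stopifnot(!is.null(term_ids), all(unlist(parents) %in% term_ids))
  children <- lapply(setNames(term_ids, term_ids), function(t) character(0))
  for (t in term_ids)
    for (p in parents[[t]])
      children[[p]] <- c(children[[p]], t)
  roots <- term_ids[vapply(parents, length, 1L) == 0]
  if (length(roots) == 0) stop("annotation DAG has no root")
  # cycle check + topological order (children before parents)
  state <- setNames(integer(length(term_ids)), term_ids)
  topo <- character(0)
  visit <- function(t) {
    if (state[[t]] == 1L) stop("annotation graph contains a cycle at ", t)
    if (state[[t]] == 2L) return()
    state[[t]] <<- 1L
    for (ch in children[[t]]) visit(ch)
    state[[t]] <<- 2L
    topo <<- c(topo, t)
  }
  for (r in roots) visit(r)
  if (any(state == 0L)) stop("terms unreachable from any root: ",
                             paste(term_ids[state == 0L], collapse = ", "))
  gs <- lapply(setNames(term_ids, term_ids),
               function(t) unique(as.character(gene_sets[[t]] %||% character(0))))
  if (propagate) {
    for (t in topo) # children first, so one upward pass suffices
      for (p in parents[[t]])
        gs[[p]] <- union(gs[[p]], gs[[t]])
  }
  structure(list(term_ids = term_ids, parents = parents, children = children,
                 gene_sets = gs, roots = roots),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set:", length(x$term_ids), "terms,",
      length(unique(unlist(x$gene_sets))), "genes,",
      length(x$roots), "root(s)\n")
  invisible(x)
}

#' Read a minimal OBO ontology file
#'
#' Parses `[Term]` stanzas for `id`, `name`, `namespace`, `is_a` and
#' `is_obsolete`; obsolete terms are dropped. Combine with a two-column
#' annotation table via [read_annotations()] and [annotation_set()].
#'
#' @param path OBO file.
#' @param namespace optional namespace filter (e.g. "biological_process").
#' @return list with `parents` (term -> parent IDs) and `names`
#'   (term -> label), suitable for [annotation_set()].
#' @export
read_obo <- function(path, namespace = NULL) {
  lines <- readLines(path, warn = FALSE)
  terms <- list(); cur <- NULL
  flush <- function(cur, terms) {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return(terms)
    if (!is.null(namespace) && !identical(cur$namespace, namespace)) return(terms)
    terms[[cur$id]] <- cur
    terms
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms); cur <- list(); in_term <- TRUE; next
    }
    if (grepl("^\\[", ln)) { # other stanza type
      terms <- flush(cur, terms); cur <- NULL; in_term <- FALSE; next
    }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id: ", ln)) cur$id <- sub("^id: ", "", ln)
    else if (grepl("^name: ", ln)) cur$name <- sub("^name: ", "", ln)
    else if (grepl("^namespace: ", ln)) cur$namespace <- sub("^namespace: ", "", ln)
    else if (grepl("^is_a: ", ln))
      cur$is_a <- c(cur$is_a, sub("\\s*!.*$", "", sub("^is_a: ", "", ln)))
    else if (grepl("^is_obsolete: true", ln)) cur$obsolete <- TRUE
  }
  terms <- flush(cur, terms)
  ids <- names(terms)
  parents <- lapply(terms, function(t) intersect(t$is_a %||% character(0), ids))
  names(parents) <- ids
  list(parents = parents,
       names = vapply(terms, function(t) t$name %||% NA_character_, character(1)))
}

#' Read a gene -> term annotation table
#'
#' @param path two-column TSV (gene, term), no header required; a header line
#'   is auto-detected if the second column matches no term when `terms` given.
#' @param terms optional term universe to filter against.
#' @return named list: term -> gene IDs.
#' @export
read_annotations <- function(path, terms = NULL) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("annotation table needs two columns (gene, term)")
  if (!is.null(terms) && nrow(tab) > 0 && !(tab[1, 2] %in% terms))
    tab <- tab[-1, , drop = FALSE] # header line
  split(as.character(tab[[1]]), as.character(tab[[2]]))
}

#' Derive standard gene classes from an annotation DAG
#'
#' Walks the DAG from the root(s) toward the leaves, counting only genes
#' present in the network. When a child's count drops below `min_size`,
#' descent stops and the parent is emitted as a class, unless the parent
#' exceeds `max_size` genes (too broad; omitted). Adequately sized leaves are
#' emitted directly. Emitted classes are deduplicated.
#'
#' @param ann an `annotation_set`.
#' @param network_genes gene IDs present in the network.
#' @param min_size,max_size class size window (defaults 30 and 300).
#' @return object of class `gene_class_set`: named list term -> network gene
#'   set, ordered by term ID.
#' @export
standard_gene_classes <- function(ann, network_genes, min_size = 30,
                                  max_size = 300) {
  cnt_set <- lapply(ann$gene_sets, intersect, x = network_genes)
  cnt <- vapply(cnt_set, length, 1L)
  emitted <- character(0)
  visited <- character(0)
  walk <- function(t) {
    if (t %in% visited) return()
    visited <<- c(visited, t)
    kids <- ann$children[[t]]
    if (length(kids) == 0) {
      if (cnt[[t]] >= min_size && cnt[[t]] <= max_size)
        emitted <<- c(emitted, t)
      return()
    }
    for (ch in kids) {
      if (cnt[[ch]] < min_size) {
        if (cnt[[t]] <= max_size) emitted <<- c(emitted, t)
      } else walk(ch)
    }
  }
  small_roots <- ann$roots[cnt[ann$roots] < min_size]
  if (length(small_roots) == length(ann$roots)) {
    warning("root(s) hold fewer than min_size network genes; no classes")
    return(structure(list(), class = "gene_class_set"))
  }
  for (r in setdiff(ann$roots, small_roots)) walk(r)
  emitted <- sort(unique(emitted))
  structure(cnt_set[emitted], class = "gene_class_set")
}

#' @export
print.gene_class_set <- function(x, ...) {
  cat("Gene class set:", length(x), "classes")
  if (length(x)) cat(", sizes", min(lengths(x)), "-", max(lengths(x)))
  cat("\n")
  invisible(x)
}

#' Perplexity of a module partition against gene classes
#'
#' Builds the module x class confusion matrix of gene co-occurrences and
#' returns `2 ^ (-sum log2 Phat(c|r) / N)`, where `Phat` row-normalizes the
#' confusion matrix. With `event_level = "gene"` (default) every placed gene
#' contributes one event per (module, class) it occupies; `"cell"` counts
#' each nonzero confusion cell once. Lower is better; a diagonal confusion
#' matrix gives exactly 1. The normalized value multiplies by the fraction of
#' dataset genes the method actually placed.
#'
#' @param part a `module_partition`.
#' @param classes a `gene_class_set`.
#' @param n_dataset_genes genes in the full dataset (for normalization).
#' @param event_level `"gene"` or `"cell"`.
#' @return list: `raw`, `normalized`, `confusion`, `n_events`.
#' @export
perplexity <- function(part, classes, n_dataset_genes,
                       event_level = c("gene", "cell")) {
  event_level <- match.arg(event_level)
  mods <- module_gene_sets(part)
  if (length(mods) == 0 || length(classes) == 0)
    stop("empty confusion matrix: no modules or no classes")
  conf <- matrix(0L, length(mods), length(classes),
                 dimnames = list(names(mods), names(classes)))
  for (r in names(mods))
    for (cc in names(classes))
      conf[r, cc] <- length(intersect(mods[[r]], classes[[cc]]))
  if (sum(conf) == 0)
    stop("empty confusion matrix: no gene is in both a module and a class")
  rs <- rowSums(conf)
  phat <- conf / ifelse(rs == 0, 1, rs)
  nz <- conf > 0
  if (event_level == "gene") {
    N <- sum(conf)
    loss <- -sum(conf[nz] * log2(phat[nz])) / N
  } else {
    N <- sum(nz)
    loss <- -sum(log2(phat[nz])) / N
  }
  raw <- 2^loss
  placed <- sum(vapply(part$modules, length, 1L) > 0)
  list(raw = raw, normalized = raw * placed / n_dataset_genes,
       confusion = conf, n_events = N)
}

#' Hypergeometric over-representation score per module
#'
#' For every module and annotation term, the one-sided over-representation
#' p-value of the overlap under the hypergeometric distribution; a module's
#' enrichment score is the maximum of -log10(p) over terms (the negative-log
#' GO enrichment reading of a DAVID-style score).
#'
#' @param part a `module_partition` (possibly multi-assigned).
#' @param ann an `annotation_set` or a `gene_class_set` / named list of gene
#'   sets to test against.
#' @param universe background gene IDs (must cover all module genes).
#' @return data.frame with one row per module: `module`, `size`, `score`,
#'   `best_term`; per-term p-values attached as attribute `"p_values"`
#'   (module x term matrix).
#' @export
module_enrichment <- function(part, ann, universe) {
  sets <- if (inherits(ann, "annotation_set")) ann$gene_sets else ann
  sets <- lapply(sets, intersect, x = universe)
  mods <- module_gene_sets(part)
  if (!all(unlist(mods) %in% universe))
    stop("universe must contain all module genes")
  N <- length(universe)
  pv <- matrix(1, length(mods), length(sets),
               dimnames = list(names(mods), names(sets)))
  for (r in names(mods)) {
    m <- length(mods[[r]])
    if (m == 0) next
    for (tt in names(sets)) {
      K <- length(sets[[tt]])
      if (K == 0) next
      k <- length(intersect(mods[[r]], sets[[tt]]))
      pv[r, tt] <- phyper(k - 1, K, N - K, m, lower.tail = FALSE)
    }
  }
  score <- apply(pv, 1, function(p) max(-log10(pmax(p, 1e-300))))
  best <- colnames(pv)[apply(pv, 1, which.min)]
  sizes <- vapply(mods, length, 1L)
  empty <- sizes == 0
  score[empty] <- 0
  out <- data.frame(module = names(mods), size = sizes, score = score,
                    best_term = best, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "p_values") <- pv
  out
}

#' Usefulness of a module decomposition
#'
#' `U = sum_i score_i / log2(N_i) - log10(M)`: enrichment rewarded, large
#' modules discounted, unplaced genes penalized. Modules of size 1 are
#' excluded (log2 1 = 0) with a warning; M = 0 is treated as M = 1 (no
#' penalty) with a message.
#'
#' @param scores per-module enrichment scores.
#' @param sizes per-module gene counts (parallel to `scores`).
#' @param n_unplaced number of genes placed in no module (M).
#' @return usefulness value.
#' @export
usefulness <- function(scores, sizes, n_unplaced) {
  stopifnot(length(scores) == length(sizes), all(sizes >= 1))
  if (any(sizes == 1)) {
    warning(sum(sizes == 1), " singleton module(s) excluded from usefulness")
    scores <- scores[sizes > 1]
    sizes <- sizes[sizes > 1]
  }
  if (n_unplaced == 0) {
    message("no unplaced genes; usefulness penalty uses M = 1")
    n_unplaced <- 1
  }
  sum(scores / log2(sizes)) - log10(n_unplaced)
}

#' Fisher-exact module preservation between two partitions
#'
#' For every module pair across two partitions of the same gene universe, the
#' overlap count and the one-sided (over-representation) Fisher exact
#' p-value of the 2x2 membership table.
#'
#' @param part_A,part_B `module_partition`s over `universe`.
#' @param universe common gene IDs.
#' @return list of class `stability_table`: `overlap` and `p_value` matrices
#'   (modules of A x modules of B).
#' @export
module_stability <- function(part_A, part_B, universe) {
  ga <- module_gene_sets(part_A)
  gb <- module_gene_sets(part_B)
  N <- length(universe)
  ov <- matrix(0L, length(ga), length(gb),
               dimnames = list(names(ga), names(gb)))
  pv <- matrix(1, length(ga), length(gb),
               dimnames = list(names(ga), names(gb)))
  for (a in names(ga)) {
    A <- intersect(ga[[a]], universe)
    for (b in names(gb)) {
      B <- intersect(gb[[b]], universe)
      k <- length(intersect(A, B))
      ov[a, b] <- k
      tab <- matrix(c(k, length(A) - k,
                      length(B) - k, N - length(A) - length(B) + k), 2, 2)
      pv[a, b] <- fisher.test(tab, alternative = "greater")$p.value
    }
  }
  structure(list(overlap = ov, p_value = pv), class = "stability_table")
}

#' @export
print.stability_table <- function(x, ...) {
  cat("Module preservation (-log10 p):\n")
  print(round(-log10(pmax(x$p_value, 1e-300)), 1))
  invisible(x)
}

#' Census of non-linear relationships: high MIC vs Pearson
#'
#' Collects all gene pairs with MIC above `mic_cut` and records their
#' absolute Pearson correlations; the fraction with |r| below `low_cut`
#' measures relationships only the information-theoretic score detects
#' (e.g. condition-dependent, gene-by-environment pairs), the fraction above
#' `high_cut` the near-perfectly linear ones.
#'
#' @param expr genes x samples matrix.
#' @param mic_cut MIC inclusion threshold (default 0.9, strict >).
#' @param low_cut,high_cut |r| boundaries (defaults 0.6 and 0.9).
#' @param subsample_to optional uniform subsample size for comparability
#'   across datasets (seeded); larger than the census leaves it unchanged.
#' @param seed subsampling seed.
#' @param mic,pearson optional precomputed association matrices (computed
#'   from `expr` when NULL).
#' @return object of class `census_result`: `n_high_mic`, `pairs`
#'   (data.frame gene1, gene2, mic, abs_r), `frac_low`, `frac_high`.
#' @export
nonlinearity_census <- function(expr, mic_cut = 0.9, low_cut = 0.6,
                                high_cut = 0.9, subsample_to = NULL, seed = 1,
                                mic = NULL, pearson = NULL) {
  if (is.null(mic)) mic <- mic_matrix(expr)
  if (is.null(pearson)) pearson <- pearson_matrix(expr, absolute = TRUE)
  stopifnot(identical(dim(mic), dim(pearson)))
  idx <- which(upper.tri(mic) & mic > mic_cut, arr.ind = TRUE)
  if (nrow(idx) == 0)
    message("no pair exceeds MIC > ", mic_cut, "; empty census")
  pairs <- data.frame(gene1 = rownames(mic)[idx[, 1]],
                      gene2 = rownames(mic)[idx[, 2]],
                      mic = mic[idx],
                      abs_r = pearson[idx],
                      stringsAsFactors = FALSE)
  n_high <- nrow(pairs)
  if (!is.null(subsample_to) && subsample_to < n_high) {
    set.seed(seed)
    pairs <- pairs[sample.int(n_high, subsample_to), , drop = FALSE]
  }
  structure(list(n_high_mic = n_high,
                 pairs = pairs,
                 frac_low = if (nrow(pairs)) mean(pairs$abs_r < low_cut) else NA_real_,
                 frac_high = if (nrow(pairs)) mean(pairs$abs_r > high_cut) else NA_real_),
            class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  cat("Non-linearity census:", x$n_high_mic, "high-MIC pairs;",
      sprintf("%.1f%% with |r| below and %.1f%% above the cuts\n",
              100 * x$frac_low, 100 * x$frac_high))
  invisible(x)
}

#' Select the membership cutoff maximizing usefulness
#'
#' Restricts the candidate cutoffs to those whose eigengene stability (mean
#' |cor| to the other cutoffs and to the weighted PCA) reaches
#' `stability_floor`, then evaluates usefulness at each via
#' [threshold_membership()] and [module_enrichment()] and returns the argmax
#' (ties to the lowest cutoff). If no cutoff passes the floor, all cutoffs
#' are scanned with a warning.
#'
#' @param expr genes x samples matrix.
#' @param mm a `membership_matrix`.
#' @param ann an `annotation_set` (or named gene sets) for enrichment.
#' @param universe background gene IDs.
#' @param cutoffs candidate membership cutoffs.
#' @param stability_floor stability requirement (default 0.99).
#' @return list: `best_cutoff`, `table` (cutoff, stability, eligible, U).
#' @export
optimal_cutoff_scan <- function(expr, mm, ann, universe,
                                cutoffs = seq(0.10, 0.90, by = 0.05),
                                stability_floor = 0.99) {
  prof <- stability_profile(expr, mm, cutoffs)
  nc <- length(cutoffs)
  stab <- vapply(seq_len(nc), function(a) {
    v <- c(prof$pairwise_corr[a, -a], prof$corr_to_weighted[a])
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  eligible <- !is.na(stab) & stab >= stability_floor
  if (!any(eligible)) {
    warning("no cutoff passes the stability floor; scanning all cutoffs")
    eligible <- rep(TRUE, nc)
  }
  U <- rep(NA_real_, nc)
  for (a in which(eligible)) {
    part <- threshold_membership(mm, cutoffs[a])
    sizes <- lengths(module_gene_sets(part))
    unplaced <- sum(vapply(part$modules, length, 1L) == 0)
    if (length(sizes) == 0 || all(sizes < 2)) next
    enr <- module_enrichment(part, ann, universe)
    keep <- enr$size >= 2
    U[a] <- suppressWarnings(
      suppressMessages(usefulness(enr$score[keep], enr$size[keep],
                                  max(unplaced, 1))))
  }
  tab <- data.frame(cutoff = cutoffs, stability = stab,
                    eligible = eligible, usefulness = U)
  if (all(is.na(U))) stop("usefulness undefined at every cutoff")
  best <- cutoffs[which(U == max(U, na.rm = TRUE))[1]]
  list(best_cutoff = best, table = tab)
}
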