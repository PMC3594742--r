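# Evaluation statistics: class traversal, perplexity, enrichment,
# usefulness, stability, census, cutoff scan.

flat_ann <- function(n_terms, genes_per_term, prefix = "T") {
  ids <- paste0(prefix, seq_len(n_terms))
  parents <- c(list(character(0)), rep(list("ROOT"), n_terms))
  names(parents) <- c("ROOT", ids)
  gene_sets <- lapply(seq_len(n_terms), function(i)
    paste0("g", (i - 1) * genes_per_term + seq_len(genes_per_term)))
  names(gene_sets) <- ids
  annotation_set(parents, gene_sets)
}

test_that("annotations propagate child to parent and cycles are rejected", {
  ann <- annotation_set(
    parents = list(root = character(0), a = "root", a1 = "a"),
    gene_sets = list(a1 = c("g1", "g2"), a = "g3"))
  expect_setequal(ann$gene_sets$root, c("g1", "g2", "g3"))
  expect_setequal(ann$gene_sets$a, c("g1", "g2", "g3"))
  expect_error(annotation_set(list(a = "b", b = "a"), list()), "root")
})

test_that("a flat ontology of mid-sized terms emits every term", {
  ann <- flat_ann(4, 50)
  classes <- standard_gene_classes(ann, paste0("g", 1:200))
  expect_setequal(names(classes), paste0("T", 1:4))
})

test_that("traversal stops at undersized children and omits oversized parents", {
  # root(400) -> A(200) -> {A1(25), A2(40)}; B(200) fills the rest
  genes <- paste0("g", 1:400)
  ann <- annotation_set(
    parents = list(root = character(0), A = "root", B = "root",
                   A1 = "A", A2 = "A"),
    gene_sets = list(A1 = genes[1:25], A2 = genes[26:65],
                     A = genes[1:200], B = genes[201:400]))
  classes <- standard_gene_classes(ann, genes)
  # A1 < 30 stops descent and emits A; A2 is an adequately sized leaf;
  # B is a leaf in range
  expect_setequal(names(classes), c("A", "A2", "B"))
  # an oversized parent with an undersized child is omitted
  ann2 <- annotation_set(
    parents = list(root = character(0), P = "root", P1 = "P"),
    gene_sets = list(P1 = genes[1:20], P = genes[1:350]))
  classes2 <- standard_gene_classes(ann2, genes)
  expect_false("P" %in% names(classes2))
})

test_that("a root below min_size yields no classes with a warning", {
  ann <- annotation_set(parents = list(root = character(0)),
                        gene_sets = list(root = paste0("g", 1:10)))
  expect_warning(cl <- standard_gene_classes(ann, paste0("g", 1:10)),
                 "fewer than min_size")
  expect_length(cl, 0)
})

test_that("perplexity closed forms: diagonal is 1, uniform over 4 is 4", {
  genes <- paste0("g", 1:80)
  classes <- structure(split(genes, rep(1:4, each = 20)),
                       class = "gene_class_set")
  names(classes) <- paste0("C", 1:4)
  # modules identical to classes
  part <- new_partition(genes, as.list(paste0("M", rep(1:4, each = 20))))
  names(classes) <- paste0("C", 1:4)
  diag_part <- perplexity(part, classes, n_dataset_genes = 80)
  expect_equal(diag_part$raw, 1, tolerance = 1e-12)
  expect_equal(diag_part$normalized, 1, tolerance = 1e-12)
  # each module spread uniformly over the 4 classes
  part_u <- new_partition(genes, as.list(paste0("M", rep(1:4, times = 20))))
  unif <- perplexity(part_u, classes, n_dataset_genes = 80)
  expect_equal(unif$raw, 4, tolerance = 1e-12)
  # both event conventions agree on these closed forms
  expect_equal(perplexity(part_u, classes, 80, event_level = "cell")$raw, 4,
               tolerance = 1e-12)
})

test_that("perplexity matches a direct evaluation of the formula", {
  # 2 modules x 3 classes with counts ((6,2,0),(1,1,8))
  conf <- rbind(c(6, 2, 0), c(1, 1, 8))
  genes <- paste0("g", 1:18)
  mods <- rep(c("M1", "M2"), rowSums(conf))
  cls <- c(rep(c("C1", "C2", "C3"), conf[1, ]),
           rep(c("C1", "C2", "C3"), conf[2, ]))
  part <- new_partition(genes, as.list(mods))
  classes <- structure(split(genes, cls), class = "gene_class_set")
  got <- perplexity(part, classes, n_dataset_genes = 20)
  # independent direct evaluation
  phat <- conf / rowSums(conf)
  events <- 0; N <- sum(conf)
  for (r in 1:2) for (cc in 1:3)
    if (conf[r, cc] > 0) events <- events + conf[r, cc] * log2(phat[r, cc])
  expect_equal(got$raw, 2^(-events / N), tolerance = 1e-12)
  expect_equal(got$normalized, got$raw * 18 / 20, tolerance = 1e-12)
  expect_gte(got$raw, 1)
})

test_that("enrichment scores equal the hypergeometric tail sum", {
  universe <- paste0("g", 1:100)
  term_genes <- paste0("g", 1:10)
  ann <- list(rare = term_genes)
  part <- new_partition(universe,
                        c(as.list(rep("M1", 10)),
                          rep(list(character(0)), 90)))
  part$modules[["g6"]] <- character(0) # module of 9: overlap 5 after edits
  part <- new_partition(universe,
                        c(as.list(rep("M1", 5)), # g1..g5 in the term
                          as.list(rep("M1", 5)), # g6..g10 also in the term
                          rep(list(character(0)), 90)))
  enr <- module_enrichment(part, ann, universe)
  # module = the term exactly: p = choose-based point tail
  p_exact <- sum(dhyper(10:10, 10, 90, 10))
  expect_equal(enr$score[enr$module == "M1"], -log10(p_exact),
               tolerance = 1e-9)
  # 2x2 table (module 10, term 10, overlap 5, universe 100)
  part2 <- new_partition(universe,
                         c(as.list(rep("M1", 5)), # overlap g1..g5
                           rep(list(character(0)), 5),
                           as.list(rep("M1", 5)), # g11..g15 outside the term
                           rep(list(character(0)), 85)))
  enr2 <- module_enrichment(part2, ann, universe)
  p_tail <- sum(dhyper(5:10, 10, 90, 10))
  expect_equal(enr2$score[1], -log10(p_tail), tolerance = 1e-9)
})

test_that("a perfectly enriched module beats random draws", {
  set.seed(17)
  universe <- paste0("g", 1:100)
  ann <- list(t1 = paste0("g", 1:10))
  perfect <- new_partition(universe,
                           c(as.list(rep("M1", 10)),
                             rep(list(character(0)), 90)))
  s_perfect <- module_enrichment(perfect, ann, universe)$score[1]
  rand_scores <- replicate(200, {
    pick <- sample(universe, 10)
    p <- new_partition(universe, lapply(universe, function(g)
      if (g %in% pick) "M1" else character(0)))
    module_enrichment(p, ann, universe)$score[1]
  })
  expect_lt(median(rand_scores), s_perfect)
})

test_that("usefulness reproduces the worked closed forms", {
  expect_equal(usefulness(4.0, 16, 10), 0.0, tolerance = 1e-12)
  expect_equal(usefulness(c(3.0, 6.0), c(8, 64), 10), 1.0, tolerance = 1e-12)
  # strictly decreasing in unplaced count, increasing in any score
  expect_gt(usefulness(c(3, 6), c(8, 64), 10),
            usefulness(c(3, 6), c(8, 64), 100))
  expect_gt(usefulness(c(4, 6), c(8, 64), 10),
            usefulness(c(3, 6), c(8, 64), 10))
  expect_warning(u <- usefulness(c(3, 5), c(8, 1), 10), "singleton")
  expect_equal(u, 3 / 3 - 1, tolerance = 1e-12)
  expect_message(u0 <- usefulness(3, 8, 0), "M = 1")
  expect_equal(u0, 1, tolerance = 1e-12)
})

test_that("module stability p-values equal the hypergeometric tail", {
  universe <- paste0("g", 1:100)
  A <- new_partition(universe, c(as.list(rep("A1", 10)),
                                 rep(list(character(0)), 90)))
  # B1 overlaps A1 in 5 genes
  B <- new_partition(universe, c(as.list(rep("B1", 5)),
                                 rep(list(character(0)), 5),
                                 as.list(rep("B1", 5)),
                                 rep(list(character(0)), 85)))
  st <- module_stability(A, B, universe)
  expect_equal(st$overlap["A1", "B1"], 5)
  p_tail <- sum(dhyper(5:10, 10, 90, 10))
  expect_equal(st$p_value["A1", "B1"], p_tail, tolerance = 1e-9)
  # symmetry under swapping the partitions
  st2 <- module_stability(B, A, universe)
  expect_equal(st$p_value["A1", "B1"], st2$p_value["B1", "A1"],
               tolerance = 1e-12)
  # identical partitions: tiny diagonal p, p = 1 for zero overlap
  A2 <- new_partition(universe, c(as.list(rep("A1", 10)),
                                  as.list(rep("A2", 10)),
                                  rep(list(character(0)), 80)))
  st3 <- module_stability(A2, A2, universe)
  expect_lt(st3$p_value["A1", "A1"], 1e-10)
  expect_equal(st3$p_value["A1", "A2"], 1)
})

test_that("census fractions and monotonicity behave on constructed data", {
  set.seed(19)
  f <- rnorm(60)
  expr <- rbind(g1 = f, g2 = f + rnorm(60, 0, 0.01),
                g3 = 2 * f + rnorm(60, 0, 0.01), g4 = rnorm(60))
  colnames(expr) <- paste0("s", 1:60)
  cen <- nonlinearity_census(expr, mic_cut = 0.9)
  expect_equal(cen$frac_low, 0) # all high-MIC pairs are linear here
  # raising the cut never increases the census size
  cen2 <- nonlinearity_census(expr, mic_cut = 0.95)
  expect_lte(cen2$n_high_mic, cen$n_high_mic)
  # subsample larger than the census returns it unchanged
  cen3 <- nonlinearity_census(expr, mic_cut = 0.9,
                              subsample_to = cen$n_high_mic + 10)
  expect_equal(nrow(cen3$pairs), cen$n_high_mic)
  # planted gxe pair: high MIC, low |r|
  set.seed(20)
  cond <- rep(c(1, -1), each = 50)
  fg <- 1.2 * cond + rnorm(100)
  e2 <- rbind(a = std_ <- (fg - mean(fg)) / sd(fg) + rnorm(100, 0, 0.05),
              b = (cond * fg - mean(cond * fg)) / sd(cond * fg) +
                rnorm(100, 0, 0.05))
  colnames(e2) <- paste0("s", 1:100)
  cenx <- nonlinearity_census(e2, mic_cut = 0.8)
  expect_equal(cenx$n_high_mic, 1)
  expect_lt(cenx$pairs$abs_r, 0.3)
})

test_that("optimal cutoff scan returns the usefulness argmax, low tie first", {
  set.seed(23)
  n_per <- 20
  f <- replicate(3, rnorm(50), simplify = FALSE)
  expr <- do.call(rbind, lapply(f, function(v)
    t(sapply(1:n_per, function(i) v + rnorm(50, 0, 0.1)))))
  dimnames(expr) <- list(paste0("g", 1:60), paste0("s", 1:50))
  true_mod <- rep(1:3, each = n_per)
  eps <- rbeta(60, 2, 12)
  mm <- sapply(1:3, function(m) ifelse(true_mod == m, 1 - eps, eps / 2))
  mm <- mm / rowSums(mm)
  dimnames(mm) <- list(rownames(expr), paste0("M", 1:3))
  class(mm) <- c("membership_matrix", "matrix")
  ann <- list(c1 = paste0("g", 1:20), c2 = paste0("g", 21:40),
              c3 = paste0("g", 41:60))
  cuts <- seq(0.35, 0.55, by = 0.05)
  scan <- suppressWarnings(suppressMessages(
    optimal_cutoff_scan(expr, mm, ann, rownames(expr), cutoffs = cuts,
                        stability_floor = 0.95)))
  # exhaustive per-cutoff evaluation oracle
  us <- sapply(cuts, function(ct) {
    part <- threshold_membership(mm, ct)
    enr <- module_enrichment(part, ann, rownames(expr))
    keep <- enr$size >= 2
    unpl <- max(sum(lengths(part$modules) == 0), 1)
    suppressWarnings(suppressMessages(
      usefulness(enr$score[keep], enr$size[keep], unpl)))
  })
  eligible <- scan$table$eligible
  expect_equal(scan$best_cutoff,
               cuts[eligible][which.max(us[eligible])])
})
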