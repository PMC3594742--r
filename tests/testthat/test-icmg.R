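# ICMg sampler: conditional formula, exact-posterior agreement, count
# conservation, separation, planted recovery, membership thresholding.

test_that("gibbs conditional matches direct scalar substitution", {
  # C = 2, M = 4, N' = 3, n' = (2, 1), alpha = 1, beta = 0.5
  n_z <- c(2, 1)
  q <- rbind(c(2, 1, 0, 0), c(0, 1, 0, 2))
  a <- 1; b <- 0.5; M <- 4
  w1 <- (2 + a) / (3 + 2 * a) * ((2 + b) * (1 + b)) /
    ((2 * 2 + 1 + M * b) * (2 * 2 + M * b))
  w2 <- (1 + a) / (3 + 2 * a) * ((0 + b) * (1 + b)) /
    ((2 * 1 + 1 + M * b) * (2 * 1 + M * b))
  expect_equal(gibbs_conditional(n_z, q, 1, 2, a, b),
               c(w1, w2) / (w1 + w2), tolerance = 1e-15)
})

test_that("empty primed counts give the uniform conditional", {
  q <- matrix(0, 3, 5)
  expect_equal(gibbs_conditional(rep(0, 3), q, 2, 4, 10, 0.1),
               rep(1 / 3, 3))
})

test_that("the conditional is scale-free in the unnormalized weights", {
  # doubling alpha-independent constants cannot change the result:
  # normalization is checked by summing to 1 across random states
  set.seed(1)
  for (i in 1:10) {
    n_z <- rpois(4, 3)
    q <- matrix(rpois(4 * 6, 1), 4, 6)
    p <- gibbs_conditional(n_z, q, 1, 6, 2, 0.3)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("count invariants hold after every sweep", {
  el <- make_edge_list(paste0("n", 1:5),
                       from = c("n1", "n2", "n3", "n1"),
                       to = c("n2", "n3", "n4", "n5"))
  cfg <- icmg_config(3, burn_in = 200, thin = 2, sampling_iters = 200,
                     seed = 11)
  # cpp-side verification errors out on any violation
  expect_no_error(run_icmg(el, cfg, check_counts = TRUE))
})

test_that("sampler co-assignment frequencies match exact enumeration", {
  # all <= 4-link shapes on small node sets, C = 2, default alpha/beta
  shapes <- list(
    path3 = cbind(c(1, 2, 3), c(2, 3, 4)),
    star3 = cbind(c(1, 1, 1), c(2, 3, 4)),
    tri = cbind(c(1, 2, 3), c(2, 3, 1)),
    path4 = cbind(c(1, 2, 3, 4), c(2, 3, 4, 5)),
    square = cbind(c(1, 2, 3, 4), c(2, 3, 4, 1)),
    tri_tail = cbind(c(1, 2, 3, 3), c(2, 3, 1, 4)))
  for (nm in names(shapes)) {
    ei <- shapes[[nm]]
    M <- max(ei)
    post <- oracle_icmg_posterior(ei, M, 2, 10, 0.1)
    co_exact <- oracle_coassignment(post)
    el <- make_edge_list(paste0("n", 1:M),
                         from = paste0("n", ei[, 1]),
                         to = paste0("n", ei[, 2]))
    cfg <- icmg_config(2, burn_in = 500, thin = 10,
                       sampling_iters = 100000, seed = 21)
    mm <- run_icmg(el, cfg, keep_draws = TRUE)
    draws <- attr(mm, "draws")
    co_hat <- co_from_draws(draws)
    se <- co_mcse(draws)
    off <- upper.tri(co_exact)
    expect_true(all(abs(co_hat[off] - co_exact[off]) <=
                      3 * pmax(se[off], 1e-4)),
                label = paste("co-assignment within 3 MCSE for", nm))
  }
})

test_that("two disjoint triangles separate into different components", {
  el <- two_triangles()
  # short sampling window: the chain stays in one labeling mode
  cfg <- icmg_config(2, burn_in = 2000, thin = 5, sampling_iters = 50,
                     seed = 1)
  mm <- run_icmg(el, cfg)
  expect_true(all(apply(mm, 1, max) > 0.9))
  lab <- partition_labels(harden(mm))
  expect_equal(length(unique(lab[c("n1", "n2", "n3")])), 1)
  expect_equal(length(unique(lab[c("n4", "n5", "n6")])), 1)
  expect_false(lab[["n1"]] == lab[["n4"]])
})

test_that("same seed gives bit-identical memberships", {
  el <- two_triangles()
  cfg <- icmg_config(2, burn_in = 300, thin = 5, sampling_iters = 100,
                     seed = 99)
  mm1 <- run_icmg(el, cfg)
  mm2 <- run_icmg(el, cfg)
  expect_identical(unclass(mm1)[, ], unclass(mm2)[, ])
})

test_that("node relabeling carries memberships along (same seed stream)", {
  el <- make_edge_list(paste0("n", 1:5),
                       from = c("n1", "n2", "n3", "n1"),
                       to = c("n2", "n3", "n4", "n5"))
  cfg <- icmg_config(2, burn_in = 200, thin = 5, sampling_iters = 100,
                     seed = 7)
  mm <- run_icmg(el, cfg)
  ren <- setNames(paste0("x", 5:1), paste0("n", 1:5))
  el2 <- make_edge_list(unname(ren[el$nodes]),
                        from = unname(ren[el$edges[, 1]]),
                        to = unname(ren[el$edges[, 2]]))
  mm2 <- run_icmg(el2, cfg)
  expect_equal(unname(unclass(mm2)[, ]), unname(unclass(mm)[, ]))
  expect_identical(rownames(mm2), unname(ren[rownames(mm)]))
})

test_that("planted 4-module graph is recovered at the reduced schedule", {
  set.seed(42)
  M <- 200
  truth <- rep(1:4, each = 50)
  P <- outer(truth, truth, function(a, b) ifelse(a == b, 0.2, 0.005))
  sel <- which(upper.tri(P) & matrix(runif(M * M), M, M) < P, arr.ind = TRUE)
  nodes <- paste0("g", 1:M)
  el <- make_edge_list(nodes, nodes[sel[, 1]], nodes[sel[, 2]])
  cfg <- icmg_config(4, burn_in = 2000, thin = 10, sampling_iters = 10000,
                     seed = 1)
  mm <- run_icmg(el, cfg)
  lab <- partition_labels(harden(mm))
  ari <- adjusted_rand_index(lab, truth)
  expect_gte(ari, 0.8)
  # the package ARI helper agrees with the reference implementation
  skip_if_not_installed("mclust")
  expect_equal(ari, mclust::adjustedRandIndex(lab, as.character(truth)),
               tolerance = 1e-12)
})

test_that("zero-degree nodes get uniform rows flagged unsupported", {
  el <- make_edge_list(c("a", "b", "c", "iso"),
                       from = c("a", "b"), to = c("b", "c"))
  cfg <- icmg_config(2, burn_in = 100, thin = 5, sampling_iters = 100,
                     seed = 3)
  mm <- run_icmg(el, cfg)
  expect_identical(attr(mm, "unsupported"), "iso")
  expect_equal(unname(mm["iso", ]), c(0.5, 0.5))
  part <- harden(mm)
  expect_length(part$modules[["iso"]], 0)
})

test_that("genes bridging two modules receive split membership", {
  # two 5-cliques sharing gene "br" wired into both
  n1 <- paste0("a", 1:5); n2 <- paste0("b", 1:5)
  pairs1 <- t(combn(n1, 2)); pairs2 <- t(combn(n2, 2))
  bridge <- rbind(cbind("br", n1), cbind("br", n2))
  el <- make_edge_list(c(n1, n2, "br"),
                       from = c(pairs1[, 1], pairs2[, 1], bridge[, 1]),
                       to = c(pairs1[, 2], pairs2[, 2], bridge[, 2]))
  cfg <- icmg_config(2, burn_in = 2000, thin = 5, sampling_iters = 100,
                     seed = 5)
  mm <- run_icmg(el, cfg)
  expect_true(all(mm["br", ] >= 0.25))
  expect_true(all(apply(mm[c(n1, n2), ], 1, max) > 0.7))
})

test_that("harden uses argmax with lowest-index ties and keeps unplaced", {
  mm <- structure(rbind(g1 = c(0.1, 0.7, 0.2),
                        g2 = c(0.5, 0.5, 0),
                        g3 = rep(1 / 3, 3)),
                  class = c("membership_matrix", "matrix"))
  colnames(mm) <- paste0("M", 1:3)
  attr(mm, "unsupported") <- "g3"
  part <- harden(mm)
  expect_identical(part$modules[["g1"]], "M2")
  expect_identical(part$modules[["g2"]], "M1")
  expect_length(part$modules[["g3"]], 0)
})

test_that("threshold_membership multi-assigns and unplaced count is monotone", {
  mm <- structure(rbind(g1 = c(0.40, 0.36, 0.24),
                        g2 = c(0.05, 0.05, 0.90)),
                  class = c("membership_matrix", "matrix"))
  colnames(mm) <- paste0("M", 1:3)
  part <- threshold_membership(mm, 0.35)
  expect_setequal(part$modules[["g1"]], c("M1", "M2"))
  expect_identical(part$modules[["g2"]], "M3")
  p9 <- threshold_membership(mm, 0.95)
  expect_length(p9$modules[["g1"]], 0)
  # monotone unplaced count on a random 100-gene membership matrix
  set.seed(6)
  raw <- matrix(rgamma(100 * 4, 0.7), 100, 4)
  m <- raw / rowSums(raw)
  dimnames(m) <- list(paste0("g", 1:100), paste0("M", 1:4))
  class(m) <- c("membership_matrix", "matrix")
  unplaced <- sapply(seq(0.1, 0.9, 0.05), function(ct)
    sum(lengths(threshold_membership(m, ct)$modules) == 0))
  expect_true(all(diff(unplaced) >= 0))
})
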