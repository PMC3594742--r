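# Independent oracles, coded from the definitions, against which the
# package's implementations are checked.

# --- MIC: brute-force enumeration over rank grids (plain R) ----------------
# Enumerates every grid with x_bins * y_bins < n^exponent (minimum 2x2 always
# admitted), cuts at boundaries between distinct values only.
oracle_mic <- function(x, y, exponent = 0.6) {
  n <- length(x)
  B <- n^exponent
  mi_grid <- function(xb, yb) {
    tab <- table(xb, yb)
    p <- tab / n
    px <- rowSums(p); py <- colSums(p)
    s <- 0
    for (i in seq_len(nrow(p)))
      for (j in seq_len(ncol(p)))
        if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    s
  }
  gx <- match(x, sort(unique(x))) # value-group index
  gy <- match(y, sort(unique(y)))
  best <- 0
  for (cx in 2:max(2, length(unique(gx)))) {
    for (cy in 2:max(2, length(unique(gy)))) {
      if (!(cx == 2 && cy == 2) && cx * cy >= B) next
      xcands <- seq_len(length(unique(gx)) - 1)
      ycands <- seq_len(length(unique(gy)) - 1)
      if (length(xcands) < cx - 1 || length(ycands) < cy - 1) next
      xcuts <- t(combn(xcands, cx - 1))
      ycuts <- t(combn(ycands, cy - 1))
      for (a in seq_len(nrow(xcuts))) {
        xb <- findInterval(gx, c(-Inf, xcuts[a, ] + 0.5))
        for (b in seq_len(nrow(ycuts))) {
          yb <- findInterval(gy, c(-Inf, ycuts[b, ] + 0.5))
          v <- as.numeric(mi_grid(xb, yb)) / log2(min(cx, cy))
          if (v > best) best <- v
        }
      }
    }
  }
  best
}

# --- ICMg: exact posterior by enumerating all joint label states -----------
# Collapsed joint: P(z) proportional to
#   prod_z rising(alpha, n_z) * prod_{z,i} rising(beta, q_zi) / rising(M beta, 2 n_z)
oracle_icmg_posterior <- function(edges_idx, M, C, alpha, beta) {
  rising <- function(a, k) if (k == 0) 1 else prod(a + 0:(k - 1))
  L <- nrow(edges_idx)
  states <- as.matrix(expand.grid(rep(list(1:C), L)))
  w <- apply(states, 1, function(z) {
    nz <- tabulate(z, C)
    q <- matrix(0L, C, M)
    for (l in 1:L) {
      q[z[l], edges_idx[l, 1]] <- q[z[l], edges_idx[l, 1]] + 1L
      q[z[l], edges_idx[l, 2]] <- q[z[l], edges_idx[l, 2]] + 1L
    }
    pr <- 1
    for (zc in 1:C) {
      pr <- pr * rising(alpha, nz[zc]) / rising(M * beta, 2 * nz[zc])
      for (i in 1:M) pr <- pr * rising(beta, q[zc, i])
    }
    pr
  })
  list(states = states, prob = w / sum(w))
}

# label-invariant summary: P(z_a == z_b) for all link pairs
oracle_coassignment <- function(post) {
  L <- ncol(post$states)
  co <- matrix(0, L, L)
  for (a in 1:L)
    for (b in 1:L)
      co[a, b] <- sum(post$prob[post$states[, a] == post$states[, b]])
  co
}

co_from_draws <- function(draws) {
  L <- ncol(draws)
  co <- matrix(0, L, L)
  for (a in 1:L)
    for (b in 1:L) co[a, b] <- mean(draws[, a] == draws[, b])
  co
}

# Monte Carlo standard error of the co-assignment estimates. Thinned draws
# are empirically uncorrelated (lag-1 acf ~ 0.01 at thin = 10 on these tiny
# graphs), so the binomial standard error applies.
co_mcse <- function(draws) {
  L <- ncol(draws)
  S <- nrow(draws)
  se <- matrix(0, L, L)
  for (a in 1:L)
    for (b in 1:L) {
      p <- mean(draws[, a] == draws[, b])
      se[a, b] <- sqrt(p * (1 - p) / S)
    }
  se
}

# --- TOM: triple-loop brute force ------------------------------------------
oracle_tom <- function(adj) {
  a <- adj
  diag(a) <- 0
  m <- nrow(a)
  k <- rowSums(a)
  out <- matrix(1, m, m, dimnames = dimnames(adj))
  for (i in 1:m)
    for (j in 1:m) {
      if (i == j) next
      s <- 0
      for (u in 1:m) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  out
}

# --- scale-free fit: independent binning + least squares -------------------
oracle_sft_r2 <- function(k, n_bins = 10) {
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  cnt <- as.integer(table(bin))
  mk <- tapply(k, bin, mean)
  ok <- cnt > 0 & !is.na(mk) & mk > 0
  lx <- log10(mk[ok]); ly <- log10(cnt[ok] / length(k))
  b <- cov(lx, ly) / var(lx)
  r2 <- cor(lx, ly)^2
  -sign(b) * r2
}

# --- hierarchical clustering: naive average linkage ------------------------
oracle_average_linkage_cut <- function(d, k) {
  m <- nrow(d)
  groups <- as.list(seq_len(m))
  while (length(groups) > k) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(groups))
      for (j in seq_along(groups)) {
        if (j <= i) next
        h <- mean(d[groups[[i]], groups[[j]]])
        if (h < bd) { bd <- h; best <- c(i, j) }
      }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  lab <- integer(m)
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  lab
}

# --- shared mid-size fixtures ----------------------------------------------
random_pair <- function(n, seed) {
  set.seed(seed)
  list(x = rnorm(n), y = rnorm(n))
}

two_triangles <- function() {
  structure(list(nodes = paste0("n", 1:6),
                 edges = cbind(from = c("n1", "n2", "n3", "n4", "n5", "n6"),
                               to = c("n2", "n3", "n1", "n5", "n6", "n4")),
                 cutoff_used = 1),
            class = "edge_list")
}

make_edge_list <- function(nodes, from, to) {
  structure(list(nodes = nodes,
                 edges = cbind(from = from, to = to),
                 cutoff_used = 1),
            class = "edge_list")
}
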