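# Scale-free topology: signed R-squared of the log-log degree-frequency
# regression, soft-power selection, hard-threshold selection, binarization.

# Signed scale-free fit of one connectivity vector.
# k values are binned into n_bins equal-width bins; nonempty bins with
# positive mean k enter a regression of log10(relative frequency) on
# log10(mean k). Sign convention: decreasing fits score positive.
sft_r2_signed <- function(k, n_bins = 10) {
  if (length(unique(k)) < 2) {
    warning("all connectivities equal; signed R^2 recorded as 0")
    return(list(r2_signed = 0, slope = NA_real_))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  cnt <- tabulate(as.integer(bin), nbins = n_bins)
  meank <- vapply(seq_len(n_bins),
                  function(b) mean(k[as.integer(bin) == b]), numeric(1))
  ok <- cnt > 0 & !is.na(meank) & meank > 0
  if (sum(ok) < 3) {
    warning("fewer than 3 usable degree bins; signed R^2 recorded as 0")
    return(list(r2_signed = 0, slope = NA_real_))
  }
  lx <- log10(meank[ok])
  ly <- log10(cnt[ok] / length(k))
  fit <- lm(ly ~ lx)
  slope <- unname(coef(fit)[2])
  # exact fits are legitimate here (constructed degree sequences)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(r2_signed = -sign(slope) * r2, slope = slope)
}

#' Scale-free topology fit across soft powers
#'
#' For each power p, connectivity k_i = sum_j != i A_ij^p; the degree
#' distribution is binned (equal width) and log10 relative frequency is
#' regressed on log10 mean connectivity per nonempty bin. The signed fit
#' -sign(slope) * R^2 is positive for decreasing, power-law-like
#' distributions.
#'
#' @param assoc association matrix (entries in \[0, 1\]).
#' @param powers integer powers to scan (default 1:20).
#' @param n_bins number of equal-width degree bins (default 10, >= 5).
#' @return object of class `sft_fit`: data.frame-like list with `powers`,
#'   `r2_signed`, `slope`, plus `n_bins`.
#' @export
sft_fit <- function(assoc, powers = 1:20, n_bins = 10) {
  stopifnot(is.matrix(assoc), n_bins >= 5)
  r2 <- slope <- numeric(length(powers))
  for (i in seq_along(powers)) {
    a <- assoc^powers[i]
    diag(a) <- 0
    k <- rowSums(a)
    f <- sft_r2_signed(k, n_bins)
    r2[i] <- f$r2_signed
    slope[i] <- f$slope
  }
  structure(list(powers = powers, r2_signed = r2, slope = slope,
                 n_bins = n_bins),
            class = "sft_fit")
}

#' @export
print.sft_fit <- function(x, ...) {
  print(data.frame(power = x$powers, r2_signed = round(x$r2_signed, 3),
                   slope = round(x$slope, 3)), row.names = FALSE)
  invisible(x)
}

#' First soft power passing the scale-free fit threshold
#'
#' @param fit an `sft_fit`.
#' @param r2_min signed R^2 threshold (default 0.9).
#' @return smallest passing power, or `NA` (with a message) when none passes.
#' @export
pick_soft_power <- function(fit, r2_min = 0.9) {
  pass <- which(fit$r2_signed >= r2_min)
  if (length(pass) == 0) {
    message("no power reaches signed R^2 >= ", r2_min)
    return(NA_integer_)
  }
  fit$powers[pass[1]]
}

#' Lowest hard threshold giving a scale-free degree distribution
#'
#' Scans cutoffs step, 2*step, ...; at each the matrix is binarized
#' (edge iff score >= cutoff, i != j) and the signed R^2 of the integer
#' degree distribution is computed as in [sft_fit()]. Cutoffs that leave no
#' edges are skipped.
#'
#' @param assoc association matrix.
#' @param step scan increment in (0, 1) (default 0.05).
#' @param r2_min signed R^2 threshold (default 0.9).
#' @param n_bins degree bins (default 10).
#' @return lowest passing cutoff, or `NA` (with a message) when none passes.
#'   The scanned cutoffs and fits are attached as attribute `"scan"`.
#' @export
pick_hard_threshold <- function(assoc, step = 0.05, r2_min = 0.9, n_bins = 10) {
  stopifnot(step > 0, step < 1)
  cutoffs <- seq(step, 1, by = step)
  r2 <- rep(NA_real_, length(cutoffs))
  a <- assoc
  diag(a) <- 0
  for (i in seq_along(cutoffs)) {
    deg <- rowSums(a >= cutoffs[i])
    if (all(deg == 0)) next
    r2[i] <- suppressWarnings(sft_r2_signed(deg, n_bins)$r2_signed)
  }
  scan <- data.frame(cutoff = cutoffs, r2_signed = r2)
  pass <- which(!is.na(r2) & r2 >= r2_min)
  out <- if (length(pass) == 0) {
    message("no cutoff reaches signed R^2 >= ", r2_min)
    NA_real_
  } else cutoffs[pass[1]]
  attr(out, "scan") <- scan
  out
}

#' Hard-threshold an association matrix into an edge list
#'
#' @param assoc association matrix with gene dimnames.
#' @param cutoff edge iff score >= cutoff, i != j; cutoff in (0, 1].
#' @return object of class `edge_list`: list with `nodes` (all genes,
#'   isolated ones included), `edges` (2-column character matrix of unordered
#'   pairs), and `cutoff_used`.
#' @export
binarize <- function(assoc, cutoff) {
  stopifnot(cutoff > 0, cutoff <= 1)
  ids <- rownames(assoc)
  idx <- which(upper.tri(assoc) & assoc >= cutoff, arr.ind = TRUE)
  edges <- cbind(ids[idx[, 1]], ids[idx[, 2]])
  colnames(edges) <- c("from", "to")
  structure(list(nodes = ids, edges = edges, cutoff_used = cutoff),
            class = "edge_list")
}

#' @export
print.edge_list <- function(x, ...) {
  cat("Edge list:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (cutoff", x$cutoff_used, ")\n")
  invisible(x)
}
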