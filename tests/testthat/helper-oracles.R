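# Independent brute-force oracles used to validate the fast implementations.
# Each recomputes the quantity from first principles, sharing no code with
# the package internals.

# Exhaustive window-of-linearity search using lm() on every 4-6 point
# window of consecutive cycles.
oracle_window <- function(cycle, log_fluor) {
  keep <- is.finite(log_fluor)
  cycle <- cycle[keep]
  log_fluor <- log_fluor[keep]
  ord <- order(cycle)
  cycle <- cycle[ord]; log_fluor <- log_fluor[ord]
  tol <- 1e-12
  best <- NULL
  for (len in 4:6) {
    for (i in seq_len(length(cycle) - len + 1)) {
      j <- i + len - 1
      if (cycle[j] - cycle[i] != len - 1) next
      x <- cycle[i:j]; y <- log_fluor[i:j]
      fit <- stats::lm(y ~ x)
      slope <- unname(stats::coef(fit)[2])
      if (is.na(slope) || slope <= 0) next
      r2 <- summary(fit)$r.squared
      if (is.null(best) ||
          r2 > best$r2 + tol ||
          (abs(r2 - best$r2) <= tol &&
             (slope > best$slope + tol ||
                (abs(slope - best$slope) <= tol && x[1] < best$start)))) {
        best <- list(start = x[1], end = x[len], slope = slope, r2 = r2)
      }
    }
  }
  best
}

# From-scratch UPGMA recomputing every cluster distance as the plain mean
# of all cross-pair distances in the ORIGINAL matrix at every step.
oracle_upgma <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  clades <- list()
  cluster_dist <- function(a, b) mean(dm[a, b])
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dd <- cluster_dist(clusters[[i]], clusters[[j]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d / 2)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clades <- c(clades, list(merged))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, clades = clades)
}

# Exponential-time global alignment score by enumerating all alignments
# (affine gaps: a gap of length L costs open + (L-1)*extend). Only for
# short strings.
oracle_nw_score <- function(a, b, match = 1, mismatch = -1,
                            gap_open = -5, gap_extend = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      pen <- if (prev == "GA") gap_extend else gap_open
      best <- max(best, pen + rec(i + 1, j, "GA"))
    }
    if (j <= m) {
      pen <- if (prev == "GB") gap_extend else gap_open
      best <- max(best, pen + rec(i, j + 1, "GB"))
    }
    best
  }
  rec(1, 1, "M")
}

`%||%` <- rlang::`%||%`

# Convenience: random uppercase DNA string.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
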