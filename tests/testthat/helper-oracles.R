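# Independent brute-force oracles used across the suite. Each is written
# from the definition of the quantity it checks, not from the package's
# implementation.

# Minimum total within-cluster sum of squares over ALL contiguous
# partitions of the sorted vector into k groups (exhaustive enumeration).
oracle_wcss <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(sse(x))
  splits <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(splits))) {
    bounds <- c(0, splits[, j], n)
    tot <- 0
    for (g in seq_len(k)) tot <- tot + sse(x[(bounds[g] + 1):bounds[g + 1]])
    best <- min(best, tot)
  }
  best
}

# Gaussian-mixture BIC recomputed from a hard partition of `x` given by
# integer labels, mirroring the documented selection contract (per-cluster
# mean/variance with the data-scaled floor, weights n_c/n, 3k - 1 params).
oracle_bic <- function(x, labels, var_floor = NULL) {
  n <- length(x)
  if (is.null(var_floor))
    var_floor <- max(1e-9, (diff(range(x)) / (100 * n))^2)
  ll <- 0
  for (c in unique(labels)) {
    xc <- x[labels == c]
    nc <- length(xc)
    vc <- max(mean((xc - mean(xc))^2), var_floor)
    ll <- ll + sum(log(nc / n) + stats::dnorm(xc, mean(xc), sqrt(vc),
                                              log = TRUE))
  }
  2 * ll - (3 * length(unique(labels)) - 1) * log(n)
}

# Base-pair coverage oracle for the three-way common-site intersection:
# marks every bp covered by each set and extracts maximal runs covered by
# all three. Coordinates must be small nonnegative integers.
oracle_common_sites <- function(a, b, c, max_coord = 500) {
  cover <- function(df) {
    v <- rep(FALSE, max_coord)
    for (i in seq_len(nrow(df))) {
      if (df$end[i] > df$start[i])
        v[(df$start[i] + 1):df$end[i]] <- TRUE # bp j covered -> index j+1
    }
    v
  }
  all3 <- cover(a) & cover(b) & cover(c)
  runs <- rle(all3)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  data.frame(start = starts[runs$values], end = ends[runs$values])
}

# (event, bait, end) double-loop oracle for link counting: returns the
# total number of bait incidences under the spec rule (either end in the
# bait counts once; both ends in the same bait still once).
oracle_link_total <- function(events, baits) {
  total <- 0
  for (i in seq_len(nrow(events))) {
    for (j in seq_len(nrow(baits))) {
      in1 <- events$chrom1[i] == baits$chrom[j] &&
        events$pos1[i] >= baits$start[j] && events$pos1[i] < baits$end[j]
      in2 <- events$chrom2[i] == baits$chrom[j] &&
        events$pos2[i] >= baits$start[j] && events$pos2[i] < baits$end[j]
      if (in1 || in2) total <- total + 1
    }
  }
  total
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments,
# computed from pairwise comparisons (independent of rank-sum formulas).
oracle_mw_exact <- function(x, y) {
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  mu <- nx * length(y) / 2
  u_obs <- u_of(x, y)
  idx <- utils::combn(n, nx)
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Jaccard overlap of two intervals on the same chromosome.
interval_jaccard <- function(a1, b1, a2, b2) {
  inter <- max(0, min(b1, b2) - max(a1, a2))
  inter / (max(b1, b2) - min(a1, a2))
}
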