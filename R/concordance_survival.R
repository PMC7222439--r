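#' Cumulative normalized expression score over a gene set
#'
#' Each gene's expression is z-scored across samples with the population
#' standard deviation (divide by n), then summed over the gene set per
#' sample. Invariant under per-gene affine rescaling of expression. A
#' zero-variance gene contributes 0 to every sample, with a warning.
#'
#' @param expression Numeric matrix (genes x samples, log2 scale), rownames
#'   are gene ids.
#' @param gene_set Character vector of gene ids (must be matrix rows).
#' @return Named numeric vector of per-sample scores.
#' @export
cumulative_score <- function(expression, gene_set) {
  missing <- setdiff(gene_set, rownames(expression))
  if (length(missing))
    stop("gene set members absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  m <- expression[gene_set, , drop = FALSE]
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  if (any(sd_pop == 0)) {
    warning(sum(sd_pop == 0), " zero-variance gene(s) contribute 0 to the ",
            "cumulative score")
  }
  z <- (m - mu) / ifelse(sd_pop == 0, 1, sd_pop)
  z[sd_pop == 0, ] <- 0
  colSums(z)
}

#' Select ATC-prone and ATC-less samples from score extremes
#'
#' Labels the `n_top` highest-scoring samples `"prone"`, the `n_top` lowest
#' `"less"`, the rest `"middle"`. Ties are broken by sample id, so the split
#' is deterministic and the two extreme sets are always disjoint.
#'
#' @param scores Named numeric vector of per-sample cumulative scores (names
#'   are sample ids).
#' @param n_top Number of samples per extreme group (default 15).
#' @return Data frame `sample`, `score`, `rank` (1 = highest score),
#'   `group`, ordered by rank.
#' @export
select_extreme_samples <- function(scores, n_top = 15) {
  n <- length(scores)
  if (n < 2 * n_top)
    stop("usage error: cohort size ", n, " < 2 * n_top = ", 2 * n_top)
  ids <- if (is.null(names(scores))) as.character(seq_len(n))
         else names(scores)
  o <- order(-scores, ids)
  group <- rep("middle", n)
  group[seq_len(n_top)] <- "prone"
  group[(n - n_top + 1):n] <- "less"
  data.frame(sample = ids[o], score = as.numeric(scores[o]),
             rank = seq_len(n), group = group, stringsAsFactors = FALSE)
}

#' Pairwise gene-gene correlation profile in genomic order
#'
#' Symmetric Pearson correlation matrix of the listed genes (rows ordered as
#' given, i.e. by genomic location), optionally restricted to a sample
#' subset first (e.g. the top-10 samples by cumulative score). Zero-variance
#' genes yield `NA` entries, which are excluded from summaries.
#'
#' @param expression Numeric matrix (genes x samples).
#' @param genes Character vector of gene ids, genomic order.
#' @param samples Optional character/integer vector of samples to use.
#' @return List of class `"correlation_profile"`: `genes`, `matrix`
#'   (symmetric, unit diagonal where defined).
#' @export
correlation_profile <- function(expression, genes, samples = NULL) {
  m <- expression[genes, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  if (ncol(m) < 3) stop("need >= 3 samples for a correlation profile")
  cm <- suppressWarnings(stats::cor(t(m)))
  diag(cm)[!is.na(diag(cm))] <- 1
  structure(list(genes = genes, matrix = cm),
            class = "correlation_profile")
}

#' Two-group log-rank test
#'
#' Standard (unweighted) two-group log-rank: at each distinct event time the
#' observed minus expected events in group 1 is accumulated under the
#' hypergeometric model, with variance
#' `d (n1/n) (1 - n1/n) (n - d) / (n - 1)`; the statistic is
#' `(sum(O - E))^2 / sum(V)` referred to chi-square with 1 df. Censoring is
#' handled by the risk sets. Returns `NA` statistics when no events exist.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Two-level group labels.
#' @return List `chisq`, `p`, `obs` (events per group), `exp` (expected
#'   events per group).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2)
    stop("usage error: exactly two groups required")
  if (any(table(group) == 0))
    stop("usage error: both groups must be nonempty")
  if (any(time <= 0)) stop("usage error: times must be positive")
  event <- as.integer(event)
  if (sum(event) == 0)
    return(list(chisq = NA_real_, p = NA_real_,
                obs = tapply(event, group, sum), exp = c(NA, NA)))
  g1 <- group == levels(group)[1]
  # risk sets by cumulative counts over unique times (ascending)
  ut <- sort(unique(time))
  f <- match(time, ut)
  m_all <- tabulate(f, length(ut))            # leaving risk set at each time
  m_g1 <- tabulate(f[g1], length(ut))
  d_all <- tabulate(f[event == 1], length(ut))  # deaths at each time
  d_g1 <- tabulate(f[event == 1 & g1], length(ut))
  n_at <- length(time) - c(0, cumsum(m_all))[seq_along(ut)]
  n1_at <- sum(g1) - c(0, cumsum(m_g1))[seq_along(ut)]
  keep <- d_all > 0
  nj <- n_at[keep]; n1j <- n1_at[keep]
  dj <- d_all[keep]; d1j <- d_g1[keep]
  ej <- dj * n1j / nj
  o_minus_e <- sum(d1j - ej)
  e1 <- sum(ej)
  ok <- nj > 1
  v <- sum((dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1))[ok])
  chisq <- if (v > 0) o_minus_e^2 / v else NA_real_
  p <- if (is.na(chisq)) NA_real_
       else stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  obs <- tapply(event, group, sum)
  list(chisq = chisq, p = p, obs = obs,
       exp = c(e1, sum(event) - e1))
}

#' Median split of scores into high/low groups
#'
#' `score > median` is `"high"`, `score <= median` is `"low"`;
#' deterministic, all-equal scores map to `"low"`.
#'
#' @param scores Numeric vector (length >= 2).
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
split_by_median <- function(scores) {
  if (length(scores) < 2) stop("usage error: need >= 2 samples")
  ifelse(scores > stats::median(scores), "high", "low")
}
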