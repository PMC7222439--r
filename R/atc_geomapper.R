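#' Assemble an analysis cohort
#'
#' Container aligning the three data layers on a shared, identically ordered
#' sample axis: log2 expression (genes x samples), segment copy number
#' (100-kb segments x samples, convention 0 = diploid, > 0 = amplified), and
#' per-sample metadata.
#'
#' @param expression Numeric matrix, genes x samples, log2 scale, finite;
#'   rownames are gene ids.
#' @param copy_number Numeric matrix, segments x samples; columns must match
#'   `expression` columns in order.
#' @param segments Data frame (`chrom`, `start`, `end`) describing the
#'   copy-number rows; 0-based half-open, tiling each chromosome.
#' @param metadata Data frame with a `sample` column matching the matrix
#'   columns; typically also `er_status`, `subtype`, `os_days`, `os_event`.
#' @return A list of class `"atc_cohort"`.
#' @export
cohort <- function(expression, copy_number, segments, metadata) {
  stopifnot(is.matrix(expression), is.matrix(copy_number),
            ncol(expression) == ncol(copy_number),
            nrow(copy_number) == nrow(segments))
  if (any(!is.finite(expression)))
    stop("expression must be finite after transformation")
  if (!is.null(colnames(expression)) && !is.null(colnames(copy_number)) &&
      !identical(colnames(expression), colnames(copy_number)))
    stop("expression and copy_number sample columns are not aligned")
  if (!is.null(metadata)) {
    stopifnot("sample" %in% names(metadata))
    if (!is.null(colnames(expression)) &&
        !identical(metadata$sample, colnames(expression)))
      stop("metadata samples are not aligned with the matrices")
  }
  structure(list(expression = expression, copy_number = copy_number,
                 segments = segments, metadata = metadata),
            class = "atc_cohort")
}

#' Log2-transform raw expression values
#'
#' `log2(x + 1)`: the pseudocount keeps zero counts finite while leaving
#' large RSEM-like values essentially on the log2 scale.
#'
#' @param expression Nonnegative numeric matrix or vector.
#' @return Same shape, log2(x + 1).
#' @export
log2_transform <- function(expression) {
  if (any(expression < 0, na.rm = TRUE))
    stop("input error: expression values must be >= 0")
  log2(expression + 1)
}

#' Copy-number vector assigned to a gene
#'
#' A gene inherits the per-sample values of the 100-kb segment containing its
#' midpoint; if that segment is absent from the grid, the nearest segment on
#' the same chromosome is used. The midpoint rule is deterministic and
#' strand-free.
#'
#' @param gene One-row data frame (or list) with `chrom`, `start`, `end`.
#' @param segments Segment table (`chrom`, `start`, `end`).
#' @param copy_number Matrix aligned with `segments` rows.
#' @return Numeric per-sample copy-number vector.
#' @export
assign_gene_copynumber <- function(gene, segments, copy_number) {
  idx <- gene_segment_index(gene$chrom, (gene$start + gene$end) %/% 2,
                            segments)
  copy_number[idx, ]
}

# Vectorized midpoint -> segment row lookup; nearest segment on the same
# chromosome when the midpoint falls in a grid gap.
gene_segment_index <- function(chrom, midpoint, segments) {
  idx <- integer(length(chrom))
  for (ch in unique(chrom)) {
    rows <- which(segments$chrom == ch)
    if (!length(rows))
      stop("lookup error: chromosome ", ch, " absent from segment grid")
    sel <- which(chrom == ch)
    o <- rows[order(segments$start[rows])]
    pos <- findInterval(midpoint[sel], segments$start[o])
    pos[pos < 1] <- 1L
    inside <- pos >= 1 &
      midpoint[sel] < segments$end[o][pmax(pos, 1)]
    # fall back to nearest segment by midpoint distance
    if (any(!inside)) {
      segmid <- (segments$start[o] + segments$end[o]) / 2
      for (j in which(!inside))
        pos[j] <- which.min(abs(segmid - midpoint[sel][j]))
    }
    idx[sel] <- o[pos]
  }
  idx
}

#' Pearson correlation between expression and copy number for one gene
#'
#' Pairwise-complete Pearson product-moment coefficient. Returns `NA` (the
#' undefined marker, excluded downstream) when either vector has zero
#' variance or fewer than 3 complete pairs remain.
#'
#' @param expr,cn Paired per-sample numeric vectors.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
correlate_gene <- function(expr, cn) {
  ok <- is.finite(expr) & is.finite(cn)
  if (sum(ok) < 3) return(NA_real_)
  e <- expr[ok]; c <- cn[ok]
  if (stats::sd(e) == 0 || stats::sd(c) == 0) return(NA_real_)
  stats::cor(e, c)
}

#' Screen genes for amplification-associated transcription coupling
#'
#' First geomapping step: every gene is assigned its midpoint segment's
#' copy-number vector and correlated (Pearson) with its log2 expression
#' across all samples jointly; genes with `r >= r_threshold` (inclusive) are
#' the putative ATC loci.
#'
#' @param cohort An [cohort()] object.
#' @param genes Gene annotation data frame (`gene_id`, `chrom`, `start`,
#'   `end`); `gene_id` must index `cohort$expression` rows.
#' @param r_threshold Inclusive correlation cutoff (default 0.6).
#' @param keep_all If `TRUE`, return every gene with its `r` (no filter);
#'   used for diagnostics.
#' @return Data frame of ATC genes (annotation columns plus `r`), sorted by
#'   chromosome then start.
#' @export
screen_atc_genes <- function(cohort, genes, r_threshold = 0.6,
                             keep_all = FALSE) {
  stopifnot(inherits(cohort, "atc_cohort"))
  expr <- cohort$expression[genes$gene_id, , drop = FALSE]
  idx <- gene_segment_index(genes$chrom, (genes$start + genes$end) %/% 2,
                            cohort$segments)
  cnm <- cohort$copy_number[idx, , drop = FALSE]
  # row-wise Pearson correlation
  ec <- expr - rowMeans(expr)
  cc <- cnm - rowMeans(cnm)
  num <- rowSums(ec * cc)
  den <- sqrt(rowSums(ec^2) * rowSums(cc^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  out <- cbind(genes, r = as.numeric(r))
  out <- out[order(match(out$chrom, unique(out$chrom)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (keep_all) return(out)
  out[!is.na(out$r) & out$r >= r_threshold, , drop = FALSE]
}

# Gaussian KDE (Silverman / nrd0 bandwidth) over a chromosome's ATC-gene
# positions, evaluated exactly at the query positions. Density is per bp, so
# a tight cluster of coupled genes lives on the 1e-8..1e-6 scale.
kde_at <- function(query, positions) {
  if (length(positions) < 2) return(rep(NA_real_, length(query)))
  bw <- tryCatch(stats::bw.nrd0(positions), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) return(rep(NA_real_, length(query)))
  vapply(query, function(q)
    mean(stats::dnorm((q - positions) / bw)) / bw, numeric(1))
}

#' Aggregate ATC genes into regions by optimal univariate k-means
#'
#' Second geomapping step: per chromosome, gene start positions are
#' partitioned with [select_k()] over `k_range`; each cluster becomes a
#' candidate region spanning its members' min start to max end. Candidates
#' are retained when all three selection criteria hold: at least `min_genes`
#' member genes, span strictly below `max_span_mb`, and per-bp Gaussian
#' kernel density (Silverman bandwidth over the chromosome's ATC-gene
#' positions, maximized over member positions) strictly above `min_density`.
#'
#' @param atc_genes [screen_atc_genes()] output (needs `gene_id`, `chrom`,
#'   `start`, `end`, `r`).
#' @param min_genes Minimum member-gene count (default 15).
#' @param max_span_mb Exclusive upper bound on the region length in Mb
#'   (default 20).
#' @param min_density Exclusive lower bound on the KDE density (default
#'   1e-8 per bp).
#' @param k_range Length-2 integer vector, inclusive range of cluster counts
#'   tried per chromosome (upper bound clamped to the chromosome's gene
#'   count, with a warning).
#' @return Data frame of regions (`region_id`, `chrom`, `start`, `end`,
#'   `gene_count`, `span_mb`, `density`) with a `members` list-column of
#'   member-gene data frames; sorted by coordinate.
#' @export
call_atc_regions <- function(atc_genes, min_genes = 15, max_span_mb = 20,
                             min_density = 1e-8, k_range = c(1L, 10L)) {
  if (nrow(atc_genes) == 0)
    return(empty_regions())
  out <- list()
  for (ch in unique(atc_genes$chrom)) {
    gch <- atc_genes[atc_genes$chrom == ch, , drop = FALSE]
    n <- nrow(gch)
    kmax <- min(k_range[2], n)
    if (kmax < k_range[2])
      warning("k_range upper bound clamped to ", kmax, " on ", ch,
              " (", n, " ATC genes)")
    kmin <- min(k_range[1], kmax)
    fit <- select_k(gch$start, kmin, kmax)
    dens_all <- kde_at(gch$start, gch$start)
    for (cl in seq_len(fit$k)) {
      m <- gch[fit$assignment == cl, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(m$start), end = max(m$end),
        gene_count = nrow(m),
        span_mb = (max(m$end) - min(m$start)) / 1e6,
        density = suppressWarnings(
          max(dens_all[fit$assignment == cl], na.rm = FALSE)),
        stringsAsFactors = FALSE)
      out[[length(out)]]$members <- I(list(m))
    }
  }
  regions <- do.call(rbind, out)
  keep <- regions$gene_count >= min_genes &
    regions$span_mb < max_span_mb &
    !is.na(regions$density) & regions$density > min_density
  regions <- regions[keep, , drop = FALSE]
  if (nrow(regions) == 0) return(empty_regions())
  regions <- regions[order(match(regions$chrom, unique(atc_genes$chrom)),
                           regions$start), , drop = FALSE]
  regions$region_id <- sprintf("R%02d", seq_len(nrow(regions)))
  rownames(regions) <- NULL
  regions[, c("region_id", "chrom", "start", "end", "gene_count",
              "span_mb", "density", "members")]
}

empty_regions <- function() {
  data.frame(region_id = character(), chrom = character(),
             start = numeric(), end = numeric(), gene_count = integer(),
             span_mb = numeric(), density = numeric(),
             members = I(list()), stringsAsFactors = FALSE)
}

#' Run the full two-step geomapping on a cohort
#'
#' Convenience wrapper: [screen_atc_genes()] then [call_atc_regions()].
#'
#' @inheritParams screen_atc_genes
#' @inheritParams call_atc_regions
#' @return List with `atc_genes` and `regions`.
#' @export
map_atc <- function(cohort, genes, r_threshold = 0.6, min_genes = 15,
                    max_span_mb = 20, min_density = 1e-8,
                    k_range = c(1L, 10L)) {
  atc_genes <- screen_atc_genes(cohort, genes, r_threshold)
  regions <- call_atc_regions(atc_genes, min_genes, max_span_mb,
                              min_density, k_range)
  list(atc_genes = atc_genes, regions = regions)
}

#' Write geomapping results
#'
#' Emits the ATC gene table (TSV with r values), the region report TSV, and
#' a region BED file (0-based half-open).
#'
#' @param result [map_atc()] output.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_atc_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$atc_genes, file.path(dir, "atc_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rep <- result$regions[, setdiff(names(result$regions), "members")]
  utils::write.table(rep, file.path(dir, "atc_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = result$regions$chrom,
                    start = result$regions$start,
                    end = result$regions$end,
                    name = result$regions$region_id)
  write_bed(bed, file.path(dir, "atc_regions.bed"))
  invisible(dir)
}
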