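#' Read a BED file of ChIP-seq peaks
#'
#' Thin wrapper over [rtracklayer::import()]; coordinates are returned
#' 0-based half-open in a plain data frame, the convention used throughout
#' this package.
#'
#' @param path BED file path.
#' @param source Label attached to every peak (e.g. a cell-line pseudonym).
#' @return Data frame with `chrom`, `start`, `end`, `source`.
#' @export
read_peaks <- function(path, source = basename(path)) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             source = source, stringsAsFactors = FALSE)
}

#' Write intervals to BED
#'
#' @param df Data frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `name` (or `source`, used as the name field).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  gr <- intervals_to_granges(df)
  nm <- if ("name" %in% names(df)) df$name
        else if ("source" %in% names(df)) df$source else NULL
  if (!is.null(nm)) S4Vectors::mcols(gr)$name <- nm
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

# 0-based half-open data frame -> GRanges (1-based closed)
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Common binding sites across three peak sets
#'
#' A common site is a maximal interval covered simultaneously (base-pair
#' level, minimum overlap 1 bp) by at least one peak from each of the three
#' sources; the strict three-way intersection is computed with
#' GenomicRanges and adjacent/overlapping results are merged. Symmetric in
#' its arguments and idempotent under re-merging.
#'
#' @param peaks_a,peaks_b,peaks_c Peak data frames (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @return Data frame of common sites (`chrom`, `start`, `end`), sorted;
#'   empty when any input is empty or the sets are disjoint.
#' @export
common_sites <- function(peaks_a, peaks_b, peaks_c) {
  if (nrow(peaks_a) == 0 || nrow(peaks_b) == 0 || nrow(peaks_c) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  red <- function(df) GenomicRanges::reduce(intervals_to_granges(df))
  common <- GenomicRanges::intersect(
    GenomicRanges::intersect(red(peaks_a), red(peaks_b),
                             ignore.strand = TRUE),
    red(peaks_c), ignore.strand = TRUE)
  granges_to_intervals(GenomicRanges::reduce(GenomicRanges::sort(common)))
}

#' Aggregate common sites into dense ERalpha binding hubs
#'
#' Per chromosome, site midpoints are clustered with [select_k()]; each
#' cluster becomes a hub spanning its members' min start to max end, so the
#' union of hubs covers every input site and hubs never overlap within a
#' chromosome (contiguity of optimal 1-D clusters). A chromosome with fewer
#' sites than the lower bound of `k_range` yields a single hub with a
#' warning.
#'
#' @param sites Common-site data frame (`chrom`, `start`, `end`).
#' @param k_range Inclusive range of cluster counts tried per chromosome
#'   (upper bound clamped to the site count).
#' @return Data frame (`hub_id`, `chrom`, `start`, `end`, `n_sites`,
#'   `length_mb`), sorted by coordinate.
#' @export
call_hubs <- function(sites, k_range = c(1L, 10L)) {
  if (nrow(sites) == 0)
    return(data.frame(hub_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_sites = integer(), length_mb = numeric(),
                      stringsAsFactors = FALSE))
  out <- list()
  for (ch in unique(sites$chrom)) {
    sch <- sites[sites$chrom == ch, , drop = FALSE]
    n <- nrow(sch)
    if (n < k_range[1]) {
      warning("only ", n, " site(s) on ", ch,
              "; emitting a single hub")
      kmin <- kmax <- 1L
    } else {
      kmin <- k_range[1]
      kmax <- min(k_range[2], n)
    }
    mids <- (sch$start + sch$end) / 2
    fit <- select_k(mids, kmin, kmax)
    for (cl in seq_len(fit$k)) {
      m <- sch[fit$assignment == cl, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(m$start), end = max(m$end),
        n_sites = nrow(m), length_mb = (max(m$end) - min(m$start)) / 1e6,
        stringsAsFactors = FALSE)
    }
  }
  hubs <- do.call(rbind, out)
  hubs <- hubs[order(match(hubs$chrom, unique(sites$chrom)), hubs$start), ,
               drop = FALSE]
  hubs$hub_id <- sprintf("H%03d", seq_len(nrow(hubs)))
  rownames(hubs) <- NULL
  hubs[, c("hub_id", "chrom", "start", "end", "n_sites", "length_mb")]
}

#' Define hubs directly from three peak BED files
#'
#' Convenience wrapper: [read_peaks()] x3, [common_sites()], [call_hubs()].
#'
#' @param paths Character vector of three BED paths.
#' @param k_range Passed to [call_hubs()].
#' @return List with `sites` and `hubs`.
#' @export
map_hubs <- function(paths, k_range = c(1L, 10L)) {
  stopifnot(length(paths) == 3)
  pk <- lapply(paths, read_peaks)
  sites <- common_sites(pk[[1]], pk[[2]], pk[[3]])
  list(sites = sites, hubs = call_hubs(sites, k_range))
}

#' Write common sites and hubs
#'
#' @param result [map_hubs()]-style list with `sites` and `hubs`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_hub_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(result$sites))
    write_bed(result$sites, file.path(dir, "common_sites.bed"))
  if (nrow(result$hubs)) {
    bed <- data.frame(chrom = result$hubs$chrom, start = result$hubs$start,
                      end = result$hubs$end, name = result$hubs$hub_id)
    write_bed(bed, file.path(dir, "er_hubs.bed"))
  }
  utils::write.table(result$hubs, file.path(dir, "er_hubs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
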