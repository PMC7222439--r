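#' Read paired-breakpoint rearrangement calls
#'
#' Two dialects are supported. `breakdancer`: whitespace-separated columns
#' `chr1 pos1 orient1 chr2 pos2 orient2 type size score num_reads [sample]`,
#' `#`-prefixed header/comment lines skipped, 1-based positions normalized to
#' 0-based. `bedpe`: standard 10 columns
#' `chrom1 start1 end1 chrom2 start2 end2 name score strand1 strand2`, with
#' the name field carrying the sample id and the score field the confidence
#' score; positions already 0-based.
#'
#' @param path Input file.
#' @param format `"breakdancer"` or `"bedpe"`.
#' @return Event data frame with columns `sample`, `chrom1`, `pos1`,
#'   `orient1`, `chrom2`, `pos2`, `orient2`, `type`, `size`, `score`,
#'   `num_reads` (0-based positions).
#' @export
read_events <- function(path, format = c("breakdancer", "bedpe")) {
  format <- match.arg(format)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(empty_events())
  fields <- strsplit(lines, "[ \t]+")
  if (format == "breakdancer") {
    bad <- which(lengths(fields) < 10)
    if (length(bad))
      stop("malformed row at line ", lineno[bad[1]], ": expected >= 10 ",
           "columns, got ", lengths(fields)[bad[1]])
    m <- do.call(rbind, fields)
    data.frame(
      sample = if (ncol(m) >= 11) m[, 11] else NA_character_,
      chrom1 = m[, 1], pos1 = as.numeric(m[, 2]) - 1, orient1 = m[, 3],
      chrom2 = m[, 4], pos2 = as.numeric(m[, 5]) - 1, orient2 = m[, 6],
      type = m[, 7], size = as.numeric(m[, 8]), score = as.numeric(m[, 9]),
      num_reads = as.integer(m[, 10]), stringsAsFactors = FALSE)
  } else {
    bad <- which(lengths(fields) < 10)
    if (length(bad))
      stop("malformed row at line ", lineno[bad[1]], ": BEDPE needs 10 ",
           "columns, got ", lengths(fields)[bad[1]])
    m <- do.call(rbind, fields)
    chrom1 <- m[, 1]; chrom2 <- m[, 4]
    pos1 <- as.numeric(m[, 2]); pos2 <- as.numeric(m[, 5])
    inter <- chrom1 != chrom2
    data.frame(
      sample = m[, 7], chrom1 = chrom1, pos1 = pos1, orient1 = m[, 9],
      chrom2 = chrom2, pos2 = pos2, orient2 = m[, 10],
      type = ifelse(inter, "CTX", "ITX"),
      size = ifelse(inter, 0, abs(pos2 - pos1)),
      score = as.numeric(m[, 8]), num_reads = NA_integer_,
      stringsAsFactors = FALSE)
  }
}

#' Write rearrangement events
#'
#' Inverse of [read_events()] for both dialects (the BEDPE dialect stores
#' each breakpoint as a 1-bp interval and the sample id in the name field).
#'
#' @param events Event data frame (see [read_events()]).
#' @param path Output file.
#' @param format `"breakdancer"` or `"bedpe"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("breakdancer", "bedpe")) {
  format <- match.arg(format)
  if (format == "breakdancer") {
    hdr <- paste("#Chr1", "Pos1", "Orientation1", "Chr2", "Pos2",
                 "Orientation2", "Type", "Size", "Score", "num_Reads",
                 "Sample", sep = "\t")
    body <- if (nrow(events)) paste(
      events$chrom1, events$pos1 + 1, events$orient1, events$chrom2,
      events$pos2 + 1, events$orient2, events$type, events$size,
      events$score, events$num_reads, events$sample, sep = "\t")
      else character(0)
    writeLines(c(hdr, body), path)
  } else {
    body <- if (nrow(events)) paste(
      events$chrom1, events$pos1, events$pos1 + 1, events$chrom2,
      events$pos2, events$pos2 + 1, events$sample, events$score,
      events$orient1, events$orient2, sep = "\t") else character(0)
    writeLines(body, path)
  }
  invisible(path)
}

#' Confidence-score quality filter
#'
#' Retains events with confidence score strictly greater than `min_score`
#' (an event scoring exactly `min_score` is dropped). Idempotent; raising
#' `min_score` never enlarges the retained set.
#'
#' @param events Event data frame.
#' @param min_score Exclusive score threshold (default 80).
#' @return Filtered event data frame.
#' @export
filter_events <- function(events, min_score = 80) {
  events[events$score > min_score, , drop = FALSE]
}

#' Classify events as inter- or intra-chromosomal
#'
#' @param events Event data frame (one or more rows).
#' @return Character vector, `"intra"` where `chrom1 == chrom2`, else
#'   `"inter"`.
#' @export
classify_events <- function(events) {
  ifelse(events$chrom1 == events$chrom2, "intra", "inter")
}

# breakpoint containment: half-open [start, end)
in_interval <- function(chrom, pos, ichrom, istart, iend) {
  chrom == ichrom & pos >= istart & pos < iend
}

check_baits <- function(baits) {
  stopifnot(all(c("chrom", "start", "end") %in% names(baits)))
  for (ch in unique(baits$chrom)) {
    b <- baits[baits$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop("bait regions must not overlap (", ch, ")")
  }
  if (!"region_id" %in% names(baits))
    baits$region_id <- sprintf("R%02d", seq_len(nrow(baits)))
  baits
}

#' Count rearrangement links between bait regions and 1-Mb partner bins
#'
#' An event contributes to bait `B` when either breakpoint lies in `B`
#' (half-open containment); the other end is the partner and is assigned to
#' its enclosing `bin_mb`-Mb bin (bins anchored at coordinate 0 per
#' chromosome). An event with both ends in the same bait is counted once
#' (intra stratum, partner taken from end 2); an event with its two ends in
#' two different baits contributes one count to each. Per-sample counts are
#' returned; pool with [pool_links()].
#'
#' @param events Filtered event data frame.
#' @param baits Non-overlapping regions (`region_id`, `chrom`, `start`,
#'   `end`).
#' @param bin_mb Partner bin width in Mb (default 1).
#' @param genome Optional genome table (`chrom`, `length`); partner
#'   breakpoints beyond the chromosome length are clamped into the last bin
#'   with a warning.
#' @return Data frame `bait`, `sample`, `stratum` (inter/intra),
#'   `partner_chrom`, `bin` (0-based index), `bin_start` (bp), `count`.
#' @export
count_links <- function(events, baits, bin_mb = 1, genome = NULL) {
  baits <- check_baits(baits)
  bw <- bin_mb * 1e6
  rows <- list()
  if (nrow(events)) {
    strat <- classify_events(events)
    for (j in seq_len(nrow(baits))) {
      in1 <- in_interval(events$chrom1, events$pos1, baits$chrom[j],
                         baits$start[j], baits$end[j])
      in2 <- in_interval(events$chrom2, events$pos2, baits$chrom[j],
                         baits$start[j], baits$end[j])
      # partner end: end 2 when end 1 anchors (or both do), else end 1
      take <- in1 | in2
      if (!any(take)) next
      use2 <- in1[take] # TRUE -> partner is end 2
      pchrom <- ifelse(use2, events$chrom2[take], events$chrom1[take])
      ppos <- ifelse(use2, events$pos2[take], events$pos1[take])
      if (!is.null(genome)) {
        len <- genome$length[match(pchrom, genome$chrom)]
        over <- !is.na(len) & ppos >= len
        if (any(over)) {
          warning(sum(over), " partner breakpoint(s) beyond chromosome ",
                  "length; clamped to last bin")
          ppos[over] <- len[over] - 1
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        bait = baits$region_id[j], sample = events$sample[take],
        stratum = strat[take], partner_chrom = pchrom,
        bin = floor(ppos / bw), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(bait = character(), sample = character(),
                      stratum = character(), partner_chrom = character(),
                      bin = numeric(), bin_start = numeric(),
                      count = integer(), stringsAsFactors = FALSE))
  inc <- do.call(rbind, rows)
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(inc))),
    by = inc[, c("bait", "sample", "stratum", "partner_chrom", "bin")],
    FUN = sum)
  agg$bin_start <- agg$bin * bw
  agg <- agg[order(agg$bait, agg$sample, agg$stratum, agg$partner_chrom,
                   agg$bin), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("bait", "sample", "stratum", "partner_chrom", "bin", "bin_start",
          "count")]
}

#' Pool per-sample link counts into a bait x partner matrix
#'
#' @param links [count_links()] or [hub_link_matrix()] output.
#' @param row_ids,col_ids Optional row/column universes (baits / partner
#'   labels) to enforce in the output.
#' @param column Which column labels the partners: `"bin"` combines
#'   `partner_chrom:bin`, `"hub"` uses the hub id.
#' @return Integer matrix of pooled counts (all samples, both strata unless
#'   pre-filtered).
#' @export
pool_links <- function(links, row_ids = NULL, col_ids = NULL,
                       column = c("bin", "hub")) {
  column <- match.arg(column)
  part <- if (column == "bin")
    paste0(links$partner_chrom, ":", links$bin) else links$hub
  rows <- if (is.null(row_ids)) sort(unique(links$bait)) else row_ids
  cols <- if (is.null(col_ids)) sort(unique(part)) else col_ids
  m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  if (nrow(links)) {
    for (i in seq_len(nrow(links)))
      m[links$bait[i], part[i]] <- m[links$bait[i], part[i]] +
        links$count[i]
  }
  m
}

#' Count links between bait regions and ERalpha hubs
#'
#' Same anchoring rule as [count_links()], with the partner breakpoint
#' assigned to its enclosing hub; partners lying in no hub fall into the
#' `"non_hub"` column.
#'
#' @param events Filtered event data frame.
#' @param baits Non-overlapping bait regions.
#' @param hubs Hub table (`hub_id`, `chrom`, `start`, `end`).
#' @return List with `links` (per-sample data frame `bait`, `sample`,
#'   `stratum`, `hub`, `count`) and `matrix` (pooled bait x hub counts,
#'   `non_hub` last column).
#' @export
hub_link_matrix <- function(events, baits, hubs) {
  baits <- check_baits(baits)
  if (!"hub_id" %in% names(hubs))
    hubs$hub_id <- sprintf("H%03d", seq_len(nrow(hubs)))
  rows <- list()
  if (nrow(events)) {
    strat <- classify_events(events)
    for (j in seq_len(nrow(baits))) {
      in1 <- in_interval(events$chrom1, events$pos1, baits$chrom[j],
                         baits$start[j], baits$end[j])
      in2 <- in_interval(events$chrom2, events$pos2, baits$chrom[j],
                         baits$start[j], baits$end[j])
      take <- in1 | in2
      if (!any(take)) next
      use2 <- in1[take]
      pchrom <- ifelse(use2, events$chrom2[take], events$chrom1[take])
      ppos <- ifelse(use2, events$pos2[take], events$pos1[take])
      hub <- rep("non_hub", sum(take))
      for (h in seq_len(nrow(hubs))) {
        inh <- in_interval(pchrom, ppos, hubs$chrom[h], hubs$start[h],
                           hubs$end[h])
        hub[inh & hub == "non_hub"] <- hubs$hub_id[h]
      }
      rows[[length(rows) + 1]] <- data.frame(
        bait = baits$region_id[j], sample = events$sample[take],
        stratum = strat[take], hub = hub, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    links <- data.frame(bait = character(), sample = character(),
                        stratum = character(), hub = character(),
                        count = integer(), stringsAsFactors = FALSE)
  } else {
    inc <- do.call(rbind, rows)
    links <- stats::aggregate(
      list(count = rep(1L, nrow(inc))),
      by = inc[, c("bait", "sample", "stratum", "hub")], FUN = sum)
    links <- links[order(links$bait, links$sample, links$stratum,
                         links$hub), , drop = FALSE]
    rownames(links) <- NULL
  }
  m <- pool_links(links, row_ids = baits$region_id,
                  col_ids = c(hubs$hub_id, "non_hub"), column = "hub")
  list(links = links, matrix = m)
}

#' Mann-Whitney U comparison of two groups of per-sample counts
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test. When both groups have
#' at most `exact_max` observations the p-value is computed by exhaustive
#' enumeration of all group assignments of the pooled values (valid under
#' ties; the permutation distribution of U is symmetric about `n1*n2/2`).
#' Otherwise the tie-corrected normal approximation is used.
#'
#' @param values Numeric vector of per-sample statistics.
#' @param labels Group labels (exactly two levels, each nonempty).
#' @param exact_max Largest per-group size for the exact path (default 10).
#' @return List with `U` (first group), `p` (two-sided), `method`.
#' @export
compare_groups <- function(values, labels, exact_max = 10) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2)
    stop("usage error: exactly two groups required")
  x <- values[labels == levels(labels)[1]]
  y <- values[labels == levels(labels)[2]]
  if (!length(x) || !length(y))
    stop("usage error: both groups must be nonempty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (nx <= exact_max && ny <= exact_max) {
    idx <- utils::combn(n, nx)
    rs <- matrix(r[idx], nrow = nx)
    Ud <- colSums(rs) - nx * (nx + 1) / 2
    p <- mean(abs(Ud - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    nt <- table(r)
    tie_term <- sum(nt^3 - nt) / (n * (n - 1))
    sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (U - mu) / sigma
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  list(U = U, p = p, method = method)
}
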