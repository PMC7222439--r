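#' Configuration for the synthetic breast-tumor-like cohort
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults are the
#' study conditions used throughout the package's analyses and tests: a
#' 200-sample cohort of 1,000 genes on two chromosomes, three planted
#' dosage-coupled regions of 30 member genes each, dosage slope 0.8 on the
#' log2 expression scale, expression noise SD 0.5, and hub-targeted
#' rearrangements at fraction 0.7. See the methods vignette for the rationale
#' behind each value.
#'
#' @param seed Integer RNG seed; every downstream draw derives from it.
#' @param n_samples Number of tumor samples.
#' @param genome Data frame with columns `chrom`, `length` (bp).
#' @param n_genes Total gene count (planted members included).
#' @param planted_regions Data frame with columns `chrom`, `start`, `end`
#'   (bp, 0-based half-open), `dosage_slope` (log2 expression units per
#'   copy-number unit), `n_genes` (member genes repositioned inside the
#'   region). Regions must lie within their chromosome and not overlap.
#' @param background_corr_sd SD of background (uncoupled) gene expression
#'   noise on the log2 scale.
#' @param expr_noise_sd SD of residual expression noise for planted genes.
#' @param cn_gain_prob Per-sample probability that a planted region is
#'   amplified in that sample.
#' @param background_gain_prob Per-segment, per-sample probability of a
#'   sporadic background amplification outside planted regions (keeps
#'   background copy number nonconstant so the correlation screen is
#'   genuinely exercised).
#' @param cn_gain_range Range of the amplified segment value; copy number is
#'   emitted on the convention 0 = diploid, > 0 = amplified.
#' @param er_positive_fraction Fraction of ER-positive samples.
#' @param n_events_per_sample Poisson mean of rearrangement events per
#'   ER-positive sample.
#' @param er_rate_ratio ER+/ER- ratio of rearrangement rates (ER-negative
#'   samples draw events at `n_events_per_sample / er_rate_ratio`).
#' @param hub_targeting_fraction Fraction of ER-positive events placing one
#'   breakpoint in a planted (bait) region and the other in a planted hub.
#' @param atc_event_coef Log-rate coefficient per SD of the cumulative ATC
#'   score on the per-sample event rate: samples with high concordant
#'   expression accumulate more rearrangements, emulating the association
#'   between transcription coupling and chromothriptic burden.
#' @param planted_hubs Data frame with columns `chrom`, `start`, `end` (bp).
#' @param peak_width_bp,peak_jitter_bp ChIP-seq peak width and per-cell-line
#'   jitter of shared hub peaks.
#' @param sites_per_hub Number of shared binding sites planted per hub.
#' @param n_noise_peaks Line-specific uniform noise peaks per peak set.
#' @param score_le80_fraction Fraction of rearrangement confidence scores
#'   drawn at or below 80 (exercises the quality filter).
#' @param survival_baseline_hazard Baseline hazard (per day) of the
#'   exponential survival model.
#' @param atc_hazard_coef Log-hazard-ratio per SD of the cumulative ATC
#'   score; positive values link high concordant expression to poor survival.
#' @param censor_rate Target fraction of censored samples (independent
#'   exponential censoring).
#' @param gene_length_bp Fixed gene length.
#' @param expr_baseline_range Range of per-gene baseline log2 expression.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 200L,
                       genome = data.frame(
                         chrom = c("chr1", "chr2"),
                         length = c(120e6, 100e6)),
                       n_genes = 1000L,
                       planted_regions = data.frame(
                         chrom = c("chr1", "chr1", "chr2"),
                         start = c(20e6, 60e6, 40e6),
                         end = c(28e6, 68e6, 48e6),
                         dosage_slope = 0.8,
                         n_genes = 30L),
                       background_corr_sd = 1,
                       expr_noise_sd = 0.5,
                       cn_gain_prob = 0.5,
                       background_gain_prob = 0.02,
                       cn_gain_range = c(0.3, 1.5),
                       er_positive_fraction = 0.7,
                       n_events_per_sample = 20L,
                       er_rate_ratio = 3,
                       hub_targeting_fraction = 0.7,
                       atc_event_coef = 0.35,
                       planted_hubs = data.frame(
                         chrom = c("chr1", "chr2", "chr2", "chr2"),
                         start = c(90e6, 10e6, 60e6, 80e6),
                         end = c(92e6, 12e6, 62e6, 82e6)),
                       peak_width_bp = 400L,
                       peak_jitter_bp = 200L,
                       sites_per_hub = 16L,
                       n_noise_peaks = 200L,
                       score_le80_fraction = 0.2,
                       survival_baseline_hazard = 3.8e-4,
                       atc_hazard_coef = 0.4,
                       censor_rate = 0.3,
                       gene_length_bp = 10000L,
                       expr_baseline_range = c(4, 10)) {
  cfg <- list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    genome = genome, n_genes = as.integer(n_genes),
    planted_regions = planted_regions,
    background_corr_sd = background_corr_sd, expr_noise_sd = expr_noise_sd,
    cn_gain_prob = cn_gain_prob, background_gain_prob = background_gain_prob,
    cn_gain_range = cn_gain_range,
    er_positive_fraction = er_positive_fraction,
    n_events_per_sample = n_events_per_sample, er_rate_ratio = er_rate_ratio,
    hub_targeting_fraction = hub_targeting_fraction,
    atc_event_coef = atc_event_coef,
    planted_hubs = planted_hubs, peak_width_bp = as.integer(peak_width_bp),
    peak_jitter_bp = as.integer(peak_jitter_bp),
    sites_per_hub = as.integer(sites_per_hub),
    n_noise_peaks = as.integer(n_noise_peaks),
    score_le80_fraction = score_le80_fraction,
    survival_baseline_hazard = survival_baseline_hazard,
    atc_hazard_coef = atc_hazard_coef, censor_rate = censor_rate,
    gene_length_bp = as.integer(gene_length_bp),
    expr_baseline_range = expr_baseline_range)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  g <- cfg$genome
  stopifnot(is.data.frame(g), all(c("chrom", "length") %in% names(g)),
            nrow(g) >= 1, all(g$length > 0), !anyDuplicated(g$chrom))
  fr <- c(cfg$cn_gain_prob, cfg$background_gain_prob,
          cfg$er_positive_fraction, cfg$hub_targeting_fraction,
          cfg$score_le80_fraction, cfg$censor_rate)
  if (any(fr < 0 | fr > 1))
    stop("config error: all fractions/probabilities must lie in [0, 1]")
  pr <- cfg$planted_regions
  if (nrow(pr) > 0) {
    if (!all(pr$chrom %in% g$chrom))
      stop("config error: planted region on unknown chromosome")
    len <- g$length[match(pr$chrom, g$chrom)]
    if (any(pr$start < 0) || any(pr$end > len) || any(pr$start >= pr$end))
      stop("config error: planted region outside chromosome bounds")
    for (ch in unique(pr$chrom)) {
      p <- pr[pr$chrom == ch, , drop = FALSE]
      p <- p[order(p$start), , drop = FALSE]
      if (nrow(p) > 1 && any(p$start[-1] < p$end[-nrow(p)]))
        stop("config error: planted regions overlap on ", ch)
    }
    # feasibility: >= 1 gene per 10 kb
    if (any(pr$n_genes * 10000 > (pr$end - pr$start)))
      stop("config error: more member genes than fit in a planted region ",
           "at >= 1 gene per 10 kb")
    if (sum(pr$n_genes) > cfg$n_genes)
      stop("config error: planted member genes exceed n_genes")
  }
  ph <- cfg$planted_hubs
  if (nrow(ph) > 0) {
    if (!all(ph$chrom %in% g$chrom))
      stop("config error: planted hub on unknown chromosome")
    len <- g$length[match(ph$chrom, g$chrom)]
    if (any(ph$start < 0) || any(ph$end > len) || any(ph$start >= ph$end))
      stop("config error: planted hub outside chromosome bounds")
  }
  invisible(cfg)
}

#' Simulate a full synthetic cohort with planted ground truth
#'
#' Generates an annotated gene set, a genes-by-samples expression matrix, a
#' 100-kb segment copy-number matrix, sample metadata (ER status, subtype,
#' censored overall survival linked to the cumulative ATC score),
#' rearrangement calls with hub-targeted breakpoints, and three ChIP-seq peak
#' sets whose three-way intersection isolates the planted hubs.
#'
#' Planted (dosage-coupled) genes live inside their region and receive, per
#' sample, the region's segment copy-number value; their log2 expression is
#' `baseline + dosage_slope * copy_number + N(0, expr_noise_sd)`. Background
#' genes are expressed independently of copy number. Expression is emitted as
#' raw RSEM-like values `2^x - 1` (clamped at 0) so the analysis-side
#' `log2(x + 1)` transform recovers the linear coupling.
#'
#' Fully reproducible: identical configs (including `seed`) give identical
#' bundles.
#'
#' @param config A [sim_config()].
#' @return A list of class `"cohort_bundle"` with elements `annotation`,
#'   `expression` (raw, genes x samples), `copy_number` (segments x samples),
#'   `segments`, `metadata`, `rearrangements`, `peaks` (list of three data
#'   frames), and `manifest` (planted regions/hubs, coupled gene ids, config).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  g <- config$genome
  pr <- config$planted_regions
  n <- config$n_samples
  glen <- config$gene_length_bp

  ## ---- gene annotation ----
  n_planted <- if (nrow(pr)) sum(pr$n_genes) else 0L
  n_bg <- config$n_genes - n_planted
  bg_chrom <- sample(g$chrom, n_bg, replace = TRUE, prob = g$length)
  bg_start <- floor(stats::runif(n_bg) *
                      (g$length[match(bg_chrom, g$chrom)] - glen))
  region_of <- rep(NA_integer_, n_bg)
  chrom <- bg_chrom; start <- bg_start
  if (nrow(pr)) {
    for (r in seq_len(nrow(pr))) {
      s <- floor(stats::runif(pr$n_genes[r]) *
                   (pr$end[r] - pr$start[r] - glen)) + pr$start[r]
      chrom <- c(chrom, rep(pr$chrom[r], pr$n_genes[r]))
      start <- c(start, s)
      region_of <- c(region_of, rep(r, pr$n_genes[r]))
    }
  }
  ord <- order(match(chrom, g$chrom), start)
  annotation <- data.frame(
    gene_id = sprintf("G%04d", seq_along(chrom)),
    chrom = chrom[ord], start = start[ord], end = start[ord] + glen,
    strand = sample(c("+", "-"), length(chrom), replace = TRUE),
    stringsAsFactors = FALSE)
  region_of <- region_of[ord]
  coupled_genes <- annotation$gene_id[!is.na(region_of)]

  ## ---- 100-kb segment grid and copy number ----
  segments <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    s <- seq(0, g$length[i] - 1, by = 1e5)
    data.frame(chrom = g$chrom[i], start = s,
               end = pmin(s + 1e5, g$length[i]), stringsAsFactors = FALSE)
  }))
  sample_ids <- sprintf("S%03d", seq_len(n))
  cn <- matrix(0, nrow = nrow(segments), ncol = n,
               dimnames = list(NULL, sample_ids))
  region_cn <- matrix(0, nrow = max(1, nrow(pr)), ncol = n)
  in_region_seg <- rep(FALSE, nrow(segments))
  if (nrow(pr)) {
    for (r in seq_len(nrow(pr))) {
      gained <- stats::runif(n) < config$cn_gain_prob
      val <- ifelse(gained,
                    stats::runif(n, config$cn_gain_range[1],
                                 config$cn_gain_range[2]), 0)
      region_cn[r, ] <- val
      rows <- segments$chrom == pr$chrom[r] &
        segments$start < pr$end[r] & segments$end > pr$start[r]
      in_region_seg <- in_region_seg | rows
      cn[rows, ] <- matrix(val, nrow = sum(rows), ncol = n, byrow = TRUE)
    }
  }
  bg_rows <- which(!in_region_seg)
  if (length(bg_rows) && config$background_gain_prob > 0) {
    m <- length(bg_rows) * n
    hit <- which(stats::runif(m) < config$background_gain_prob)
    if (length(hit)) {
      vals <- stats::runif(length(hit), config$cn_gain_range[1],
                           config$cn_gain_range[2])
      sub <- matrix(0, nrow = length(bg_rows), ncol = n)
      sub[hit] <- vals
      cn[bg_rows, ] <- sub
    }
  }

  ## ---- expression (log2 scale, emitted raw) ----
  baseline <- stats::runif(config$n_genes, config$expr_baseline_range[1],
                           config$expr_baseline_range[2])
  log2e <- matrix(baseline, nrow = config$n_genes, ncol = n,
                  dimnames = list(annotation$gene_id, sample_ids))
  is_planted <- !is.na(region_of)
  if (any(is_planted)) {
    slopes <- pr$dosage_slope[region_of[is_planted]]
    log2e[is_planted, ] <- log2e[is_planted, ] +
      slopes * region_cn[region_of[is_planted], , drop = FALSE] +
      matrix(stats::rnorm(sum(is_planted) * n, 0, config$expr_noise_sd),
             ncol = n)
  }
  if (any(!is_planted)) {
    log2e[!is_planted, ] <- log2e[!is_planted, ] +
      matrix(stats::rnorm(sum(!is_planted) * n, 0, config$background_corr_sd),
             ncol = n)
  }
  expression <- pmax(2^log2e - 1, 0)

  ## ---- metadata: ER status, subtype, survival tied to ATC score ----
  er <- ifelse(stats::runif(n) < config$er_positive_fraction,
               "positive", "negative")
  subtype <- character(n)
  npos <- sum(er == "positive")
  subtype[er == "positive"] <- sample(c("LumA", "LumB", "Her2"), npos,
                                      replace = TRUE,
                                      prob = c(0.55, 0.35, 0.10))
  subtype[er == "negative"] <- sample(c("Basal", "Her2"), n - npos,
                                      replace = TRUE, prob = c(0.8, 0.2))
  score <- cumulative_score(log2(expression + 1), coupled_genes)
  z <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score)
       else rep(0, n)
  hazard <- config$survival_baseline_hazard * exp(config$atc_hazard_coef * z)
  t_event <- stats::rexp(n, hazard)
  if (config$censor_rate > 0) {
    cens_rate <- config$censor_rate / (1 - config$censor_rate) * mean(hazard)
    t_cens <- stats::rexp(n, cens_rate)
  } else t_cens <- rep(Inf, n)
  metadata <- data.frame(
    sample = sample_ids, er_status = er, subtype = subtype,
    os_days = pmax(round(pmin(t_event, t_cens), 2), 0.01),
    os_event = as.integer(t_event <= t_cens), stringsAsFactors = FALSE)

  ## ---- rearrangements and peaks ----
  rearr <- simulate_rearrangements(config, pr, config$planted_hubs,
                                   er_positive = er == "positive",
                                   sample_ids = sample_ids,
                                   rate_multiplier =
                                     exp(config$atc_event_coef * z))
  peaks <- simulate_peaks(config)

  structure(
    list(annotation = annotation, expression = expression,
         copy_number = cn, segments = segments, metadata = metadata,
         rearrangements = rearr, peaks = peaks,
         manifest = list(planted_regions = pr,
                         planted_hubs = config$planted_hubs,
                         coupled_genes = coupled_genes,
                         region_of_gene = region_of,
                         config = config)),
    class = "cohort_bundle")
}

empty_events <- function() {
  data.frame(sample = character(), chrom1 = character(), pos1 = integer(),
             orient1 = character(), chrom2 = character(), pos2 = integer(),
             orient2 = character(), type = character(), size = integer(),
             score = numeric(), num_reads = integer(),
             stringsAsFactors = FALSE)
}

#' Simulate rearrangement calls with hub-targeted breakpoints
#'
#' For ER-positive samples a fraction `hub_targeting_fraction` of events puts
#' one breakpoint uniformly inside a randomly chosen bait region and the other
#' uniformly inside a randomly chosen hub (end order randomized); all
#' remaining events place both breakpoints uniformly on the genome
#' (chromosome chosen proportional to length). ER-negative samples draw
#' events at `n_events_per_sample / er_rate_ratio` and are never targeted.
#' Integer confidence scores are drawn so a fraction `score_le80_fraction`
#' falls in 40..80 (filtered downstream) and the rest in 81..99.
#'
#' @param config A [sim_config()]; supplies the genome, rates and score mix.
#' @param regions Bait regions: data frame with `chrom`, `start`, `end`.
#' @param hubs Hubs: data frame with `chrom`, `start`, `end`.
#' @param er_positive Optional logical vector of per-sample ER status; drawn
#'   from `config` when omitted.
#' @param sample_ids Optional sample identifiers.
#' @param rate_multiplier Optional per-sample multiplier on the event rate
#'   (the cohort generator passes `exp(atc_event_coef * z_score)`); default
#'   1 for all samples.
#' @return Event table (0-based positions) with columns `sample`, `chrom1`,
#'   `pos1`, `orient1`, `chrom2`, `pos2`, `orient2`, `type`, `size`, `score`,
#'   `num_reads`.
#' @export
simulate_rearrangements <- function(config, regions, hubs,
                                    er_positive = NULL, sample_ids = NULL,
                                    rate_multiplier = NULL) {
  g <- config$genome
  if (config$hub_targeting_fraction > 0 &&
      (is.null(regions) || nrow(regions) == 0 ||
       is.null(hubs) || nrow(hubs) == 0))
    stop("config error: hub_targeting_fraction > 0 requires nonempty ",
         "bait regions and hubs")
  n <- config$n_samples
  if (is.null(er_positive))
    er_positive <- stats::runif(n) < config$er_positive_fraction
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n))
  mean_ev <- ifelse(er_positive, config$n_events_per_sample,
                    config$n_events_per_sample / config$er_rate_ratio)
  if (!is.null(rate_multiplier)) mean_ev <- mean_ev * rate_multiplier
  n_ev <- stats::rpois(n, mean_ev)
  total <- sum(n_ev)
  if (total == 0) return(empty_events())

  samp <- rep(sample_ids, n_ev)
  is_pos <- rep(er_positive, n_ev)
  targeted <- is_pos & stats::runif(total) < config$hub_targeting_fraction

  chrom1 <- chrom2 <- character(total)
  pos1 <- pos2 <- numeric(total)
  nt <- sum(targeted)
  if (nt) {
    ri <- sample.int(nrow(regions), nt, replace = TRUE)
    hi <- sample.int(nrow(hubs), nt, replace = TRUE)
    bpos <- floor(regions$start[ri] +
                    stats::runif(nt) * (regions$end[ri] - regions$start[ri]))
    hpos <- floor(hubs$start[hi] +
                    stats::runif(nt) * (hubs$end[hi] - hubs$start[hi]))
    swap <- stats::runif(nt) < 0.5
    chrom1[targeted] <- ifelse(swap, hubs$chrom[hi], regions$chrom[ri])
    pos1[targeted] <- ifelse(swap, hpos, bpos)
    chrom2[targeted] <- ifelse(swap, regions$chrom[ri], hubs$chrom[hi])
    pos2[targeted] <- ifelse(swap, bpos, hpos)
  }
  nb <- total - nt
  if (nb) {
    for (endi in 1:2) {
      ci <- sample.int(nrow(g), nb, replace = TRUE, prob = g$length)
      p <- floor(stats::runif(nb) * g$length[ci])
      if (endi == 1) { chrom1[!targeted] <- g$chrom[ci]; pos1[!targeted] <- p }
      else { chrom2[!targeted] <- g$chrom[ci]; pos2[!targeted] <- p }
    }
  }
  low <- stats::runif(total) < config$score_le80_fraction
  score <- ifelse(low, sample(40:80, total, replace = TRUE),
                  sample(81:99, total, replace = TRUE))
  inter <- chrom1 != chrom2
  data.frame(
    sample = samp, chrom1 = chrom1, pos1 = pos1,
    orient1 = sample(c("+", "-"), total, replace = TRUE),
    chrom2 = chrom2, pos2 = pos2,
    orient2 = sample(c("+", "-"), total, replace = TRUE),
    type = ifelse(inter, "CTX", "ITX"),
    size = ifelse(inter, 0, abs(pos2 - pos1)),
    score = score, num_reads = 2L + stats::rpois(total, 8),
    stringsAsFactors = FALSE)
}

# Three pseudo-cell-line peak sets: shared hub sites jittered per line plus
# line-specific uniform noise peaks, so only hub sites survive the
# three-way intersection.
simulate_peaks <- function(config) {
  g <- config$genome
  ph <- config$planted_hubs
  w <- config$peak_width_bp
  jit <- config$peak_jitter_bp
  centers <- if (nrow(ph)) do.call(rbind, lapply(seq_len(nrow(ph)),
    function(h) {
      data.frame(chrom = ph$chrom[h],
                 center = floor(stats::runif(config$sites_per_hub,
                                             ph$start[h] + w,
                                             ph$end[h] - w)),
                 stringsAsFactors = FALSE)
    })) else data.frame(chrom = character(), center = numeric())
  lines <- c("cellA", "cellB", "cellC")
  peaks <- lapply(lines, function(ln) {
    hub_start <- if (nrow(centers))
      centers$center + floor(stats::runif(nrow(centers), -jit, jit)) -
        w %/% 2 else numeric(0)
    ci <- sample.int(nrow(g), config$n_noise_peaks, replace = TRUE,
                     prob = g$length)
    noise_start <- floor(stats::runif(config$n_noise_peaks) *
                           (g$length[ci] - w))
    df <- data.frame(
      chrom = c(as.character(centers$chrom), g$chrom[ci]),
      start = c(hub_start, noise_start), stringsAsFactors = FALSE)
    df$end <- df$start + w
    df$source <- ln
    df[order(match(df$chrom, g$chrom), df$start), , drop = FALSE]
  })
  names(peaks) <- lines
  peaks
}

#' Write a cohort bundle to disk as plain-text files
#'
#' Emits the TSV/BED/BEDPE files consumed by the analysis stages:
#' `annotation.tsv`, `expression.tsv` (raw RSEM-like values),
#' `copy_number.tsv` (segment grid), `metadata.tsv`,
#' `rearrangements.breakdancer.tsv` and `rearrangements.bedpe`, one
#' `peaks_<line>.bed` per pseudo cell line, and a `manifest/` directory
#' holding the planted ground truth (regions, hubs, coupled genes) plus the
#' generator config as YAML. Output is byte-deterministic for a fixed config.
#'
#' @param bundle A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, file) utils::write.table(
    df, file.path(dir, file), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(bundle$annotation, "annotation.tsv")
  expr <- data.frame(gene_id = rownames(bundle$expression),
                     round(bundle$expression, 4), check.names = FALSE)
  tsv(expr, "expression.tsv")
  cnd <- data.frame(bundle$segments, round(bundle$copy_number, 4),
                    check.names = FALSE)
  tsv(cnd, "copy_number.tsv")
  tsv(bundle$metadata, "metadata.tsv")
  write_events(bundle$rearrangements,
               file.path(dir, "rearrangements.breakdancer.tsv"),
               format = "breakdancer")
  write_events(bundle$rearrangements, file.path(dir, "rearrangements.bedpe"),
               format = "bedpe")
  for (ln in names(bundle$peaks))
    write_bed(bundle$peaks[[ln]], file.path(dir, sprintf("peaks_%s.bed", ln)))
  mdir <- file.path(dir, "manifest")
  dir.create(mdir, showWarnings = FALSE)
  utils::write.table(bundle$manifest$planted_regions,
                     file.path(mdir, "planted_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$manifest$planted_hubs,
                     file.path(mdir, "planted_hubs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(bundle$manifest$coupled_genes,
             file.path(mdir, "coupled_genes.txt"))
  cfg <- bundle$manifest$config
  cfg$genome <- as.list(cfg$genome)
  cfg$planted_regions <- as.list(cfg$planted_regions)
  cfg$planted_hubs <- as.list(cfg$planted_hubs)
  yaml::write_yaml(unclass(cfg), file.path(mdir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort directory back into an analysis-ready object
#'
#' Loads the annotation, expression, copy-number and metadata files written by
#' [write_cohort()] (or equivalently formatted external files) and assembles
#' the [cohort()] container with log2-transformed expression.
#'
#' @param dir Directory holding `annotation.tsv`, `expression.tsv`,
#'   `copy_number.tsv`, `metadata.tsv`.
#' @return A list with `cohort` (see [cohort()]) and `annotation`.
#' @export
read_cohort <- function(dir) {
  rt <- function(f) utils::read.table(file.path(dir, f), header = TRUE,
                                      sep = "\t", check.names = FALSE,
                                      stringsAsFactors = FALSE)
  annotation <- rt("annotation.tsv")
  expr_df <- rt("expression.tsv")
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df$gene_id
  cn_df <- rt("copy_number.tsv")
  segments <- cn_df[, c("chrom", "start", "end")]
  cnm <- as.matrix(cn_df[, -(1:3), drop = FALSE])
  metadata <- rt("metadata.tsv")
  list(cohort = cohort(log2_transform(expr), cnm, segments, metadata),
       annotation = annotation)
}
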