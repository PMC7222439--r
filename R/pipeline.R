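#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulates a cohort from `config`, writes it to `out_dir/cohort`, reads the
#' files back, and runs every analysis stage: two-step geomapping (ATC genes
#' and regions), common ERalpha sites and hubs from the three peak sets,
#' confidence-filtered rearrangement link counting against the called
#' regions (1-Mb partner bins and the bait x hub matrix), the ER+/ER-
#' event-count comparison, and cumulative-score survival stratification with
#' the log-rank test. All outputs are plain-text tables; a fixed config
#' (including its seed) yields byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param r_threshold,min_genes,max_span_mb,min_density,k_range Geomapping
#'   parameters, see [map_atc()].
#' @param min_score Rearrangement confidence filter, see [filter_events()].
#' @param bin_mb Partner bin width in Mb.
#' @return Invisibly, a list with the main in-memory results (`bundle`,
#'   `atc`, `hubs`, `links`, `hub_links`, `er_test`, `logrank`, `scores`).
#' @export
run_pipeline <- function(config, out_dir, r_threshold = 0.6,
                         min_genes = 15, max_span_mb = 20,
                         min_density = 1e-8, k_range = c(1L, 10L),
                         min_score = 80, bin_mb = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort_dir <- file.path(out_dir, "cohort")
  bundle <- simulate_cohort(config)
  write_cohort(bundle, cohort_dir)
  cd <- read_cohort(cohort_dir)

  ## geomapping
  atc <- map_atc(cd$cohort, cd$annotation, r_threshold, min_genes,
                 max_span_mb, min_density, k_range)
  write_atc_results(atc, file.path(out_dir, "atc"))

  ## ERalpha hubs from the three peak sets
  peak_paths <- file.path(cohort_dir,
                          sprintf("peaks_%s.bed", names(bundle$peaks)))
  hubs <- map_hubs(peak_paths, k_range)
  write_hub_results(hubs, file.path(out_dir, "hubs"))

  ## rearrangements
  events <- read_events(file.path(cohort_dir,
                                  "rearrangements.breakdancer.tsv"),
                        format = "breakdancer")
  filtered <- filter_events(events, min_score)
  rdir <- file.path(out_dir, "rearrangements")
  dir.create(rdir, showWarnings = FALSE)
  baits <- atc$regions
  links <- NULL; hl <- NULL
  if (nrow(baits) && nrow(filtered)) {
    links <- count_links(filtered, baits, bin_mb, genome = config$genome)
    utils::write.table(links, file.path(rdir, "links_per_sample.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    circos <- circos_link_table(links, baits, bin_mb)
    utils::write.table(circos, file.path(rdir, "circos_links.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    hl <- hub_link_matrix(filtered, baits, hubs$hubs)
    utils::write.table(
      data.frame(bait = rownames(hl$matrix), hl$matrix,
                 check.names = FALSE),
      file.path(rdir, "bait_by_hub_matrix.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }

  ## per-sample filtered event counts, ER comparison
  meta <- cd$cohort$metadata
  counts <- table(factor(filtered$sample, levels = meta$sample))
  er_test <- tryCatch(
    compare_groups(as.numeric(counts), meta$er_status),
    error = function(e) NULL)
  utils::write.table(
    data.frame(sample = meta$sample, er_status = meta$er_status,
               n_events = as.integer(counts)),
    file.path(rdir, "event_counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  ## concordance + survival
  sdir <- file.path(out_dir, "survival")
  dir.create(sdir, showWarnings = FALSE)
  scores <- NULL; lr <- NULL
  if (nrow(atc$atc_genes) >= 2) {
    scores <- cumulative_score(cd$cohort$expression, atc$atc_genes$gene_id)
    names(scores) <- meta$sample
    tab <- select_extreme_samples(scores,
                                  n_top = min(15, length(scores) %/% 2))
    utils::write.table(tab, file.path(sdir, "atc_score_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    grp <- split_by_median(scores)
    lr <- tryCatch(logrank_test(meta$os_days, meta$os_event, grp),
                   error = function(e) NULL)
    if (!is.null(lr)) {
      utils::write.table(
        data.frame(chisq = lr$chisq, p = lr$p,
                   n_high = sum(grp == "high"), n_low = sum(grp == "low")),
        file.path(sdir, "logrank_report.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    }
    prof <- correlation_profile(cd$cohort$expression, atc$atc_genes$gene_id)
    utils::write.table(round(prof$matrix, 4),
                       file.path(sdir, "expression_correlation.tsv"),
                       sep = "\t", quote = FALSE)
  }

  invisible(list(bundle = bundle, atc = atc, hubs = hubs, links = links,
                 hub_links = hl, er_test = er_test, logrank = lr,
                 scores = scores))
}

# Circos-compatible link table: chrA startA endA chrB startB endB count,
# pooled over samples and strata.
circos_link_table <- function(links, baits, bin_mb = 1) {
  bw <- bin_mb * 1e6
  agg <- stats::aggregate(
    list(count = links$count),
    by = links[, c("bait", "partner_chrom", "bin")], FUN = sum)
  i <- match(agg$bait, baits$region_id)
  out <- data.frame(chrA = baits$chrom[i], startA = baits$start[i],
                    endA = baits$end[i], chrB = agg$partner_chrom,
                    startB = agg$bin * bw, endB = (agg$bin + 1) * bw,
                    count = agg$count, stringsAsFactors = FALSE)
  out[order(out$chrA, out$startA, out$chrB, out$startB), , drop = FALSE]
}
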