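#!/usr/bin/env Rscript
# Stage 4 — rearrangement link counting and group comparisons.
#
# Reads the BreakDancer-style calls, applies the confidence filter
# (score > 80), classifies inter/intra events, counts links from the called
# ATC regions (baits) to 1-Mb partner bins and to the called hubs, and
# compares per-sample event counts between ER+ and ER- samples and between
# ATC-prone and ATC-less samples (top/bottom 15 by cumulative score) with
# the Mann-Whitney U test. Output: results/rearrangements/.

library(atcgeomap)

cohort_dir <- file.path("results", "cohort")
cd <- read_cohort(cohort_dir)
events <- read_events(file.path(cohort_dir, "rearrangements.breakdancer.tsv"),
                      "breakdancer")
filtered <- filter_events(events, 80)
cat(sprintf("events: %d read, %d pass score > 80 (%.1f%%)\n",
            nrow(events), nrow(filtered),
            100 * nrow(filtered) / nrow(events)))
strat <- classify_events(filtered)
cat(sprintf("  inter: %d  intra: %d (%.0f%% intra)\n", sum(strat == "inter"),
            sum(strat == "intra"), 100 * mean(strat == "intra")))

atc_genes <- utils::read.table(file.path("results", "atc", "atc_genes.tsv"),
                               header = TRUE, sep = "\t")
regions <- utils::read.table(file.path("results", "atc", "atc_regions.tsv"),
                             header = TRUE, sep = "\t")
hubs <- utils::read.table(file.path("results", "hubs", "er_hubs.tsv"),
                          header = TRUE, sep = "\t")
out <- file.path("results", "rearrangements")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- data.frame(chrom = c("chr1", "chr2"), length = c(120e6, 100e6))
links <- count_links(filtered, regions, bin_mb = 1, genome = genome)
utils::write.table(links, file.path(out, "links_per_sample.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
hl <- hub_link_matrix(filtered, regions, hubs)
utils::write.table(data.frame(bait = rownames(hl$matrix), hl$matrix,
                              check.names = FALSE),
                   file.path(out, "bait_by_hub_matrix.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("bait x hub link matrix (pooled):\n")
print(hl$matrix)

## ER+ vs ER- per-sample event counts
meta <- cd$cohort$metadata
counts <- as.numeric(table(factor(filtered$sample, levels = meta$sample)))
er <- compare_groups(counts, meta$er_status)
cat(sprintf("ER+ vs ER- filtered events/sample: U = %.1f, p = %.3g (%s)\n",
            er$U, er$p, er$method))

## ATC-prone vs ATC-less (top/bottom 15 by cumulative score)
scores <- cumulative_score(cd$cohort$expression, atc_genes$gene_id)
names(scores) <- meta$sample
tab <- select_extreme_samples(scores, 15)
extreme <- tab[tab$group != "middle", ]
cnt <- counts[match(extreme$sample, meta$sample)]
pl <- compare_groups(cnt, extreme$group)
cat(sprintf("ATC-prone vs ATC-less events/sample: U = %.1f, p = %.3g\n",
            pl$U, pl$p))
utils::write.table(
  data.frame(comparison = c("er_pos_vs_neg", "prone_vs_less"),
             U = c(er$U, pl$U), p = c(er$p, pl$p)),
  file.path(out, "group_comparisons.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("written to results/rearrangements\n")
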