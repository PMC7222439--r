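test_that("log2 transform applies the pseudocount and rejects negatives", {
  expect_equal(log2_transform(0), 0)
  expect_equal(log2_transform(1), 1)
  expect_equal(log2_transform(1023), 10, tolerance = 1e-6)
  expect_error(log2_transform(c(1, -0.5)), ">= 0")
})

segs_toy <- data.frame(chrom = rep("chr1", 4),
                       start = c(0, 1e5, 2e5, 3e5),
                       end = c(1e5, 2e5, 3e5, 4e5))

test_that("genes inherit the copy number of their midpoint segment", {
  cn <- matrix(1:8, nrow = 4, byrow = TRUE) # segment i -> values 2i-1, 2i
  g <- list(chrom = "chr1", start = 150000, end = 160000)
  expect_equal(assign_gene_copynumber(g, segs_toy, cn), c(3, 4))
  # boundary-spanning gene, midpoint 199990 -> segment [1e5, 2e5)
  g2 <- list(chrom = "chr1", start = 190000, end = 209980)
  expect_equal(assign_gene_copynumber(g2, segs_toy, cn), c(3, 4))
  # midpoint in a grid gap -> nearest segment on the chromosome
  gappy <- segs_toy[c(1, 4), ]
  g3 <- list(chrom = "chr1", start = 240000, end = 260000)
  expect_equal(assign_gene_copynumber(g3, gappy, cn[c(1, 4), ]), c(7, 8))
  expect_error(
    assign_gene_copynumber(list(chrom = "chrZ", start = 0, end = 10),
                           segs_toy, cn), "absent")
})

test_that("correlate_gene handles exact, degenerate and short inputs", {
  expect_equal(correlate_gene(c(1, 2, 3, 4), c(0, 1, 2, 3)), 1.0)
  expect_equal(correlate_gene(c(1, 2, 3, 4), c(3, 2, 1, 0)), -1.0)
  expect_true(is.na(correlate_gene(c(2, 2, 2, 2), c(1, 2, 3, 4))))
  expect_true(is.na(correlate_gene(c(1, 2), c(1, 2))))
  expect_true(is.na(correlate_gene(c(1, 2, NA, 4), c(1, NA, 3, 4))))
})

test_that("screen threshold is inclusive at r = 0.6 and monotone", {
  # three genes engineered to correlate perfectly, anticorrelate, and sit
  # at the stored threshold value itself
  expr <- rbind(G1 = c(1, 2, 3, 4), G2 = c(4, 3, 2, 1), G3 = c(1, 2, 2, 3))
  cn <- matrix(c(0, 1, 2, 3), nrow = 1)
  segs <- data.frame(chrom = "chr1", start = 0, end = 1e5)
  genes <- data.frame(gene_id = c("G1", "G2", "G3"), chrom = "chr1",
                      start = c(0, 1, 2) * 1e4, end = c(1, 2, 3) * 1e4)
  co <- cohort(expr, cn, segs, NULL)
  all_r <- screen_atc_genes(co, genes, keep_all = TRUE)
  # inclusive boundary: filtering at exactly a gene's r keeps that gene
  r3 <- all_r$r[all_r$gene_id == "G3"]
  kept <- screen_atc_genes(co, genes, r_threshold = r3)
  expect_true("G3" %in% kept$gene_id)
  dropped <- screen_atc_genes(co, genes,
                              r_threshold = r3 + 1e-12)
  expect_false("G3" %in% dropped$gene_id)
  expect_false("G2" %in% kept$gene_id)
  # raising the threshold never enlarges the retained set
  b <- simulate_cohort(small_config(seed = 2))
  co2 <- cohort(log2_transform(b$expression), b$copy_number, b$segments,
                b$metadata)
  sets <- lapply(c(0.3, 0.6, 0.9), function(th)
    screen_atc_genes(co2, b$annotation, th)$gene_id)
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("region selection enforces all three criteria", {
  # candidate with 14 genes in a tight cluster -> excluded by gene count
  mk_genes <- function(n, start, spacing, chrom = "chr1")
    data.frame(gene_id = sprintf("g%s_%d", chrom, seq_len(n)), chrom = chrom,
               start = start + (seq_len(n) - 1) * spacing,
               end = start + (seq_len(n) - 1) * spacing + 1e4,
               r = 0.9, stringsAsFactors = FALSE)
  g14 <- mk_genes(14, 1e6, 5e4)
  expect_equal(nrow(call_atc_regions(g14, k_range = c(1, 3))), 0)
  g15 <- mk_genes(15, 1e6, 5e4)
  r15 <- call_atc_regions(g15, k_range = c(1, 3))
  expect_equal(nrow(r15), 1)
  expect_equal(r15$gene_count, 15)
  # 25-Mb span -> excluded by length
  gwide <- mk_genes(30, 1e6, 25e6 / 29)
  expect_equal(nrow(call_atc_regions(gwide, k_range = c(1, 1))), 0)
  # emitted regions satisfy every criterion on recomputation
  b <- simulate_cohort(small_config(seed = 4, n_samples = 80))
  co <- cohort(log2_transform(b$expression), b$copy_number, b$segments,
               b$metadata)
  res <- map_atc(co, b$annotation)
  for (i in seq_len(nrow(res$regions))) {
    m <- res$regions$members[[i]]
    expect_gte(nrow(m), 15)
    expect_lt((max(m$end) - min(m$start)) / 1e6, 20)
    expect_gt(res$regions$density[i], 1e-8)
    expect_equal(res$regions$start[i], min(m$start))
    expect_equal(res$regions$end[i], max(m$end))
  }
  # same-chromosome regions never overlap
  reg <- res$regions
  for (ch in unique(reg$chrom)) {
    rr <- reg[reg$chrom == ch, ]
    rr <- rr[order(rr$start), ]
    if (nrow(rr) > 1)
      expect_true(all(rr$start[-1] >= rr$end[-nrow(rr)]))
  }
})

test_that("k range wider than the gene count is clamped with a warning", {
  g5 <- data.frame(gene_id = paste0("g", 1:5), chrom = "chr1",
                   start = c(1, 2, 3, 40, 41) * 1e6,
                   end = c(1, 2, 3, 40, 41) * 1e6 + 1e4, r = 0.8)
  expect_warning(res <- call_atc_regions(g5, min_genes = 1,
                                         k_range = c(1, 10)),
                 "clamped")
  expect_gte(nrow(res), 1)
})

test_that("planted regions are recovered on a compact cohort", {
  b <- simulate_cohort(small_config(seed = 6, n_samples = 120,
                                    expr_noise_sd = 0.3))
  co <- cohort(log2_transform(b$expression), b$copy_number, b$segments,
               b$metadata)
  res <- map_atc(co, b$annotation)
  pr <- b$manifest$planted_regions
  expect_equal(nrow(res$regions), 1)
  expect_gte(interval_jaccard(res$regions$start, res$regions$end,
                              pr$start, pr$end), 0.8)
})
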