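test_that("BreakDancer and BEDPE dialects round-trip", {
  set.seed(2)
  ev <- random_events(25)
  f1 <- tempfile(); f2 <- tempfile()
  write_events(ev, f1, "breakdancer")
  back <- read_events(f1, "breakdancer")
  expect_equal(back$chrom1, ev$chrom1)
  expect_equal(back$pos1, ev$pos1)
  expect_equal(back$pos2, ev$pos2)
  expect_equal(back$score, ev$score)
  expect_equal(back$sample, ev$sample)
  write_events(ev, f2, "bedpe")
  back2 <- read_events(f2, "bedpe")
  expect_equal(back2$pos1, ev$pos1)
  expect_equal(back2$pos2, ev$pos2)
  expect_equal(back2$score, ev$score)
  expect_equal(back2$sample, ev$sample)
  expect_equal(back2$orient1, ev$orient1)
  # header-only file -> empty list
  writeLines("#Chr1\tPos1", f1)
  expect_equal(nrow(read_events(f1, "breakdancer")), 0)
  # malformed row reports its line number
  writeLines(c("#hdr", "chr1\t100\t+"), f1)
  expect_error(read_events(f1, "breakdancer"), "line 2")
  unlink(c(f1, f2))
})

test_that("score filter is strict at the boundary, idempotent and
           monotone", {
  ev <- random_events(10)
  ev$score <- c(79, 80, 80, 81, 90, 10, 100, 80.5, 99, 81)
  kept <- filter_events(ev, 80)
  expect_false(any(kept$score <= 80))
  expect_true(all(c(81, 90, 100, 80.5, 99) %in% kept$score))
  expect_equal(nrow(kept), 6)
  expect_identical(filter_events(kept, 80), kept)
  expect_lte(nrow(filter_events(ev, 90)), nrow(kept))
  ev$score <- rep(80, 10)
  expect_equal(nrow(filter_events(ev, 80)), 0)
})

test_that("events classify by chromosome identity", {
  ev <- data.frame(chrom1 = c("chr17", "chr17"), chrom2 = c("chr20", "chr17"))
  expect_equal(classify_events(ev), c("inter", "intra"))
})

test_that("link counting places partners in 1-Mb bins as specified", {
  baits <- data.frame(region_id = "B1", chrom = "chr17",
                      start = 10e6, end = 12e6)
  ev <- data.frame(sample = "s1", chrom1 = "chr17", pos1 = 11e6,
                   orient1 = "+", chrom2 = "chr20", pos2 = 13.4e6,
                   orient2 = "-", type = "CTX", size = 0, score = 90,
                   num_reads = 5)
  lm <- count_links(ev, baits)
  expect_equal(nrow(lm), 1)
  expect_equal(lm$partner_chrom, "chr20")
  expect_equal(lm$bin, 13)
  expect_equal(lm$bin_start, 13e6)
  expect_equal(lm$stratum, "inter")
  expect_equal(lm$count, 1L)
  # no breakpoint in any bait -> empty
  ev2 <- ev; ev2$pos1 <- 1e6; ev2$chrom2 <- "chr20"
  expect_equal(nrow(count_links(ev2, baits)), 0)
  # both ends inside the same bait: one count, intra stratum
  ev3 <- ev; ev3$chrom2 <- "chr17"; ev3$pos2 <- 11.5e6
  lm3 <- count_links(ev3, baits)
  expect_equal(sum(lm3$count), 1L)
  expect_equal(lm3$stratum, "intra")
  # overlapping baits are rejected
  bad <- data.frame(region_id = c("a", "b"), chrom = "chr17",
                    start = c(0, 1e6), end = c(2e6, 3e6))
  expect_error(count_links(ev, bad), "overlap")
})

test_that("link totals match the (event, bait, end) double-loop oracle", {
  set.seed(31)
  for (rep in 1:8) {
    ev <- random_events(50)
    baits <- data.frame(region_id = c("B1", "B2"),
                        chrom = c("chr1", "chr2"),
                        start = c(5e6, 20e6), end = c(15e6, 30e6))
    lm <- count_links(ev, baits)
    expect_equal(sum(lm$count), oracle_link_total(ev, baits))
  }
})

test_that("partner breakpoints beyond the chromosome end are clamped", {
  baits <- data.frame(region_id = "B1", chrom = "chr1",
                      start = 0, end = 1e6)
  ev <- data.frame(sample = "s", chrom1 = "chr1", pos1 = 5e5, orient1 = "+",
                   chrom2 = "chr2", pos2 = 99e6, orient2 = "-",
                   type = "CTX", size = 0, score = 95, num_reads = 3)
  genome <- data.frame(chrom = c("chr1", "chr2"), length = c(50e6, 40e6))
  expect_warning(lm <- count_links(ev, baits, genome = genome), "clamped")
  expect_equal(lm$bin, 39)
})

test_that("hub link matrix routes partners into hubs or non_hub", {
  baits <- data.frame(region_id = "B1", chrom = "chr17",
                      start = 10e6, end = 12e6)
  hubs <- data.frame(hub_id = "H001", chrom = "chr20",
                     start = 13e6, end = 15e6)
  ev_in <- data.frame(sample = "s1", chrom1 = "chr17", pos1 = 11e6,
                      orient1 = "+", chrom2 = "chr20", pos2 = 14e6,
                      orient2 = "-", type = "CTX", size = 0, score = 90,
                      num_reads = 5)
  ev_out <- ev_in; ev_out$pos2 <- 20e6
  hm <- hub_link_matrix(rbind(ev_in, ev_out), baits, hubs)
  expect_equal(hm$matrix["B1", "H001"], 1L)
  expect_equal(hm$matrix["B1", "non_hub"], 1L)
})

test_that("targeted simulation concentrates links on the planted
           (bait, hub) cell", {
  ok <- 0
  nseeds <- 40
  for (s in 1:nseeds) {
    cfg <- small_config(seed = s, hub_targeting_fraction = 0.7,
                        planted_hubs = data.frame(chrom = "chr2",
                                                  start = 25e6, end = 27e6))
    set.seed(s)
    ev <- simulate_rearrangements(cfg, cfg$planted_regions,
                                  cfg$planted_hubs)
    ev <- filter_events(ev, 80)
    baits <- cfg$planted_regions
    baits$region_id <- "B1"
    hm <- hub_link_matrix(ev, baits, data.frame(
      hub_id = "H1", chrom = "chr2", start = 25e6, end = 27e6))
    m <- hm$matrix
    ok <- ok + (m["B1", "H1"] == max(m))
  }
  expect_gte(ok / nseeds, 0.95)
})

test_that("Mann-Whitney handles symmetry, separation and ties exactly", {
  # identical multisets in both groups -> p = 1 by enumeration symmetry
  res <- compare_groups(c(1, 2, 2, 5, 1, 2, 2, 5),
                        rep(c("a", "b"), each = 4))
  expect_equal(res$p, 1)
  # complete separation -> U = 0 for the low group
  res2 <- compare_groups(c(1, 2, 3, 10, 11, 12),
                         rep(c("a", "b"), each = 3))
  expect_equal(res2$U, 0)
  expect_equal(res2$p, oracle_mw_exact(c(1, 2, 3), c(10, 11, 12)))
  expect_error(compare_groups(1:4, rep("a", 4)), "two groups")
})

test_that("Mann-Whitney agrees with independent oracles", {
  set.seed(41)
  # exact path vs enumeration oracle (with ties)
  for (i in 1:10) {
    x <- sample(1:6, sample(4:8, 1), replace = TRUE)
    y <- sample(2:8, sample(4:8, 1), replace = TRUE)
    mine <- compare_groups(c(x, y), rep(c("a", "b"), c(length(x),
                                                       length(y))))
    expect_equal(mine$p, oracle_mw_exact(x, y), tolerance = 1e-12)
  }
  # large-sample path vs stats::wilcox.test on tie-free data
  for (i in 1:5) {
    x <- rnorm(25); y <- rnorm(30, 0.5)
    mine <- compare_groups(c(x, y), rep(c("a", "b"), c(25, 30)))
    ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("ER-status rate difference is detected by the group comparison", {
  hits <- 0
  nseeds <- 40
  for (s in 1:nseeds) {
    set.seed(s)
    pos <- rpois(15, 15); neg <- rpois(15, 5) # 3x rate difference
    res <- compare_groups(c(pos, neg), rep(c("pos", "neg"), each = 15))
    hits <- hits + (res$p < 0.05)
  }
  expect_gte(hits / nseeds, 0.9)
})

test_that("a bait without planted targeting collects only uniform
           background", {
  ok <- 0
  nseeds <- 20
  for (s in 1:nseeds) {
    cfg <- small_config(seed = s, hub_targeting_fraction = 0,
                        n_events_per_sample = 60)
    set.seed(s)
    ev <- simulate_rearrangements(cfg, cfg$planted_regions,
                                  cfg$planted_hubs)
    # negative-control bait where nothing was planted
    ctrl <- data.frame(region_id = "NC", chrom = "chr1",
                       start = 30e6, end = 36e6)
    lm <- count_links(filter_events(ev, 80), ctrl)
    # partner bins on chr2 should look uniform
    tab <- table(factor(lm$bin[lm$partner_chrom == "chr2"], levels = 0:39))
    counts <- as.vector(tapply(lm$count[lm$partner_chrom == "chr2"],
                               factor(lm$bin[lm$partner_chrom == "chr2"],
                                      levels = 0:39), sum))
    counts[is.na(counts)] <- 0
    p <- suppressWarnings(chisq.test(counts)$p.value)
    ok <- ok + (p > 0.01)
  }
  expect_gte(ok, ceiling(0.95 * nseeds) - 1)
})

test_that("null Mann-Whitney p-values are approximately uniform", {
  set.seed(55)
  ps <- replicate(200, {
    v <- rpois(30, 10)
    compare_groups(v, rep(c("a", "b"), each = 15))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
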