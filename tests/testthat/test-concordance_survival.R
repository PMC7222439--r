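test_that("cumulative score is the sum of population-sd z-scores", {
  m <- matrix(c(1, 3), nrow = 1, dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(cumulative_score(m, "g1")), c(-1, 1))
  # constant matrix -> zero scores, with a warning
  mc <- matrix(5, nrow = 2, ncol = 4,
               dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expect_warning(sc <- cumulative_score(mc, c("a", "b")), "zero-variance")
  expect_equal(unname(sc), rep(0, 4))
  # invariant under per-gene affine rescaling
  set.seed(8)
  m2 <- matrix(rnorm(40), nrow = 4,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  s1 <- cumulative_score(m2, rownames(m2))
  s2 <- cumulative_score(m2 * 7 + 3, rownames(m2))
  expect_equal(s1, s2)
  expect_error(cumulative_score(m2, "nope"), "absent")
})

test_that("extreme-sample selection is exhaustive, ordered and disjoint", {
  set.seed(12)
  sc <- setNames(rnorm(30), sprintf("S%02d", 1:30))
  tab <- select_extreme_samples(sc, 15)
  expect_setequal(tab$group, c("prone", "less"))
  expect_equal(sum(tab$group == "prone"), 15)
  # strictly increasing scores by index -> prone = last 15 sample ids
  sc2 <- setNames(seq_len(30), sprintf("S%02d", 1:30))
  tab2 <- select_extreme_samples(sc2, 15)
  expect_setequal(tab2$sample[tab2$group == "prone"], sprintf("S%02d", 16:30))
  expect_true(all(tab2$score[tab2$group == "prone"] >
                    max(tab2$score[tab2$group == "less"])))
  # disjoint for any n_top
  set.seed(13)
  for (i in 1:10) {
    n <- sample(10:40, 1); nt <- sample(1:(n %/% 2), 1)
    sc3 <- setNames(sample(1:5, n, TRUE), paste0("x", seq_len(n)))
    t3 <- select_extreme_samples(sc3, nt)
    expect_length(intersect(t3$sample[t3$group == "prone"],
                            t3$sample[t3$group == "less"]), 0)
  }
  expect_error(select_extreme_samples(sc[1:10], 15), "cohort size")
})

test_that("prone samples carry more planted copy number than less samples", {
  signs <- sapply(1:6, function(s) {
    b <- simulate_cohort(small_config(seed = s, n_samples = 60))
    sc <- cumulative_score(log2_transform(b$expression),
                           b$manifest$coupled_genes)
    names(sc) <- b$metadata$sample
    tab <- select_extreme_samples(sc, 10)
    pr <- b$manifest$planted_regions
    seg <- b$segments$chrom == pr$chrom & b$segments$start < pr$end &
      b$segments$end > pr$start
    cn_mean <- colMeans(b$copy_number[seg, , drop = FALSE])
    mean(cn_mean[tab$sample[tab$group == "prone"]]) >
      mean(cn_mean[tab$sample[tab$group == "less"]])
  })
  expect_true(all(signs))
})

test_that("correlation profiles are symmetric with unit diagonal and flag
           degenerate genes", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4) * 2,
             g3 = c(4, 1, 3, 2), g4 = c(2, 2, 2, 2))
  colnames(m) <- paste0("s", 1:4)
  prof <- correlation_profile(m, rownames(m))
  expect_equal(prof$matrix["g1", "g2"], 1.0)
  expect_equal(prof$matrix, t(prof$matrix))
  expect_equal(unname(diag(prof$matrix)[1:3]), rep(1, 3))
  expect_true(all(is.na(prof$matrix["g4", c("g1", "g2", "g3")])))
  expect_error(correlation_profile(m[, 1:2], rownames(m)), ">= 3 samples")
})

test_that("noise-free planted region yields a unit within-region block and
           near-zero background correlation", {
  b <- simulate_cohort(small_config(seed = 14, expr_noise_sd = 0))
  expr <- log2_transform(b$expression)
  coupled <- b$manifest$coupled_genes
  bg <- setdiff(rownames(expr), coupled)[1:20]
  prof <- correlation_profile(expr, c(coupled, bg))
  within <- prof$matrix[coupled, coupled]
  expect_true(all(abs(within - 1) < 1e-9, na.rm = TRUE))
  cross <- prof$matrix[coupled, bg]
  expect_lt(abs(mean(cross, na.rm = TRUE)), 0.15)
})

test_that("log-rank statistic behaves under symmetry and matches
           survival::survdiff", {
  tm <- c(5, 8, 12, 20, 25, 33)
  ev <- c(1, 1, 0, 1, 1, 0)
  # two copies of the same data -> statistic 0, p 1
  res <- logrank_test(c(tm, tm), c(ev, ev), rep(c("a", "b"), each = 6))
  expect_equal(res$chisq, 0)
  expect_equal(res$p, 1)
  skip_if_not_installed("survival")
  set.seed(17)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    t2 <- rexp(n, 0.02); e2 <- rbinom(n, 1, 0.7)
    g2 <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(g2)) < 2 || sum(e2) == 0) next
    mine <- logrank_test(t2, e2, g2)
    ref <- survival::survdiff(survival::Surv(t2, e2) ~ g2)
    expect_equal(mine$chisq, ref$chisq, tolerance = 1e-8)
  }
  # no events at all -> undefined marker
  expect_true(is.na(logrank_test(c(1, 2), c(0, 0), c("a", "b"))$chisq))
})

test_that("log-rank matches the hand-derived statistic and the exact
           permutation tail on a complete-separation instance", {
  # group A events at t = 1, 2; group B events at t = 3, 4 (no censoring):
  # O - E = (1 - 1/2) + (1 - 1/3) = 7/6, V = 1/4 + 2/9 = 17/36,
  # so chisq = (7/6)^2 / (17/36) = 49/17
  tm <- c(1, 2, 3, 4)
  ev <- c(1, 1, 1, 1)
  gr <- c("A", "A", "B", "B")
  res <- logrank_test(tm, ev, gr)
  expect_equal(res$chisq, 49 / 17, tolerance = 1e-12)
  # full enumeration of the 6 label assignments: the observed separation is
  # maximal, attained by exactly the 2 mirror-image assignments
  combos <- utils::combn(4, 2)
  stats <- apply(combos, 2, function(ii) {
    g <- rep("B", 4); g[ii] <- "A"
    logrank_test(tm, ev, g)$chisq
  })
  expect_equal(mean(stats >= res$chisq - 1e-12), 2 / 6)
  expect_equal(max(stats), res$chisq, tolerance = 1e-12)
})

test_that("median split labels deterministically with ties low", {
  expect_equal(split_by_median(c(1, 2, 3, 4)),
               c("low", "low", "high", "high"))
  expect_equal(split_by_median(rep(2, 5)), rep("low", 5))
  set.seed(29)
  for (i in 1:100) {
    n <- sample(3:41, 1)
    s <- rnorm(n)
    g <- split_by_median(s)
    if (n %% 2 == 1)
      expect_lte(abs(sum(g == "high") - sum(g == "low")), 1)
  }
  expect_error(split_by_median(1), ">= 2")
})
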