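test_that("normalization is per 10,000 reads and scale invariant", {
  expect_equal(normalize_abundance(10, 10000), 10)
  expect_equal(normalize_abundance(0, 5000), 0)
  expect_error(normalize_abundance(1, 0), "positive")
  expect_equal(normalize_abundance(50, 20000),
               normalize_abundance(50, 20000))
  expect_equal(fold_change(20, 100, 10, 100), 2)
  expect_equal(fold_change(20, 100, 10, 100),
               fold_change(20, 1000, 10, 1000))
})

test_that("fold change handles one-sided and two-sided zeros", {
  expect_equal(fold_change(1363, 273431, 0, 273431), Inf)
  expect_true(is.nan(fold_change(0, 100, 0, 100)))
  # the FbLate-2 style contrast: 1028 vs 335 at equal totals is ~3-fold
  expect_equal(round(fold_change(1028, 1e5, 335, 1e5), 2), 3.07)
})

test_that("the R statistic matches hand-evaluated cases", {
  expect_equal(stekel_r(c(10, 20), c(100, 200)), 0)
  expect_equal(stekel_r(c(5, 5, 5), c(100, 100, 100)), 0)
  expect_equal(stekel_r(c(0, 10), c(100, 100)), 10 * log(2))
  expect_error(stekel_r(c(0, 0), c(100, 100)), "undefined")
  expect_error(stekel_r(10, 100), "length")
  # heterogeneous counts give strictly positive R
  expect_gt(stekel_r(c(2, 40), c(100, 100)), 0)
})

test_that("Fisher's exact test equals the enumeration oracle", {
  expect_equal(fisher_exact_2x2(2, 0, 0, 2), 1 / 3)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)
  set.seed(10)
  for (i in 1:60) {
    tb <- sample(0:30, 4, replace = TRUE)
    p <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, fisher_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12, info = paste(tb, collapse = ","))
    # cross-check against the stats implementation
    if (sum(tb) > 0) {
      expect_equal(p, stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                   tolerance = 1e-8)
    }
    # symmetry under row and column swaps, p in (0, 1]
    expect_equal(p, fisher_exact_2x2(tb[3], tb[4], tb[1], tb[2]))
    expect_equal(p, fisher_exact_2x2(tb[2], tb[1], tb[4], tb[3]))
    expect_true(p > 0 && p <= 1)
  }
})

test_that("chi-squared p of 2R agrees with Fisher in the significance tail", {
  set.seed(11)
  checked <- 0
  while (checked < 25) {
    N <- sample(10000:40000, 2, replace = TRUE)
    f <- runif(1, 5e-4, 5e-3)
    x <- rbinom(2, N, f)
    if (any(N * sum(x) / sum(N) < 10) || all(x == 0)) next
    p_fis <- fisher_exact_2x2(x[1], N[1] - x[1], x[2], N[2] - x[2])
    if (p_fis > 0.05) next
    expect_lte(abs(stekel_r_pvalue(x, N) - p_fis), 0.02 + 1e-6)
    checked <- checked + 1
  }
})

test_that("group comparison flags one-sided extremes and spares balanced contigs", {
  counts <- rbind(fblate = c(0, 0, 335, 1028),
                  flat = c(50, 50, 50, 50),
                  quiet = c(0, 0, 0, 0))
  colnames(counts) <- c("Gh10", "Gb10", "Gh22", "Gb22")
  tbl <- count_table(counts, lib_totals = c(Gh10 = 5e4, Gb10 = 5e4,
                                            Gh22 = 5e4, Gb22 = 5e4))
  res <- compare_groups(tbl, list(libraries = c("Gh10", "Gb10")),
                        list(libraries = c("Gh22", "Gb22")))
  expect_identical(res$flag[res$contig == "fblate"], "group2")
  expect_equal(res$fold[res$contig == "fblate"], 0)
  expect_identical(res$flag[res$contig == "flat"], "none")
  expect_identical(res$flag[res$contig == "quiet"], "none")
  expect_true(is.nan(res$fold[res$contig == "quiet"]))

  expect_error(compare_groups(tbl, list(libraries = "Gh10"),
                              list(libraries = "Gh10")), "disjoint")
  expect_error(compare_groups(tbl, list(libraries = character(0)),
                              list(libraries = "Gh10")), "librar")
})

test_that("planted four-fold changes are recovered with correct direction", {
  sim <- simulate_count_table(n_contigs = 200L, reads_per_library = 20000L,
                              de_fraction = 0.2, de_fold = 4, seed = 21L)
  res <- compare_groups(sim$table, list(libraries = c("Gh10", "Gb10")),
                        list(libraries = c("Gh22", "Gb22")))
  de <- sim$truth$de
  want <- ifelse(sim$truth$up_stage == "10", "group1", "group2")
  recovery <- mean(res$flag[de] == want[de])
  expect_gte(recovery, 0.9)
})

test_that("null count tables stay within the type-I budget", {
  sim <- simulate_count_table(n_contigs = 1000L, reads_per_library = 20000L,
                              de_fraction = 0, seed = 22L)
  res <- compare_groups(sim$table, list(libraries = c("Gh10", "Gb10")),
                        list(libraries = c("Gh22", "Gb22")))
  expect_lte(mean(res$flag != "none"), 0.05)
})

test_that("the comparison matrix enumerates nested contrasts symmetrically", {
  sim <- simulate_count_table(n_contigs = 150L, reads_per_library = 10000L,
                              de_fraction = 0.3, de_fold = 4, seed = 23L)
  cm <- comparison_matrix(sim$table)
  expect_setequal(unique(cm$factor), c("stage", "genotype"))
  expect_equal(sum(cm$factor == "stage"), 3L)     # overall, within Gh, Gb
  expect_equal(sum(cm$factor == "genotype"), 3L)

  # planted DE is at stage level only: genotype contrasts behave as null
  gflag <- cm[cm$factor == "genotype", ]
  expect_lte(max(gflag$n_up_group1 + gflag$n_up_group2), 0.05 * 150 + 5)
  sflag <- cm[cm$comparison == "10 vs 22", ]
  expect_gt(sflag$n_up_group1 + sflag$n_up_group2, 20)

  # relabeling the groups swaps the two counts
  cnt2 <- sim$table$counts[, c("Gh22", "Gb22", "Gh10", "Gb10")]
  colnames(cnt2) <- c("Gh10", "Gb10", "Gh22", "Gb22")
  cm2 <- comparison_matrix(count_table(cnt2))
  expect_equal(cm2[cm2$comparison == "10 vs 22", "n_up_group1"],
               sflag$n_up_group2)
  expect_equal(cm2[cm2$comparison == "10 vs 22", "n_up_group2"],
               sflag$n_up_group1)
})

test_that("tag contrasts without tagged reads are skipped with a warning", {
  counts <- matrix(10L, 5, 4,
                   dimnames = list(paste0("c", 1:5),
                                   c("Gh10", "Gb10", "Gh22", "Gb22")))
  tags <- array(0L, dim = c(5, 4, 3),
                dimnames = list(paste0("c", 1:5), colnames(counts),
                                c("A", "D", "unknown")))
  tbl <- count_table(counts, tag_counts = tags)
  w <- capture_warnings(cm <- comparison_matrix(tbl))
  expect_gt(length(w), 0L)
  expect_true(all(grepl("no reads", w)))
  expect_false(any(cm$factor == "tag"))
})

test_that("platform concordance tallies directions", {
  a <- c(rep("g1", 242), rep("g2", 161), rep("g1", 55), rep("g2", 85))
  b <- c(rep("g1", 242), rep("g2", 161), rep("g2", 55), rep("g1", 85))
  pc <- platform_concordance(a, b)
  expect_equal(pc$n_common, 543)
  expect_equal(pc$n_same_dir_g1, 242)
  expect_equal(pc$n_same_dir_g2, 161)
  expect_equal(pc$n_discordant, 140)
  expect_equal(pc$pct_concordant, 74)

  expect_equal(platform_concordance(rep("g1", 7),
                                    rep("g1", 7))$pct_concordant, 100)
  empty <- platform_concordance(character(0), character(0))
  expect_equal(empty$n_common, 0)
  expect_true(is.na(empty$pct_concordant))
  expect_error(platform_concordance("up", "down"), "g1")
})
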