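test_that("median PSS interval matches the sort-diff-median oracle", {
  expect_equal(median_pss_interval(c(5, 10, 15, 20)), 5)
  expect_true(is.na(median_pss_interval(12)))
  expect_true(is.na(median_pss_interval(integer(0))))
  expect_error(median_pss_interval(c(3, 3, 7)), "duplicate")
  set.seed(17)
  for (rep in 1:200) {
    pos <- sample(1000, sample(2:30, 1))
    expect_identical(median_pss_interval(pos), oracle_median_interval(pos))
  }
})

test_that("aggregation filter excludes D_med <= 10 inclusive, keeps NA", {
  d <- c(3, 10, 10.5, 11, NA)
  ex <- aggregation_filter(d)
  expect_identical(ex, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(sum(aggregation_filter(c(3, 10, 11, NA))), 2L)
  # configurable cutoff
  expect_identical(aggregation_filter(c(3, 10), cutoff = 5),
                   c(TRUE, FALSE))
})

test_that("bh_fdr reproduces the independent step-up implementation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(23)
  for (rep in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-15)
  }
})

test_that("gc3_lrt_correlation matches the covariance-ratio formula", {
  set.seed(5)
  x <- runif(30); y <- 0.4 * x + rnorm(30, sd = 0.2)
  res <- gc3_lrt_correlation(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  tstat <- r_hand * sqrt(28 / (1 - r_hand^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 28), tolerance = 1e-12)
  expect_equal(gc3_lrt_correlation(x, x)$r, 1)
  expect_error(gc3_lrt_correlation(x, rep(0.2, 30)), "zero variance")
  expect_error(gc3_lrt_correlation(x[1:2], y[1:2]), "at least 3")
})

test_that("run_scan applies the cascade, skips untestable genes, and is
           deterministic", {
  tr <- h_tree6()
  st <- simulate_study(8, 0.25, tr,
                       param_ranges = list(L = c(100, 150),
                                           omega2 = c(8, 8)),
                       seed = 31)
  # one gene lacking hippo: untestable for whippomorpha/hippo branches
  st$genes[[3]]$states["hippo", ] <- NA_integer_
  scan <- run_scan(st$genes, h_tree6(NULL), h_clades6(), n_starts = 2,
                   seed = 7)
  res <- scan$results
  smry <- scan$summary

  # skipped combinations are absent from results but logged
  expect_false(any(res$gene == "g0003" &
                   res$branch %in% c("whippomorpha", "hippo")))
  expect_true(any(res$gene == "g0003" & res$branch == "cetacea"))
  expect_true(any(grepl("g0003 SKIP foreground_untestable", scan$log)))

  # cascade monotonicity per branch
  expect_true(all(smry$n_datasets >= smry$n_raw_significant))
  expect_true(all(smry$n_raw_significant >= smry$n_filtered_significant))
  expect_true(all(smry$n_filtered_significant >= smry$n_fdr_significant))

  # q-values only on filtered raw-significant genes, within [0,1]
  has_q <- !is.na(res$q)
  expect_true(all(res$raw_significant[has_q] &
                  !res$aggregation_excluded[has_q]))
  expect_true(all(res$q[has_q] >= 0 & res$q[has_q] <= 1))
  # BH ordering consistency within each branch family
  for (b in unique(res$branch)) {
    rb <- res[res$branch == b & has_q, ]
    if (nrow(rb) > 1) {
      ord <- order(rb$p)
      expect_true(all(diff(rb$q[ord]) >= -1e-12))
    }
  }

  # determinism: identical reruns byte for byte
  scan2 <- run_scan(st$genes, h_tree6(NULL), h_clades6(), n_starts = 2,
                    seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scan(scan, d1); write_scan(scan2, d2)
  for (f in c("results.tsv", "summary.tsv", "config.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("clade definition files round-trip through JSON and TSV", {
  cl <- h_clades6()
  f <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(cl), f)
  expect_identical(lapply(read_clade_definitions(f), sort),
                   lapply(cl, sort))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(branch = rep(names(cl), lengths(cl)),
                    tip = unlist(cl))
  write.table(tab, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_clade_definitions(f2)
  expect_identical(lapply(got[names(cl)], sort), lapply(cl, sort))
})
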