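test_that("SNP-index arithmetic matches forced examples", {
  rec <- make_record(ref_high = 10L, alt_high = 30L,
                     ref_low = 30L, alt_low = 10L)
  pt <- snp_index(rec)
  expect_equal(pt$index_high, 0.75)
  expect_equal(pt$index_low, 0.25)
  expect_equal(pt$delta, 0.50)

  sym <- snp_index(make_record(ref_high = 7L, alt_high = 13L,
                               ref_low = 7L, alt_low = 13L))
  expect_equal(sym$delta, 0)
})

test_that("zero-depth sites are masked, not scored as zero", {
  rec <- rbind(make_record(pos = 100L, ref_high = 0L, alt_high = 0L),
               make_record(pos = 200L))
  pt <- snp_index(rec)
  expect_true(pt$masked[1])
  expect_true(is.na(pt$delta[1]))
  expect_false(pt$masked[2])
  # masked points never reach windows
  w <- sliding_window(pt, window_snps = 1)
  expect_equal(nrow(w), 1L)
  expect_equal(w$start_pos, 200L)
})

test_that("random records match a brute-force index recomputation", {
  set.seed(99)
  n <- 100L
  records <- make_records(n)
  records$ref_high <- rpois(n, 20); records$alt_high <- rpois(n, 25)
  records$ref_low <- rpois(n, 25); records$alt_low <- rpois(n, 20)
  pt <- snp_index(records)
  for (i in seq_len(n)) {
    dh <- records$ref_high[i] + records$alt_high[i]
    dl <- records$ref_low[i] + records$alt_low[i]
    if (dh == 0 || dl == 0) {
      expect_true(pt$masked[i])
    } else {
      expect_equal(pt$delta[i],
                   records$alt_high[i] / dh - records$alt_low[i] / dl)
    }
  }
  expect_true(all(abs(pt$delta) <= 1, na.rm = TRUE))
})

test_that("high-parent orientation flips homozygous-ref parent sites", {
  recs <- rbind(
    make_record(pos = 100L, gt_male = "G/G"),  # male carries alt -> as is
    make_record(pos = 200L, gt_male = "A/A"),  # male carries ref -> flip
    make_record(pos = 300L, gt_male = "A/G")   # het -> fallback, flagged
  )
  pt <- snp_index(recs, orientation = "high_parent", high_parent = "male")
  expect_equal(pt$index_high, c(0.75, 0.25, 0.75))
  expect_equal(pt$orientation_fallback, c(FALSE, FALSE, TRUE))
})

test_that("window means equal brute-force averages", {
  pts <- snp_index(make_records(10))
  pts$delta <- rep(0.2, 10)
  w <- sliding_window(pts, window_snps = 10)
  expect_equal(nrow(w), 1L)
  expect_equal(w$m, 0.2)
  expect_equal(w$n_snps, 10L)

  pts12 <- snp_index(make_records(12))
  expect_equal(nrow(sliding_window(pts12, 10, 1)), 3L)

  set.seed(3)
  pts200 <- snp_index(make_records(200))
  pts200$delta <- runif(200, -1, 1)
  w200 <- sliding_window(pts200, 10, 1)
  for (i in seq_len(nrow(w200))) {
    expect_equal(w200$m[i], mean(pts200$delta[i:(i + 9)]))
  }
  expect_true(all(abs(w200$m) <= 1))
  # midpoint is the median member position
  expect_equal(w200$midpoint_pos[1], median(pts200$pos[1:10]))
})

test_that("windows never span chromosomes and need enough points", {
  pts <- rbind(snp_index(make_records(15, chrom = "chr1")),
               snp_index(make_records(9, chrom = "chr2")))
  w <- sliding_window(pts, 10, 1)
  expect_equal(unique(w$chrom), "chr1")
  expect_equal(nrow(w), 6L)
})

test_that("null thresholds are monotone, deterministic, and vanish in the limit", {
  thr <- simulate_null_threshold(bulk_size = 30, depth = 45,
                                 n_replicates = 2000, seed = 42)
  expect_equal(thr$threshold, sort(thr$threshold))
  expect_true(all(diff(thr$threshold) >= 0))

  thr2 <- simulate_null_threshold(bulk_size = 30, depth = 45,
                                  n_replicates = 2000, seed = 42)
  expect_identical(thr$threshold, thr2$threshold)

  # law-of-large-numbers limit: huge bulks and depths -> thresholds near 0
  lim <- simulate_null_threshold(bulk_size = 5000, depth = 5000,
                                 n_replicates = 500, seed = 1)
  expect_lt(max(lim$threshold), 0.02)
})

test_that("simulated thresholds are self-consistent across seeds", {
  a <- simulate_null_threshold(bulk_size = 30, depth = 45,
                               n_replicates = 10000, confidence = 0.99,
                               seed = 7)
  b <- simulate_null_threshold(bulk_size = 30, depth = 45,
                               n_replicates = 10000, confidence = 0.99,
                               seed = 1234)
  # Monte-Carlo error at the 99th percentile of 10k draws is a few percent
  expect_lt(abs(a$threshold - b$threshold) / a$threshold, 0.10)
})

test_that("F2 nulls are wider than F1 pseudo-testcross nulls", {
  f1 <- simulate_null_threshold(design = "F1_pseudo_testcross",
                                n_replicates = 5000, confidence = 0.99,
                                seed = 2)
  f2 <- simulate_null_threshold(design = "F2", n_replicates = 5000,
                                confidence = 0.99, seed = 2)
  # F2 pool frequencies average over twice as many allele draws
  expect_lt(f2$threshold, f1$threshold)
})

test_that("empirical threshold is the nearest-rank percentile of |m|", {
  w <- make_window("chr1", 1:5, 1:5 * 100L, 1:5 * 100L + 50L,
                   m = rep(0.3, 5))
  expect_equal(empirical_threshold(w, 99)$threshold, 0.3)

  w2 <- make_window("chr1", 1:100, 1:100 * 100L, 1:100 * 100L + 50L,
                    m = (1:100) / 100)
  # nearest rank: ceiling(p * n)
  expect_equal(empirical_threshold(w2, 99)$threshold, 0.99)
  expect_equal(empirical_threshold(w2, 90)$threshold, 0.90)
  expect_equal(empirical_threshold(w2, 50)$threshold, 0.50)
  expect_error(empirical_threshold(w2[0, ], 99), "at least one")
})

test_that("nearest-rank percentile matches a hand enumeration", {
  x <- c(5, 1, 4, 2, 3)
  expect_equal(quantile_nearest_rank(x, 0.2), 1)
  expect_equal(quantile_nearest_rank(x, 0.21), 2)
  expect_equal(quantile_nearest_rank(x, 1), 5)
  expect_error(quantile_nearest_rank(numeric(0), 0.5), "empty")
})

test_that("bsa_scan assembles points, windows and thresholds coherently", {
  sim <- simulate_bsa_experiment(sim_config(seed = 21, n_markers = 300))
  res <- filter_snps(sim$records)
  scan <- bsa_scan(res$retained, n_replicates = 1000, seed = 21)
  expect_s3_class(scan, "bsa_scan")
  expect_equal(nrow(scan$points), nrow(res$retained))
  expect_equal(nrow(scan$windows),
               sum(!scan$points$masked) - scan$params$window_snps + 1L)
  expect_equal(nrow(scan$thresholds), 3L)
  expect_equal(scan$empirical$method, "empirical_percentile")
  expect_output(print(scan), "threshold")
  s <- summary(scan)
  expect_output(print(s), "windows")
  # plotting works headless
  pdf(NULL)
  plot(scan)
  dev.off()
})
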