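phred_chars <- function(q) intToUtf8(q + 33L)

test_that("read QC drops N-heavy and low-quality reads", {
  rule <- read_qc_rule()
  # 2 Ns in 10 bases = 20% > 10% -> dropped
  expect_false(read_qc_keep("ACGTNNACGT", phred_chars(rep(40, 10)), rule))
  # exactly 10% N is tolerated (rule is "more than 10%")
  expect_true(read_qc_keep("ACGTNACGTA", phred_chars(rep(40, 10)), rule))
  # all high quality -> kept
  expect_true(read_qc_keep("ACGTACGTAC", phred_chars(rep(40, 10)), rule))
  # 5 of 10 bases at Q <= 10 reaches the 50% bound -> dropped
  expect_false(read_qc_keep("ACGTACGTAC",
                            phred_chars(c(rep(10, 5), rep(40, 5))), rule))
  # 4 of 10 low-quality bases -> kept
  expect_true(read_qc_keep("ACGTACGTAC",
                           phred_chars(c(rep(2, 4), rep(40, 6))), rule))
  # malformed record rejected
  expect_error(read_qc_keep("ACGT", phred_chars(rep(40, 3))), "mismatch")
})

test_that("FASTQ filtering writes only the clean reads", {
  tmp <- withr::local_tempdir()
  fq <- file.path(tmp, "in.fastq")
  writeLines(c(
    "@good", "ACGTACGTAC", "+", strrep("I", 10),       # Q40 everywhere
    "@n_heavy", "ACGNNNACGT", "+", strrep("I", 10),    # 30% N
    "@low_qual", "ACGTACGTAC", "+",
    paste0(strrep("+", 5), strrep("I", 5))             # 50% at Q10
  ), fq)
  out <- file.path(tmp, "clean.fastq")
  res <- filter_reads(fq, out)
  expect_equal(res$kept, 1L)
  expect_equal(res$dropped, 2L)
  clean <- readLines(out)
  expect_equal(clean[1], "@good")
  expect_equal(length(clean), 4L)
})

test_that("each filter stage removes its planted violation", {
  r <- list(
    clean = make_record(pos = 100L),
    multi = make_record(pos = 200L, alt = "G,T"),
    low = make_record(pos = 300L, ref_high = 1L, alt_high = 2L),
    uniform = make_record(pos = 400L, ref_high = 10L, alt_high = 30L,
                          ref_low = 5L, alt_low = 15L),
    parent = make_record(pos = 500L, gt_male = "A/A", gt_female = "A/A",
                         alt_high = 20L),
    qualbad = make_record(pos = 600L, qual = 10)
  )
  records <- do.call(rbind, r)
  res <- filter_snps(records)
  expect_equal(res$ledger$total, 6L)
  expect_equal(res$ledger$removed_multiallelic, 1L)
  expect_equal(res$ledger$removed_low_support, 1L)
  expect_equal(res$ledger$removed_uniform_pools, 1L)
  expect_equal(res$ledger$removed_parent_inconsistent, 1L)
  expect_equal(res$ledger$removed_quality, 1L)
  expect_equal(res$ledger$retained, 1L)
  expect_equal(res$retained$pos, 100L)
})

test_that("thresholds are applied exactly as printed", {
  base <- 100L
  rec <- function(i, ...) make_record(pos = base + i * 10L, ...)
  records <- rbind(
    rec(1, qual = 30),    # QUAL < 30 removes; 30 passes
    rec(2, qual = 29.99),
    rec(3, qd = 2.0), rec(4, qd = 1.99),
    rec(5, fs = 60.0), rec(6, fs = 60.01),
    rec(7, mq = 40.0), rec(8, mq = 39.99),
    rec(9, ref_high = 2L, alt_high = 2L),  # depth 4 passes "< 4"
    rec(10, ref_high = 2L, alt_high = 1L)  # depth 3 fails
  )
  res <- filter_snps(records)
  expect_equal(res$ledger$removed_quality, 4L)
  expect_equal(res$ledger$removed_low_support, 1L)
  expect_equal(res$ledger$retained, 5L)
})

test_that("ledger conserves counts on random planted sets", {
  set.seed(101)
  n <- 1000L
  records <- make_records(n)
  # plant independent violations at random
  pick <- function(p) runif(n) < p
  i_multi <- pick(0.05)
  records$alt[i_multi] <- "G,T"
  i_low <- pick(0.08)
  records$ref_high[i_low] <- 1L
  records$alt_high[i_low] <- 1L
  i_unif <- pick(0.06)
  records$ref_high[i_unif] <- 12L; records$alt_high[i_unif] <- 4L
  records$ref_low[i_unif] <- 12L; records$alt_low[i_unif] <- 4L
  i_par <- pick(0.04)
  records$gt_male[i_par] <- "A/A"; records$gt_female[i_par] <- "A/A"
  i_qual <- pick(0.07)
  records$mq[i_qual] <- 20

  res <- filter_snps(records)
  led <- res$ledger

  # conservation identity holds by construction
  expect_equal(led$total,
               led$retained + led$removed_multiallelic +
                 led$removed_low_support + led$removed_uniform_pools +
                 led$removed_parent_inconsistent + led$removed_quality)

  # per-stage counts match an independent per-record oracle with
  # first-failing-stage attribution
  oracle <- oracle_filter_flags(records)
  first <- apply(oracle, 1, function(f) {
    hit <- which(f)
    if (length(hit)) colnames(oracle)[hit[1]] else NA_character_
  })
  expect_equal(led$removed_multiallelic, sum(first == "multiallelic",
                                             na.rm = TRUE))
  expect_equal(led$removed_low_support, sum(first == "low_support",
                                            na.rm = TRUE))
  expect_equal(led$removed_uniform_pools, sum(first == "uniform_pools",
                                              na.rm = TRUE))
  expect_equal(led$removed_parent_inconsistent,
               sum(first == "parent_inconsistent", na.rm = TRUE))
  expect_equal(led$removed_quality, sum(first == "quality", na.rm = TRUE))
  expect_equal(led$retained, sum(is.na(first)))
})

test_that("filtering is idempotent and stage order only moves attribution", {
  set.seed(55)
  records <- make_records(300)
  records$alt[runif(300) < 0.1] <- "G,T"
  records$mq[runif(300) < 0.1] <- 10
  shallow <- runif(300) < 0.1
  records$ref_high[shallow] <- 0L
  records$alt_high[shallow] <- 2L

  res <- filter_snps(records)
  again <- filter_snps(res$retained)
  expect_equal(again$ledger$retained, nrow(res$retained))
  expect_equal(again$ledger$total - again$ledger$retained, 0L)

  permuted <- filter_snps(records, stage_order = c(
    "quality", "parent_inconsistent", "uniform_pools", "low_support",
    "multiallelic"))
  expect_equal(permuted$retained, res$retained)
})

test_that("unsorted input and missing columns are rejected", {
  records <- rbind(make_record(pos = 200L), make_record(pos = 100L))
  expect_error(filter_snps(records), "sorted")
  expect_error(filter_snps(make_record()[, -3]), "missing columns")
})

test_that("missing parent genotypes follow the strictness flag", {
  rec <- make_record(gt_male = "./.", gt_female = "./.")
  strict <- filter_snps(rec, strict_parents = TRUE)
  expect_equal(strict$ledger$removed_parent_inconsistent, 1L)
  lax <- filter_snps(rec, strict_parents = FALSE)
  expect_equal(lax$ledger$retained, 1L)
})

test_that("published-table shape combines the last two stages", {
  led <- slafbsa:::filter_ledger(
    total = 100L,
    removed = c(multiallelic = 10L, low_support = 20L,
                uniform_pools = 5L, parent_inconsistent = 12L,
                quality = 3L),
    retained = 50L)
  t1 <- ledger_table1(led)
  expect_equal(t1$filtered_by_parent, 15L)
  expect_equal(t1$high_quality_snp, 50L)
  # constructor enforces conservation
  expect_error(slafbsa:::filter_ledger(
    total = 100L,
    removed = c(multiallelic = 1L, low_support = 1L, uniform_pools = 1L,
                parent_inconsistent = 1L, quality = 1L),
    retained = 50L), "conservation")
})

test_that("SNP records survive a VCF round trip", {
  sim <- simulate_bsa_experiment(sim_config(seed = 13, n_markers = 120))
  tmp <- withr::local_tempdir()
  vcf <- file.path(tmp, "test.vcf")
  slafbsa:::write_sim_vcf(sim$records, vcf)
  back <- read_snp_vcf(vcf)
  expect_equal(back$chrom, sim$records$chrom)
  expect_equal(back$pos, sim$records$pos)
  expect_equal(back$ref, sim$records$ref)
  expect_equal(back$gt_male, sim$records$gt_male)
  expect_equal(back$gt_female, sim$records$gt_female)
  expect_equal(back$ref_high, sim$records$ref_high)
  expect_equal(back$alt_low, sim$records$alt_low)
  expect_equal(back$qd, sim$records$qd, tolerance = 1e-2)

  tsv <- file.path(tmp, "test.tsv")
  write_snp_tsv(sim$records, tsv)
  back2 <- read_snp_tsv(tsv)
  expect_equal(back2$pos, sim$records$pos)
  expect_equal(back2$qual, sim$records$qual, tolerance = 1e-6)
})
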