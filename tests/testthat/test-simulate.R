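test_that("zero recombination transmits intact parental haplotypes", {
  cfg <- sim_config(seed = 8, n_markers = 60, n_plants = 80,
                    recomb_rate = 0)
  sim <- simulate_parents_and_f1(cfg)
  # with r = 0 each gamete is one whole parental haplotype, so every
  # plant's dose vector must be one of the four haplotype combinations
  markers <- sim$markers
  ref <- markers$ref
  gm <- strsplit(markers$gt_male, "/")
  gf <- strsplit(markers$gt_female, "/")
  hapm <- cbind(vapply(gm, `[`, character(1), 1) != ref,
                vapply(gm, `[`, character(1), 2) != ref)
  hapf <- cbind(vapply(gf, `[`, character(1), 1) != ref,
                vapply(gf, `[`, character(1), 2) != ref)
  combos <- list()
  for (a in 1:2) for (b in 1:2) {
    combos[[length(combos) + 1L]] <- hapm[, a] + hapf[, b]
  }
  for (i in seq_len(nrow(sim$dose))) {
    match_any <- any(vapply(combos, function(cc) {
      all(sim$dose[i, ] == cc)
    }, logical(1)))
    expect_true(match_any)
  }
})

test_that("pseudo-testcross markers segregate 1:1", {
  cfg <- sim_config(seed = 9, n_markers = 40, n_plants = 10000,
                    het_male = 1, het_female = 0)
  sim <- simulate_parents_and_f1(cfg)
  ci <- sim$truth$causal_index
  # male het, female hom-ref: doses are 0/1, expect frequency 1/2
  p_hat <- mean(sim$dose[, ci])
  se <- sqrt(0.25 / nrow(sim$dose))
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("simulation is deterministic in the seed", {
  a <- simulate_bsa_experiment(sim_config(seed = 77, n_markers = 100))
  b <- simulate_bsa_experiment(sim_config(seed = 77, n_markers = 100))
  expect_identical(a$dose, b$dose)
  expect_identical(a$records, b$records)
  expect_identical(a$trait, b$trait)
})

test_that("noise-free traits collapse onto dose classes", {
  cfg <- sim_config(seed = 5, n_markers = 50, trait_sd = 0,
                    causal_effect = 10)
  sim <- simulate_parents_and_f1(cfg)
  y <- simulate_trait(sim$dose[, sim$truth$causal_index], cfg)
  expect_lte(length(unique(y)), 3L)
  expect_true(all(unique(y) %in% (28 + 10 * (0:2))))
})

test_that("null effect gives near-zero expected delta at the causal site", {
  cfg <- sim_config(seed = 6, n_markers = 80, causal_effect = 0)
  sim <- simulate_bsa_experiment(cfg)
  # bulks are random with respect to genotype: expected delta is 0, and
  # the realized value is a mean over 30+30 plants
  expect_lt(abs(sim$truth$expected_delta_causal), 0.25)
})

test_that("locus heritability matches the analytic variance ratio", {
  cfg <- sim_config(seed = 10, n_markers = 30, n_plants = 5000,
                    het_male = 1, het_female = 0,
                    causal_effect = 5, trait_sd = 2.5)
  sim <- simulate_parents_and_f1(cfg)
  dose <- sim$dose[, sim$truth$causal_index]
  y <- simulate_trait(dose, cfg)
  # doses are Bernoulli(1/2): genetic variance = effect^2 / 4
  h2_expected <- (25 / 4) / (25 / 4 + 2.5^2)
  h2_realized <- var(cfg$causal_effect * dose) / var(y)
  expect_equal(h2_realized, h2_expected, tolerance = 0.1)
})

test_that("pooled read sampling respects frequency and depth models", {
  cfg <- sim_config(seed = 12, n_markers = 1000, n_plants = 60,
                    bulk_size = 30, seq_error = 0)
  sim <- simulate_parents_and_f1(cfg)
  # force fixation: every plant homozygous alt at every marker
  sim$dose[] <- 2L
  rec <- simulate_pooled_reads(sim, list(high_idx = 1:30, low_idx = 31:60),
                               cfg)
  expect_true(all(rec$ref_high == 0L))
  expect_true(all(rec$ref_low == 0L))

  # Poisson depth oracle: mean within 3 SE of bulk_depth_mean
  depth <- rec$ref_high + rec$alt_high
  se <- sqrt(cfg$bulk_depth_mean / nrow(rec))
  expect_lt(abs(mean(depth) - cfg$bulk_depth_mean), 3 * se)
})

test_that("half-frequency pools converge to index 0.5 at high depth", {
  cfg <- sim_config(seed = 14, n_markers = 400, n_plants = 60,
                    bulk_size = 30, bulk_depth_mean = 4000, seq_error = 0)
  sim <- simulate_parents_and_f1(cfg)
  sim$dose[] <- 1L   # every plant heterozygous: pool frequency 1/2
  rec <- simulate_pooled_reads(sim, list(high_idx = 1:30, low_idx = 31:60),
                               cfg)
  idx <- rec$alt_high / (rec$ref_high + rec$alt_high)
  expect_equal(mean(idx), 0.5, tolerance = 0.005)
})

test_that("planted quality violations are exactly the filtered ones", {
  cfg <- sim_config(seed = 15, n_markers = 500, violation_fraction = 0.1)
  sim <- simulate_bsa_experiment(cfg)
  planted <- attr(sim$records, "planted_violations")
  bad <- with(sim$records, qual < 30 | qd < 2 | fs > 60 | mq < 40)
  expect_equal(bad, planted)
})

test_that("fixtures round-trip through every reader", {
  sim <- simulate_bsa_experiment(sim_config(seed = 33, n_markers = 150))
  tmp <- withr::local_tempdir()
  out <- file.path(tmp, "fix")
  paths <- emit_fixtures(sim, out)
  expect_true(all(file.exists(paths)))
  # refuses to clobber
  expect_error(emit_fixtures(sim, out), "not empty")

  # digest fixture: planted in-window fragments are found exactly
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  fr <- digest_genome(paths["fasta"], c("RsaI", "HaeIII"))
  tags <- select_tags(fr, c(314, 364), "internal_only")
  planted_in_window <- sum(truth$digest_fixture$fragment_lengths >= 314 &
                             truth$digest_fixture$fragment_lengths <= 364)
  expect_equal(nrow(tags), planted_in_window)

  # truth json round trip
  expect_equal(truth$causal_pos, sim$truth$causal_pos)
  expect_equal(truth$expected_delta_causal,
               sim$truth$expected_delta_causal)
  expect_equal(truth$high_ids, sim$bulks$high_ids)

  # VCF and phenotype readers reproduce the in-memory objects
  rec <- read_snp_vcf(paths["vcf"])
  expect_equal(rec$pos, sim$records$pos)
  expect_equal(rec$alt_high, sim$records$alt_high)
  ph <- read_phenotypes(paths["phenotypes"])
  expect_equal(ph$fiber_content,
               sim$phenotypes$fiber_content, tolerance = 1e-6)
  genes <- read_gene_models(paths["gff"])
  expect_gt(nrow(genes), 0L)
  expect_true(all(genes$start < genes$end))
})
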