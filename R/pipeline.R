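#' Default pipeline configuration
#'
#' The full parameter set of a pipeline run, with defaults matching the
#' published study design: RsaI+HaeIII digestion with a 314-364 bp
#' selection window, bulks of 30, read support >= 4, hard filters
#' QUAL >= 30 / QD >= 2.0 / FS <= 60.0 / MQ >= 40.0, a 10-SNP sliding
#' window, 10,000 null replications and confidence levels 0.90/0.95/0.99.
#'
#' @param ... overrides for any default field (input paths `vcf`,
#'   `phenotypes`, `gff`, `fasta`, the `out_dir`, or any parameter below).
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    vcf = NULL, snp_tsv = NULL, phenotypes = NULL, gff = NULL,
    fasta = NULL, out_dir = "slafbsa_run",
    enzymes = c("RsaI", "HaeIII"), size_min = 314, size_max = 364,
    flank_rule = "internal_only",
    parents = c("R01", "R02"), bulk_samples = c("aa", "ab"),
    bulk_size = 30, min_support = 4,
    qual_min = 30, qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
    window_snps = 10, step_snps = 1, n_replicates = 10000,
    design = "F1_pseudo_testcross",
    confidence = c(0.90, 0.95, 0.99),
    empirical_percentile = 99,
    max_gap_snps = 0,
    seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown run_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Flat key-value YAML; keys are [run_config()] fields.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes digest (if a FASTA is configured), bulk selection (if a
#' phenotype table is configured), SNP filtering, the SNP-index scan, and
#' region calling/annotation in order, writing every stage's outputs under
#' `out_dir` and recording them in a manifest with md5 content hashes. Any
#' stage failure aborts with the stage name. The same configuration and
#' seed always reproduce byte-identical outputs.
#'
#' @param config a [run_config()] (or a YAML path).
#' @return invisibly, a list with `manifest` (data.frame of `file`, `md5`),
#'   `ledger`, `scan`, `regions`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  log_lines <- c(sprintf("slafbsa pipeline run, seed %s", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  need_file <- function(path, what) {
    if (!is.null(path) && !file.exists(path)) {
      stop(sprintf("%s file not found: %s", what, path))
    }
    path
  }

  # --- digest ---------------------------------------------------------
  if (!is.null(config$fasta)) {
    stage("digest", {
      need_file(config$fasta, "FASTA")
      frags <- digest_genome(config$fasta, config$enzymes)
      tags <- select_tags(frags, c(config$size_min, config$size_max),
                          config$flank_rule)
      genes <- if (!is.null(config$gff)) {
        read_gene_models(need_file(config$gff, "GFF3"))
      }
      mask <- softmask_intervals(config$fasta)
      report <- score_enzyme_combination(
        frags, gene_intervals = genes,
        mask = if (nrow(mask)) mask else NULL,
        size_window = c(config$size_min, config$size_max),
        flank_rule = config$flank_rule)
      prefix <- file.path(config$out_dir, "digest")
      bed <- write_tags_bed(tags, paste0(prefix, "_tags.bed"))
      reps <- write_digest_report(report, prefix)
      outputs <- c(outputs, bed, reps)
      log_lines <- c(log_lines, sprintf(
        "digest: %d fragments, %d tags in %d-%d bp (%s)",
        report$n_fragments, report$n_tags_in_window,
        config$size_min, config$size_max, config$flank_rule))
    })
  }

  # --- bulks ----------------------------------------------------------
  bulks <- NULL
  if (!is.null(config$phenotypes)) {
    stage("bulks", {
      need_file(config$phenotypes, "phenotype")
      phen <- read_phenotypes(config$phenotypes)
      bulks <- select_bulks(phen, bulk_size = config$bulk_size)
      path <- write_bulks(bulks, file.path(config$out_dir, "bulks.tsv"))
      outputs <- c(outputs, path)
      log_lines <- c(log_lines, sprintf(
        "bulks: %d plants, high %.2f-%.2f, low %.2f-%.2f",
        nrow(phen), bulks$high_range[1], bulks$high_range[2],
        bulks$low_range[1], bulks$low_range[2]))
    })
  }

  # --- filter ---------------------------------------------------------
  if (is.null(config$vcf) && is.null(config$snp_tsv)) {
    stop("stage 'filter' failed: no VCF or SNP TSV configured",
         call. = FALSE)
  }
  filt <- stage("filter", {
    records <- if (!is.null(config$vcf)) {
      read_snp_vcf(need_file(config$vcf, "VCF"),
                   parents = config$parents, bulks = config$bulk_samples)
    } else {
      read_snp_tsv(need_file(config$snp_tsv, "SNP TSV"))
    }
    res <- filter_snps(records, min_support = config$min_support,
                       qual_min = config$qual_min, qd_min = config$qd_min,
                       fs_max = config$fs_max, mq_min = config$mq_min)
    retained_path <- write_snp_tsv(
      res$retained, file.path(config$out_dir, "snps_filtered.tsv"))
    ledger_path <- file.path(config$out_dir, "filter_ledger.tsv")
    utils::write.table(ledger_table1(res$ledger), ledger_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, retained_path, ledger_path)
    log_lines <- c(log_lines, sprintf(
      "filter: %d total -> %d retained", res$ledger$total,
      res$ledger$retained))
    res
  })

  # --- scan -----------------------------------------------------------
  scan <- stage("scan", {
    s <- bsa_scan(filt$retained, window_snps = config$window_snps,
                  step_snps = config$step_snps,
                  design = config$design, bulk_size = config$bulk_size,
                  n_replicates = config$n_replicates,
                  confidence = config$confidence,
                  empirical_percentile = config$empirical_percentile,
                  seed = config$seed)
    paths <- write_scan(s, file.path(config$out_dir, "scan"))
    outputs <- c(outputs, paths)
    log_lines <- c(log_lines, sprintf(
      "scan: %d windows; |m| threshold @%.2f = %.4f",
      nrow(s$windows), max(s$thresholds$confidence),
      s$thresholds$threshold[which.max(s$thresholds$confidence)]))
    s
  })

  # --- regions --------------------------------------------------------
  regions <- stage("regions", {
    r <- call_regions(scan, scan$thresholds,
                      max_gap_snps = config$max_gap_snps)
    if (!is.null(config$gff) && nrow(r)) {
      r <- annotate_regions(r, read_gene_models(config$gff))
    }
    paths <- write_regions(r, file.path(config$out_dir, "candidate"))
    outputs <- c(outputs, paths)
    log_lines <- c(log_lines, sprintf(
      "regions: %d region(s), total %.3f Mb",
      nrow(r), if (nrow(r)) sum(r$length_mb) else 0))
    r
  })

  log_path <- file.path(config$out_dir, "pipeline.log")
  writeLines(log_lines, log_path)
  outputs <- c(outputs, log_path)
  manifest <- data.frame(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)),
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(config$out_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(manifest = manifest, ledger = filt$ledger, scan = scan,
                 regions = regions))
}
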