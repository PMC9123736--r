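#' Read-level QC rule
#'
#' The two read-quality rules applied to raw reads before alignment: a read
#' is discarded if more than `max_n_fraction` of its bases are undetermined
#' (N), or if bases at or below phred `low_qual_threshold` account for at
#' least `max_low_qual_fraction` of the read. Defaults: > 10% N, and Q <= 10
#' bases making up >= 50% of the read (the boundary is taken inclusively,
#' the conservative reading).
#'
#' @param max_n_fraction maximum tolerated N fraction (exclusive bound).
#' @param low_qual_threshold phred score counted as low quality (<=).
#' @param max_low_qual_fraction low-quality fraction at which the read is
#'   dropped (inclusive bound).
#' @return a list of class `read_qc_rule`.
#' @export
read_qc_rule <- function(max_n_fraction = 0.10, low_qual_threshold = 10,
                         max_low_qual_fraction = 0.50) {
  stopifnot(max_n_fraction > 0, max_n_fraction <= 1,
            max_low_qual_fraction > 0, max_low_qual_fraction <= 1)
  structure(list(max_n_fraction = max_n_fraction,
                 low_qual_threshold = low_qual_threshold,
                 max_low_qual_fraction = max_low_qual_fraction),
            class = "read_qc_rule")
}

# Per-read keep/drop decision on raw sequence + phred+33 quality strings.
read_qc_keep <- function(seqs, quals, rule = read_qc_rule()) {
  stopifnot(length(seqs) == length(quals))
  vapply(seq_along(seqs), function(i) {
    s <- toupper(seqs[i]); q <- quals[i]
    n <- nchar(s)
    if (nchar(q) != n) stop(sprintf("read %d: seq/qual length mismatch", i))
    if (n == 0L) return(FALSE)
    n_frac <- lengths(regmatches(s, gregexpr("N", s))) / n
    phred <- utf8ToInt(q) - 33L
    lq_frac <- mean(phred <= rule$low_qual_threshold)
    n_frac <= rule$max_n_fraction && lq_frac < rule$max_low_qual_fraction
  }, logical(1))
}

#' Filter a FASTQ file by read quality
#'
#' Drops reads with too many undetermined bases or too many low-quality
#' bases (see [read_qc_rule()]); phred+33 qualities are assumed.
#'
#' @param fastq input FASTQ path (gzip accepted).
#' @param out output FASTQ path for the clean reads, or `NULL` to skip
#'   writing.
#' @param rule a [read_qc_rule()].
#' @return a list with `kept`, `dropped` counts and, when `out` is given,
#'   the output path.
#' @export
filter_reads <- function(fastq, out = NULL, rule = read_qc_rule()) {
  # the reader warns when dropping FASTQ metadata columns; irrelevant here
  reads <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(fastq))
  seqs <- as.character(reads)
  quals <- as.character(Biostrings::quality(reads))
  keep <- read_qc_keep(seqs, quals, rule)
  if (!is.null(out)) {
    Biostrings::writeQualityScaledXStringSet(reads[keep], out)
  }
  list(kept = sum(keep), dropped = sum(!keep), out = out)
}

snp_required_cols <- c("chrom", "pos", "ref", "alt", "gt_male", "gt_female",
                       "ref_high", "alt_high", "ref_low", "alt_low",
                       "qual", "qd", "fs", "mq")

validate_snp_records <- function(records) {
  missing <- setdiff(snp_required_cols, names(records))
  if (length(missing)) {
    stop("SNP records missing columns: ", paste(missing, collapse = ", "))
  }
  depths <- records[c("ref_high", "alt_high", "ref_low", "alt_low")]
  if (any(unlist(depths) < 0, na.rm = TRUE)) stop("negative allele depth")
  if (!identical(order(records$chrom, records$pos),
                 seq_len(nrow(records)))) {
    stop("SNP records must be sorted by (chrom, pos)")
  }
  invisible(records)
}

split_gt <- function(gt) {
  strsplit(ifelse(is.na(gt) | gt %in% c(".", "./.", ".|."), "", gt), "[/|]")
}

# Per-record rule evaluation. Each rule is defined independently of the
# others so that stage order only changes attribution, never the retained
# set.
snp_rule_flags <- function(records, min_support = 4, qual_min = 30,
                           qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
                           support_mode = c("per_bulk", "total"),
                           strict_parents = TRUE) {
  support_mode <- match.arg(support_mode)
  n <- nrow(records)
  multiallelic <- grepl(",", records$alt)

  dh <- records$ref_high + records$alt_high
  dl <- records$ref_low + records$alt_low
  low_support <- if (support_mode == "per_bulk") {
    dh < min_support | dl < min_support
  } else {
    (dh + dl) < min_support
  }

  idx_h <- ifelse(dh > 0, records$alt_high / dh, NA_real_)
  idx_l <- ifelse(dl > 0, records$alt_low / dl, NA_real_)
  major_h <- ifelse(records$alt_high > records$ref_high, "alt", "ref")
  major_l <- ifelse(records$alt_low > records$ref_low, "alt", "ref")
  uniform_pools <- !is.na(idx_h) & !is.na(idx_l) &
    major_h == major_l & idx_h == idx_l

  gts_m <- split_gt(records$gt_male)
  gts_f <- split_gt(records$gt_female)
  parent_inconsistent <- vapply(seq_len(n), function(i) {
    parental <- unique(c(gts_m[[i]], gts_f[[i]]))
    parental <- parental[parental != "" & parental != "."]
    if (length(parental) == 0L) return(strict_parents)
    observed <- character(0)
    if (records$ref_high[i] >= min_support ||
        records$ref_low[i] >= min_support) {
      observed <- c(observed, records$ref[i])
    }
    alts <- strsplit(records$alt[i], ",")[[1]]
    # biallelic path: first alt carries the bulk alt depth
    if (records$alt_high[i] >= min_support ||
        records$alt_low[i] >= min_support) {
      observed <- c(observed, alts[1])
    }
    !all(observed %in% parental)
  }, logical(1))

  quality <- records$qual < qual_min | records$qd < qd_min |
    records$fs > fs_max | records$mq < mq_min
  quality[is.na(quality)] <- TRUE

  data.frame(multiallelic = multiallelic, low_support = low_support,
             uniform_pools = uniform_pools,
             parent_inconsistent = parent_inconsistent, quality = quality)
}

FILTER_STAGES <- c("multiallelic", "low_support", "uniform_pools",
                   "parent_inconsistent", "quality")

#' Five-stage hard-filter cascade for pooled SNP calls
#'
#' Applies, in order: (1) multiallelic sites (more than one alternate
#' allele); (2) low read support (either bulk's total depth below
#' `min_support`; set `support_mode = "total"` to threshold the summed
#' depth instead); (3) genotypic uniformity between the two pools (same
#' major allele and identical SNP-index in both bulks); (4) parental
#' inconsistency (an allele supported by at least `min_support` reads in a
#' bulk that is absent from both parent genotypes); (5) caller quality
#' (`QUAL < qual_min`, `QD < qd_min`, `FS > fs_max` or `MQ < mq_min`). Every
#' removed site is attributed to the first stage it fails, so the ledger
#' satisfies `total == retained + sum(removed)` by construction. Permuting
#' the stage order redistributes the per-stage counts but never changes the
#' retained set.
#'
#' @param records SNP record data.frame (see [read_snp_vcf()] /
#'   [read_snp_tsv()] for the columns), sorted by `(chrom, pos)`.
#' @param min_support minimum read support (default 4).
#' @param qual_min,qd_min,fs_max,mq_min hard-filter thresholds
#'   (defaults 30, 2.0, 60.0, 40.0, applied exactly as stated:
#'   `<`, `<`, `>`, `<`).
#' @param support_mode `"per_bulk"` (default) or `"total"`.
#' @param strict_parents if `TRUE` (default) records with both parent
#'   genotypes missing are routed to the parental-inconsistency stage;
#'   if `FALSE` they pass that stage.
#' @param stage_order permutation of the five stage names; affects only the
#'   attribution of removals, not the retained set.
#' @return a list with `retained` (the surviving records) and `ledger`
#'   (class `filter_ledger`).
#' @export
filter_snps <- function(records, min_support = 4, qual_min = 30,
                        qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
                        support_mode = "per_bulk", strict_parents = TRUE,
                        stage_order = FILTER_STAGES) {
  validate_snp_records(records)
  stopifnot(setequal(stage_order, FILTER_STAGES))
  flags <- snp_rule_flags(records, min_support, qual_min, qd_min, fs_max,
                          mq_min, support_mode, strict_parents)
  n <- nrow(records)
  first_fail <- rep(NA_character_, n)
  for (stage in rev(stage_order)) {
    first_fail[flags[[stage]]] <- stage
  }
  retained <- records[is.na(first_fail), , drop = FALSE]
  rownames(retained) <- NULL
  counts <- vapply(FILTER_STAGES, function(s) sum(first_fail == s,
                                                  na.rm = TRUE), integer(1))
  ledger <- filter_ledger(total = n, removed = counts,
                          retained = nrow(retained))
  list(retained = retained, ledger = ledger)
}

filter_ledger <- function(total, removed, retained) {
  stopifnot(identical(sort(names(removed)), sort(FILTER_STAGES)))
  if (total != retained + sum(removed)) {
    stop("ledger conservation violated: total != retained + sum(removed)")
  }
  structure(list(
    total = total,
    removed_multiallelic = unname(removed["multiallelic"]),
    removed_low_support = unname(removed["low_support"]),
    removed_uniform_pools = unname(removed["uniform_pools"]),
    removed_parent_inconsistent = unname(removed["parent_inconsistent"]),
    removed_quality = unname(removed["quality"]),
    retained = retained
  ), class = "filter_ledger")
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("SNP filter ledger\n")
  cat(sprintf("  total:               %d\n", x$total))
  cat(sprintf("  multiallelic:        %d\n", x$removed_multiallelic))
  cat(sprintf("  low read support:    %d\n", x$removed_low_support))
  cat(sprintf("  uniform pools:       %d\n", x$removed_uniform_pools))
  cat(sprintf("  parent-inconsistent: %d\n", x$removed_parent_inconsistent))
  cat(sprintf("  quality filters:     %d\n", x$removed_quality))
  cat(sprintf("  retained:            %d\n", x$retained))
  invisible(x)
}

#' Ledger in published-table shape
#'
#' One-row data.frame with the parental-inconsistency and quality stages
#' reported as a single combined column ("filtered by the parent"), the
#' shape used in the study's filtering statistics table.
#'
#' @param ledger a `filter_ledger`.
#' @return a one-row data.frame.
#' @export
ledger_table1 <- function(ledger) {
  stopifnot(inherits(ledger, "filter_ledger"))
  data.frame(
    total_snp = ledger$total,
    multiple_alleles = ledger$removed_multiallelic,
    read_support_lt4 = ledger$removed_low_support,
    pool_genotypic_uniformity = ledger$removed_uniform_pools,
    filtered_by_parent = ledger$removed_parent_inconsistent +
      ledger$removed_quality,
    high_quality_snp = ledger$retained
  )
}

#' Read pooled SNP records from a VCF
#'
#' Expects four samples (two parents, two bulks) with per-sample `AD`
#' allelic depths and `GT` genotypes, and INFO keys `QD`, `FS`, `MQ`.
#' Genotypes are translated to allele letters; bulk `AD` fields provide the
#' ref/alt depths. Multiallelic records keep their comma-separated ALT and
#' the depth of the first alternate allele (they are removed by the filter
#' cascade anyway, but must be counted).
#'
#' @param path VCF file (plain or bgzipped).
#' @param parents length-2 character: sample names of the male and female
#'   parent, in that order.
#' @param bulks length-2 character: sample names of the high and low bulk.
#' @return SNP record data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gt_male`, `gt_female`, `ref_high`, `alt_high`, `ref_low`, `alt_low`,
#'   `qual`, `qd`, `fs`, `mq`, sorted by `(chrom, pos)`.
#' @export
read_snp_vcf <- function(path, parents = c("R01", "R02"),
                         bulks = c("aa", "ab")) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  samples <- colnames(vcf@gt)[-1]
  need <- c(parents, bulks)
  if (!all(need %in% samples)) {
    stop("VCF is missing samples: ",
         paste(setdiff(need, samples), collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  qd <- as.numeric(vcfR::extract.info(vcf, element = "QD"))
  fs <- as.numeric(vcfR::extract.info(vcf, element = "FS"))
  mq <- as.numeric(vcfR::extract.info(vcf, element = "MQ"))

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt1 <- vapply(strsplit(alt, ","), `[`, character(1), 1L)
  gt_letters <- function(g, i) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return("./.")
    codes <- as.integer(strsplit(g, "[/|]")[[1]])
    alleles <- c(ref[i], strsplit(alt[i], ",")[[1]])
    paste(alleles[codes + 1L], collapse = "/")
  }
  ad_pair <- function(a) {
    if (is.na(a)) return(c(0L, 0L))
    d <- as.integer(strsplit(a, ",")[[1]])
    c(d[1], if (length(d) >= 2L) d[2] else 0L)
  }
  n <- nrow(fix)
  gm <- vapply(seq_len(n), function(i) gt_letters(gt[i, parents[1]], i),
               character(1))
  gf <- vapply(seq_len(n), function(i) gt_letters(gt[i, parents[2]], i),
               character(1))
  ad_h <- vapply(ad[, bulks[1]], ad_pair, integer(2))
  ad_l <- vapply(ad[, bulks[2]], ad_pair, integer(2))
  out <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt,
    gt_male = gm, gt_female = gf,
    ref_high = ad_h[1, ], alt_high = ad_h[2, ],
    ref_low = ad_l[1, ], alt_low = ad_l[2, ],
    qual = as.numeric(fix[, "QUAL"]),
    qd = qd, fs = fs, mq = mq,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out$alt1 <- NULL
  out
}

#' Read/write SNP records as headered TSV
#'
#' The TSV mirror of the VCF representation (columns as in
#' [read_snp_vcf()]).
#'
#' @param path file path.
#' @return [read_snp_tsv()]: the record data.frame; [write_snp_tsv()]:
#'   `path`, invisibly.
#' @export
read_snp_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(chrom = "character",
                                            ref = "character",
                                            alt = "character"))
  validate_snp_records(df)
  df
}

#' @rdname read_snp_tsv
#' @param records SNP record data.frame.
#' @export
write_snp_tsv <- function(records, path) {
  utils::write.table(records[snp_required_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
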