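# Shared fixtures and independent oracles for the test suite.

# One SNP record with sensible defaults; override any field.
make_record <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                        gt_male = "A/G", gt_female = "A/A",
                        ref_high = 10L, alt_high = 30L,
                        ref_low = 30L, alt_low = 10L,
                        qual = 500, qd = 25, fs = 2, mq = 58) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             gt_male = gt_male, gt_female = gt_female,
             ref_high = ref_high, alt_high = alt_high,
             ref_low = ref_low, alt_low = alt_low,
             qual = qual, qd = qd, fs = fs, mq = mq,
             stringsAsFactors = FALSE)
}

# n clean records at distinct positions.
make_records <- function(n, chrom = "chr1") {
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_record(chrom = chrom, pos = i * 100L)
  }))
}

# Independent cut-site oracle: plain regex scan with lookahead so that
# overlapping occurrences are counted too.
oracle_cut_sites <- function(seq, motif, offset) {
  seq <- toupper(seq)
  hits <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L + offset
}

# Independent digestion oracle: partition [0, n) at the sorted union of
# per-enzyme cut positions.
oracle_fragment_bounds <- function(seq, motifs, offsets) {
  n <- nchar(seq)
  cuts <- sort(unique(unlist(mapply(oracle_cut_sites,
                                    motif = motifs, offset = offsets,
                                    MoreArgs = list(seq = seq),
                                    SIMPLIFY = FALSE))))
  cuts <- cuts[cuts > 0 & cuts < n]
  cbind(start = c(0L, cuts), end = c(cuts, n))
}

# Independent per-record filter-rule oracle (deliberately naive loop).
oracle_filter_flags <- function(records, min_support = 4) {
  t(vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    multi <- grepl(",", r$alt)
    dh <- r$ref_high + r$alt_high
    dl <- r$ref_low + r$alt_low
    low <- dh < min_support || dl < min_support
    ih <- if (dh > 0) r$alt_high / dh else NA
    il <- if (dl > 0) r$alt_low / dl else NA
    maj_h <- if (r$alt_high > r$ref_high) "alt" else "ref"
    maj_l <- if (r$alt_low > r$ref_low) "alt" else "ref"
    unif <- !is.na(ih) && !is.na(il) && maj_h == maj_l && ih == il
    parental <- setdiff(unique(unlist(strsplit(c(r$gt_male, r$gt_female),
                                               "[/|]"))), c("", "."))
    obs <- c(if (r$ref_high >= min_support || r$ref_low >= min_support)
               r$ref,
             if (r$alt_high >= min_support || r$alt_low >= min_support)
               strsplit(r$alt, ",")[[1]][1])
    parent_bad <- if (length(parental) == 0L) TRUE else !all(obs %in% parental)
    qual_bad <- r$qual < 30 || r$qd < 2 || r$fs > 60 || r$mq < 40
    c(multiallelic = multi, low_support = low, uniform_pools = unif,
      parent_inconsistent = parent_bad, quality = qual_bad)
  }, logical(5)))
}

# A window data.frame row for region-calling tests.
make_window <- function(chrom, idx, start_pos, end_pos, m, n_snps = 10L) {
  data.frame(chrom = chrom, window_index = idx, start_pos = start_pos,
             end_pos = end_pos, midpoint_pos = (start_pos + end_pos) / 2,
             m = m, n_snps = n_snps, stringsAsFactors = FALSE)
}
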