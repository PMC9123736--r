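#' Call candidate regions from a window scan
#'
#' Merges maximal runs of windows whose |m| meets or exceeds the threshold
#' into candidate regions, optionally bridging up to `max_gap_snps`
#' consecutive below-threshold windows inside a run. Region boundaries are
#' anchored at member SNP positions: from the first SNP of the first member
#' window to the last SNP of the last member window, reported 0-based
#' half-open.
#'
#' @param windows window data.frame from [sliding_window()] (or a
#'   `bsa_scan`).
#' @param threshold a numeric |m| cutoff, or a `null_threshold` data.frame
#'   (its highest-confidence row is used).
#' @param max_gap_snps below-threshold windows tolerated inside a region
#'   (default 0).
#' @return data.frame of regions with `chrom`, `start`, `end`, `length_mb`,
#'   `n_windows`, `n_snps`, `peak_m`; regions per chromosome are disjoint
#'   and sorted.
#' @export
call_regions <- function(windows, threshold, max_gap_snps = 0) {
  if (inherits(windows, "bsa_scan")) windows <- windows$windows
  if (inherits(threshold, "null_threshold") || is.data.frame(threshold)) {
    threshold <- threshold$threshold[which.max(threshold$confidence)]
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            max_gap_snps >= 0)
  if (is.null(windows) || nrow(windows) == 0L) return(empty_regions())
  out <- lapply(split(windows, windows$chrom), function(w) {
    w <- w[order(w$window_index), , drop = FALSE]
    hit <- abs(w$m) >= threshold
    if (!any(hit)) return(NULL)
    idx <- which(hit)
    # a new run starts when the gap to the previous hit window exceeds
    # max_gap_snps + 1 window indices
    run_id <- cumsum(c(1L, diff(idx) > max_gap_snps + 1L))
    do.call(rbind, lapply(split(idx, run_id), function(members) {
      first <- members[1]; last <- members[length(members)]
      span <- first:last
      start0 <- w$start_pos[first] - 1L   # 1-based SNP pos -> 0-based start
      end0 <- w$end_pos[last]
      data.frame(
        chrom = w$chrom[1],
        start = start0, end = end0,
        length_mb = (end0 - start0) / 1e6,
        n_windows = length(span),
        n_snps = end_snp_count(w, first, last),
        peak_m = w$m[span][which.max(abs(w$m[span]))],
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty_regions())
  out <- merge_overlapping_regions(out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Step-1 windows overlap by window_snps - 1 SNPs, so the SNP spans of two
# separate window runs can themselves overlap; regions on a chromosome must
# be disjoint, so overlapping spans are unioned.
merge_overlapping_regions <- function(regions) {
  do.call(rbind, lapply(split(regions, regions$chrom), function(r) {
    r <- r[order(r$start), , drop = FALSE]
    group <- cumsum(c(1, r$start[-1] >= cummax(r$end)[-nrow(r)]))
    do.call(rbind, lapply(split(r, group), function(g) {
      data.frame(
        chrom = g$chrom[1],
        start = min(g$start), end = max(g$end),
        length_mb = (max(g$end) - min(g$start)) / 1e6,
        n_windows = sum(g$n_windows),
        n_snps = sum(g$n_snps),
        peak_m = g$peak_m[which.max(abs(g$peak_m))],
        stringsAsFactors = FALSE
      )
    }))
  }))
}

# Distinct SNPs covered by windows first..last (step-1 windows of w SNPs
# overlap by w-1, so the union is last - first + window_snps).
end_snp_count <- function(w, first, last) {
  (last - first) + w$n_snps[1]
}

empty_regions <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             length_mb = numeric(0), n_windows = integer(0),
             n_snps = integer(0), peak_m = numeric(0),
             stringsAsFactors = FALSE)
}

#' Build a region table from known intervals
#'
#' Convenience constructor for a region table from interval coordinates
#' (e.g. intervals reported in Mb), for summarizing and annotating
#' externally defined candidate regions.
#'
#' @param chrom chromosome name(s).
#' @param start_mb,end_mb interval bounds in Mb.
#' @param genes optional per-interval gene counts, stored as `n_genes`.
#' @return region data.frame as in [call_regions()].
#' @export
regions_from_intervals <- function(chrom, start_mb, end_mb, genes = NULL) {
  stopifnot(length(start_mb) == length(end_mb), all(start_mb < end_mb))
  out <- data.frame(
    chrom = rep_len(chrom, length(start_mb)),
    start = as.numeric(start_mb) * 1e6,
    end = as.numeric(end_mb) * 1e6,
    stringsAsFactors = FALSE
  )
  out$length_mb <- (out$end - out$start) / 1e6
  out$n_windows <- NA_integer_
  out$n_snps <- NA_integer_
  out$peak_m <- NA_real_
  if (!is.null(genes)) out$n_genes <- genes
  out
}

#' Summarize candidate regions
#'
#' @param regions region data.frame.
#' @return a list with `n_regions`, `total_length_mb`, `total_genes` (sum
#'   of `n_genes` if present, else `NA`), and the per-region `table`.
#' @export
summarize_regions <- function(regions) {
  list(
    n_regions = nrow(regions),
    total_length_mb = if (nrow(regions)) sum(regions$length_mb) else 0,
    total_genes = if ("n_genes" %in% names(regions) && nrow(regions)) {
      sum(regions$n_genes)
    } else {
      NA_integer_
    },
    table = regions
  )
}

#' Read gene models from GFF3
#'
#' Imports `gene`-type features and returns a gene model table.
#'
#' @param gff GFF3 path.
#' @param feature_type feature type to keep (default `"gene"`).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
read_gene_models <- function(gff, feature_type = "gene") {
  gr <- rtracklayer::import(gff)
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[as.character(gr$type) == feature_type]
  }
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$ID)
  } else if ("gene_id" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$gene_id)
  } else {
    paste0("gene", seq_along(gr))
  }
  data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Annotate regions with overlapping genes
#'
#' Assigns a gene to a region when their intervals overlap by at least one
#' base (strand-ignorant; both half-open, so a gene abutting a region end
#' does not overlap). Duplicate gene ids keep their first record with a
#' warning.
#'
#' @param regions region data.frame from [call_regions()].
#' @param genes gene model data.frame from [read_gene_models()].
#' @return `regions` with added `n_genes` and a `genes` list-column of gene
#'   ids; attribute `"gene_union"` carries the deduplicated union of
#'   assigned gene ids.
#' @export
annotate_regions <- function(regions, genes) {
  if (anyDuplicated(genes$gene_id)) {
    warning("duplicate gene ids in gene models; keeping first occurrence")
    genes <- genes[!duplicated(genes$gene_id), , drop = FALSE]
  }
  if (nrow(regions) == 0L) {
    regions$n_genes <- integer(0)
    regions$genes <- list()
    attr(regions, "gene_union") <- character(0)
    return(regions)
  }
  rg <- as_intervals_granges(regions)
  gg <- as_intervals_granges(genes)
  hits <- GenomicRanges::findOverlaps(rg, gg, ignore.strand = TRUE)
  lists <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                 factor(S4Vectors::queryHits(hits),
                        levels = seq_len(nrow(regions))))
  regions$genes <- unname(lapply(lists, as.character))
  regions$n_genes <- lengths(regions$genes)
  attr(regions, "gene_union") <- unique(unlist(regions$genes))
  regions
}

#' Write regions as BED and TSV
#'
#' `<prefix>_regions.bed` (0-based half-open), `<prefix>_regions.tsv`, and
#' when annotation is present `<prefix>_region_genes.tsv` (one row per
#' region-gene assignment).
#'
#' @param regions region data.frame.
#' @param out_prefix path prefix.
#' @return the paths, invisibly.
#' @export
write_regions <- function(regions, out_prefix) {
  bed_path <- paste0(out_prefix, "_regions.bed")
  tsv_path <- paste0(out_prefix, "_regions.tsv")
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(regions$end, scientific = FALSE,
                                 trim = TRUE),
                    name = sprintf("region%d", seq_len(nrow(regions))),
                    score = regions$peak_m)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  flat <- regions
  flat$genes <- NULL
  utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(bed_path, tsv_path)
  if (!is.null(regions$genes)) {
    gene_path <- paste0(out_prefix, "_region_genes.tsv")
    rows <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
      g <- regions$genes[[i]]
      if (length(g) == 0L) return(NULL)
      data.frame(region = sprintf("region%d", i), chrom = regions$chrom[i],
                 gene_id = g, stringsAsFactors = FALSE)
    }))
    if (is.null(rows)) {
      rows <- data.frame(region = character(0), chrom = character(0),
                         gene_id = character(0))
    }
    utils::write.table(rows, gene_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, gene_path)
  }
  invisible(paths)
}
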