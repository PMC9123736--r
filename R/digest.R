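#' In-silico digestion of one sequence
#'
#' Cuts a sequence at the union of all enzymes' cut sites and returns the
#' resulting fragments as 0-based half-open intervals. Fragments tile the
#' sequence exactly: they are disjoint, ordered, and their lengths sum to the
#' sequence length. The flanks record which enzyme produced each cut;
#' fragment ends that are sequence ends are labelled `SEQ_END`.
#'
#' @param seq DNA string or [Biostrings::DNAString].
#' @param enzymes enzymes as in [find_cut_sites()].
#' @param chrom sequence name recorded in the output.
#' @return a data.frame of fragments with columns `chrom`, `start`, `end`,
#'   `left_enzyme`, `right_enzyme`, `length`.
#' @examples
#' digest_sequence("AAGTACAA", slaf_enzymes("RsaI"))
#' @export
digest_sequence <- function(seq, enzymes, chrom = "seq") {
  if (methods::is(seq, "DNAString") || methods::is(seq, "BString")) {
    seq <- as.character(seq)
  }
  seq <- normalize_dna(seq)
  n <- nchar(seq)
  if (n == 0L) {
    return(empty_fragments())
  }
  sites <- find_cut_sites(seq, enzymes)
  # Cuts at position 0 or n produce empty leading/trailing fragments; drop
  # them but keep the enzyme label on the adjacent flank.
  keep <- sites$pos > 0L & sites$pos < n
  sites <- sites[keep, , drop = FALSE]
  # A site can in principle be cut by two enzymes at the same position
  # (ambiguous motifs); collapse to one breakpoint, first enzyme name kept.
  dup <- duplicated(sites$pos)
  sites <- sites[!dup, , drop = FALSE]
  bounds <- c(0L, sites$pos, n)
  left <- c("SEQ_END", sites$enzyme)
  right <- c(sites$enzyme, "SEQ_END")
  out <- data.frame(
    chrom = chrom,
    start = bounds[-length(bounds)],
    end = bounds[-1L],
    left_enzyme = left,
    right_enzyme = right,
    stringsAsFactors = FALSE
  )
  out$length <- out$end - out$start
  out
}

empty_fragments <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             left_enzyme = character(0), right_enzyme = character(0),
             length = integer(0), stringsAsFactors = FALSE)
}

#' Digest a whole genome
#'
#' Applies [digest_sequence()] to every sequence of a genome and binds the
#' fragment tables. Input can be a FASTA path (optionally gzipped) or a named
#' [Biostrings::DNAStringSet].
#'
#' @param genome FASTA file path or `DNAStringSet`.
#' @param enzymes enzymes as in [find_cut_sites()].
#' @return fragment data.frame as in [digest_sequence()].
#' @export
digest_genome <- function(genome, enzymes) {
  seqs <- load_genome(genome)
  frags <- lapply(seq_along(seqs), function(i) {
    digest_sequence(as.character(seqs[[i]]), enzymes,
                    chrom = names(seqs)[i])
  })
  do.call(rbind, frags)
}

load_genome <- function(genome) {
  if (is.character(genome)) {
    seqs <- Biostrings::readDNAStringSet(genome)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    seqs
  } else if (methods::is(genome, "DNAStringSet")) {
    genome
  } else {
    stop("genome must be a FASTA path or a DNAStringSet")
  }
}

#' Select SLAF tags by fragment size
#'
#' Keeps fragments whose length falls inside the size-selection window
#' (inclusive on both ends) and whose flanks satisfy the flank rule:
#' \describe{
#'   \item{internal_only}{both flanks are enzyme cut sites (default — a
#'     sequencing tag needs two ligatable ends);}
#'   \item{mixed_enzymes}{both flanks are cut sites and from different
#'     enzymes (strict double-digest tags);}
#'   \item{any}{length window alone.}
#' }
#'
#' @param fragments fragment data.frame from [digest_sequence()].
#' @param size_window numeric length-2, `c(min_bp, max_bp)`; default the
#'   314–364 bp SLAF selection window.
#' @param flank_rule one of `"internal_only"`, `"mixed_enzymes"`, `"any"`.
#' @return the selected subset of `fragments`.
#' @export
select_tags <- function(fragments, size_window = c(314, 364),
                        flank_rule = c("internal_only", "mixed_enzymes",
                                       "any")) {
  flank_rule <- match.arg(flank_rule)
  stopifnot(length(size_window) == 2L, size_window[1] <= size_window[2])
  in_window <- fragments$length >= size_window[1] &
    fragments$length <= size_window[2]
  internal <- fragments$left_enzyme != "SEQ_END" &
    fragments$right_enzyme != "SEQ_END"
  keep <- switch(flank_rule,
    any = in_window,
    internal_only = in_window & internal,
    mixed_enzymes = in_window & internal &
      fragments$left_enzyme != fragments$right_enzyme
  )
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score an enzyme combination
#'
#' Evaluates a digest for library design: how many fragments fall in the
#' size window, what fraction of tag bases lie in repeats (soft-masked
#' intervals), and what fraction of tags overlap annotated genes. Low repeat
#' fraction and high gene coverage favour an enzyme combination.
#'
#' @param fragments fragment data.frame from [digest_genome()].
#' @param gene_intervals gene intervals: a data.frame with `chrom`, `start`,
#'   `end` (0-based half-open) or a [GenomicRanges::GRanges]; may be `NULL`.
#' @param mask soft-mask (repeat) intervals in the same form; may be `NULL`.
#' @param size_window,flank_rule passed to [select_tags()].
#' @return an object of class `digest_report`: a list with `n_fragments`,
#'   `n_tags_in_window`, `size_window`, `per_chrom_counts`,
#'   `repeat_fraction`, `gene_coverage` (fractions are `NA` when there are
#'   no selected tags).
#' @export
score_enzyme_combination <- function(fragments, gene_intervals = NULL,
                                     mask = NULL,
                                     size_window = c(314, 364),
                                     flank_rule = "internal_only") {
  tags <- select_tags(fragments, size_window, flank_rule)
  n_tags <- nrow(tags)
  per_chrom <- if (n_tags) table(tags$chrom) else table(character(0))
  repeat_fraction <- NA_real_
  gene_coverage <- NA_real_
  if (n_tags > 0L) {
    tag_gr <- fragments_to_granges(tags)
    total_bases <- sum(tags$length)
    if (!is.null(mask)) {
      mask_gr <- GenomicRanges::reduce(as_intervals_granges(mask))
      # disjoint seqlevels (mask on other sequences) are legitimate input
      masked <- sum(IRanges::width(suppressWarnings(GenomicRanges::intersect(
        tag_gr, mask_gr, ignore.strand = TRUE))))
      repeat_fraction <- masked / total_bases
    } else {
      repeat_fraction <- 0
    }
    if (!is.null(gene_intervals)) {
      gene_gr <- as_intervals_granges(gene_intervals)
      hits <- suppressWarnings(
        GenomicRanges::countOverlaps(tag_gr, gene_gr,
                                     ignore.strand = TRUE))
      gene_coverage <- mean(hits > 0L)
    }
  }
  structure(list(
    n_fragments = nrow(fragments),
    n_tags_in_window = n_tags,
    size_window = size_window,
    per_chrom_counts = per_chrom,
    repeat_fraction = repeat_fraction,
    gene_coverage = gene_coverage
  ), class = "digest_report")
}

#' @export
print.digest_report <- function(x, ...) {
  cat("SLAF digest report\n")
  cat(sprintf("  fragments:        %d\n", x$n_fragments))
  cat(sprintf("  tags in %d-%d bp: %d\n", x$size_window[1], x$size_window[2],
              x$n_tags_in_window))
  cat(sprintf("  repeat fraction:  %s\n", format_frac(x$repeat_fraction)))
  cat(sprintf("  gene coverage:    %s\n", format_frac(x$gene_coverage)))
  invisible(x)
}

format_frac <- function(x) {
  if (is.na(x)) "NA (no tags)" else sprintf("%.4f", x)
}

# 0-based half-open data.frame (chrom/start/end) -> GRanges (1-based closed)
as_intervals_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

fragments_to_granges <- function(fragments) {
  as_intervals_granges(fragments)
}

#' Write predicted tags as BED
#'
#' Standard 0-based half-open BED with `name` = `left/right` enzyme labels
#' and `score` = fragment length.
#'
#' @param tags fragment data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tags_bed <- function(tags, path) {
  bed <- data.frame(
    chrom = tags$chrom, start = tags$start, end = tags$end,
    name = paste0(tags$left_enzyme, "/", tags$right_enzyme),
    score = tags$length
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a digest report and per-chromosome tag counts as TSV
#'
#' @param report a `digest_report`.
#' @param out_prefix path prefix; writes `<prefix>_report.tsv` and
#'   `<prefix>_per_chrom.tsv`.
#' @return the two paths, invisibly.
#' @export
write_digest_report <- function(report, out_prefix) {
  rep_path <- paste0(out_prefix, "_report.tsv")
  chrom_path <- paste0(out_prefix, "_per_chrom.tsv")
  summary_df <- data.frame(
    n_fragments = report$n_fragments,
    n_tags_in_window = report$n_tags_in_window,
    size_min = report$size_window[1], size_max = report$size_window[2],
    repeat_fraction = report$repeat_fraction,
    gene_coverage = report$gene_coverage
  )
  utils::write.table(summary_df, rep_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  chrom_df <- data.frame(chrom = names(report$per_chrom_counts),
                         n_tags = as.integer(report$per_chrom_counts))
  utils::write.table(chrom_df, chrom_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(rep_path, chrom_path))
}

#' Soft-mask intervals of a FASTA file
#'
#' Reads a FASTA preserving case and returns the lowercase (soft-masked)
#' runs as 0-based half-open intervals, the repeat definition used by
#' [score_enzyme_combination()].
#'
#' @param fasta path to a FASTA file.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
softmask_intervals <- function(fasta) {
  seqs <- Biostrings::readBStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    m <- gregexpr("[acgtn]+", s)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(chrom = names(seqs)[i],
               start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + attr(m, "match.length"))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  }
  out
}
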