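#' Per-site SNP-index and delta
#'
#' The SNP-index of a bulk at a site is the fraction of its reads carrying
#' the oriented allele; delta is `index_high - index_low`. With the default
#' `ref_alt` orientation the oriented allele is the alternate allele, as
#' given by the VCF. With `high_parent` orientation the index is polarized
#' by the allele carried by the high-trait parent where that parent is
#' homozygous; at sites where it is heterozygous or missing the orientation
#' falls back to `ref_alt` and the point is flagged. Sites where a bulk has
#' zero total depth are masked (`masked = TRUE`) and excluded from windows
#' rather than scored as zero.
#'
#' @param records SNP record data.frame (see [read_snp_vcf()]).
#' @param orientation `"ref_alt"` (default) or `"high_parent"`.
#' @param high_parent which parent is the high-trait parent, `"male"` or
#'   `"female"`; used only for `high_parent` orientation.
#' @return data.frame with `chrom`, `pos`, `index_high`, `index_low`,
#'   `delta`, `depth_high`, `depth_low`, `masked`, `orientation_fallback`.
#' @export
snp_index <- function(records, orientation = c("ref_alt", "high_parent"),
                      high_parent = c("male", "female")) {
  orientation <- match.arg(orientation)
  high_parent <- match.arg(high_parent)
  validate_snp_records(records)
  dh <- records$ref_high + records$alt_high
  dl <- records$ref_low + records$alt_low
  masked <- dh == 0L | dl == 0L

  oriented_high <- records$alt_high
  oriented_low <- records$alt_low
  fallback <- rep(FALSE, nrow(records))
  if (orientation == "high_parent") {
    gt <- if (high_parent == "male") records$gt_male else records$gt_female
    alleles <- split_gt(gt)
    alt1 <- vapply(strsplit(records$alt, ","), `[`, character(1), 1L)
    carries <- vapply(seq_along(alleles), function(i) {
      a <- unique(alleles[[i]])
      a <- a[a != "" & a != "."]
      if (length(a) != 1L) return("ambiguous")
      if (a == records$ref[i]) return("ref")
      if (a == alt1[i]) return("alt")
      "ambiguous"
    }, character(1))
    flip <- carries == "ref"
    oriented_high[flip] <- records$ref_high[flip]
    oriented_low[flip] <- records$ref_low[flip]
    fallback <- carries == "ambiguous"
  }
  idx_h <- ifelse(dh > 0, oriented_high / dh, NA_real_)
  idx_l <- ifelse(dl > 0, oriented_low / dl, NA_real_)
  data.frame(
    chrom = records$chrom, pos = records$pos,
    index_high = idx_h, index_low = idx_l,
    delta = idx_h - idx_l,
    depth_high = dh, depth_low = dl,
    masked = masked, orientation_fallback = fallback,
    stringsAsFactors = FALSE
  )
}

#' Sliding-window mean of delta SNP-index
#'
#' The scanned statistic m: the arithmetic mean of delta over
#' `window_snps` consecutive (unmasked) SNPs, advancing by `step_snps`
#' SNPs. Windows never span chromosomes; a chromosome with fewer than
#' `window_snps` usable points contributes no windows.
#'
#' @param points SNP-index points from [snp_index()], sorted by
#'   `(chrom, pos)`.
#' @param window_snps SNPs per window (default 10).
#' @param step_snps step between window starts in SNPs (default 1).
#' @return data.frame with `chrom`, `window_index` (per chromosome, from 1),
#'   `start_pos`, `end_pos` (first/last member SNP positions),
#'   `midpoint_pos` (median member position), `m`, `n_snps`.
#' @export
sliding_window <- function(points, window_snps = 10, step_snps = 1) {
  stopifnot(window_snps >= 1, step_snps >= 1)
  pts <- points[!points$masked & !is.na(points$delta), , drop = FALSE]
  pts <- pts[order(pts$chrom, pts$pos), , drop = FALSE]
  out <- lapply(split(pts, pts$chrom), function(p) {
    n <- nrow(p)
    if (n < window_snps) return(NULL)
    starts <- seq.int(1L, n - window_snps + 1L, by = step_snps)
    cs <- c(0, cumsum(p$delta))
    m <- (cs[starts + window_snps] - cs[starts]) / window_snps
    data.frame(
      chrom = p$chrom[1],
      window_index = seq_along(starts),
      start_pos = p$pos[starts],
      end_pos = p$pos[starts + window_snps - 1L],
      midpoint_pos = vapply(starts, function(s) {
        stats::median(p$pos[s:(s + window_snps - 1L)])
      }, numeric(1)),
      m = m,
      n_snps = window_snps,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), window_index = integer(0),
                      start_pos = integer(0), end_pos = integer(0),
                      midpoint_pos = numeric(0), m = numeric(0),
                      n_snps = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Simulated null thresholds for the windowed delta SNP-index
#'
#' Permutation-style null for an F1 pseudo-testcross (or F2) bulked design
#' with no marker-trait association. Per replicate and per window SNP, each
#' bulk's allele frequency is drawn from the segregation of an unlinked
#' marker — F1 pseudo-testcross: the mean of `bulk_size` Bernoulli(1/2)
#' plant doses (1:1 segregation of a marker heterozygous in one parent);
#' F2: plant doses 0, 1/2, 1 with probabilities 1/4, 1/2, 1/4 — then read
#' depths are drawn binomially at that frequency for both bulks, delta is
#' computed, and the window mean m over `window_snps` sites gives one null
#' draw. Thresholds are two-sided nearest-rank quantiles of |m| at each
#' confidence level.
#'
#' @param bulk_size plants per bulk (default 30).
#' @param depth the depth model: a single number (both bulks), a length-2
#'   vector `c(high, low)`, or a data.frame with `depth_high`/`depth_low`
#'   columns whose rows are resampled with replacement (preserves the
#'   observed depth distribution).
#' @param window_snps SNPs per window (default 10).
#' @param n_replicates null replicates (default 10000).
#' @param design `"F1_pseudo_testcross"` (default) or `"F2"`.
#' @param confidence confidence levels (default 0.90, 0.95, 0.99).
#' @param seed RNG seed; identical seeds give identical thresholds.
#' @param return_null also return the vector of null m draws.
#' @return data.frame of class `null_threshold` with `confidence`,
#'   `threshold`, `method`, `n_replicates`, `seed`; when `return_null`,
#'   the null draws as attribute `"null_m"`.
#' @export
simulate_null_threshold <- function(bulk_size = 30, depth = 45,
                                    window_snps = 10, n_replicates = 10000,
                                    design = c("F1_pseudo_testcross", "F2"),
                                    confidence = c(0.90, 0.95, 0.99),
                                    seed = NULL, return_null = FALSE) {
  design <- match.arg(design)
  stopifnot(bulk_size >= 1, window_snps >= 1, n_replicates >= 1,
            all(confidence > 0 & confidence < 1))
  if (!is.null(seed)) set.seed(seed)
  n <- n_replicates * window_snps

  draw_freq <- function() {
    if (design == "F1_pseudo_testcross") {
      stats::rbinom(n, bulk_size, 0.5) / bulk_size
    } else {
      stats::rbinom(n, 2L * bulk_size, 0.5) / (2L * bulk_size)
    }
  }
  if (is.data.frame(depth)) {
    stopifnot(all(c("depth_high", "depth_low") %in% names(depth)),
              nrow(depth) >= 1)
    i <- sample.int(nrow(depth), n, replace = TRUE)
    dh <- pmax(depth$depth_high[i], 1L)
    dl <- pmax(depth$depth_low[i], 1L)
  } else {
    stopifnot(all(depth >= 1))
    dh <- rep_len(depth[1], n)
    dl <- rep_len(depth[min(2L, length(depth))], n)
  }
  fh <- draw_freq()
  fl <- draw_freq()
  delta <- stats::rbinom(n, dh, fh) / dh - stats::rbinom(n, dl, fl) / dl
  m <- rowMeans(matrix(delta, nrow = n_replicates, ncol = window_snps))

  confidence <- sort(confidence)
  out <- data.frame(
    confidence = confidence,
    threshold = quantile_nearest_rank(abs(m), confidence),
    method = "simulation",
    n_replicates = n_replicates,
    seed = if (is.null(seed)) NA_integer_ else seed
  )
  class(out) <- c("null_threshold", "data.frame")
  if (return_null) attr(out, "null_m") <- m
  out
}

#' Empirical percentile threshold
#'
#' Threshold from the data itself: the stated nearest-rank percentile of
#' the |m| distribution over all windows, the fallback used when the
#' simulated null leaves no region above threshold.
#'
#' @param windows window data.frame from [sliding_window()].
#' @param percentile percentile of |m| (default 99).
#' @return one-row data.frame of class `null_threshold` with
#'   `method = "empirical_percentile"`.
#' @export
empirical_threshold <- function(windows, percentile = 99) {
  if (is.null(windows) || nrow(windows) == 0L) {
    stop("empirical_threshold needs at least one window")
  }
  stopifnot(percentile > 0, percentile <= 100)
  out <- data.frame(
    confidence = percentile / 100,
    threshold = quantile_nearest_rank(abs(windows$m), percentile / 100),
    method = "empirical_percentile",
    n_replicates = nrow(windows),
    seed = NA_integer_
  )
  class(out) <- c("null_threshold", "data.frame")
  out
}

#' Bulked-segregant SNP-index genome scan
#'
#' The central analysis: computes per-site SNP-index and delta for the two
#' bulks, smooths delta with a sliding window of `window_snps` consecutive
#' SNPs, and derives significance thresholds both by simulating the F1 (or
#' F2) null (`n_replicates` replications, resampling the observed per-site
#' bulk depths by default) and by the empirical 99th percentile of |m|.
#'
#' @param records filtered SNP record data.frame (output of
#'   [filter_snps()]).
#' @param window_snps,step_snps window geometry (defaults 10 and 1).
#' @param orientation,high_parent see [snp_index()].
#' @param design,bulk_size,n_replicates,confidence see
#'   [simulate_null_threshold()].
#' @param depth_model `"resample"` (default; the observed per-site bulk
#'   depths are resampled for the null) or `"constant"` (use `depth`).
#' @param depth constant depth(s) for `depth_model = "constant"`.
#' @param empirical_percentile percentile for the empirical threshold
#'   (default 99).
#' @param seed RNG seed for the null simulation.
#' @return an object of class `bsa_scan`: list with `points`, `windows`,
#'   `thresholds` (simulation), `empirical` (empirical percentile), and
#'   `params`.
#' @examples
#' sim <- simulate_bsa_experiment(sim_config(n_markers = 200, seed = 7))
#' scan <- bsa_scan(sim$records, n_replicates = 500, seed = 7)
#' summary(scan)
#' @export
bsa_scan <- function(records, window_snps = 10, step_snps = 1,
                     orientation = "ref_alt", high_parent = "male",
                     design = "F1_pseudo_testcross", bulk_size = 30,
                     n_replicates = 10000,
                     confidence = c(0.90, 0.95, 0.99),
                     depth_model = c("resample", "constant"), depth = 45,
                     empirical_percentile = 99, seed = NULL) {
  depth_model <- match.arg(depth_model)
  points <- snp_index(records, orientation = orientation,
                      high_parent = high_parent)
  windows <- sliding_window(points, window_snps, step_snps)
  depth_arg <- if (depth_model == "resample") {
    usable <- points[!points$masked, c("depth_high", "depth_low")]
    if (nrow(usable) == 0L) stop("no unmasked points to resample depths from")
    usable
  } else {
    depth
  }
  thresholds <- simulate_null_threshold(
    bulk_size = bulk_size, depth = depth_arg, window_snps = window_snps,
    n_replicates = n_replicates, design = design, confidence = confidence,
    seed = seed
  )
  emp <- if (nrow(windows)) {
    empirical_threshold(windows, empirical_percentile)
  } else {
    NULL
  }
  structure(list(
    points = points,
    windows = windows,
    thresholds = thresholds,
    empirical = emp,
    params = list(window_snps = window_snps, step_snps = step_snps,
                  orientation = orientation, design = design,
                  bulk_size = bulk_size, n_replicates = n_replicates,
                  depth_model = depth_model, seed = seed)
  ), class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat("Bulked-segregant SNP-index scan\n")
  cat(sprintf("  sites: %d (%d masked), windows of %d SNPs: %d\n",
              nrow(x$points), sum(x$points$masked), x$params$window_snps,
              nrow(x$windows)))
  cat(sprintf("  null: %s, %d replicates\n", x$params$design,
              x$params$n_replicates))
  for (i in seq_len(nrow(x$thresholds))) {
    cat(sprintf("  |m| threshold @ %.2f: %.4f\n",
                x$thresholds$confidence[i], x$thresholds$threshold[i]))
  }
  if (!is.null(x$empirical)) {
    cat(sprintf("  empirical %.0fth pct of |m|: %.4f\n",
                x$empirical$confidence * 100, x$empirical$threshold))
  }
  invisible(x)
}

#' @export
summary.bsa_scan <- function(object, ...) {
  w <- object$windows
  peak <- if (nrow(w)) w[which.max(abs(w$m)), ] else NULL
  out <- list(
    n_sites = nrow(object$points),
    n_masked = sum(object$points$masked),
    n_windows = nrow(w),
    delta_range = if (nrow(object$points)) {
      range(object$points$delta, na.rm = TRUE)
    } else c(NA, NA),
    peak = peak,
    thresholds = object$thresholds,
    empirical = object$empirical
  )
  class(out) <- "summary.bsa_scan"
  out
}

#' @export
print.summary.bsa_scan <- function(x, ...) {
  cat(sprintf("Scan of %d sites (%d masked), %d windows\n",
              x$n_sites, x$n_masked, x$n_windows))
  cat(sprintf("  delta range: [%.3f, %.3f]\n",
              x$delta_range[1], x$delta_range[2]))
  if (!is.null(x$peak)) {
    cat(sprintf("  peak |m| = %.4f at %s:%.0f\n", abs(x$peak$m),
                x$peak$chrom, x$peak$midpoint_pos))
  }
  print(as.data.frame(x$thresholds), row.names = FALSE)
  invisible(x)
}

#' Plot a scan: per-bulk SNP-index and delta panels
#'
#' Three stacked panels per chromosome: high-bulk SNP-index, low-bulk
#' SNP-index, and windowed delta with the simulated threshold lines.
#'
#' @param x a `bsa_scan`.
#' @param chrom chromosome to plot; default the first.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bsa_scan <- function(x, chrom = NULL, ...) {
  pts <- x$points[!x$points$masked, ]
  if (is.null(chrom)) chrom <- pts$chrom[1]
  pts <- pts[pts$chrom == chrom, ]
  w <- x$windows[x$windows$chrom == chrom, ]
  old <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  mb <- pts$pos / 1e6
  graphics::plot(mb, pts$index_high, pch = 16, cex = 0.4,
                 col = "firebrick", ylim = c(0, 1), xlab = "",
                 ylab = "SNP-index (high)", main = chrom, ...)
  graphics::plot(mb, pts$index_low, pch = 16, cex = 0.4,
                 col = "steelblue", ylim = c(0, 1), xlab = "",
                 ylab = "SNP-index (low)", ...)
  graphics::plot(mb, pts$delta, pch = 16, cex = 0.4, col = "grey60",
                 ylim = c(-1, 1), xlab = "position (Mb)",
                 ylab = expression(Delta ~ "SNP-index"), ...)
  if (nrow(w)) {
    graphics::lines(w$midpoint_pos / 1e6, w$m, col = "black", lwd = 1.5)
  }
  for (i in seq_len(nrow(x$thresholds))) {
    graphics::abline(h = c(-1, 1) * x$thresholds$threshold[i],
                     lty = 2, col = "red")
  }
  invisible(x)
}

#' Write scan outputs as TSV
#'
#' Writes `<prefix>_snp_index.tsv` (per-site), `<prefix>_windows.tsv` and
#' `<prefix>_thresholds.tsv` (simulated plus empirical).
#'
#' @param scan a `bsa_scan`.
#' @param out_prefix path prefix.
#' @return the paths, invisibly.
#' @export
write_scan <- function(scan, out_prefix) {
  paths <- paste0(out_prefix, c("_snp_index.tsv", "_windows.tsv",
                                "_thresholds.tsv"))
  utils::write.table(scan$points, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scan$windows, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  thr <- rbind(as.data.frame(scan$thresholds),
               if (!is.null(scan$empirical)) as.data.frame(scan$empirical))
  utils::write.table(thr, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
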