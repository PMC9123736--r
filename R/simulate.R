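#' Configuration for a synthetic F1 bulked-segregant experiment
#'
#' Collects every parameter of the forward simulation. Defaults emulate the
#' study design this package targets: an F1 population of 305 plants from a
#' cross of two heterozygous outcrossing parents, extreme bulks of 30,
#' pooled sequencing at ~45X per bulk and ~10X per parent, and a 0-100%
#' trait (fiber content) driven by one causal locus plus environmental
#' noise.
#'
#' @param seed RNG seed for the whole simulation.
#' @param n_plants F1 population size (default 305).
#' @param bulk_size plants per extreme bulk (default 30).
#' @param n_chroms number of chromosomes (default 1).
#' @param chrom_length_bp chromosome length in bp (default 1e8, the scale
#'   of a large plant chromosome).
#' @param n_markers total marker count across chromosomes (default 2000).
#' @param het_male,het_female fraction of markers heterozygous in each
#'   parent (default 0.45 each; markers heterozygous in one parent
#'   segregate 1:1 in the F1 — the pseudo-testcross configuration — and
#'   markers heterozygous in both segregate 1:2:1).
#' @param causal_index marker index of the causal locus; default the middle
#'   marker. The causal marker is forced heterozygous in the male parent
#'   and homozygous reference in the female parent, so its alternate allele
#'   segregates 1:1.
#' @param causal_effect trait units added per alternate-allele dose at the
#'   causal locus (default 5).
#' @param trait_mean,trait_sd baseline trait mean and environmental SD in
#'   percent (defaults 28 and 2.5).
#' @param phase_coupling probability that, at a heterozygous marker, the
#'   alternate allele lies on the same parental haplotype as the causal
#'   alternate allele (default 0.95). Values above 0.5 emulate the haplotype
#'   structure of a wide cross where the reference genome is closer to one
#'   parent, which is what makes the signed windowed delta informative;
#'   0.5 gives fully random phase.
#' @param recomb_rate recombination rate in Morgans per bp (default 2e-8,
#'   i.e. 2 cM/Mb); crossovers follow the Haldane model (no interference).
#' @param unlinked if `TRUE`, markers segregate independently (as if
#'   separated by >= 50 cM); used for null-calibration studies.
#' @param bulk_depth_mean,parent_depth_mean Poisson mean sequencing depths
#'   (defaults 45 and 10).
#' @param seq_error per-read allele flip probability (default 0.001).
#' @param violation_fraction fraction of sites given a planted caller
#'   quality-filter violation (default 0.02).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_plants = 305, bulk_size = 30,
                       n_chroms = 1, chrom_length_bp = 1e8,
                       n_markers = 2000, het_male = 0.45, het_female = 0.45,
                       causal_index = NULL, causal_effect = 5,
                       trait_mean = 28, trait_sd = 2.5,
                       phase_coupling = 0.95,
                       recomb_rate = 2e-8, unlinked = FALSE,
                       bulk_depth_mean = 45, parent_depth_mean = 10,
                       seq_error = 0.001, violation_fraction = 0.02) {
  cfg <- list(seed = seed, n_plants = as.integer(n_plants),
              bulk_size = as.integer(bulk_size),
              n_chroms = as.integer(n_chroms),
              chrom_length_bp = chrom_length_bp,
              n_markers = as.integer(n_markers),
              het_male = het_male, het_female = het_female,
              causal_index = causal_index, causal_effect = causal_effect,
              trait_mean = trait_mean, trait_sd = trait_sd,
              phase_coupling = phase_coupling,
              recomb_rate = recomb_rate, unlinked = isTRUE(unlinked),
              bulk_depth_mean = bulk_depth_mean,
              parent_depth_mean = parent_depth_mean,
              seq_error = seq_error,
              violation_fraction = violation_fraction)
  stopifnot(cfg$n_plants >= 2L * cfg$bulk_size, cfg$n_chroms >= 1,
            cfg$n_markers >= 1, cfg$bulk_depth_mean > 0,
            cfg$parent_depth_mean > 0,
              cfg$het_male >= 0, cfg$het_male <= 1,
              cfg$het_female >= 0, cfg$het_female <= 1,
              cfg$phase_coupling >= 0, cfg$phase_coupling <= 1,
              cfg$seq_error >= 0, cfg$seq_error < 0.5,
              cfg$violation_fraction >= 0, cfg$violation_fraction <= 1)
  if (is.null(cfg$causal_index)) {
    cfg$causal_index <- as.integer(ceiling(cfg$n_markers / 2))
  }
  stopifnot(cfg$causal_index >= 1, cfg$causal_index <= cfg$n_markers)
  class(cfg) <- "sim_config"
  cfg
}

# One meiosis per row: haplotype state (1 or 2) along markers with
# Haldane-model switches at rate r between adjacent markers on the same
# chromosome; independent across chromosomes.
sample_gametes <- function(n, hap1, hap2, switch_prob) {
  m <- length(hap1)
  # switch_prob[j] applies between marker j and j+1 (length m, first entry
  # is the chromosome-start probability 0.5)
  s <- matrix(stats::rbinom(n * m, 1L, rep(switch_prob, each = n)), n, m)
  states <- t(apply(s, 1L, cumsum)) %% 2L
  h1 <- matrix(hap1, n, m, byrow = TRUE)
  h2 <- matrix(hap2, n, m, byrow = TRUE)
  (1L - states) * h1 + states * h2
}

#' Simulate parents and an F1 population
#'
#' Draws marker maps and parental haplotypes, then forms each F1 plant from
#' one recombinant gamete per parent (Haldane crossovers, no interference).
#' Markers heterozygous in exactly one parent segregate 1:1 in the F1;
#' markers heterozygous in both segregate 1:2:1.
#'
#' @param config a [sim_config()].
#' @return list with `markers` (chrom, pos, ref, alt, parental genotype
#'   strings), `dose` (plants x markers matrix of alternate-allele counts
#'   0-2), and `truth` (causal locus coordinates and parental haplotypes).
#' @export
simulate_parents_and_f1 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 11L))
  m <- config$n_markers
  per_chrom <- diff(round(seq(0, m, length.out = config$n_chroms + 1L)))
  chrom <- rep(sprintf("chr%d", seq_len(config$n_chroms)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) {
    sort(sample.int(config$chrom_length_bp - 1L, k)) + 1L
  }))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  het_m <- stats::rbinom(m, 1L, config$het_male) == 1L
  het_f <- stats::rbinom(m, 1L, config$het_female) == 1L
  ci <- config$causal_index
  het_m[ci] <- TRUE
  het_f[ci] <- FALSE

  # haplotype 2 preferentially carries the alternate allele at het sites
  # (phase_coupling), mimicking a wide cross where the reference genome is
  # closer to one ancestral background
  make_haps <- function(het) {
    alt_on_h2 <- stats::rbinom(m, 1L, config$phase_coupling)
    hom_alt <- stats::rbinom(m, 1L, 0.5)
    h1 <- ifelse(het, 1L - alt_on_h2, hom_alt)
    h2 <- ifelse(het, alt_on_h2, hom_alt)
    list(h1 = as.integer(h1), h2 = as.integer(h2))
  }
  hm <- make_haps(het_m)
  hf <- make_haps(het_f)
  hm$h1[ci] <- 0L; hm$h2[ci] <- 1L  # causal alt on male haplotype 2
  hf$h1[ci] <- 0L; hf$h2[ci] <- 0L  # female homozygous reference at QTL

  # between-marker recombination probabilities (Haldane), reset per chrom
  d <- c(0, diff(pos))
  new_chrom <- !duplicated(chrom)
  r <- 0.5 * (1 - exp(-2 * config$recomb_rate * d))
  r[new_chrom] <- 0.5
  if (config$unlinked) r <- rep(0.5, m)

  gam_m <- sample_gametes(config$n_plants, hm$h1, hm$h2, r)
  gam_f <- sample_gametes(config$n_plants, hf$h1, hf$h2, r)
  dose <- gam_m + gam_f

  gt_string <- function(h1, h2) {
    a1 <- ifelse(h1 == 1L, alt, ref)
    a2 <- ifelse(h2 == 1L, alt, ref)
    paste(a1, a2, sep = "/")
  }
  markers <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    gt_male = gt_string(hm$h1, hm$h2),
    gt_female = gt_string(hf$h1, hf$h2),
    stringsAsFactors = FALSE
  )
  truth <- list(
    causal_index = ci,
    causal_chrom = chrom[ci],
    causal_pos = pos[ci],
    het_male = het_m, het_female = het_f
  )
  list(markers = markers, dose = dose, truth = truth)
}

#' Simulate the quantitative trait
#'
#' trait = trait_mean + causal_effect x dose + Normal(0, trait_sd), clipped
#' to the 0-100% scale of a content trait.
#'
#' @param dose_causal vector of causal-locus alternate-allele doses (0-2).
#' @param config a [sim_config()].
#' @return numeric trait values, one per plant.
#' @export
simulate_trait <- function(dose_causal, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 23L))
  y <- config$trait_mean + config$causal_effect * dose_causal +
    stats::rnorm(length(dose_causal), 0, config$trait_sd)
  pmin(pmax(y, 0), 100)
}

#' Simulate pooled sequencing of the bulks and parents
#'
#' Per site and bulk, the true pool allele frequency is the mean plant
#' dose / 2; total depth is Poisson(`bulk_depth_mean`) and the alternate
#' depth binomial at the error-perturbed frequency. Parents are sequenced
#' at Poisson(`parent_depth_mean`). Caller annotations QUAL/QD/FS/MQ are
#' drawn from clean distributions, with `violation_fraction` of sites given
#' one planted hard-filter violation.
#'
#' @param sim output of [simulate_parents_and_f1()].
#' @param bulks a `bulk_assignment` from [select_bulks()]; plant ids must
#'   be `plant_<row>` as produced by [simulate_bsa_experiment()], or a
#'   list with integer `high_idx`/`low_idx` row indices.
#' @param config a [sim_config()].
#' @return SNP record data.frame as in [read_snp_vcf()], with attribute
#'   `"planted_violations"` (logical vector).
#' @export
simulate_pooled_reads <- function(sim, bulks, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 37L))
  if (inherits(bulks, "bulk_assignment")) {
    high_idx <- as.integer(sub("^plant_", "", bulks$high_ids))
    low_idx <- as.integer(sub("^plant_", "", bulks$low_ids))
  } else {
    high_idx <- bulks$high_idx
    low_idx <- bulks$low_idx
  }
  m <- nrow(sim$markers)
  eps <- config$seq_error
  perturb <- function(f) f * (1 - eps) + (1 - f) * eps

  freq_high <- colMeans(sim$dose[high_idx, , drop = FALSE]) / 2
  freq_low <- colMeans(sim$dose[low_idx, , drop = FALSE]) / 2
  dh <- stats::rpois(m, config$bulk_depth_mean)
  dl <- stats::rpois(m, config$bulk_depth_mean)
  ah <- stats::rbinom(m, dh, perturb(freq_high))
  al <- stats::rbinom(m, dl, perturb(freq_low))

  qual <- stats::runif(m, 100, 1000)
  qd <- stats::runif(m, 10, 35)
  fs <- stats::runif(m, 0, 10)
  mq <- stats::runif(m, 55, 60)
  planted <- stats::rbinom(m, 1L, config$violation_fraction) == 1L
  which_metric <- sample(4L, m, replace = TRUE)
  qual[planted & which_metric == 1L] <-
    stats::runif(sum(planted & which_metric == 1L), 0, 29.9)
  qd[planted & which_metric == 2L] <-
    stats::runif(sum(planted & which_metric == 2L), 0, 1.9)
  fs[planted & which_metric == 3L] <-
    stats::runif(sum(planted & which_metric == 3L), 60.1, 200)
  mq[planted & which_metric == 4L] <-
    stats::runif(sum(planted & which_metric == 4L), 0, 39.9)

  out <- data.frame(
    chrom = sim$markers$chrom, pos = sim$markers$pos,
    ref = sim$markers$ref, alt = sim$markers$alt,
    gt_male = sim$markers$gt_male, gt_female = sim$markers$gt_female,
    ref_high = dh - ah, alt_high = ah,
    ref_low = dl - al, alt_low = al,
    qual = qual, qd = qd, fs = fs, mq = mq,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "planted_violations") <- planted[order(sim$markers$chrom,
                                                   sim$markers$pos)]
  out
}

#' Run a complete synthetic bulked-segregant experiment
#'
#' Orchestrates [simulate_parents_and_f1()], [simulate_trait()], phenotype
#' construction (stem and bast weights consistent with the trait),
#' [select_bulks()] and [simulate_pooled_reads()].
#'
#' @param config a [sim_config()].
#' @return list of class `bsa_sim` with `config`, `markers`, `dose`,
#'   `trait`, `phenotypes`, `bulks`, `records`, `truth`.
#' @examples
#' sim <- simulate_bsa_experiment(sim_config(n_markers = 100, seed = 42))
#' head(sim$records)
#' @export
simulate_bsa_experiment <- function(config = sim_config()) {
  sim <- simulate_parents_and_f1(config)
  trait <- simulate_trait(sim$dose[, sim$truth$causal_index], config)
  set.seed(derive_seed(config$seed, 41L))
  stem <- stats::rnorm(config$n_plants, 600, 60)
  stem <- pmax(stem, 100)
  phen <- data.frame(
    plant_id = sprintf("plant_%d", seq_len(config$n_plants)),
    stem_weight_g = stem,
    bast_weight_g = stem * trait / 100,
    stringsAsFactors = FALSE
  )
  phen$fiber_content <- fiber_content(phen$stem_weight_g,
                                      phen$bast_weight_g)
  bulks <- select_bulks(phen, bulk_size = config$bulk_size)
  records <- simulate_pooled_reads(sim, bulks, config)

  high_idx <- as.integer(sub("^plant_", "", bulks$high_ids))
  low_idx <- as.integer(sub("^plant_", "", bulks$low_ids))
  ci <- sim$truth$causal_index
  truth <- c(sim$truth, list(
    expected_delta_causal =
      mean(sim$dose[high_idx, ci]) / 2 - mean(sim$dose[low_idx, ci]) / 2
  ))
  structure(list(
    config = config, markers = sim$markers, dose = sim$dose,
    trait = trait, phenotypes = phen, bulks = bulks,
    records = records, truth = truth
  ), class = "bsa_sim")
}

#' @export
print.bsa_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic F1 BSA experiment: %d plants, %d markers on %d chromosome(s)\n",
    x$config$n_plants, x$config$n_markers, x$config$n_chroms))
  cat(sprintf("  causal locus: %s:%d (effect %.2f, trait sd %.2f)\n",
              x$truth$causal_chrom, x$truth$causal_pos,
              x$config$causal_effect, x$config$trait_sd))
  cat(sprintf("  expected delta at causal site: %.3f\n",
              x$truth$expected_delta_causal))
  invisible(x)
}

#' Random genome with planted restriction sites
#'
#' Builds a motif-free random background and plants enzyme recognition
#' sites so that the distances between consecutive cut positions — hence
#' the internal fragment lengths — are exactly the requested values. Used
#' to construct digestion fixtures with a known answer.
#'
#' @param internal_lengths lengths (bp) of the internal cut-to-cut
#'   fragments, in order.
#' @param enzymes enzymes to alternate at the junctions (built-ins by
#'   default).
#' @param pad_left,pad_right motif-free padding before the first and after
#'   the last cut site (defaults 200).
#' @param seed RNG seed.
#' @return a list with `seq` (the genome string), `cut_positions` (0-based)
#'   and `fragment_lengths` as planted.
#' @export
random_genome_with_sites <- function(internal_lengths,
                                     enzymes = slaf_enzymes(),
                                     pad_left = 200, pad_right = 200,
                                     seed = 1) {
  enzymes <- as_enzyme_list(enzymes)
  set.seed(seed)
  motifs <- vapply(enzymes, function(e) e$recognition, character(1))
  offsets <- vapply(enzymes, function(e) e$cut_offset, integer(1))
  stopifnot(all(internal_lengths >= max(nchar(motifs))))

  motif_free <- function(n) {
    if (n <= 0L) return("")
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    repeat {
      hit <- regexpr(paste(motifs, collapse = "|"), s)
      if (hit == -1L) return(s)
      # disrupt the motif by flipping its second base
      i <- as.integer(hit) + 1L
      old <- substr(s, i, i)
      substr(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
  }
  k <- length(internal_lengths) + 1L  # number of cut sites
  which_enzyme <- rep_len(seq_along(enzymes), k)
  # motif start positions: cut j at p_j + offset; distances between
  # consecutive cuts must equal internal_lengths
  cut_pos <- integer(k)
  cut_pos[1] <- pad_left + offsets[which_enzyme[1]]
  if (k > 1L) {
    cut_pos[-1] <- cut_pos[1] + cumsum(internal_lengths)
  }
  motif_start <- cut_pos - offsets[which_enzyme]
  pieces <- character(0)
  cursor <- 0L
  for (j in seq_len(k)) {
    gap <- motif_start[j] - cursor
    stopifnot(gap >= 0L)
    pieces <- c(pieces, motif_free(gap), motifs[which_enzyme[j]])
    cursor <- motif_start[j] + nchar(motifs[which_enzyme[j]])
  }
  pieces <- c(pieces, motif_free(pad_right))
  genome <- paste(pieces, collapse = "")
  # planted motifs can abut filler and create chance motifs at the seams;
  # verify and report the realized cut set instead of assuming
  realized <- find_cut_sites(genome, enzymes)
  list(seq = genome, cut_positions = cut_pos,
       fragment_lengths = internal_lengths,
       realized_cut_positions = realized$pos)
}

#' Write simulation fixtures to disk
#'
#' Emits the standard-format files that exercise every pipeline reader:
#' `genome.fa` (a small genome with planted cut sites), `genes.gff3`
#' (random non-overlapping genes on the marker chromosomes),
#' `variants.vcf` (parents + bulks with AD and QD/FS/MQ), `phenotypes.tsv`
#' and `truth.json`.
#'
#' @param sim a `bsa_sim` from [simulate_bsa_experiment()].
#' @param out_dir output directory; must be empty or absent unless
#'   `force = TRUE`.
#' @param n_genes number of random genes to emit (default 50).
#' @param force overwrite a non-empty directory.
#' @return named character vector of the written paths.
#' @export
emit_fixtures <- function(sim, out_dir, n_genes = 50, force = FALSE) {
  stopifnot(inherits(sim, "bsa_sim"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force) {
    stop("out_dir exists and is not empty; use force = TRUE to overwrite")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(sim$config$seed, 53L))

  fasta <- file.path(out_dir, "genome.fa")
  g <- random_genome_with_sites(
    internal_lengths = c(320, 500, 340, 120, 360, 900, 314),
    seed = derive_seed(sim$config$seed, 59L)
  )
  seqs <- Biostrings::DNAStringSet(g$seq)
  names(seqs) <- "toy_digest_chr"
  Biostrings::writeXStringSet(seqs, fasta)

  gff <- file.path(out_dir, "genes.gff3")
  genes <- random_gene_models(sim$markers, n_genes)
  write_gene_models_gff3(genes, gff)

  vcf <- file.path(out_dir, "variants.vcf")
  write_sim_vcf(sim$records, vcf)

  phen <- file.path(out_dir, "phenotypes.tsv")
  utils::write.table(
    sim$phenotypes[c("plant_id", "stem_weight_g", "bast_weight_g")],
    phen, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- file.path(out_dir, "truth.json")
  truth_obj <- list(
    causal_chrom = sim$truth$causal_chrom,
    causal_pos = sim$truth$causal_pos,
    causal_index = sim$truth$causal_index,
    expected_delta_causal = sim$truth$expected_delta_causal,
    high_ids = sim$bulks$high_ids,
    low_ids = sim$bulks$low_ids,
    seed = sim$config$seed,
    digest_fixture = list(
      fragment_lengths = g$fragment_lengths,
      cut_positions = g$cut_positions
    )
  )
  jsonlite::write_json(truth_obj, truth, auto_unbox = TRUE, digits = NA)

  c(fasta = fasta, gff = gff, vcf = vcf, phenotypes = phen, truth = truth)
}

# Random non-overlapping genes covering the marker span of each chromosome.
random_gene_models <- function(markers, n_genes) {
  chroms <- unique(markers$chrom)
  per <- diff(round(seq(0, n_genes, length.out = length(chroms) + 1L)))
  out <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    k <- per[i]
    if (k == 0L) return(NULL)
    span <- range(markers$pos[markers$chrom == chroms[i]])
    slots <- seq(span[1], span[2], length.out = k + 1L)
    width <- pmax(floor(diff(slots) * 0.4), 50)
    start <- floor(slots[-length(slots)])
    data.frame(
      gene_id = sprintf("%s_gene%03d", chroms[i], seq_len(k)),
      chrom = chroms[i],
      start = as.integer(start),
      end = as.integer(start + width),
      strand = sample(c("+", "-"), k, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  out
}

# Gene models (0-based half-open) -> GFF3 via rtracklayer.
write_gene_models_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$source <- "slafbsa_sim"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# SNP records -> minimal VCFv4.2 with GT:AD for parents (R01, R02) and
# bulks (aa, ab). Round-trips through read_snp_vcf().
write_sim_vcf <- function(records, path) {
  gt_code <- function(gt, ref, alt) {
    vapply(seq_along(gt), function(i) {
      if (is.na(gt[i]) || gt[i] %in% c("./.", ".", ".|.")) return("./.")
      alleles <- strsplit(gt[i], "[/|]")[[1]]
      codes <- match(alleles, c(ref[i], strsplit(alt[i], ",")[[1]])) - 1L
      if (any(is.na(codes))) return("./.")
      paste(codes, collapse = "/")
    }, character(1))
  }
  # parents reported as genotype calls with token depths split evenly
  parent_ad <- function(code) {
    vapply(code, function(g) {
      if (g == "./.") return(".")
      a <- as.integer(strsplit(g, "/")[[1]])
      ref_d <- sum(a == 0L) * 5L
      alt_d <- sum(a > 0L) * 5L
      paste(ref_d, alt_d, sep = ",")
    }, character(1), USE.NAMES = FALSE)
  }
  gm <- gt_code(records$gt_male, records$ref, records$alt)
  gf <- gt_code(records$gt_female, records$ref, records$alt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=slafbsa_sim",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "R01\tR02\taa\tab")
  )
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%.2f\t.\tQD=%.2f;FS=%.2f;MQ=%.2f\tGT:AD\t%s:%s\t%s:%s\t./.:%d,%d\t./.:%d,%d",
    records$chrom, records$pos, records$ref, records$alt, records$qual,
    records$qd, records$fs, records$mq,
    gm, parent_ad(gm), gf, parent_ad(gf),
    records$ref_high, records$alt_high, records$ref_low, records$alt_low
  )
  writeLines(c(header, body), path)
  invisible(path)
}
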