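#' Define a restriction enzyme
#'
#' A restriction enzyme is described by its recognition motif (IUPAC letters,
#' uppercase) and the cut offset: the number of bases from the start of the
#' motif to the cut position on the top strand. Both built-in enzymes used
#' for SLAF library design, RsaI (GT^AC) and HaeIII (GG^CC), are blunt
#' cutters with palindromic 4-base motifs, so a forward-strand scan finds
#' every site.
#'
#' @param name enzyme name.
#' @param recognition recognition motif, uppercase IUPAC DNA letters.
#' @param cut_offset integer offset of the cut from the motif start,
#'   `0 <= cut_offset <= nchar(recognition)`.
#' @return an object of class `enzyme_spec`.
#' @examples
#' restriction_enzyme("RsaI", "GTAC", 2L)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(recognition) || length(recognition) != 1L ||
      !nzchar(recognition)) {
    stop("recognition motif must be a non-empty string")
  }
  if (grepl(sprintf("[^%s]", paste(names(IUPAC_EXPANSION), collapse = "")),
            recognition)) {
    stop("recognition motif must use uppercase IUPAC letters")
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("cut_offset must lie within the motif (0..motif length)")
  }
  structure(
    list(name = name, recognition = recognition, cut_offset = cut_offset),
    class = "enzyme_spec"
  )
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme %s: %s, cut at +%d>\n",
              x$name, x$recognition, x$cut_offset))
  invisible(x)
}

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Built-in SLAF enzymes
#'
#' The double-digest combination used for SLAF tag prediction: RsaI (GTAC,
#' blunt, cut after position 2) and HaeIII (GGCC, blunt, cut after
#' position 2).
#'
#' @param names character vector of enzyme names to return; default both.
#' @return a named list of `enzyme_spec` objects.
#' @export
slaf_enzymes <- function(names = c("RsaI", "HaeIII")) {
  builtin <- list(
    RsaI   = restriction_enzyme("RsaI",   "GTAC", 2L),
    HaeIII = restriction_enzyme("HaeIII", "GGCC", 2L)
  )
  missing <- setdiff(names, names(builtin))
  if (length(missing)) {
    stop("unknown built-in enzyme(s): ", paste(missing, collapse = ", "))
  }
  builtin[names]
}

as_enzyme_list <- function(enzymes) {
  if (inherits(enzymes, "enzyme_spec")) enzymes <- list(enzymes)
  if (is.character(enzymes)) enzymes <- slaf_enzymes(enzymes)
  stopifnot(all(vapply(enzymes, inherits, logical(1), "enzyme_spec")))
  enzymes
}

#' Find restriction cut sites in a sequence
#'
#' Scans the forward strand for every occurrence of each enzyme's
#' recognition motif and reports the cut position (0-based, counted from the
#' sequence start: `match_start + cut_offset`). Matching is case-insensitive
#' and IUPAC ambiguity codes in the motif expand to their base sets; `N` in
#' the subject sequence never matches. For palindromic motifs such as GTAC
#' and GGCC the forward scan is complete — the reverse strand contributes no
#' additional sites.
#'
#' @param seq a DNA sequence: a single character string or a
#'   [Biostrings::DNAString].
#' @param enzymes a list of [restriction_enzyme()] objects, a character
#'   vector of built-in names, or a single `enzyme_spec`.
#' @return a data.frame with columns `pos` (0-based cut position) and
#'   `enzyme`, sorted by position.
#' @examples
#' find_cut_sites("AAGTACAA", slaf_enzymes("RsaI"))
#' @export
find_cut_sites <- function(seq, enzymes) {
  if (methods::is(seq, "DNAString") || methods::is(seq, "BString")) {
    seq <- as.character(seq)
  }
  seq <- normalize_dna(seq)
  enzymes <- as_enzyme_list(enzymes)
  if (nchar(seq) == 0L) {
    return(data.frame(pos = integer(0), enzyme = character(0)))
  }
  subject <- Biostrings::DNAString(seq)
  out <- lapply(enzymes, function(e) {
    ambiguous <- grepl("[^ACGT]", e$recognition)
    m <- Biostrings::matchPattern(
      e$recognition, subject,
      # fixed pattern for plain motifs; expand IUPAC codes otherwise while
      # keeping the subject literal so N never matches.
      fixed = if (ambiguous) "subject" else TRUE
    )
    starts <- BiocGenerics::start(m)  # 1-based
    if (length(starts) == 0L) {
      return(data.frame(pos = integer(0), enzyme = character(0)))
    }
    data.frame(pos = starts - 1L + e$cut_offset, enzyme = e$name,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$pos, res$enzyme), , drop = FALSE]
  rownames(res) <- NULL
  res
}
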