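#' Fiber content from stem and bast weights
#'
#' Fiber content (percent) = bast fiber weight / stem weight x 100. Both
#' weights are fresh weights in grams; the bast is the phloem fiber peeled
#' from the stem, so it can never outweigh the stem it came from.
#'
#' @param stem_weight stem weight in grams, strictly positive.
#' @param bast_weight bast fiber weight in grams, `0 <= bast <= stem`.
#' @return fiber content in percent, vectorized.
#' @examples
#' fiber_content(100, 25)  # 25
#' @export
fiber_content <- function(stem_weight, bast_weight) {
  if (any(is.na(stem_weight)) || any(is.na(bast_weight))) {
    stop("weights must not be missing")
  }
  if (any(stem_weight <= 0)) stop("stem_weight must be > 0")
  if (any(bast_weight < 0)) stop("bast_weight must be >= 0")
  if (any(bast_weight > stem_weight)) {
    stop("bast_weight cannot exceed stem_weight")
  }
  bast_weight / stem_weight * 100
}

#' Read a phenotype table
#'
#' Headered TSV with columns `plant_id`, `stem_weight_g`, `bast_weight_g`;
#' fiber content is (re)computed from the weights.
#'
#' @param path TSV file path.
#' @return data.frame with `plant_id`, `stem_weight_g`, `bast_weight_g`,
#'   `fiber_content`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("plant_id", "stem_weight_g", "bast_weight_g")
  if (!all(req %in% names(df))) {
    stop("phenotype table needs columns: ", paste(req, collapse = ", "))
  }
  df$plant_id <- as.character(df$plant_id)
  df$fiber_content <- fiber_content(df$stem_weight_g, df$bast_weight_g)
  df
}

#' Select extreme high/low bulks
#'
#' Ranks plants by fiber content (or any trait column) and takes the top
#' `bulk_size` as the high bulk and the bottom `bulk_size` as the low bulk.
#' Ties are broken by `plant_id` in lexicographic order, which makes the
#' assignment invariant to input row order.
#'
#' @param phenotypes data.frame with `plant_id` and a trait column.
#' @param bulk_size plants per bulk (default 30).
#' @param trait name of the trait column (default `"fiber_content"`).
#' @return an object of class `bulk_assignment`: list with `high_ids`,
#'   `low_ids`, `bulk_size`, and the trait ranges of each bulk.
#' @examples
#' ph <- data.frame(plant_id = paste0("p", 1:5),
#'                  fiber_content = c(10, 20, 30, 40, 50))
#' select_bulks(ph, bulk_size = 2)
#' @export
select_bulks <- function(phenotypes, bulk_size = 30,
                         trait = "fiber_content") {
  stopifnot(is.data.frame(phenotypes),
            all(c("plant_id", trait) %in% names(phenotypes)))
  bulk_size <- as.integer(bulk_size)
  n <- nrow(phenotypes)
  if (n < 2L * bulk_size) {
    stop(sprintf("need at least %d plants for two bulks of %d, got %d",
                 2L * bulk_size, bulk_size, n))
  }
  if (anyDuplicated(phenotypes$plant_id)) stop("duplicate plant_id values")
  id <- as.character(phenotypes$plant_id)
  y <- phenotypes[[trait]]
  # one total order guarantees disjoint bulks even under massive ties
  ord <- order(-y, id)
  high_ids <- id[ord][seq_len(bulk_size)]
  low_sel <- ord[seq.int(n - bulk_size + 1L, n)]
  low_ids <- id[low_sel][order(y[low_sel], id[low_sel])]
  if (min(y[match(high_ids, id)]) <= max(y[match(low_ids, id)])) {
    warning("high and low bulks are not separated in ", trait,
            " (ties at the selection boundary)")
  }
  structure(list(
    high_ids = high_ids,
    low_ids = low_ids,
    bulk_size = bulk_size,
    high_range = range(y[match(high_ids, id)]),
    low_range = range(y[match(low_ids, id)]),
    trait = trait
  ), class = "bulk_assignment")
}

#' @export
print.bulk_assignment <- function(x, ...) {
  cat(sprintf("Bulk assignment (%d + %d plants, trait: %s)\n",
              x$bulk_size, x$bulk_size, x$trait))
  cat(sprintf("  high bulk: %.2f - %.2f\n", x$high_range[1], x$high_range[2]))
  cat(sprintf("  low bulk:  %.2f - %.2f\n", x$low_range[1], x$low_range[2]))
  invisible(x)
}

#' Write a bulk assignment as TSV
#'
#' Two columns: `plant_id`, `bulk` (`high`/`low`), one row per selected
#' plant.
#'
#' @param assignment a `bulk_assignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bulks <- function(assignment, path) {
  df <- data.frame(
    plant_id = c(assignment$high_ids, assignment$low_ids),
    bulk = rep(c("high", "low"), each = assignment$bulk_size)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
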