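#' Rarefy a count table to a common depth
#'
#' Draws `depth` reads per sample *without replacement* (multivariate
#' hypergeometric): "random selection" of reads from a finite sample is
#' subsampling without replacement, not a multinomial redraw. Samples whose
#' total is below `depth` cannot be rarefied and are dropped; the drop
#' report is attached as the `"dropped"` attribute. A sample whose total
#' equals `depth` is returned unchanged.
#'
#' @param x an [abundance_table()] of counts (whole numbers).
#' @param depth target reads per retained sample (> 0).
#' @param seed integer seed for the random draws.
#' @return an [abundance_table()] of counts whose retained columns all sum
#'   to `depth`; attribute `"dropped"` is a data.frame (`sample_id`,
#'   `total`) of the excluded samples.
#' @export
rarefy <- function(x, depth, seed = 1L) {
  stopifnot(inherits(x, "abundance_table"))
  if (unit_kind(x) != "counts") stop("rarefy needs a counts table", call. = FALSE)
  depth <- as.numeric(depth)
  if (length(depth) != 1L || is.na(depth) || depth <= 0) {
    stop("depth must be a positive integer", call. = FALSE)
  }
  vals <- unclass(x)
  if (any(vals != round(vals))) stop("counts must be whole numbers", call. = FALSE)
  totals <- colSums(vals)
  drop <- totals < depth
  dropped <- data.frame(sample_id = colnames(vals)[drop], total = totals[drop],
                        row.names = NULL, stringsAsFactors = FALSE)
  kept <- vals[, !drop, drop = FALSE]
  if (ncol(kept)) {
    set.seed(seed)
    # vegan's rrarefy works on a samples-by-taxa community matrix; its
    # "observed counts" heuristic warning is spurious here because whole
    # numbers and depth <= totals are already guaranteed above
    kept <- withCallingHandlers(
      t(vegan::rrarefy(t(kept), depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  out <- abundance_table(kept, unit_kind = "counts")
  attr(out, "dropped") <- dropped
  out
}

#' Remove whole-dataset singleton taxa
#'
#' Drops exactly those taxa whose total count across *all* samples is 1,
#' i.e. taxa present in a single sample with a single read. A taxon with one
#' read in each of two samples (total 2) is retained.
#'
#' @param x an [abundance_table()] of counts.
#' @return the filtered [abundance_table()]; attribute `"removed"` lists the
#'   dropped taxon ids.
#' @export
filter_singletons <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (unit_kind(x) != "counts") stop("singleton filter needs a counts table", call. = FALSE)
  totals <- rowSums(unclass(x))
  keep <- totals != 1
  out <- x[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(x)[!keep]
  out
}

#' Diversity indices of one sample (or every sample of a table)
#'
#' Three indices: richness `N0` (number of taxa with abundance > 0),
#' Shannon entropy `H = -sum(Pi * log(Pi))` in natural log, and Shannon
#' evenness `E = exp(H) / N0`. `Pi` is the proportion of taxon i among the
#' positive abundances, so all three indices are invariant to rescaling a
#' sample by a positive constant, and the natural log is forced by the
#' identity `E = exp(H)/N0 <= 1`.
#'
#' @param x a non-negative numeric vector with at least one positive entry,
#'   or an [abundance_table()] (one result row per sample).
#' @return for a vector, a one-row data.frame with `N0`, `H`, `E`;
#'   for a table, a data.frame with a `sample_id` column.
#' @export
diversity_indices <- function(x) {
  if (inherits(x, "abundance_table")) {
    rows <- lapply(seq_len(ncol(x)), function(j) diversity_indices(unclass(x)[, j]))
    out <- do.call(rbind, rows)
    return(cbind(data.frame(sample_id = colnames(x), stringsAsFactors = FALSE), out))
  }
  if (!is.numeric(x) || any(x < 0) || anyNA(x)) {
    stop("abundances must be non-negative numbers", call. = FALSE)
  }
  pos <- x[x > 0]
  if (!length(pos)) stop("all-zero sample: diversity is undefined", call. = FALSE)
  n0 <- length(pos)
  h <- as.numeric(vegan::diversity(pos, index = "shannon"))
  data.frame(N0 = n0, H = h, E = exp(h) / n0)
}
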