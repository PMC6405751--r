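#' Published land-use group means (reference table)
#'
#' Group means of diversity indices and network metrics reported by a
#' national-scale soil survey comparing bacterial communities across four
#' land uses (forest, grassland, crop system, vineyards; 100 replicate
#' networks of 30 sites each). Used for reporting arithmetic -- percent
#' reductions along the land-use gradient and the evenness identity
#' `E = exp(H) / N0` -- not as test data for the inference pipeline, whose
#' inputs are synthetic.
#'
#' @return data.frame with columns `metric`, `forest`, `grassland`, `crop`,
#'   `vineyards`.
#' @export
reference_group_means <- function() {
  path <- system.file("extdata", "landuse_reference_means.tsv", package = "occnet",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
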