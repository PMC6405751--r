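#' Pipeline configuration
#'
#' Bundles every tunable of the replicated network pipeline so that a single
#' document (echoed as YAML next to each output) records the full provenance
#' of a run.
#'
#' @param alpha per-network significance level applied to BH-adjusted
#'   p-values (default 0.05).
#' @param min_abs_rho optional absolute-correlation floor for edges. The
#'   default `NULL` applies no floor: at 30 samples the p-threshold alone
#'   already implies |rho| > 0.5 for surviving edges, so the floor is a
#'   consequence, not an independent filter.
#' @param k_subsample number of samples drawn per network replicate
#'   (default 30, the standardized subsample size).
#' @param n_replicates number of replicate networks per group (default 100).
#' @param rarefaction_depth reads per sample after rarefaction
#'   (default 10000).
#' @param connectance_convention,degree_convention,path_convention
#'   denominator/normalization conventions, see [connectance()],
#'   [average_degree()], [average_path_length()].
#' @param rng_seed master seed; per-group child seeds are derived by a fixed
#'   counter scheme so results do not depend on execution order.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05,
                            min_abs_rho = NULL,
                            k_subsample = 30L,
                            n_replicates = 100L,
                            rarefaction_depth = 10000L,
                            connectance_convention = c("ordered_panel",
                                                       "unordered_panel",
                                                       "unordered_present"),
                            degree_convention = c("two_l_over_panel",
                                                  "l_over_panel",
                                                  "two_l_over_present",
                                                  "l_over_present"),
                            path_convention = c("global_efficiency",
                                                "mean_geodesic_connected_pairs"),
                            rng_seed = 1L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (!is.null(min_abs_rho)) {
    stopifnot(is.numeric(min_abs_rho), min_abs_rho >= 0, min_abs_rho <= 1)
  }
  k_subsample <- as.integer(k_subsample)
  n_replicates <- as.integer(n_replicates)
  rarefaction_depth <- as.integer(rarefaction_depth)
  if (k_subsample < 3L) stop("k_subsample must be >= 3", call. = FALSE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (rarefaction_depth < 1L) stop("rarefaction_depth must be >= 1", call. = FALSE)
  structure(list(alpha = alpha,
                 min_abs_rho = min_abs_rho,
                 k_subsample = k_subsample,
                 n_replicates = n_replicates,
                 rarefaction_depth = rarefaction_depth,
                 connectance_convention = match.arg(connectance_convention),
                 degree_convention = match.arg(degree_convention),
                 path_convention = match.arg(path_convention),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path `.yaml` path written by [write_config()].
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

# Fixed counter scheme deriving child seeds from a master seed. Keeps every
# derived seed a valid 32-bit integer and makes replicate streams independent
# of execution order.
seed_child <- function(master, i, j = 0L) {
  as.integer((as.double(master) + 1000003 * as.double(i) + 7919 * as.double(j)) %%
               2147483647)
}
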