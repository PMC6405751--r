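#' Design replicated standardized subsamples of a site pool
#'
#' Draws `R` *distinct* subsets of `k` sites, uniformly over all
#' `choose(n, k)` possibilities, by rejection sampling on a canonical
#' sorted-tuple key. Standardizing `k` across groups removes the sampling
#' size effect on network inference; drawing many replicates integrates the
#' within-group heterogeneity of the sites.
#'
#' @param site_pool character vector of available sample ids.
#' @param k subset size.
#' @param R number of replicates; must not exceed `choose(length(site_pool), k)`.
#' @param seed integer seed.
#' @return a `replicate_design`: list with `site_pool`, `k`, `R`, `subsets`
#'   (list of `R` sorted id vectors), `seed`, `coverage` (fraction of the
#'   pool appearing in at least one subset) and `n_possible`
#'   (`choose(n, k)`).
#' @export
design_replicates <- function(site_pool, k, R, seed = 1L) {
  site_pool <- as.character(site_pool)
  if (anyDuplicated(site_pool)) stop("site_pool has duplicate ids", call. = FALSE)
  k <- as.integer(k)
  R <- as.integer(R)
  n <- length(site_pool)
  if (k < 1L || k > n) stop("k must be between 1 and the pool size", call. = FALSE)
  n_possible <- choose(n, k)
  if (n_possible < R) {
    stop(sprintf("cannot draw %d distinct subsets: only %s are possible with %d sites and k = %d",
                 R, format(n_possible, big.mark = ",", scientific = FALSE), n, k),
         call. = FALSE)
  }
  set.seed(seed)
  subsets <- vector("list", R)
  seen <- character(R)
  i <- 0L
  tries <- 0L
  max_tries <- 1000L + 100L * R
  while (i < R) {
    tries <- tries + 1L
    if (tries > max_tries) stop("rejection sampling failed to find distinct subsets",
                                call. = FALSE)
    s <- sort(sample(site_pool, k))
    key <- paste(s, collapse = "\r")
    if (key %in% seen[seq_len(i)]) next
    i <- i + 1L
    subsets[[i]] <- s
    seen[i] <- key
  }
  structure(list(site_pool = site_pool, k = k, R = R, subsets = subsets,
                 seed = seed,
                 coverage = length(unique(unlist(subsets))) / n,
                 n_possible = n_possible),
            class = "replicate_design")
}

#' @export
print.replicate_design <- function(x, ...) {
  cat(sprintf("replicate_design: %d subsets of %d sites from a pool of %d (coverage %.1f%%, seed %d)\n",
              x$R, x$k, length(x$site_pool), 100 * x$coverage, x$seed))
  invisible(x)
}

#' Run the replicated network pipeline over all groups
#'
#' For every group and each of its `n_replicates` subsets of `k_subsample`
#' samples: subset the table's columns, infer one network
#' ([build_network()]) on the full-table taxon panel, compute the seven
#' topology metrics and the per-sample diversity indices averaged over the
#' subset, and record every node's degree. Per-group subset designs are
#' seeded by child seeds derived from `config$rng_seed`, so groups are
#' independent and the run is reproducible regardless of execution order.
#'
#' @param x an [abundance_table()] (counts or relative abundances; Spearman
#'   inference is invariant to per-sample closure at equal depth).
#' @param metadata data.frame `sample_id`, `group` covering every column
#'   of `x`.
#' @param config a [pipeline_config()].
#' @param groups groups to analyze, default all in `metadata` (in order of
#'   first appearance).
#' @return list with `metrics` (one row per group x replicate: the seven
#'   metrics plus mean `N0`, `H`, `E`), `degrees` (long data.frame `group`,
#'   `replicate`, `taxon`, `degree`), and `designs` (per-group
#'   [design_replicates()] objects).
#' @export
run_replicated <- function(x, metadata, config = pipeline_config(),
                           groups = unique(metadata$group)) {
  stopifnot(inherits(x, "abundance_table"), inherits(config, "pipeline_config"))
  validate_samples(x, metadata)
  missing_groups <- setdiff(groups, metadata$group)
  if (length(missing_groups)) {
    stop("groups absent from metadata: ", paste(missing_groups, collapse = ", "),
         call. = FALSE)
  }
  panel <- rownames(x)
  div_all <- diversity_indices(x)
  rownames(div_all) <- div_all$sample_id

  metrics <- list()
  degrees <- list()
  designs <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    pool <- metadata$sample_id[metadata$group == g]
    des <- design_replicates(pool, config$k_subsample, config$n_replicates,
                             seed = seed_child(config$rng_seed, gi))
    designs[[g]] <- des
    for (r in seq_len(des$R)) {
      sub <- des$subsets[[r]]
      net <- build_network(x[, sub, drop = FALSE], panel = panel,
                           alpha = config$alpha, min_abs_rho = config$min_abs_rho)
      m <- network_metrics(net,
                           connectance_convention = config$connectance_convention,
                           degree_convention = config$degree_convention,
                           path_convention = config$path_convention)
      dv <- div_all[sub, c("N0", "H", "E")]
      metrics[[length(metrics) + 1L]] <- cbind(
        data.frame(group = g, replicate = r, stringsAsFactors = FALSE),
        m, data.frame(N0 = mean(dv$N0), H = mean(dv$H), E = mean(dv$E)))
      deg <- degree_table(net)
      degrees[[length(degrees) + 1L]] <- data.frame(
        group = g, replicate = r, taxon = names(deg), degree = unname(deg),
        stringsAsFactors = FALSE)
    }
  }
  list(metrics = do.call(rbind, metrics),
       degrees = do.call(rbind, degrees),
       designs = designs)
}

#' Percent change between two group means
#'
#' `100 * (1 - mean_to / mean_from)`: the percent reduction from `mean_from`
#' to `mean_to` (negative when the value increased). Summaries round to the
#' nearest integer.
#'
#' @param mean_from,mean_to the two means being compared.
#' @return a real percentage; `NA` when `mean_from` is 0.
#' @export
percent_change <- function(mean_from, mean_to) {
  ifelse(mean_from == 0, NA_real_, 100 * (1 - mean_to / mean_from))
}
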