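#' Link counts and the positive:negative ratio
#'
#' @param net a [signed_network()].
#' @return list with `L` (total links), `L_pos`, `L_neg`, and `pn_ratio`
#'   (`L_pos / L_neg`, `NA` -- never infinity -- when there are no negative
#'   links, so replicate-level ratios can be averaged safely).
#' @export
count_links <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  l_pos <- sum(net$edges$sign == "positive")
  l_neg <- sum(net$edges$sign == "negative")
  list(L = l_pos + l_neg, L_pos = l_pos, L_neg = l_neg,
       pn_ratio = if (l_neg == 0L) NA_real_ else l_pos / l_neg)
}

#' Connectance: realized fraction of potential links
#'
#' The denominator convention must be declared, because published values are
#' not always computed over unordered pairs:
#' `"unordered_panel"` uses `N(N-1)/2` potential links on the panel of `N`
#' nodes; `"ordered_panel"` uses `N(N-1)`; `"unordered_present"` restricts
#' `N` to non-isolated nodes.
#'
#' @param net a [signed_network()].
#' @param convention denominator convention.
#' @return a real in `[0, 1]`, or `NA` when fewer than 2 nodes qualify.
#' @export
connectance <- function(net, convention = c("unordered_panel", "ordered_panel",
                                            "unordered_present")) {
  stopifnot(inherits(net, "signed_network"))
  convention <- match.arg(convention)
  n <- if (convention == "unordered_present") {
    length(unique(c(net$edges$taxon_a, net$edges$taxon_b)))
  } else {
    length(net$panel)
  }
  if (n < 2L) return(NA_real_)
  l <- nrow(net$edges)
  denom <- if (convention == "ordered_panel") n * (n - 1) else n * (n - 1) / 2
  l / denom
}

#' Average degree of a network
#'
#' Degree of a node = number of incident edges. The handshake lemma gives
#' `sum(degree) = 2L`, so the standard mean degree is `2L / N`
#' (`"two_l_over_panel"`); the other conventions (`L/N`, and the `_present`
#' variants restricting `N` to non-isolated nodes) are offered because
#' published tables do not always state which normalization was used.
#'
#' @param net a [signed_network()].
#' @param convention numerator/denominator convention.
#' @return a non-negative real, `NA` on an empty panel.
#' @export
average_degree <- function(net, convention = c("two_l_over_panel", "l_over_panel",
                                               "two_l_over_present", "l_over_present")) {
  stopifnot(inherits(net, "signed_network"))
  convention <- match.arg(convention)
  present <- grepl("_present$", convention)
  n <- if (present) {
    length(unique(c(net$edges$taxon_a, net$edges$taxon_b)))
  } else {
    length(net$panel)
  }
  if (n == 0L) return(NA_real_)
  num <- if (grepl("^two_l", convention)) 2 * nrow(net$edges) else nrow(net$edges)
  num / n
}

#' Average path length of a network
#'
#' Paths are unweighted shortest paths on the signed graph (signs ignored
#' for reachability). Two conventions:
#' `"mean_geodesic_connected_pairs"` averages geodesic length over all
#' unordered pairs in the same component (`NA` when there are no edges);
#' `"global_efficiency"` averages `1/d` over *all* unordered panel pairs,
#' disconnected pairs contributing 0 (an edgeless network scores 0). Global
#' efficiency is bounded by 1 and *increases* with cohesion, which makes it
#' the convention compatible with published path-length values below 1 that
#' decrease as networks lose links.
#'
#' @param net a [signed_network()].
#' @param convention path-length convention.
#' @return a non-negative real (see conventions for the degenerate cases);
#'   `NA` when the panel has fewer than 2 nodes.
#' @export
average_path_length <- function(net,
                                convention = c("mean_geodesic_connected_pairs",
                                               "global_efficiency")) {
  stopifnot(inherits(net, "signed_network"))
  convention <- match.arg(convention)
  if (length(net$panel) < 2L) return(NA_real_)
  if (nrow(net$edges) == 0L) {
    return(if (convention == "global_efficiency") 0 else NA_real_)
  }
  d <- igraph::distances(as_igraph(net))
  ut <- d[upper.tri(d)]
  if (convention == "mean_geodesic_connected_pairs") {
    mean(ut[is.finite(ut)])
  } else {
    inv <- 1 / ut
    inv[!is.finite(inv)] <- 0
    mean(inv)
  }
}

#' Per-node degree table
#'
#' @param net a [signed_network()].
#' @return named integer vector over the full panel; isolated nodes report 0.
#' @export
degree_table <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  deg <- table(factor(c(net$edges$taxon_a, net$edges$taxon_b), levels = net$panel))
  stats::setNames(as.integer(deg), net$panel)
}

#' All seven topology metrics of one network
#'
#' @param net a [signed_network()].
#' @param connectance_convention,degree_convention,path_convention
#'   conventions, see the individual metric functions; defaults follow
#'   [pipeline_config()].
#' @return one-row data.frame: `L`, `L_pos`, `L_neg`, `pn_ratio`,
#'   `connectance`, `avg_path_length`, `avg_degree`, plus the three
#'   convention tags so every output records how it was computed.
#' @export
network_metrics <- function(net,
                            connectance_convention = "ordered_panel",
                            degree_convention = "two_l_over_panel",
                            path_convention = "global_efficiency") {
  cl <- count_links(net)
  data.frame(L = cl$L, L_pos = cl$L_pos, L_neg = cl$L_neg,
             pn_ratio = cl$pn_ratio,
             connectance = connectance(net, connectance_convention),
             avg_path_length = average_path_length(net, path_convention),
             avg_degree = average_degree(net, degree_convention),
             connectance_convention = connectance_convention,
             degree_convention = degree_convention,
             path_convention = path_convention,
             stringsAsFactors = FALSE)
}
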