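#' Construct a signed co-occurrence network
#'
#' An undirected graph on a fixed taxon panel. Each edge carries the Spearman
#' correlation `rho`, the FDR-adjusted p-value `q`, and a sign
#' (`"positive"` iff `rho > 0`). The panel is fixed before inference, so
#' isolated taxa (no significant correlation, or zero variance in the
#' subsample) stay part of the node set and enter connectance and degree
#' denominators.
#'
#' @param panel character vector: the ordered node set.
#' @param edges data.frame with columns `taxon_a`, `taxon_b`, `rho`, `q`
#'   (may have zero rows). Pairs are stored once, with
#'   `taxon_a < taxon_b` lexicographically.
#' @param alpha the significance level used at construction; every edge must
#'   satisfy `q < alpha`.
#' @return a `signed_network`: list with elements `panel` and `edges`
#'   (columns `taxon_a`, `taxon_b`, `rho`, `q`, `sign`), attribute `alpha`.
#' @export
signed_network <- function(panel, edges = NULL, alpha = 0.05) {
  panel <- as.character(panel)
  if (anyDuplicated(panel)) stop("panel has duplicated taxon ids", call. = FALSE)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(taxon_a = character(), taxon_b = character(),
                        rho = numeric(), q = numeric(), sign = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    need <- c("taxon_a", "taxon_b", "rho", "q")
    if (!all(need %in% colnames(edges))) {
      stop("edges need columns: ", paste(need, collapse = ", "), call. = FALSE)
    }
    a <- pmin(edges$taxon_a, edges$taxon_b)
    b <- pmax(edges$taxon_a, edges$taxon_b)
    edges$taxon_a <- a
    edges$taxon_b <- b
    if (any(a == b)) stop("self-edges are not allowed", call. = FALSE)
    key <- paste(a, b, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges", call. = FALSE)
    out <- !(a %in% panel) | !(b %in% panel)
    if (any(out)) {
      stop("edge endpoints outside the panel: ",
           paste(unique(c(a[out], b[out])), collapse = ", "), call. = FALSE)
    }
    if (any(abs(edges$rho) > 1 + 1e-12)) stop("rho outside [-1, 1]", call. = FALSE)
    if (any(edges$q >= alpha)) {
      stop("every edge must have q < alpha (", alpha, ")", call. = FALSE)
    }
    if (any(edges$rho == 0)) stop("edges with rho == 0 carry no sign", call. = FALSE)
    edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
    edges <- edges[order(edges$taxon_a, edges$taxon_b),
                   c("taxon_a", "taxon_b", "rho", "q", "sign")]
    rownames(edges) <- NULL
  }
  structure(list(panel = panel, edges = edges),
            alpha = alpha, class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  npos <- sum(x$edges$sign == "positive")
  cat(sprintf("signed_network: %d nodes, %d edges (%d positive, %d negative), alpha = %g\n",
              length(x$panel), nrow(x$edges), npos, nrow(x$edges) - npos,
              attr(x, "alpha")))
  invisible(x)
}

#' Convert a signed network to an igraph graph
#'
#' Vertices are the full panel (isolated nodes included); edges carry
#' `rho`, `q` and `sign` attributes and the graph carries `alpha`.
#'
#' @param net a [signed_network()].
#' @return an undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$panel))
  igraph::graph_attr(g, "alpha") <- attr(net, "alpha")
  g
}

#' Write a network edge list as TSV
#'
#' Columns `taxon_a`, `taxon_b`, `rho`, `q`, `sign`; each unordered pair is
#' written once, `taxon_a < taxon_b` lexicographically. `rho` and `q` are
#' written at full precision (`%.17g`) so a round trip is value-exact.
#' An empty network yields a header-only file.
#'
#' @param net a [signed_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "signed_network"))
  e <- net$edges
  out <- data.frame(taxon_a = e$taxon_a, taxon_b = e$taxon_b,
                    rho = sprintf("%.17g", e$rho), q = sprintf("%.17g", e$q),
                    sign = e$sign, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network edge list written by [write_edge_list()]
#'
#' The TSV carries no panel information, so isolated nodes are recovered only
#' if `panel` is supplied (GraphML keeps them; see [read_graphml()]).
#'
#' @param path edge-list TSV path.
#' @param panel optional node set; defaults to the union of edge endpoints.
#' @param alpha significance level of the original construction.
#' @return a [signed_network()].
#' @export
read_edge_list <- function(path, panel = NULL, alpha = 0.05) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric",
                                         "numeric", "character"))
  if (is.null(panel)) panel <- sort(unique(c(df$taxon_a, df$taxon_b)))
  signed_network(panel, df, alpha = alpha)
}

#' Export a signed network as GraphML
#'
#' Keeps the full panel (isolated nodes included) and all edge attributes,
#' so the GraphML round trip is lossless up to numeric precision.
#'
#' @param net a [signed_network()].
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file written by [write_graphml()]
#' @param path `.graphml` path.
#' @return a [signed_network()].
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  alpha <- igraph::graph_attr(g, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  e <- igraph::as_data_frame(g, what = "edges")
  edges <- if (nrow(e)) {
    data.frame(taxon_a = e$from, taxon_b = e$to, rho = e$rho, q = e$q,
               stringsAsFactors = FALSE)
  } else NULL
  signed_network(igraph::V(g)$name, edges, alpha = alpha)
}
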