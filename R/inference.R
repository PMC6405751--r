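#' Spearman rank correlation with a t-approximation p-value
#'
#' `rho` is the Pearson correlation of the average-tie rank vectors. The
#' two-sided p-value uses `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom -- the approximation that stays tractable when
#' hundreds of thousands of pairs are tested per network. For small-n
#' validation an exact permutation p-value is available
#' (`method = "permutation"`).
#'
#' @param x,y equal-length numeric vectors (n >= 3), each with at least two
#'   distinct values.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm number of permutations when `method = "permutation"`; the
#'   p-value is `(1 + #{|rho*| >= |rho|}) / (1 + n_perm)`.
#' @param seed seed for the permutation draw.
#' @return list with `rho` and `p`.
#' @export
spearman <- function(x, y, method = c("t", "permutation"), n_perm = 1000L,
                     seed = 1L) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("zero-variance input: Spearman correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (method == "t") {
    spearman_p(rho, n)
  } else {
    set.seed(seed)
    rx <- rank(x)
    ry <- rank(y)
    hits <- sum(vapply(seq_len(n_perm), function(b) {
      abs(stats::cor(rx, sample(ry))) >= abs(rho) - 1e-12
    }, logical(1L)))
    (1 + hits) / (1 + n_perm)
  }
  list(rho = rho, p = p)
}

# Two-sided p from the t-approximation; rho of +/-1 maps to p = 0.
spearman_p <- function(rho, n) {
  denom <- 1 - rho^2
  p <- ifelse(denom <= 0, 0,
              2 * stats::pt(-abs(rho * sqrt((n - 2) / pmax(denom, 1e-300))), n - 2))
  pmin(p, 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with the p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order. An empty input returns an empty vector.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

# All-pairs Spearman on the rows of a taxa-by-samples matrix: rank each row
# (average ties), Pearson-correlate the rank rows. Returns the taxa x taxa
# rho matrix.
spearman_matrix <- function(values) {
  ranks <- t(apply(values, 1L, rank))
  cr <- stats::cor(t(ranks))
  cr[cr > 1] <- 1
  cr[cr < -1] <- -1
  cr
}

#' Infer one signed co-occurrence network from an abundance table
#'
#' For every unordered pair of taxa with nonzero variance across the given
#' samples, computes the Spearman correlation and its p-value, applies a
#' Benjamini-Hochberg adjustment *once over all tested pairs of this
#' network*, and keeps an edge iff `q < alpha` (and `|rho| >= min_abs_rho`
#' when a floor is configured). Zero-variance taxa are excluded from testing
#' but retained in the panel as isolated nodes, so connectance and degree
#' denominators stay comparable across replicates.
#'
#' @param x an [abundance_table()] whose columns are the subsample.
#' @param panel node set; defaults to all taxa of `x`. Must contain every
#'   taxon of `x`.
#' @param alpha per-network significance level on adjusted p-values.
#' @param min_abs_rho optional absolute-correlation floor (default none).
#' @param p_method `"t"` or `"permutation"` (pair-by-pair, small scale only).
#' @param n_perm,seed permutation settings, see [spearman()].
#' @return a [signed_network()]; attributes `n_samples` (columns used) and
#'   `n_tested` (size of the BH family).
#' @export
build_network <- function(x, panel = rownames(x), alpha = 0.05,
                          min_abs_rho = NULL, p_method = c("t", "permutation"),
                          n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(x, "abundance_table"))
  p_method <- match.arg(p_method)
  n <- ncol(x)
  if (n < 3L) stop("fewer than 3 usable samples", call. = FALSE)
  panel <- as.character(panel)
  if (!all(rownames(x) %in% panel)) {
    stop("panel must contain every taxon of the table", call. = FALSE)
  }
  vals <- unclass(x)
  usable <- apply(vals, 1L, function(r) length(unique(r)) > 1L)
  taxa <- rownames(vals)[usable]
  edges <- NULL
  if (length(taxa) >= 2L) {
    sub <- vals[usable, , drop = FALSE]
    rho_m <- spearman_matrix(sub)
    ut <- upper.tri(rho_m)
    rho <- rho_m[ut]
    if (p_method == "t") {
      p <- spearman_p(rho, n)
    } else {
      ij <- which(ut, arr.ind = TRUE)
      p <- vapply(seq_len(nrow(ij)), function(k) {
        spearman(sub[ij[k, 1L], ], sub[ij[k, 2L], ], method = "permutation",
                 n_perm = n_perm, seed = seed_child(seed, k))$p
      }, numeric(1L))
    }
    q <- bh_adjust(p)
    keep <- q < alpha
    if (!is.null(min_abs_rho)) keep <- keep & abs(rho) >= min_abs_rho
    keep <- keep & rho != 0
    if (any(keep)) {
      ij <- which(ut, arr.ind = TRUE)[keep, , drop = FALSE]
      edges <- data.frame(taxon_a = taxa[ij[, 1L]], taxon_b = taxa[ij[, 2L]],
                          rho = rho[keep], q = q[keep], stringsAsFactors = FALSE)
    }
  }
  net <- signed_network(panel, edges, alpha = alpha)
  attr(net, "n_samples") <- n
  attr(net, "n_tested") <- if (length(taxa) >= 2L) choose(length(taxa), 2L) else 0L
  net
}
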