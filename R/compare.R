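#' Compact letter display from pairwise significance
#'
#' Items sharing a letter are not significantly different. Letters are the
#' maximal cliques of the "not significantly different" graph, ordered by
#' the best mean they contain, so the top item always carries "a". This
#' covers every non-significant pair and never places a significant pair
#' under one letter; the clique enumeration is deterministic.
#'
#' @param means named numeric vector of item means.
#' @param sig logical matrix (items x items): `TRUE` where the pair differs
#'   significantly. Row/column names must match `names(means)`.
#' @return named character vector of letter strings, in `names(means)` order.
#' @export
compact_letters <- function(means, sig) {
  items <- names(means)
  stopifnot(!is.null(items), identical(rownames(sig), items),
            identical(colnames(sig), items))
  nsd <- !sig
  diag(nsd) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(nsd, mode = "undirected")
  cliques <- igraph::max_cliques(g)
  members <- lapply(cliques, function(cl) sort(items[as.integer(cl)]))
  best <- vapply(members, function(m) max(means[m]), numeric(1L))
  key <- vapply(members, paste, character(1L), collapse = "\r")
  ord <- order(-best, key)
  members <- members[ord]
  if (length(members) > 26L) {
    stop("more than 26 letter groups; refine the comparison", call. = FALSE)
  }
  out <- stats::setNames(rep("", length(items)), items)
  for (i in seq_along(members)) {
    out[members[[i]]] <- paste0(out[members[[i]]], letters[i])
  }
  out
}

#' Compare one metric across groups: ANOVA + Tukey HSD letters
#'
#' One-way analysis of variance on the per-replicate values of a metric,
#' followed by Tukey HSD comparison of all group pairs at the declared
#' family level and a compact letter display (groups sharing a letter are
#' not significantly different).
#'
#' @param records per-replicate data.frame from [run_replicated()]`$metrics`
#'   (needs a `group` column and the metric column).
#' @param metric name of the metric column to compare.
#' @param level family significance level for Tukey HSD (default 0.05).
#' @return data.frame (one row per group, ordered by decreasing mean):
#'   `group`, `mean`, `sd`, `n`, `letter`. Attributes: `anova_p` (omnibus
#'   F-test p-value), `values` (the underlying per-replicate values).
#' @export
compare_metrics <- function(records, metric, level = 0.05) {
  if (!metric %in% colnames(records)) stop("no column '", metric, "'", call. = FALSE)
  df <- data.frame(group = as.character(records$group),
                   value = as.numeric(records[[metric]]),
                   stringsAsFactors = FALSE)
  if (anyNA(df$value)) {
    warning(sum(is.na(df$value)), " NA values of '", metric, "' dropped")
    df <- df[!is.na(df$value), , drop = FALSE]
  }
  groups <- unique(df$group)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  counts <- table(df$group)
  if (any(counts < 2L)) stop("need at least 2 replicates per group", call. = FALSE)
  wvar <- tapply(df$value, df$group, stats::var)
  if (all(wvar == 0)) stop("degenerate ANOVA: zero within-group variance everywhere",
                           call. = FALSE)
  df$group <- factor(df$group, levels = groups)
  fit <- stats::aov(value ~ group, data = df)
  anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - level)$group
  sig <- matrix(FALSE, length(groups), length(groups),
                dimnames = list(groups, groups))
  pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pair_names)) {
    a <- pair_names[[i]][1L]
    b <- pair_names[[i]][2L]
    s <- tk[i, "p adj"] < level
    sig[a, b] <- s
    sig[b, a] <- s
  }
  means <- tapply(df$value, df$group, mean)[groups]
  lets <- compact_letters(means, sig)
  out <- data.frame(group = groups,
                    mean = as.numeric(means),
                    sd = as.numeric(tapply(df$value, df$group, stats::sd)[groups]),
                    n = as.integer(counts[groups]),
                    letter = unname(lets),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "anova_p") <- anova_p
  attr(out, "values") <- df
  out
}

#' Identify hub genera of one group from replicate degree distributions
#'
#' Collects each taxon's degree across the replicate networks of one group,
#' ranks taxa by mean degree, keeps the `top_n` most connected, compares
#' every pair of those taxa with a two-sample Kruskal-Wallis rank test
#' (chi-square approximation), applies a Bonferroni correction with
#' `m = top_n * (top_n - 1) / 2`, and encodes the adjusted comparisons as a
#' compact letter display. The Bonferroni family is the pairwise comparisons
#' among the top taxa within this group.
#'
#' @param degrees long data.frame `group`, `replicate`, `taxon`, `degree`
#'   from [run_replicated()]`$degrees`.
#' @param group which group to analyze.
#' @param top_n how many top-ranked taxa to keep (clamped with a warning if
#'   it exceeds the panel).
#' @param level significance level applied to Bonferroni-adjusted p-values.
#' @param omnibus if `TRUE`, run an omnibus Kruskal-Wallis across all
#'   `top_n` taxa first and skip the pairwise tests (single shared letter)
#'   when it is not significant.
#' @return data.frame (Table-2 shape): `taxon`, `group`, `mean_degree`,
#'   `rank` (1 = most connected, no gaps), `letters`.
#' @export
identify_hubs <- function(degrees, group, top_n = 20L, level = 0.05,
                          omnibus = FALSE) {
  d <- degrees[degrees$group == group, , drop = FALSE]
  if (!nrow(d)) stop("no degree records for group '", group, "'", call. = FALSE)
  if (length(unique(d$replicate)) < 2L) stop("need at least 2 replicates", call. = FALSE)
  mean_deg <- tapply(d$degree, d$taxon, mean)
  taxa <- names(sort(mean_deg, decreasing = TRUE))
  # deterministic tie-break: mean degree desc, then taxon id
  taxa <- taxa[order(-mean_deg[taxa], taxa)]
  top_n <- as.integer(top_n)
  if (top_n > length(taxa)) {
    warning("top_n exceeds the panel size; clamped to ", length(taxa))
    top_n <- length(taxa)
  }
  top <- taxa[seq_len(top_n)]
  vecs <- lapply(top, function(tx) d$degree[d$taxon == tx])
  names(vecs) <- top

  m <- top_n * (top_n - 1L) / 2L
  sig <- matrix(FALSE, top_n, top_n, dimnames = list(top, top))
  run_pairwise <- TRUE
  if (omnibus && top_n > 1L) {
    po <- kw_p(vecs)
    if (is.na(po) || po >= level) run_pairwise <- FALSE
  }
  if (run_pairwise && top_n > 1L) {
    for (i in seq_len(top_n - 1L)) {
      for (j in seq(i + 1L, top_n)) {
        p <- kw_p(vecs[c(i, j)])
        padj <- min(1, p * m)
        s <- !is.na(padj) && padj < level
        sig[i, j] <- s
        sig[j, i] <- s
      }
    }
  }
  lets <- compact_letters(mean_deg[top], sig)
  data.frame(taxon = top, group = group,
             mean_degree = as.numeric(mean_deg[top]),
             rank = seq_len(top_n),
             letters = unname(lets),
             stringsAsFactors = FALSE)
}

# Kruskal-Wallis p-value robust to fully tied inputs (p = 1 when the test
# statistic is undefined because every observation is identical).
kw_p <- function(vecs) {
  if (length(unique(unlist(vecs))) < 2L) return(1)
  tryCatch(stats::kruskal.test(vecs)$p.value, error = function(e) 1)
}
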