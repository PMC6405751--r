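#' Specify one synthetic sample group
#'
#' A group (e.g. one land use) is simulated as a latent Gaussian copula over
#' log-normal abundances: planted pairwise associations are written into a
#' latent correlation matrix, each taxon's latent value is mapped through a
#' monotone exponential to a positive abundance, and reads are drawn by a
#' multinomial at fixed sequencing depth. Because Spearman correlation is
#' invariant to monotone transforms, a planted latent correlation of
#' magnitude `latent_assoc_strength` maps predictably to the analyzed
#' statistic (attenuated only by counting noise).
#'
#' Planted edges are organized into *guilds*: disjoint components in which
#' each taxon carries a sign and every within-component pair correlates at
#' `latent_assoc_strength * sign_i * sign_j`. Each guild is a rank-1 factor
#' block, so the latent matrix is positive definite by construction at any
#' strength below 1 and the planted magnitude is realized exactly, at any
#' edge density. (A flat construction that writes `+/-strength` into an
#' identity matrix and then clips eigenvalues attenuates the planted signal
#' more severely the denser the group, which scrambles planted density
#' gradients; see the methods vignette.)
#'
#' A hub is a designated taxon correlated at `hub_strength` with
#' `hub_degree` partner taxa through a shared latent factor. Positive
#' semidefiniteness forces the partners of any strong star to co-correlate
#' at about the square of the hub strength; the factor construction attains
#' that lower bound, so hub stars are as close to pure stars as a
#' correlation matrix allows.
#'
#' @param name group label.
#' @param n_samples number of samples in the group (>= 1).
#' @param n_positive_edges,n_negative_edges planted edge counts (guild
#'   edges; hub edges come on top).
#' @param latent_assoc_strength absolute latent correlation per planted
#'   guild edge, in (0, 1).
#' @param guild_size maximal guild component size (>= 2). Smaller guilds
#'   spread the same number of edges over more taxa and keep per-taxon
#'   planted degree low.
#' @param hub_degree planted hub degree (0 = no hub).
#' @param hub_strength latent correlation between the hub and each partner.
#' @return a `group_spec` list.
#' @export
group_spec <- function(name, n_samples,
                       n_positive_edges = 0L, n_negative_edges = 0L,
                       latent_assoc_strength = 0.9,
                       guild_size = 6L,
                       hub_degree = 0L, hub_strength = 0.8) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_samples <- as.integer(n_samples)
  n_positive_edges <- as.integer(n_positive_edges)
  n_negative_edges <- as.integer(n_negative_edges)
  guild_size <- as.integer(guild_size)
  hub_degree <- as.integer(hub_degree)
  if (n_samples < 1L) stop("group '", name, "' has no samples", call. = FALSE)
  if (n_positive_edges < 0L || n_negative_edges < 0L) {
    stop("planted edge counts must be >= 0", call. = FALSE)
  }
  if (latent_assoc_strength <= 0 || latent_assoc_strength >= 1) {
    stop("latent_assoc_strength must be in (0, 1)", call. = FALSE)
  }
  if (hub_strength <= 0 || hub_strength >= 1) {
    stop("hub_strength must be in (0, 1)", call. = FALSE)
  }
  if (guild_size < 2L) stop("guild_size must be >= 2", call. = FALSE)
  if (hub_degree < 0L) stop("hub_degree must be >= 0", call. = FALSE)
  structure(list(name = name, n_samples = n_samples,
                 n_positive_edges = n_positive_edges,
                 n_negative_edges = n_negative_edges,
                 latent_assoc_strength = latent_assoc_strength,
                 guild_size = guild_size,
                 hub_degree = hub_degree, hub_strength = hub_strength),
            class = "group_spec")
}

#' Specify a synthetic multi-group study
#'
#' @param n_taxa size of the shared taxon panel.
#' @param groups list of [group_spec()] objects with distinct names.
#' @param baseline_log_mean,baseline_log_sd location and spread of the
#'   log-normal abundance map `exp(mean + sd * z)` applied to each taxon's
#'   latent Gaussian value.
#' @param sampling_depth multinomial reads per sample (mirrors a rarefied
#'   dataset; every generated sample column sums exactly to this depth).
#' @return a `study_spec` list.
#' @export
study_spec <- function(n_taxa, groups,
                       baseline_log_mean = 0, baseline_log_sd = 1,
                       sampling_depth = 10000L) {
  n_taxa <- as.integer(n_taxa)
  stopifnot(n_taxa >= 2L, is.list(groups), length(groups) >= 1L)
  if (!all(vapply(groups, inherits, logical(1L), "group_spec"))) {
    stop("groups must be a list of group_spec objects", call. = FALSE)
  }
  nm <- vapply(groups, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate group names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "),
         call. = FALSE)
  }
  names(groups) <- nm
  if (baseline_log_sd < 0) stop("baseline_log_sd must be >= 0", call. = FALSE)
  sampling_depth <- as.integer(sampling_depth)
  if (sampling_depth < 1L) stop("sampling_depth must be >= 1", call. = FALSE)
  structure(list(n_taxa = n_taxa, groups = groups,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 sampling_depth = sampling_depth),
            class = "study_spec")
}

#' Default four-group study: a gradient of planted network density
#'
#' Four groups named after the land uses of a cropping-intensity gradient,
#' with planted edge totals 400 > 150 > 100 > 50 (3:1 positive:negative),
#' one hub per group, and guild sizes and hub degrees scaling with group
#' density -- denser communities host larger guilds and better-connected
#' hubs, as observed in real soil networks. 200 taxa, 40 samples per group,
#' 10,000 reads per sample.
#'
#' @return a [study_spec()].
#' @export
default_study_spec <- function() {
  study_spec(
    n_taxa = 200L,
    groups = list(
      group_spec("forest",    40L, n_positive_edges = 300L, n_negative_edges = 100L,
                 guild_size = 7L, hub_degree = 24L),
      group_spec("grassland", 40L, n_positive_edges = 112L, n_negative_edges = 38L,
                 guild_size = 6L, hub_degree = 18L),
      group_spec("crop",      40L, n_positive_edges = 75L,  n_negative_edges = 25L,
                 guild_size = 5L, hub_degree = 14L),
      group_spec("vineyards", 40L, n_positive_edges = 38L,  n_negative_edges = 12L,
                 guild_size = 4L, hub_degree = 10L)
    )
  )
}

# Partition planted edge counts into guild components. Returns a list of
# sign vectors (+1/-1). Mixed components supply negative edges in bulk
# (plus their unavoidable within-sign positive pairs); leftover negatives
# become opposite-sign pairs; leftover positives become cliques capped at
# guild_size, greedily largest-first (every integer is a sum of triangular
# numbers, so the loop terminates at zero).
plan_guilds <- function(n_pos, n_neg, guild_size) {
  comps <- list()
  pos_left <- n_pos
  neg_left <- n_neg
  m1 <- max(1L, guild_size %/% 2L)
  m2 <- guild_size - m1
  mix_n <- m1 * m2
  mix_p <- choose(m1, 2L) + choose(m2, 2L)
  while (mix_n > 1L && neg_left >= mix_n && pos_left >= mix_p) {
    comps[[length(comps) + 1L]] <- c(rep(1L, m1), rep(-1L, m2))
    neg_left <- neg_left - mix_n
    pos_left <- pos_left - mix_p
  }
  while (neg_left > 0L) {
    comps[[length(comps) + 1L]] <- c(1L, -1L)
    neg_left <- neg_left - 1L
  }
  while (pos_left > 0L) {
    m <- guild_size
    while (choose(m, 2L) > pos_left) m <- m - 1L
    comps[[length(comps) + 1L]] <- rep(1L, m)
    pos_left <- pos_left - choose(m, 2L)
  }
  comps
}

# Nearest-PSD repair by eigenvalue clipping and diagonal rescaling. The
# guild/hub construction is positive definite by itself; this is a safety
# net for custom or overlapping structures.
make_psd <- function(S, eps = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= eps) return(S)
  v <- pmax(e$values, eps)
  S2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(S2))
  S2 / tcrossprod(d)
}

# Latent correlation matrix for one group: guild blocks +/- strength, hub
# factor star. `comp_idx` is a list of taxon index vectors (disjoint).
build_latent_sigma <- function(n_taxa, comp_idx, comp_sign, strength,
                               hub_idx = NULL, hub_strength = 0.8) {
  S <- diag(n_taxa)
  for (k in seq_along(comp_idx)) {
    idx <- comp_idx[[k]]
    s <- comp_sign[[k]]
    block <- strength * tcrossprod(s)
    diag(block) <- 1
    S[idx, idx] <- block
  }
  if (!is.null(hub_idx)) {
    h <- hub_idx[1L]
    nb <- hub_idx[-1L]
    S[h, nb] <- hub_strength
    S[nb, h] <- hub_strength
    block <- matrix(hub_strength^2, length(nb), length(nb))
    diag(block) <- 1
    S[nb, nb] <- block
  }
  S
}

#' Generate one group's abundance table with planted network structure
#'
#' Implements the latent Gaussian copula described in [group_spec()]:
#' (1) lay out guild components and the optional hub star on taxa sampled
#' from the panel; (2) draw `n_samples` latent Gaussian vectors with the
#' planted correlation structure; (3) map each latent value through
#' `exp(baseline_log_mean + baseline_log_sd * z)`; (4) close each sample to
#' proportions and draw `sampling_depth` multinomial reads.
#'
#' @param study a [study_spec()].
#' @param group group name; may be omitted when the study has one group.
#' @param seed integer seed (fully reproducible).
#' @return list with `table` (an [abundance_table()], counts, column sums
#'   equal to the sampling depth) and `truth` (list with `edges`, a
#'   data.frame of planted signed pairs, and `hub`, the hub taxon or `NA`).
#' @export
generate_group <- function(study, group = NULL, seed = 1L) {
  stopifnot(inherits(study, "study_spec"))
  if (is.null(group)) {
    if (length(study$groups) != 1L) stop("study has several groups; name one", call. = FALSE)
    group <- names(study$groups)[1L]
  }
  gs <- study$groups[[group]]
  if (is.null(gs)) stop("no group named '", group, "' in the study spec", call. = FALSE)
  n_taxa <- study$n_taxa
  if (gs$hub_degree > n_taxa - 1L) {
    stop("infeasible hub degree ", gs$hub_degree, " with ", n_taxa, " taxa",
         call. = FALSE)
  }
  n_edges <- gs$n_positive_edges + gs$n_negative_edges + gs$hub_degree
  if (n_edges > choose(n_taxa, 2L)) {
    stop("more planted edges than taxon pairs", call. = FALSE)
  }
  comps <- plan_guilds(gs$n_positive_edges, gs$n_negative_edges, gs$guild_size)
  n_hub_taxa <- if (gs$hub_degree > 0L) gs$hub_degree + 1L else 0L
  needed <- sum(lengths(comps)) + n_hub_taxa
  if (needed > n_taxa) {
    stop(sprintf(
      "planted structure needs %d taxa but the panel has %d; lower the edge counts or raise guild_size",
      needed, n_taxa), call. = FALSE)
  }
  panel <- sprintf("g%0*d", nchar(as.character(n_taxa)), seq_len(n_taxa))

  set.seed(seed)
  placed <- sample.int(n_taxa, needed)
  hub_idx <- NULL
  off <- 0L
  if (n_hub_taxa > 0L) {
    hub_idx <- placed[seq_len(n_hub_taxa)]
    off <- n_hub_taxa
  }
  comp_idx <- vector("list", length(comps))
  for (k in seq_along(comps)) {
    comp_idx[[k]] <- placed[off + seq_along(comps[[k]])]
    off <- off + length(comps[[k]])
  }

  S <- build_latent_sigma(n_taxa, comp_idx, comps, gs$latent_assoc_strength,
                          hub_idx, gs$hub_strength)
  U <- tryCatch(chol(S), error = function(e) chol(make_psd(S)))
  Z <- matrix(stats::rnorm(gs$n_samples * n_taxa), gs$n_samples) %*% U
  A <- exp(study$baseline_log_mean + study$baseline_log_sd * t(Z))
  counts <- apply(A, 2L, function(col) {
    stats::rmultinom(1L, study$sampling_depth, col / sum(col))
  })
  sample_ids <- sprintf("%s_s%02d", group, seq_len(gs$n_samples))
  tab <- abundance_table(counts, panel, sample_ids, unit_kind = "counts")

  edges <- planted_edges(panel, comp_idx, comps, hub_idx)
  list(table = tab,
       truth = list(edges = edges,
                    hub = if (is.null(hub_idx)) NA_character_ else panel[hub_idx[1L]]))
}

# Enumerate planted edges (guild pairs signed by the sign product, hub star
# edges positive), pairs lexicographically oriented.
planted_edges <- function(panel, comp_idx, comp_sign, hub_idx) {
  a <- character(0); b <- character(0); sg <- character(0)
  for (k in seq_along(comp_idx)) {
    idx <- comp_idx[[k]]
    s <- comp_sign[[k]]
    if (length(idx) < 2L) next
    pr <- utils::combn(seq_along(idx), 2L)
    a <- c(a, panel[idx[pr[1L, ]]])
    b <- c(b, panel[idx[pr[2L, ]]])
    sg <- c(sg, ifelse(s[pr[1L, ]] * s[pr[2L, ]] > 0, "positive", "negative"))
  }
  if (!is.null(hub_idx)) {
    a <- c(a, rep(panel[hub_idx[1L]], length(hub_idx) - 1L))
    b <- c(b, panel[hub_idx[-1L]])
    sg <- c(sg, rep("positive", length(hub_idx) - 1L))
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  out <- data.frame(taxon_a = lo, taxon_b = hi, sign = sg, stringsAsFactors = FALSE)
  out <- out[order(out$taxon_a, out$taxon_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a full multi-group study with ground truth
#'
#' Concatenates per-group tables over the shared taxon panel and attaches
#' group labels. Each group is generated from a child seed derived from
#' `seed` by a fixed counter scheme, so per-group data are independent and
#' the whole study is byte-reproducible.
#'
#' @param study a [study_spec()].
#' @param seed integer master seed.
#' @return list with `table` (counts [abundance_table()]), `metadata`
#'   (data.frame `sample_id`, `group`) and `truth` (per-group list of
#'   `edges` and `hub`).
#' @export
generate_study <- function(study, seed = 1L) {
  stopifnot(inherits(study, "study_spec"))
  nm <- names(study$groups)
  parts <- lapply(seq_along(nm), function(i) {
    generate_group(study, nm[i], seed = seed_child(seed, i))
  })
  tab <- do.call(cbind, lapply(parts, function(p) unclass(p$table)))
  tab <- abundance_table(tab, unit_kind = "counts")
  metadata <- data.frame(
    sample_id = colnames(tab),
    group = rep(nm, vapply(parts, function(p) ncol(p$table), integer(1L))),
    stringsAsFactors = FALSE)
  truth <- lapply(parts, `[[`, "truth")
  names(truth) <- nm
  list(table = tab, metadata = metadata, truth = truth)
}

#' Score recovery of a planted edge set by an inferred network
#'
#' Edge-level precision and recall ignore signs; the per-sign rows require
#' the edge to be present *and* its sign to agree. `sign_accuracy` is the
#' fraction of recovered planted edges whose inferred sign matches.
#' An empty inferred network yields `NA` precision and recall 0.
#'
#' @param truth planted edges: data.frame `taxon_a`, `taxon_b`, `sign`
#'   (as in the `truth$edges` element of [generate_group()]).
#' @param net an inferred [signed_network()].
#' @return data.frame with rows `overall`, `positive`, `negative` and
#'   columns `precision`, `recall`, plus attribute `sign_accuracy`.
#' @export
score_recovery <- function(truth, net) {
  stopifnot(inherits(net, "signed_network"))
  pk <- paste(pmin(truth$taxon_a, truth$taxon_b),
              pmax(truth$taxon_a, truth$taxon_b), sep = "\r")
  e <- net$edges
  ik <- paste(e$taxon_a, e$taxon_b, sep = "\r")
  hit <- pk %in% ik
  prec <- if (length(ik)) sum(ik %in% pk) / length(ik) else NA_real_
  rec <- if (length(pk)) mean(hit) else NA_real_
  # sign-aware keys
  pks <- paste(pk, truth$sign)
  iks <- paste(ik, e$sign)
  by_sign <- function(sgn) {
    p_s <- pks[truth$sign == sgn]
    i_s <- iks[e$sign == sgn]
    c(precision = if (length(i_s)) sum(i_s %in% p_s) / length(i_s) else NA_real_,
      recall = if (length(p_s)) mean(p_s %in% iks) else NA_real_)
  }
  recovered <- pks[hit]
  sign_acc <- if (length(recovered)) mean(recovered %in% iks) else NA_real_
  out <- rbind(overall = c(precision = prec, recall = rec),
               positive = by_sign("positive"),
               negative = by_sign("negative"))
  out <- as.data.frame(out)
  attr(out, "sign_accuracy") <- sign_acc
  out
}
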