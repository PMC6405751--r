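# Small in-code fixtures shared across test files.

# counts table with known structure: 3 taxa x 4 samples
toy_counts <- function() {
  m <- matrix(c(5, 0, 3,
                2, 1, 0,
                8, 4, 1,
                1, 2, 6), nrow = 3,
              dimnames = list(c("taxA", "taxB", "taxC"), paste0("s", 1:4)))
  abundance_table(m, unit_kind = "counts")
}

# hand-built signed network on a given panel; edges = list of c(a, b, rho)
make_net <- function(panel, edges = list(), alpha = 0.05, q = 1e-3) {
  e <- if (length(edges)) {
    data.frame(taxon_a = vapply(edges, `[[`, character(1), 1),
               taxon_b = vapply(edges, `[[`, character(1), 2),
               rho = as.numeric(vapply(edges, `[[`, character(1), 3)),
               q = q, stringsAsFactors = FALSE)
  } else NULL
  signed_network(panel, e, alpha = alpha)
}

# a table whose first two taxa are perfectly co-monotone and the rest are
# independent noise
comonotone_table <- function(n_taxa = 10, n = 30, seed = 99) {
  set.seed(seed)
  base <- sample(seq_len(1000), n)
  m <- rbind(base, base * 2L,
             matrix(sample.int(1000, (n_taxa - 2) * n, replace = TRUE),
                    n_taxa - 2))
  rownames(m) <- sprintf("t%02d", seq_len(n_taxa))
  colnames(m) <- sprintf("s%02d", seq_len(n))
  abundance_table(m, unit_kind = "counts")
}

# one-group study spec: n_pos/n_neg planted as disjoint pairs (guild_size 2)
pairs_study <- function(n_taxa = 50, n_samples = 30, n_pos = 8, n_neg = 2,
                        strength = 0.9) {
  study_spec(n_taxa, list(
    group_spec("g1", n_samples, n_positive_edges = n_pos,
               n_negative_edges = n_neg, latent_assoc_strength = strength,
               guild_size = 2L)))
}
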