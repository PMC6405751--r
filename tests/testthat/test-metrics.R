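test_that("link counts and the positive:negative ratio follow their definitions", {
  tri <- make_net(c("a", "b", "c"),
                  list(c("a", "b", "0.9"), c("b", "c", "0.8"), c("a", "c", "0.7")))
  cl <- count_links(tri)
  expect_equal(cl[c("L", "L_pos", "L_neg")], list(L = 3L, L_pos = 3L, L_neg = 0L))
  expect_true(is.na(cl$pn_ratio))  # NA, never infinity

  cyc <- make_net(c("a", "b", "c", "d"),
                  list(c("a", "b", "0.9"), c("b", "c", "-0.8"),
                       c("c", "d", "0.7"), c("a", "d", "-0.6")))
  cl2 <- count_links(cyc)
  expect_equal(cl2$L, 4L)
  expect_equal(cl2$pn_ratio, 1.0)
})

test_that("connectance honours its denominator conventions", {
  tri <- make_net(c("a", "b", "c"),
                  list(c("a", "b", "0.9"), c("b", "c", "0.8"), c("a", "c", "0.7")))
  expect_equal(connectance(tri, "unordered_panel"), 1.0)
  expect_equal(connectance(tri, "ordered_panel"), 0.5)

  big <- make_net(sprintf("g%04d", 1:1355), list(c("g0001", "g0002", "0.9")))
  expect_equal(connectance(big, "unordered_panel"), 1 / (1355 * 1354 / 2))
  expect_equal(connectance(big, "unordered_present"), 1.0)

  lone <- make_net("a")
  expect_true(is.na(connectance(lone, "unordered_panel")))
})

test_that("average degree conventions and the handshake lemma hold", {
  star <- make_net(letters[1:5],
                   lapply(letters[2:5], function(x) c("a", x, "0.9")))
  expect_equal(average_degree(star, "two_l_over_panel"), 8 / 5)
  expect_equal(average_degree(star, "l_over_panel"), 4 / 5)
  deg <- degree_table(star)
  expect_equal(unname(deg["a"]), 4L)
  expect_true(all(deg[letters[2:5]] == 1L))

  tri <- make_net(c("a", "b", "c"),
                  list(c("a", "b", "0.9"), c("b", "c", "0.8"), c("a", "c", "0.7")))
  expect_equal(average_degree(tri, "two_l_over_panel"), 2.0)

  set.seed(51)
  for (i in 1:10) {
    panel <- sprintf("n%02d", 1:8)
    pairs <- combn(panel, 2)
    pick <- sample(ncol(pairs), sample(0:10, 1))
    net <- make_net(panel, lapply(pick, function(k) {
      c(pairs[1, k], pairs[2, k], sprintf("%.3f", runif(1, 0.5, 0.99)))
    }))
    expect_equal(sum(degree_table(net)), 2L * nrow(net$edges))
  }
})

test_that("path length matches enumeration on small graphs", {
  path3 <- make_net(c("A", "B", "C"), list(c("A", "B", "0.9"), c("B", "C", "0.8")))
  expect_equal(average_path_length(path3, "mean_geodesic_connected_pairs"), 4 / 3)
  expect_equal(average_path_length(path3, "global_efficiency"), 5 / 6)

  two_edges <- make_net(c("a", "b", "c", "d"),
                        list(c("a", "b", "0.9"), c("c", "d", "0.8")))
  expect_equal(average_path_length(two_edges, "mean_geodesic_connected_pairs"), 1.0)
  expect_equal(average_path_length(two_edges, "global_efficiency"), 2 / 6)

  empty <- make_net(letters[1:3])
  expect_true(is.na(average_path_length(empty, "mean_geodesic_connected_pairs")))
  expect_equal(average_path_length(empty, "global_efficiency"), 0)
})

test_that("path metrics agree with exhaustive shortest-path enumeration", {
  set.seed(52)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    panel <- sprintf("n%02d", seq_len(n))
    pairs <- combn(panel, 2)
    pick <- sample(ncol(pairs), sample(seq_len(ncol(pairs)), 1))
    net <- make_net(panel, lapply(pick, function(k) {
      c(pairs[1, k], pairs[2, k], sprintf("%.3f", runif(1, 0.51, 0.99) * sign(runif(1, -1, 1))))
    }))
    oracle <- oracle_path_metrics(net)
    expect_equal(average_path_length(net, "mean_geodesic_connected_pairs"),
                 oracle$geodesic)
    expect_equal(average_path_length(net, "global_efficiency"), oracle$efficiency)
  }
})

test_that("complete graphs attain geodesic 1 and efficiency 1", {
  panel <- letters[1:6]
  pairs <- combn(panel, 2)
  net <- make_net(panel, lapply(seq_len(ncol(pairs)), function(k) {
    c(pairs[1, k], pairs[2, k], "0.9")
  }))
  expect_equal(average_path_length(net, "mean_geodesic_connected_pairs"), 1)
  expect_equal(average_path_length(net, "global_efficiency"), 1)
})

test_that("metrics are invariant under node relabeling", {
  panel <- letters[1:6]
  edges <- list(c("a", "b", "0.9"), c("b", "c", "-0.7"), c("d", "e", "0.6"))
  net <- make_net(panel, edges)
  relabel <- setNames(rev(LETTERS[1:6]), panel)
  net2 <- make_net(unname(relabel[panel]),
                   lapply(edges, function(e) c(relabel[e[1]], relabel[e[2]], e[3])))
  for (conv in c("unordered_panel", "ordered_panel")) {
    expect_equal(connectance(net, conv), connectance(net2, conv))
  }
  expect_equal(average_degree(net), average_degree(net2))
  expect_equal(average_path_length(net, "global_efficiency"),
               average_path_length(net2, "global_efficiency"))
  expect_equal(sort(unname(degree_table(net))), sort(unname(degree_table(net2))))
})

test_that("adding an edge never decreases the monotone metrics", {
  set.seed(53)
  panel <- sprintf("n%02d", 1:7)
  pairs <- combn(panel, 2)
  idx <- sample(ncol(pairs))
  prev <- make_net(panel)
  for (k in idx[1:12]) {
    grown_edges <- rbind(prev$edges[, c("taxon_a", "taxon_b", "rho", "q")],
                         data.frame(taxon_a = pairs[1, k], taxon_b = pairs[2, k],
                                    rho = 0.9, q = 1e-3))
    grown <- signed_network(panel, grown_edges)
    expect_gte(nrow(grown$edges), nrow(prev$edges))
    expect_gte(connectance(grown, "unordered_panel"),
               connectance(prev, "unordered_panel"))
    expect_gte(average_degree(grown), average_degree(prev))
    expect_gte(average_path_length(grown, "global_efficiency"),
               average_path_length(prev, "global_efficiency"))
    prev <- grown
  }
})

test_that("network_metrics bundles the seven metrics with their conventions", {
  net <- make_net(c("a", "b", "c"), list(c("a", "b", "0.9"), c("b", "c", "-0.8")))
  m <- network_metrics(net)
  expect_identical(m$L, 2L)
  expect_identical(m$L_pos, 1L)
  expect_identical(m$L_neg, 1L)
  expect_equal(m$pn_ratio, 1)
  expect_equal(m$connectance, 2 / 6)
  expect_identical(m$connectance_convention, "ordered_panel")
  expect_equal(m$avg_degree, 4 / 3)
  expect_equal(m$avg_path_length, (1 + 1 + 0.5) / 3)
})
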