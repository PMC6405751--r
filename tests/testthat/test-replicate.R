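test_that("replicate designs draw distinct subsets and report coverage", {
  pool <- sprintf("site%03d", 1:40)
  des <- design_replicates(pool, k = 5, R = 30, seed = 3)
  expect_identical(length(des$subsets), 30L)
  expect_true(all(vapply(des$subsets, function(s) length(unique(s)) == 5L, logical(1))))
  keys <- vapply(des$subsets, paste, character(1), collapse = "|")
  expect_false(anyDuplicated(keys) > 0)
  expect_equal(des$coverage, length(unique(unlist(des$subsets))) / 40)
  # reproducibility
  des2 <- design_replicates(pool, k = 5, R = 30, seed = 3)
  expect_identical(des$subsets, des2$subsets)
})

test_that("the k = pool-size boundary yields the single possible subset", {
  pool <- sprintf("s%02d", 1:30)
  des <- design_replicates(pool, k = 30, R = 1, seed = 1)
  expect_identical(des$subsets[[1]], sort(pool))
  expect_error(design_replicates(pool, k = 30, R = 2), "only 1")
})

test_that("a 100x30 design over 500 sites covers nearly the whole pool", {
  pool <- sprintf("s%03d", 1:500)
  des <- design_replicates(pool, k = 30, R = 100, seed = 11)
  expect_gte(des$coverage, 0.95)
})

test_that("replicated pipeline agrees with a direct single-network run", {
  set.seed(61)
  study <- study_spec(25, list(group_spec("g1", 10, 5, 2, guild_size = 3)),
                      sampling_depth = 2000)
  s <- generate_study(study, seed = 4)
  cfg <- pipeline_config(k_subsample = 10, n_replicates = 1, rng_seed = 2)
  rr <- run_replicated(s$table, s$metadata, cfg)
  expect_identical(nrow(rr$metrics), 1L)
  direct <- build_network(s$table, alpha = cfg$alpha)
  dm <- network_metrics(direct)
  expect_equal(rr$metrics$L, dm$L)
  expect_equal(rr$metrics$connectance, dm$connectance)
  expect_equal(rr$metrics$avg_degree, dm$avg_degree)
  deg <- degree_table(direct)
  expect_equal(rr$degrees$degree, unname(deg[rr$degrees$taxon]))
  # diversity columns are means over the subset samples
  dv <- diversity_indices(s$table)
  expect_equal(rr$metrics$H, mean(dv$H))
  expect_error(run_replicated(s$table, s$metadata, cfg, groups = "nope"),
               "absent from metadata")
})

test_that("records carry group and replicate labels for every subset", {
  study <- study_spec(15, list(group_spec("a", 8, 3, 0, guild_size = 3),
                               group_spec("b", 8, 3, 0, guild_size = 3)),
                      sampling_depth = 1000)
  s <- generate_study(study, seed = 6)
  cfg <- pipeline_config(k_subsample = 5, n_replicates = 4, rng_seed = 9)
  rr <- run_replicated(s$table, s$metadata, cfg)
  expect_identical(nrow(rr$metrics), 8L)
  expect_identical(sort(unique(rr$metrics$group)), c("a", "b"))
  expect_identical(unique(table(rr$degrees$group)), 4L * 15L)
})

test_that("compare_metrics separates far-apart groups and letters them", {
  set.seed(71)
  records <- data.frame(group = rep(c("low", "high"), each = 100),
                        L = c(rnorm(100, 0, 1), rnorm(100, 10, 1)))
  cmp <- compare_metrics(records, "L")
  expect_identical(cmp$group, c("high", "low"))  # ordered by mean, best first
  expect_identical(cmp$letter, c("a", "b"))
  expect_lt(attr(cmp, "anova_p"), 1e-10)
})

test_that("groups drawn from one distribution usually share a letter", {
  share <- vapply(1:10, function(s) {
    set.seed(s)
    records <- data.frame(group = rep(c("x", "y"), each = 100),
                          L = rnorm(200))
    cmp <- compare_metrics(records, "L")
    cmp$letter[1] == cmp$letter[2]
  }, logical(1))
  expect_gte(mean(share), 0.8)  # type-I control near the nominal 5%
})

test_that("compare_metrics validates its preconditions", {
  rec <- data.frame(group = c("a", "a", "b", "b"), L = c(1, 1, 1, 1))
  expect_error(compare_metrics(rec, "L"), "degenerate ANOVA")
  expect_error(compare_metrics(rec, "nope"), "no column")
  expect_error(compare_metrics(rec[1:2, ], "L"), "2 groups")
})

test_that("compact letter display respects the significance structure", {
  means <- c(a = 10, b = 9, c = 1)
  sig <- matrix(FALSE, 3, 3, dimnames = list(names(means), names(means)))
  sig["a", "c"] <- sig["c", "a"] <- TRUE
  sig["b", "c"] <- sig["c", "b"] <- TRUE
  lets <- compact_letters(means, sig)
  expect_identical(unname(lets[c("a", "b")]), c("a", "a"))
  expect_identical(unname(lets["c"]), "b")
  # all different
  sig[] <- TRUE
  diag(sig) <- FALSE
  expect_identical(unname(compact_letters(means, sig)), c("a", "b", "c"))
  # none different
  sig[] <- FALSE
  expect_identical(unname(compact_letters(means, sig)), c("a", "a", "a"))
})

test_that("identify_hubs ranks by mean degree and letters by Kruskal-Wallis", {
  # 3 taxa over 20 replicates: one clear hub, two exchangeable others
  set.seed(81)
  degrees <- do.call(rbind, lapply(1:20, function(r) {
    data.frame(group = "g", replicate = r,
               taxon = c("hub", "t1", "t2"),
               degree = c(rpois(1, 20), rpois(1, 2), rpois(1, 2)))
  }))
  hb <- identify_hubs(degrees, "g", top_n = 3)
  expect_identical(hb$taxon[1], "hub")
  expect_identical(hb$rank, 1:3)
  expect_false(grepl(hb$letters[1], hb$letters[2], fixed = TRUE))
  # hub letter not shared with either background taxon
  expect_false(any(strsplit(hb$letters[1], "")[[1]] %in%
                   unlist(strsplit(hb$letters[2:3], ""))))
})

test_that("identical degree vectors produce one shared letter", {
  degrees <- data.frame(group = "g", replicate = rep(1:2, each = 3),
                        taxon = rep(c("a", "b", "c"), 2),
                        degree = rep(c(4, 4, 4), 2))
  hb <- identify_hubs(degrees, "g", top_n = 3)
  expect_identical(unique(hb$letters), "a")
  expect_error(identify_hubs(degrees[degrees$replicate == 1, ], "g"),
               "2 replicates")
})

test_that("exchangeable taxa are rarely separated after Bonferroni", {
  seps <- vapply(1:10, function(s) {
    set.seed(s)
    degrees <- do.call(rbind, lapply(1:30, function(r) {
      data.frame(group = "g", replicate = r, taxon = sprintf("t%02d", 1:10),
                 degree = rpois(10, 5))
    }))
    hb <- identify_hubs(degrees, "g", top_n = 10)
    length(unique(hb$letters)) > 1
  }, logical(1))
  expect_lte(mean(seps), 0.1)
})

test_that("top_n clamps with a warning and omnibus mode short-circuits", {
  degrees <- data.frame(group = "g", replicate = rep(1:3, each = 2),
                        taxon = rep(c("a", "b"), 3),
                        degree = c(5, 1, 6, 2, 4, 1))
  expect_warning(hb <- identify_hubs(degrees, "g", top_n = 10), "clamped")
  expect_identical(nrow(hb), 2L)
  hb2 <- identify_hubs(degrees, "g", top_n = 2, omnibus = TRUE, level = 1e-6)
  expect_identical(unique(hb2$letters), "a")  # omnibus not significant at 1e-6
})

test_that("percent change reproduces reporting arithmetic", {
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(200, 50), 75)
  expect_true(is.na(percent_change(0, 5)))
  expect_equal(percent_change(100, 150), -50)  # increases are negative
})
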