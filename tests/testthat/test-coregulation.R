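test_that("co-target counts match explicit set intersection", {
  net <- regulatory_network(c("A", "A", "B", "B", "C"),
                            c("g1", "g2", "g2", "g3", "g4"))
  cts <- cotarget_counts(net)
  expect_equal(cts, data.frame(r1 = "A", r2 = "B", x = 1,
                               stringsAsFactors = FALSE))
  kb <- complete_bipartite(2, 3)
  expect_equal(cotarget_counts(kb)$x, 3)
  for (s in 1:5) {
    rnd <- make_bipartite_network(10, 30, "poisson", mean_degree = 4,
                                  seed = 3000 + s)
    got <- cotarget_counts(rnd)
    ora <- brute_cotarget_counts(rnd)
    rownames(got) <- rownames(ora) <- NULL
    expect_equal(got, ora, ignore_attr = TRUE)
  }
})

test_that("CC filter removes edges at chance level and keeps over-represented ones", {
  kb <- complete_bipartite(3, 4)
  st <- null_cotarget_stats(kb, ensemble_size = 100, seed = 1)
  filtered <- build_coregulation(kb, st, "cc")
  expect_equal(nrow(filtered$edges), 0)
  all_kept <- build_coregulation(kb, st, "none")
  expect_equal(nrow(all_kept$edges), 3)
  expect_true(all(all_kept$edges$cc == 1))

  # two block-identical regulators are over-represented relative to null
  net <- regulatory_network(
    c("A", "A", "A", "B", "B", "B", "C", "D"),
    c("g1", "g2", "g3", "g1", "g2", "g3", "g4", "g4"))
  st2 <- null_cotarget_stats(net, ensemble_size = 500, seed = 2)
  cg <- build_coregulation(net, st2, "cc")
  ab <- cg$edges[cg$edges$r1 == "A" & cg$edges$r2 == "B", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$x, 3)
  expect_gt(ab$cc, 1)
})

test_that("z > 0 retention coincides with CC > 1 wherever sigma > 0", {
  net <- make_bipartite_network(20, 100, "poisson", mean_degree = 6,
                                seed = 11)
  st <- null_cotarget_stats(net, ensemble_size = 200, seed = 12)
  e <- build_coregulation(net, st, "none")$edges
  pos <- e$sigma > 0
  expect_gt(sum(pos), 0)
  expect_equal((e$cc > 1)[pos], (e$z > 0)[pos])

  by_cc <- build_coregulation(net, st, "cc", threshold = 1)$edges
  by_z <- build_coregulation(net, st, "z", threshold = 0)$edges
  pk <- function(d) paste(d$r1, d$r2)
  expect_setequal(pk(by_cc[by_cc$sigma > 0, ]), pk(by_z[by_z$sigma > 0, ]))
})

test_that("threshold raising is monotone and filters nest in the unfiltered set", {
  net <- make_bipartite_network(15, 60, "poisson", mean_degree = 5, seed = 21)
  st <- null_cotarget_stats(net, ensemble_size = 100, seed = 22)
  none <- build_coregulation(net, st, "none")
  lo <- build_coregulation(net, st, "cc", threshold = 1)
  hi <- build_coregulation(net, st, "cc", threshold = 1.5)
  pk <- function(cg) paste(cg$edges$r1, cg$edges$r2)
  expect_true(all(pk(lo) %in% pk(none)))
  expect_true(all(pk(hi) %in% pk(lo)))
  expect_error(build_coregulation(net, st, "cc", threshold = -1), "negative")
})

test_that("missing null statistics are reported with the offending pair", {
  net <- toy_net()
  st <- null_cotarget_stats(net, ensemble_size = 10, seed = 1)
  st$pairs <- st$pairs[0, ]
  expect_error(build_coregulation(net, st, "cc"), "\\(A, B\\)")
})

test_that("partner degrees count filtered adjacencies, zero for absentees", {
  net <- make_bipartite_network(12, 40, "poisson", mean_degree = 4, seed = 31)
  st <- null_cotarget_stats(net, ensemble_size = 50, seed = 32)
  cg <- build_coregulation(net, st, "none")
  f <- partner_counts(cg)
  expect_equal(sum(f), 2 * nrow(cg$edges))
  for (r in names(f)) {
    expect_equal(unname(f[r]),
                 sum(cg$edges$r1 == r) + sum(cg$edges$r2 == r))
  }
  expect_true(all(f <= length(cg$nodes) - 1))

  # disjoint regulons: empty partnership network under every filter
  disj <- make_bipartite_network(8, 100, "poisson", mean_degree = 4,
                                 allow_shared_targets = FALSE, seed = 33)
  std <- null_cotarget_stats(disj, ensemble_size = 20, seed = 34)
  for (flt in c("cc", "z", "none")) {
    expect_true(all(partner_counts(build_coregulation(disj, std, flt)) == 0))
  }
})

test_that("target-level dual equals co-targeting of the reversed network", {
  net <- regulatory_network(c("A", "A", "B"), c("g1", "g2", "g3"))
  dual <- co_regulated_targets(net)
  expect_equal(dual$edges$t1, "g1")
  expect_equal(dual$edges$t2, "g2")
  # disjoint regulons -> no edges between different regulators' targets
  expect_equal(nrow(dual$edges), 1)

  rnd <- make_bipartite_network(10, 25, "poisson", mean_degree = 3, seed = 41)
  dual2 <- co_regulated_targets(rnd)
  rev_net <- regulatory_network(rnd$edges$target, rnd$edges$regulator)
  ora <- brute_cotarget_counts(rev_net)
  expect_equal(dual2$edges$t1, ora$r1)
  expect_equal(dual2$edges$t2, ora$r2)
  expect_equal(dual2$edges$x, ora$x)
})
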