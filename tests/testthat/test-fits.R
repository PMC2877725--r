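mk_series <- function(k, f) partner_target_series(paste0("r", seq_along(k)), k, f)

test_that("degree distribution is a proper probability mass function", {
  net <- regulatory_network(c("A", "A", "B", "B", "C", "C"),
                            c("g1", "g2", "g1", "g3", "g2", "g3"))
  st <- null_cotarget_stats(net, ensemble_size = 10, seed = 1)
  cg <- build_coregulation(net, st, "none")  # triangle A-B-C
  dd <- degree_distribution(cg)
  expect_equal(dd$k, 2)
  expect_equal(dd$p, 1)
  for (s in 1:3) {
    rnd <- make_bipartite_network(10, 30, "poisson", mean_degree = 4,
                                  seed = 50 + s)
    str <- null_cotarget_stats(rnd, ensemble_size = 20, seed = 60 + s)
    cgr <- build_coregulation(rnd, str, "none")
    dd <- degree_distribution(cgr)
    expect_equal(sum(dd$p), 1)
    f <- partner_counts(cgr)
    p0 <- if (0 %in% dd$k) dd$p[dd$k == 0] else 0
    expect_equal(p0, mean(f == 0))
  }
})

test_that("log-log regression recovers exact and noisy power laws", {
  k <- 1:20
  p <- k^-2 / sum(k^-2)
  fit <- fit_powerlaw(data.frame(k = k, p = p))
  expect_equal(unname(fit$params["gamma"]), 2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  unif <- fit_powerlaw(data.frame(k = 1:20, p = rep(1 / 20, 20)))
  expect_equal(unname(unif$params["gamma"]), 0, tolerance = 1e-9)
  expect_equal(unif$r_squared, 0, tolerance = 1e-9)

  expect_error(fit_powerlaw(data.frame(k = 1:2, p = c(.5, .5))), "3")

  # recovery: empirical mass of samples from p(k) ~ k^-1.8 on 1..50
  gam <- vapply(1:50, function(s) {
    set.seed(700 + s)
    draws <- sample(1:50, 4000, replace = TRUE, prob = (1:50)^-1.8)
    tab <- table(draws)
    d <- data.frame(k = as.integer(names(tab)),
                    p = as.numeric(tab) / length(draws))
    unname(fit_powerlaw(d)$params["gamma"])
  }, 0)
  expect_lt(abs(mean(gam) - 1.8) / 1.8, 0.10)
})

test_that("linear fits agree with closed-form normal equations", {
  exact <- fit_linear(mk_series(1:10, 2 * (1:10) + 1))
  expect_equal(unname(exact$params), c(2, 1), tolerance = 1e-12)
  expect_equal(exact$r_squared, 1)

  flat <- fit_linear(mk_series(1:10, rep(3, 10)))
  expect_equal(unname(flat$params["slope"]), 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0)

  set.seed(8)
  k <- runif(40, 0, 50)
  f <- pmax(0, 3 + 0.5 * k + rnorm(40, 0, 2))
  got <- fit_linear(mk_series(k, f))
  # normal-equations oracle
  slope <- sum((k - mean(k)) * (f - mean(f))) / sum((k - mean(k))^2)
  intercept <- mean(f) - slope * mean(k)
  expect_equal(unname(got$params), c(slope, intercept), tolerance = 1e-9)

  expect_error(fit_linear(mk_series(c(2, 2, 2), c(1, 2, 3))), "variance")
})

test_that("saturation fits recover their own curve exactly and under noise", {
  s <- make_saturation_scatter(50, 0.1, 1:100)
  fit <- fit_exp_saturation(s)
  expect_lt(abs(fit$params[["a"]] - 50) / 50, 1e-6)
  expect_lt(abs(fit$params[["b"]] - 0.1) / 0.1, 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # plateau at half the regulator pool, slow approach
  s2 <- make_saturation_scatter(78.5, 0.05, 1:150)
  fit2 <- fit_exp_saturation(s2)
  expect_lt(abs(fit2$params[["a"]] - 78.5) / 78.5, 1e-6)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-9)

  a_hat <- vapply(1:50, function(s) {
    sc <- make_saturation_scatter(50, 0.1, 1:200, noise_sd = 2,
                                  seed = 900 + s)
    fit_exp_saturation(sc)$params[["a"]]
  }, 0)
  expect_lt(abs(mean(a_hat) - 50) / 50, 0.05)

  expect_error(fit_exp_saturation(mk_series(1:5, rep(0, 5))), "zero")
})

test_that("model comparison prefers the generating family where identifiable", {
  plateau <- make_saturation_scatter(40, 0.08, 1:120, noise_sd = 2, seed = 1)
  cmp <- compare_fits(plateau)
  expect_equal(cmp$preferred, "exp_saturation")

  # near-linear regime: b*k << 1 throughout, families indistinguishable
  lin_regime <- make_saturation_scatter(50, 0.001, seq(1, 5, length.out = 60),
                                        noise_sd = 0)
  cmp2 <- compare_fits(lin_regime)
  expect_gt(cmp2$linear$r_squared, 0.999)
  expect_gt(cmp2$exp_saturation$r_squared, 0.999)
  expect_lt(abs(cmp2$delta_r_squared), 0.001)

  expect_error(compare_fits(mk_series(1:5, rep(0, 5))))
})

test_that("operon collapse merges targets and never raises out-degrees", {
  net <- regulatory_network(rep("A", 3), c("g1", "g2", "g3"))
  map <- operon_map(c("g1", "g2", "g3"), c("op1", "op1", "op2"))
  col <- collapse_operons(net, map)
  expect_setequal(col$edges$target, c("op1", "op2"))

  ident <- operon_map(c("g1", "g2", "g3"), c("g1", "g2", "g3"))
  expect_identical(collapse_operons(net, ident)$edges, net$edges)

  syn <- make_operon_network(15, 60, "poisson", mean_degree = 4, seed = 5)
  col2 <- collapse_operons(syn$network, syn$map)
  od_gene <- out_degrees(syn$network)
  od_op <- out_degrees(col2)[names(od_gene)]
  expect_true(all(od_op <= od_gene))
  # oracle: distinct operons among former targets
  for (r in regulators(syn$network)) {
    genes <- syn$network$edges$target[syn$network$edges$regulator == r]
    expect_equal(unname(od_op[r]), length(unique(unclass(syn$map)[genes])))
  }
})

test_that("down-sampling honors its count contract and sub-seed independence", {
  net <- make_bipartite_network(20, 80, "poisson", mean_degree = 5, seed = 71)
  same <- downsample(net, 0, "nodes", trials = 3, seed = 1)
  for (tr in same) expect_identical(tr$edges, net$edges)

  ne <- nrow(net$edges)
  ds <- downsample(net, 0.2, "edges", trials = 3, seed = 2)
  for (tr in ds) expect_equal(nrow(tr$edges), ne - round(0.2 * ne))
  # different trials remove different subsets (overwhelmingly likely)
  expect_false(identical(ds[[1]]$edges, ds[[2]]$edges))

  dn <- downsample(net, 0.4, "nodes", trials = 3, seed = 3)
  for (tr in dn)
    expect_equal(length(tr$nodes),
                 length(net$nodes) - round(0.4 * length(net$nodes)))
})

test_that("partners-vs-targets joins the two networks per regulator", {
  net <- regulatory_network(c("A", "B"), c("g1", "g1"))
  st <- null_cotarget_stats(net, ensemble_size = 5, seed = 1)
  cg <- build_coregulation(net, st, "none")
  ser <- partners_vs_targets(net, cg)
  expect_equal(ser$k, c(1, 1))
  expect_equal(ser$f, c(1, 1))

  other <- make_bipartite_network(5, 10, "fixed", mean_degree = 2, seed = 2)
  expect_error(partners_vs_targets(other, cg), "differ")

  rnd <- make_bipartite_network(12, 40, "poisson", mean_degree = 4, seed = 81)
  str <- null_cotarget_stats(rnd, ensemble_size = 30, seed = 82)
  cgr <- build_coregulation(rnd, str, "cc")
  ser2 <- partners_vs_targets(rnd, cgr)
  # independent recomputation from raw structures
  for (i in seq_len(nrow(ser2))) {
    r <- ser2$regulator[i]
    expect_equal(ser2$k[i], sum(rnd$edges$regulator == r))
    expect_equal(ser2$f[i],
                 sum(cgr$edges$r1 == r) + sum(cgr$edges$r2 == r))
  }
})

test_that("restricted partner pools saturate below their randomization", {
  fit_a <- function(net, sd) {
    st <- null_cotarget_stats(net, ensemble_size = 50, seed = sd)
    cg <- build_coregulation(net, st, "cc")
    fit_exp_saturation(partners_vs_targets(net, cg))$params[["a"]]
  }
  for (s in 1:2) {
    blocks <- block_structured_network(4, 39, 1100, seed = 100 * s)
    mixed <- shuffle_preserving_degrees(blocks, seed = 100 * s + 50)
    a_blocks <- fit_a(blocks, 100 * s + 60)
    a_mixed <- fit_a(mixed, 100 * s + 70)
    expect_lt(a_blocks, a_mixed)
    # within-block plateau cannot exceed the block's partner pool by much
    expect_lt(a_blocks, 39 * 1.5)
  }
})
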