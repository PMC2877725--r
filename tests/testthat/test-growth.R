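test_that("the closed-form partner curve obeys its stated limits", {
  expect_equal(analytic_partner_curve(0, 20, 1000, 10), 0)
  expect_lt(abs(analytic_partner_curve(1e9, 20, 1000, 10) - 20), 1e-6)
  expect_equal(analytic_partner_curve(100, 20, 1000, 10),
               20 * (1 - exp(-1)), tolerance = 1e-12)
  # monotone increasing (non-strict once the plateau saturates in double
  # precision), bounded by m
  k <- seq(0, 5000, by = 25)
  f <- analytic_partner_curve(k, 35, 2000, 15)
  expect_true(all(diff(f) >= 0))
  expect_true(all(diff(f)[k[-1] <= 1000] > 0))
  expect_true(all(f <= 35))
})

test_that("finite differences of the closed form satisfy the rate equation", {
  m <- 20; N <- 5000; n <- 25; h <- 0.5
  k <- seq(0, 400, by = h)
  f <- analytic_partner_curve(k, m, N, n)
  df <- diff(f) / h
  rhs <- (n / N) * (m - analytic_partner_curve(k[-1] - h / 2, m, N, n))
  expect_lt(max(abs(df - rhs)), 1e-6)
})

test_that("the acquisition oracle matches the exact hypergeometric expectation", {
  m <- 12; N <- 800; n <- 15; k_max <- 80
  acq <- simulate_random_acquisition(m, N, n, k_max, replicates = 400,
                                     seed = 5)
  exact <- (m - 1) * (1 - exp(lchoose(N - acq$k, n) - lchoose(N, n)))
  z <- (exact - acq$f) / pmax(acq$se, 1e-9)
  expect_lt(max(abs(z)), 4)

  # no possible partners when alone
  alone <- simulate_random_acquisition(1, 100, 5, 10, replicates = 10,
                                       seed = 1)
  expect_true(all(alone$f == 0))
  expect_error(simulate_random_acquisition(5, 50, 5, k_max = 60), "k_max")
})

test_that("growth config validates its move distribution", {
  expect_error(growth_config(add_tf = 0.5), "sum to 1")
  expect_error(growth_config(add_tf = -0.006, add_tg = 0.092), "nonnegative")
  cfg <- growth_config(seed = 1)
  expect_equal(sum(cfg$move_probs), 1, tolerance = 1e-12)
  expect_equal(cfg$inheritance_rate, 0.3)
  expect_equal(cfg$iterations, 10000L)
})

test_that("forced trajectories and audit bookkeeping are exact", {
  # all probability on target addition: nothing else can ever happen
  cfg <- growth_config(add_tf = 0, add_tg = 1, dup_tf = 0, dup_tg = 0,
                       tf_to_tg = 0, add_edge = 0, del_edge = 0,
                       del_node = 0, iterations = 200, seed = 3)
  net <- simulate_growth(cfg)
  a <- attr(net, "audit")
  expect_equal(a$n_tf, 1)
  expect_equal(a$n_tg, 1 + 200)
  expect_equal(nrow(net$edges), 1)
  expect_equal(length(net$nodes), 202)
  expect_equal(sum(unlist(a$applied)) + sum(unlist(a$skipped)), 200)
})

test_that("edge counts never decrease when deletion moves are disabled", {
  cfg <- growth_config(add_tf = 0.01, add_tg = 0.20, dup_tf = 0.03,
                       dup_tg = 0.20, tf_to_tg = 0.01, add_edge = 0.55,
                       del_edge = 0, del_node = 0, iterations = 2000,
                       seed = 17)
  net <- simulate_growth(cfg)
  traj <- attr(net, "audit")$edge_trajectory
  expect_true(all(diff(traj) >= 0))
})

test_that("growth is bit-reproducible and lands near the reference scale", {
  a <- simulate_growth(growth_config(iterations = 1500, seed = 23))
  b <- simulate_growth(growth_config(iterations = 1500, seed = 23))
  expect_identical(a$edges, b$edges)
  expect_identical(attr(a, "audit")$applied, attr(b, "audit")$applied)

  full <- simulate_growth(growth_config(seed = 2))
  aud <- attr(full, "audit")
  n_tf_like <- aud$n_tf + aud$n_tftg
  expect_gt(n_tf_like, 100)
  expect_lt(n_tf_like, 320)
  expect_gt(aud$n_tg, 1500)
  expect_lt(aud$n_tg, 2800)
})
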