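test_that("closed-form performance matches its defining limits and values", {
  # symmetric zero-drift case
  perf0 <- ddm_expected_performance(ddm_params(v = 0, a = 2))
  expect_equal(perf0$er, 0.5)
  expect_equal(perf0$dt, 1.0)

  # strong drift drives the error rate to zero
  expect_lt(ddm_expected_performance(ddm_params(v = 50, a = 2))$er, 1e-12)

  # moderate drift: ER = 1/(1+e^2), DT = tanh(1)
  perf <- ddm_expected_performance(ddm_params(v = 1, a = 2))
  expect_equal(perf$er, 1 / (1 + exp(2)), tolerance = 1e-12)
  expect_equal(perf$dt, tanh(1), tolerance = 1e-12)

  # sigma rescales: (v, a, sigma) and (v/sigma, a/sigma, 1) agree
  p1 <- ddm_expected_performance(ddm_params(1.3, 1.7, sigma = 0.5))
  p2 <- ddm_expected_performance(ddm_params(1.3 / 0.5^2, 1.7, sigma = 1))
  expect_equal(p1$er, 1 / (1 + exp(1.7 * 1.3 / 0.25)), tolerance = 1e-12)

  # the v -> 0 singularity is removable: values converge to the limit
  near <- ddm_expected_performance(ddm_params(v = 1e-8, a = 2))
  expect_equal(near$er, 0.5, tolerance = 1e-7)
  expect_equal(near$dt, 1.0, tolerance = 1e-7)
})

test_that("invalid parameters raise domain errors naming the field", {
  expect_error(ddm_params(1, a = -1), "`a`", class = "ddmrr_domain_error")
  expect_error(ddm_params(1, 2, sigma = 0), "`sigma`",
               class = "ddmrr_domain_error")
  expect_error(ddm_params(Inf, 2), class = "ddmrr_domain_error")
  expect_error(ddm_params(1, 2, ndt = -0.1), "`ndt`",
               class = "ddmrr_domain_error")
})

test_that("ER and DT are monotone in drift and threshold as theory demands", {
  v <- seq(0.1, 4, length.out = 15)
  a <- seq(0.5, 4, length.out = 15)
  er_v <- vapply(v, function(x)
    ddm_expected_performance(ddm_params(x, 2))$er, 0)
  expect_true(all(diff(er_v) < 0))
  er_a <- vapply(a, function(x)
    ddm_expected_performance(ddm_params(1.5, x))$er, 0)
  expect_true(all(diff(er_a) < 0))
  dt_a <- vapply(a, function(x)
    ddm_expected_performance(ddm_params(1.5, x))$dt, 0)
  expect_true(all(diff(dt_a) > 0))
})

test_that("sampler is deterministic under a seed and respects ndt", {
  p <- ddm_params(1, 2, ndt = 0.4)
  t1 <- simulate_trials(p, 50, seed = 99)
  t2 <- simulate_trials(p, 50, seed = 99)
  expect_identical(t1, t2)
  expect_true(all(t1$rt >= 0.4))
  one <- simulate_trial(p, seed = 99)
  expect_equal(one$rt, t1$rt[1])
  expect_equal(one$correct, t1$correct[1])
})

test_that("simulated accuracy and decision time converge to the closed form", {
  p <- ddm_params(1, 2, ndt = 0.4)
  n <- 2e4
  tr <- simulate_trials(p, n, seed = 4)
  er_se <- sqrt(0.8808 * 0.1192 / n)
  expect_lt(abs(mean(tr$correct) - (1 - 1 / (1 + exp(2)))), 3 * er_se)
  dt_se <- sd(tr$rt) / sqrt(n)
  expect_lt(abs(mean(tr$rt) - 0.4 - tanh(1)), 3 * dt_se)

  tr0 <- simulate_trials(ddm_params(0, 2), n, seed = 5)
  expect_lt(abs(mean(tr0$correct) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("moment estimator recovers generating parameters at large n", {
  truth <- ddm_params(v = 1.5, a = 1.8, ndt = 0.35)
  tr <- simulate_trials(truth, 1e5, seed = 21)
  est <- estimate_ddm(tr)
  expect_lt(abs(est$v - 1.5) / 1.5, 0.05)
  expect_lt(abs(est$a - 1.8) / 1.8, 0.05)
  expect_lt(abs(est$ndt - 0.35), 0.02)
})

test_that("estimation error shrinks as the trial count grows", {
  truth <- ddm_params(v = 1.2, a = 1.6, ndt = 0.3)
  rel_err <- vapply(c(1e3, 1e5), function(n) {
    est <- estimate_ddm(simulate_trials(truth, n, seed = 31))
    abs(est$v - truth$v) / truth$v + abs(est$a - truth$a) / truth$a
  }, 0)
  expect_gt(rel_err[1], rel_err[2])
})

test_that("degenerate accuracies raise classed edge-case conditions", {
  base <- data.frame(rt = rep(0.6, 200), correct = TRUE)
  err <- tryCatch(estimate_ddm(base), condition = identity)
  expect_s3_class(err, "ddmrr_edge_case")
  expect_identical(err$code, "all_correct")

  base$correct <- FALSE
  err <- tryCatch(estimate_ddm(base), condition = identity)
  expect_identical(err$code, "all_errors")

  base$correct <- rep(c(TRUE, FALSE), 100)
  base$rt <- runif(200, 0.4, 1)
  err <- tryCatch(estimate_ddm(base), condition = identity)
  expect_identical(err$code, "chance_accuracy")

  expect_error(estimate_ddm(data.frame(rt = rep(0.5, 50),
                                       correct = rep(c(TRUE, FALSE), 25))),
               "at least", class = "ddmrr_domain_error")
})

test_that("Wiener first-passage density integrates to the choice probability", {
  v <- 1.2; a <- 1.7
  er <- 1 / (1 + exp(a * v))
  tt <- seq(1e-4, 20, length.out = 20000)
  dtt <- tt[2] - tt[1]
  p_up <- sum(ddmrr:::wiener_fpt_density(tt, v, a, boundary = "upper")) * dtt
  p_lo <- sum(ddmrr:::wiener_fpt_density(tt, v, a, boundary = "lower")) * dtt
  expect_equal(p_up, 1 - er, tolerance = 1e-3)
  expect_equal(p_lo, er, tolerance = 1e-3)
  # mean decision time implied by the density matches the closed form
  m <- sum(tt * (ddmrr:::wiener_fpt_density(tt, v, a, boundary = "upper") +
                   ddmrr:::wiener_fpt_density(tt, v, a, boundary = "lower"))) * dtt
  expect_equal(m, (a / (2 * v)) * tanh(a * v / 2), tolerance = 1e-3)
})

test_that("compiled Wiener likelihood matches the series density in R", {
  set.seed(70)
  rt <- runif(50, 0.45, 2)
  correct <- runif(50) < 0.85
  for (par in list(c(1.2, 1.7, 0.3), c(0.6, 2.5, 0.4), c(2.5, 0.9, 0.2))) {
    td <- rt - par[3]
    d <- numeric(length(td))
    d[correct] <- ddmrr:::wiener_fpt_density(td[correct], par[1], par[2],
                                             boundary = "upper")
    d[!correct] <- ddmrr:::wiener_fpt_density(td[!correct], par[1], par[2],
                                              boundary = "lower")
    expect_equal(ddmrr:::wiener_nll_cpp(rt, correct, par[1], par[2], par[3], 1),
                 -sum(log(d)), tolerance = 1e-8)
  }
})

test_that("maximum-likelihood refinement stays close to the generating truth", {
  truth <- ddm_params(v = 1.5, a = 1.8, ndt = 0.35)
  tr <- simulate_trials(truth, 3000, seed = 44)
  est <- estimate_ddm(tr, method = "ml")
  expect_lt(abs(est$v - truth$v) / truth$v, 0.1)
  expect_lt(abs(est$a - truth$a) / truth$a, 0.1)
  expect_lt(abs(est$ndt - truth$ndt), 0.03)
})
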