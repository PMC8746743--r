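test_that("reward rate reproduces hand-computed values", {
  p <- ddm_params(v = 1, a = 2, ndt = 0.4)
  w <- incentive_weights(5, 5)
  er <- 1 / (1 + exp(2))
  expected <- (5 * (1 - er) - 5 * er) / (tanh(1) + 0.4) - 1
  expect_equal(reward_rate(p, w), expected, tolerance = 1e-12)
  expect_equal(reward_rate(p, w), 2.278, tolerance = 1e-3)

  # dropping the quadratic cost adds back exactly v^2 = 1
  expect_equal(reward_rate(p, w, cost_spec("none")),
               reward_rate(p, w) + 1, tolerance = 1e-12)

  # zero drift with symmetric incentives: numerator cancels, cost(0) = 0
  expect_equal(reward_rate(ddm_params(0, 2, 0.4), incentive_weights(7, 7)),
               0, tolerance = 1e-12)
})

test_that("cost forms evaluate and differentiate as specified", {
  p <- ddm_params(v = 1, a = 2, ndt = 0.4)
  w <- incentive_weights(5, 5)
  base <- reward_rate(p, w, cost_spec("none"))
  expect_equal(reward_rate(p, w, cost_spec("linear", 2)), base - 2 * 1)
  expect_equal(reward_rate(p, w, cost_spec("exponential")),
               base - (exp(1) - 1))
  # quadratic cost converges pointwise to the uncosted objective as E -> 0
  for (E in c(1e-2, 1e-5)) {
    expect_equal(reward_rate(p, w, cost_spec("quadratic", E)), base - E,
                 tolerance = 1e-12)
  }
  # linear cost is non-differentiable at v = 0
  expect_error(reward_rate_gradient(ddm_params(0, 2, 0.4), w,
                                    cost_spec("linear")),
               class = "ddmrr_nondifferentiable")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(7)
  w <- incentive_weights(12, 30)
  for (i in 1:10) {
    v <- runif(1, 0.2, 4); a <- runif(1, 0.3, 4); ndt <- runif(1, 0.2, 0.6)
    for (form in c("quadratic", "linear", "exponential")) {
      cost <- cost_spec(form)
      g <- reward_rate_gradient(ddm_params(v, a, ndt), w, cost)
      h <- 1e-5
      fd_v <- (reward_rate(ddm_params(v + h, a, ndt), w, cost) -
                 reward_rate(ddm_params(v - h, a, ndt), w, cost)) / (2 * h)
      fd_a <- (reward_rate(ddm_params(v, a + h, ndt), w, cost) -
                 reward_rate(ddm_params(v, a - h, ndt), w, cost)) / (2 * h)
      expect_equal(g[["dv"]], fd_v, tolerance = 1e-6)
      expect_equal(g[["da"]], fd_a, tolerance = 1e-6)
    }
  }
})

test_that("gradient components are affine in the incentive weights", {
  p <- ddm_params(1.3, 1.1, 0.4)
  cost <- cost_spec()
  g1 <- reward_rate_gradient(p, incentive_weights(6, 9), cost)
  g2 <- reward_rate_gradient(p, incentive_weights(12, 18), cost)
  cd <- 2 * p$v  # drift-cost derivative, incentive-independent
  expect_equal(g2[["dv"]] + cd, 2 * (g1[["dv"]] + cd), tolerance = 1e-10)
  expect_equal(g2[["da"]], 2 * g1[["da"]], tolerance = 1e-10)
})

test_that("reward rate increases in R and decreases in P at interior points", {
  p <- ddm_params(1, 1.5, 0.4)
  rr <- function(R, P) reward_rate(p, incentive_weights(R, P))
  expect_gt(rr(11, 10), rr(10, 10))
  expect_lt(rr(10, 11), rr(10, 10))
})

test_that("without an effort cost the objective grows without bound in drift", {
  w <- incentive_weights(5, 5)
  sup_at <- vapply(c(5, 10, 20, 40), function(V) {
    a <- exp(seq(log(0.01), log(20), length.out = 200))
    max(vapply(a, function(ai)
      reward_rate(ddm_params(V, ai, 0.4), w, cost_spec("none")), 0))
  }, 0)
  expect_true(all(diff(sup_at) > 0))
})
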