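test_that("condition sets and designs encode the two task layouts", {
  cs1 <- condition_set(1)
  expect_equal(nrow(cs1), 4)
  expect_setequal(cs1$reward_level, c(1, 10))
  cs2 <- condition_set(2)
  expect_equal(nrow(cs2), 9)
  expect_setequal(unique(cs2$penalty_level), c(1, 5, 10))

  d1 <- experiment_design(study = 1)
  expect_equal(d1$intervals_per_condition, 20L)
  d2 <- experiment_design(study = 2)
  expect_equal(d2$intervals_per_condition, 8L)
  expect_error(experiment_design(congruent_fraction = 1),
               class = "ddmrr_config_error")
})

test_that("profiles inherit optimality and congruence structure", {
  # equal weights in all conditions -> identical parameters everywhere
  wts <- condition_set(1)
  wts$reward <- 10; wts$penalty <- 10
  prof <- build_profile(weights = wts)
  congr <- prof$table[prof$table$congruent == 1, ]
  expect_equal(var(congr$v), 0, tolerance = 1e-12)
  expect_equal(var(congr$a), 0, tolerance = 1e-12)

  # default map: higher reward level -> strictly larger congruent drift
  prof2 <- build_profile(study = 1)
  congr2 <- prof2$table[prof2$table$congruent == 1, ]
  for (p in unique(congr2$penalty_level)) {
    sub <- congr2[congr2$penalty_level == p, ]
    expect_gt(sub$v[sub$reward_level == 10], sub$v[sub$reward_level == 1])
  }
  # incongruent trials: lower drift, higher threshold
  incon <- prof2$table[prof2$table$congruent == 0, ]
  expect_true(all(incon$v <= congr2$v))
  expect_true(all(incon$a >= congr2$a))

  # zero offsets -> shared parameters across congruence
  prof3 <- build_profile(study = 1,
                         congruence_offsets = list(drift = 0, threshold = 0))
  expect_equal(prof3$table$v[prof3$table$congruent == 0],
               prof3$table$v[prof3$table$congruent == 1])

  # invalid offsets are rejected
  expect_error(build_profile(study = 1,
                             congruence_offsets = list(drift = 0.2,
                                                       threshold = 0.1)),
               class = "ddmrr_config_error")
})

test_that("generated sessions are reproducible and conserve accounting", {
  des <- experiment_design(study = 1, n_subjects = 2,
                           intervals_per_condition = 3)
  prof <- build_profile(study = 1)
  sim1 <- generate_experiment(des, prof, seed = 123)
  sim2 <- generate_experiment(des, prof, seed = 123)
  expect_identical(sim1, sim2)

  tr <- sim1$trials; iv <- sim1$intervals
  # earnings conservation per interval and overall
  for (i in seq_len(nrow(iv))) {
    expect_equal(iv$earnings[i],
                 iv$condition_reward[i] * iv$n_correct[i] -
                   iv$condition_penalty[i] * iv$n_error[i])
  }
  expect_equal(sum(tr$earnings), sum(iv$earnings))
  expect_equal(iv$correct_per_second, iv$n_correct / iv$duration)
  # cumulative earnings are a running sum within subject
  for (s in unique(iv$subject)) {
    sub <- iv[iv$subject == s, ]
    expect_equal(sub$cum_earnings, cumsum(sub$earnings))
  }
  # trials fit inside their interval
  agg <- tapply(tr$rt, interaction(tr$subject, tr$interval, drop = TRUE), sum)
  key <- interaction(iv$subject, iv$interval, drop = TRUE)
  expect_true(all(agg <= iv$duration[match(names(agg), as.character(key))]))
  expect_true(all(iv$duration >= 8 & iv$duration <= 12))
})

test_that("trial counts follow the renewal expectation duration / mean RT", {
  # a single condition with known parameters: mean RT = DT + ndt
  params <- data.frame(reward_level = 1, penalty_level = 1, v = 2, a = 1.2)
  prof <- build_profile(params = params, ndt = 0.4,
                        congruence_offsets = list(drift = 0, threshold = 0))
  des <- experiment_design(study = 1, n_subjects = 1,
                           intervals_per_condition = 60)
  des$conditions <- des$conditions[des$conditions$reward_level == 1 &
                                     des$conditions$penalty_level == 1, ]
  sim <- generate_experiment(des, prof, seed = 17)
  perf <- ddm_expected_performance(ddm_params(2, 1.2))
  mean_rt <- perf$dt + 0.4
  expected <- mean(sim$intervals$duration) / mean_rt
  observed <- mean(sim$intervals$n_trials)
  # packing discards the in-flight trial, so slightly below expectation
  expect_lt(abs(observed - expected) / expected, 0.12)
})

test_that("congruence is i.i.d. with the design fraction, varying by interval", {
  des <- experiment_design(study = 1, n_subjects = 1,
                           intervals_per_condition = 10)
  sim <- generate_experiment(des, build_profile(study = 1), seed = 5)
  f <- mean(sim$trials$congruent)
  n <- nrow(sim$trials)
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / n))
  by_int <- tapply(sim$trials$congruent, sim$trials$interval, mean)
  expect_gt(sd(by_int), 0)  # proportion varies across intervals
})

test_that("truncate mode records the in-flight trial as an omission", {
  des <- experiment_design(study = 1, n_subjects = 1,
                           intervals_per_condition = 3,
                           interval_end = "truncate")
  sim <- generate_experiment(des, build_profile(study = 1), seed = 2)
  om <- sim$trials[is.na(sim$trials$correct), ]
  expect_gt(nrow(om), 0)
  expect_true(all(om$earnings == 0))
  # omissions don't enter the interval scoring
  expect_equal(sum(sim$intervals$n_trials),
               sum(!is.na(sim$trials$correct)))
})

test_that("a profile missing a design condition is a configuration error", {
  des <- experiment_design(study = 2, n_subjects = 1,
                           intervals_per_condition = 1)
  prof <- build_profile(study = 1)  # lacks the 5-cent conditions
  expect_error(generate_experiment(des, prof, seed = 1),
               "lacks condition", class = "ddmrr_config_error")
})

test_that("behavioral summary reproduces hand-computed values on a toy table", {
  toy <- toy_tables()
  s <- summarize_behavior(toy$trials, toy$intervals, n_boot = 50)
  row1 <- s$by_condition[s$by_condition$condition_reward == 1, ]
  expect_equal(row1$accuracy, 0.75)
  expect_equal(row1$rt_correct, mean(c(0.5, 0.7, 0.8)))
  expect_equal(row1$correct_per_second, 0.3)
  # duration 10 s with 8 correct responses -> 0.8 correct per second
  expect_equal(8 / 10, 0.8)
  con <- s$contrasts
  cps <- con[con$measure == "correct_per_second" & con$incentive == "reward", ]
  expect_equal(cps$estimate, 0.1)
})

test_that("summary warns on missing condition cells instead of dropping them", {
  toy <- toy_tables()
  # remove one condition from the interval table only
  expect_error(summarize_behavior(toy$trials[0, ], toy$intervals),
               class = "ddmrr_domain_error")
  tr <- toy$trials
  tr$condition_penalty[tr$condition_reward == 1] <- 10
  expect_warning(summarize_behavior(tr, toy$intervals), "no data")
})
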