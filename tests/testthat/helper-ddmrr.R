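# shared fixtures and small oracles for the test suite

# closed-form reference values computed directly from the ER/DT formulas
# (independent arithmetic, not via the package's vectorized path)
ref_perf <- function(v, a, sigma = 1) {
  if (abs(v) < 1e-12) return(list(er = 0.5, dt = a^2 / (4 * sigma^2)))
  list(er = 1 / (1 + exp(a * v / sigma^2)),
       dt = (a / (2 * v)) * tanh(a * v / (2 * sigma^2)))
}

# brute-force reward rate on a dense log grid; returns the argmax cell
grid_argmax <- function(R, P, ndt = 0.4, E = 1, n = 400,
                        v_rng = c(1e-3, 50), a_rng = c(1e-2, 20)) {
  vg <- exp(seq(log(v_rng[1]), log(v_rng[2]), length.out = n))
  ag <- exp(seq(log(a_rng[1]), log(a_rng[2]), length.out = n))
  best <- c(v = NA, a = NA, rr = -Inf)
  for (a in ag) {
    er <- 1 / (1 + exp(a * vg))
    dt <- ifelse(abs(vg) < 1e-9, a^2 / 4, (a / (2 * vg)) * tanh(a * vg / 2))
    rr <- (R * (1 - er) - P * er) / (dt + ndt) - E * vg^2
    i <- which.max(rr)
    if (rr[i] > best["rr"]) best <- c(v = vg[i], a = a, rr = rr[i])
  }
  list(v = unname(best["v"]), a = unname(best["a"]), rr = unname(best["rr"]),
       log_step_v = diff(log(v_rng)) / (n - 1),
       log_step_a = diff(log(a_rng)) / (n - 1))
}

# tiny deterministic trial table for summary arithmetic checks
toy_tables <- function() {
  trials <- data.frame(
    subject = 1L, block = 1L, interval = rep(1:2, each = 4), trial = rep(1:4, 2),
    condition_reward = rep(c(1, 10), each = 4),
    condition_penalty = 1,
    congruent = rep(c(1L, 0L), 4),
    rt = c(0.5, 0.7, 0.6, 0.8, 0.4, 0.5, 0.6, 0.5),
    correct = c(1L, 1L, 0L, 1L, 1L, 1L, 1L, 1L),
    earnings = c(1, 1, -1, 1, 10, 10, 10, 10))
  intervals <- data.frame(
    subject = 1L, interval = 1:2,
    condition_reward = c(1, 10), condition_penalty = 1,
    duration = c(10, 10), n_trials = c(4L, 4L),
    n_correct = c(3L, 4L), n_error = c(1L, 0L),
    correct_per_second = c(0.3, 0.4),
    earnings = c(2, 40), cum_earnings = c(2, 42))
  list(trials = trials, intervals = intervals)
}
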