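#' Incentive conditions of the interval-based Stroop task
#'
#' The task crosses a cued reward per correct response with a cued penalty
#' per error, both in cents. The two-level design crosses {1, 10} cents
#' with {1, 10} cents (four conditions); the three-level design crosses
#' {1, 5, 10} cents with {1, 5, 10} cents (nine conditions).
#'
#' @param study 1 (2 x 2 design) or 2 (3 x 3 design).
#' @return data.frame with columns `reward_level`, `penalty_level` (cents)
#'   and `label`.
#' @examples
#' condition_set(1)
#' @export
condition_set <- function(study = 1) {
  levels <- switch(as.character(study),
                   "1" = c(1, 10),
                   "2" = c(1, 5, 10),
                   stop_ddmrr("`study` must be 1 or 2", "ddmrr_config_error"))
  cs <- expand.grid(reward_level = levels, penalty_level = levels,
                    KEEP.OUT.ATTRS = FALSE)
  cs$label <- sprintf("R%d_P%d", cs$reward_level, cs$penalty_level)
  cs
}

#' Experiment design for the interval-based incentivized Stroop task
#'
#' Describes the self-paced task structure: fixed-duration intervals
#' (uniform on 8--12 s) during which a simulated participant completes as
#' many Stroop trials as fit, with congruent and incongruent trials mixed
#' 1:1 on average (congruence is i.i.d. per trial, so the realized
#' proportion varies slightly across intervals). Each incentive condition
#' is cued per interval and repeated `intervals_per_condition` times (20 in
#' the two-level design, 8 in the three-level one). The block and
#' counterbalance structure (one incentive fixed per block, the other
#' varying, swapped halfway) is recorded as metadata only; it does not
#' enter the generative process.
#'
#' @param study 1 or 2 (sets the condition set and per-condition interval
#'   count defaults).
#' @param n_subjects number of simulated participants.
#' @param intervals_per_condition intervals per condition per subject.
#' @param interval_duration_range length-2 numeric (s), uniform sampling
#'   range.
#' @param congruent_fraction probability a trial is congruent, in (0, 1).
#' @param interval_end one of `"discard"` (a trial still running when the
#'   interval ends is dropped) or `"truncate"` (recorded as an omission
#'   with censored RT and no earnings).
#' @return object of class `experiment_design`.
#' @examples
#' experiment_design(study = 1, n_subjects = 2)
#' @export
experiment_design <- function(study = 1, n_subjects = 1,
                              intervals_per_condition = NULL,
                              interval_duration_range = c(8, 12),
                              congruent_fraction = 0.5,
                              interval_end = c("discard", "truncate")) {
  interval_end <- match.arg(interval_end)
  conditions <- condition_set(study)
  if (is.null(intervals_per_condition))
    intervals_per_condition <- if (study == 1) 20L else 8L
  stopifnot(n_subjects >= 1, intervals_per_condition >= 1,
            length(interval_duration_range) == 2L,
            interval_duration_range[1] <= interval_duration_range[2],
            all(interval_duration_range >= 8),
            all(interval_duration_range <= 12))
  if (congruent_fraction <= 0 || congruent_fraction >= 1)
    stop_ddmrr("`congruent_fraction` must be strictly inside (0, 1)",
               "ddmrr_config_error")
  n_blocks <- if (study == 1) 4L else 6L
  structure(list(
    study = study, n_subjects = as.integer(n_subjects),
    conditions = conditions,
    intervals_per_condition = as.integer(intervals_per_condition),
    interval_duration_range = as.numeric(interval_duration_range),
    congruent_fraction = congruent_fraction,
    interval_end = interval_end,
    block_scheme = sprintf(
      "%d blocks; one incentive fixed per block, the other varying, swapped halfway; counterbalanced order (metadata only)",
      n_blocks),
    n_blocks = n_blocks
  ), class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "Incentivized Stroop design (study %d): %d subject(s), %d conditions x %d intervals, %g-%g s intervals\n",
    x$study, x$n_subjects, nrow(x$conditions), x$intervals_per_condition,
    x$interval_duration_range[1], x$interval_duration_range[2]))
  invisible(x)
}

#' Default mapping from incentive cents to subjective weights
#'
#' Converts cued monetary levels into subjective incentive weights in
#' effort-cost units, log-linearly in the cent amount: reward 1 cent maps
#' to weight 8 and 10 cents to 20 (the span over which the normative
#' predictions are tabulated), and penalty weight is `5 * cents` (1 cent
#' maps to 5, 10 cents to 50), reflecting the steeper subjective weighting
#' of losses. Both mappings are monotone in the cued amount.
#'
#' @param conditions data.frame with `reward_level` and `penalty_level`
#'   columns in cents (e.g. from [condition_set()]).
#' @return the input with `reward` and `penalty` weight columns added.
#' @examples
#' default_incentive_map(condition_set(1))
#' @export
default_incentive_map <- function(conditions) {
  stopifnot(all(c("reward_level", "penalty_level") %in% names(conditions)))
  out <- conditions
  out$reward <- 8 * 2.5^log10(out$reward_level)
  out$penalty <- 5 * out$penalty_level
  out
}

#' Build a subject profile of condition-wise DDM parameters
#'
#' Turns ground-truth incentive weights into the condition-wise control
#' configuration a reward-rate-optimizing participant would adopt: for each
#' condition, `(v, a)` is the optimum under that condition's weights, and
#' incongruent trials get a drift decrement and threshold increment on top
#' (the Stroop congruence effect). Alternatively, explicit per-condition
#' DDM parameters can be supplied via `params`, bypassing the optimization.
#'
#' @param weights data.frame mapping conditions to subjective weights:
#'   columns `reward_level`, `penalty_level`, `reward`, `penalty`. Defaults
#'   to [default_incentive_map()] over `conditions`.
#' @param conditions condition table (default [condition_set()] for
#'   `study`); ignored when `weights` is given.
#' @param study used only for the default `conditions`.
#' @param congruence_offsets list with `drift` (<= 0, added to incongruent
#'   drift) and `threshold` (>= 0, added to incongruent threshold).
#' @param ndt non-decision time (s), shared across conditions.
#' @param cost a [cost_spec()].
#' @param sigma diffusion coefficient.
#' @param params optional data.frame with columns `reward_level`,
#'   `penalty_level`, `v`, `a`: explicit congruent-trial parameters per
#'   condition.
#' @param ... passed to [optimize_policy()].
#' @return object of class `subject_profile` with a `table` of per
#'   condition x congruence DDM parameters.
#' @examples
#' prof <- build_profile(study = 1)
#' prof$table
#' @export
build_profile <- function(weights = NULL, conditions = NULL, study = 1,
                          congruence_offsets = list(drift = -0.3,
                                                    threshold = 0.1),
                          ndt = 0.4, cost = cost_spec(), sigma = 1,
                          params = NULL, ...) {
  cost <- as_cost_spec(cost)
  d_off <- congruence_offsets$drift
  a_off <- congruence_offsets$threshold
  if (is.null(d_off) || is.null(a_off) || d_off > 0 || a_off < 0)
    stop_ddmrr(paste("congruence offsets must have drift <= 0 and",
                     "threshold >= 0 (incongruent trials cannot have higher",
                     "drift or lower threshold than congruent ones)"),
               "ddmrr_config_error")

  if (is.null(params)) {
    if (is.null(weights)) {
      if (is.null(conditions)) conditions <- condition_set(study)
      weights <- default_incentive_map(conditions)
    }
    stopifnot(all(c("reward_level", "penalty_level", "reward", "penalty")
                  %in% names(weights)))
    if (any(weights$reward <= 0) || any(weights$penalty < 0))
      stop_ddmrr("subjective weights must be positive", "ddmrr_config_error")
    base <- do.call(rbind, lapply(seq_len(nrow(weights)), function(i) {
      pol <- optimize_policy(
        incentive_weights(weights$reward[i], weights$penalty[i]),
        ndt = ndt, cost = cost, sigma = sigma, ...)
      data.frame(reward_level = weights$reward_level[i],
                 penalty_level = weights$penalty_level[i],
                 reward = weights$reward[i], penalty = weights$penalty[i],
                 v = pol$v_star, a = pol$a_star)
    }))
  } else {
    stopifnot(all(c("reward_level", "penalty_level", "v", "a")
                  %in% names(params)))
    base <- params
    base$reward <- NA_real_
    base$penalty <- NA_real_
  }

  tab <- rbind(
    transform(base, congruent = 1L),
    transform(base, congruent = 0L, v = base$v + d_off,
              a = base$a + a_off)
  )
  if (any(tab$v[tab$congruent == 0L] > tab$v[tab$congruent == 1L]) ||
      any(tab$a[tab$congruent == 0L] < tab$a[tab$congruent == 1L]))
    stop_ddmrr("congruence offsets violate the profile invariants",
               "ddmrr_config_error")
  rownames(tab) <- NULL
  structure(list(table = tab, ndt = ndt, sigma = sigma, cost = cost,
                 congruence_offsets = list(drift = d_off, threshold = a_off),
                 weights = if (is.null(params)) weights else NULL),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "Subject profile: %d conditions, ndt = %.3g s, congruence offsets (drift %+.3g, threshold %+.3g)\n",
    nrow(x$table) / 2, x$ndt, x$congruence_offsets$drift,
    x$congruence_offsets$threshold))
  print(x$table[x$table$congruent == 1L,
                c("reward_level", "penalty_level", "v", "a")], row.names = FALSE)
  invisible(x)
}

#' Simulate the interval-based incentivized Stroop experiment
#'
#' Packs self-paced DDM trials into fixed-duration intervals: within each
#' interval a new trial starts immediately after each response, congruence
#' is drawn i.i.d., and the trial whose RT would overrun the interval end
#' is discarded (or recorded as an omission, per the design). Each correct
#' response earns the condition's reward level in cents and each error
#' loses its penalty level; interval records track the per-second rate of
#' correct responses and cumulative earnings.
#'
#' @param design an [experiment_design()].
#' @param profiles a single [build_profile()] result (shared by all
#'   subjects) or a list of one per subject.
#' @param seed master integer seed; per-subject streams are derived from it
#'   with [derive_seeds()].
#' @param dt integration step for the trial sampler (s).
#' @return list with `trials` and `intervals` data.frames. Trial columns:
#'   `subject`, `block`, `interval`, `trial`, `condition_reward`,
#'   `condition_penalty`, `congruent` (0/1), `rt` (s), `correct` (0/1; NA
#'   for a truncated omission), `earnings` (cents). Interval columns add
#'   `duration`, `n_trials`, `n_correct`, `n_error`, `correct_per_second`,
#'   `earnings`, `cum_earnings`.
#' @examples
#' \donttest{
#' des <- experiment_design(study = 1, n_subjects = 1,
#'                          intervals_per_condition = 2)
#' sim <- generate_experiment(des, build_profile(study = 1), seed = 1)
#' head(sim$intervals)
#' }
#' @export
generate_experiment <- function(design, profiles, seed, dt = 1e-3) {
  stopifnot(inherits(design, "experiment_design"))
  if (inherits(profiles, "subject_profile"))
    profiles <- rep(list(profiles), design$n_subjects)
  if (length(profiles) != design$n_subjects)
    stop_ddmrr("need one profile, or one per subject", "ddmrr_config_error")

  seeds <- derive_seeds(seed, design$n_subjects)
  all_trials <- vector("list", design$n_subjects)
  all_intervals <- vector("list", design$n_subjects)

  for (s in seq_len(design$n_subjects)) {
    prof <- profiles[[s]]
    # every design condition must be present in the profile
    key_d <- with(design$conditions, paste(reward_level, penalty_level))
    key_p <- with(prof$table, paste(reward_level, penalty_level))
    if (!all(key_d %in% key_p))
      stop_ddmrr(sprintf(
        "profile for subject %d lacks condition(s): %s", s,
        paste(setdiff(key_d, key_p), collapse = ", ")),
        "ddmrr_config_error")

    res <- with_seed(seeds[s],
                     simulate_subject(design, prof, subject = s, dt = dt))
    all_trials[[s]] <- res$trials
    all_intervals[[s]] <- res$intervals
  }
  list(trials = do.call(rbind, all_trials),
       intervals = do.call(rbind, all_intervals))
}

# one subject's session; assumes the RNG stream is already positioned
simulate_subject <- function(design, prof, subject, dt) {
  cond <- design$conditions
  n_int <- nrow(cond) * design$intervals_per_condition
  order_idx <- sample(rep(seq_len(nrow(cond)), design$intervals_per_condition))
  durations <- runif(n_int, design$interval_duration_range[1],
                     design$interval_duration_range[2])
  per_block <- ceiling(n_int / design$n_blocks)

  lookup <- prof$table
  trials <- list()
  intervals <- list()
  cum <- 0
  for (i in seq_len(n_int)) {
    ci <- order_idx[i]
    rl <- cond$reward_level[ci]; pl <- cond$penalty_level[ci]
    rows_c <- lookup[lookup$reward_level == rl & lookup$penalty_level == pl, ]
    t_used <- 0
    k <- 0L
    rec <- list()
    repeat {
      congr <- as.integer(runif(1) < design$congruent_fraction)
      pr <- rows_c[rows_c$congruent == congr, ]
      one <- ddm_sample_cpp(1L, pr$v, pr$a, prof$ndt, prof$sigma, dt, 30)
      rt <- one$rt[1]
      if (t_used + rt > durations[i]) {
        if (design$interval_end == "truncate") {
          k <- k + 1L
          rec[[k]] <- data.frame(
            subject = subject, block = ceiling(i / per_block), interval = i,
            trial = k, condition_reward = rl, condition_penalty = pl,
            congruent = congr, rt = durations[i] - t_used,
            correct = NA_integer_, earnings = 0)
        }
        break
      }
      t_used <- t_used + rt
      k <- k + 1L
      corr <- as.integer(one$correct[1])
      rec[[k]] <- data.frame(
        subject = subject, block = ceiling(i / per_block), interval = i,
        trial = k, condition_reward = rl, condition_penalty = pl,
        congruent = congr, rt = rt, correct = corr,
        earnings = if (corr == 1L) rl else -pl)
    }
    tr <- if (k > 0L) do.call(rbind, rec) else NULL
    n_correct <- if (is.null(tr)) 0L else sum(tr$correct == 1L, na.rm = TRUE)
    n_error <- if (is.null(tr)) 0L else sum(tr$correct == 0L, na.rm = TRUE)
    earn <- rl * n_correct - pl * n_error
    cum <- cum + earn
    intervals[[i]] <- data.frame(
      subject = subject, interval = i, condition_reward = rl,
      condition_penalty = pl, duration = durations[i],
      n_trials = n_correct + n_error, n_correct = n_correct,
      n_error = n_error, correct_per_second = n_correct / durations[i],
      earnings = earn, cum_earnings = cum)
    if (!is.null(tr)) trials[[length(trials) + 1L]] <- tr
  }
  list(trials = do.call(rbind, trials),
       intervals = do.call(rbind, intervals))
}

#' Condition-level behavioral summary with incentive contrasts
#'
#' Descriptive layer over the simulated tables: per condition, the mean RT
#' of correct responses, accuracy, and correct responses per second; plus
#' within-subject contrasts of each measure between the highest and lowest
#' reward level (averaged over penalty) and between the highest and lowest
#' penalty level (averaged over reward), with percentile bootstrap
#' confidence intervals from resampling subjects (with a single subject the
#' CIs are NA).
#'
#' @param trials,intervals tables from [generate_experiment()].
#' @param n_boot bootstrap replicates for the contrast CIs.
#' @param conf confidence level.
#' @param seed optional seed for the bootstrap.
#' @return list with `by_condition` (one row per condition) and
#'   `contrasts` (one row per measure x incentive axis, with `estimate`,
#'   `lower`, `upper`).
#' @export
summarize_behavior <- function(trials, intervals, n_boot = 1000,
                               conf = 0.95, seed = NULL) {
  need_t <- c("subject", "condition_reward", "condition_penalty", "rt", "correct")
  need_i <- c("subject", "condition_reward", "condition_penalty",
              "correct_per_second")
  if (!is.data.frame(trials) || nrow(trials) == 0 ||
      !all(need_t %in% names(trials)))
    stop_ddmrr("`trials` is empty or lacks required columns",
               "ddmrr_domain_error")
  if (!is.data.frame(intervals) || nrow(intervals) == 0 ||
      !all(need_i %in% names(intervals)))
    stop_ddmrr("`intervals` is empty or lacks required columns",
               "ddmrr_domain_error")

  # per-subject x condition cell means
  cells <- subject_condition_cells(trials, intervals)

  # condition-level summary (mean over subjects)
  agg <- aggregate(cells[c("rt_correct", "accuracy", "correct_per_second")],
                   by = cells[c("condition_reward", "condition_penalty")],
                   FUN = mean, na.rm = TRUE)
  full <- expand.grid(condition_reward = sort(unique(trials$condition_reward)),
                      condition_penalty = sort(unique(trials$condition_penalty)),
                      KEEP.OUT.ATTRS = FALSE)
  agg <- merge(full, agg, all.x = TRUE)
  if (anyNA(agg[c("rt_correct", "accuracy", "correct_per_second")]))
    warning("some condition cells have no data; summaries are NA there")

  contrasts <- incentive_contrasts(cells, n_boot = n_boot, conf = conf,
                                   seed = seed)
  list(by_condition = agg, contrasts = contrasts)
}

subject_condition_cells <- function(trials, intervals) {
  key <- interaction(trials$subject, trials$condition_reward,
                     trials$condition_penalty, drop = TRUE)
  scored <- !is.na(trials$correct)
  rtc <- tapply(trials$rt[scored & trials$correct == 1L],
                key[scored & trials$correct == 1L], mean)
  acc <- tapply(trials$correct[scored], key[scored], mean)
  cell_ids <- unique(trials[c("subject", "condition_reward",
                              "condition_penalty")])
  cell_ids <- cell_ids[order(cell_ids$subject, cell_ids$condition_reward,
                             cell_ids$condition_penalty), ]
  k <- with(cell_ids, interaction(subject, condition_reward,
                                  condition_penalty, drop = TRUE))
  cell_ids$rt_correct <- as.numeric(rtc[as.character(k)])
  cell_ids$accuracy <- as.numeric(acc[as.character(k)])
  ikey <- interaction(intervals$subject, intervals$condition_reward,
                      intervals$condition_penalty, drop = TRUE)
  cps <- tapply(intervals$correct_per_second, ikey, mean)
  cell_ids$correct_per_second <- as.numeric(cps[as.character(k)])
  rownames(cell_ids) <- NULL
  cell_ids
}

incentive_contrasts <- function(cells, n_boot, conf, seed) {
  measures <- c("rt_correct", "accuracy", "correct_per_second")
  rlev <- sort(unique(cells$condition_reward))
  plev <- sort(unique(cells$condition_penalty))

  per_subject <- function(cdf) {
    out <- c()
    for (m in measures) {
      hi_r <- mean(cdf[[m]][cdf$condition_reward == max(rlev)], na.rm = TRUE)
      lo_r <- mean(cdf[[m]][cdf$condition_reward == min(rlev)], na.rm = TRUE)
      hi_p <- mean(cdf[[m]][cdf$condition_penalty == max(plev)], na.rm = TRUE)
      lo_p <- mean(cdf[[m]][cdf$condition_penalty == min(plev)], na.rm = TRUE)
      out <- c(out, hi_r - lo_r, hi_p - lo_p)
    }
    names(out) <- paste(rep(measures, each = 2), c("reward", "penalty"),
                        sep = ".")
    out
  }

  subs <- unique(cells$subject)
  mat <- t(vapply(subs, function(s)
    per_subject(cells[cells$subject == s, ]), numeric(2 * length(measures))))
  est <- colMeans(mat, na.rm = TRUE)

  boot <- with_seed(seed, {
    if (length(subs) > 1) {
      t(vapply(seq_len(n_boot), function(b) {
        idx <- sample(length(subs), replace = TRUE)
        colMeans(mat[idx, , drop = FALSE], na.rm = TRUE)
      }, est))
    } else {
      NULL
    }
  })
  alpha <- (1 - conf) / 2
  lower <- upper <- rep(NA_real_, length(est))
  if (!is.null(boot)) {
    lower <- apply(boot, 2, quantile, probs = alpha, na.rm = TRUE)
    upper <- apply(boot, 2, quantile, probs = 1 - alpha, na.rm = TRUE)
  }
  data.frame(
    measure = rep(measures, each = 2),
    incentive = rep(c("reward", "penalty"), length(measures)),
    contrast = "high - low",
    estimate = as.numeric(est), lower = as.numeric(lower),
    upper = as.numeric(upper))
}
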