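#' Configuration of a full simulation-and-inference run
#'
#' A run is fully reproducible from its configuration plus the master seed:
#' the config chooses the task design, the ground-truth weight scheme, the
#' effort cost, estimator settings, and (optionally) a recovery study; the
#' seed fans out deterministically into per-subject and per-stage streams.
#'
#' @param study 1 or 2.
#' @param n_subjects simulated participants.
#' @param seed master integer seed.
#' @param weights optional data.frame of per-condition subjective weights
#'   (`reward_level`, `penalty_level`, `reward`, `penalty`); default
#'   [default_incentive_map()].
#' @param congruence_offsets list with `drift` (<= 0) and `threshold`
#'   (>= 0).
#' @param ndt non-decision time (s).
#' @param cost a [cost_spec()] (or list/character coercible to one).
#' @param intervals_per_condition override the design default.
#' @param interval_end `"discard"` or `"truncate"`.
#' @param pool_subjects if `TRUE` (default) DDM parameters are estimated
#'   per condition on trials pooled across subjects; otherwise per subject
#'   and condition.
#' @param min_trials minimum trials per estimated cell.
#' @param recovery `NULL`, or a list of arguments for [run_recovery()]
#'   (e.g. `list(regime = "fitted", n_trials = 2000)`).
#' @param out_dir optional output directory; when set,
#'   [run_full_pipeline()] writes all tables there as CSV/JSON.
#' @return object of class `run_config`.
#' @examples
#' run_config(study = 1, n_subjects = 2, seed = 42)
#' @export
run_config <- function(study = 1, n_subjects = 4, seed = 1, weights = NULL,
                       congruence_offsets = list(drift = -0.3, threshold = 0.1),
                       ndt = 0.4, cost = cost_spec(),
                       intervals_per_condition = NULL,
                       interval_end = "discard",
                       pool_subjects = TRUE, min_trials = 100L,
                       recovery = NULL, out_dir = NULL) {
  cfg <- list(study = study, n_subjects = n_subjects, seed = as.integer(seed),
              weights = weights, congruence_offsets = congruence_offsets,
              ndt = ndt, cost = as_cost_spec(cost),
              intervals_per_condition = intervals_per_condition,
              interval_end = interval_end, pool_subjects = pool_subjects,
              min_trials = as.integer(min_trials), recovery = recovery,
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "Run config: study %d, %d subject(s), seed %d, cost %s (E = %g)%s\n",
    x$study, x$n_subjects, x$seed, x$cost$form, x$cost$weight,
    if (is.null(x$recovery)) "" else ", with recovery study"))
  invisible(x)
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @return [read_run_config()] returns a `run_config`;
#'   [write_run_config()] returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop_ddmrr(sprintf("unknown config field(s): %s",
                       paste(bad, collapse = ", ")), "ddmrr_config_error")
  if (!is.null(raw$weights)) raw$weights <- as.data.frame(raw$weights)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param cfg a [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- unclass(cfg)
  out$cost <- unclass(out$cost)
  if (!is.null(out$weights)) out$weights <- as.list(out$weights)
  yaml::write_yaml(out, path)
  invisible(path)
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

#' Run the full simulate -> summarize -> estimate -> invert pipeline
#'
#' Executes the analysis chain end to end on synthetic data: build
#' reward-rate-optimal subject profiles from the ground-truth weights,
#' simulate the interval-based Stroop task, summarize behavior, estimate
#' condition-wise DDM parameters from the simulated trials, invert the
#' optimality conditions into recovered incentive sensitivities, and
#' optionally run a parameter-recovery study. Every artifact is stamped
#' with the config hash and master seed; a stage failure halts the run
#' with the stage name while preserving the stages already completed.
#'
#' @param cfg a [run_config()].
#' @return list of class `run_bundle`: `config`, `config_hash`, `seed`,
#'   `profile`, `trials`, `intervals`, `summary`, `ddm_estimates`,
#'   `sensitivities`, `recovery` (or `NULL`), and `log` (stage timings).
#' @examples
#' \donttest{
#' bundle <- run_full_pipeline(run_config(n_subjects = 2, seed = 1,
#'                                        intervals_per_condition = 3))
#' bundle$log
#' }
#' @export
run_full_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  hash <- config_hash(cfg)
  seeds <- derive_seeds(cfg$seed, 3L)  # generator / recovery / bootstrap
  bundle <- list(config = cfg, config_hash = hash, seed = cfg$seed)
  log <- list()
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e) {
      stop_ddmrr(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)),
                 "ddmrr_stage_error", stage = name, partial = bundle)
    })
    log[[length(log) + 1L]] <<- data.frame(
      stage = name, elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
    val
  }

  design <- t_stage("design", experiment_design(
    study = cfg$study, n_subjects = cfg$n_subjects,
    intervals_per_condition = cfg$intervals_per_condition,
    interval_end = cfg$interval_end))

  profile <- t_stage("profile", build_profile(
    weights = cfg$weights, study = cfg$study,
    congruence_offsets = cfg$congruence_offsets, ndt = cfg$ndt,
    cost = cfg$cost))
  bundle$profile <- profile

  sim <- t_stage("simulate", generate_experiment(design, profile,
                                                 seed = seeds[1]))
  bundle$trials <- sim$trials
  bundle$intervals <- sim$intervals

  bundle$summary <- t_stage("summarize", summarize_behavior(
    sim$trials, sim$intervals, seed = seeds[3]))

  bundle$ddm_estimates <- t_stage("estimate", estimate_conditions(
    sim$trials, pool_subjects = cfg$pool_subjects,
    min_trials = cfg$min_trials))

  bundle$sensitivities <- t_stage("invert", invert_conditions(
    bundle$ddm_estimates, cost = cfg$cost))

  bundle$recovery <- if (!is.null(cfg$recovery)) {
    t_stage("recover", do.call(run_recovery, modifyList(
      list(seed = seeds[2], ndt = cfg$ndt, cost = cfg$cost),
      cfg$recovery)))
  } else NULL

  bundle$log <- do.call(rbind, log)
  class(bundle) <- "run_bundle"

  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

#' @export
print.run_bundle <- function(x, ...) {
  cat(sprintf(
    "Pipeline run %s (seed %d): %d trials, %d intervals, %d estimated condition cells\n",
    substr(x$config_hash, 1, 8), x$seed, nrow(x$trials), nrow(x$intervals),
    nrow(x$ddm_estimates)))
  invisible(x)
}

#' Estimate condition-wise DDM parameters from a trial table
#'
#' Applies [estimate_ddm()] to every incentive condition (pooled over the
#' congruence mixture, and over subjects unless `pool_subjects = FALSE`).
#' Cells whose estimation fails (too few trials, degenerate accuracy)
#' appear with NA parameters and the condition message in `note`.
#'
#' @param trials trial table with `rt`, `correct`, `condition_reward`,
#'   `condition_penalty`, `subject` columns.
#' @param pool_subjects pool trials across subjects per condition.
#' @param min_trials minimum trials per cell.
#' @return data.frame with one row per estimated cell: identifiers,
#'   `v_hat`, `a_hat`, `ndt_hat`, `n`, `accuracy`, `note`.
#' @export
estimate_conditions <- function(trials, pool_subjects = TRUE,
                                min_trials = 100L) {
  scored <- trials[!is.na(trials$correct), ]
  keys <- if (pool_subjects) c("condition_reward", "condition_penalty")
          else c("subject", "condition_reward", "condition_penalty")
  cells <- unique(scored[keys])
  cells <- cells[do.call(order, as.list(cells)), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(scored))
    for (k in keys) sel <- sel & scored[[k]] == cells[[k]][i]
    cell <- scored[sel, ]
    out <- cbind(cells[i, , drop = FALSE],
                 data.frame(v_hat = NA_real_, a_hat = NA_real_,
                            ndt_hat = NA_real_, n = nrow(cell),
                            accuracy = mean(cell$correct), note = ""))
    tryCatch({
      est <- estimate_ddm(cell, min_trials = min_trials)
      out$v_hat <- est$v; out$a_hat <- est$a; out$ndt_hat <- est$ndt
      out
    }, error = function(e) {
      out$note <- conditionMessage(e)
      out
    })
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Invert estimated DDM parameters into incentive sensitivities
#'
#' Applies [invert_sensitivities()] to each row of a condition-wise DDM
#' estimate table, producing recovered subjective reward and penalty
#' weights with validity flags and solve diagnostics.
#'
#' @param estimates output of [estimate_conditions()] (or any data.frame
#'   with `v_hat`, `a_hat`, `ndt_hat`).
#' @param cost a [cost_spec()].
#' @return the input with `reward_hat`, `penalty_hat`, `valid`,
#'   `residual`, `kappa` columns added.
#' @export
invert_conditions <- function(estimates, cost = cost_spec()) {
  stopifnot(all(c("v_hat", "a_hat", "ndt_hat") %in% names(estimates)))
  cost <- as_cost_spec(cost)
  out <- estimates
  out$reward_hat <- NA_real_
  out$penalty_hat <- NA_real_
  out$valid <- FALSE
  out$residual <- NA_real_
  out$kappa <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (!is.finite(out$v_hat[i])) next
    inv <- tryCatch(
      invert_sensitivities(ddm_params(out$v_hat[i], out$a_hat[i],
                                      out$ndt_hat[i]), cost = cost),
      error = function(e) NULL)
    if (is.null(inv)) next
    out$reward_hat[i] <- inv$reward
    out$penalty_hat[i] <- inv$penalty
    out$valid[i] <- inv$valid
    out$residual[i] <- inv$diagnostics$residual
    out$kappa[i] <- inv$diagnostics$kappa
  }
  out
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = bundle$config_hash, seed = bundle$seed,
                package_version = as.character(utils::packageVersion("ddmrr")))
  w <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  w(bundle$trials, "trials.csv")
  w(bundle$intervals, "intervals.csv")
  w(bundle$summary$by_condition, "summary_by_condition.csv")
  w(bundle$summary$contrasts, "summary_contrasts.csv")
  w(bundle$ddm_estimates, "ddm_estimates.csv")
  w(bundle$sensitivities, "sensitivities.csv")
  w(bundle$log, "stage_log.csv")
  if (!is.null(bundle$recovery)) {
    w(bundle$recovery$table, "recovery_table.csv")
    stamp$recovery <- list(corr_reward = bundle$recovery$corr_reward,
                           corr_penalty = bundle$recovery$corr_penalty,
                           regime = bundle$recovery$regime,
                           n_trials = bundle$recovery$n_trials)
  }
  # ground truth for downstream recovery scoring
  stamp$profile <- list(ndt = bundle$profile$ndt,
                        sigma = bundle$profile$sigma,
                        congruence_offsets = bundle$profile$congruence_offsets,
                        table = bundle$profile$table)
  jsonlite::write_json(stamp, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_run_config(bundle$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Compare optimal-policy predictions across effort-cost forms
#'
#' Tabulates the optimal control configuration over an incentive grid for
#' each requested drift-cost form and reports whether the qualitative
#' comparative statics agree: drift rate increasing with reward and
#' threshold increasing with penalty. The linear form's kink at `v = 0`
#' never binds because the search space is `v > 0`.
#'
#' @param reward_levels,penalty_levels incentive grids (effort-cost units).
#' @param forms subset of `"quadratic"`, `"linear"`, `"exponential"`.
#' @param weight cost weight `E` shared by all forms.
#' @param ndt non-decision time (s).
#' @param ... passed to [optimize_policy()] via [prediction_grid()].
#' @return list with `table` (per form x grid cell policies) and
#'   `agreement` (per form: signs of the reward and penalty effects).
#' @examples
#' \donttest{
#' cmp <- compare_cost_forms(c(8, 20), c(5, 50))
#' cmp$agreement
#' }
#' @export
compare_cost_forms <- function(reward_levels = exp(seq(log(8), log(20),
                                                       length.out = 4)),
                               penalty_levels = exp(seq(log(5), log(625),
                                                        length.out = 4)),
                               forms = c("quadratic", "linear", "exponential"),
                               weight = 1, ndt = 0.4, ...) {
  forms <- match.arg(forms, several.ok = TRUE)
  tabs <- lapply(forms, function(f) {
    g <- prediction_grid(reward_levels, penalty_levels, ndt = ndt,
                         cost = cost_spec(f, weight), ...)
    g$form <- f
    g
  })
  tab <- do.call(rbind, tabs)

  agreement <- do.call(rbind, lapply(forms, function(f) {
    g <- tab[tab$form == f, ]
    # finite-difference signs across the grid
    dv_dR <- sign_of_effect(g, "reward", "v_star")
    da_dP <- sign_of_effect(g, "penalty", "a_star")
    data.frame(form = f,
               drift_up_with_reward = all(dv_dR > 0),
               threshold_up_with_penalty = all(da_dP > 0))
  }))
  list(table = tab, agreement = agreement)
}

# pairwise differences of `val` along `axis`, within levels of the other axis
sign_of_effect <- function(g, axis, val) {
  other <- if (axis == "reward") "penalty" else "reward"
  out <- c()
  for (lev in unique(g[[other]])) {
    sub <- g[g[[other]] == lev, ]
    sub <- sub[order(sub[[axis]]), ]
    out <- c(out, diff(sub[[val]]))
  }
  sign(out)
}
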