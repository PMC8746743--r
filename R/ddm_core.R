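#' Drift-diffusion decision-process parameters
#'
#' Bundles the parameters of a two-boundary drift diffusion model with an
#' unbiased starting point: evidence starts at `a/2` and accumulates with
#' mean rate `v` (signed toward the correct boundary at `a`; the error
#' boundary sits at 0) and diffusion noise `sigma` until a boundary is hit.
#' `ndt` is the non-decision time added to every response (stimulus encoding
#' and motor execution).
#'
#' `sigma` only sets the evidence scale: `v` and `a` are interpretable in
#' units of `sigma`, and the conventional choice `sigma = 1` is the default.
#'
#' @param v drift rate (evidence units / s); finite, may be zero or negative.
#' @param a boundary separation (evidence units); strictly positive.
#' @param ndt non-decision time (s); non-negative.
#' @param sigma diffusion coefficient (evidence units / sqrt(s)); positive.
#' @return an object of class `ddm_params`.
#' @examples
#' ddm_params(v = 1, a = 2, ndt = 0.4)
#' @export
ddm_params <- function(v, a, ndt = 0, sigma = 1) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop_ddmrr("`v` must be a single finite number", "ddmrr_domain_error")
  a <- check_number(a, "a", lower = 0)
  ndt <- check_number(ndt, "ndt", lower = 0, allow_zero_lower = TRUE)
  sigma <- check_number(sigma, "sigma", lower = 0)
  structure(list(v = as.numeric(v), a = a, ndt = ndt, sigma = sigma),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("DDM parameters: v = %.4g, a = %.4g, ndt = %.4g s, sigma = %.4g\n",
              x$v, x$a, x$ndt, x$sigma))
  invisible(x)
}

as_ddm_params <- function(p) {
  if (inherits(p, "ddm_params")) return(p)
  if (is.list(p) && all(c("v", "a") %in% names(p))) {
    return(ddm_params(p$v, p$a, if (is.null(p$ndt)) 0 else p$ndt,
                      if (is.null(p$sigma)) 1 else p$sigma))
  }
  stop_ddmrr("cannot interpret input as DDM parameters", "ddmrr_domain_error")
}

# drift magnitudes below this use the analytic v -> 0 limits (removable 0/0)
.V_EPS <- 1e-6

#' Expected error rate and decision time of the DDM
#'
#' Closed-form expected performance of the unbiased two-boundary diffusion:
#' with `x = a * v / sigma^2`,
#' \deqn{ER = 1 / (1 + e^{x}), \qquad
#'       DT = \frac{a}{2v} \tanh\!\left(\frac{a v}{2\sigma^2}\right),}
#' with the removable singularity at `v = 0` handled by its analytic limit
#' `ER = 1/2`, `DT = a^2 / (4 sigma^2)`. Both are continuous in `v`; `ER`
#' is strictly decreasing in `v * a`.
#'
#' @param p a [ddm_params()] object (or a list with fields `v`, `a`, and
#'   optionally `ndt`, `sigma`).
#' @return list of class `ddm_performance` with fields `er` (error
#'   probability) and `dt` (expected decision time, s).
#' @examples
#' ddm_expected_performance(ddm_params(v = 1, a = 2))  # er ~ 0.119, dt ~ 0.762
#' @export
ddm_expected_performance <- function(p) {
  p <- as_ddm_params(p)
  perf <- ddm_perf_vec(p$v, p$a, p$sigma)
  structure(list(er = perf$er, dt = perf$dt), class = "ddm_performance")
}

# vectorized core shared by the objective / optimizer (no class dispatch)
ddm_perf_vec <- function(v, a, sigma) {
  len <- max(length(v), length(a), length(sigma))
  v <- rep_len(v, len); a <- rep_len(a, len); sigma <- rep_len(sigma, len)
  er <- 1 / (1 + exp(a * v / sigma^2))
  dt <- a^2 / (4 * sigma^2)               # v -> 0 limit
  idx <- which(abs(v) >= .V_EPS)
  if (length(idx)) {
    dt[idx] <- (a[idx] / (2 * v[idx])) *
      tanh(a[idx] * v[idx] / (2 * sigma[idx]^2))
  }
  list(er = er, dt = dt)
}

#' @export
print.ddm_performance <- function(x, ...) {
  cat(sprintf("DDM expected performance: ER = %.4f, DT = %.4f s\n", x$er, x$dt))
  invisible(x)
}

#' Simulate first-passage trials from the DDM
#'
#' Draws response times and accuracies by simulating the diffusion path with
#' an Euler--Maruyama scheme (default step 1 ms) plus a within-step
#' Brownian-bridge boundary-crossing test, which removes the leading
#' discretization bias in first-passage probabilities. Reproducible under
#' `seed`.
#'
#' @param p a [ddm_params()] object.
#' @param n number of trials.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @param dt integration step (s), at most 1 ms by default.
#' @param t_max censoring horizon for the decision time (s).
#' @return data.frame with columns `rt` (s, includes `ndt`) and `correct`
#'   (logical).
#' @examples
#' trials <- simulate_trials(ddm_params(v = 1, a = 2, ndt = 0.4), 500, seed = 1)
#' mean(trials$correct)
#' @export
simulate_trials <- function(p, n, seed = NULL, dt = 1e-3, t_max = 30) {
  p <- as_ddm_params(p)
  stopifnot(n >= 1, dt > 0, t_max > dt)
  with_seed(seed, ddm_sample_cpp(as.integer(n), p$v, p$a, p$ndt, p$sigma,
                                 dt, t_max))
}

#' @rdname simulate_trials
#' @export
simulate_trial <- function(p, seed = NULL, dt = 1e-3, t_max = 30) {
  out <- simulate_trials(p, 1L, seed = seed, dt = dt, t_max = t_max)
  list(rt = out$rt[1L], correct = out$correct[1L])
}

#' Moment-based DDM parameter estimation for one condition
#'
#' Recovers `(v, a, ndt)` from the accuracy, mean, and variance of correct
#' response times by closed-form moment inversion (the EZ-diffusion scheme),
#' with `sigma` fixed at a convention value. Optionally refines the moment
#' estimate by maximum likelihood under the Wiener first-passage density.
#'
#' Accuracy exactly 0, 1, or 1/2 makes the moment inversion undefined
#' (the log-odds of a correct response is the carrier of the drift signal);
#' such inputs raise a classed condition (`ddmrr_edge_case`) whose
#' `code` field is one of `"all_errors"`, `"all_correct"`,
#' `"chance_accuracy"` rather than returning a silent number.
#'
#' @param trials data.frame with numeric `rt` (s, > 0) and logical/0-1
#'   `correct` columns, all from a single task condition.
#' @param sigma fixed diffusion coefficient (default 1).
#' @param method `"ez"` for pure moment inversion (deterministic), or
#'   `"ml"` to refine it by Wiener maximum likelihood.
#' @param min_trials minimum number of trials required (default 100).
#' @return a [ddm_params()] object with an `"estimate"` attribute holding
#'   `n`, `accuracy`, and the method used.
#' @export
estimate_ddm <- function(trials, sigma = 1, method = c("ez", "ml"),
                         min_trials = 100L) {
  method <- match.arg(method)
  if (!is.data.frame(trials) || !all(c("rt", "correct") %in% names(trials)))
    stop_ddmrr("`trials` must have `rt` and `correct` columns",
               "ddmrr_domain_error")
  rt <- as.numeric(trials$rt)
  correct <- as.logical(trials$correct)
  if (anyNA(rt) || anyNA(correct) || any(rt <= 0))
    stop_ddmrr("RTs must be positive and complete", "ddmrr_domain_error")
  n <- length(rt)
  if (n < min_trials)
    stop_ddmrr(sprintf("need at least %d trials, got %d", min_trials, n),
               "ddmrr_domain_error")

  pc <- mean(correct)
  if (pc == 1) stop_ddmrr("accuracy is exactly 1: error rate carries no information for moment inversion",
                          "ddmrr_edge_case", code = "all_correct")
  if (pc == 0) stop_ddmrr("accuracy is exactly 0: no correct responses to take moments of",
                          "ddmrr_edge_case", code = "all_errors")
  if (pc == 0.5) stop_ddmrr("accuracy is exactly 1/2: drift direction is unidentified",
                            "ddmrr_edge_case", code = "chance_accuracy")

  mrt <- mean(rt[correct])
  vrt <- var(rt[correct])
  if (!is.finite(vrt) || vrt <= 0)
    stop_ddmrr("variance of correct RTs must be positive",
               "ddmrr_edge_case", code = "degenerate_rt_variance")

  # EZ moment inversion (unit-variance form rescaled by sigma)
  s <- sigma
  L <- log(pc / (1 - pc))
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * s * x^(1 / 4)
  a <- s^2 * L / v
  mdt <- (a / (2 * v)) * (1 - exp(-v * a / s^2)) / (1 + exp(-v * a / s^2))
  ndt <- mrt - mdt
  if (ndt < 0) ndt <- 0

  est <- ddm_params(v = v, a = a, ndt = ndt, sigma = sigma)

  if (method == "ml") {
    est <- refine_ddm_ml(est, rt, correct, min_rt = min(rt))
  }
  attr(est, "estimate") <- list(n = n, accuracy = pc, method = method)
  est
}

# Wiener first-passage density at the correct (upper) / error (lower)
# boundary, unbiased start.  Reference implementation with generously
# over-provisioned series terms (small-time expansion below tau = 0.5,
# large-time above; both truncated far past machine precision); the
# compiled likelihood uses the accuracy-matched switch instead.
wiener_fpt_density <- function(t, v, a, sigma = 1,
                               boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  # rescale to unit diffusion
  v <- v / sigma
  a <- a / sigma
  w <- 0.5
  if (boundary == "upper") v <- -v  # upper density = lower with flipped drift
  tt <- pmax(t, 1e-12)
  tau <- tt / a^2
  f <- numeric(length(tt))
  for (i in seq_along(tt)) {
    ti <- tau[i]
    if (ti < 0.5) {
      k <- -12:12
      f[i] <- sum((w + 2 * k) * exp(-((w + 2 * k)^2) / (2 * ti))) /
        sqrt(2 * pi * ti^3)
    } else {
      k <- 1:60
      f[i] <- pi * sum(k * exp(-(k^2) * pi^2 * ti / 2) * sin(k * pi * w))
    }
  }
  pmax(f, 0) * exp(-v * a * w - v^2 * tt / 2) / a^2
}

refine_ddm_ml <- function(init, rt, correct, min_rt) {
  nll <- function(par) {
    v <- par[1]; a <- exp(par[2]); ndt <- par[3]
    if (ndt < 0 || ndt >= min_rt) return(1e10)
    val <- wiener_nll_cpp(rt, correct, v, a, ndt, init$sigma)
    if (!is.finite(val)) 1e10 else val
  }
  par0 <- c(init$v, log(init$a), min(init$ndt, 0.95 * min_rt))
  fit <- optim(par0, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  ddm_params(v = fit$par[1], a = exp(fit$par[2]), ndt = fit$par[3],
             sigma = init$sigma)
}
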