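#' Subjective incentive weights
#'
#' Subjective value placed on the outcome of a single response: `reward` is
#' the value of a correct response and `penalty` the (positive) weight on the
#' loss incurred by an error. Because the drift-cost weight is normalized to
#' `E = 1` in the objective, both are expressed in units of effort cost, and
#' the optimal control configuration depends on incentives only through the
#' ratios `reward / E` and `penalty / E`.
#'
#' @param reward subjective reward per correct response (> 0), effort-cost
#'   units.
#' @param penalty subjective penalty per error (>= 0), effort-cost units.
#' @return object of class `incentive_weights`.
#' @examples
#' incentive_weights(10, 10)
#' @export
incentive_weights <- function(reward, penalty) {
  reward <- check_number(reward, "reward", lower = 0)
  penalty <- check_number(penalty, "penalty", lower = 0,
                          allow_zero_lower = TRUE)
  structure(list(reward = reward, penalty = penalty),
            class = "incentive_weights")
}

#' @export
print.incentive_weights <- function(x, ...) {
  cat(sprintf("Incentive weights: R = %.4g, P = %.4g (effort-cost units)\n",
              x$reward, x$penalty))
  invisible(x)
}

as_incentive_weights <- function(w) {
  if (inherits(w, "incentive_weights")) return(w)
  if (is.list(w) && all(c("reward", "penalty") %in% names(w)))
    return(incentive_weights(w$reward, w$penalty))
  if (is.numeric(w) && length(w) == 2L)
    return(incentive_weights(w[[1]], w[[2]]))
  stop_ddmrr("cannot interpret input as incentive weights",
             "ddmrr_domain_error")
}

#' Effort-cost specification for the drift rate
#'
#' The cost of sustaining a drift rate `v`, subtracted from the reward rate.
#' Forms: `quadratic` (`E * v^2`, the default), `linear` (`E * |v|`),
#' `exponential` (`E * (exp(v) - 1)`, zero at `v = 0`), or `none`. Only
#' drift rate is costed; `threshold_weight` is a hook for an additional
#' quadratic threshold cost and defaults to zero, since the threshold
#' already pays an implicit cost through the speed-accuracy tradeoff.
#'
#' @param form one of `"quadratic"`, `"linear"`, `"exponential"`, `"none"`.
#' @param weight cost weight `E` (>= 0, default 1).
#' @param threshold_weight weight on an optional quadratic threshold cost
#'   (default 0).
#' @return object of class `cost_spec`.
#' @examples
#' cost_spec()                  # quadratic, E = 1
#' cost_spec("linear", 0.5)
#' @export
cost_spec <- function(form = c("quadratic", "linear", "exponential", "none"),
                      weight = 1, threshold_weight = 0) {
  form <- match.arg(form)
  weight <- check_number(weight, "weight", lower = 0, allow_zero_lower = TRUE)
  threshold_weight <- check_number(threshold_weight, "threshold_weight",
                                   lower = 0, allow_zero_lower = TRUE)
  structure(list(form = form, weight = weight,
                 threshold_weight = threshold_weight),
            class = "cost_spec")
}

#' @export
print.cost_spec <- function(x, ...) {
  cat(sprintf("Effort cost: %s, E = %.4g%s\n", x$form, x$weight,
              if (x$threshold_weight > 0)
                sprintf(", threshold weight = %.4g", x$threshold_weight)
              else ""))
  invisible(x)
}

as_cost_spec <- function(cost) {
  if (inherits(cost, "cost_spec")) return(cost)
  if (is.character(cost) && length(cost) == 1L) return(cost_spec(cost))
  if (is.list(cost)) {
    return(cost_spec(form = if (is.null(cost$form)) "quadratic" else cost$form,
                     weight = if (is.null(cost$weight)) 1 else cost$weight,
                     threshold_weight = if (is.null(cost$threshold_weight)) 0
                                        else cost$threshold_weight))
  }
  stop_ddmrr("cannot interpret input as a cost specification",
             "ddmrr_domain_error")
}

cost_value <- function(cost, v) {
  switch(cost$form,
         quadratic = cost$weight * v^2,
         linear = cost$weight * abs(v),
         exponential = cost$weight * (exp(v) - 1),
         none = 0 * v)
}

cost_deriv <- function(cost, v) {
  if (cost$form == "linear" && any(v == 0))
    stop_ddmrr("linear cost is not differentiable at v = 0",
               "ddmrr_nondifferentiable")
  switch(cost$form,
         quadratic = 2 * cost$weight * v,
         linear = cost$weight * sign(v),
         exponential = cost$weight * exp(v),
         none = 0 * v)
}

#' Effort-discounted reward rate
#'
#' The objective the decision maker is assumed to maximize: expected net
#' payoff per second, minus an effort cost on drift rate,
#' \deqn{RR(v, a) = \frac{R (1 - ER) - P \cdot ER}{DT + NDT} - E \, c(v),}
#' with `ER` and `DT` the closed-form error rate and decision time of
#' [ddm_expected_performance()]. Without the cost term the objective is
#' unbounded in `v` (ever-higher drift is always better), which is why the
#' cost is part of the normative model.
#'
#' @param p a [ddm_params()] object (its `ndt` enters the denominator).
#' @param w an [incentive_weights()] object.
#' @param cost a [cost_spec()]; default quadratic with `E = 1`.
#' @return scalar reward rate (reward units per second).
#' @examples
#' p <- ddm_params(v = 1, a = 2, ndt = 0.4)
#' reward_rate(p, incentive_weights(5, 5))  # ~ 2.278
#' @export
reward_rate <- function(p, w, cost = cost_spec()) {
  p <- as_ddm_params(p)
  w <- as_incentive_weights(w)
  cost <- as_cost_spec(cost)
  rr_vec(p$v, p$a, p$ndt, p$sigma, w$reward, w$penalty, cost)
}

# vectorized objective used by the optimizer and grid oracle
rr_vec <- function(v, a, ndt, sigma, R, P, cost) {
  perf <- ddm_perf_vec(v, a, sigma)
  total_t <- perf$dt + ndt
  if (any(total_t <= 0))
    stop_ddmrr("DT + NDT must be positive", "ddmrr_domain_error")
  (R * (1 - perf$er) - P * perf$er) / total_t -
    cost_value(cost, v) - cost$threshold_weight * a^2
}

#' Analytic gradient of the reward rate
#'
#' Partial derivatives of [reward_rate()] with respect to drift rate and
#' boundary separation, from differentiating the closed forms:
#' with `ER' = -ER (1 - ER) * (a or v) / sigma^2` and the corresponding
#' `DT` derivatives of the scaled `tanh`. Both components are affine in
#' `(R, P)` at a fixed `(v, a)`, which is what makes the inverse problem a
#' linear solve. Matches central finite differences of [reward_rate()] to
#' high relative accuracy at interior points.
#'
#' @inheritParams reward_rate
#' @return named numeric vector `c(dv = dRR/dv, da = dRR/da)`.
#' @examples
#' p <- ddm_params(v = 1, a = 2, ndt = 0.4)
#' reward_rate_gradient(p, incentive_weights(5, 5))
#' @export
reward_rate_gradient <- function(p, w, cost = cost_spec()) {
  p <- as_ddm_params(p)
  w <- as_incentive_weights(w)
  cost <- as_cost_spec(cost)
  g <- rr_grad_vec(p$v, p$a, p$ndt, p$sigma, w$reward, w$penalty, cost)
  c(dv = g$dv, da = g$da)
}

# ER/DT partials; v near 0 handled by analytic limits
ddm_perf_partials <- function(v, a, sigma) {
  perf <- ddm_perf_vec(v, a, sigma)
  er <- perf$er
  dt <- perf$dt
  er_v <- -(a / sigma^2) * er * (1 - er)
  er_a <- -(v / sigma^2) * er * (1 - er)
  len <- max(length(v), length(a), length(sigma))
  v <- rep_len(v, len); a <- rep_len(a, len); sigma <- rep_len(sigma, len)
  dt_v <- numeric(len)                       # v -> 0 limit is 0
  dt_a <- a / (2 * sigma^2)                  # v -> 0 limit
  idx <- which(abs(v) >= .V_EPS)
  if (length(idx)) {
    u <- a[idx] * v[idx] / (2 * sigma[idx]^2)
    th <- tanh(u)
    sech2 <- 1 / cosh(u)^2
    dt_v[idx] <- -(a[idx] / (2 * v[idx]^2)) * th +
      (a[idx]^2 / (4 * v[idx] * sigma[idx]^2)) * sech2
    dt_a[idx] <- th / (2 * v[idx]) + (a[idx] / (4 * sigma[idx]^2)) * sech2
  }
  list(er = er, dt = dt, er_v = er_v, er_a = er_a, dt_v = dt_v, dt_a = dt_a)
}

rr_grad_vec <- function(v, a, ndt, sigma, R, P, cost) {
  pp <- ddm_perf_partials(v, a, sigma)
  total_t <- pp$dt + ndt
  if (any(total_t <= 0))
    stop_ddmrr("DT + NDT must be positive", "ddmrr_domain_error")
  num <- R * (1 - pp$er) - P * pp$er
  dv <- (-(R + P) * pp$er_v * total_t - num * pp$dt_v) / total_t^2 -
    cost_deriv(cost, v)
  da <- (-(R + P) * pp$er_a * total_t - num * pp$dt_a) / total_t^2 -
    2 * cost$threshold_weight * a
  list(dv = dv, da = da)
}
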