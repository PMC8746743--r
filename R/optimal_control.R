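#' Reward-rate-maximizing control configuration
#'
#' Finds the pair (drift rate, boundary separation) that maximizes the
#' effort-discounted reward rate for given incentive weights. The search is
#' deterministic and two-stage: a coarse log-spaced grid locates the basin,
#' then a bounded quasi-Newton refinement with the analytic gradient
#' ([reward_rate_gradient()]) polishes the optimum; a final Newton polish
#' drives the gradient to numerical zero. The returned point is verified
#' against a 200 x 200 coarse grid over the bounds, and an optimum on the
#' search boundary is flagged as non-converged rather than silently
#' returned.
#'
#' With no effort cost (`cost$form == "none"`) the objective is unbounded:
#' reward rate keeps growing with drift rate, so there is no interior
#' optimum and the call errors.
#'
#' @param w an [incentive_weights()] object (or `c(R, P)`).
#' @param ndt non-decision time (s), default 0.4.
#' @param cost a [cost_spec()]; must have a cost on drift rate.
#' @param bounds list with elements `v` and `a`, each `c(lower, upper)`, in
#'   sigma units.
#' @param sigma diffusion coefficient (default 1).
#' @param coarse_n per-axis size of the first-stage grid.
#' @param grad_tol tolerance on the scaled gradient max-norm for
#'   convergence.
#' @return object of class `control_policy`: `v_star`, `a_star`, `rr_star`,
#'   `converged`, `gradient` (at the optimum), `grid_meta`.
#' @examples
#' optimize_policy(incentive_weights(10, 10))
#' @export
optimize_policy <- function(w, ndt = 0.4, cost = cost_spec(),
                            bounds = list(v = c(1e-3, 50), a = c(1e-2, 20)),
                            sigma = 1, coarse_n = 64, grad_tol = 1e-5) {
  w <- as_incentive_weights(w)
  cost <- as_cost_spec(cost)
  ndt <- check_number(ndt, "ndt", lower = 0, allow_zero_lower = TRUE)
  if (cost$form == "none")
    stop_ddmrr(paste("no effort cost on drift rate: the reward rate is",
                     "unbounded in v and has no interior optimum"),
               "ddmrr_unbounded_objective")
  stopifnot(all(unlist(bounds) > 0), bounds$v[1] < bounds$v[2],
            bounds$a[1] < bounds$a[2])

  obj <- function(v, a) rr_vec(v, a, ndt, sigma, w$reward, w$penalty, cost)

  # stage 1: coarse log-spaced grid
  vg <- exp(seq(log(bounds$v[1]), log(bounds$v[2]), length.out = coarse_n))
  ag <- exp(seq(log(bounds$a[1]), log(bounds$a[2]), length.out = coarse_n))
  grid <- expand.grid(v = vg, a = ag)
  vals <- obj(grid$v, grid$a)
  best <- which.max(vals)

  # stage 2: bounded quasi-Newton on log-parameters with analytic gradient
  negobj <- function(par) -obj(exp(par[1]), exp(par[2]))
  neggrad <- function(par) {
    v <- exp(par[1]); a <- exp(par[2])
    g <- rr_grad_vec(v, a, ndt, sigma, w$reward, w$penalty, cost)
    -c(g$dv * v, g$da * a)
  }
  fit <- optim(log(c(grid$v[best], grid$a[best])), negobj, neggrad,
               method = "L-BFGS-B",
               lower = log(c(bounds$v[1], bounds$a[1])),
               upper = log(c(bounds$v[2], bounds$a[2])),
               control = list(maxit = 500, factr = 10, pgtol = 1e-14))
  v_star <- exp(fit$par[1]); a_star <- exp(fit$par[2])

  # stage 3: Newton polish on (v, a) using finite differences of the
  # analytic gradient (cheap 2x2 Hessian); stays inside the bounds
  for (iter in 1:25) {
    g <- rr_grad_vec(v_star, a_star, ndt, sigma, w$reward, w$penalty, cost)
    gv <- c(g$dv, g$da)
    if (max(abs(gv)) < 1e-12) break
    h <- 1e-6 * c(max(v_star, 1), max(a_star, 1))
    gpv <- rr_grad_vec(v_star + h[1], a_star, ndt, sigma, w$reward, w$penalty, cost)
    gmv <- rr_grad_vec(v_star - h[1], a_star, ndt, sigma, w$reward, w$penalty, cost)
    gpa <- rr_grad_vec(v_star, a_star + h[2], ndt, sigma, w$reward, w$penalty, cost)
    gma <- rr_grad_vec(v_star, a_star - h[2], ndt, sigma, w$reward, w$penalty, cost)
    H <- cbind(c(gpv$dv - gmv$dv, gpv$da - gmv$da) / (2 * h[1]),
               c(gpa$dv - gma$dv, gpa$da - gma$da) / (2 * h[2]))
    step <- tryCatch(solve(H, gv), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- c(v_star, a_star) - step
    if (any(cand <= c(bounds$v[1], bounds$a[1])) ||
        any(cand >= c(bounds$v[2], bounds$a[2]))) break
    if (obj(cand[1], cand[2]) < obj(v_star, a_star) - 1e-12) break
    v_star <- cand[1]; a_star <- cand[2]
  }
  rr_star <- obj(v_star, a_star)

  # verification: beat a 200 x 200 coarse grid over the bounds
  v200 <- exp(seq(log(bounds$v[1]), log(bounds$v[2]), length.out = 200))
  a200 <- exp(seq(log(bounds$a[1]), log(bounds$a[2]), length.out = 200))
  check <- expand.grid(v = v200, a = a200)
  grid_max <- max(obj(check$v, check$a))
  beats_grid <- rr_star >= grid_max - 1e-10 * max(1, abs(grid_max))

  g <- rr_grad_vec(v_star, a_star, ndt, sigma, w$reward, w$penalty, cost)
  grad <- c(dv = g$dv, da = g$da)
  scale <- max(1, abs(rr_star))
  grad_scaled <- c(grad[["dv"]] * v_star, grad[["da"]] * a_star) / scale

  on_boundary <-
    v_star <= bounds$v[1] * (1 + 1e-6) || v_star >= bounds$v[2] * (1 - 1e-6) ||
    a_star <= bounds$a[1] * (1 + 1e-6) || a_star >= bounds$a[2] * (1 - 1e-6)

  structure(list(
    v_star = v_star, a_star = a_star, rr_star = rr_star,
    converged = !on_boundary && beats_grid && max(abs(grad_scaled)) < grad_tol,
    gradient = grad,
    grid_meta = list(bounds = bounds, coarse_n = coarse_n,
                     grad_tol = grad_tol, on_boundary = on_boundary,
                     beats_grid = beats_grid, ndt = ndt, sigma = sigma,
                     cost = cost, weights = w)
  ), class = "control_policy")
}

#' @export
print.control_policy <- function(x, ...) {
  cat(sprintf(
    "Optimal control policy: v* = %.4f, a* = %.4f, RR* = %.4f (%s)\n",
    x$v_star, x$a_star, x$rr_star,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Normative prediction grid over incentive levels
#'
#' Tabulates the optimal control configuration for every combination of
#' reward and penalty weights. Across such a grid the model predicts that
#' the optimal drift rate rises with reward, the optimal threshold rises
#' with penalty, and the threshold falls (weakly) with reward.
#'
#' @param reward_levels,penalty_levels positive numeric vectors of incentive
#'   weights (effort-cost units).
#' @inheritParams optimize_policy
#' @param ... passed on to [optimize_policy()].
#' @return data.frame with columns `reward`, `penalty`, `v_star`, `a_star`,
#'   `rr_star`, `converged`.
#' @examples
#' prediction_grid(c(8, 20), c(5, 50))
#' @export
prediction_grid <- function(reward_levels, penalty_levels, ndt = 0.4,
                            cost = cost_spec(), ...) {
  stopifnot(all(reward_levels > 0), all(penalty_levels > 0))
  cells <- expand.grid(reward = reward_levels, penalty = penalty_levels,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    pol <- tryCatch(
      optimize_policy(incentive_weights(cells$reward[i], cells$penalty[i]),
                      ndt = ndt, cost = cost, ...),
      error = function(e) {
        stop_ddmrr(sprintf("optimization failed at (R = %g, P = %g): %s",
                           cells$reward[i], cells$penalty[i],
                           conditionMessage(e)),
                   "ddmrr_grid_cell_error")
      })
    data.frame(reward = cells$reward[i], penalty = cells$penalty[i],
               v_star = pol$v_star, a_star = pol$a_star,
               rr_star = pol$rr_star, converged = pol$converged)
  })
  do.call(rbind, res)
}
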