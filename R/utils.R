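# internal helpers: argument checking, conditions, seed fan-out

stop_ddmrr <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "ddmrr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_ddmrr(sprintf("`%s` must be a single finite number", name),
               "ddmrr_domain_error")
  }
  ok_low <- if (allow_zero_lower) x >= lower else x > lower
  if (!ok_low || x > upper) {
    stop_ddmrr(sprintf("`%s` = %g is outside its valid range", name, x),
               "ddmrr_domain_error")
  }
  as.numeric(x)
}

#' Derive child seeds from a master seed
#'
#' One master seed deterministically fans out into independent per-stage or
#' per-subject seeds, so pipeline stages can be re-run in isolation while the
#' whole run stays reproducible from a single integer.
#'
#' @param master_seed single integer.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed), n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}
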