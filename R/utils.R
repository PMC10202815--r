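#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG state seeded with `seed`; if `seed` is NULL the
# global RNG stream is used (and advanced) as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(structure(class = c("couplemr_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_infeasible <- function(...) {
  stop(structure(class = c("couplemr_infeasible_model", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop_invalid(name, " must lie strictly in (0, 1)")
  invisible(x)
}

check_corr <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || abs(x) > 1)
    stop_invalid(name, " must be a correlation in [-1, 1]")
  invisible(x)
}

# standardize a vector to zero mean, unit sd
zscale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop_invalid("cannot standardize a constant vector")
  (x - mean(x)) / s
}
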