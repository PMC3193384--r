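# internal helpers: argument checking and seeded RNG scoping

.check_num <- function(x, name, lower = -Inf, upper = Inf,
                       open_lower = FALSE, open_upper = FALSE,
                       allow_vector = TRUE) {
  if (!is.numeric(x) || length(x) < 1L || (!allow_vector && length(x) != 1L))
    stop(sprintf("'%s' must be %s numeric", name,
                 if (allow_vector) "a" else "a single"), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' contains missing or non-finite values", name), call. = FALSE)
  bad <- if (open_lower) any(x <= lower) else any(x < lower)
  bad <- bad || if (open_upper) any(x >= upper) else any(x > upper)
  if (bad) {
    lb <- if (open_lower) "(" else "["
    ub <- if (open_upper) ")" else "]"
    stop(sprintf("'%s' must lie in %s%g, %g%s", name, lb, lower, upper, ub),
         call. = FALSE)
  }
  invisible(x)
}

# unchecked algebraic signal for internal hot paths (amplitude may be any sign)
.alg_signal <- function(amplitude, tau, rho1) {
  2 * amplitude * rho1 * tau / (tau^2 + 2 * rho1)
}

# evaluate `expr` under a fixed RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
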