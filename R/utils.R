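# Internal validation and small numeric helpers shared across modules.

stop_domain <- function(msg, ...) {
  abort(msg, class = "cardiomr_error_domain", ...)
}

stop_insufficient <- function(msg, ...) {
  abort(msg, class = "cardiomr_error_insufficient_instruments", ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_domain(sprintf(
      "`%s` = %g is outside %s%g, %g%s.", name, x,
      if (open_lower) "(" else "[", lower, upper,
      if (open_upper) ")" else "]"
    ))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop_domain(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Two-sided normal p-value for a Wald z statistic; z = 0/0 maps to p = 1.
# Floored at the smallest normalized double so p stays within (0, 1] even
# when the tail probability underflows.
wald_p <- function(beta, se) {
  z <- ifelse(se > 0, beta / se, Inf)
  z[beta == 0] <- 0
  pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
}

# Weighted median with the half-weight cumulative convention: the estimate
# interpolates linearly between the two order statistics whose standardized
# cumulative weights p_j = cumsum(w)_j - w_j/2 bracket 1/2.
weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(x[1])
  n <- length(x)
  if (p[n] <= 0.5) return(x[n])
  hi <- which(p >= 0.5)[1]
  lo <- hi - 1L
  x[lo] + (x[hi] - x[lo]) * (0.5 - p[lo]) / (p[hi] - p[lo])
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# (or removing) the caller's .Random.seed afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
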