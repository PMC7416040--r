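#' Evaluate the Gompertz learning curve
#'
#' `a * exp(-exp(b - c * t))`: a negatively accelerated sigmoid. `a` is the
#' asymptote (learning capacity); the curve's inflection sits at `t = b / c`
#' and `c` sets the per-block rate of approach.
#'
#' @param a Asymptote.
#' @param b Shape offset (dimensionless).
#' @param c Rate (per block).
#' @param t Time (block index); vectorized.
#' @return Curve value(s).
#' @export
#' @examples
#' gompertz_value(0.8, 0, 1, 0)  # 0.8 * exp(-1)
gompertz_value <- function(a, b, c, t) {
  a * exp(-exp(b - c * t))
}

.default_gompertz_bounds <- function() {
  list(a = c(0, 1.05), b = c(-10, 10), c = c(0, 10))
}

# Data-driven starting values: a0 = max fraction; (b0, c0) from the
# linearization log(-log(y / a0)) = b - c t on interior points.
.gompertz_starts <- function(fractions, times, bounds, n_starts) {
  a0 <- min(max(max(fractions), 0.05), bounds$a[2])
  y <- pmin(pmax(fractions / a0, 1e-6), 1 - 1e-6)
  w <- log(-log(y))
  cf <- tryCatch(stats::coef(stats::lm(w ~ times)), error = function(e) c(2, -0.5))
  b0 <- min(max(cf[1], bounds$b[1]), bounds$b[2])
  c0 <- min(max(-cf[2], bounds$c[1] + 1e-3), bounds$c[2])
  # deterministic jitter pattern around the data-driven start
  jit <- rbind(c(0, 0, 0),
               c(0, 1, 0.5), c(0, -1, -0.3),
               c(-0.05, 2, 1), c(0.05, -2, 0.3),
               c(0, 3, -0.4), c(-0.1, -3, 1.5))
  starts <- lapply(seq_len(min(n_starts, nrow(jit))), function(k) {
    s <- c(a = a0, b = b0, c = c0) + jit[k, ]
    c(a = min(max(s[1], bounds$a[1] + 1e-4), bounds$a[2]),
      b = min(max(s[2], bounds$b[1]), bounds$b[2]),
      c = min(max(s[3], bounds$c[1]), bounds$c[2]))
  })
  starts
}

#' Fit the Gompertz learning curve by bounded nonlinear least squares
#'
#' Minimizes the sum of squared residuals of `a exp(-exp(b - c t))` against
#' the observed per-block fractions, within box bounds, using
#' Levenberg-Marquardt ([minpack.lm::nlsLM]) from several deterministic
#' starting points (data-driven start from a log-log linearization, plus
#' fixed jitters); a bounded quasi-Newton polish on the raw SSE acts as a
#' fallback when the L-M solver fails. The best converged start wins.
#'
#' @param fractions Per-block fractions correct, in \[0, 1\], length >= 3.
#' @param times Block times (default `1..n`).
#' @param bounds List with elements `a`, `b`, `c`, each `c(lower, upper)`.
#' @param n_starts Number of starting points (default 5).
#' @param tol Solver convergence tolerance.
#' @return A `gompertz_fit`: list with `a`, `b`, `c`, `inflection_time`
#'   (= b/c), `sse`, `converged`, `degenerate`, `n_blocks`, `fitted`.
#' @export
#' @examples
#' y <- gompertz_value(0.9, 2, 0.8, 1:8)
#' fit <- fit_gompertz(y)
#' round(c(fit$a, fit$b, fit$c), 4)
fit_gompertz <- function(fractions, times = seq_along(fractions),
                         bounds = .default_gompertz_bounds(),
                         n_starts = 5, tol = 1e-10) {
  fractions <- as.numeric(fractions)
  if (length(fractions) < 3L) {
    stop("need at least 3 blocks to fit 3 parameters", call. = FALSE)
  }
  if (any(!is.finite(fractions)) || any(fractions < 0 | fractions > 1)) {
    stop("fractions must be finite and in [0, 1]", call. = FALSE)
  }
  if (all(fractions == 0)) {
    return(structure(list(a = 0, b = 0, c = 0, inflection_time = NaN,
                          sse = 0, converged = TRUE, degenerate = TRUE,
                          n_blocks = length(fractions),
                          fitted = rep(0, length(fractions))),
                     class = "gompertz_fit"))
  }

  lower <- c(bounds$a[1], bounds$b[1], bounds$c[1])
  upper <- c(bounds$a[2], bounds$b[2], bounds$c[2])
  sse_fun <- function(p) {
    sum((fractions - gompertz_value(p[1], p[2], p[3], times))^2)
  }

  best <- NULL
  for (st in .gompertz_starts(fractions, times, bounds, n_starts)) {
    fit <- tryCatch({
      m <- minpack.lm::nlsLM(
        fractions ~ a * exp(-exp(b - c * times)),
        start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = tol,
                                             ptol = tol))
      p <- stats::coef(m)
      list(p = p, sse = sse_fun(p))
    }, error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch({
        o <- stats::optim(st, sse_fun, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 500, factr = 1e4))
        list(p = o$par, sse = o$value)
      }, error = function(e) NULL)
    }
    if (!is.null(fit) && (is.null(best) || fit$sse < best$sse)) best <- fit
  }

  if (is.null(best)) {
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                          inflection_time = NA_real_, sse = NA_real_,
                          converged = FALSE, degenerate = FALSE,
                          n_blocks = length(fractions),
                          fitted = rep(NA_real_, length(fractions))),
                     class = "gompertz_fit"))
  }
  p <- unname(best$p)
  structure(list(a = p[1], b = p[2], c = p[3],
                 inflection_time = if (p[3] != 0) p[2] / p[3] else NaN,
                 sse = best$sse, converged = TRUE, degenerate = FALSE,
                 n_blocks = length(fractions),
                 fitted = gompertz_value(p[1], p[2], p[3], times)),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf(
    "Gompertz fit: a = %.4f, b = %.4f, c = %.4f (inflection at t = %.2f), sse = %.3g%s\n",
    x$a, x$b, x$c, x$inflection_time, x$sse,
    if (!x$converged) " [NOT CONVERGED]" else if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Fit Gompertz curves for every subject in a behavior table
#'
#' @param behavior Long data frame with `subject_id`, `group`, `block`,
#'   `fraction` (as produced by [simulate_learning_curves()] or read from a
#'   behavior table).
#' @param ... Passed to [fit_gompertz()].
#' @return Data frame, one row per subject: `subject_id`, `group`, `a`, `b`,
#'   `c`, `inflection_time`, `sse`, `converged`, `degenerate`.
#' @export
fit_gompertz_cohort <- function(behavior, ...) {
  ids <- unique(behavior$subject_id)
  rows <- lapply(ids, function(id) {
    d <- behavior[behavior$subject_id == id, ]
    d <- d[order(d$block), ]
    f <- fit_gompertz(d$fraction, times = d$block, ...)
    data.frame(subject_id = id, group = d$group[1], a = f$a, b = f$b,
               c = f$c, inflection_time = f$inflection_time, sse = f$sse,
               converged = f$converged, degenerate = f$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
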