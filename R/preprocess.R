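#' Normalize a trace to unit initial amplitude
#'
#' @param tr A [trace()] object with `v[1] != 0`.
#' @return The trace scaled so that `v[1] == 1`.
#' @export
normalize_trace <- function(tr) {
  stopifnot(is_trace(tr))
  if (tr$v[1] == 0) stop("cannot normalize: initial amplitude is zero")
  trace(tr$t, tr$v / tr$v[1], tr$t_mix)
}

#' Reference deconvolution of a trace set
#'
#' Divides every main trace by the short-mixing-time reference trace,
#' cancelling multiplicative artifacts that do not depend on the mixing time
#' (e.g. the instrumental echo envelope). Main traces are first linearly
#' interpolated onto the reference time grid. Because division by a
#' near-zero reference amplifies noise without bound, all traces are
#' truncated at the first time where the reference falls below `floor`
#' (truncation, not clipping, is the conservative contract).
#'
#' @param set A [trace_set()] with a reference trace.
#' @param floor Reference amplitude below which traces are truncated.
#'   Default 0.05.
#' @return A reference-divided [trace_set()] (`deconvolved = TRUE`,
#'   reference removed, its mixing time kept in `ref_t_mix`).
#' @export
reference_deconvolve <- function(set, floor = 0.05) {
  stopifnot(is_trace_set(set))
  if (set$deconvolved) stop("set is already reference-divided")
  if (is.null(set$reference)) stop("set has no reference trace")
  ref <- set$reference
  # common support: reference grid restricted to the range of every main trace
  t_max <- min(vapply(set$main, function(tr) max(tr$t), numeric(1)), max(ref$t))
  t_min <- max(vapply(set$main, function(tr) min(tr$t), numeric(1)), min(ref$t))
  keep <- ref$t >= t_min & ref$t <= t_max
  if (!any(keep)) stop("no common time support between main and reference traces")
  t_common <- ref$t[keep]
  v_ref <- ref$v[keep]
  below <- which(v_ref < floor)
  if (length(below) && below[1] == 1L) {
    stop("reference trace is below the division floor from the first point")
  }
  if (length(below)) {
    idx <- seq_len(below[1] - 1L)
    t_common <- t_common[idx]
    v_ref <- v_ref[idx]
  }
  divided <- lapply(set$main, function(tr) {
    v <- stats::approx(tr$t, tr$v, xout = t_common)$y
    trace(t_common, v / v_ref, tr$t_mix)
  })
  trace_set(divided, reference = NULL, deconvolved = TRUE,
            ref_t_mix = ref$t_mix)
}

# centred cubic Savitzky-Golay weights for a window of 2h+1 points, and the
# variance factor of the centre residual under white noise
sg_center <- function(half = 4L, order = 3L) {
  x <- seq(-half, half)
  A <- outer(x, 0:order, `^`)
  c_row <- drop(A[half + 1L, , drop = FALSE] %*% solve(crossprod(A), t(A)))
  list(w = c_row, var_factor = 1 - 2 * c_row[half + 1L] + sum(c_row^2))
}

#' Estimate the noise standard deviation of a trace
#'
#' Detrends the trace with a moving local cubic polynomial (window of 9
#' points) and returns the residual scale, corrected for the variance
#' absorbed by the local fit. Used as inverse-variance weighting in the
#' global fit.
#'
#' @param tr A [trace()] with at least 16 points.
#' @return Non-negative noise standard deviation (amplitude units).
#' @export
estimate_noise <- function(tr) {
  stopifnot(is_trace(tr))
  n <- length(tr$v)
  if (n < 16L) stop("need at least 16 points to estimate noise")
  sg <- sg_center(half = 4L, order = 3L)
  idx <- 5:(n - 4L)
  resid <- vapply(idx, function(j) {
    tr$v[j] - sum(sg$w * tr$v[(j - 4L):(j + 4L)])
  }, numeric(1))
  sqrt(mean(resid^2) / sg$var_factor)
}

#' Stretched-exponential fit of a decay trace
#'
#' Least-squares fit of v(t) = exp(−k·(t/μs)^β_s), the compact two-parameter
#' summary used for hyperfine-filtered decay traces. A log–log regression of
#' −log(v) on t provides starting values; the fit is refined with
#' Levenberg–Marquardt under the constraints k ≥ 0, 0 < β_s ≤ 3.
#'
#' @param tr A [trace()] with at least 8 points and positive amplitudes
#'   over the fit range.
#' @return An object of class `stretched_exp_fit`: list with `k`
#'   (μs^(−β_s)), `beta_s` (dimensionless) and `rss`.
#' @export
stretched_exp_fit <- function(tr) {
  stopifnot(is_trace(tr))
  if (length(tr$t) < 8L) stop("need at least 8 points for a stretched-exponential fit")
  if (any(tr$v <= 0)) stop("amplitudes must be positive over the fit range")
  t <- tr$t
  v <- tr$v
  y <- -log(v)
  ok <- t > 0 & y > 1e-10
  if (sum(ok) < 3L) {
    # (numerically) constant trace: no decay, exponent unidentifiable
    fit <- list(k = 0, beta_s = 1, rss = sum((v - 1)^2))
    class(fit) <- "stretched_exp_fit"
    return(fit)
  }
  start_fit <- stats::lm(log(y[ok]) ~ log(t[ok]))
  b0 <- min(max(unname(stats::coef(start_fit)[2]), 0.05), 3)
  k0 <- exp(unname(stats::coef(start_fit)[1]))
  df <- data.frame(t = t, v = v)
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(v ~ exp(-k * t^b), data = df,
                      start = list(k = k0, b = b0),
                      lower = c(0, 1e-3), upper = c(Inf, 3),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) stop("stretched-exponential fit did not converge: ",
                             conditionMessage(e)))
  est <- stats::coef(nls_fit)
  fit <- list(k = unname(est["k"]), beta_s = unname(est["b"]),
              rss = sum(stats::resid(nls_fit)^2))
  class(fit) <- "stretched_exp_fit"
  fit
}

#' @export
print.stretched_exp_fit <- function(x, ...) {
  cat(sprintf("stretched-exponential fit: [k, beta] = [%.5g, %.5g], rss = %.3g\n",
              x$k, x$beta_s, x$rss))
  invisible(x)
}
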