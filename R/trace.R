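#' A single time-domain decay trace
#'
#' A decay record on a strictly increasing time grid (μs) with its mixing
#' time T_mix (μs), the interval during which magnetization is stored
#' longitudinally and the proton bath evolves.
#'
#' @param t Time grid, μs; strictly increasing, `t[1] >= 0`.
#' @param v Real amplitudes, dimensionless; same length as `t`, all finite.
#' @param t_mix Mixing time, μs; single non-negative number (may be `Inf`
#'   for the fully levelled-grid limit).
#' @return An object of class `ridme_trace`.
#' @export
trace <- function(t, v, t_mix) {
  t <- as.numeric(t); v <- as.numeric(v)
  if (length(t) == 0L) stop("empty time grid")
  if (length(t) != length(v)) stop("t and v must have equal length")
  if (!all(is.finite(t)) || !all(is.finite(v))) stop("t and v must be finite")
  if (t[1] < 0) stop("t must start at a non-negative time")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (!is.numeric(t_mix) || length(t_mix) != 1L || is.na(t_mix) || t_mix < 0) {
    stop("t_mix must be a single non-negative number")
  }
  structure(list(t = t, v = v, t_mix = t_mix), class = "ridme_trace")
}

is_trace <- function(x) inherits(x, "ridme_trace")

#' @export
print.ridme_trace <- function(x, ...) {
  cat(sprintf("ih-RIDME trace: %d points, t in [%g, %g] us, T_mix = %g us\n",
              length(x$t), x$t[1], x$t[length(x$t)], x$t_mix))
  invisible(x)
}

#' A set of decay traces sharing one experiment
#'
#' Holds the main traces recorded at different mixing times, plus (before
#' reference deconvolution) a reference trace at a mixing time shorter than
#' any main one. After [reference_deconvolve()] the reference is consumed:
#' the returned set has `reference = NULL`, `deconvolved = TRUE`, and the
#' reference mixing time retained in `ref_t_mix`.
#'
#' @param main List of [trace()] objects (at least one; at least two are
#'   required for global fitting).
#' @param reference A [trace()] with `t_mix` below every main `t_mix`, or
#'   `NULL` for an already reference-divided set.
#' @param deconvolved Logical; `TRUE` marks a reference-divided set.
#' @param ref_t_mix Mixing time (μs) of the consumed reference; filled
#'   automatically from `reference` when one is supplied.
#' @return An object of class `ridme_trace_set`.
#' @export
trace_set <- function(main, reference = NULL, deconvolved = FALSE,
                      ref_t_mix = NULL) {
  if (is_trace(main)) main <- list(main)
  if (!is.list(main) || length(main) < 1L || !all(vapply(main, is_trace, logical(1)))) {
    stop("'main' must be a non-empty list of trace objects")
  }
  t_mixes <- vapply(main, function(x) x$t_mix, numeric(1))
  if (anyDuplicated(t_mixes)) stop("duplicate mixing times among main traces")
  main <- main[order(t_mixes)]
  t_mixes <- sort(t_mixes)
  if (!is.null(reference)) {
    if (!is_trace(reference)) stop("'reference' must be a trace object")
    if (reference$t_mix >= min(t_mixes)) {
      stop("reference t_mix must be smaller than every main t_mix")
    }
    ref_t_mix <- reference$t_mix
  }
  if (deconvolved && is.null(ref_t_mix)) {
    stop("a deconvolved set must record the reference mixing time in 'ref_t_mix'")
  }
  structure(list(main = main, reference = reference,
                 deconvolved = isTRUE(deconvolved), ref_t_mix = ref_t_mix),
            class = "ridme_trace_set")
}

is_trace_set <- function(x) inherits(x, "ridme_trace_set")

#' @export
print.ridme_trace_set <- function(x, ...) {
  cat(sprintf("ih-RIDME trace set: %d main trace(s), T_mix = {%s} us\n",
              length(x$main),
              paste(vapply(x$main, function(z) format(z$t_mix), character(1)),
                    collapse = ", ")))
  if (!is.null(x$reference)) {
    cat(sprintf("  reference trace at T_mix = %g us\n", x$reference$t_mix))
  } else if (x$deconvolved) {
    cat(sprintf("  reference-divided (reference T_mix = %g us)\n", x$ref_t_mix))
  }
  invisible(x)
}

# all main traces on one identical time grid?
common_grid <- function(set) {
  t0 <- set$main[[1]]$t
  same <- all(vapply(set$main, function(tr) {
    length(tr$t) == length(t0) && all(tr$t == t0)
  }, logical(1)))
  if (!same) stop("main traces are not on a common time grid; preprocess first")
  t0
}
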