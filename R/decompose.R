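#' Gaussian mixture description of p(C_H)
#'
#' A sum of Gaussian components Σ cᵢ·N(μᵢ, σᵢ) used to summarize a fitted
#' concentration distribution. "Width" throughout this package means the
#' Gaussian standard deviation σᵢ, not the FWHM.
#'
#' @param means Component means μᵢ, mol/L.
#' @param widths Component standard deviations σᵢ, mol/L, all > 0.
#' @param fractions Component fractions cᵢ, summing to 1 within 1e-6 (or
#'   renormalized when `normalize = TRUE`).
#' @param normalize Renormalize fractions to unit sum. Default `FALSE`.
#' @return An object of class `gaussian_mixture` with components sorted by
#'   ascending mean.
#' @examples
#' bbg1 <- gaussian_mixture(c(4.35, 10.35, 28.5), c(1.4, 3.6, 3.0),
#'                          c(0.40, 0.54, 0.06))
#' @export
gaussian_mixture <- function(means, widths, fractions, normalize = FALSE) {
  n <- length(means)
  if (length(widths) != n || length(fractions) != n || n < 1L) {
    stop("means, widths and fractions must have equal positive length")
  }
  if (any(!is.finite(c(means, widths, fractions)))) stop("parameters must be finite")
  if (any(widths <= 0)) stop("widths must be positive")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  s <- sum(fractions)
  if (normalize) {
    if (s <= 0) stop("fractions sum to zero")
    fractions <- fractions / s
  } else if (abs(s - 1) > 1e-6) {
    stop("fractions must sum to 1 (got ", format(s), ")")
  }
  ord <- order(means)
  structure(list(means = means[ord], widths = widths[ord],
                 fractions = fractions[ord]),
            class = "gaussian_mixture")
}

is_mixture <- function(x) inherits(x, "gaussian_mixture")

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat("Gaussian mixture (mol/L):\n")
  df <- data.frame(Mean = x$means, Width = x$widths, Fraction = x$fractions)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Evaluate a Gaussian mixture density
#' @param mixture A [gaussian_mixture].
#' @param x Evaluation points, mol/L.
#' @return Mixture density values.
#' @export
mixture_pdf <- function(mixture, x) {
  stopifnot(is_mixture(mixture))
  out <- numeric(length(x))
  for (i in seq_along(mixture$means)) {
    out <- out + mixture$fractions[i] *
      stats::dnorm(x, mixture$means[i], mixture$widths[i])
  }
  out
}

#' Fit a Gaussian mixture to a density curve
#'
#' Approximates a fitted p(C_H) by Σ cᵢ·N(μᵢ, σᵢ) under cᵢ ≥ 0, Σcᵢ = 1
#' (softmax parameterization) and σᵢ > 0, with seeded multi-start
#' optimization. This is a curve fit to the distribution — the object being
#' decomposed is a fitted curve, not sample data, so EM on samples would be
#' the wrong tool. The least squares are taken in the cumulative domain
#' (fitting Σ cᵢ·Φ((c−μᵢ)/σᵢ) to the cumulative mass of `density`): point
#' wiggle from the regularized inversion integrates out there, and a broad
#' low-amplitude component — a few percent of mass spread over several
#' mol/L, nearly invisible in a density-domain metric — appears as a
#' persistent step. Component widths are capped at a quarter of the grid
#' span; anything broader is background, not an interpretable environment
#' class. For `n_components > 1` one start is inherited from the
#' (n−1)-component solution plus a vanishing extra component, so the
#' residual never increases with model order.
#'
#' @param density A [density_distribution].
#' @param n_components Number of Gaussian components, default 3.
#' @param seed Integer seed for the multi-start jitter.
#' @param n_starts Number of random starts, default 16.
#' @return A [gaussian_mixture] with attributes `rss` (cumulative-domain
#'   residual sum of squares on the grid) and `n_starts`.
#' @export
fit_mixture <- function(density, n_components = 3L, seed = 1L,
                        n_starts = 16L) {
  stopifnot(is_density(density))
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("n_components must be at least 1")
  x <- density$c_grid
  y <- density$p
  # cumulative mass through cell i estimates the CDF at the cell's right
  # edge x_i + dc/2, not at the cell centre; the model is evaluated there.
  # Residuals are weighted by local mass (plus a small uniform floor), so
  # the comparison is effectively uniform in probability — long empty
  # stretches of the concentration axis do not outvote the populated ones.
  Y <- cumsum(y) * density$dc
  x_edge <- x + density$dc / 2
  wts <- y * density$dc + 1 / length(x)
  rng <- diff(range(x))

  unpack <- function(theta) {
    n <- n_components
    mu <- theta[seq_len(n)]
    sg <- exp(theta[n + seq_len(n)])
    z <- theta[2L * n + seq_len(n)]
    cc <- exp(z - max(z))
    cc <- cc / sum(cc)
    list(mu = mu, sigma = sg, c = cc)
  }
  objective <- function(theta) {
    par <- unpack(theta)
    m <- numeric(length(x))
    for (i in seq_len(n_components)) {
      m <- m + par$c[i] * stats::pnorm(x_edge, par$mu[i], par$sigma[i])
    }
    sum(wts * (m - Y)^2)
  }
  lower <- c(rep(min(x), n_components),
             rep(log(density$dc / 4), n_components),
             rep(-12, n_components))
  upper <- c(rep(max(x), n_components),
             rep(log(rng / 4), n_components),
             rep(12, n_components))

  # deterministic quantile-based start
  cdf <- Y / max(Y)
  qs <- vapply((seq_len(n_components) - 0.5) / n_components,
               function(p) x[which.min(abs(cdf - p))], numeric(1))
  base_start <- c(qs, rep(log(max(rng / (4 * n_components), density$dc)),
                          n_components), rep(0, n_components))

  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      if (s == 1L) return(base_start)
      th <- base_start
      n <- n_components
      th[seq_len(n)] <- th[seq_len(n)] + stats::rnorm(n, 0, rng / 8)
      th[n + seq_len(n)] <- th[n + seq_len(n)] + stats::rnorm(n, 0, 0.5)
      th[2L * n + seq_len(n)] <- stats::rnorm(n, 0, 1)
      pmin(pmax(th, lower), upper)
    })
  })
  if (n_components > 1L) {
    prev <- fit_mixture(density, n_components - 1L, seed = seed,
                        n_starts = n_starts)
    resid <- y - mixture_pdf(prev, x)
    extra_mu <- x[which.max(resid)]
    th <- c(c(prev$means, extra_mu),
            log(c(prev$widths, max(rng / 20, density$dc))),
            c(log(pmax(prev$fractions, 1e-8)), -10))
    starts <- c(starts, list(pmin(pmax(th, lower), upper)))
  }

  best <- NULL
  for (th in starts) {
    fit <- tryCatch(
      stats::nlminb(th, objective, lower = lower, upper = upper,
                    control = list(iter.max = 1000, eval.max = 2000,
                                   rel.tol = 1e-14, x.tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    tie <- !is.null(best) &&
      abs(fit$objective - best$objective) <= 1e-9 * max(best$objective, 1e-12)
    if (is.null(best) ||
        (!tie && fit$objective < best$objective) ||
        (tie &&
         sum(exp(fit$par[n_components + seq_len(n_components)])) <
         sum(exp(best$par[n_components + seq_len(n_components)])))) {
      best <- fit
    }
  }
  if (is.null(best)) stop("mixture fit did not converge from any start")
  par <- unpack(best$par)
  out <- gaussian_mixture(par$mu, par$sigma, par$c, normalize = TRUE)
  attr(out, "rss") <- best$objective
  attr(out, "n_starts") <- length(starts)
  out
}

#' Compare two Gaussian mixtures component-by-component
#'
#' Matches components greedily by nearest means (closest pair first) and
#' returns the signed parameter differences `b − a` per matched pair,
#' ordered by the means of `a`.
#'
#' @param a,b [gaussian_mixture] objects with the same number of components.
#' @return A data frame with columns `mu_a`, `mu_b`, `delta_mu`,
#'   `delta_sigma`, `delta_c`.
#' @export
compare_mixtures <- function(a, b) {
  stopifnot(is_mixture(a), is_mixture(b))
  n <- length(a$means)
  if (length(b$means) != n) stop("mixtures must have the same number of components")
  avail_a <- seq_len(n)
  avail_b <- seq_len(n)
  match_b <- integer(n)
  for (step in seq_len(n)) {
    d <- abs(outer(a$means[avail_a], b$means[avail_b], `-`))
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    match_b[avail_a[ij[1]]] <- avail_b[ij[2]]
    avail_a <- avail_a[-ij[1]]
    avail_b <- avail_b[-ij[2]]
  }
  data.frame(mu_a = a$means,
             mu_b = b$means[match_b],
             delta_mu = b$means[match_b] - a$means,
             delta_sigma = b$widths[match_b] - a$widths,
             delta_c = b$fractions[match_b] - a$fractions)
}

#' Residuals of mixture fits of increasing order
#'
#' Reports the curve-fit residual for n = 1 … `n_max` components; model
#' order is otherwise chosen by inspection, not automatically.
#'
#' @param density A [density_distribution].
#' @param n_max Largest order to fit, default 5.
#' @param seed Multi-start seed.
#' @return Data frame with columns `n_components` and `rss`.
#' @export
mixture_order_scan <- function(density, n_max = 5L, seed = 1L) {
  rss <- vapply(seq_len(n_max), function(n) {
    attr(fit_mixture(density, n, seed = seed), "rss")
  }, numeric(1))
  data.frame(n_components = seq_len(n_max), rss = rss)
}
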