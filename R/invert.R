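#' Global model-free inversion of a reference-divided trace set
#'
#' Recovers the distribution of local proton concentration p(C_H) from a set
#' of ih-RIDME traces recorded at several mixing times, after normalization
#' and reference deconvolution.
#'
#' A reference-divided trace obeys V_i(τ) = (K_i p)(τ) / (K_ref p)(τ), where
#' K_i and K_ref are the LSD decay kernels ([kernel_matrix()]) at the main
#' and reference mixing times: the division renormalizes the decay by the
#' surviving part of the ensemble, so the model is a ratio of two integrals
#' over p rather than a single linear kernel. The fit minimizes the
#' generalized-least-squares misfit
#'
#'   Σ_t ||Σ_t^{−1/2} (V(t) − a∘(K x)(t)/(K_ref x)(t))||² + λ||L x||²
#'     + μ·(Σx − 1)² + Σ_i (a_i − 1)²/(2σ_i²),
#'
#' over cell masses x = p·Δc ≥ 0 and per-trace amplitudes a_i. The error
#' covariance Σ_t accounts for the noise structure that reference division
#' creates: per-trace white noise (inverse-variance weights from
#' [estimate_noise()]), amplification by 1/r(t) where the reference has
#' decayed, and the common-mode component that the one shared noisy
#' reference injects into every divided trace. The amplitudes a_i absorb
#' the coherent scale error left by normalizing each trace to its own noisy
#' first point (prior variance 2σ_i²). L is the second-difference
#' (curvature) operator with zero boundary conditions and μ a unit-mass
#' anchor removing the scale invariance of the ratio. The problem is solved
#' by Gauss–Newton iteration whose linearized subproblems are exact
#' active-set NNLS solves, with step halving on the true objective; the
#' result is renormalized to unit mass. Correlated changes across mixing
#' times pin down the D/σ³ normalization, which is why the multi-trace
#' global fit is far better conditioned than inversion of any single trace.
#'
#' @param set A reference-divided [trace_set()] with at least two main
#'   traces on a common time grid (see [reference_deconvolve()]).
#' @param c_grid Concentration grid, mol/L. Default [default_c_grid()].
#' @param constants A [kernel_constants] object.
#' @param lambda_reg Regularization weight λ > 0, or `"auto"` for
#'   discrepancy-based selection via [select_lambda()]. The default 10 is
#'   calibrated to the default concentration grid: the curvature seminorm
#'   of a smooth unit-mass multi-component density on a 0.25 mol/L grid is
#'   ~1e-5 while grid-scale oscillation reaches ~1e-2, so λ = 10 prices
#'   wiggle at the level of the misfit of a typical five-trace set while
#'   leaving smooth multi-component structure essentially unpenalized.
#' @param fit_k3 If `TRUE`, the rate normalization k₃ is refined by an outer
#'   one-dimensional search (Brent on log k₃) around its configured value,
#'   keeping the inner problem convex.
#' @param noise_floor Lower bound on the per-trace noise scale used for
#'   weighting, guarding against zero-noise synthetic traces.
#' @return An object of class `ridme_fit`: list with `density`
#'   (a [density_distribution]), `lambda_reg`, `k3_fitted` (NULL unless
#'   `fit_k3`), `constants` (with k₃ replaced by the fitted value if any),
#'   `residual_norms` (per trace, unweighted, of the divided traces against
#'   the ratio model), `objective`, `weights`, and `uncertainty_band`
#'   (NULL until [uncertainty_band()] is run).
#' @export
global_fit <- function(set, c_grid = default_c_grid(),
                       constants = kernel_constants(),
                       lambda_reg = 10, fit_k3 = FALSE,
                       noise_floor = 1e-6) {
  prob <- build_problem(set, c_grid, constants, noise_floor,
                        min_traces = 2L)
  if (identical(lambda_reg, "auto")) {
    lam_sel <- select_lambda_internal(prob)
    lambda_reg <- lam_sel$lambda
  } else {
    if (!is.numeric(lambda_reg) || length(lambda_reg) != 1L || lambda_reg <= 0) {
      stop("lambda_reg must be a positive number or \"auto\"")
    }
  }
  k3_fitted <- NULL
  if (isTRUE(fit_k3)) {
    obj_k3 <- function(log_k3) {
      kc <- constants
      kc$k3 <- exp(log_k3)
      solve_penalized(rebuild_kernel(prob, kc), lambda_reg)$objective
    }
    opt <- stats::optimize(obj_k3,
                           interval = log(constants$k3) + c(-log(5), log(5)),
                           tol = 1e-4)
    k3_fitted <- exp(opt$minimum)
    constants$k3 <- k3_fitted
    prob <- rebuild_kernel(prob, constants)
  }
  sol <- solve_penalized(prob, lambda_reg)
  if (all(sol$x == 0)) stop("degenerate fit: all-zero solution")
  density <- density_distribution(c_grid, sol$x / prob$dc)
  res_norms <- per_trace_residuals(prob, sol$x)
  structure(list(density = density,
                 lambda_reg = lambda_reg,
                 k3_fitted = k3_fitted,
                 constants = constants,
                 residual_norms = res_norms,
                 objective = sol$objective,
                 weights = prob$w,
                 uncertainty_band = NULL,
                 problem = prob),
            class = "ridme_fit")
}

#' @export
print.ridme_fit <- function(x, ...) {
  cat("ih-RIDME global fit\n")
  cat(sprintf("  lambda = %.4g%s\n", x$lambda_reg,
              if (is.null(x$k3_fitted)) ""
              else sprintf(", fitted k3 = %.4g us^-1 MHz^-3", x$k3_fitted)))
  cat(sprintf("  per-trace residual norms: %s\n",
              paste(sprintf("%.3g", x$residual_norms), collapse = ", ")))
  print(x$density)
  invisible(x)
}

# Assemble the weighted cross-multiplied linear inverse problem shared by
# global_fit, select_lambda, uncertainty_band and degeneracy_diagnostic.
build_problem <- function(set, c_grid, constants, noise_floor = 1e-6,
                          min_traces = 2L) {
  stopifnot(is_trace_set(set))
  if (!set$deconvolved) {
    stop("the global fit consumes a reference-divided set; ",
         "run reference_deconvolve() first")
  }
  if (length(set$main) < min_traces) {
    stop(sprintf("need at least %d main trace(s)", min_traces))
  }
  check_conc(c_grid)
  if (any(diff(c_grid) <= 0)) stop("c_grid must be strictly increasing")
  t_grid <- common_grid(set)
  nt <- length(t_grid)
  t_mix_list <- vapply(set$main, function(tr) tr$t_mix, numeric(1))
  V <- unlist(lapply(set$main, function(tr) tr$v), use.names = FALSE)
  noise <- vapply(set$main, function(tr) {
    if (length(tr$v) >= 16L) estimate_noise(tr) else noise_floor
  }, numeric(1))
  w <- 1 / pmax(noise, noise_floor)^2
  w <- w / mean(w)                      # relative weights; keeps lambda scale stable
  prob <- list(set = set, t_grid = t_grid, t_mix_list = t_mix_list,
               c_grid = c_grid, dc = mean(diff(c_grid)),
               constants = constants, V = V, w = w, noise = noise,
               L = second_difference(length(c_grid)),
               mass_weight = length(V))
  prob$LtL <- crossprod(prob$L)
  assemble_system(prob, constants)
}

# second-difference operator with zero boundary conditions: p is taken to
# vanish outside the grid, so edge cells carry full curvature rows and
# boundary spikes are penalized like interior ones
second_difference <- function(n) {
  if (n < 3L) return(matrix(0, 0, n))
  L <- matrix(0, n, n)
  L[1, 1:2] <- c(-2, 1)
  for (i in 2:(n - 1L)) L[i, (i - 1L):(i + 1L)] <- c(1, -2, 1)
  L[n, (n - 1L):n] <- c(1, -2)
  L
}

# kernels at the current constants for the cross-multiplied system
# [sqrt(w_i) s(t) (diag(V_i) K_ref - K_i); sqrt(mu) 1'] x ~ [0; sqrt(mu)]
assemble_system <- function(prob, constants) {
  prob$constants <- constants
  prob$K_main <- kernel_matrix(prob$t_grid, prob$t_mix_list, prob$c_grid,
                               constants)
  prob$K_ref <- kernel_matrix(prob$t_grid, prob$set$ref_t_mix, prob$c_grid,
                              constants)
  prob
}

rebuild_kernel <- function(prob, constants) assemble_system(prob, constants)

# replace the data vector (same constants/weights); used by the bootstrap
replace_data <- function(prob, V) {
  prob$V <- V
  prob
}

# Generalized-least-squares metric for reference-divided traces. Division
# by one measured reference makes the errors of the m divided traces
# correlated at each time point:
#   e_i(t) = eps_i(t)/r(t) - V_i(t) eps_ref(t)/r(t),
# so Cov[e(t)] = (1/r(t)^2) [diag(sigma_i^2) + sigma_ref^2 v(t) v(t)'] with
# v the model values and r the model reference decay. The whitening
# transform (Sherman-Morrison square root of the inverse) is
#   Sigma_t^{-1/2} = r(t) (I - theta_t u_t u_t') W^{1/2},
# with W = diag(w_i) the per-trace inverse variances (relative units),
# u_t = W^{1/2} v(t) and theta_t = (1 - 1/sqrt(1 + s_r^2 |u_t|^2))/|u_t|^2.
# The common-mode direction is discounted instead of being chased by p.
whiten_parts <- function(prob, x) {
  nt <- length(prob$t_grid)
  m <- length(prob$t_mix_list)
  xn <- x / max(sum(x), .Machine$double.eps)
  den <- pmax(drop(prob$K_ref %*% xn), 1e-6)
  num <- matrix(drop(prob$K_main %*% xn), nt, m)
  Vfit <- num / den
  Vfit <- sweep(Vfit, 2L, profile_scales(matrix(prob$V, nt, m), Vfit, prob$noise), `*`)
  sr2 <- mean(1 / prob$w)
  U <- sweep(Vfit, 2L, sqrt(prob$w), `*`)
  nrm2 <- rowSums(U^2)
  theta <- ifelse(nrm2 > 0,
                  (1 - 1 / sqrt(1 + sr2 * nrm2)) / nrm2, 0)
  list(r = den, U = U, theta = theta, Vfit = Vfit)
}

# whitened residual sum of squares of data matrix Vmat (nt x m) against
# model matrix Mmat under the metric `parts`
whitened_rss <- function(prob, parts, Vmat, Mmat) {
  E1 <- sweep(Vmat - Mmat, 2L, sqrt(prob$w), `*`)
  s <- rowSums(E1 * parts$U)
  Ew <- (E1 - (parts$theta * s) * parts$U) * parts$r
  sum(Ew^2)
}

# Per-trace amplitude nuisance: normalizing each measured trace by its noisy
# first point leaves a coherent scale error on the whole trace (one noisy
# point from the main trace and one from the reference, so Var(a_i) ~
# 2 sigma_i^2) that the shape model cannot absorb. The scale of each trace
# is profiled out by ridge least squares with that prior, anchored at 1.
profile_scales <- function(Vmat, Mmat, noise) {
  s2 <- pmax(noise, 1e-6)^2
  prior_prec <- 1 / (2 * s2)
  a <- (colSums(Vmat * Mmat) / s2 + prior_prec) /
       (pmax(colSums(Mmat^2), .Machine$double.eps) / s2 + prior_prec)
  pmin(pmax(a, 0.9), 1.1)
}

# true penalized objective of cell masses x and per-trace scales a (unit
# mass anchor and scale prior included); the GLS metric is evaluated at
# `metric_parts` when supplied (frozen per Gauss-Newton iteration)
penalized_objective <- function(prob, lambda, x, scales = NULL,
                                metric_parts = NULL) {
  nt <- length(prob$t_grid)
  m <- length(prob$t_mix_list)
  parts <- if (is.null(metric_parts)) whiten_parts(prob, x) else metric_parts
  xn <- x / max(sum(x), .Machine$double.eps)
  den <- pmax(drop(prob$K_ref %*% xn), 1e-6)
  Mmat <- matrix(drop(prob$K_main %*% xn), nt, m) / den
  Vmat <- matrix(prob$V, nt, m)
  if (is.null(scales)) scales <- profile_scales(Vmat, Mmat, prob$noise)
  Mmat <- sweep(Mmat, 2L, scales, `*`)
  rss_w <- whitened_rss(prob, parts, Vmat, Mmat)
  pen <- drop(crossprod(x, prob$LtL %*% x))
  list(rss_w = rss_w, penalty = pen,
       objective = rss_w + lambda * pen +
         prob$mass_weight * (sum(x) - 1)^2 +
         sum(prob$w / 2 * (scales - 1)^2))
}

# Penalized non-negative fit of the ratio model
#   V_i(t) ~ (K_i x)(t) / (K_ref x)(t)
# by Gauss-Newton with exact NNLS subproblems: the model is linearized
# around the current iterate, the resulting non-negative linear
# least-squares problem (plus curvature penalty and unit-mass anchor) is
# solved by active-set NNLS, and steps are halved until the true objective
# does not increase. Started from the uniform distribution; deterministic.
solve_penalized <- function(prob, lambda, max_iter = 40L, tol = 1e-10) {
  nt <- length(prob$t_grid)
  n <- length(prob$c_grid)
  m <- length(prob$t_mix_list)
  mass_row <- c(rep(sqrt(prob$mass_weight), n), numeric(m))
  x <- rep(1 / n, n)
  a <- rep(1, m)
  parts <- whiten_parts(prob, x)
  f0 <- penalized_objective(prob, lambda, x, scales = a, metric_parts = parts)
  for (it in seq_len(max_iter)) {
    num <- drop(prob$K_main %*% x)
    den <- pmax(rep(drop(prob$K_ref %*% x), times = m), 1e-6)
    Mmat <- matrix(num / den, nt, m)
    a_rep <- rep(a, each = nt)
    r_vec <- prob$V - a_rep * (num / den)
    # Jacobian of the scaled ratio model wrt (x, a): the x block is the
    # scaled ratio-model Jacobian, the a block is block-diagonal with the
    # unscaled model values; both are GLS-whitened per time point (scale
    # the trace dimension by sqrt(w_i), project out the common-mode
    # direction, scale rows by the reference decay r(t))
    Jraw <- a_rep * (prob$K_main / den -
      (num / den^2) * prob$K_ref[rep(seq_len(nt), times = m), ])
    Sx <- matrix(0, nt, n)
    Sa <- matrix(0, nt, m)
    for (i in seq_len(m)) {
      idx <- ((i - 1L) * nt + 1L):(i * nt)
      Sx <- Sx + parts$U[, i] * (sqrt(prob$w[i]) * Jraw[idx, , drop = FALSE])
      Sa[, i] <- parts$U[, i] * sqrt(prob$w[i]) * Mmat[, i]
    }
    E1 <- sweep(matrix(r_vec, nt, m), 2L, sqrt(prob$w), `*`)
    s_res <- rowSums(E1 * parts$U)
    J <- matrix(0, nt * m, n + m)
    b <- numeric(nt * m)
    for (i in seq_len(m)) {
      idx <- ((i - 1L) * nt + 1L):(i * nt)
      J1 <- sqrt(prob$w[i]) * Jraw[idx, , drop = FALSE]
      J[idx, seq_len(n)] <- parts$r * (J1 - (parts$theta * parts$U[, i]) * Sx)
      Ja_own <- sqrt(prob$w[i]) * Mmat[, i]
      for (k in seq_len(m)) {
        J[idx, n + k] <- parts$r *
          ((if (k == i) Ja_own else numeric(nt)) -
             parts$theta * parts$U[, i] * Sa[, k])
      }
      b[idx] <- parts$r * (E1[, i] - parts$theta * parts$U[, i] * s_res)
    }
    b <- b + drop(J %*% c(x, a))
    prior_prec <- prob$w / 2
    AtA <- crossprod(J) + tcrossprod(mass_row) +
      lambda * rbind(cbind(prob$LtL, matrix(0, n, m)), matrix(0, m, n + m))
    diag(AtA)[n + seq_len(m)] <- diag(AtA)[n + seq_len(m)] + prior_prec
    Atb <- drop(crossprod(J, b)) + mass_row * sqrt(prob$mass_weight)
    Atb[n + seq_len(m)] <- Atb[n + seq_len(m)] + prior_prec
    u <- fnnls(AtA, Atb)
    x_new <- u[seq_len(n)]
    a_new <- pmin(pmax(u[n + seq_len(m)], 0.9), 1.1)
    f_new <- penalized_objective(prob, lambda, x_new, scales = a_new,
                                 metric_parts = parts)
    f0_here <- penalized_objective(prob, lambda, x, scales = a,
                                   metric_parts = parts)
    halvings <- 0L
    while (f_new$objective > f0_here$objective + 1e-14 && halvings < 10L) {
      x_new <- (x_new + x) / 2
      a_new <- (a_new + a) / 2
      f_new <- penalized_objective(prob, lambda, x_new, scales = a_new,
                                   metric_parts = parts)
      halvings <- halvings + 1L
    }
    if (f_new$objective > f0_here$objective + 1e-14) break
    step <- max(abs(x_new - x))
    x <- x_new
    a <- a_new
    parts <- whiten_parts(prob, x)
    f0 <- penalized_objective(prob, lambda, x, scales = a,
                              metric_parts = parts)
    if (step < tol) break
  }
  list(x = x, scales = a, rss_w = f0$rss_w, penalty = f0$penalty,
       objective = f0$rss_w + lambda * f0$penalty)
}

# divided-trace model a_i (K_i x)/(K_ref x) for a cell-mass vector x, with
# the per-trace amplitude nuisance profiled out
ratio_model <- function(prob, x) {
  nt <- length(prob$t_grid)
  m <- length(prob$t_mix_list)
  num <- drop(prob$K_main %*% x)
  den <- pmax(rep(drop(prob$K_ref %*% x), times = m), 1e-6)
  Mmat <- matrix(num / den, nt, m)
  scales <- profile_scales(matrix(prob$V, nt, m), Mmat, prob$noise)
  as.vector(sweep(Mmat, 2L, scales, `*`))
}

per_trace_residuals <- function(prob, x) {
  nt <- length(prob$t_grid)
  fit <- ratio_model(prob, x)
  vapply(seq_along(prob$t_mix_list), function(i) {
    idx <- ((i - 1L) * nt + 1L):(i * nt)
    sqrt(sum((prob$V[idx] - fit[idx])^2))
  }, numeric(1))
}

#' Regularization weight by the discrepancy criterion
#'
#' Solves the penalized non-negative inversion over a logarithmic grid of λ
#' and selects the largest λ whose noise-normalized residual
#' Σ_i ||V_i − fit_i||²/σ̂_i² stays within a factor `1 + kappa` of the
#' number of fitted points — the strongest smoothing still statistically
#' consistent with the estimated noise. Deterministic given the inputs. If
#' no grid point is consistent with the noise level (model mismatch), the
#' selection falls back to λ = 1 with a warning.
#'
#' @inheritParams global_fit
#' @param lambda_grid Candidate weights; default `10^seq(-2, 4)` with 25
#'   points.
#' @param kappa Relative slack on the noise-floor residual. Default 0.15.
#' @return Selected λ (scalar).
#' @export
select_lambda <- function(set, c_grid = default_c_grid(),
                          constants = kernel_constants(),
                          lambda_grid = 10^seq(-2, 4, length.out = 25),
                          kappa = 0.15) {
  prob <- build_problem(set, c_grid, constants, min_traces = 1L)
  select_lambda_internal(prob, lambda_grid, kappa)$lambda
}

select_lambda_internal <- function(prob,
                                   lambda_grid = 10^seq(-2, 4, length.out = 25),
                                   kappa = 0.15) {
  lambda_grid <- sort(lambda_grid)
  nt <- length(prob$t_grid)
  noise2 <- pmax(prob$noise, 1e-6)^2
  rss_noise <- vapply(lambda_grid, function(l) {
    sol <- solve_penalized(prob, l)
    fit <- ratio_model(prob, sol$x / max(sum(sol$x), .Machine$double.eps))
    tot <- 0
    for (i in seq_along(prob$t_mix_list)) {
      idx <- ((i - 1L) * nt + 1L):(i * nt)
      tot <- tot + sum((prob$V[idx] - fit[idx])^2) / noise2[i]
    }
    tot
  }, numeric(1))
  target <- (1 + kappa) * length(prob$V)
  feasible <- which(rss_noise <= target)
  if (!length(feasible)) {
    warning("no regularization weight is consistent with the estimated ",
            "noise level; falling back to lambda = 1")
    return(list(lambda = 1, lambda_grid = lambda_grid,
                rss_noise = rss_noise, target = target))
  }
  list(lambda = lambda_grid[max(feasible)], lambda_grid = lambda_grid,
       rss_noise = rss_noise, target = target)
}

#' Bootstrap uncertainty band for a fitted density
#'
#' Residual-resampling bootstrap: each replicate adds residuals resampled
#' (with replacement, per trace) to the fitted divided-trace model and
#' refits with the same λ and k₃; the band is the pointwise 5th/95th
#' percentile envelope of p across replicates. The widths of decomposed
#' components are the main beneficiary of this diagnostic — they are
#' typically far less certain than the component positions.
#'
#' @param set The reference-divided [trace_set()] that was fitted.
#' @param result A `ridme_fit` from [global_fit()].
#' @param n_boot Number of bootstrap refits, at least 10. Default 100.
#' @param seed Integer seed; the band is reproducible bit-for-bit.
#' @return `result` with `uncertainty_band` set to a list
#'   `(lower, upper, n_boot, seed)`.
#' @export
uncertainty_band <- function(set, result, n_boot = 100L, seed = 1L) {
  stopifnot(inherits(result, "ridme_fit"))
  if (n_boot < 10L) stop("n_boot must be at least 10")
  prob <- result$problem
  nt <- length(prob$t_grid)
  x_hat <- result$density$p * prob$dc
  fit <- ratio_model(prob, x_hat)
  resid <- prob$V - fit
  P <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      Vb <- fit
      for (i in seq_along(prob$t_mix_list)) {
        idx <- ((i - 1L) * nt + 1L):(i * nt)
        Vb[idx] <- Vb[idx] + sample(resid[idx], length(idx), replace = TRUE)
      }
      pb <- replace_data(prob, Vb)
      xb <- solve_penalized(pb, result$lambda_reg)$x
      m <- sum(xb)
      if (m > 0) xb <- xb / m
      xb / prob$dc
    }, numeric(length(prob$c_grid)))
  })
  band <- apply(P, 1, stats::quantile, probs = c(0.05, 0.95), names = FALSE)
  result$uncertainty_band <- list(lower = band[1, ], upper = band[2, ],
                                  n_boot = n_boot, seed = seed)
  result
}

#' Degeneracy diagnostic: how well does the set constrain D/σ³?
#'
#' Refits the density over a grid of k₃ values (±`span` around the
#' configured value) at fixed λ and reports the profile of the fit
#' objective together with a sharpness score: the normalized convexity
#' (o_first + o_last − 2·o_mid)/(2·o_min) of the profile. When p(C_H) is
#' degenerate with the spectral diffusion rate normalization — the
#' situation expected when only one or two traces are fitted — the refitted
#' objective is flat or slides monotonically across the scan and the score
#' is near zero; a full multi-mixing-time set produces a pronounced
#' interior minimum and a large score.
#'
#' @param set A reference-divided [trace_set()] (one trace suffices).
#' @param c_grid Concentration grid, mol/L.
#' @param constants A [kernel_constants] object; the scan is centred on its k₃.
#' @param lambda Fixed regularization weight for the scan. Default 1e-2.
#' @param n_k3 Number of scan points, default 11.
#' @param span Relative half-width of the scan, default 0.5.
#' @return List with `k3_grid`, `objective` and the scalar `score`.
#' @export
degeneracy_diagnostic <- function(set, c_grid = default_c_grid(),
                                  constants = kernel_constants(),
                                  lambda = 1e-2, n_k3 = 11L, span = 0.5) {
  prob <- build_problem(set, c_grid, constants, min_traces = 1L)
  k3_grid <- seq(constants$k3 * (1 - span), constants$k3 * (1 + span),
                 length.out = n_k3)
  obj <- vapply(k3_grid, function(k3) {
    kc <- constants
    kc$k3 <- k3
    solve_penalized(rebuild_kernel(prob, kc), lambda)$objective
  }, numeric(1))
  mid <- (n_k3 + 1L) %/% 2L
  score <- max(0, (obj[1] + obj[n_k3] - 2 * obj[mid]) /
                 (2 * max(min(obj), .Machine$double.eps)))
  list(k3_grid = k3_grid, objective = obj, score = score)
}
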