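#' Hyperfine shift width from local proton concentration
#'
#' The distribution of hyperfine frequency shifts experienced by the electron
#' spin is Gaussian with standard deviation proportional to the local proton
#' concentration, σ = γ_σ·C_H.
#'
#' @param c_h Local proton concentration, mol/L (vectorized, all ≥ 0).
#' @param constants A [kernel_constants] object.
#' @return Width σ in MHz.
#' @examples
#' sigma_from_concentration(14, kernel_constants())  # 0.2996 MHz
#' @export
sigma_from_concentration <- function(c_h, constants = kernel_constants()) {
  check_conc(c_h)
  constants$gamma_sigma * c_h
}

check_conc <- function(c_h) {
  if (!is.numeric(c_h) || any(!is.finite(c_h)) || any(c_h < 0)) {
    stop("concentration must be finite and non-negative")
  }
  invisible(c_h)
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stop(what, " must be non-negative")
  }
  invisible(x)
}

#' Homogeneous Gaussian decay factor (long-mixing-time limit)
#'
#' Echo attenuation by longitudinal spectral diffusion for a homogeneous
#' proton environment once the polarization grid is fully levelled:
#' F(τ) = exp(−4·β·C_H²·τ²). The factor 4 is a calibration convention of
#' this package tied to the trace time axis; with it the 1/e decay times are
#' exactly 1/(2·√β·C_H), reproducing the canonical sensitivity-window
#' boundaries (4.2, 8.4, 12.8 μs at 14, 7, 4.6 M).
#'
#' @param tau Dipolar-axis time, μs (vectorized, ≥ 0).
#' @param c_h Local proton concentration, mol/L (≥ 0).
#' @param constants A [kernel_constants] object.
#' @return Amplitude in (0, 1].
#' @export
homogeneous_decay <- function(tau, c_h, constants = kernel_constants()) {
  check_nonneg(tau, "tau")
  check_conc(c_h)
  exp(-4 * constants$beta * c_h^2 * tau^2)
}

#' Mixing-time-dependent LSD decay
#'
#' Forward model of the ih-RIDME echo decay:
#' V(τ; T_mix, C_H) = exp(−4·β·C_H²·τ²·f(τ, T_mix, σ)) with the saturation
#' factor f = 1 − exp(−k₃·σ³·τ²·T_mix) and σ = γ_σ·C_H.
#'
#' The saturation factor is a Gauss–Markov stand-in for the dipolar
#' frequency correlation decay: during the mixing time the electron
#' resonance frequency diffuses (coefficient D = k₃·σ³, with the
#' concentration-invariant normalization D/σ³) across the stored
#' polarization grid, whose finesse is set by the defocusing time — the
#' grid period is 1/τ, so leveling it takes a time ∝ 1/(D·τ²). Longer
#' mixing and finer grids therefore deepen the decay until the homogeneous
#' limit is reached. The model reduces to 1 at T_mix = 0 and to
#' [homogeneous_decay()] as T_mix → ∞ (for τ > 0), and is monotonically
#' non-increasing in τ, T_mix and C_H.
#'
#' @param tau Dipolar-axis time, μs (vectorized, ≥ 0).
#' @param t_mix Mixing time, μs (≥ 0, may be `Inf`).
#' @param c_h Local proton concentration, mol/L (≥ 0).
#' @param constants A [kernel_constants] object.
#' @return Amplitude in (0, 1].
#' @export
lsd_decay <- function(tau, t_mix, c_h, constants = kernel_constants()) {
  check_nonneg(tau, "tau")
  if (!is.numeric(t_mix) || any(is.na(t_mix)) || any(t_mix < 0)) {
    stop("t_mix must be non-negative")
  }
  check_conc(c_h)
  f <- lsd_saturation(tau, t_mix, c_h, constants)
  exp(-4 * constants$beta * c_h^2 * tau^2 * f)
}

# saturation factor f(tau, T_mix, sigma) in [0, 1];
# 0 whenever sigma = 0, tau = 0 or T_mix = 0
lsd_saturation <- function(tau, t_mix, c_h, constants) {
  sigma <- constants$gamma_sigma * c_h
  rate <- constants$k3 * sigma^3 * tau^2
  x <- rate * t_mix
  x[rate == 0 | t_mix == 0] <- 0  # avoid 0 * Inf
  1 - exp(-x)
}

#' Discretized forward kernel for global inversion
#'
#' Evaluates the LSD decay model on the tensor grid (mixing times × time
#' points) × concentration cells. Rows are ordered trace-major: row
#' `(i-1)*length(t_grid) + j` corresponds to mixing time `t_mix_list[i]` at
#' time `t_grid[j]`; column `k` to concentration `c_grid[k]`.
#'
#' With `t_mix_ref` supplied, entries are the reference-divided model
#' lsd_decay(τ, T_mix, c) / lsd_decay(τ, T_ref, c): the forward model of a
#' trace set after reference deconvolution, per concentration cell. With the
#' default `t_mix_ref = NULL` the plain decay model is returned.
#'
#' @param t_grid Time grid, μs (non-empty, ≥ 0).
#' @param t_mix_list Mixing times, μs (non-empty).
#' @param c_grid Concentration grid, mol/L (non-empty, ≥ 0).
#' @param constants A [kernel_constants] object.
#' @param t_mix_ref Optional reference mixing time, μs.
#' @return Matrix of amplitudes, `length(t_mix_list)*length(t_grid)` rows by
#'   `length(c_grid)` columns; all entries in (0, 1].
#' @export
kernel_matrix <- function(t_grid, t_mix_list, c_grid,
                          constants = kernel_constants(), t_mix_ref = NULL) {
  if (length(t_grid) == 0L || length(t_mix_list) == 0L || length(c_grid) == 0L) {
    stop("kernel grids must be non-empty")
  }
  check_nonneg(t_grid, "t_grid")
  check_conc(c_grid)
  nt <- length(t_grid)
  K <- matrix(NA_real_, nrow = nt * length(t_mix_list), ncol = length(c_grid))
  for (k in seq_along(c_grid)) {
    col <- vapply(t_mix_list,
                  function(tm) lsd_decay(t_grid, tm, c_grid[k], constants),
                  numeric(nt))
    col <- as.vector(col)
    if (!is.null(t_mix_ref)) {
      ref <- lsd_decay(t_grid, t_mix_ref, c_grid[k], constants)
      col <- col / rep(ref, times = length(t_mix_list))
    }
    K[, k] <- col
  }
  K
}

#' Time at which the LSD decay reaches 1/e
#'
#' In the long-mixing-time limit the 1/e time has the closed form
#' 1/(2·√β·C_H). For finite mixing times the equation
#' lsd_decay(τ) = e⁻¹ is solved by bisection to 1e-4 μs.
#'
#' @param c_h Local proton concentration, mol/L; must be > 0.
#' @param t_mix Mixing time, μs; default `Inf` (levelled-grid limit).
#' @param constants A [kernel_constants] object.
#' @return The 1/e time, μs.
#' @examples
#' one_over_e_time(14)   # 4.2 us
#' one_over_e_time(7)    # 8.4 us
#' @export
one_over_e_time <- function(c_h, t_mix = Inf, constants = kernel_constants()) {
  if (!is.numeric(c_h) || length(c_h) != 1L || !is.finite(c_h) || c_h <= 0) {
    stop("c_h must be a single positive concentration; the decay of a ",
         "proton-free environment never reaches 1/e")
  }
  if (is.infinite(t_mix)) {
    return(1 / (2 * sqrt(constants$beta) * c_h))
  }
  if (t_mix <= 0) stop("no spectral diffusion at t_mix = 0: decay never reaches 1/e")
  # the levelled-grid 1/e time bounds the solution from below; grow the
  # bracket until the model crosses 1/e, then bisect the model itself
  lo <- 0
  hi <- 2 / (2 * sqrt(constants$beta) * c_h)
  target <- exp(-1)
  while (lsd_decay(hi, t_mix, c_h, constants) > target) hi <- hi * 2
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (lsd_decay(mid, t_mix, c_h, constants) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Sensitivity-window boundaries on the trace time axis
#'
#' Traces are predominantly sensitive to high concentrations at early times
#' and to progressively lower concentrations later. For a list of threshold
#' concentrations (given high → low) this returns the 1/e time of each,
#' which partitions the time axis into windows: the canonical thresholds
#' 14, 7, 4.6 M give boundaries 4.2, 8.4, 12.8 μs in the long-mixing-time
#' limit. The thresholds provide rough guidance only — every concentration
#' contributes to the decay at all times.
#'
#' @param thresholds Concentrations, mol/L, strictly decreasing.
#' @param t_mix Mixing time, μs; default `Inf`.
#' @param constants A [kernel_constants] object.
#' @return Strictly increasing time boundaries, μs.
#' @export
sensitivity_windows <- function(thresholds, t_mix = Inf,
                                constants = kernel_constants()) {
  if (length(thresholds) < 1L || any(!is.finite(thresholds)) ||
      any(thresholds <= 0)) {
    stop("thresholds must be positive concentrations")
  }
  if (length(thresholds) > 1L && any(diff(thresholds) >= 0)) {
    stop("thresholds must be strictly decreasing (high to low concentration)")
  }
  vapply(thresholds, one_over_e_time, numeric(1),
         t_mix = t_mix, constants = constants)
}
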