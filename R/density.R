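#' Discretized distribution of local proton concentration
#'
#' Represents p(C_H) on a regular concentration grid: non-negative weights
#' normalized so that sum(p) * Δc = 1.
#'
#' @param c_grid Strictly increasing, (near-)uniform concentration grid,
#'   mol/L, starting at a non-negative value.
#' @param p Non-negative weights per grid cell. Renormalized to unit mass
#'   unless `normalize = FALSE`, in which case unit mass is asserted.
#' @param normalize Logical, default `TRUE`.
#' @return An object of class `density_distribution`.
#' @export
density_distribution <- function(c_grid, p, normalize = TRUE) {
  c_grid <- as.numeric(c_grid); p <- as.numeric(p)
  if (length(c_grid) < 2L) stop("concentration grid needs at least two cells")
  if (length(c_grid) != length(p)) stop("c_grid and p must have equal length")
  if (c_grid[1] < 0 || any(diff(c_grid) <= 0)) {
    stop("c_grid must be strictly increasing and non-negative")
  }
  dc <- diff(c_grid)
  if (max(dc) - min(dc) > 1e-8 * mean(dc)) {
    stop("c_grid must be (near-)uniformly spaced")
  }
  dc <- mean(dc)
  if (any(!is.finite(p))) stop("p must be finite")
  if (any(p < -1e-12 * max(abs(p), 1))) stop("p must be non-negative")
  p <- pmax(p, 0)
  mass <- sum(p) * dc
  if (normalize) {
    if (mass <= 0) stop("p has zero mass")
    p <- p / mass
  } else if (abs(mass - 1) > 1e-9) {
    stop("p is not unit mass (sum(p)*dc = ", format(mass), ")")
  }
  structure(list(c_grid = c_grid, p = p, dc = dc),
            class = "density_distribution")
}

is_density <- function(x) inherits(x, "density_distribution")

#' @export
print.density_distribution <- function(x, ...) {
  cat(sprintf(
    "p(C_H) on [%g, %g] mol/L (step %g): mean %.3g mol/L, mode at %.3g mol/L\n",
    x$c_grid[1], x$c_grid[length(x$c_grid)], x$dc,
    density_mean(x), x$c_grid[which.max(x$p)]))
  invisible(x)
}

#' Mean concentration of a density distribution
#' @param d A [density_distribution].
#' @return Mean of C_H under p, mol/L.
#' @export
density_mean <- function(d) {
  stopifnot(is_density(d))
  sum(d$c_grid * d$p) * d$dc
}
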