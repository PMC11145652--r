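#' Fast non-negative least squares on normal equations
#'
#' Solves min ||Ax - b||^2 subject to x >= 0 given the cross products
#' AtA = A'A and Atb = A'b (Bro & De Jong's variant of Lawson-Hanson).
#' Working from the normal equations lets the regularized inversion reuse
#' one Gram matrix across many penalty weights.
#'
#' @param AtA Symmetric positive (semi-)definite Gram matrix.
#' @param Atb Right-hand side A'b.
#' @param tol Dual-feasibility tolerance; default scales with the problem.
#' @param max_iter Safety cap on outer iterations.
#' @return Non-negative solution vector.
#' @keywords internal
fnnls <- function(AtA, Atb, tol = NULL,
                  max_iter = 30L * length(Atb)) {
  n <- length(Atb)
  stopifnot(nrow(AtA) == n, ncol(AtA) == n)
  if (is.null(tol)) tol <- 1e-12 * max(abs(Atb), 1e-300)
  x <- numeric(n)
  passive <- logical(n)
  w <- Atb
  iter <- 0L
  solve_passive <- function(P) {
    M <- AtA[P, P, drop = FALSE]
    tryCatch(solve(M, Atb[P]),
             error = function(e) {
               # near-singular passive set: ridge-stabilized fallback
               solve(M + diag(1e-12 * max(diag(M)), nrow(M)), Atb[P])
             })
  }
  while (any(!passive) && max(w[!passive]) > tol) {
    iter <- iter + 1L
    if (iter > max_iter) stop("fnnls did not converge")
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- solve_passive(passive)
      if (all(s[passive] > 0)) {
        x <- s
        break
      }
      neg <- passive & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > .Machine$double.eps * max(x, 1)
      x[!passive] <- 0
      if (!any(passive)) {
        x <- numeric(n)
        break
      }
    }
    w <- Atb - drop(AtA %*% x)
  }
  x
}
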