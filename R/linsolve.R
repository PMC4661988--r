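# Krylov linear solvers.  The momentum and pressure systems are nonsymmetric
# (convection) M-matrices, solved with BiCGSTAB; the regularized normal
# equations are SPD and solved with preconditioned CG using operator products
# only (S^T S is never formed).

#' Solve a sparse linear system with BiCGSTAB
#'
#' Biconjugate-gradient-stabilized iteration with Jacobi (diagonal)
#' preconditioning and optional warm start.  Terminates when
#' `||S x - f|| <= lin_tol * ||f||`.
#'
#' @param S square sparse matrix (`dgCMatrix` or coercible).
#' @param f right-hand side vector.
#' @param lin_tol relative residual tolerance (default `1e-8`).
#' @param x0 optional initial guess (warm start); defaults to zeros.
#' @param maxit iteration cap (default `10 * length(f)`, at least 200).
#' @return the solution vector, with attribute `iterations`.
#' @export
solve_sparse <- function(S, f, lin_tol = 1e-8, x0 = NULL, maxit = NULL) {
  nr <- nrow(S)
  if (nr != ncol(S)) stop("S must be square", call. = FALSE)
  if (length(f) != nr) stop("length(f) != nrow(S)", call. = FALSE)
  if (anyNA(f) || any(!is.finite(f))) stop("non-finite right-hand side", call. = FALSE)
  fn <- sqrt(sum(f * f))
  if (fn == 0) return(structure(numeric(nr), iterations = 0L))
  d <- Matrix::diag(S)
  if (any(d == 0)) stop("singular input: zero diagonal entry", call. = FALSE)
  Minv <- 1 / d
  if (is.null(maxit)) maxit <- max(200L, 10L * nr)
  x <- if (is.null(x0)) numeric(nr) else as.numeric(x0)
  r <- f - as.numeric(S %*% x)
  tol_abs <- lin_tol * fn
  if (sqrt(sum(r * r)) <= tol_abs) return(structure(x, iterations = 0L))
  r0 <- r
  rho <- alpha <- omega <- 1
  vv <- p <- numeric(nr)
  for (it in seq_len(maxit)) {
    rho1 <- sum(r0 * r)
    if (rho1 == 0) break # breakdown
    if (it == 1L) {
      p <- r
    } else {
      beta <- (rho1 / rho) * (alpha / omega)
      p <- r + beta * (p - omega * vv)
    }
    rho <- rho1
    ph <- Minv * p
    vv <- as.numeric(S %*% ph)
    alpha <- rho / sum(r0 * vv)
    s <- r - alpha * vv
    if (sqrt(sum(s * s)) <= tol_abs) {
      x <- x + alpha * ph
      return(structure(x, iterations = it))
    }
    sh <- Minv * s
    t <- as.numeric(S %*% sh)
    tt <- sum(t * t)
    if (tt == 0) break
    omega <- sum(t * s) / tt
    x <- x + alpha * ph + omega * sh
    r <- s - omega * t
    if (sqrt(sum(r * r)) <= tol_abs)
      return(structure(x, iterations = it))
    if (omega == 0) break
  }
  res <- sqrt(sum((f - as.numeric(S %*% x))^2)) / fn
  stop(sprintf("BiCGSTAB did not converge: relative residual %.3e after %d iterations",
               res, maxit), call. = FALSE)
}

# Preconditioned conjugate gradients for an SPD operator given as a function.
# Used for the Tikhonov normal equations A(x) = S^T(S x) + lambda G^T(G x).
cg_operator <- function(apply_A, b, precond = NULL, tol = 1e-10, x0 = NULL,
                        maxit = NULL) {
  n <- length(b)
  bn <- sqrt(sum(b * b))
  if (bn == 0) return(structure(numeric(n), iterations = 0L))
  if (is.null(maxit)) maxit <- max(500L, 10L * n)
  if (is.null(precond)) precond <- function(r) r
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  r <- b - apply_A(x)
  tol_abs <- tol * bn
  if (sqrt(sum(r * r)) <= tol_abs) return(structure(x, iterations = 0L))
  z <- precond(r)
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- apply_A(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) <= tol_abs) return(structure(x, iterations = it))
    z <- precond(r)
    rz1 <- sum(r * z)
    p <- z + (rz1 / rz) * p
    rz <- rz1
  }
  warning(sprintf("CG reached iteration cap (%d); relative residual %.3e",
                  maxit, sqrt(sum(r * r)) / bn))
  structure(x, iterations = maxit)
}
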