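# PC-MRI blurring operator and generalized-Tikhonov momentum solves.
#
# A Cartesian (3DFT) acquisition has a separable sinc point-spread function
#   psi(x, y, z) = sinc(x/dx_mri) * sinc(y/dy_mri) * sinc(z/dz_mri),
# truncated to the box |x| <= 2 dx_mri (etc.).  The sparse operator Gamma
# samples this kernel on the CFD grid so that Gamma %*% v_cfd predicts the
# measured voxel values; each row is normalized to unit sum so constant
# velocity fields are fixed points (unit DC gain).  The regularized momentum
# solve returns the minimizer of
#   J(x) = 1/2 ||S x - f||^2 + lambda/2 ||G x - m||^2,
# i.e. the solution of (S^T S + lambda G^T G) x = S^T f + lambda G^T m,
# computed matrix-free with preconditioned CG.

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Truncated-sinc point-spread-function kernel
#'
#' Samples the separable sinc PSF of a 3DFT PC-MRI acquisition on CFD-grid
#' offsets, truncated to twice the MRI voxel size per axis.
#'
#' @param mri_spacing MRI voxel size, numeric 3-vector, meters.
#' @param cfd_spacing CFD grid spacing, numeric 3-vector, meters.
#' @return object of class `psf_kernel`: per-axis offset and weight vectors
#'   (unnormalized; value 1 at zero offset), plus the spacings.
#' @export
build_psf <- function(mri_spacing, cfd_spacing) {
  mri_spacing <- as.numeric(mri_spacing); cfd_spacing <- as.numeric(cfd_spacing)
  if (length(mri_spacing) != 3L || any(!is.finite(mri_spacing)) || any(mri_spacing <= 0))
    stop("`mri_spacing` must be 3 positive lengths", call. = FALSE)
  if (length(cfd_spacing) != 3L || any(!is.finite(cfd_spacing)) || any(cfd_spacing <= 0))
    stop("`cfd_spacing` must be 3 positive lengths", call. = FALSE)
  axes <- lapply(1:3, function(ax) {
    delta <- mri_spacing[ax]; h <- cfd_spacing[ax]
    nmax <- floor(2 * delta / h + 1e-9)
    off <- (-nmax:nmax) * h
    list(offsets = off, weights = sinc(off / delta))
  })
  structure(list(axes = axes, mri_spacing = mri_spacing,
                 cfd_spacing = cfd_spacing),
            class = "psf_kernel")
}

#' Evaluate the truncated PSF at arbitrary offsets
#'
#' @param psf a [build_psf()] kernel.
#' @param x,y,z offsets in meters (vectors recycled to a common length).
#' @return the separable kernel value `psi * B` (0 outside the box support).
#' @export
psf_value <- function(psf, x, y, z) {
  d <- psf$mri_spacing
  inside <- abs(x) <= 2 * d[1] & abs(y) <= 2 * d[2] & abs(z) <= 2 * d[3]
  v <- sinc(x / d[1]) * sinc(y / d[2]) * sinc(z / d[3])
  v[!inside] <- 0
  v
}

#' Build the MRI blurring/resampling operator
#'
#' Constructs the sparse `M x N` operator mapping cell-centered CFD
#' velocities (N = CFD cells) to MRI voxels (M = MRI voxels): each row holds
#' the truncated-sinc kernel centred on one MRI voxel, sampled at the CFD
#' cell centers and normalized to unit sum (rows near the volume edge are
#' renormalized over their clipped support).  With `identity = TRUE` and
#' coinciding grids the operator is the identity matrix, reproducing the
#' equal-resolution phantom configuration.
#'
#' @param psf a [build_psf()] kernel.
#' @param cfd_grid,mri_grid [grid_spec()]s; the MRI domain must be covered by
#'   the CFD domain.
#' @param identity request the identity special case (errors if the grids do
#'   not coincide).
#' @param lambda_u,lambda_v,lambda_w nonnegative per-component weights stored
#'   with the operator.
#' @return object of class `regularization_operator` with sparse `Gamma_u`,
#'   `Gamma_v`, `Gamma_w` (shared matrix), the weights, and `M`, `N`.
#' @export
build_gamma <- function(psf, cfd_grid, mri_grid, identity = FALSE,
                        lambda_u = 0, lambda_v = 0, lambda_w = 0) {
  if (any(c(lambda_u, lambda_v, lambda_w) < 0))
    stop("lambda weights must be nonnegative", call. = FALSE)
  N <- as.integer(cell_count(cfd_grid))
  M <- as.integer(cell_count(mri_grid))
  same <- identical(cfd_grid$n, mri_grid$n) &&
    isTRUE(all.equal(cfd_grid$spacing, mri_grid$spacing)) &&
    isTRUE(all.equal(cfd_grid$origin, mri_grid$origin))
  if (identity) {
    if (!same)
      stop("identity operator requested but CFD and MRI grids differ", call. = FALSE)
    G <- Matrix::Diagonal(N)
  } else {
    # separable 1-D weight matrices per axis, then the Kronecker product
    # (x fastest, so the z factor is outermost)
    w1 <- lapply(1:3, function(ax) {
      xc <- axis_centers(cfd_grid, ax)
      xm <- axis_centers(mri_grid, ax)
      if (min(xm) < min(xc) - 1e-9 || max(xm) > max(xc) + 1e-9)
        stop("MRI grid extends beyond the CFD domain", call. = FALSE)
      delta <- psf$mri_spacing[ax]
      off <- outer(xm, xc, "-")
      w <- sinc(off / delta)
      w[abs(off) > 2 * delta + 1e-12] <- 0
      Matrix::Matrix(w, sparse = TRUE)
    })
    G <- Matrix::kronecker(w1[[3]], Matrix::kronecker(w1[[2]], w1[[1]]))
    rs <- Matrix::rowSums(G)
    if (any(rs == 0)) stop("empty overlap: some MRI voxels see no CFD cell",
                           call. = FALSE)
    G <- Matrix::Diagonal(x = 1 / rs) %*% G
  }
  G <- methods::as(methods::as(G, "CsparseMatrix"), "generalMatrix")
  structure(list(Gamma_u = G, Gamma_v = G, Gamma_w = G,
                 lambda_u = lambda_u, lambda_v = lambda_v, lambda_w = lambda_w,
                 M = M, N = N),
            class = "regularization_operator")
}

#' @export
print.regularization_operator <- function(x, ...) {
  cat(sprintf("<regularization_operator> %d x %d, %d nonzeros, lambda = (%g, %g, %g)\n",
              x$M, x$N, length(x$Gamma_u@x),
              x$lambda_u, x$lambda_v, x$lambda_w))
  invisible(x)
}

#' Tikhonov-regularized momentum solve
#'
#' Returns the minimizer of
#' `1/2 ||S x - f||^2 + lambda/2 ||G x - m||^2`, computed by solving the
#' normal equations `(S'S + lambda G'G) x = S'f + lambda G'm` with
#' preconditioned conjugate gradients using only operator products (the
#' normal matrix is never formed).  With `lambda = 0` this reduces exactly to
#' [solve_sparse()] on `S x = f`.
#'
#' @param S sparse momentum matrix over the free unknowns.
#' @param f momentum right-hand side.
#' @param G sparse penalty operator mapping unknowns to measured voxels
#'   (typically the MRI blur composed with face-to-center averaging).
#' @param lambda nonnegative weight.
#' @param m measured values (same length as `nrow(G)`).
#' @param lin_tol relative tolerance (the normal equations are solved to
#'   `min(lin_tol, 1e-10)` on the normal-residual scale).
#' @param x0 warm start.
#' @param Gt,gdiag optional precomputed `t(G)` and `colSums(G^2)`.
#' @return solution vector with attribute `iterations`.
#' @export
regularized_solve <- function(S, f, G, lambda, m, lin_tol = 1e-8, x0 = NULL,
                              Gt = NULL, gdiag = NULL) {
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  if (lambda == 0) return(solve_sparse(S, f, lin_tol = lin_tol, x0 = x0))
  if (nrow(G) != length(m)) stop("length(m) != nrow(G)", call. = FALSE)
  if (ncol(G) != ncol(S)) stop("G and S disagree on the number of unknowns",
                               call. = FALSE)
  St <- Matrix::t(S)
  if (is.null(Gt)) Gt <- Matrix::t(G)
  b <- as.numeric(St %*% f) + lambda * as.numeric(Gt %*% m)
  sd2 <- Matrix::colSums(S * S)
  if (is.null(gdiag)) gdiag <- Matrix::colSums(G * G)
  dprec <- sd2 + lambda * gdiag
  dprec[dprec == 0] <- 1
  apply_A <- function(x)
    as.numeric(St %*% (S %*% x)) + lambda * as.numeric(Gt %*% (G %*% x))
  # the normal equations square the conditioning, so drive the residual much
  # further down than the requested solution accuracy
  tol <- min(lin_tol * 1e-4, 1e-12)
  cg_operator(apply_A, b, precond = function(r) r / dprec, tol = tol, x0 = x0)
}

#' Tikhonov objective value
#'
#' `1/2 ||S x - f||^2 + lambda/2 ||G x - m||^2`; exposed for optimality
#' diagnostics.
#' @inheritParams regularized_solve
#' @param x candidate solution.
#' @return scalar objective value.
#' @export
tikhonov_objective <- function(x, S, f, G, lambda, m) {
  r1 <- as.numeric(S %*% x) - f
  r2 <- as.numeric(G %*% x) - m
  0.5 * sum(r1^2) + 0.5 * lambda * sum(r2^2)
}

#' Attach MRI measurements to a solver run
#'
#' Bundles the blurring operator (with its per-component weights), the
#' stacked measurement vectors, and optional per-component row masks
#' (measured-voxel subsets; unmeasured rows are omitted, so M < N scan-time
#' reduction scenarios are expressed by masking).
#'
#' @param operator a [build_gamma()] operator carrying the lambda weights.
#' @param meas an [mri_measurement()].
#' @param rows optional list with logical/integer index vectors `u`, `v`, `w`
#'   selecting the measured rows (e.g. lumen voxels); `NULL` keeps all rows.
#' @return a regularization spec for [run_steady_state()].
#' @export
attach_measurement <- function(operator, meas, rows = NULL) {
  stopifnot(inherits(operator, "regularization_operator"))
  m <- list(u = as.numeric(meas$u), v = as.numeric(meas$v), w = as.numeric(meas$w))
  if (length(m$u) != operator$M)
    stop("measurement size does not match the operator's M", call. = FALSE)
  list(operator = operator, m = m,
       rows = if (is.null(rows)) list(u = NULL, v = NULL, w = NULL) else rows)
}

#' Export / import a sparse operator in MatrixMarket format
#'
#' Coordinate-format interchange for inspection and cross-implementation
#' comparison of the blurring operator.
#'
#' @param G sparse matrix (for writing).
#' @param path file path (`.mtx`).
#' @return `read_operator_mtx` returns a `dgCMatrix`.
#' @export
write_operator_mtx <- function(G, path) {
  Matrix::writeMM(methods::as(methods::as(G, "CsparseMatrix"), "generalMatrix"),
                  path)
  invisible(path)
}

#' @rdname write_operator_mtx
#' @export
read_operator_mtx <- function(path) {
  methods::as(methods::as(Matrix::readMM(path), "CsparseMatrix"), "generalMatrix")
}
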