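# Shared fixtures, built in code at test time.

tiny_grid <- function(n = c(4, 4, 6), h = c(1e-3, 1e-3, 1e-3))
  grid_spec(n, h)

# fully open rectangular duct mask: all FLUID except inlet/outlet layers
duct_mask <- function(grid) {
  n <- grid$n
  labels <- array(MASK_WALL, n)
  labels[2:(n[1] - 1), 2:(n[2] - 1), ] <- MASK_FLUID
  labels[2:(n[1] - 1), 2:(n[2] - 1), 1] <- MASK_INLET
  labels[2:(n[1] - 1), 2:(n[2] - 1), n[3]] <- MASK_OUTLET
  lumen_mask(labels, grid)
}

# random staggered field with a fixed seed
random_field <- function(grid, seed = 1, scale = 0.1) {
  set.seed(seed)
  staggered_field(grid,
    u = array(rnorm(prod(face_dim_t(grid, "u")), 0, scale), face_dim_t(grid, "u")),
    v = array(rnorm(prod(face_dim_t(grid, "v")), 0, scale), face_dim_t(grid, "v")),
    w = array(rnorm(prod(face_dim_t(grid, "w")), 0, scale), face_dim_t(grid, "w")))
}

face_dim_t <- function(grid, comp) {
  d <- grid$n
  i <- match(comp, c("u", "v", "w"))
  d[i] <- d[i] + 1L
  d
}

# diagonally dominant random sparse system (the class the momentum matrices
# belong to: positive diagonal, bounded off-diagonal mass)
random_dd_system <- function(n, density = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- Matrix::rsparsematrix(n, n, density = density)
  S <- A + Matrix::Diagonal(n, x = Matrix::rowSums(abs(A)) + runif(n, 0.5, 2))
  methods::as(methods::as(S, "CsparseMatrix"), "generalMatrix")
}

random_sparse_general <- function(m, n, density = 0.2) {
  methods::as(methods::as(Matrix::rsparsematrix(m, n, density = density),
                          "CsparseMatrix"), "generalMatrix")
}
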