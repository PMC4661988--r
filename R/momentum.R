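# Finite-volume momentum assembly on the staggered control volume, using
# Patankar's power-law convection-diffusion scheme:
#   a_nb = D * max(0, (1 - 0.1 |P|)^5) + max(-+F, 0),      P = F / D,
# with D the diffusive conductance mu*A/delta and F the mass flow rate rho*U*A
# through the control-volume face.  The pseudo-transient term rho*dV/dt enters
# the diagonal and (with the previous pseudo-time-step velocity) the source.
# Under-relaxation follows the standard Patankar form a_P/alpha with the
# deferred part added to the source.

DIR_TABLE <- list(
  E = c(1L,  1L), W = c(1L, -1L),
  N = c(2L,  1L), S = c(2L, -1L),
  T = c(3L,  1L), B = c(3L, -1L)
)

# Static (per run) assembly structure for one velocity component: free faces,
# neighbour indexing per direction, conductance geometry factors (with the
# half-distance doubling at wall-ghost links), advecting-velocity index pairs,
# and the two pressure cells flanking each face.
momentum_structure <- function(comp, grid, mask) {
  comp <- match.arg(comp, c("u", "v", "w"))
  ax <- match(comp, c("u", "v", "w"))
  n <- grid$n
  h <- grid$spacing
  fd <- face_dim(grid, comp)
  free <- free_faces(mask, comp)
  idx <- which(free)
  nfree <- length(idx)
  map <- integer(prod(fd)); map[idx] <- seq_len(nfree)
  ijk <- arrayInd(idx, fd)
  wall <- unclass(mask) == MASK_WALL

  off_own <- c(1L, fd[1], fd[1] * fd[2])               # own face array strides
  area <- c(h[2] * h[3], h[1] * h[3], h[1] * h[2])     # CV face areas per axis
  Gfac <- area / h                                      # A/delta per axis
  dV <- prod(h)

  # strides of the three face arrays and the cell array
  fdims <- lapply(c("u", "v", "w"), function(cc) face_dim(grid, cc))
  names(fdims) <- c("u", "v", "w")
  lin3 <- function(i, j, k, d) (k - 1L) * (d[1] * d[2]) + (j - 1L) * d[1] + i
  cell_lin <- function(i, j, k) (k - 1L) * (n[1] * n[2]) + (j - 1L) * n[1] + i

  # cells flanking each free face along the component axis
  i <- ijk[, 1]; j <- ijk[, 2]; k <- ijk[, 3]
  if (comp == "u") {
    cell_lo <- cell_lin(i - 1L, j, k); cell_hi <- cell_lin(i, j, k)
  } else if (comp == "v") {
    cell_lo <- cell_lin(i, j - 1L, k); cell_hi <- cell_lin(i, j, k)
  } else {
    cell_lo <- cell_lin(i, j, k - 1L); cell_hi <- cell_lin(i, j, k)
  }

  # advecting-velocity sample indices for the CV face in direction (axis, s):
  # inline -> mean of own faces (idx, neighbour); transverse -> mean of the
  # two faces of the cross component bounding the CV face.
  dirs <- vector("list", 6L)
  names(dirs) <- names(DIR_TABLE)
  for (dn in names(DIR_TABLE)) {
    axis <- DIR_TABLE[[dn]][1]; s <- DIR_TABLE[[dn]][2]
    d <- list(axis = axis, s = s)
    # neighbour face of the same component
    co <- ijk[, axis] + s
    d$in_arr <- co >= 1L & co <= fd[axis]
    nb <- idx + s * off_own[axis]
    nb[!d$in_arr] <- NA_integer_
    d$nb <- nb
    col <- integer(nfree)
    col[d$in_arr] <- map[nb[d$in_arr]]
    d$col <- col
    # wall-ghost: both cells adjacent to the neighbour face are WALL
    ghost <- rep(FALSE, nfree)
    if (axis != ax) {
      ii <- i; jj <- j; kk <- k
      if (axis == 1L) ii <- ii + s else if (axis == 2L) jj <- jj + s else kk <- kk + s
      ok <- d$in_arr
      if (comp == "u") {
        c1 <- cell_lin(pmax(ii - 1L, 1L), jj, kk); c2 <- cell_lin(pmin(ii, n[1]), jj, kk)
      } else if (comp == "v") {
        c1 <- cell_lin(ii, pmax(jj - 1L, 1L), kk); c2 <- cell_lin(ii, pmin(jj, n[2]), kk)
      } else {
        c1 <- cell_lin(ii, jj, pmax(kk - 1L, 1L)); c2 <- cell_lin(ii, jj, pmin(kk, n[3]))
      }
      ghost[ok] <- wall[c1[ok]] & wall[c2[ok]]
    }
    d$Gfac <- ifelse(ghost, 2, 1) * Gfac[axis]
    d$Gfac[!d$in_arr] <- 0
    d$area <- area[axis]

    # advecting velocity at the CV face (mean of two samples)
    if (axis == ax) {
      # CV face centred on the lo/hi cell: mean of own faces idx and nb
      d$adv_arr <- comp
      d$adv1 <- idx
      d$adv2 <- nb
    } else {
      cross <- c("u", "v", "w")[axis]
      cd <- fdims[[cross]]
      # face index of the cross component on the +s (or -s) side of the CV
      # CV spans cells cell_lo .. cell_hi along comp axis; the cross face sits
      # at cross-axis index (axis coord + (s>0)), for both flanking cells.
      ii1 <- i; jj1 <- j; kk1 <- k        # cross-face of the lo cell
      ii2 <- i; jj2 <- j; kk2 <- k        # cross-face of the hi cell
      if (comp == "u") { ii1 <- ii1 - 1L } else if (comp == "v") { jj1 <- jj1 - 1L } else kk1 <- kk1 - 1L
      bump <- as.integer(s > 0)
      if (axis == 1L) { ii1 <- ii1 + bump; ii2 <- ii2 + bump }
      if (axis == 2L) { jj1 <- jj1 + bump; jj2 <- jj2 + bump }
      if (axis == 3L) { kk1 <- kk1 + bump; kk2 <- kk2 + bump }
      d$adv_arr <- cross
      d$adv1 <- lin3(ii1, jj1, kk1, cd)
      d$adv2 <- lin3(ii2, jj2, kk2, cd)
    }
    dirs[[dn]] <- d
  }

  list(comp = comp, ax = ax, fd = fd, free = free, idx = idx, nfree = nfree,
       map = map, dirs = dirs, area_inline = area[ax], dV = dV,
       cell_lo = cell_lo, cell_hi = cell_hi)
}

power_law <- function(P) {
  a <- 1 - 0.1 * abs(P)
  a[a < 0] <- 0
  a * a * a * a * a
}

# Assemble one component's momentum system from the current state.
# Returns coefficients and the sparse matrix over free faces; the right-hand
# side excludes the pressure term (added by momentum_rhs) so the same
# coefficients serve the pseudo-velocity, momentum and correction stages.
assemble_component <- function(st, state, state_old, props, grid, cfg) {
  comp <- st$comp
  nfree <- st$nfree
  rho <- props$rho; mu <- props$mu
  ucur <- state[[comp]][st$idx]
  uold <- state_old[[comp]][st$idx]
  aP0 <- if (is.finite(cfg$dt)) rho * st$dV / cfg$dt else 0

  aP <- rep(aP0, nfree)
  b_fix <- numeric(nfree)
  sum_anb_u <- numeric(nfree)
  ti <- tj <- tx <- vector("list", 6L)
  coef <- vector("list", 6L); names(coef) <- names(st$dirs)

  for (dn in names(st$dirs)) {
    d <- st$dirs[[dn]]
    ok <- d$in_arr
    a <- numeric(nfree)
    if (any(ok)) {
      arr <- state[[d$adv_arr]]
      Uf <- 0.5 * (arr[d$adv1[ok]] + arr[d$adv2[ok]])
      FF <- rho * Uf * d$area
      D <- mu * d$Gfac[ok]
      a_ok <- D * power_law(FF / D) + pmax(if (d$s > 0) -FF else FF, 0)
      a[ok] <- a_ok
      aP[ok] <- aP[ok] + a_ok
      nbv <- state[[comp]][d$nb[ok]]
      sum_anb_u[ok] <- sum_anb_u[ok] + a_ok * nbv
      fixed_nb <- d$col[ok] == 0L
      if (any(fixed_nb)) {
        bf <- numeric(sum(ok))
        bf[fixed_nb] <- a_ok[fixed_nb] * nbv[fixed_nb]
        b_fix[ok] <- b_fix[ok] + bf
      }
    }
    coef[[dn]] <- a
  }

  alpha <- cfg$relax_u
  aPr <- aP / alpha
  defer <- (1 - alpha) * aPr * ucur
  b0 <- aP0 * uold + b_fix + defer
  hat <- (sum_anb_u + aP0 * uold + defer) / aPr
  dcoef <- st$area_inline / aPr

  # sparse system over free faces
  rows <- seq_len(nfree)
  ti_all <- rows; tj_all <- rows; tx_all <- aPr
  for (dn in names(st$dirs)) {
    d <- st$dirs[[dn]]
    sel <- d$in_arr & d$col > 0L
    if (any(sel)) {
      ti_all <- c(ti_all, rows[sel])
      tj_all <- c(tj_all, d$col[sel])
      tx_all <- c(tx_all, -coef[[dn]][sel])
    }
  }
  S <- Matrix::sparseMatrix(i = ti_all, j = tj_all, x = tx_all,
                            dims = c(nfree, nfree))

  list(comp = comp, S = S, b0 = b0, hat = hat, d = dcoef, aPr = aPr,
       struct = st)
}

# add the pressure-difference source to the momentum RHS
momentum_rhs <- function(sys, pressure) {
  st <- sys$struct
  sys$b0 + (pressure[st$cell_lo] - pressure[st$cell_hi]) * st$area_inline
}

#' Assemble a discrete momentum system
#'
#' Builds the sparse convection-diffusion system `S x = f` for one velocity
#' component on its staggered control volumes, from the current velocity field
#' (advecting flow and deferred under-relaxation source), the previous
#' pseudo-time-step field (transient source), and the current pressure.
#' Rows/columns run over the component's free faces in linear (x-fastest)
#' order, so the pattern is hepta-diagonal: the diagonal is positive and the
#' at-most six off-diagonals are nonpositive.
#'
#' @param comp `"u"`, `"v"` or `"w"`.
#' @param state current [staggered_field()] with boundary values enforced.
#' @param pressure cell-centered pressure array (Pa), dim `grid$n`.
#' @param props a [fluid_properties()].
#' @param grid a [grid_spec()].
#' @param mask a [lumen_mask()].
#' @param cfg a [solver_config()].
#' @param state_old field at the previous pseudo-time step (defaults to
#'   `state`).
#' @return list of class `momentum_system`: sparse `S`, right-hand side `f`,
#'   component tag, free-face indices `free_idx`, and the per-face coefficient
#'   fields used by the pressure equations (`d`, `hat`).
#' @export
assemble_momentum <- function(comp, state, pressure, props, grid, mask, cfg,
                              state_old = state) {
  if (anyNA(state$u) || anyNA(state$v) || anyNA(state$w) ||
      !all(is.finite(state$u), is.finite(state$v), is.finite(state$w)))
    stop("state contains non-finite velocities", call. = FALSE)
  st <- momentum_structure(comp, grid, mask)
  sys <- assemble_component(st, state, state_old, props, grid, cfg)
  structure(list(comp = comp, S = sys$S, f = momentum_rhs(sys, pressure),
                 free_idx = st$idx, d = sys$d, hat = sys$hat,
                 struct = st, b0 = sys$b0),
            class = "momentum_system")
}
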