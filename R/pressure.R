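# Pressure and pressure-correction equations.
#
# Substituting the momentum-derived face velocities u = u_hat + d*(p_P - p_nb)
# into the discrete continuity equation yields a Poisson-type system on the
# FLUID pressure cells with coefficients a_nb = rho * A * d at free faces and
# zero (homogeneous Neumann) at prescribed-velocity faces; in the limit of a
# dominant transient term (d ~ dt / (rho*h)) this is the classical
# discretization of  lap(p) = (1/dt) div(v).  The same system, driven by the
# starred-velocity mass imbalance, is the pressure-correction equation.  The
# all-Neumann nullspace is fixed by pinning the first FLUID cell to zero.

pressure_structure <- function(grid, mask) {
  n <- grid$n
  h <- grid$spacing
  m <- unclass(mask)
  pcells <- which(m == MASK_FLUID)
  nP <- length(pcells)
  if (nP == 0L) stop("no FLUID cells in the mask", call. = FALSE)
  pmap <- integer(prod(n)); pmap[pcells] <- seq_len(nP)
  ijk <- arrayInd(pcells, n)
  i <- ijk[, 1]; j <- ijk[, 2]; k <- ijk[, 3]
  area <- c(h[2] * h[3], h[1] * h[3], h[1] * h[2])

  fdu <- c(n[1] + 1L, n[2], n[3])
  fdv <- c(n[1], n[2] + 1L, n[3])
  fdw <- c(n[1], n[2], n[3] + 1L)
  linu <- function(a, b, c) (c - 1L) * (fdu[1] * fdu[2]) + (b - 1L) * fdu[1] + a
  linv <- function(a, b, c) (c - 1L) * (fdv[1] * fdv[2]) + (b - 1L) * fdv[1] + a
  linw <- function(a, b, c) (c - 1L) * (fdw[1] * fdw[2]) + (b - 1L) * fdw[1] + a
  cell <- function(a, b, c) (c - 1L) * (n[1] * n[2]) + (b - 1L) * n[1] + a

  # per direction: bounding face index, face component, neighbour cell column
  mk <- function(comp, face_lin, nb_ok, nb_lin, axis) {
    col <- integer(nP)
    col[nb_ok] <- pmap[nb_lin[nb_ok]]
    list(comp = comp, face = face_lin, col = col, area = area[axis])
  }
  dirs <- list(
    E = mk("u", linu(i + 1L, j, k), i < n[1], cell(pmin(i + 1L, n[1]), j, k), 1L),
    W = mk("u", linu(i, j, k),      i > 1L,   cell(pmax(i - 1L, 1L), j, k), 1L),
    N = mk("v", linv(i, j + 1L, k), j < n[2], cell(i, pmin(j + 1L, n[2]), k), 2L),
    S = mk("v", linv(i, j, k),      j > 1L,   cell(i, pmax(j - 1L, 1L), k), 2L),
    T = mk("w", linw(i, j, k + 1L), k < n[3], cell(i, j, pmin(k + 1L, n[3])), 3L),
    B = mk("w", linw(i, j, k),      k > 1L,   cell(i, j, pmax(k - 1L, 1L)), 3L)
  )
  list(pcells = pcells, nP = nP, pmap = pmap, dirs = dirs, pin = 1L)
}

# Assemble and solve the pressure (or correction) system.
# d_fields: per-component full face arrays of d = A/a_P (0 at fixed faces).
# vel: per-component full face arrays of the driving velocities (pseudo or
# starred, with boundary values at fixed faces).
solve_pressure_system <- function(ps, d_fields, vel, props, grid, lin_tol,
                                  x0 = NULL) {
  rho <- props$rho
  nP <- ps$nP
  rows <- seq_len(nP)
  aP <- numeric(nP)
  b <- numeric(nP)
  ti <- rows; tj <- rows  # diagonal placeholder, values appended last
  oi <- list(); oj <- list(); ox <- list()
  for (dn in names(ps$dirs)) {
    d <- ps$dirs[[dn]]
    dval <- d_fields[[d$comp]][d$face]
    a <- rho * d$area * dval            # 0 at fixed faces by construction
    aP <- aP + a
    sgn <- if (dn %in% c("E", "N", "T")) -1 else 1
    b <- b + sgn * rho * d$area * vel[[d$comp]][d$face]
    sel <- d$col > 0L & a != 0
    if (any(sel)) {
      oi[[dn]] <- rows[sel]; oj[[dn]] <- d$col[sel]; ox[[dn]] <- -a[sel]
    }
  }
  # pin the reference cell: identity row
  pin <- ps$pin
  b[pin] <- 0
  i_all <- c(rows, unlist(oi)); j_all <- c(rows, unlist(oj))
  x_all <- c(aP, unlist(ox))
  drop_pin <- i_all == pin & j_all != pin
  i_all <- i_all[!drop_pin]; j_all <- j_all[!drop_pin]; x_all <- x_all[!drop_pin]
  x_all[i_all == pin & j_all == pin] <- max(aP[-pin], 1)
  S <- Matrix::sparseMatrix(i = i_all, j = j_all, x = x_all, dims = c(nP, nP))
  solve_sparse(S, b, lin_tol = lin_tol, x0 = x0)
}

#' Solve the discrete pressure equation
#'
#' Runs one SIMPLER pressure solve on the FLUID cells of the mask: assembles
#' momentum coefficients from `state`, forms the pressure (mode
#' `"pressure"`, driven by pseudo-velocities) or pressure-correction system
#' (mode `"correction"`, driven by the given starred field), and returns the
#' cell-centered solution with the reference cell pinned to zero.
#'
#' @param state a [staggered_field()] with boundary values enforced.
#' @param props a [fluid_properties()].
#' @param grid a [grid_spec()].
#' @param mask a [lumen_mask()].
#' @param cfg a [solver_config()].
#' @param mode `"pressure"` or `"correction"`.
#' @return cell-centered array (dim `grid$n`), zero outside FLUID cells.
#' @export
solve_pressure <- function(state, props, grid, mask, cfg,
                           mode = c("pressure", "correction")) {
  mode <- match.arg(mode)
  ps <- pressure_structure(grid, mask)
  d_fields <- list(); vel <- list()
  for (comp in c("u", "v", "w")) {
    st <- momentum_structure(comp, grid, mask)
    sys <- assemble_component(st, state, state, props, grid, cfg)
    dfull <- array(0, st$fd); dfull[st$idx] <- sys$d
    d_fields[[comp]] <- dfull
    if (mode == "pressure") {
      vfull <- state[[comp]]            # fixed faces keep their BC values
      vfull[st$idx] <- sys$hat
      vel[[comp]] <- vfull
    } else {
      vel[[comp]] <- state[[comp]]
    }
  }
  sol <- solve_pressure_system(ps, d_fields, vel, props, grid, cfg$lin_tol)
  p <- array(0, grid$n)
  p[ps$pcells] <- sol
  p
}
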