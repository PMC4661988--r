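# The SIMPLER pressure-velocity coupling and the pseudo-transient outer loop.
#
# One SIMPLER pass:
#   1. momentum coefficients from the current field; pseudo-velocities
#      u_hat = (sum a_nb u_nb + b) / a_P  (no pressure term);
#   2. pressure equation driven by the pseudo-velocities;
#   3. momentum solves with that pressure -> starred velocities (replaced by
#      the Tikhonov-regularized solves when MRI data are attached);
#   4. pressure-correction equation driven by the starred mass imbalance;
#   5. velocity correction u = u* + d*(p'_P - p'_nb)  (pressure not corrected).
# Each pseudo-time step runs SIMPLER passes until max |div v| <= div_tol over
# FLUID cells, then advances; the run stops when the steady-state rate
# ||v(t+dt) - v(t)|| / dt  (RMS over solver unknowns) drops below eps.

#' Solver configuration
#'
#' @param dt pseudo-time step, s.  Acts as the implicit-relaxation scale of
#'   the pseudo-transient continuation; `Inf` removes the transient term.
#' @param eps steady-state tolerance on the velocity rate of change,
#'   (m/s)/s, RMS over solver unknowns.
#' @param div_tol continuity tolerance, 1/s (max-norm over FLUID cells).
#' @param max_outer cap on pseudo-time steps.
#' @param max_inner cap on SIMPLER passes per pseudo-time step.
#' @param lin_tol relative tolerance of the inner linear solves.
#' @param relax_u momentum under-relaxation factor in (0, 1].
#' @param relax_p pressure update blending factor in (0, 1].
#' @return object of class `solver_config`.
#' @export
solver_config <- function(dt = 1e-3, eps = 1e-3, div_tol = 1e-4,
                          max_outer = 500L, max_inner = 30L, lin_tol = 1e-8,
                          relax_u = 0.7, relax_p = 0.3) {
  stopifnot(dt > 0, eps > 0, div_tol > 0, lin_tol > 0,
            relax_u > 0, relax_u <= 1, relax_p > 0, relax_p <= 1,
            max_outer >= 1, max_inner >= 1)
  structure(list(dt = dt, eps = eps, div_tol = div_tol,
                 max_outer = as.integer(max_outer),
                 max_inner = as.integer(max_inner),
                 lin_tol = lin_tol, relax_u = relax_u, relax_p = relax_p),
            class = "solver_config")
}

# Precompute everything that does not change between iterations: assembly
# structures, the pressure stencil, and (if regularizing) the per-component
# penalty operators restricted to free faces.
prepare_problem <- function(grid, mask, props, cfg, reg = NULL, bc = NULL) {
  structs <- lapply(c(u = "u", v = "v", w = "w"),
                    momentum_structure, grid = grid, mask = mask)
  ps <- pressure_structure(grid, mask)
  pen <- NULL
  if (!is.null(reg)) {
    pen <- list()
    for (comp in c("u", "v", "w")) {
      lam <- reg$operator[[paste0("lambda_", comp)]]
      if (lam <= 0) { pen[[comp]] <- NULL; next }
      G <- reg$operator[[paste0("Gamma_", comp)]]
      rows_keep <- reg$rows[[comp]]
      if (!is.null(rows_keep)) G <- G[rows_keep, , drop = FALSE]
      A <- face_average_operator(grid, comp)
      Gfull <- G %*% A
      st <- structs[[comp]]
      free_idx <- st$idx
      Gf <- Gfull[, free_idx, drop = FALSE]
      m <- reg$m[[comp]]
      if (!is.null(rows_keep)) m <- m[rows_keep]
      # fixed-face contribution: constant during the run (BC values static)
      fixed_idx <- setdiff(seq_len(prod(st$fd)), free_idx)
      vfix <- if (is.null(bc)) numeric(length(fixed_idx)) else bc[[comp]][fixed_idx]
      m_eff <- m - as.numeric(Gfull[, fixed_idx, drop = FALSE] %*% vfix)
      pen[[comp]] <- list(lambda = lam, G = Gf, m = m_eff,
                          Gt = Matrix::t(Gf),
                          gd = Matrix::colSums(Gf * Gf))
    }
  }
  list(structs = structs, ps = ps, pen = pen)
}

#' One SIMPLER pass
#'
#' Runs a single pressure-velocity coupling pass (pseudo-velocities, pressure,
#' momentum, pressure correction, velocity correction) and returns the updated
#' field, pressure and the max-norm continuity residual over FLUID cells.
#' When `reg` is supplied, the momentum solves become Tikhonov-regularized
#' solves against the attached MRI data (see [regularized_solve()]).
#'
#' @param state a [staggered_field()] with boundary values enforced.
#' @param pressure cell-centered pressure array.
#' @param props,grid,mask,cfg see [solver_config()] and companions.
#' @param reg optional regularization spec from [attach_measurement()].
#' @param state_old field at the previous pseudo-time step (transient source);
#'   defaults to `state`.
#' @param prep internal cache from repeated calls; recomputed when `NULL`.
#' @return list with `state`, `pressure`, `div_max`, and linear-solve
#'   iteration counts.
#' @export
simpler_iteration <- function(state, pressure, props, grid, mask, cfg,
                              reg = NULL, state_old = state, prep = NULL) {
  if (is.null(prep)) prep <- prepare_problem(grid, mask, props, cfg, reg,
                                             bc = NULL)
  lin_iters <- 0L

  sys <- lapply(prep$structs, assemble_component, state = state,
                state_old = state_old, props = props, grid = grid, cfg = cfg)

  # stage 1-2: pseudo-velocities -> pressure equation
  d_fields <- list(); vel <- list()
  for (comp in c("u", "v", "w")) {
    st <- prep$structs[[comp]]
    dfull <- array(0, st$fd); dfull[st$idx] <- sys[[comp]]$d
    d_fields[[comp]] <- dfull
    vfull <- state[[comp]]; vfull[st$idx] <- sys[[comp]]$hat
    vel[[comp]] <- vfull
  }
  p_old_vec <- pressure[prep$ps$pcells]
  p_new <- solve_pressure_system(prep$ps, d_fields, vel, props, grid,
                                 cfg$lin_tol, x0 = p_old_vec)
  lin_iters <- lin_iters + attr(p_new, "iterations")
  p_vec <- p_old_vec + cfg$relax_p * (as.numeric(p_new) - p_old_vec)
  pressure[prep$ps$pcells] <- p_vec

  # stage 3: momentum solves (plain or regularized)
  for (comp in c("u", "v", "w")) {
    st <- prep$structs[[comp]]
    f <- momentum_rhs(sys[[comp]], pressure)
    x0 <- state[[comp]][st$idx]
    pen <- prep$pen[[comp]]
    x <- if (is.null(pen)) {
      solve_sparse(sys[[comp]]$S, f, lin_tol = cfg$lin_tol, x0 = x0)
    } else {
      regularized_solve(sys[[comp]]$S, f, pen$G, pen$lambda, pen$m,
                        lin_tol = cfg$lin_tol, x0 = x0, Gt = pen$Gt,
                        gdiag = pen$gd)
    }
    lin_iters <- lin_iters + attr(x, "iterations")
    state[[comp]][st$idx] <- as.numeric(x)
  }

  # stage 4: pressure correction from the starred field
  for (comp in c("u", "v", "w")) vel[[comp]] <- state[[comp]]
  pc <- solve_pressure_system(prep$ps, d_fields, vel, props, grid, cfg$lin_tol)
  lin_iters <- lin_iters + attr(pc, "iterations")
  pcorr <- array(0, grid$n)
  pcorr[prep$ps$pcells] <- as.numeric(pc)

  # stage 5: velocity correction (restores discrete continuity)
  for (comp in c("u", "v", "w")) {
    st <- prep$structs[[comp]]
    state[[comp]][st$idx] <- state[[comp]][st$idx] +
      sys[[comp]]$d * (pcorr[st$cell_lo] - pcorr[st$cell_hi])
  }

  div <- divergence(state, grid)
  div_max <- max(abs(div[unclass(mask) == MASK_FLUID]))
  list(state = state, pressure = pressure, div_max = div_max,
       lin_iters = lin_iters)
}

#' Run the solver to a steady state
#'
#' Pseudo-transient continuation: each pseudo-time step runs SIMPLER passes
#' until the continuity residual drops below `cfg$div_tol`, then the step is
#' accepted and the steady-state criterion `||v(t+dt) - v(t)|| / dt < eps`
#' (RMS over solver unknowns) is tested.  With `reg`, every momentum solve is
#' the regularized fusion of flow physics and MRI data, so the converged field
#' is the divergence-free flow closest (in the weighted least-squares sense)
#' to the measurements.
#'
#' @param state initial [staggered_field()] (an inlet-matched plug profile is
#'   a good default, see [initial_plug_field()]); boundary values are enforced
#'   from `bc` before the run.
#' @param bc a [flow_bc()] with inlet/outlet (and any lid) values.
#' @param props,grid,mask,cfg see companions.
#' @param reg optional regularization spec from [attach_measurement()].
#' @param pressure0 optional initial pressure field (e.g. from a previous
#'   [run_steady_state()] result, so a converged state restarts as a fixed
#'   point); defaults to zero.
#' @param verbose print per-step residuals.
#' @return object of class `solver_result`: final `state` and `pressure`,
#'   `outer_steps`, `inner_iterations` (per step), `rate_history` (the
#'   steady-state criterion), `div_history`, and `converged` flag.
#' @export
run_steady_state <- function(state, bc, props, grid, mask, cfg, reg = NULL,
                             pressure0 = NULL, verbose = FALSE) {
  state <- enforce_bc(state, mask, bc)
  prep <- prepare_problem(grid, mask, props, cfg, reg, bc = bc)
  pressure <- if (is.null(pressure0)) array(0, grid$n) else pressure0
  nfree <- sum(vapply(prep$structs, function(s) s$nfree, numeric(1)))
  rate_hist <- numeric(0)
  div_hist <- numeric(0)
  inner_hist <- integer(0)
  converged <- FALSE
  for (step in seq_len(cfg$max_outer)) {
    state_old <- state
    div_max <- Inf
    inner <- 0L
    while (inner < cfg$max_inner) {
      inner <- inner + 1L
      it <- simpler_iteration(state, pressure, props, grid, mask, cfg,
                              reg = reg, state_old = state_old, prep = prep)
      state <- it$state
      pressure <- it$pressure
      div_max <- it$div_max
      if (div_max <= cfg$div_tol) break
    }
    d2 <- sum((state$u - state_old$u)^2) + sum((state$v - state_old$v)^2) +
      sum((state$w - state_old$w)^2)
    rate <- sqrt(d2 / nfree) / cfg$dt
    rate_hist <- c(rate_hist, rate)
    div_hist <- c(div_hist, div_max)
    inner_hist <- c(inner_hist, inner)
    if (verbose)
      message(sprintf("step %4d  inner %2d  max|div| %.3e  rate %.3e",
                      step, inner, div_max, rate))
    if (rate < cfg$eps && div_max <= cfg$div_tol) { converged <- TRUE; break }
  }
  structure(list(state = state, pressure = pressure,
                 outer_steps = length(rate_hist),
                 inner_iterations = inner_hist,
                 rate_history = rate_hist, div_history = div_hist,
                 converged = converged, cfg = cfg),
            class = "solver_result")
}

#' @export
print.solver_result <- function(x, ...) {
  cat(sprintf("<solver_result> %s after %d pseudo-time steps (%d SIMPLER passes)\n",
              if (x$converged) "converged" else "NOT converged (cap reached)",
              x$outer_steps, sum(x$inner_iterations)))
  cat(sprintf("  final max|div| = %.3e 1/s, final rate = %.3e (m/s)/s\n",
              utils::tail(x$div_history, 1), utils::tail(x$rate_history, 1)))
  invisible(x)
}

#' Plug-flow initial guess
#'
#' Uniform axial velocity over the fluid+boundary cells matching the inlet
#' flux (the solver needs an initial velocity estimate, not a pressure one).
#'
#' @param grid a [grid_spec()].
#' @param mask a [lumen_mask()].
#' @param bc a [flow_bc()] whose inlet profile determines the flux.
#' @return a [staggered_field()].
#' @export
initial_plug_field <- function(grid, mask, bc) {
  n <- grid$n
  m <- unclass(mask)
  sel_in <- m[, , 1] == MASK_INLET
  state <- staggered_field(grid)
  if (any(sel_in)) {
    flux_cells <- sum(bc$w[, , 1][sel_in])          # sum of face velocities
    open <- m != MASK_WALL
    for (k in seq_len(n[3] + 1L)) {
      klo <- max(k - 1L, 1L); khi <- min(k, n[3])
      sel <- open[, , klo] & open[, , khi]
      na <- sum(sel)
      if (na > 0) state$w[, , k][sel] <- flux_cells / na
    }
  }
  enforce_bc(state, mask, bc)
}
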