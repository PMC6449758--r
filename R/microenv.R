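# Voxelised extracellular space: substrates diffuse and decay on a regular
# mesh (operator-split implicit finite volumes, unconditionally stable),
# cells act as saturating sources / first-order sinks in their containing
# voxel, injection schedules drive a Dirichlet rim at the domain boundary,
# and the ECM can be carried as a non-diffusing density.

#' Create a voxel grid
#'
#' The domain is `[bounds[1], bounds[2]]` per axis (2 or 3 axes), discretised
#' into cubic voxels of edge `dx` (micrometres).  Substrate fields are added
#' with [add_substrate()].  The grid has reference semantics: all operations
#' modify it in place.
#'
#' @param bounds numeric(2): lower and upper domain bound, micrometres
#'   (applied to every axis), or a 2-column matrix with one row per axis.
#' @param dx voxel edge in micrometres.
#' @param ndim 2 or 3.
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(bounds, dx = 20, ndim = 3) {
  stopifnot(ndim %in% c(2, 3), dx > 0)
  if (is.matrix(bounds)) {
    stopifnot(nrow(bounds) == ndim, ncol(bounds) == 2)
  } else {
    bounds <- matrix(rep(as.numeric(bounds), each = ndim), ncol = 2)
  }
  nvox <- pmax(1L, as.integer(round((bounds[, 2] - bounds[, 1]) / dx)))
  dims <- c(nvox, rep(1L, 3 - ndim))
  g <- new.env(parent = emptyenv())
  g$ndim <- as.integer(ndim)
  g$dx <- dx
  g$origin <- c(bounds[, 1], rep(0, 3 - ndim))
  g$dims <- dims
  g$substrates <- list()
  class(g) <- "voxel_grid"
  g
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(x$dims[seq_len(x$ndim)], collapse = " x "),
      "voxels, dx =", x$dx, "um,", length(x$substrates), "substrate(s)\n")
  invisible(x)
}

#' Add a substrate field to a grid
#'
#' @param grid a [voxel_grid()].
#' @param name substrate name.
#' @param D diffusion coefficient, um^2/min (>= 0).
#' @param decay decay rate lambda, 1/min (>= 0).
#' @param diffusing if `FALSE` the diffusion step is a no-op for this
#'   substrate (used for the ECM density).
#' @param initial initial density (scalar, or full array).
#' @param max_density clamp ceiling for [ecm_modify()].
#' @return the grid, invisibly.
#' @export
add_substrate <- function(grid, name, D, decay = 0, diffusing = TRUE,
                          initial = 0, max_density = Inf) {
  stopifnot(inherits(grid, "voxel_grid"), D >= 0, decay >= 0)
  dens <- array(0, dim = grid$dims[seq_len(grid$ndim)])
  dens[] <- initial
  grid$substrates[[name]] <- list(name = name, D = D, lambda = decay,
                                  diffusing = isTRUE(diffusing),
                                  rim_value = NA_real_,
                                  max_density = max_density)
  # density arrays are stored one env slot per substrate so C++ can mutate
  # them without copying
  grid[[paste0(".dens.", name)]] <- dens
  invisible(grid)
}

.ge_dens <- function(grid, name) {
  d <- grid[[paste0(".dens.", name)]]
  if (is.null(d)) stop("unknown substrate '", name, "'", call. = FALSE)
  d
}

#' Get or set a substrate density array
#' @param grid a [voxel_grid()].
#' @param name substrate name.
#' @return the density array (dimensions = voxel counts per axis).
#' @export
density_array <- function(grid, name) .ge_dens(grid, name)

#' @rdname density_array
#' @param value replacement array or scalar.
#' @export
`density_array<-` <- function(grid, name, value) {
  d <- .ge_dens(grid, name)
  d[] <- value
  grid[[paste0(".dens.", name)]] <- d
  grid
}

# voxel index (1-based per axis) of positions; error when outside the domain
.vox_index <- function(grid, pos) {
  pos <- .as_pos_matrix(pos, grid$ndim)
  idx <- matrix(1L, nrow(pos), 3)
  for (a in seq_len(grid$ndim)) {
    i <- floor((pos[, a] - grid$origin[a]) / grid$dx) + 1
    if (any(i < 1 | i > grid$dims[a] | !is.finite(i)))
      stop("position outside the grid domain (axis ", a, ")", call. = FALSE)
    idx[, a] <- as.integer(i)
  }
  idx
}

.vox_linear <- function(grid, idx) {
  (idx[, 3] - 1L) * grid$dims[1] * grid$dims[2] +
    (idx[, 2] - 1L) * grid$dims[1] + idx[, 1]
}

.as_pos_matrix <- function(pos, ndim) {
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1)
  if (ncol(pos) == 2) pos <- cbind(pos, 0)
  pos
}

#' Sample a substrate at a position
#'
#' Nearest-voxel convention: returns the density of the containing voxel.
#'
#' @inheritParams add_substrate
#' @param pos position (x, y[, z]) in micrometres, or a matrix of positions.
#' @return density value(s).
#' @export
sample_density <- function(grid, name, pos) {
  dens <- .ge_dens(grid, name)
  dens[.vox_linear(grid, .vox_index(grid, pos))]
}

#' One diffusion/decay step
#'
#' Operator-split implicit update: one backward-Euler tridiagonal sweep per
#' axis (Thomas algorithm, zero-flux boundaries) followed by exact
#' exponential decay `exp(-lambda*dt)`.  Unconditionally stable, preserves
#' positivity, conserves mass when `lambda = 0` and no Dirichlet rim is
#' active.  Non-diffusing substrates are left untouched (no-op, not an
#' error), except for their decay if any.
#'
#' @inheritParams add_substrate
#' @param dt time step in minutes (> 0).
#' @param nsub number of sub-steps of length `dt` to take.
#' @return the grid, invisibly.
#' @export
diffuse_decay <- function(grid, name, dt, nsub = 1L) {
  stopifnot(dt > 0)
  sub <- grid$substrates[[name]]
  if (is.null(sub)) stop("unknown substrate '", name, "'", call. = FALSE)
  if (!sub$diffusing) return(invisible(grid))
  dens <- .ge_dens(grid, name)
  cpp_diffuse(dens, grid$dims[1], grid$dims[2], grid$dims[3], grid$dx,
              sub$D, sub$lambda, dt, as.integer(nsub), sub$rim_value)
  grid[[paste0(".dens.", name)]] <- dens
  invisible(grid)
}

#' Total substrate mass on the grid
#' @inheritParams add_substrate
#' @return sum of density times voxel volume (2D: voxel area).
#' @export
total_mass <- function(grid, name) {
  sum(.ge_dens(grid, name)) * grid$dx^grid$ndim
}

#' Cell-driven sources and sinks
#'
#' Each agent contributes a saturating source (`secretion * (saturation - c)`,
#' never pushing the voxel density above the saturation value) and a
#' first-order sink (`uptake * c`) in its containing voxel.  The per-voxel
#' update is solved implicitly, so densities stay non-negative for any time
#' step.  Returns the amount taken up per agent (density units), for
#' receptor bookkeeping.
#'
#' @inheritParams sample_density
#' @param secretion,uptake per-agent rates, 1/min (>= 0, recycled).
#' @param saturation per-agent saturation density (recycled).
#' @param dt time step in minutes.
#' @return numeric vector: uptaken amount per agent.
#' @export
apply_sources_sinks <- function(grid, name, pos, secretion, uptake,
                                saturation, dt) {
  pos <- .as_pos_matrix(pos, grid$ndim)
  n <- nrow(pos)
  if (n == 0) return(numeric(0))
  secretion <- rep_len(secretion, n); uptake <- rep_len(uptake, n)
  saturation <- rep_len(saturation, n)
  if (any(secretion < 0) || any(uptake < 0))
    stop("secretion/uptake rates must be >= 0", call. = FALSE)
  dens <- .ge_dens(grid, name)
  vox <- .vox_linear(grid, .vox_index(grid, pos))
  S <- rowsum(secretion, vox)               # summed source rates per voxel
  Sc <- rowsum(secretion * saturation, vox) # rate-weighted targets
  U <- rowsum(uptake, vox)
  uvox <- as.integer(rownames(S))
  c_old <- dens[uvox]
  c_new <- (c_old + dt * Sc[, 1]) / (1 + dt * (S[, 1] + U[, 1]))
  dens[uvox] <- c_new
  grid[[paste0(".dens.", name)]] <- dens
  # per-agent uptake based on the post-update voxel density
  cn <- c_new[match(vox, uvox)]
  unname(uptake * cn * dt)
}

#' Injection schedule
#'
#' Describes how a substrate is injected into the medium over time.  Modes:
#' `none` (no injection, no rim), `continuous` (held at `concentration`),
#' `pulsed` (`concentration` during `pulse_duration` at the start of every
#' `period`), `stop_at` (continuous until `switch_time`, then off) and
#' `step_change` (continuous at `concentration` until `switch_time`, then at
#' `new_concentration`).
#'
#' @param mode one of `"none"`, `"continuous"`, `"pulsed"`, `"stop_at"`,
#'   `"step_change"`.
#' @param concentration injected concentration (e.g. ng/mL).
#' @param pulse_duration,period pulse on-time and repetition period, min.
#' @param switch_time time of the stop/step switch, min.
#' @param new_concentration concentration after a `step_change`.
#' @return object of class `injection_schedule`.
#' @export
injection_schedule <- function(mode = c("none", "continuous", "pulsed",
                                        "stop_at", "step_change"),
                               concentration = 0, pulse_duration = NA,
                               period = NA, switch_time = NA,
                               new_concentration = NA) {
  mode <- match.arg(mode)
  if (mode == "pulsed") {
    if (!is.finite(pulse_duration) || !is.finite(period) ||
        pulse_duration <= 0 || pulse_duration > period)
      stop("pulsed schedule needs 0 < pulse_duration <= period", call. = FALSE)
  }
  if (mode %in% c("stop_at", "step_change")) {
    if (!is.finite(switch_time) || switch_time <= 0)
      stop(mode, " schedule needs switch_time > 0", call. = FALSE)
    if (mode == "step_change" && !is.finite(new_concentration))
      stop("step_change schedule needs new_concentration", call. = FALSE)
  }
  structure(list(mode = mode, concentration = concentration,
                 pulse_duration = pulse_duration, period = period,
                 switch_time = switch_time,
                 new_concentration = new_concentration),
            class = "injection_schedule")
}

#' Rim concentration of a schedule at time t
#'
#' Returns the Dirichlet value the medium rim is held at: the injected
#' concentration while the schedule is "on", 0 while it is "off" (the
#' substrate washes out), and `NA` for mode `"none"` (no rim at all).
#'
#' @param schedule an [injection_schedule()].
#' @param t time in minutes.
#' @return concentration or `NA`.
#' @export
schedule_value <- function(schedule, t) {
  switch(schedule$mode,
    none = NA_real_,
    continuous = schedule$concentration,
    pulsed = {
      phase <- t %% schedule$period
      if (phase < schedule$pulse_duration) schedule$concentration else 0
    },
    stop_at = if (t < schedule$switch_time) schedule$concentration else 0,
    step_change = if (t < schedule$switch_time) schedule$concentration
                  else schedule$new_concentration
  )
}

# linear indices of the boundary-adjacent ("medium rim") voxels
.rim_indices <- function(grid) {
  d <- grid$dims
  ix <- array(FALSE, dim = d)
  if (d[1] > 1) { ix[1, , ] <- TRUE; ix[d[1], , ] <- TRUE }
  if (d[2] > 1) { ix[, 1, ] <- TRUE; ix[, d[2], ] <- TRUE }
  if (d[3] > 1) { ix[, , 1] <- TRUE; ix[, , d[3]] <- TRUE }
  which(ix)
}

#' Apply an injection schedule at time t
#'
#' While the schedule is on, all boundary-adjacent voxels are held at the
#' scheduled concentration (Dirichlet rim, modelling a well-stirred medium);
#' while off, the rim is held at zero so the substrate washes out.  The rim
#' value is also enforced inside every subsequent [diffuse_decay()] substep
#' until the schedule changes it.
#'
#' @inheritParams add_substrate
#' @param schedule an [injection_schedule()].
#' @param t current time, minutes.
#' @return the grid, invisibly.
#' @export
apply_injection <- function(grid, name, schedule, t) {
  sub <- grid$substrates[[name]]
  if (is.null(sub)) stop("unknown substrate '", name, "'", call. = FALSE)
  v <- schedule_value(schedule, t)
  grid$substrates[[name]]$rim_value <- v
  if (is.finite(v)) {
    dens <- .ge_dens(grid, name)
    dens[.rim_indices(grid)] <- v
    grid[[paste0(".dens.", name)]] <- dens
  }
  invisible(grid)
}

#' Modify a non-diffusing ECM density
#'
#' Cells degrade and deposit matrix density in their containing voxel at
#' linear rates; the density is clamped to `[0, max_density]`.  The ECM
#' substrate must be non-diffusing.
#'
#' @inheritParams sample_density
#' @param degrade,deposit per-agent rates (density/min, recycled).
#' @param dt time step, minutes.
#' @return the grid, invisibly.
#' @export
ecm_modify <- function(grid, name, pos, degrade, deposit = 0, dt = 1) {
  sub <- grid$substrates[[name]]
  if (is.null(sub)) stop("unknown substrate '", name, "'", call. = FALSE)
  if (sub$diffusing)
    stop("ecm_modify requires a non-diffusing substrate", call. = FALSE)
  pos <- .as_pos_matrix(pos, grid$ndim)
  n <- nrow(pos)
  if (n == 0) return(invisible(grid))
  degrade <- rep_len(degrade, n); deposit <- rep_len(deposit, n)
  dens <- .ge_dens(grid, name)
  vox <- .vox_linear(grid, .vox_index(grid, pos))
  delta <- rowsum((deposit - degrade) * dt, vox)
  uvox <- as.integer(rownames(delta))
  dens[uvox] <- pmin(pmax(dens[uvox] + delta[, 1], 0), sub$max_density)
  grid[[paste0(".dens.", name)]] <- dens
  invisible(grid)
}
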