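# Off-lattice centre-based cell agents.  The population is a mutable
# struct-of-arrays (one environment, parallel vectors) so the mechanics and
# signalling kernels can operate on whole columns; passive ECM spheres share
# the same arrays with type = 1.

# fate codes
.FATE_PROLIF <- 0L
.FATE_APOPTOSIS <- 1L
.FATE_NONACD <- 2L
.FATE_LEVELS <- c("Proliferative", "Apoptosis", "NonACD")

# volume-program parameters (per-minute rates; see the methods vignette)
.BC_APOP_SHRINK_RATE <- 0.01  # apoptotic shrinkage
.BC_NECRO_SWELL_RATE <- 0.01  # necrotic swelling toward 1.5x
.BC_NECRO_SWELL_TARGET <- 1.5
.BC_NECRO_DURATION <- 360     # min until a necrotic cell is removed
.BC_APOP_REMOVAL_FRACTION <- 0.05
.BC_DIVISION_VOLUME_GATE <- 0.95  # of the doubled target
.BC_SPHERE_REMOVAL_RADIUS <- 0.5  # um

.radius_from_volume <- function(v) (3 * v / (4 * pi))^(1 / 3)

#' Create an empty cell population
#'
#' @param strains list of [strain_params()].
#' @param network optional `boolean_network` attached to every cell.
#' @param ndim 2 or 3 (2D mode freezes z at 0).
#' @param seed master seed; every agent derives its own random stream from
#'   (seed, id).
#' @return object of class `cell_population` (reference semantics).
#' @export
cell_population <- function(strains, network = NULL, ndim = 3, seed = 1) {
  if (inherits(strains, "strain_params")) strains <- list(strains)
  p <- new.env(parent = emptyenv())
  p$strains <- strains
  p$network <- network
  p$ndim <- as.integer(ndim)
  p$seed <- as.double(seed)
  p$next_id <- 1L
  n0 <- 0L
  p$id <- integer(n0); p$type <- integer(n0)
  p$x <- numeric(n0); p$y <- numeric(n0); p$z <- numeric(n0)
  p$strain <- integer(n0); p$fate <- integer(n0)
  p$v_fluid <- numeric(n0); p$v_cyto <- numeric(n0); p$v_nucl <- numeric(n0)
  p$radius <- numeric(n0)
  p$age <- numeric(n0); p$cycle_duration <- numeric(n0)
  p$arrest <- logical(n0)
  p$px <- numeric(n0); p$py <- numeric(n0); p$pz <- numeric(n0)
  p$adhcoef <- numeric(n0)
  p$activated <- logical(n0); p$secreting <- logical(n0)
  p$bound <- numeric(n0); p$internalised <- numeric(n0)
  p$death_clock <- numeric(n0); p$commit_volume <- numeric(n0)
  p$friction <- numeric(n0); p$pinned <- logical(n0); p$degradable <- logical(n0)
  p$next_signal <- numeric(n0)
  p$rng <- matrix(0L, n0, 4)
  k <- if (is.null(network)) 0L else length(network$nodes)
  p$net_states <- matrix(0L, n0, k)
  # bookkeeping: every id ever created is a cell, a sphere, or removed
  p$n_created_cells <- 0L
  p$n_created_spheres <- 0L
  p$n_removed <- 0L
  p$committed <- matrix(0L, length(strains), 2,
                        dimnames = list(NULL, c("Apoptosis", "NonACD")))
  # death commits that happened without the cell ever activating NFkB
  p$committed_unactivated <- matrix(0L, length(strains), 2,
                                    dimnames = list(NULL, c("Apoptosis", "NonACD")))
  class(p) <- "cell_population"
  p
}

#' @export
print.cell_population <- function(x, ...) {
  cat("cell_population:", sum(x$type == 0L), "cells,",
      sum(x$type == 1L), "passive spheres,",
      length(x$strains), "strain(s),", x$ndim, "D\n")
  if (length(x$fate)) {
    f <- table(factor(.FATE_LEVELS[x$fate[x$type == 0L] + 1L],
                      levels = .FATE_LEVELS))
    print(f)
  }
  invisible(x)
}

# append rows to all per-agent vectors
.pop_append <- function(p, n, fields) {
  for (nm in setdiff(names(fields), c(".rng", ".net_states")))
    p[[nm]] <- c(p[[nm]], fields[[nm]])
  p$rng <- rbind(p$rng, fields$.rng)
  p$net_states <- rbind(p$net_states, fields$.net_states)
  invisible(p)
}

#' Add cells to a population
#'
#' New cells start proliferative at their strain's reference volume with a
#' freshly drawn Erlang cycle timer, a random polarity and (if a network is
#' attached) an initial network state drawn from the network's initial-state
#' distribution, all from the cell's own random stream.
#'
#' @param p a [cell_population()].
#' @param x,y,z positions in micrometres.
#' @param strain strain index (1-based, recycled).
#' @param adhesion_coefficient initial adhesion coefficient (recycled).
#' @return ids of the new cells, invisibly.
#' @export
add_cells <- function(p, x, y, z = 0, strain = 1L, adhesion_coefficient = 1) {
  n <- length(x)
  if (n == 0) return(invisible(integer(0)))
  y <- rep_len(y, n); z <- rep_len(z, n)
  strain <- rep_len(as.integer(strain), n)
  adhesion_coefficient <- rep_len(adhesion_coefficient, n)
  ids <- seq.int(p$next_id, length.out = n)
  p$next_id <- p$next_id + n
  p$n_created_cells <- p$n_created_cells + n
  k <- ncol(p$net_states)
  rngm <- matrix(0L, n, 4)
  states <- matrix(0L, n, k)
  pol <- matrix(0, n, 3)
  vref <- vapply(p$strains, function(s) s$volume_total, 1.0)[strain]
  ffrac <- vapply(p$strains, function(s) s$fluid_fraction, 1.0)[strain]
  nrad <- vapply(p$strains, function(s) s$nuclear_radius, 1.0)[strain]
  cyc <- vapply(p$strains, function(s) s$cycle_duration, 1.0)[strain]
  dur <- numeric(n); stagger <- numeric(n)
  for (i in seq_len(n)) {
    rng <- bc_rng(p$seed, ids[i])
    dur[i] <- rng_erlang(rng, 4L, cyc[i])
    pol[i, ] <- rng_unit_vector(rng, p$ndim)
    stagger[i] <- rng_unif(rng)
    if (k > 0) {
      u <- rng_unif(rng, k)
      states[i, ] <- as.integer(u < p$network$istate)
    }
    rngm[i, ] <- rng$state
  }
  v_nucl_total <- (4 / 3) * pi * nrad^3
  v_nucl <- (1 - ffrac) * v_nucl_total
  v_cyto <- (1 - ffrac) * (vref - v_nucl_total)
  v_fluid <- vref - v_nucl - v_cyto
  .pop_append(p, n, list(
    id = ids, type = rep(0L, n), x = x, y = y,
    z = if (p$ndim == 2) rep(0, n) else z,
    strain = strain, fate = rep(.FATE_PROLIF, n),
    v_fluid = v_fluid, v_cyto = v_cyto, v_nucl = v_nucl,
    radius = .radius_from_volume(vref),
    age = rep(0, n), cycle_duration = dur, arrest = rep(FALSE, n),
    px = pol[, 1], py = pol[, 2], pz = pol[, 3],
    adhcoef = adhesion_coefficient,
    activated = rep(FALSE, n), secreting = rep(FALSE, n),
    bound = rep(0, n), internalised = rep(0, n),
    death_clock = rep(0, n), commit_volume = rep(NA_real_, n),
    friction = rep(1, n), pinned = rep(FALSE, n), degradable = rep(FALSE, n),
    next_signal = stagger,   # scaled by dt_signalling by the coupling loop
    .rng = rngm, .net_states = states))
  invisible(ids)
}

#' Add passive ECM spheres
#'
#' Passive spheres are pushed by cells and other spheres according to their
#' friction coefficient (`pinned = TRUE` makes them immovable), can be
#' degraded on contact, and are removed once their radius falls below
#' 0.5 micron.
#'
#' @inheritParams add_cells
#' @param radius sphere radii, micrometres.
#' @param friction drag coefficient (velocity = force / friction).
#' @param pinned logical: immovable spheres.
#' @param degradable logical: cells may shrink these on contact.
#' @return ids of the new spheres, invisibly.
#' @export
add_spheres <- function(p, x, y, z = 0, radius = 8.4, friction = 1,
                        pinned = FALSE, degradable = TRUE) {
  n <- length(x)
  if (n == 0) return(invisible(integer(0)))
  y <- rep_len(y, n); z <- rep_len(z, n); radius <- rep_len(radius, n)
  friction <- rep_len(friction, n); pinned <- rep_len(pinned, n)
  degradable <- rep_len(degradable, n)
  ids <- seq.int(p$next_id, length.out = n)
  p$next_id <- p$next_id + n
  p$n_created_spheres <- p$n_created_spheres + n
  k <- ncol(p$net_states)
  rngm <- matrix(0L, n, 4)
  for (i in seq_len(n)) rngm[i, ] <- bc_rng(p$seed, ids[i])$state
  .pop_append(p, n, list(
    id = ids, type = rep(1L, n), x = x, y = y,
    z = if (p$ndim == 2) rep(0, n) else z,
    strain = rep(1L, n), fate = rep(.FATE_PROLIF, n),
    v_fluid = rep(0, n), v_cyto = rep(0, n), v_nucl = rep(0, n),
    radius = radius,
    age = rep(0, n), cycle_duration = rep(Inf, n), arrest = rep(TRUE, n),
    px = rep(0, n), py = rep(0, n), pz = rep(0, n),
    adhcoef = rep(1, n),
    activated = rep(FALSE, n), secreting = rep(FALSE, n),
    bound = rep(0, n), internalised = rep(0, n),
    death_clock = rep(0, n), commit_volume = rep(NA_real_, n),
    friction = friction, pinned = pinned, degradable = degradable,
    next_signal = rep(Inf, n),
    .rng = rngm, .net_states = matrix(0L, n, k)))
  invisible(ids)
}

# drop agents by row index (removal bookkeeping included)
.pop_remove <- function(p, rows) {
  if (!length(rows)) return(invisible(p))
  keep <- setdiff(seq_along(p$id), rows)
  p$n_removed <- p$n_removed + length(rows)
  for (nm in c("id", "type", "x", "y", "z", "strain", "fate", "v_fluid",
               "v_cyto", "v_nucl", "radius", "age", "cycle_duration",
               "arrest", "px", "py", "pz", "adhcoef", "activated",
               "secreting", "bound", "internalised", "death_clock",
               "commit_volume", "friction", "pinned", "degradable",
               "next_signal")) {
    p[[nm]] <- p[[nm]][keep]
  }
  p$rng <- p$rng[keep, , drop = FALSE]
  p$net_states <- p$net_states[keep, , drop = FALSE]
  invisible(p)
}

#' Pairwise interaction force (reference implementation)
#'
#' Force on agent `a` exerted by agent `b` for the soft-sphere law:
#' repulsion `c_rep*(1 - d/R)^2` inside the radii sum `R` (directed apart)
#' and adhesion `c_adh*(1 - d/(f*R))^2` inside `f*R` (directed together),
#' where `f` is the interaction-distance multiplier.  `c_adh` combines the
#' strain pair's adhesion strength with the geometric mean of the two
#' agents' adhesion coefficients; the force on `b` is the exact negative.
#' Coincident centres (`d = 0`) give a deterministic repulsion along +x.
#'
#' This scalar version is the documented reference; simulations use the
#' identical compiled kernel (see [compute_forces()]).
#'
#' @param a,b lists with `pos` (numeric 2 or 3), `radius`, and optionally
#'   `type` ("cell"/"sphere"), `strain` (index), `adhesion_coefficient`.
#' @param strains list of [strain_params()].
#' @param sphere_repulsion repulsion strength of passive spheres.
#' @return force vector (length 3) on `a`.
#' @export
pairwise_force <- function(a, b, strains, sphere_repulsion = 10) {
  get <- function(o, f, d) if (is.null(o[[f]])) d else o[[f]]
  pa <- c(a$pos, 0)[1:3]; pb <- c(b$pos, 0)[1:3]
  dvec <- pa - pb
  d <- sqrt(sum(dvec^2))
  u <- if (d <= 0) c(1, 0, 0) else dvec / d
  ta <- get(a, "type", "cell"); tb <- get(b, "type", "cell")
  sa <- get(a, "strain", 1L); sb <- get(b, "strain", 1L)
  ca <- get(a, "adhesion_coefficient", 1); cb <- get(b, "adhesion_coefficient", 1)
  f <- strains[[1]]$interaction_distance_multiplier
  R <- a$radius + b$radius
  maxd <- f * R
  if (d >= maxd) return(c(0, 0, 0))
  if (ta == "cell" && tb == "cell") {
    if (sa == sb) {
      c_adh <- strains[[sa]]$adhesion_homotypic
    } else {
      c_adh <- sqrt(strains[[sa]]$adhesion_heterotypic *
                    strains[[sb]]$adhesion_heterotypic)
    }
    c_rep <- sqrt(strains[[sa]]$repulsion * strains[[sb]]$repulsion)
  } else if (ta != tb) {
    cs <- if (ta == "cell") sa else sb
    c_adh <- strains[[cs]]$adhesion_matrix
    c_rep <- sqrt(strains[[cs]]$repulsion * sphere_repulsion)
  } else {
    c_adh <- 0
    c_rep <- sphere_repulsion
  }
  c_adh <- c_adh * sqrt(ca * cb)
  fm <- 0
  if (d < R) fm <- fm + c_rep * (1 - d / R)^2
  fm <- fm - c_adh * (1 - d / maxd)^2
  fm * u
}

#' Compute interaction forces for a whole population
#'
#' @param p a [cell_population()].
#' @param method `"hash"` (spatial hashing) or `"allpairs"`; both return
#'   exactly the same forces (identical summation order).
#' @param sphere_repulsion repulsion strength of passive spheres.
#' @return n x 3 force matrix.
#' @export
compute_forces <- function(p, method = c("hash", "allpairs"),
                           sphere_repulsion = 10) {
  method <- match.arg(method)
  sm <- .strain_matrices(p$strains)
  cpp_forces(p$x, p$y, p$z, p$radius, p$type, p$strain - 1L, p$adhcoef,
             sm$adh, sm$rep, sm$mat_adh, sphere_repulsion, sm$f,
             p$ndim, method == "hash")
}

#' Overdamped motion integration
#'
#' Velocity = (interaction forces + motile force) / drag; cells have unit
#' drag, passive spheres use their friction coefficient and pinned spheres
#' do not move.  In 2D mode z stays frozen at 0.
#'
#' @param p a [cell_population()].
#' @param forces n x 3 matrix from [compute_forces()].
#' @param motile n x 3 matrix of motile forces (or NULL).
#' @param dt time step, minutes.
#' @return the population, invisibly.
#' @export
integrate_motion <- function(p, forces, motile = NULL, dt = 0.1) {
  stopifnot(dt > 0)
  if (!length(p$id)) return(invisible(p))
  F <- forces
  if (!is.null(motile)) F <- F + motile
  drag <- ifelse(p$type == 1L, p$friction, 1)
  mob <- ifelse(p$pinned, 0, 1 / drag)
  p$x <- p$x + F[, 1] * mob * dt
  p$y <- p$y + F[, 2] * mob * dt
  if (p$ndim == 3) p$z <- p$z + F[, 3] * mob * dt
  invisible(p)
}

#' Polarity decorrelation and motile force
#'
#' Run-and-tumble persistence: each cell's polarity is redrawn uniformly at
#' Poisson rate `1/tau` (per-strain persistence time); the motile force is
#' `speed * polarity` (unit drag).  With `tau = Inf` the polarity never
#' changes (ballistic limit); with `speed = 0` the motile force vanishes.
#'
#' @param p a [cell_population()].
#' @param dt time step, minutes.
#' @return n x 3 matrix of motile forces.
#' @export
update_polarity_motility <- function(p, dt) {
  n <- length(p$id)
  Fm <- matrix(0, n, 3)
  if (!n) return(Fm)
  cells <- which(p$type == 0L)
  if (length(cells)) {
    taus <- vapply(p$strains, function(s) s$persistence_time, 1.0)
    speeds <- vapply(p$strains, function(s) s$motility_speed, 1.0)
    for (s in unique(p$strain[cells])) {
      rows <- cells[p$strain[cells] == s]
      cpp_update_polarity(p$px, p$py, p$pz, p$rng, rows, taus[s], dt, p$ndim)
    }
    sp <- speeds[p$strain[cells]]
    Fm[cells, 1] <- sp * p$px[cells]
    Fm[cells, 2] <- sp * p$py[cells]
    Fm[cells, 3] <- sp * p$pz[cells]
  }
  Fm
}

# phase-dependent volume targets; returns list of target vectors and rates
.volume_targets <- function(p) {
  n <- length(p$id)
  vref <- vapply(p$strains, function(s) s$volume_total, 1.0)[p$strain]
  ffrac <- vapply(p$strains, function(s) s$fluid_fraction, 1.0)[p$strain]
  nrad <- vapply(p$strains, function(s) s$nuclear_radius, 1.0)[p$strain]
  v_nucl_tot <- (4 / 3) * pi * nrad^3
  t_nucl <- (1 - ffrac) * v_nucl_tot
  t_cyto <- (1 - ffrac) * (vref - v_nucl_tot)
  t_fluid <- vref - t_nucl - t_cyto
  scale <- rep(1, n)
  rate <- vapply(p$strains, function(s) s$volume_growth_rate, 1.0)[p$strain]
  grow <- p$fate == .FATE_PROLIF & !p$arrest & p$type == 0L
  scale[grow] <- 2                       # targets double over the cycle
  apop <- p$fate == .FATE_APOPTOSIS
  scale[apop] <- 0
  rate[apop] <- .BC_APOP_SHRINK_RATE
  necro <- p$fate == .FATE_NONACD
  scale[necro] <- .BC_NECRO_SWELL_TARGET
  rate[necro] <- .BC_NECRO_SWELL_RATE
  list(fluid = t_fluid * scale, cyto = t_cyto * scale, nucl = t_nucl * scale,
       rate = rate)
}

#' Volume dynamics step
#'
#' Each volume compartment (fluid, cytoplasmic solid, nuclear solid) relaxes
#' exponentially toward its phase-dependent target: proliferative cells grow
#' toward doubled targets, apoptotic cells shrink toward zero and are
#' removed below 5% of their volume at death commitment, necrotic (NonACD)
#' cells swell toward 1.5x and lyse (are removed) after 6 h.  The radius is
#' recomputed from the total volume.
#'
#' @param p a [cell_population()].
#' @param dt time step, minutes.
#' @return the population, invisibly.
#' @export
update_volume <- function(p, dt) {
  stopifnot(dt > 0)
  cells <- p$type == 0L
  if (!any(cells)) return(invisible(p))
  tg <- .volume_targets(p)
  f <- exp(-tg$rate * dt)
  p$v_fluid[cells] <- tg$fluid[cells] + (p$v_fluid[cells] - tg$fluid[cells]) * f[cells]
  p$v_cyto[cells] <- tg$cyto[cells] + (p$v_cyto[cells] - tg$cyto[cells]) * f[cells]
  p$v_nucl[cells] <- tg$nucl[cells] + (p$v_nucl[cells] - tg$nucl[cells]) * f[cells]
  vtot <- p$v_fluid + p$v_cyto + p$v_nucl
  p$radius[cells] <- .radius_from_volume(vtot[cells])
  p$death_clock[p$fate != .FATE_PROLIF] <-
    p$death_clock[p$fate != .FATE_PROLIF] + dt
  # removals
  gone_apop <- which(cells & p$fate == .FATE_APOPTOSIS &
                     vtot < .BC_APOP_REMOVAL_FRACTION * p$commit_volume)
  gone_necro <- which(cells & p$fate == .FATE_NONACD &
                      p$death_clock >= .BC_NECRO_DURATION)
  .pop_remove(p, c(gone_apop, gone_necro))
  invisible(p)
}

#' Cell-cycle progression and division
#'
#' The cycle is a single-phase timer with Erlang-distributed duration
#' (shape 4, mean = the strain's `cycle_duration`), advancing only while the
#' cell is proliferative and not arrested.  Division requires the timer to
#' have elapsed and the volume to exceed 95% of the doubled reference
#' volume; daughters are placed at the mother's position +/- r/2 along a
#' random direction, receive half of each volume compartment, a fresh
#' Erlang timer and polarity from their own streams, and a bitwise copy of
#' the mother's network state.
#'
#' @param p a [cell_population()].
#' @param dt time step, minutes.
#' @param dt_signalling signalling period used to stagger the daughters'
#'   update phases.
#' @param t current time (for daughters' signalling schedule).
#' @return ids of daughters created this step, invisibly.
#' @export
cycle_and_divide <- function(p, dt, dt_signalling = 10, t = 0) {
  cells <- which(p$type == 0L & p$fate == .FATE_PROLIF)
  if (!length(cells)) return(invisible(integer(0)))
  adv <- cells[!p$arrest[cells]]
  p$age[adv] <- p$age[adv] + dt
  vref <- vapply(p$strains, function(s) s$volume_total, 1.0)[p$strain]
  vtot <- p$v_fluid + p$v_cyto + p$v_nucl
  ready <- adv[p$age[adv] >= p$cycle_duration[adv] &
               vtot[adv] >= .BC_DIVISION_VOLUME_GATE * 2 * vref[adv]]
  if (!length(ready)) return(invisible(integer(0)))
  daughters <- integer(0)
  # daughters are appended first, mothers removed afterwards, so the row
  # indices in `ready` stay valid throughout
  for (i in ready) {
    rng <- new.env(parent = emptyenv())
    rng$state <- p$rng[i, ]
    class(rng) <- "bc_rng"
    dir <- rng_unit_vector(rng, p$ndim)
    p$rng[i, ] <- rng$state
    half <- c(p$v_fluid[i], p$v_cyto[i], p$v_nucl[i]) / 2
    off <- dir * p$radius[i] / 2
    ids <- add_cells(p, x = p$x[i] + c(off[1], -off[1]),
                     y = p$y[i] + c(off[2], -off[2]),
                     z = p$z[i] + c(off[3], -off[3]),
                     strain = p$strain[i],
                     adhesion_coefficient = p$adhcoef[i])
    rows <- match(ids, p$id)
    for (r in rows) {
      p$v_fluid[r] <- half[1]; p$v_cyto[r] <- half[2]; p$v_nucl[r] <- half[3]
      p$radius[r] <- .radius_from_volume(sum(half))
      if (ncol(p$net_states)) p$net_states[r, ] <- p$net_states[i, ]
      p$activated[r] <- p$activated[i]
      p$secreting[r] <- p$secreting[i]
      p$arrest[r] <- p$arrest[i]
      p$bound[r] <- p$bound[i] / 2
      p$internalised[r] <- p$internalised[i] / 2
      p$next_signal[r] <- t + p$next_signal[r] * dt_signalling
    }
    daughters <- c(daughters, ids)
  }
  .pop_remove(p, ready)  # retire the mother ids (counted in n_removed)
  invisible(daughters)
}

#' Set a cell's fate
#'
#' Proliferative cells may commit to Apoptosis or NonACD, which starts the
#' corresponding volume program; death fates are terminal, so any transition
#' out of Apoptosis or NonACD is silently ignored.
#'
#' @param p a [cell_population()].
#' @param rows row indices of the cells.
#' @param fate `"Proliferative"`, `"Apoptosis"` or `"NonACD"`.
#' @return the population, invisibly.
#' @export
set_fate <- function(p, rows, fate) {
  code <- match(fate, .FATE_LEVELS) - 1L
  if (is.na(code)) stop("unknown fate '", fate, "'", call. = FALSE)
  rows <- rows[p$type[rows] == 0L & p$fate[rows] == .FATE_PROLIF]
  if (!length(rows) || code == .FATE_PROLIF) return(invisible(p))
  p$fate[rows] <- code
  p$death_clock[rows] <- 0
  p$commit_volume[rows] <- p$v_fluid[rows] + p$v_cyto[rows] + p$v_nucl[rows]
  p$secreting[rows] <- FALSE
  for (s in unique(p$strain[rows])) {
    p$committed[s, .FATE_LEVELS[code + 1L]] <-
      p$committed[s, .FATE_LEVELS[code + 1L]] + sum(p$strain[rows] == s)
    p$committed_unactivated[s, .FATE_LEVELS[code + 1L]] <-
      p$committed_unactivated[s, .FATE_LEVELS[code + 1L]] +
      sum(p$strain[rows] == s & !p$activated[rows])
  }
  invisible(p)
}

#' Oxygen-threshold necrosis check
#'
#' A proliferative cell whose local oxygen is strictly below its strain's
#' `oxygen_necrosis_threshold` commits to NonACD.
#'
#' @param p a [cell_population()].
#' @param o2_local per-cell local oxygen (mmHg), aligned with the agent rows.
#' @return the population, invisibly.
#' @export
oxygen_death_check <- function(p, o2_local) {
  thr <- vapply(p$strains, function(s) s$oxygen_necrosis_threshold, 1.0)
  hit <- which(p$type == 0L & p$fate == .FATE_PROLIF &
               o2_local < thr[p$strain])
  if (length(hit)) set_fate(p, hit, "NonACD")
  invisible(p)
}

#' Degrade (or reinforce) passive spheres on contact
#'
#' Every degradable sphere in contact with a cell (`d < r_cell + r_sphere`)
#' shrinks at the cell strain's `ecm_degrade_rate` (micron/min; negative
#' rates grow the sphere).  Spheres below 0.5 micron are removed, leaving a
#' track.
#'
#' @param p a [cell_population()].
#' @param dt time step, minutes.
#' @return the population, invisibly.
#' @export
degrade_passive_spheres <- function(p, dt) {
  sph <- which(p$type == 1L & p$degradable)
  cells <- which(p$type == 0L)
  if (!length(sph) || !length(cells)) return(invisible(p))
  rates <- vapply(p$strains, function(s) s$ecm_degrade_rate, 1.0)
  if (all(rates == 0)) return(invisible(p))
  for (j in sph) {
    d2 <- (p$x[cells] - p$x[j])^2 + (p$y[cells] - p$y[j])^2 +
          (p$z[cells] - p$z[j])^2
    touching <- cells[d2 < (p$radius[cells] + p$radius[j])^2]
    if (length(touching))
      p$radius[j] <- p$radius[j] - sum(rates[p$strain[touching]]) * dt
  }
  gone <- which(p$type == 1L & p$radius < .BC_SPHERE_REMOVAL_RADIUS)
  .pop_remove(p, gone)
  invisible(p)
}

#' Population census
#'
#' @param p a [cell_population()].
#' @return data.frame with one row per strain x fate: live counts, plus
#'   cumulative committed death counts and activated-cell counts.
#' @export
census <- function(p) {
  S <- length(p$strains)
  out <- expand.grid(strain = seq_len(S), fate = .FATE_LEVELS,
                     stringsAsFactors = FALSE)
  cells <- p$type == 0L
  out$count <- mapply(function(s, f) {
    sum(cells & p$strain == s & p$fate == (match(f, .FATE_LEVELS) - 1L))
  }, out$strain, out$fate)
  out$committed <- mapply(function(s, f) {
    if (f == "Proliferative") NA_integer_ else p$committed[s, f]
  }, out$strain, out$fate)
  out$activated <- vapply(seq_len(nrow(out)), function(i) {
    sum(cells & p$strain == out$strain[i] &
        p$fate == (match(out$fate[i], .FATE_LEVELS) - 1L) & p$activated)
  }, 1L)
  out$strain_name <- vapply(p$strains, function(s) s$name, "")[out$strain]
  out
}
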