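# TNF receptor kinetics, autocrine secretion and the bundled cell-fate
# Boolean network.  The receptor scheme is a three-pool linear model:
# extracellular ligand binds at k_on, bound ligand internalises at k_int,
# internalised ligand clears at k_clear.  The internalised pool is what the
# signalling input rule thresholds on ("TNF internalised or not").

#' Default TNF receptor kinetics
#'
#' Rates in 1/min; `theta` is the internalised-pool threshold that switches
#' the network's TNF input node on.  These values are calibrated
#' reconstructions (see the methods vignette), exposed so users can refit
#' them.
#'
#' @param substrate substrate name carrying the ligand.
#' @param k_on binding rate per unit local concentration, 1/min.
#' @param k_int internalisation rate, 1/min.
#' @param k_clear clearance rate of the internalised pool, 1/min.
#' @param theta input-node threshold on the internalised pool.
#' @return list used as the `receptor` slot of [sim_config()].
#' @export
tnf_receptor_params <- function(substrate = "TNF", k_on = 0.1, k_int = 0.5,
                                k_clear = 0.05, theta = 0.15) {
  list(substrate = substrate, k_on = k_on, k_int = k_int, k_clear = k_clear,
       theta = theta)
}

#' Receptor state update (single cell)
#'
#' Explicit update over `dt`: `bound += k_on*conc*dt - k_int*bound*dt`,
#' `internalised += k_int*bound*dt - k_clear*internalised*dt`.  The uptaken
#' amount (`k_on*conc*dt`, removed from the local voxel by the caller) is
#' returned and is capped so the voxel density never goes negative.
#'
#' @param rs list with `bound`, `internalised`, `k_on`, `k_int`, `k_clear`.
#' @param local_conc local ligand concentration.
#' @param dt time step, minutes.
#' @param available maximum amount that can be taken from the voxel
#'   (default: no cap).
#' @return list with the updated `rs` and `uptaken`.
#' @export
receptor_update <- function(rs, local_conc, dt, available = Inf) {
  stopifnot(dt > 0)
  uptaken <- min(rs$k_on * local_conc * dt, available)
  b0 <- rs$bound
  rs$bound <- b0 + uptaken - rs$k_int * b0 * dt
  rs$internalised <- rs$internalised + rs$k_int * b0 * dt -
    rs$k_clear * rs$internalised * dt
  list(rs = rs, uptaken = uptaken)
}

# vectorised in-loop version: updates the population pools and removes the
# uptaken ligand from the grid (capped per voxel so density stays >= 0)
receptor_update_population <- function(p, grid, receptor, dt, rows) {
  pos <- cbind(p$x[rows], p$y[rows], p$z[rows])
  vox <- .vox_linear(grid, .vox_index(grid, pos))
  dens <- .ge_dens(grid, receptor$substrate)
  conc <- dens[vox]
  desired <- receptor$k_on * conc * dt
  tot <- rowsum(desired, vox)
  uvox <- as.integer(rownames(tot))
  avail <- dens[uvox]
  scale <- ifelse(tot[, 1] > avail, avail / pmax(tot[, 1], 1e-300), 1)
  uptaken <- desired * scale[match(vox, uvox)]
  dens[uvox] <- avail - pmin(tot[, 1], avail)
  grid[[paste0(".dens.", receptor$substrate)]] <- dens
  b0 <- p$bound[rows]
  p$bound[rows] <- b0 + uptaken - receptor$k_int * b0 * dt
  p$internalised[rows] <- p$internalised[rows] + receptor$k_int * b0 * dt -
    receptor$k_clear * p$internalised[rows] * dt
  invisible(uptaken)
}

#' Autocrine/paracrine secretion update
#'
#' Cells whose NFkB read-out switched secretion on add their strain's TNF
#' secretion rate times `dt` to their containing voxel; all other cells
#' leave the grid unchanged.
#'
#' @param p a [cell_population()].
#' @param grid a [voxel_grid()].
#' @param substrate substrate name.
#' @param rates per-strain secretion rates (density/min).
#' @param dt time step, minutes.
#' @param rows rows of the secreting cells (default: flagged cells).
#' @return the grid, invisibly.
#' @export
secretion_update <- function(p, grid, substrate, rates = NULL, dt = 0.1,
                             rows = NULL) {
  if (is.null(rows)) rows <- which(p$type == 0L & p$secreting)
  if (!length(rows)) return(invisible(grid))
  if (is.null(rates))
    rates <- vapply(p$strains, function(s) s$tnf_secretion_rate, 1.0)
  dens <- .ge_dens(grid, substrate)
  pos <- cbind(p$x[rows], p$y[rows], p$z[rows])
  vox <- .vox_linear(grid, .vox_index(grid, pos))
  add <- rowsum(rates[p$strain[rows]] * dt, vox)
  uvox <- as.integer(rownames(add))
  dens[uvox] <- dens[uvox] + add[, 1]
  grid[[paste0(".dens.", substrate)]] <- dens
  invisible(grid)
}

#' The bundled TNF cell-fate Boolean network
#'
#' Loads the package's reconstructed cell-fate decision model: TNF receptor
#' engagement branching into the NFkB survival pathway, the CASP8/CASP3
#' apoptotic cascade and the RIP1/ROS/MPT non-apoptotic death branch, with
#' the read-outs Survival, Apoptosis and NonACD, plus mRNA intermediate
#' nodes (mXIAP, mROS) whose slower rates introduce transcription/
#' translation delays.  This is a synthetic reconstruction of the published
#' cell-fate topology (see `inst/extdata/cellfate_synthetic.bnd`), not a
#' redistribution of any original model files.
#'
#' @param transcription_rate_scale multiplier (> 0) applied to all
#'   mRNA-node rates; the default 0.2 makes transcription five-fold slower
#'   than protein events.  Increasing it accelerates mXIAP (apoptosis
#'   inhibition) and mROS (ROS production), shifting fates toward NonACD.
#' @return a `boolean_network` whose sole input node is TNF.
#' @export
build_cell_fate_network <- function(transcription_rate_scale = 0.2) {
  stopifnot(transcription_rate_scale > 0)
  model <- system.file("extdata", "cellfate_synthetic.bnd",
                       package = "boolcell", mustWork = TRUE)
  config <- system.file("extdata", "cellfate_synthetic.cfg",
                        package = "boolcell", mustWork = TRUE)
  base_rt <- 0.02  # 1/min, the default mRNA rate at scale 1 is $u * scale
  parse_network_files(model, config,
                      symbols = list(rt = base_rt * transcription_rate_scale /
                                       0.2))
}

#' Fraction of ever-activated cells
#'
#' The activated flag latches the first time a cell's NFkB read-out is
#' active.  The census is the number of flagged cells among those present at
#' the end, divided by the initial viable count.
#'
#' @param p the final [cell_population()].
#' @param initial_viable initial viable cell count (> 0).
#' @return fraction (dimensionless; can exceed 1 if the population grew).
#' @export
activation_census <- function(p, initial_viable) {
  if (initial_viable <= 0) stop("initial viable count must be > 0", call. = FALSE)
  sum(p$activated[p$type == 0L]) / initial_viable
}
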