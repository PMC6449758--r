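# The multi-rate orchestration layer: diffusion, mechanics and signalling
# run on their own clocks (dt_diffusion <= dt_mechanics <= dt_signalling,
# integer multiples), each cell's Boolean model reads its inputs from the
# microenvironment and writes its read-outs back into phenotype.

#' Multi-rate clock configuration
#'
#' @param dt_diffusion,dt_mechanics,dt_signalling time steps in minutes;
#'   each larger step must be an integer multiple of the smaller.
#' @param t_end simulation horizon, minutes.
#' @param snapshot_interval census/snapshot recording period, minutes.
#' @return object of class `clock_config`.
#' @export
clock_config <- function(dt_diffusion = 0.01, dt_mechanics = 0.1,
                         dt_signalling = 10, t_end = 1440,
                         snapshot_interval = 60) {
  if (!(dt_diffusion <= dt_mechanics && dt_mechanics <= dt_signalling))
    stop("clock error: need dt_diffusion <= dt_mechanics <= dt_signalling",
         call. = FALSE)
  ratio1 <- dt_mechanics / dt_diffusion
  ratio2 <- dt_signalling / dt_mechanics
  if (abs(ratio1 - round(ratio1)) > 1e-9 || abs(ratio2 - round(ratio2)) > 1e-9)
    stop("clock error: each larger step must be an integer multiple of the smaller",
         call. = FALSE)
  stopifnot(t_end >= 0, snapshot_interval > 0)
  structure(list(dt_diffusion = dt_diffusion, dt_mechanics = dt_mechanics,
                 dt_signalling = dt_signalling, t_end = t_end,
                 snapshot_interval = snapshot_interval),
            class = "clock_config")
}

#' Input rule: microenvironment to network input node
#'
#' Sets an input node to 1 iff the source quantity strictly exceeds the
#' threshold.  Sources: `"substrate"` (local substrate density at the cell's
#' voxel), `"receptor"` (the cell's internalised ligand pool), `"contact"`
#' (number of touching neighbour cells).
#'
#' @param node the target input node name.
#' @param source one of `"substrate"`, `"receptor"`, `"contact"`.
#' @param threshold threshold in the source's units.
#' @param substrate substrate name (for `"substrate"` source).
#' @return object of class `input_rule`.
#' @export
input_rule <- function(node, source = c("substrate", "receptor", "contact"),
                       threshold, substrate = NULL) {
  source <- match.arg(source)
  structure(list(node = node, source = source, threshold = threshold,
                 substrate = substrate), class = "input_rule")
}

#' Output rule: network read-out to phenotype
#'
#' Actions: `"set_fate"` (commit to `fate`, latching — death fates are
#' irreversible), `"proliferation_gate"` (node = 1 keeps cycling enabled,
#' node = 0 arrests the cycle clock without killing), `"secrete"` (node = 1
#' switches on secretion of `substrate` at the strain's rate and latches the
#' cell's activated flag), `"adhesion_scale"` (adhesion coefficient is
#' `scale` while the node is active, 1 otherwise).
#'
#' @param node read-out node name.
#' @param action see above.
#' @param fate target fate for `"set_fate"`.
#' @param substrate substrate name for `"secrete"`.
#' @param scale adhesion coefficient for `"adhesion_scale"`.
#' @return object of class `output_rule`.
#' @export
output_rule <- function(node, action = c("set_fate", "proliferation_gate",
                                         "secrete", "adhesion_scale"),
                        fate = NULL, substrate = NULL, scale = 1) {
  action <- match.arg(action)
  if (action == "set_fate" && !fate %in% c("Apoptosis", "NonACD"))
    stop("set_fate output rules must target Apoptosis or NonACD", call. = FALSE)
  structure(list(node = node, action = action, fate = fate,
                 substrate = substrate, scale = scale),
            class = "output_rule")
}

#' Default output rules of the cell-fate model
#'
#' Apoptosis and NonACD read-outs latch the corresponding death fate;
#' Survival gates the cycle clock; NFkB switches autocrine TNF secretion
#' and latches the activated flag.
#'
#' @return list of [output_rule()].
#' @export
default_output_rules <- function() {
  list(output_rule("Apoptosis", "set_fate", fate = "Apoptosis"),
       output_rule("NonACD", "set_fate", fate = "NonACD"),
       output_rule("Survival", "proliferation_gate"),
       output_rule("NFkB", "secrete", substrate = "TNF"))
}

.check_rules <- function(net, input_rules, output_rules) {
  for (r in input_rules) {
    i <- net$index[[r$node]]
    if (is.null(i))
      stop("input rule targets unknown node '", r$node, "'", call. = FALSE)
    if (!net$is_input[i])
      stop("input rule targets node '", r$node,
           "', which is not an input node", call. = FALSE)
  }
  for (r in output_rules) {
    if (is.null(net$index[[r$node]]))
      stop("output rule reads unknown node '", r$node, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Synchronise network inputs from the microenvironment
#'
#' Applies every input rule to the given cells: the target input node is set
#' to 1 iff the source quantity exceeds the rule's threshold; all other node
#' values are untouched.  Rules on disjoint nodes commute.
#'
#' @param p a [cell_population()] with an attached network.
#' @param grid a [voxel_grid()] (needed for substrate rules).
#' @param rules list of [input_rule()].
#' @param rows row indices to update (default: all cells).
#' @return the population, invisibly.
#' @export
sync_inputs <- function(p, grid, rules, rows = NULL) {
  if (is.null(rows)) rows <- which(p$type == 0L)
  if (!length(rows) || !length(rules)) return(invisible(p))
  for (r in rules) {
    j <- p$network$index[[r$node]]
    val <- switch(r$source,
      substrate = sample_density(grid, r$substrate,
                                 cbind(p$x[rows], p$y[rows], p$z[rows])),
      receptor = p$internalised[rows],
      contact = .contact_counts(p, rows))
    p$net_states[rows, j] <- as.integer(val > r$threshold)
  }
  invisible(p)
}

.contact_counts <- function(p, rows) {
  cells <- which(p$type == 0L)
  vapply(rows, function(i) {
    d2 <- (p$x[cells] - p$x[i])^2 + (p$y[cells] - p$y[i])^2 +
      (p$z[cells] - p$z[i])^2
    sum(d2 < (p$radius[cells] + p$radius[i])^2) - 1L
  }, 1L)
}

#' Apply network read-outs to phenotype
#'
#' Death read-outs latch their fate; the proliferation gate arrests or
#' releases the cycle clock; secretion read-outs toggle the secreting flag
#' and latch the activated marker the first time they switch on.
#'
#' @inheritParams sync_inputs
#' @param rules list of [output_rule()].
#' @return the population, invisibly.
#' @export
apply_outputs <- function(p, rules, rows = NULL) {
  if (is.null(rows)) rows <- which(p$type == 0L)
  if (!length(rows) || !length(rules)) return(invisible(p))
  for (r in rules) {
    j <- p$network$index[[r$node]]
    on <- p$net_states[rows, j] == 1L
    switch(r$action,
      set_fate = {
        hit <- rows[on]
        if (length(hit)) set_fate(p, hit, r$fate)
      },
      proliferation_gate = {
        p$arrest[rows] <- !on
      },
      secrete = {
        p$secreting[rows] <- on & p$fate[rows] == .FATE_PROLIF
        p$activated[rows[on]] <- TRUE
      },
      adhesion_scale = {
        p$adhcoef[rows] <- ifelse(on, r$scale, 1)
      })
  }
  invisible(p)
}

#' Full simulation configuration
#'
#' Assembles and validates all ingredients of a coupled run.  Every
#' cross-reference is checked up front (strain overrides against network
#' nodes, rules against node flags, substrates against schedules) and a
#' named error is raised before t = 0 on any failure.
#'
#' @param strains list of [strain_params()].
#' @param positions data.frame with columns `type` ("cell"/"sphere"),
#'   `strain` (index), `x`, `y`, `z`, `radius` (used for spheres).
#' @param network optional `boolean_network`; per-strain `rate_overrides`
#'   are applied to per-strain copies.
#' @param substrates named list; each element a list with `D`, `decay`,
#'   optional `initial`, `diffusing`, `schedule` (an [injection_schedule()]).
#' @param bounds,dx,ndim domain geometry (see [voxel_grid()]).
#' @param input_rules,output_rules coupling rules; `output_rules = "default"`
#'   uses [default_output_rules()] filtered to nodes present in the network.
#' @param receptor optional receptor kinetics for a ligand substrate: list
#'   with `substrate`, `k_on`, `k_int`, `k_clear` (1/min).
#' @param oxygen optional oxygen coupling: list with `substrate` and
#'   `uptake` (1/min per cell).
#' @param clock a [clock_config()].
#' @param seed master seed (integer).
#' @param sphere_repulsion passive-sphere repulsion strength.
#' @param record_snapshots keep per-cell snapshots at every census time.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(strains, positions, network = NULL,
                       substrates = list(), bounds = c(-200, 200), dx = 20,
                       ndim = 3, input_rules = list(),
                       output_rules = "default", receptor = NULL,
                       oxygen = NULL, clock = clock_config(),
                       seed = 1, sphere_repulsion = 10,
                       record_snapshots = FALSE) {
  if (inherits(strains, "strain_params")) strains <- list(strains)
  need <- c("type", "strain", "x", "y")
  missing_cols <- setdiff(need, names(positions))
  if (length(missing_cols))
    stop("positions is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(positions$z)) positions$z <- 0
  if (is.null(positions$radius)) positions$radius <- NA_real_
  if (any(positions$strain > length(strains)))
    stop("positions reference strain index beyond the strain list", call. = FALSE)
  if (!is.null(network)) {
    for (s in strains) {
      for (ov in s$rate_overrides) {
        if (is.null(network$index[[ov$node]]))
          stop("strain '", s$name, "' overrides unknown node '", ov$node, "'",
               call. = FALSE)
      }
    }
    if (identical(output_rules, "default")) {
      output_rules <- Filter(function(r) !is.null(network$index[[r$node]]),
                             default_output_rules())
    }
    .check_rules(network, input_rules, output_rules)
  } else {
    if (identical(output_rules, "default")) output_rules <- list()
    if (length(input_rules))
      stop("input rules given but no network attached", call. = FALSE)
  }
  for (nm in names(substrates)) {
    s <- substrates[[nm]]
    if (is.null(s$D)) stop("substrate '", nm, "' has no D", call. = FALSE)
    if (is.null(s$decay)) substrates[[nm]]$decay <- 0
    if (is.null(s$initial)) substrates[[nm]]$initial <- 0
    if (is.null(s$diffusing)) substrates[[nm]]$diffusing <- TRUE
    if (is.null(s$schedule)) substrates[[nm]]$schedule <- injection_schedule("none")
  }
  for (r in input_rules) {
    if (r$source == "substrate" && !r$substrate %in% names(substrates))
      stop("input rule on node '", r$node, "' references unknown substrate '",
           r$substrate, "'", call. = FALSE)
  }
  if (!is.null(receptor) && !receptor$substrate %in% names(substrates))
    stop("receptor substrate '", receptor$substrate, "' not defined",
         call. = FALSE)
  if (!is.null(oxygen) && !oxygen$substrate %in% names(substrates))
    stop("oxygen substrate '", oxygen$substrate, "' not defined", call. = FALSE)
  structure(list(strains = strains, positions = positions, network = network,
                 substrates = substrates, bounds = bounds, dx = dx,
                 ndim = as.integer(ndim), input_rules = input_rules,
                 output_rules = output_rules, receptor = receptor,
                 oxygen = oxygen, clock = clock, seed = seed,
                 sphere_repulsion = sphere_repulsion,
                 record_snapshots = record_snapshots),
            class = "sim_config")
}

# per-strain networks with the strain's rate overrides applied
.strain_networks <- function(network, strains) {
  lapply(strains, function(s) {
    if (length(s$rate_overrides)) apply_overrides(network, s$rate_overrides)
    else network
  })
}

#' Run a coupled multi-scale simulation
#'
#' The main loop advances mechanics every `dt_mechanics` (forces, motion,
#' volume, cycle/division, oxygen check), the substrate fields every
#' `dt_diffusion` (injection rim, diffusion/decay, cell sources and sinks)
#' and each cell's Boolean network every `dt_signalling` (input sync,
#' Gillespie advance, read-out application).  Per-cell signalling phases are
#' staggered by a random fraction of `dt_signalling` fixed at birth
#' (`stagger = FALSE` synchronises them).  Fully reproducible given the
#' master seed.
#'
#' @param config a [sim_config()].
#' @param stagger stagger per-cell signalling updates (default TRUE).
#' @return object of class `simulation_output`: `population` (time series of
#'   counts per strain and fate, with cumulative committed-death and
#'   activated counts), `snapshots` (if recorded), `final` (the final
#'   [cell_population()]), `grid`, `initial_census` and `config`.
#' @export
run_simulation <- function(config, stagger = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  ck <- config$clock
  ndim <- config$ndim

  grid <- voxel_grid(config$bounds, config$dx, ndim)
  for (nm in names(config$substrates)) {
    s <- config$substrates[[nm]]
    add_substrate(grid, nm, D = s$D, decay = s$decay, diffusing = s$diffusing,
                  initial = s$initial)
  }

  pop <- cell_population(config$strains, network = config$network,
                         ndim = ndim, seed = config$seed)
  pos <- config$positions
  is_cell <- pos$type == "cell"
  if (any(is_cell))
    add_cells(pop, pos$x[is_cell], pos$y[is_cell], pos$z[is_cell],
              strain = pos$strain[is_cell])
  if (any(!is_cell))
    add_spheres(pop, pos$x[!is_cell], pos$y[!is_cell], pos$z[!is_cell],
                radius = ifelse(is.na(pos$radius[!is_cell]), 8.4,
                                pos$radius[!is_cell]))
  # initial signalling phases: stagger fraction was stored at birth
  pop$next_signal[pop$type == 0L] <-
    if (stagger) pop$next_signal[pop$type == 0L] * ck$dt_signalling else 0

  nets <- if (!is.null(config$network))
    .strain_networks(config$network, config$strains) else NULL
  has_net <- !is.null(nets)
  single_net <- has_net &&
    !any(vapply(config$strains, function(s) length(s$rate_overrides) > 0, TRUE))

  n_diff_sub <- max(1L, as.integer(round(ck$dt_mechanics / ck$dt_diffusion)))
  n_steps <- as.integer(round(ck$t_end / ck$dt_mechanics))
  snap_every <- max(1L, as.integer(round(ck$snapshot_interval / ck$dt_mechanics)))

  o2_thresholds_on <- any(vapply(config$strains,
    function(s) is.finite(s$oxygen_necrosis_threshold), TRUE))
  secretion_rates <- vapply(config$strains,
                            function(s) s$tnf_secretion_rate, 1.0)
  ecm_rates_on <- any(vapply(config$strains,
                             function(s) s$ecm_degrade_rate != 0, TRUE))

  # track the secretion read-out (NFkB) inside the Gillespie window so that
  # transient activation between sampling instants still sets the latch
  act_node <- -1L
  if (has_net) {
    sec_rules <- Filter(function(r) r$action == "secrete", config$output_rules)
    if (length(sec_rules))
      act_node <- config$network$index[[sec_rules[[1]]$node]] - 1L
  }

  ts_rows <- list()
  snapshots <- list()
  initial_census <- census(pop)

  record <- function(t) {
    cs <- census(pop)
    cs$t <- t
    ts_rows[[length(ts_rows) + 1L]] <<- cs
    if (config$record_snapshots) {
      cells <- pop$type == 0L
      snapshots[[sprintf("%g", t)]] <<- data.frame(
        id = pop$id, x = pop$x, y = pop$y, z = pop$z, radius = pop$radius,
        type = ifelse(cells, "cell", "sphere"),
        strain = pop$strain, fate = .FATE_LEVELS[pop$fate + 1L])
    }
  }
  record(0)

  for (step in seq_len(n_steps)) {
    t_prev <- (step - 1) * ck$dt_mechanics
    t <- step * ck$dt_mechanics

    ## --- microenvironment -------------------------------------------------
    for (nm in names(config$substrates)) {
      s <- config$substrates[[nm]]
      if (s$schedule$mode != "none") apply_injection(grid, nm, s$schedule, t_prev)
      if (s$diffusing && s$D + s$decay > 0)
        diffuse_decay(grid, nm, ck$dt_diffusion, nsub = n_diff_sub)
    }

    cells <- which(pop$type == 0L)

    ## receptor ligand binding / internalisation
    if (!is.null(config$receptor) && length(cells)) {
      receptor_update_population(pop, grid, config$receptor, ck$dt_mechanics,
                                 rows = cells)
    }

    ## oxygen uptake
    if (!is.null(config$oxygen) && length(cells)) {
      live <- cells[pop$fate[cells] == .FATE_PROLIF]
      if (length(live))
        apply_sources_sinks(grid, config$oxygen$substrate,
                            cbind(pop$x[live], pop$y[live], pop$z[live]),
                            secretion = 0, uptake = config$oxygen$uptake,
                            saturation = 0, dt = ck$dt_mechanics)
    }

    ## autocrine secretion
    if (!is.null(config$receptor) && length(cells)) {
      sec <- cells[pop$secreting[cells]]
      if (length(sec))
        secretion_update(pop, grid, config$receptor$substrate,
                         secretion_rates, ck$dt_mechanics, rows = sec)
    }

    ## --- mechanics --------------------------------------------------------
    if (length(pop$id)) {
      Fm <- update_polarity_motility(pop, ck$dt_mechanics)
      Fi <- compute_forces(pop, "hash", config$sphere_repulsion)
      integrate_motion(pop, Fi, Fm, ck$dt_mechanics)
      update_volume(pop, ck$dt_mechanics)
      cycle_and_divide(pop, ck$dt_mechanics, ck$dt_signalling, t)
      if (ecm_rates_on) degrade_passive_spheres(pop, ck$dt_mechanics)
      if (o2_thresholds_on && !is.null(config$oxygen)) {
        cells <- which(pop$type == 0L)
        o2 <- sample_density(grid, config$oxygen$substrate,
                             cbind(pop$x, pop$y, pop$z))
        oxygen_death_check(pop, o2)
      }
    }

    ## --- signalling -------------------------------------------------------
    if (has_net) {
      due <- which(pop$type == 0L & pop$fate == .FATE_PROLIF &
                   pop$next_signal <= t + 1e-9)
      if (length(due)) {
        sync_inputs(pop, grid, config$input_rules, rows = due)
        if (single_net) {
          net <- nets[[1]]
          ever <- cpp_advance_cells(net$flat$code, net$flat$off, net$flat$len,
                                    net$rate_up, net$rate_down,
                                    as.integer(net$is_input),
                                    pop$net_states, pop$rng, due,
                                    ck$dt_signalling, act_node)
          pop$activated[due] <- pop$activated[due] | ever
        } else {
          for (s in unique(pop$strain[due])) {
            net <- nets[[s]]
            rows_s <- due[pop$strain[due] == s]
            ever <- cpp_advance_cells(net$flat$code, net$flat$off, net$flat$len,
                                      net$rate_up, net$rate_down,
                                      as.integer(net$is_input),
                                      pop$net_states, pop$rng, rows_s,
                                      ck$dt_signalling, act_node)
            pop$activated[rows_s] <- pop$activated[rows_s] | ever
          }
        }
        apply_outputs(pop, config$output_rules, rows = due)
        pop$next_signal[due] <- pop$next_signal[due] + ck$dt_signalling
      }
    }

    if (step %% snap_every == 0L) record(t)
  }
  if (n_steps %% snap_every != 0L) record(n_steps * ck$dt_mechanics)

  out <- list(population = do.call(rbind, ts_rows), snapshots = snapshots,
              final = pop, grid = grid, initial_census = initial_census,
              config = config)
  class(out) <- "simulation_output"
  out
}

#' @export
print.simulation_output <- function(x, ...) {
  tmax <- max(x$population$t)
  cat("simulation_output: t_end =", tmax, "min,",
      length(unique(x$population$t)), "census times\n")
  fin <- x$population[x$population$t == tmax, ]
  tot <- aggregate(count ~ fate, fin, sum)
  cat("final counts:", paste(tot$fate, tot$count, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.simulation_output <- function(object, ...) {
  pop <- object$population
  tmax <- max(pop$t)
  ini <- sum(pop$count[pop$t == 0])
  fin <- sum(pop$count[pop$t == tmax])
  committed <- pop[pop$t == tmax & pop$fate != "Proliferative", ]
  structure(list(t_end = tmax, initial_count = ini, final_count = fin,
                 fold_change = fin / ini,
                 committed_apoptosis = sum(committed$committed[
                   committed$fate == "Apoptosis"]),
                 committed_nonacd = sum(committed$committed[
                   committed$fate == "NonACD"])),
            class = "summary.simulation_output")
}

#' @export
print.summary.simulation_output <- function(x, ...) {
  cat("t_end:", x$t_end, "min\n")
  cat("cells:", x$initial_count, "->", x$final_count,
      sprintf("(%.2f-fold)\n", x$fold_change))
  cat("cumulative committed: Apoptosis", x$committed_apoptosis,
      "| NonACD", x$committed_nonacd, "\n")
  invisible(x)
}

#' @export
plot.simulation_output <- function(x, ...) {
  pop <- aggregate(count ~ t + fate, x$population, sum)
  cols <- c(Proliferative = "forestgreen", Apoptosis = "red2", NonACD = "black")
  plot(range(pop$t), range(pop$count), type = "n",
       xlab = "time (min)", ylab = "cells", ...)
  for (f in names(cols)) {
    d <- pop[pop$fate == f, ]
    graphics::lines(d$t, d$count, col = cols[[f]], lwd = 2)
  }
  graphics::legend("topleft", legend = names(cols), col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Write simulation outputs as CSV
#'
#' Writes `population.csv` (t, strain, fate, count, committed, activated)
#' and, when snapshots were recorded, one `snapshot_<t>.csv` per census time
#' (id, x, y, z, radius, type, strain, fate).
#'
#' @param out a `simulation_output`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation_csv <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop <- out$population
  pop <- pop[, c("t", "strain_name", "fate", "count", "committed", "activated")]
  names(pop)[2] <- "strain"
  write.csv(pop, file.path(dir, "population.csv"), row.names = FALSE,
            quote = FALSE)
  for (nm in names(out$snapshots)) {
    write.csv(out$snapshots[[nm]],
              file.path(dir, paste0("snapshot_", nm, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
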