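# Scripted, seedable population experiments: monolayer dose-response,
# spheroid treatment regimes, heterogeneous clone mixtures and
# differential-adhesion cell sorting, plus the Hill-response analysis.
# Radii and horizons default to desk scale (minutes of CPU); the published
# geometries (400 um disk, 100-200 um spheroids) are reached by passing the
# corresponding radius.

# default substrate physics (calibrated reconstructions; see the vignette)
.TNF_D <- 1200        # um^2/min
.TNF_DECAY <- 0.0275  # 1/min
.O2_D <- 6000         # um^2/min
.O2_BOUNDARY <- 38    # mmHg
.O2_THRESHOLD <- 5    # mmHg
.O2_UPTAKE <- 10      # 1/min per cell

.tnf_substrate <- function(schedule) {
  list(TNF = list(D = .TNF_D, decay = .TNF_DECAY, initial = 0,
                  schedule = schedule))
}

.monolayer_strain <- function(...) {
  strain_params(name = "WT", cycle_duration = 970, tnf_secretion_rate = 0.05,
                ...)
}

# spheroid experiments use a faster-cycling line (untreated 24 h growth
# is ~4.5-fold)
.spheroid_strain <- function(name = "WT", ...) {
  strain_params(name = name, cycle_duration = 600, volume_growth_rate = 0.008,
                tnf_secretion_rate = 0.05, ...)
}

.tnf_input_rules <- function(receptor) {
  list(input_rule("TNF", source = "receptor", threshold = receptor$theta))
}

#' Dose-response point
#'
#' @param concentration ng/mL.
#' @param duration injection duration, min.
#' @param activated_fraction fraction of ever-NFkB-active cells.
#' @return data.frame row with the stimulus area in ng s/mL
#'   (concentration x duration x 60).
#' @export
dose_response_point <- function(concentration, duration, activated_fraction) {
  data.frame(concentration = concentration, duration = duration,
             stimulus_area = concentration * duration * 60,
             activated_fraction = activated_fraction)
}

#' Monolayer TNF pulse experiment
#'
#' A 2D disk of proliferative cells receives a single TNF pulse (`dose`
#' ng/mL for `duration` min) through the medium rim; the run records the
#' per-fate time series, the ever-activated fraction at the horizon
#' (relative to the initial viable count) and the fraction of cells that
#' committed to Apoptosis without ever activating NFkB.
#'
#' @param dose ng/mL (0 = untreated control).
#' @param duration pulse duration, min.
#' @param seed master seed.
#' @param radius initial disk radius, um (published geometry: 400).
#' @param t_end horizon, min (default 8 h).
#' @param transcription_rate_scale passed to [build_cell_fate_network()].
#' @param clock optional [clock_config()] override.
#' @return list with `output` (a `simulation_output`), `point` (a
#'   [dose_response_point()]) and `summary` (activated fraction, death
#'   fractions, apoptosis-without-NFkB fraction).
#' @export
scenario_monolayer <- function(dose, duration, seed = 1, radius = 100,
                               t_end = 480, transcription_rate_scale = 0.2,
                               clock = NULL) {
  net <- build_cell_fate_network(transcription_rate_scale)
  receptor <- tnf_receptor_params()
  sched <- if (dose > 0) {
    injection_schedule("stop_at", concentration = dose, switch_time = duration)
  } else injection_schedule("none")
  margin <- 3 * 20
  geom <- geometry_spec("disk", radius = radius)
  positions <- generate_initial_positions(geom, seed = seed)
  cfg <- sim_config(
    strains = .monolayer_strain(),
    positions = positions, network = net,
    substrates = .tnf_substrate(sched),
    bounds = c(-(radius + margin), radius + margin), dx = 20, ndim = 2,
    input_rules = .tnf_input_rules(receptor),
    receptor = receptor,
    clock = clock %||% clock_config(dt_diffusion = 0.05, dt_mechanics = 0.1,
                                    dt_signalling = 10, t_end = t_end),
    seed = seed)
  out <- run_simulation(cfg)
  n0 <- sum(cfg$positions$type == "cell")
  act <- activation_census(out$final, n0)
  apop_no_nfkb <- sum(out$final$committed_unactivated[, "Apoptosis"]) / n0
  death_frac <- sum(out$final$committed) / n0
  list(output = out,
       point = dose_response_point(dose, duration, act),
       summary = list(initial = n0, activated_fraction = act,
                      apoptosis_without_nfkb_fraction = apop_no_nfkb,
                      death_committed_fraction = death_frac))
}

#' Monolayer dose-response sweep
#'
#' Runs [scenario_monolayer()] over a grid of doses and durations and
#' returns the dose-response table for [fit_hill()].
#'
#' @param doses,durations vectors (combined elementwise after recycling to
#'   a full grid).
#' @inheritParams scenario_monolayer
#' @return data.frame of [dose_response_point()] rows.
#' @export
dose_response_sweep <- function(doses, durations, seed = 1, radius = 100,
                                t_end = 480) {
  grid <- expand.grid(dose = doses, duration = durations)
  pts <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- scenario_monolayer(grid$dose[i], grid$duration[i],
                             seed = seed + i, radius = radius, t_end = t_end)
    sc$point
  })
  do.call(rbind, pts)
}

#' Spheroid TNF treatment regimes
#'
#' 3D spheroid under one of the injection regimes: `"none"`, `"continuous"`
#' (0.5 ng/mL), `"stop_at"` (0.5 ng/mL stopped at 600 min), `"step_up"`
#' (0.5 to 5 ng/mL at 600 min) or `"pulsed"` (0.5 ng/mL for 10 min every
#' `period` min).
#'
#' @param regime regime name.
#' @param seed master seed.
#' @param radius initial spheroid radius, um (published geometry: 100).
#' @param t_end horizon, min (default 24 h).
#' @param concentration base TNF dose, ng/mL.
#' @param period pulse period, min (150 or 600 in the published runs).
#' @param pulse_duration pulse length, min.
#' @param transcription_rate_scale passed to [build_cell_fate_network()].
#' @param clock optional [clock_config()] override.
#' @return a `simulation_output` with a `scenario` summary attribute:
#'   fold change, committed death fraction of the initial population.
#' @export
scenario_spheroid <- function(regime = c("none", "continuous", "stop_at",
                                         "step_up", "pulsed"),
                              seed = 1, radius = 50, t_end = 1440,
                              concentration = 0.5, period = 150,
                              pulse_duration = 10,
                              transcription_rate_scale = 0.2, clock = NULL) {
  regime <- match.arg(regime)
  sched <- switch(regime,
    none = injection_schedule("none"),
    continuous = injection_schedule("continuous", concentration),
    stop_at = injection_schedule("stop_at", concentration, switch_time = 600),
    step_up = injection_schedule("step_change", concentration,
                                 switch_time = 600,
                                 new_concentration = 10 * concentration),
    pulsed = injection_schedule("pulsed", concentration,
                                pulse_duration = pulse_duration,
                                period = period))
  net <- build_cell_fate_network(transcription_rate_scale)
  receptor <- tnf_receptor_params()
  margin <- 3 * 20
  geom <- geometry_spec("sphere", radius = radius)
  positions <- generate_initial_positions(geom, seed = seed)
  cfg <- sim_config(
    strains = .spheroid_strain(),
    positions = positions, network = net,
    substrates = .tnf_substrate(sched),
    bounds = c(-(radius + margin), radius + margin), dx = 20, ndim = 3,
    input_rules = .tnf_input_rules(receptor),
    receptor = receptor,
    clock = clock %||% clock_config(dt_diffusion = 0.05, dt_mechanics = 0.1,
                                    dt_signalling = 10, t_end = t_end),
    seed = seed)
  out <- run_simulation(cfg)
  n0 <- sum(cfg$positions$type == "cell")
  nT <- sum(out$population$count[out$population$t == max(out$population$t)])
  out$scenario <- list(regime = regime, initial = n0, final = nT,
                       fold_change = nT / n0,
                       death_committed_fraction = sum(out$final$committed) / n0)
  out
}

#' Heterogeneous spheroid: wild type mixed with a resistant clone
#'
#' A 3D spheroid initialised from a uniform-random mixture of wild-type
#' cells and a mutant strain (by default IKK and cFLIP over-expressed, which
#' drastically promotes survival) under continuous 0.5 ng/mL TNF.  With
#' `oxygen_enabled` the oxygen field, per-cell uptake and the
#' oxygen-threshold necrosis check are added, so the strains additionally
#' compete for oxygen.
#'
#' @param fractions numeric(2): (WT, mutant) fractions summing to 1.
#' @param oxygen_enabled logical.
#' @param seed master seed.
#' @param radius initial spheroid radius, um (published geometry: 200).
#' @param t_end horizon, min.
#' @param mutant_overrides list of [rate_override()] defining the clone
#'   (default: `overexpress("IKK")`, `overexpress("cFLIP")`).
#' @param tnf logical: apply the continuous TNF injection.
#' @param clock optional [clock_config()] override.
#' @return a `simulation_output` with a per-strain `scenario` summary.
#' @export
scenario_heterogeneous <- function(fractions = c(0.75, 0.25),
                                   oxygen_enabled = FALSE, seed = 1,
                                   radius = 50, t_end = 1440,
                                   mutant_overrides = list(
                                     overexpress("IKK"), overexpress("cFLIP")),
                                   tnf = TRUE, clock = NULL) {
  stopifnot(abs(sum(fractions) - 1) < 1e-6, length(fractions) == 2)
  net <- build_cell_fate_network()
  receptor <- tnf_receptor_params()
  thr <- if (oxygen_enabled) .O2_THRESHOLD else -Inf
  strains <- list(
    .spheroid_strain("WT", oxygen_necrosis_threshold = thr),
    .spheroid_strain("mutant", oxygen_necrosis_threshold = thr))
  strains[[2]]$rate_overrides <- mutant_overrides
  geom <- geometry_spec("sphere", radius = radius)
  positions <- generate_initial_positions(geom, seed = seed)
  positions <- assign_strains(positions, fractions, seed = seed)
  sched <- if (tnf) injection_schedule("continuous", 0.5)
           else injection_schedule("none")
  substrates <- .tnf_substrate(sched)
  oxygen <- NULL
  if (oxygen_enabled) {
    substrates$oxygen <- list(D = .O2_D, decay = 0, initial = .O2_BOUNDARY,
                              schedule = injection_schedule("continuous",
                                                            .O2_BOUNDARY))
    oxygen <- list(substrate = "oxygen", uptake = .O2_UPTAKE)
  }
  margin <- 3 * 20
  cfg <- sim_config(
    strains = strains, positions = positions, network = net,
    substrates = substrates,
    bounds = c(-(radius + margin), radius + margin), dx = 20, ndim = 3,
    input_rules = .tnf_input_rules(receptor),
    receptor = receptor, oxygen = oxygen,
    clock = clock %||% clock_config(dt_diffusion = 0.05, dt_mechanics = 0.1,
                                    dt_signalling = 10, t_end = t_end),
    seed = seed)
  out <- run_simulation(cfg)
  pos <- cfg$positions
  n0 <- c(sum(pos$type == "cell" & pos$strain == 1),
          sum(pos$type == "cell" & pos$strain == 2))
  pop <- out$population
  tmax <- max(pop$t)
  fin <- pop[pop$t == tmax, ]
  surv <- vapply(1:2, function(s)
    sum(fin$count[fin$strain == s & fin$fate == "Proliferative"]), 1)
  out$scenario <- list(
    initial = n0,
    final_proliferative = surv,
    surviving_ratio = surv / pmax(n0, 1),
    committed = out$final$committed,
    oxygen_enabled = oxygen_enabled)
  out
}

#' Differential-adhesion cell sorting
#'
#' Two motile strains, one forming strong homotypic junctions and one weakly
#' adhesive, start uniformly mixed in a disk surrounded by a ring of passive
#' ECM spheres.  After the run the mean radial position of each strain is
#' reported; with differential adhesion the strongly adhesive strain ends up
#' interior.
#'
#' @param seed master seed.
#' @param radius initial disk radius, um.
#' @param t_end horizon, min (default 24 h).
#' @param adhesion_strong,adhesion_weak homotypic adhesion strengths.
#' @param strong_matrix_adhesion matrix adhesion of the strong strain (the
#'   variant where only that strain can attach to the ECM).
#' @param speed motility speed, um/min.
#' @param clock optional [clock_config()] override.
#' @return a `simulation_output` with `scenario$mean_radius` per strain.
#' @export
scenario_sorting <- function(seed = 1, radius = 60, t_end = 1440,
                             adhesion_strong = 8, adhesion_weak = 1,
                             strong_matrix_adhesion = 0, speed = 1,
                             clock = NULL) {
  strains <- list(
    strain_params("strong", adhesion_homotypic = adhesion_strong,
                  adhesion_heterotypic = adhesion_weak,
                  adhesion_matrix = strong_matrix_adhesion,
                  motility_speed = speed, persistence_time = 5,
                  cycle_duration = 1e9),
    strain_params("weak", adhesion_homotypic = adhesion_weak,
                  adhesion_heterotypic = adhesion_weak,
                  motility_speed = speed, persistence_time = 5,
                  cycle_duration = 1e9))
  geom <- geometry_spec("disk", radius = radius)
  positions <- generate_initial_positions(geom, seed = seed)
  positions <- assign_strains(positions, c(0.5, 0.5), seed = seed)
  # ECM ring: two shells of passive spheres around the disk
  ring <- do.call(rbind, lapply(c(radius + 12, radius + 26), function(rr) {
    nth <- max(8, floor(2 * pi * rr / 15))
    th <- 2 * pi * (seq_len(nth) - 1) / nth
    data.frame(type = "sphere", strain = 1L, x = rr * cos(th),
               y = rr * sin(th), z = 0, radius = 8)
  }))
  positions <- rbind(positions, ring)
  cfg <- sim_config(
    strains = strains, positions = positions, network = NULL,
    substrates = list(),
    bounds = c(-(radius + 60), radius + 60), dx = 20, ndim = 2,
    clock = clock %||% clock_config(dt_diffusion = 0.1, dt_mechanics = 0.1,
                                    dt_signalling = 10, t_end = t_end),
    seed = seed)
  out <- run_simulation(cfg)
  p <- out$final
  cells <- p$type == 0L
  r <- sqrt(p$x^2 + p$y^2)
  out$scenario <- list(mean_radius = c(
    strong = mean(r[cells & p$strain == 1L]),
    weak = mean(r[cells & p$strain == 2L])))
  out
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of `fraction = plateau * A^n / (K^n + A^n)` over the
#' stimulus area `A`: a fixed multi-start grid over `(n, K)` with the
#' plateau profiled in closed form, followed by Nelder-Mead refinement.
#' Deterministic given the points.
#'
#' @param points data.frame with columns `stimulus_area` and
#'   `activated_fraction` (at least 4 points spanning the transition).
#' @return object of class `hill_fit` with elements `coefficient` (n),
#'   `half_max` (K), `plateau` and `residual`.
#' @export
fit_hill <- function(points) {
  A <- points$stimulus_area
  y <- points$activated_fraction
  if (length(A) < 4) stop("fit_hill needs at least 4 points", call. = FALSE)
  if (max(y) - min(y) < 1e-12)
    stop("degenerate dose-response: all fractions equal", call. = FALSE)
  Apos <- A[A > 0]
  sse <- function(n, K) {
    g <- ifelse(A > 0, A^n / (K^n + A^n), 0)
    plateau <- sum(y * g) / max(sum(g^2), 1e-300)
    c(sum((y - plateau * g)^2), plateau)
  }
  best <- c(Inf, NA, NA, NA)
  for (n in c(0.5, 1, 1.5, 2, 3, 4, 4.8, 6, 8)) {
    for (K in exp(seq(log(min(Apos) / 2), log(max(Apos) * 2), length.out = 25))) {
      v <- sse(n, K)
      if (v[1] < best[1]) best <- c(v[1], n, K, v[2])
    }
  }
  refine <- optim(log(best[2:3]), function(par) {
    sse(exp(par[1]), exp(par[2]))[1]
  }, method = "Nelder-Mead",
  control = list(maxit = 500, reltol = 1e-12))
  n <- exp(refine$par[1]); K <- exp(refine$par[2])
  v <- sse(n, K)
  structure(list(coefficient = n, half_max = K, plateau = v[2],
                 residual = v[1], points = points),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit: coefficient n = %.3f, half-max K = %.1f ng s/mL, plateau = %.3f (SSE %.4g)\n",
    x$coefficient, x$half_max, x$plateau, x$residual))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(coefficient = object$coefficient, half_max = object$half_max,
    plateau = object$plateau)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  A <- if (is.null(newdata)) object$points$stimulus_area
       else if (is.data.frame(newdata)) newdata$stimulus_area else newdata
  ifelse(A > 0,
         object$plateau * A^object$coefficient /
           (object$half_max^object$coefficient + A^object$coefficient), 0)
}

#' Unconstrained growth and population doubling time
#'
#' Seeds well-spaced proliferative cells in 2D, runs without TNF and fits an
#' exponential to the live-cell time series.
#'
#' @param n0 initial cell count.
#' @param t_end horizon, min.
#' @param seed master seed.
#' @param spacing initial grid spacing, um.
#' @param clock optional [clock_config()] override.
#' @return list with `doubling_time_h`, the count time series and the
#'   `simulation_output`.
#' @export
scenario_growth <- function(n0 = 50, t_end = 2880, seed = 1, spacing = 60,
                            clock = NULL) {
  side <- ceiling(sqrt(n0))
  ix <- (seq_len(n0) - 1) %% side
  iy <- (seq_len(n0) - 1) %/% side
  positions <- data.frame(type = "cell", strain = 1L,
                          x = (ix - (side - 1) / 2) * spacing,
                          y = (iy - (side - 1) / 2) * spacing,
                          z = 0, radius = 8.4)
  half <- side * spacing / 2 + 100
  cfg <- sim_config(
    strains = .monolayer_strain(), positions = positions,
    network = NULL, substrates = list(),
    bounds = c(-half, half), dx = 20, ndim = 2,
    clock = clock %||% clock_config(dt_diffusion = 0.1, dt_mechanics = 0.1,
                                    dt_signalling = 10, t_end = t_end,
                                    snapshot_interval = 120),
    seed = seed)
  out <- run_simulation(cfg)
  counts <- aggregate(count ~ t, out$population, sum)
  fit <- lm(log(count) ~ t, data = counts)
  dt_h <- log(2) / coef(fit)[["t"]] / 60
  list(doubling_time_h = dt_h, counts = counts, output = out)
}
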