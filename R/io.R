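# Geometry generation, initial-condition files, SVG snapshots and the
# master YAML configuration loader.

#' Initial-condition geometry specification
#'
#' @param shape one of `"disk"`, `"sphere"`, `"rectangle"`, `"cylinder"`,
#'   `"from_image"`.
#' @param radius disk/sphere/cylinder radius, micrometres.
#' @param extent numeric(2 or 3) rectangle edge lengths, micrometres.
#' @param height cylinder height, micrometres.
#' @param cell_radius cell radius used for lattice spacing.
#' @param packing packing fraction; defaults 0.80 (2D) / 0.64 (3D), capped
#'   at the hexagonal/HCP maxima 0.9069 / 0.7405.
#' @param image binary matrix (TRUE/1 = seeded area) or path to a PNG file,
#'   for `"from_image"`.
#' @param pixel_size micrometres per image pixel.
#' @return object of class `geometry_spec`.
#' @export
geometry_spec <- function(shape = c("disk", "sphere", "rectangle", "cylinder",
                                    "from_image"),
                          radius = 100, extent = c(100, 100), height = 100,
                          cell_radius = 8.4, packing = NULL, image = NULL,
                          pixel_size = 10) {
  shape <- match.arg(shape)
  ndim <- if (shape %in% c("disk", "from_image") ||
              (shape == "rectangle" && length(extent) == 2)) 2L else 3L
  if (is.null(packing)) packing <- if (ndim == 2L) 0.80 else 0.64
  maxp <- if (ndim == 2L) pi / (2 * sqrt(3)) else pi / (3 * sqrt(2))
  if (packing <= 0 || packing > maxp + 1e-9)
    stop("packing fraction must be in (0, ", round(maxp, 4), "] for ",
         ndim, "D", call. = FALSE)
  if (shape == "from_image" && is.null(image))
    stop("from_image geometry needs an image", call. = FALSE)
  structure(list(shape = shape, radius = radius, extent = extent,
                 height = height, cell_radius = cell_radius,
                 packing = packing, image = image, pixel_size = pixel_size,
                 ndim = ndim),
            class = "geometry_spec")
}

# lattice sites of a hexagonal (2D) / HCP (3D) packing covering a box
.lattice_sites <- function(spacing, lo, hi, ndim) {
  if (ndim == 2L) {
    dy <- spacing * sqrt(3) / 2
    js <- seq(floor(lo[2] / dy), ceiling(hi[2] / dy))
    out <- lapply(js, function(j) {
      offx <- if (j %% 2 == 0) 0 else spacing / 2
      is <- seq(floor((lo[1] - offx) / spacing),
                ceiling((hi[1] - offx) / spacing))
      cbind(is * spacing + offx, j * dy, 0)
    })
    do.call(rbind, out)
  } else {
    dy <- spacing * sqrt(3) / 2
    dz <- spacing * sqrt(6) / 3
    ks <- seq(floor(lo[3] / dz), ceiling(hi[3] / dz))
    out <- lapply(ks, function(k) {
      offs <- if (k %% 2 == 0) c(0, 0) else c(spacing / 2, dy / 3)
      js <- seq(floor((lo[2] - offs[2]) / dy), ceiling((hi[2] - offs[2]) / dy))
      lay <- lapply(js, function(j) {
        offx <- offs[1] + if (j %% 2 == 0) 0 else spacing / 2
        is <- seq(floor((lo[1] - offx) / spacing),
                  ceiling((hi[1] - offx) / spacing))
        cbind(is * spacing + offx, j * dy + offs[2], k * dz)
      })
      do.call(rbind, lay)
    })
    do.call(rbind, out)
  }
}

#' Generate initial cell positions
#'
#' Fills the requested shape with a hexagonal (2D) or hexagonal-close-packed
#' (3D) lattice whose spacing realises the requested packing fraction, then
#' jitters every site by at most 5% of the spacing.  Deterministic given the
#' spec and seed.
#'
#' @param spec a [geometry_spec()].
#' @param seed integer seed for the jitter.
#' @param strain strain index assigned to all records.
#' @return data.frame with columns `type`, `strain`, `x`, `y`, `z`,
#'   `radius`, suitable as the `positions` slot of [sim_config()] and for
#'   [write_positions()].
#' @export
generate_initial_positions <- function(spec, seed = 1, strain = 1L) {
  stopifnot(inherits(spec, "geometry_spec"))
  a <- spec$cell_radius
  ndim <- spec$ndim
  if (ndim == 2L) {
    # site area = sqrt(3)/2 s^2; packing = pi a^2 / site area
    s <- sqrt(2 * pi * a^2 / (sqrt(3) * spec$packing))
  } else {
    # site volume = s^3 / sqrt(2); packing = (4/3) pi a^3 / site volume
    s <- (sqrt(2) * (4 / 3) * pi * a^3 / spec$packing)^(1 / 3)
  }
  box <- switch(spec$shape,
    disk = ,
    sphere = ,
    cylinder = {
      r <- spec$radius
      h <- if (spec$shape == "cylinder") spec$height / 2 else r
      list(lo = c(-r, -r, -h), hi = c(r, r, h))
    },
    rectangle = {
      e <- c(spec$extent, 0)[1:3] / 2
      list(lo = -e, hi = e)
    },
    from_image = {
      img <- .load_binary_image(spec$image)
      w <- ncol(img) * spec$pixel_size
      h <- nrow(img) * spec$pixel_size
      list(lo = c(0, 0, 0), hi = c(w, h, 0))
    })
  sites <- .lattice_sites(s, box$lo, box$hi, ndim)
  keep <- switch(spec$shape,
    disk = sqrt(sites[, 1]^2 + sites[, 2]^2) <= spec$radius,
    sphere = sqrt(rowSums(sites^2)) <= spec$radius,
    cylinder = sqrt(sites[, 1]^2 + sites[, 2]^2) <= spec$radius &
      abs(sites[, 3]) <= spec$height / 2,
    rectangle = {
      e <- c(spec$extent, 0)[1:3] / 2
      ok <- abs(sites[, 1]) <= e[1] & abs(sites[, 2]) <= e[2]
      if (ndim == 3L) ok <- ok & abs(sites[, 3]) <= e[3]
      ok
    },
    from_image = {
      img <- .load_binary_image(spec$image)
      px <- pmin(pmax(floor(sites[, 1] / spec$pixel_size) + 1, 1), ncol(img))
      py <- pmin(pmax(floor(sites[, 2] / spec$pixel_size) + 1, 1), nrow(img))
      inside <- sites[, 1] >= 0 & sites[, 1] <= ncol(img) * spec$pixel_size &
        sites[, 2] >= 0 & sites[, 2] <= nrow(img) * spec$pixel_size
      inside & img[cbind(py, px)]
    })
  sites <- sites[keep, , drop = FALSE]
  if (!nrow(sites))
    stop("geometry produced no cell positions (shape smaller than one cell?)",
         call. = FALSE)
  rng <- bc_rng(seed, 971L)
  jit <- matrix(rng_unif(rng, nrow(sites) * 3) * 2 - 1, ncol = 3) * 0.05 * s
  if (ndim == 2L) jit[, 3] <- 0
  sites <- sites + jit
  data.frame(type = "cell", strain = as.integer(strain),
             x = sites[, 1], y = sites[, 2], z = sites[, 3],
             radius = a)
}

.load_binary_image <- function(image) {
  if (is.matrix(image)) return(image > 0.5)
  if (!file.exists(image))
    stop("image file not readable: ", image, call. = FALSE)
  if (!requireNamespace("png", quietly = TRUE))
    stop("reading PNG images requires the png package", call. = FALSE)
  img <- png::readPNG(image)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write / read an initial-condition position file
#'
#' Plain text, one record per line: `type strain x y z radius`, with a
#' header comment stating the units.  Round-trips exactly.
#'
#' @param positions data.frame as produced by
#'   [generate_initial_positions()].
#' @param path file path.
#' @export
write_positions <- function(positions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# boolcell initial conditions",
               "# type strain x y z radius   (positions and radii in um)"),
             con)
  write.table(format(positions[, c("type", "strain", "x", "y", "z", "radius")],
                     digits = 17, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_positions
#' @return `read_positions`: the positions data.frame.
#' @export
read_positions <- function(path) {
  df <- read.table(path, comment.char = "#", col.names =
                     c("type", "strain", "x", "y", "z", "radius"),
                   colClasses = c("character", "integer", "numeric",
                                  "numeric", "numeric", "numeric"))
  df
}

# fate colour legend: green proliferative, red apoptosis, black NonACD
.FATE_COLOURS <- c(Proliferative = "#2ca02c", Apoptosis = "#d62728",
                   NonACD = "#000000")
.STRAIN_PALETTE <- c("#ff7f0e", "#9467bd", "#1f77b4", "#8c564b", "#e377c2")

#' Write an SVG snapshot of a population
#'
#' One radius-true circle per agent (micrometre scale); cells coloured by
#' fate (green/red/black) or by strain (orange, purple, ...); passive
#' spheres light grey.
#'
#' @param p a [cell_population()] or a snapshot data.frame with columns
#'   x, y, radius, type, strain, fate.
#' @param path output file.
#' @param mode `"by_fate"` or `"by_strain"`.
#' @param bounds plot window, micrometres (default: fits the agents).
#' @return the path, invisibly.
#' @export
write_svg_snapshot <- function(p, path, mode = c("by_fate", "by_strain"),
                               bounds = NULL) {
  mode <- match.arg(mode)
  if (inherits(p, "cell_population")) {
    df <- data.frame(x = p$x, y = p$y, radius = p$radius,
                     type = ifelse(p$type == 0L, "cell", "sphere"),
                     strain = p$strain, fate = .FATE_LEVELS[p$fate + 1L])
  } else df <- p
  if (is.null(bounds)) {
    bounds <- if (nrow(df)) c(min(df$x - df$radius), max(df$x + df$radius),
                              min(df$y - df$radius), max(df$y + df$radius))
    else c(-100, 100, -100, 100)
  }
  w <- bounds[2] - bounds[1]; h <- bounds[4] - bounds[3]
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot write SVG to '", path, "'", call. = FALSE)
  on.exit(close(con))
  writeLines(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="%g" viewBox="%g %g %g %g">',
    w, h, bounds[1], bounds[3], w, h), con)
  writeLines(sprintf('<rect x="%g" y="%g" width="%g" height="%g" fill="white"/>',
                     bounds[1], bounds[3], w, h), con)
  if (nrow(df)) {
    fill <- ifelse(df$type == "sphere", "#d0d0d0",
                   if (mode == "by_fate") .FATE_COLOURS[df$fate]
                   else .STRAIN_PALETTE[(df$strain - 1) %%
                                        length(.STRAIN_PALETTE) + 1])
    writeLines(sprintf('<circle cx="%.3f" cy="%.3f" r="%.3f" fill="%s"/>',
                       df$x, df$y, df$radius, fill), con)
  }
  writeLines("</svg>", con)
  invisible(path)
}

#' Load a full simulation configuration from a YAML file
#'
#' The file names the network model/config files, substrates and injection
#' schedules, strains (with mutations as node rate overrides), initial
#' geometry or a positions file, coupling rules, clock and seed; every unset
#' key falls back to a documented default and every failed cross-validation
#' names the offending key.  The effective configuration is echoed to the
#' log (message stream) so a run can be reproduced from its log.
#'
#' @param path YAML file path.
#' @param quiet suppress the config echo.
#' @return a validated [sim_config()].
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(f) if (file.exists(f)) f else file.path(base, f)

  network <- NULL
  if (!is.null(y$network)) {
    if (!is.null(y$network$builtin)) {
      network <- build_cell_fate_network(
        transcription_rate_scale = y$network$transcription_rate_scale %||% 0.2)
    } else {
      if (is.null(y$network$model))
        stop("config key 'network.model' is required when a network block is given",
             call. = FALSE)
      network <- parse_network_files(rel(y$network$model),
                                     if (!is.null(y$network$config))
                                       rel(y$network$config))
    }
  }
  substrates <- list()
  for (nm in names(y$substrates %||% list())) {
    s <- y$substrates[[nm]]
    sched <- if (is.null(s$schedule)) injection_schedule("none") else
      injection_schedule(mode = s$schedule$mode %||% "none",
                         concentration = s$schedule$concentration %||% 0,
                         pulse_duration = s$schedule$pulse_duration %||% NA,
                         period = s$schedule$period %||% NA,
                         switch_time = s$schedule$switch_time %||% NA,
                         new_concentration = s$schedule$new_concentration %||% NA)
    substrates[[nm]] <- list(D = s$D %||% stop("substrate '", nm, "' needs D"),
                             decay = s$decay %||% 0,
                             initial = s$initial %||% 0,
                             diffusing = s$diffusing %||% TRUE,
                             schedule = sched)
  }
  strains <- lapply(y$strains %||% list(list(name = "WT")), function(s) {
    ov <- lapply(s$overrides %||% list(), function(o) {
      if (identical(o$kind, "overexpress")) overexpress(o$node)
      else if (identical(o$kind, "knockout")) knockout(o$node)
      else rate_override(o$node, o$rate_up %||% NA_real_,
                         o$rate_down %||% NA_real_)
    })
    args <- s[setdiff(names(s), c("overrides", "fraction"))]
    args$rate_overrides <- ov
    do.call(strain_params, args)
  })
  if (!is.null(y$positions_file)) {
    positions <- read_positions(rel(y$positions_file))
  } else if (!is.null(y$geometry)) {
    g <- y$geometry
    spec <- geometry_spec(shape = g$shape %||% "disk",
                          radius = g$radius %||% 100,
                          extent = unlist(g$extent %||% c(100, 100)),
                          height = g$height %||% 100,
                          cell_radius = g$cell_radius %||% 8.4,
                          packing = g$packing)
    positions <- generate_initial_positions(spec, seed = y$seed %||% 1)
  } else {
    stop("config needs either 'positions_file' or a 'geometry' block",
         call. = FALSE)
  }
  # strain fractions: assign strains to generated cells deterministically
  fracs <- vapply(y$strains %||% list(), function(s) s$fraction %||% NA_real_, 1)
  if (length(fracs) && !all(is.na(fracs))) {
    fracs[is.na(fracs)] <- 0
    if (abs(sum(fracs) - 1) > 1e-6)
      stop("strain fractions must sum to 1", call. = FALSE)
    positions <- assign_strains(positions, fracs, seed = y$seed %||% 1)
  }
  if (isTRUE(y$ecm$passive_spheres %||% FALSE) && is.null(y$ecm$positions_file))
    stop("ECM-enabled runs need key 'ecm.positions_file' (matrix initial ",
         "conditions)", call. = FALSE)
  if (!is.null(y$ecm$positions_file)) {
    positions <- rbind(positions, read_positions(rel(y$ecm$positions_file)))
  }
  input_rules <- lapply(y$input_rules %||% list(), function(r)
    input_rule(r$node, r$source %||% "substrate", r$threshold,
               substrate = r$substrate))
  clock <- clock_config(dt_diffusion = y$clock$dt_diffusion %||% 0.01,
                        dt_mechanics = y$clock$dt_mechanics %||% 0.1,
                        dt_signalling = y$clock$dt_signalling %||% 10,
                        t_end = y$clock$t_end %||% 1440,
                        snapshot_interval = y$clock$snapshot_interval %||% 60)
  receptor <- if (!is.null(y$receptor))
    tnf_receptor_params(substrate = y$receptor$substrate %||% "TNF",
                        k_on = y$receptor$k_on %||% 0.1,
                        k_int = y$receptor$k_int %||% 0.5,
                        k_clear = y$receptor$k_clear %||% 0.05,
                        theta = y$receptor$theta %||% 0.01)
  oxygen <- if (!is.null(y$oxygen))
    list(substrate = y$oxygen$substrate %||% "oxygen",
         uptake = y$oxygen$uptake %||% 10)
  cfg <- sim_config(strains = strains, positions = positions,
                    network = network, substrates = substrates,
                    bounds = unlist(y$bounds %||% c(-200, 200)),
                    dx = y$dx %||% 20, ndim = y$ndim %||% 3,
                    input_rules = input_rules, receptor = receptor,
                    oxygen = oxygen, clock = clock, seed = y$seed %||% 1,
                    record_snapshots = y$record_snapshots %||% FALSE)
  if (!quiet) {
    message("effective configuration:")
    message(yaml::as.yaml(y))
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign strains to positions by fractions
#'
#' Uniform-random assignment (deterministic given the seed) matching the
#' requested fractions as closely as counts allow.
#'
#' @param positions positions data.frame.
#' @param fractions numeric vector summing to 1.
#' @param seed integer seed.
#' @return the positions with the `strain` column reassigned.
#' @export
assign_strains <- function(positions, fractions, seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-6)
  n <- nrow(positions)
  cells <- which(positions$type == "cell")
  counts <- floor(fractions * length(cells))
  while (sum(counts) < length(cells))
    counts[which.max(fractions * length(cells) - counts)] <-
      counts[which.max(fractions * length(cells) - counts)] + 1L
  lab <- rep(seq_along(fractions), counts)
  rng <- bc_rng(seed, 733L)
  u <- rng_unif(rng, length(cells))
  positions$strain[cells] <- lab[order(u)]
  positions
}
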