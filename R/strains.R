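# A strain is a sub-population sharing physical parameters and Boolean
# transition-rate overrides (the genotype analogue).  Mutants are strains
# whose rate_overrides pin or re-rate individual network nodes.

#' Define a cell strain
#'
#' @param name strain name.
#' @param adhesion_homotypic,adhesion_heterotypic cell-cell adhesion
#'   strengths (micron/min force scale under unit drag).  Pairs combine as
#'   the homotypic strength within a strain and as the geometric mean of the
#'   heterotypic strengths across strains.
#' @param adhesion_matrix adhesion strength to passive-sphere / ECM agents.
#' @param repulsion repulsion strength; pairs combine by geometric mean.
#' @param interaction_distance_multiplier adhesion range as a multiple of
#'   the radii sum (default 1.25).
#' @param motility_speed random-motility speed, micron/min.
#' @param persistence_time polarity persistence time tau, min.
#' @param cycle_duration mean cell-cycle duration, min (Erlang shape 4).
#' @param volume_growth_rate exponential relaxation rate of the volume
#'   compartments toward their doubled targets, 1/min.
#' @param volume_total target (reference) cell volume, micron^3; the default
#'   2494 gives a radius of about 8.4 micron.
#' @param nuclear_radius micron.
#' @param fluid_fraction fraction of the volume that is fluid.
#' @param oxygen_necrosis_threshold local oxygen (mmHg) below which a
#'   proliferative cell commits to NonACD; `-Inf` disables the check.
#' @param tnf_secretion_rate TNF source rate while NFkB is active
#'   (density/min added to the cell's voxel).
#' @param ecm_degrade_rate radius decrease rate of contacted degradable
#'   passive spheres, micron/min (negative values reinforce).
#' @param rate_overrides list of [rate_override()] defining the strain's
#'   mutations.
#' @return object of class `strain_params`.
#' @export
strain_params <- function(name,
                          adhesion_homotypic = 0.4,
                          adhesion_heterotypic = 0.4,
                          adhesion_matrix = 0,
                          repulsion = 10,
                          interaction_distance_multiplier = 1.25,
                          motility_speed = 0,
                          persistence_time = 10,
                          cycle_duration = 970,
                          volume_growth_rate = 0.005,
                          volume_total = 2494,
                          nuclear_radius = 5,
                          fluid_fraction = 0.75,
                          oxygen_necrosis_threshold = -Inf,
                          tnf_secretion_rate = 0,
                          ecm_degrade_rate = 0,
                          rate_overrides = list()) {
  stopifnot(adhesion_homotypic >= 0, adhesion_heterotypic >= 0,
            adhesion_matrix >= 0, repulsion >= 0, cycle_duration > 0,
            volume_total > 0, fluid_fraction >= 0, fluid_fraction < 1)
  structure(list(name = name,
                 adhesion_homotypic = adhesion_homotypic,
                 adhesion_heterotypic = adhesion_heterotypic,
                 adhesion_matrix = adhesion_matrix,
                 repulsion = repulsion,
                 interaction_distance_multiplier = interaction_distance_multiplier,
                 motility_speed = motility_speed,
                 persistence_time = persistence_time,
                 cycle_duration = cycle_duration,
                 volume_growth_rate = volume_growth_rate,
                 volume_total = volume_total,
                 nuclear_radius = nuclear_radius,
                 fluid_fraction = fluid_fraction,
                 oxygen_necrosis_threshold = oxygen_necrosis_threshold,
                 tnf_secretion_rate = tnf_secretion_rate,
                 ecm_degrade_rate = ecm_degrade_rate,
                 rate_overrides = rate_overrides),
            class = "strain_params")
}

# strain list -> pairwise mechanics matrices for the C++ kernel
.strain_matrices <- function(strains) {
  S <- length(strains)
  adh <- matrix(0, S, S)
  rep_ <- matrix(0, S, S)
  for (a in seq_len(S)) for (b in seq_len(S)) {
    if (a == b) {
      adh[a, b] <- strains[[a]]$adhesion_homotypic
    } else {
      adh[a, b] <- sqrt(strains[[a]]$adhesion_heterotypic *
                        strains[[b]]$adhesion_heterotypic)
    }
    rep_[a, b] <- sqrt(strains[[a]]$repulsion * strains[[b]]$repulsion)
  }
  list(adh = adh, rep = rep_,
       mat_adh = vapply(strains, function(s) s$adhesion_matrix, 1.0),
       f = strains[[1]]$interaction_distance_multiplier)
}
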