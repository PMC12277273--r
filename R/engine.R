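#' Simulation protocol configuration
#'
#' MD protocol for relaxation and tensile testing: 10 fs timestep,
#' 300 K Langevin thermostat, engineering-rate axial deformation under
#' longitudinal periodic boundaries, virial stress recording.
#'
#' @param timestep Integration step, fs.
#' @param temperature Thermostat target, K.
#' @param relax_steps Total relaxation steps (split equally between the
#'   stress-release stage and plain NVT). The full-fibril default is
#'   1e5 (1 ns); desk-scale runs use ~1e4.
#' @param damping Langevin damping time, fs.
#' @param strain_rate Engineering strain rate, 1/fs. The default
#'   1e-7/fs (1e8/s) is typical for coarse-grained fibril pulling.
#' @param max_strain Tensile run end strain.
#' @param record_interval Steps between records.
#' @param deformation_mode `"BOX_STRAIN"` (affine axial box scaling,
#'   default) or `"END_CLAMP"` (end slabs driven apart at +-v/2).
#' @param clamp_width End-slab width for `END_CLAMP`, Angstrom.
#' @param kinetic_virial Include the kinetic term in the virial stress.
#' @param volume_percentile Radial bead-distance percentile defining
#'   the stress-normalization cylinder radius (see [fibril_volume()]).
#' @param skin Neighbor-list skin, Angstrom.
#' @param npt_gain Axial box controller gain, relative length change
#'   per GPa of mean axial stress.
#' @param npt_interval Steps between box-controller updates.
#' @param npt_max_step Cap on the relative length change per update.
#' @param stress_tolerance Residual axial stress tolerance after
#'   relaxation, MPa.
#' @param seed Integer seed for thermostat noise.
#' @return Object of class `protocol_config`.
#' @export
protocol_config <- function(timestep = 10,
                            temperature = 300,
                            relax_steps = 1e5,
                            damping = 1000,
                            strain_rate = 1e-7,
                            max_strain = 0.6,
                            record_interval = 100L,
                            deformation_mode = c("BOX_STRAIN", "END_CLAMP"),
                            clamp_width = 30,
                            kinetic_virial = TRUE,
                            volume_percentile = 0.95,
                            skin = 4,
                            npt_gain = 0.002,
                            npt_interval = 100L,
                            npt_max_step = 0.002,
                            stress_tolerance = 20,
                            seed = 1L) {
  stopifnot(timestep > 0, strain_rate >= 0, max_strain > 0)
  structure(list(timestep = timestep, temperature = temperature,
                 relax_steps = relax_steps, damping = damping,
                 strain_rate = strain_rate, max_strain = max_strain,
                 record_interval = as.integer(record_interval),
                 deformation_mode = match.arg(deformation_mode),
                 clamp_width = clamp_width,
                 kinetic_virial = kinetic_virial,
                 volume_percentile = volume_percentile,
                 skin = skin, npt_gain = npt_gain,
                 npt_interval = as.integer(npt_interval),
                 npt_max_step = npt_max_step,
                 stress_tolerance = stress_tolerance,
                 seed = as.integer(seed)),
            class = "protocol_config")
}

# flatten a forcefield into the tables the C++ core indexes:
# pair key = species_i + species_j (0 ColCol, 1 ColHAp, 2 HApHAp),
# bond type 0 = Col-Col, 1 = HAp-HAp
.ff_tables <- function(ff) {
  p <- list(ff$pair$col_col, ff$pair$col_hap, ff$pair$hap_hap)
  b <- list(ff$bond$col_col, ff$bond$hap_hap)
  list(pair_eps = vapply(p, `[[`, 0, "epsilon"),
       pair_sigma = vapply(p, `[[`, 0, "sigma"),
       pair_cutoff = vapply(p, `[[`, 0, "cutoff"),
       bond_r0 = vapply(b, `[[`, 0, "r0"),
       bond_r1 = vapply(b, `[[`, 0, "r1"),
       bond_rb = vapply(b, `[[`, 0, "rb"),
       bond_KT0 = vapply(b, `[[`, 0, "KT0"),
       bond_KT1 = vapply(b, `[[`, 0, "KT1"),
       bond_r1bar = vapply(b, `[[`, 0, "r1bar"),
       ktheta = ff$angle$col$ktheta)
}

# cross-section area tiled by the molecule columns (hexagonal cells)
.area_hex <- function(model) {
  nmol <- if (!is.null(model$sites)) nrow(model$sites)
          else length(unique(model$molecule[model$species == 0L]))
  nmol * sqrt(3) / 2 * model$config$lattice_constant^2
}

#' Create a simulation state from a fibril model
#'
#' Attaches velocities (Maxwell-Boltzmann at `temperature`, net
#' momentum removed), per-angle equilibrium angles and the flattened
#' force-field tables. The returned state is the unit the engine
#' functions advance.
#'
#' @param model A `fibril_model`.
#' @param ff A `forcefield` (default [default_forcefield()]).
#' @param temperature Initial velocity temperature, K (0 = at rest).
#' @param seed Seed for the velocity draw.
#' @return Object of class `simulation_state`.
#' @export
simulation_state <- function(model, ff = default_forcefield(),
                             temperature = 300, seed = 1L) {
  n <- nrow(model$positions)
  v <- matrix(0, n, 3)
  if (temperature > 0) {
    local_seed(derive_seed(seed, "velocities"))
    sd <- sqrt(.kB * temperature / (model$mass * .mv2e))
    v <- matrix(stats::rnorm(3 * n, sd = rep(sd, 3)), n, 3)
    v <- sweep(v, 2, colSums(v * model$mass) / sum(model$mass)) # zero momentum
  }
  structure(list(
    positions = wrap_positions(model$positions, model$cell$Lz),
    velocities = v,
    mass = model$mass,
    species = model$species,
    bonds = model$bonds,
    bond_type = model$bond_type,
    broken = rep(FALSE, nrow(model$bonds)),
    angles = model$angles,
    theta0 = rep(pi, nrow(model$angles)),
    ff_tables = .ff_tables(ff),
    cell = list(Lz = model$cell$Lz, periodic_z = TRUE),
    area_hex = .area_hex(model),
    model_config = model$config,
    time = 0
  ), class = "simulation_state")
}

#' Evaluate forces, potential energy and virial for a state
#'
#' Neighbor-listed evaluation of all LJ pair, bond and angle terms.
#' Bonds at or beyond their breaking distance contribute nothing (the
#' broken flag itself is only advanced by the integrator).
#'
#' @param state A `simulation_state`.
#' @return List: `forces` (N x 3, kcal/mol/A), `epot` (kcal/mol),
#'   `virial` (xx, yy, zz components of sum r_ij * f_ij, kcal/mol).
#' @export
compute_forces <- function(state) {
  .md_forces_cpp(state, skin = 2.0)
}

# shared low-level driver
.run <- function(state, nsteps, p, thermostat, box_strain, strain_rate,
                 npt, end_clamp = FALSE, seed = p$seed) {
  nsteps <- as.integer(nsteps)
  stopifnot(nsteps >= p$record_interval)
  opts <- list(nsteps = as.double(nsteps), timestep = p$timestep,
               thermostat = thermostat, temperature = p$temperature,
               damping = p$damping, strain_rate = strain_rate,
               box_strain = box_strain, end_clamp = end_clamp,
               clamp_width = p$clamp_width,
               record_interval = p$record_interval,
               kinetic_virial = p$kinetic_virial,
               area_hex = state$area_hex,
               volume_percentile = p$volume_percentile,
               npt = npt, npt_gain = p$npt_gain / .kcalA3_to_GPa,
               npt_interval = p$npt_interval,
               npt_max_step = p$npt_max_step,
               skin = p$skin, seed = as.double(seed))
  res <- .md_run_cpp(state, opts)
  state$positions <- res$positions
  state$velocities <- res$velocities
  state$broken <- res$broken
  state$cell$Lz <- res$Lz
  state$time <- state$time + nsteps * p$timestep
  rec <- res$records
  rec$stress_MPa <- rec$stress * .kcalA3_to_GPa * 1000
  list(state = state, records = rec, blew_up = res$blew_up)
}

#' Advance a state by plain MD
#'
#' Velocity-Verlet integration, optionally Langevin-thermostatted.
#' With `thermostat = FALSE` this is NVE.
#'
#' @param state A `simulation_state`.
#' @param nsteps Number of steps.
#' @param protocol A `protocol_config`.
#' @param thermostat Couple to the Langevin bath?
#' @param seed Seed for thermostat noise (default from protocol).
#' @return List `state`, `records` (data.frame), `blew_up`.
#' @export
run_md <- function(state, nsteps, protocol = protocol_config(),
                   thermostat = TRUE, seed = protocol$seed) {
  .run(state, nsteps, protocol, thermostat = thermostat,
       box_strain = FALSE, strain_rate = 0, npt = FALSE, seed = seed)
}

#' Relax a freshly built model
#'
#' Stage 1: Langevin NVT with a proportional axial box-length
#' controller steering the mean axial virial stress to zero (the
#' surrogate for the NPT stage; only the axial direction is periodic).
#' Stage 2: plain NVT. Warns if the residual axial stress exceeds
#' `stress_tolerance`.
#'
#' @param state A `simulation_state`.
#' @param protocol A `protocol_config`; `relax_steps` are split
#'   equally between the stages.
#' @param seed Seed for thermostat noise.
#' @return List `state`, `records` (both stages concatenated),
#'   `residual_stress_MPa`.
#' @export
relax <- function(state, protocol = protocol_config(),
                  seed = protocol$seed) {
  half <- max(protocol$record_interval, floor(protocol$relax_steps / 2))
  s1 <- .run(state, half, protocol, thermostat = TRUE, box_strain = FALSE,
             strain_rate = 0, npt = TRUE, seed = derive_seed(seed, "relax1"))
  s2 <- .run(s1$state, half, protocol, thermostat = TRUE, box_strain = FALSE,
             strain_rate = 0, npt = FALSE, seed = derive_seed(seed, "relax2"))
  rec <- rbind(s1$records, s2$records)
  tail_n <- max(1, floor(nrow(s2$records) * 0.2))
  resid <- mean(utils::tail(s2$records$stress_MPa, tail_n))
  if (abs(resid) > protocol$stress_tolerance)
    warning(sprintf("relax: residual axial stress %.1f MPa exceeds tolerance %.1f MPa",
                    resid, protocol$stress_tolerance))
  list(state = s2$state, records = rec, residual_stress_MPa = resid)
}

#' Constant-rate tensile deformation
#'
#' `BOX_STRAIN` (default): the axial cell length grows at the
#' engineering `strain_rate` with affine remapping of z-coordinates;
#' `END_CLAMP`: beads in the two end slabs are driven apart at +-v/2
#' with transverse freedom. Bond rupture (distance past the breaking
#' distance, minimum image) is permanent. Stress is the tension-
#' positive axial virial over the fibril volume.
#'
#' @param state A relaxed `simulation_state`.
#' @param protocol A `protocol_config`.
#' @param seed Seed for thermostat noise.
#' @return Object of class `stress_strain`: data.frame of records
#'   (`strain`, `stress_MPa`, `temperature`, `epot`, `ekin`, `Lz`,
#'   `broken_bonds`, `time`) with the final state in
#'   `attr(, "final_state")` and `attr(, "blew_up")`.
#' @export
tensile_run <- function(state, protocol = protocol_config(),
                        seed = protocol$seed) {
  if (protocol$strain_rate <= 0)
    stop("tensile_run: strain_rate must be positive")
  nsteps <- ceiling(protocol$max_strain /
                    (protocol$strain_rate * protocol$timestep))
  mode_clamp <- protocol$deformation_mode == "END_CLAMP"
  res <- .run(state, nsteps, protocol, thermostat = TRUE,
              box_strain = !mode_clamp,
              strain_rate = protocol$strain_rate,
              npt = FALSE, end_clamp = mode_clamp,
              seed = derive_seed(seed, "tensile"))
  if (res$blew_up)
    warning("tensile_run: integrator blow-up; returning partial record")
  curve <- res$records
  attr(curve, "final_state") <- res$state
  attr(curve, "blew_up") <- res$blew_up
  class(curve) <- c("stress_strain", class(curve))
  curve
}

#' Fibril volume for stress normalization
#'
#' Cylinder estimate: axial cell length times `pi * R^2`. The radius
#' is the larger of (i) the radius of the circle whose area equals
#' the hexagonal cells tiled by the molecule columns (`R_hex`,
#' matching the nominal fibril radius for the full model) and (ii)
#' the `percentile` radial distance of the *collagen* beads from the
#' cross-section centroid (`R_p95`). Two deliberate choices: the
#' percentile alone under-counts the outer half-cells and would
#' inflate stress at microfibril scale (hence `R_hex`); and the
#' reference cylinder excludes extrafibrillar mineral — a volume that
#' grew with accreting shells would make the apparent modulus fall
#' steeply with mineral fraction, contradicting the flat modulus
#' observed across the insertion.
#'
#' @param state A `simulation_state`.
#' @param percentile Radial distance percentile (default 0.95).
#' @return Volume, Angstrom^3, with attributes `R_hex`, `R_p95`.
#' @export
fibril_volume <- function(state, percentile = 0.95) {
  keep <- if (any(state$species == 0L)) state$species == 0L
          else rep(TRUE, length(state$species))
  xy <- state$positions[keep, 1:2, drop = FALSE]
  ctr <- colMeans(xy)
  r <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  k <- min(length(r), max(1, ceiling(percentile * length(r))))
  r95 <- sort(r, partial = k)[k]
  R_hex <- sqrt(state$area_hex / pi)
  A <- max(state$area_hex, pi * r95^2)
  structure(A * state$cell$Lz, R_hex = R_hex, R_p95 = r95)
}
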