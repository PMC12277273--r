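#' Fibril geometry configuration
#'
#' Structural parameters of the mineral-free fibril: bead-chain
#' molecules on a quasi-hexagonal lattice, axially staggered in five
#' classes so that gap/overlap banding repeats with the D-period. The
#' defaults describe a 21.5 nm diameter fibril of 151 molecules
#' (32,918 beads) in a 3,410 A axially periodic cell.
#'
#' @param beads_per_molecule Beads per collagen molecule.
#' @param bead_mass Mass of one bead, Da.
#' @param molecule_length End-to-end molecule length, Angstrom.
#' @param gap Gap-zone length, Angstrom.
#' @param overlap Overlap-zone length, Angstrom.
#' @param n_periods D-periods per periodic cell (also the number of
#'   stagger classes).
#' @param lattice_constant Hexagonal lattice constant, Angstrom.
#' @param fibril_diameter Fibril diameter, Angstrom; lattice sites
#'   within `fibril_diameter / 2` of the axis are populated.
#' @param n_molecules Optional: keep only the `n_molecules` lattice
#'   sites closest to the axis (used by [microfibril_preset()]).
#' @return Object of class `geometry_config`; derived fields
#'   `d_period = gap + overlap`, `cell_length = n_periods * d_period`
#'   and `bead_spacing = molecule_length / (beads_per_molecule - 1)`.
#' @export
geometry_config <- function(beads_per_molecule = 218L,
                            bead_mass = 1316,
                            molecule_length = 3011,
                            gap = 400,
                            overlap = 282,
                            n_periods = 5L,
                            lattice_constant = 16.52,
                            fibril_diameter = 215,
                            n_molecules = NULL) {
  cfg <- list(beads_per_molecule = as.integer(beads_per_molecule),
              bead_mass = bead_mass,
              molecule_length = molecule_length,
              gap = gap, overlap = overlap,
              n_periods = as.integer(n_periods),
              lattice_constant = lattice_constant,
              fibril_diameter = fibril_diameter,
              n_molecules = if (is.null(n_molecules)) NULL else as.integer(n_molecules))
  cfg$d_period <- gap + overlap
  cfg$cell_length <- n_periods * cfg$d_period
  cfg$bead_spacing <- molecule_length / (beads_per_molecule - 1)
  if (cfg$beads_per_molecule < 2) stop("need at least 2 beads per molecule")
  if (molecule_length >= cfg$cell_length)
    stop("molecule_length must be shorter than the periodic cell")
  structure(cfg, class = "geometry_config")
}

#' Reduced-size microfibril configurations
#'
#' Desk-scale fibrils with 7, 19 or 37 molecules (1, 2 or 3 hexagonal
#' shells around the axis), preserving the lattice constant, D-period,
#' bead spacing and stagger scheme of the full model. The nominal
#' diameter is set to the outermost selected site radius plus one
#' lattice constant (the outer half-cells).
#'
#' @param n_molecules One of 7, 19, 37 (hexagonal shell counts).
#' @param n_periods D-periods per cell (default 5).
#' @param beads_per_molecule Beads per molecule (default 218).
#' @param ... Further overrides passed to [geometry_config()].
#' @return A `geometry_config`.
#' @export
microfibril_preset <- function(n_molecules = c(7L, 19L, 37L),
                               n_periods = 5L,
                               beads_per_molecule = 218L, ...) {
  n_molecules <- as.integer(n_molecules[1])
  if (!n_molecules %in% c(7L, 19L, 37L))
    stop("microfibril_preset: n_molecules must be 7, 19 or 37")
  a <- 16.52
  shell_r <- unname(c(`7` = 1, `19` = 2, `37` = 3)[as.character(n_molecules)])
  geometry_config(n_periods = n_periods,
                  beads_per_molecule = beads_per_molecule,
                  fibril_diameter = 2 * shell_r * a + a,
                  n_molecules = n_molecules, ...)
}

#' Triangular-lattice sites inside the fibril cross-section
#'
#' Generates the sites `i * (a, 0) + j * (a/2, a*sqrt(3)/2)` of a
#' triangular lattice whose distance from the axis is at most
#' `fibril_diameter / 2`. The integer coordinates are retained for the
#' stagger coloring. For the default full-fibril parameters the count
#' is 151.
#'
#' @param lattice_constant Lattice constant `a`, Angstrom.
#' @param fibril_diameter Fibril diameter, Angstrom.
#' @return data.frame with columns `i`, `j` (integers), `x`, `y`
#'   (Angstrom) and `r` (radius), ordered by radius then (i, j).
#' @export
hex_lattice_sites <- function(lattice_constant, fibril_diameter) {
  stopifnot(lattice_constant > 0, fibril_diameter > 0)
  a <- lattice_constant
  rmax <- fibril_diameter / 2
  n <- ceiling(rmax / a * 2) + 2
  g <- expand.grid(i = -n:n, j = -n:n)
  x <- g$i * a + g$j * a / 2
  y <- g$j * a * sqrt(3) / 2
  r <- sqrt(x^2 + y^2)
  keep <- r <= rmax
  out <- data.frame(i = g$i[keep], j = g$j[keep],
                    x = x[keep], y = y[keep], r = r[keep])
  out[order(out$r, out$i, out$j), , drop = FALSE]
}

#' Axial stagger class of a lattice site
#'
#' Hodge-Petruska-compatible 5-coloring of the triangular lattice:
#' class `(i + 2j) mod 5`. Any five consecutive sites along a lattice
#' row carry all five classes, so neighboring molecules realize the
#' full gap/overlap stagger. A molecule of class `s` starts at axial
#' offset `s * d_period` (modulo the cell length).
#'
#' @param i,j Integer lattice coordinates (vectorized).
#' @param n_classes Number of stagger classes (default 5).
#' @return Integer class in `0:(n_classes - 1)`.
#' @export
assign_stagger <- function(i, j, n_classes = 5L) {
  as.integer((i + 2L * j) %% n_classes)
}

#' Build one bead-chain molecule
#'
#' Places `beads_per_molecule` collinear beads along the fibril axis
#' (z) with uniform spacing `molecule_length / (n - 1)`, starting at
#' `axial_offset`, at the given cross-section site; z-coordinates are
#' wrapped into the periodic cell.
#'
#' @param config A `geometry_config`.
#' @param axial_offset Axial start position, Angstrom.
#' @param lattice_site Numeric length-2 (x, y), Angstrom.
#' @return n x 3 matrix of positions.
#' @export
build_molecule <- function(config, axial_offset, lattice_site) {
  n <- config$beads_per_molecule
  z <- axial_offset + (seq_len(n) - 1) * config$bead_spacing
  z <- z %% config$cell_length
  cbind(x = rep(lattice_site[1], n), y = rep(lattice_site[2], n), z = z)
}

#' Build the mineral-free fibril model
#'
#' Assembles the full bead/bond/angle topology: one bead chain per
#' lattice site, staggered axially by its 5-class coloring, in a cell
#' periodic along z only. Chain bonds connect consecutive beads
#' (wrapping across the boundary via minimum image in the engine);
#' angles span consecutive bead triplets with straight (180 degree)
#' equilibrium.
#'
#' @param config A `geometry_config`.
#' @return Object of class `fibril_model`: list with `positions`
#'   (N x 3), `species` (integer, 0 = collagen, 1 = hydroxyapatite),
#'   `molecule` (integer id), `mass`, `bonds` (nb x 2, 1-based),
#'   `bond_type` (0 = Col-Col, 1 = HAp-HAp), `angles` (na x 3),
#'   `cell` (list `Lz`, `periodic_z`), `config`, and an empty
#'   `inclusion_log`.
#' @export
build_fibril <- function(config) {
  sites <- hex_lattice_sites(config$lattice_constant, config$fibril_diameter)
  if (!is.null(config$n_molecules)) {
    if (nrow(sites) < config$n_molecules)
      stop("build_fibril: fewer lattice sites than requested molecules")
    sites <- sites[seq_len(config$n_molecules), , drop = FALSE]
  }
  if (anyDuplicated(sites[, c("i", "j")]))
    stop("build_fibril: duplicate lattice sites (overlap rejection)")
  nmol <- nrow(sites)
  nb_per <- config$beads_per_molecule
  stagger <- assign_stagger(sites$i, sites$j, config$n_periods)

  pos <- matrix(0.0, nmol * nb_per, 3)
  molecule <- integer(nmol * nb_per)
  for (m in seq_len(nmol)) {
    idx <- ((m - 1) * nb_per + 1):(m * nb_per)
    pos[idx, ] <- build_molecule(config,
                                 axial_offset = stagger[m] * config$d_period,
                                 lattice_site = c(sites$x[m], sites$y[m]))
    molecule[idx] <- m
  }

  first <- (seq_len(nmol) - 1) * nb_per
  bonds <- do.call(rbind, lapply(first, function(f)
    cbind(f + seq_len(nb_per - 1), f + seq_len(nb_per - 1) + 1L)))
  angles <- do.call(rbind, lapply(first, function(f)
    cbind(f + seq_len(nb_per - 2), f + seq_len(nb_per - 2) + 1L,
          f + seq_len(nb_per - 2) + 2L)))

  structure(list(
    positions = pos,
    species = integer(nmol * nb_per),             # all collagen
    molecule = molecule,
    mass = rep(config$bead_mass, nmol * nb_per),
    bonds = bonds,
    bond_type = integer(nrow(bonds)),             # 0 = Col-Col
    angles = angles,
    cell = list(Lz = config$cell_length, periodic_z = TRUE),
    sites = sites,
    stagger = stagger,
    config = config,
    inclusion_log = NULL
  ), class = "fibril_model")
}

#' @export
print.fibril_model <- function(x, ...) {
  nhap <- sum(x$species == 1L)
  cat("<fibril_model> ", nrow(x$positions), " beads (",
      sum(x$species == 0L), " collagen, ", nhap, " mineral), ",
      nrow(x$bonds), " bonds, ", nrow(x$angles), " angles, Lz = ",
      x$cell$Lz, " A\n", sep = "")
  if (nhap > 0)
    cat("  mineral volume fraction: ", round(compute_mvf(x), 4), "\n", sep = "")
  invisible(x)
}

#' Wrap z-coordinates into the periodic cell
#'
#' @param positions N x 3 matrix.
#' @param Lz Cell length along z, Angstrom.
#' @return Matrix with `z` mapped into `[0, Lz)`. Idempotent.
#' @export
wrap_positions <- function(positions, Lz) {
  positions[, 3] <- positions[, 3] - Lz * floor(positions[, 3] / Lz)
  positions
}

#' Axial mass-density profile
#'
#' Histogram of bead z-coordinates (mass-weighted), used to visualize
#' the gap/overlap banding: the profile of the default fibril shows
#' `n_periods` density minima of roughly gap width per cell.
#'
#' @param model A `fibril_model`.
#' @param nbins Number of z-bins.
#' @param species Optional species filter (0 collagen, 1 mineral).
#' @return data.frame with bin centers `z` and `density` (Da/A).
#' @export
axial_density_profile <- function(model, nbins = 200L, species = NULL) {
  keep <- if (is.null(species)) rep(TRUE, nrow(model$positions))
          else model$species %in% species
  z <- model$positions[keep, 3] %% model$cell$Lz
  m <- model$mass[keep]
  br <- seq(0, model$cell$Lz, length.out = nbins + 1)
  bin <- findInterval(z, br, rightmost.closed = TRUE)
  dens <- vapply(seq_len(nbins), function(b) sum(m[bin == b]), numeric(1))
  data.frame(z = (br[-1] + br[-(nbins + 1)]) / 2,
             density = dens / diff(br))
}

#' Gap-zone axial bands of the staggered fibril
#'
#' Each stagger class is absent from one axial window per cell; those
#' windows are the gap bands (density minima). They start at
#' `overlap_eff + k * d_period` where
#' `overlap_eff = molecule_length - (n_periods - 1) * d_period`.
#'
#' @param config A `geometry_config`.
#' @return data.frame with `zlo`, `zhi` per band (within `[0, cell)`).
#' @export
gap_bands <- function(config) {
  over_eff <- config$molecule_length - (config$n_periods - 1) * config$d_period
  if (over_eff < 0 || over_eff > config$d_period)
    stop("gap_bands: molecule_length inconsistent with the D-stagger")
  k <- 0:(config$n_periods - 1)
  data.frame(zlo = over_eff + k * config$d_period,
             zhi = (k + 1) * config$d_period)
}
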