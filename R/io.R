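#' Write a fibril model as a LAMMPS data file
#'
#' Atom style `molecular`; sections `Masses`, `PairIJ Coeffs`
#' (`lj/cut` epsilon/sigma/cutoff), `Atoms`, `Bonds`, `Angles`.
#' Atom type 1 = collagen, 2 = hydroxyapatite; bond type 1 = Col-Col,
#' 2 = HAp-HAp; one harmonic angle type. z is the periodic axis;
#' x/y bounds pad the structure by three collagen LJ sigmas.
#'
#' @param model A `fibril_model`.
#' @param path Output path.
#' @param ff A `forcefield` for the pair coefficients.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(model, path, ff = default_forcefield()) {
  pos <- model$positions
  pad <- 3 * ff$pair$col_col$sigma
  xr <- range(pos[, 1]) + c(-pad, pad)
  yr <- range(pos[, 2]) + c(-pad, pad)
  n <- nrow(pos)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LAMMPS data file: mesoscopic mineralized collagen fibril (mcfibril)")
  w("")
  w("%d atoms", n)
  w("%d bonds", nrow(model$bonds))
  w("%d angles", nrow(model$angles))
  w("")
  w("2 atom types")
  w("2 bond types")
  w("1 angle types")
  w("")
  w("%.6f %.6f xlo xhi", xr[1], xr[2])
  w("%.6f %.6f ylo yhi", yr[1], yr[2])
  w("%.6f %.6f zlo zhi", 0, model$cell$Lz)
  w("")
  w("Masses")
  w("")
  mass_by_type <- vapply(0:1, function(s) {
    m <- model$mass[model$species == s]
    if (length(m)) m[1] else model$mass[1]
  }, numeric(1))
  w("1 %.4f", mass_by_type[1])
  w("2 %.4f", mass_by_type[2])
  w("")
  w("PairIJ Coeffs # lj/cut")
  w("")
  pp <- list(`1 1` = ff$pair$col_col, `1 2` = ff$pair$col_hap,
             `2 2` = ff$pair$hap_hap)
  for (k in names(pp))
    w("%s %.6f %.6f %.6f", k, pp[[k]]$epsilon, pp[[k]]$sigma, pp[[k]]$cutoff)
  w("")
  w("Atoms # molecular")
  w("")
  writeLines(sprintf("%d %d %d %.8f %.8f %.8f",
                     seq_len(n), model$molecule, model$species + 1L,
                     pos[, 1], pos[, 2], pos[, 3]), con)
  w("")
  w("Bonds")
  w("")
  if (nrow(model$bonds))
    writeLines(sprintf("%d %d %d %d", seq_len(nrow(model$bonds)),
                       model$bond_type + 1L, model$bonds[, 1],
                       model$bonds[, 2]), con)
  w("")
  w("Angles")
  w("")
  if (nrow(model$angles))
    writeLines(sprintf("%d 1 %d %d %d", seq_len(nrow(model$angles)),
                       model$angles[, 1], model$angles[, 2],
                       model$angles[, 3]), con)
  invisible(path)
}

#' Read back a LAMMPS data file written by [write_lammps_data()]
#'
#' @param path File path.
#' @return A `fibril_model`-shaped list (positions, species, molecule,
#'   mass, bonds, bond_type, angles, cell). Geometry config is not
#'   recoverable from the file and is left `NULL`.
#' @export
read_lammps_data <- function(path) {
  lines <- readLines(path)
  grab <- function(pat) {
    ln <- grep(paste0("^\\s*\\d+\\s+", pat, "\\s*$"), lines, value = TRUE)[1]
    as.numeric(sub(paste0("\\s*", pat, "\\s*$"), "", ln))
  }
  n <- grab("atoms")
  nb <- grab("bonds")
  na <- grab("angles")
  zline <- strsplit(trimws(grep("zlo zhi", lines, value = TRUE)[1]), "\\s+")[[1]]
  Lz <- as.numeric(zline[2]) - as.numeric(zline[1])
  section <- function(name, ncol, nrows) {
    i <- grep(paste0("^", name, "\\b"), lines)[1]
    if (is.na(i) || nrows == 0) return(matrix(0, 0, ncol))
    block <- lines[(i + 2):(i + 1 + nrows)]
    do.call(rbind, lapply(strsplit(trimws(block), "\\s+"),
                          function(v) as.numeric(v[seq_len(ncol)])))
  }
  mass_tab <- section("Masses", 2, 2)
  atoms <- section("Atoms", 6, n)
  atoms <- atoms[order(atoms[, 1]), , drop = FALSE]
  bonds <- section("Bonds", 4, nb)
  angles <- section("Angles", 5, na)
  species <- as.integer(atoms[, 3]) - 1L
  structure(list(
    positions = unname(atoms[, 4:6, drop = FALSE]),
    species = species,
    molecule = as.integer(atoms[, 2]),
    mass = mass_tab[species + 1L, 2],
    bonds = matrix(as.integer(bonds[, 3:4]), ncol = 2),
    bond_type = as.integer(bonds[, 2]) - 1L,
    angles = matrix(as.integer(angles[, 3:5]), ncol = 3),
    cell = list(Lz = Lz, periodic_z = TRUE),
    config = NULL,
    inclusion_log = NULL
  ), class = "fibril_model")
}

#' Write trajectory frames as a LAMMPS text dump
#'
#' @param frames List of N x 3 position matrices.
#' @param species Integer species vector (0 collagen, 1 mineral).
#' @param Lz Periodic cell length (may be a vector, one per frame).
#' @param path Output path.
#' @param timesteps Integer timestep labels (default frame index).
#' @return `path`, invisibly.
#' @export
write_dump <- function(frames, species, Lz, path, timesteps = NULL) {
  if (is.null(timesteps)) timesteps <- seq_along(frames) - 1L
  Lz <- rep_len(Lz, length(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    pos <- wrap_positions(frames[[f]], Lz[f])
    writeLines(c("ITEM: TIMESTEP", format(timesteps[f]),
                 "ITEM: NUMBER OF ATOMS", format(nrow(pos)),
                 "ITEM: BOX BOUNDS ff ff pp",
                 sprintf("%.6f %.6f", min(pos[, 1]), max(pos[, 1])),
                 sprintf("%.6f %.6f", min(pos[, 2]), max(pos[, 2])),
                 sprintf("%.6f %.6f", 0, Lz[f]),
                 "ITEM: ATOMS id type x y z",
                 sprintf("%d %d %.6f %.6f %.6f", seq_len(nrow(pos)),
                         species + 1L, pos[, 1], pos[, 2], pos[, 3])), con)
  }
  invisible(path)
}

#' Write positions as an XYZ file for visualization
#'
#' @param model A `fibril_model` (or any list with `positions` and
#'   `species`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(model, path) {
  pos <- model$positions
  lab <- ifelse(model$species == 0L, "COL", "HAP")
  writeLines(c(format(nrow(pos)), "mcfibril mesoscopic fibril",
               sprintf("%s %.6f %.6f %.6f", lab, pos[, 1], pos[, 2], pos[, 3])),
             path)
  invisible(path)
}

#' Write a stress-strain curve as CSV
#'
#' @param curve A `stress_strain` data.frame from [tensile_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  cols <- intersect(c("time", "strain", "stress_MPa", "temperature",
                      "epot", "ekin", "Lz", "broken_bonds"),
                    names(curve))
  utils::write.csv(as.data.frame(curve)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write run metadata (configs and seeds) as JSON
#'
#' @param path Output path.
#' @param ... Named configuration objects (protocols, seeds, configs);
#'   serialized with class attributes dropped.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, ...) {
  obj <- lapply(list(...), function(x) if (is.object(x)) unclass(x) else x)
  obj$package_version <- as.character(utils::packageVersion("mcfibril"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
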