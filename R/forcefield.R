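#' Lennard-Jones pair parameters
#'
#' Nonbonded interactions between bead species follow the 12-6
#' Lennard-Jones form \eqn{E(r) = 4\epsilon[(\sigma/r)^{12} -
#' (\sigma/r)^6]}, truncated at `cutoff` and shifted so the energy is
#' zero there. `sigma` is the zero-crossing distance and `epsilon` the
#' well depth.
#'
#' @param epsilon Well depth, kcal/mol (> 0).
#' @param sigma Characteristic distance, Angstrom (> 0).
#' @param cutoff Truncation distance, Angstrom; default `2.5 * sigma`.
#' @return Object of class `pair_params`.
#' @export
pair_params <- function(epsilon, sigma, cutoff = 2.5 * sigma) {
  stopifnot(is.numeric(epsilon), is.numeric(sigma), is.numeric(cutoff))
  if (epsilon <= 0 || sigma <= 0 || cutoff <= sigma)
    stop("pair_params: need epsilon > 0, sigma > 0, cutoff > sigma")
  structure(list(epsilon = epsilon, sigma = sigma, cutoff = cutoff),
            class = "pair_params")
}

#' Piecewise hyperelastic bond parameters
#'
#' Bonded beads interact through a bilinear force law: harmonic with
#' stiffness `KT0` about `r0` until the critical distance `r1`, then a
#' stiffer hyperelastic branch with stiffness `KT1` up to the breaking
#' distance `rb`, beyond which the bond carries no force and is
#' permanently broken. The hyperelastic reference distance `r1bar` is
#' not free: it is derived from force continuity at `r1`
#' (see [derive_r1bar()]).
#'
#' @param r0 Equilibrium distance, Angstrom.
#' @param r1 Critical hyperelastic distance, Angstrom (`r0 < r1`).
#' @param rb Bond breaking distance, Angstrom (`r1 < rb`).
#' @param KT0,KT1 Stretching stiffnesses, kcal/mol/A^2.
#' @return Object of class `bond_params` with the derived `r1bar` filled in.
#' @export
bond_params <- function(r0, r1, rb, KT0, KT1) {
  if (!(r0 < r1 && r1 < rb))
    stop("bond_params: need r0 < r1 < rb")
  if (KT0 <= 0 || KT1 <= 0)
    stop("bond_params: stiffnesses must be positive")
  b <- structure(list(r0 = r0, r1 = r1, rb = rb, KT0 = KT0, KT1 = KT1,
                      r1bar = NA_real_), class = "bond_params")
  b$r1bar <- derive_r1bar(b)
  b
}

#' Derive the hyperelastic reference distance from force continuity
#'
#' The bilinear bond force must be continuous at the branch switch
#' `r1`: `KT0 * (r1 - r0) = KT1 * (r1 - r1bar)`, giving
#' `r1bar = r1 - KT0 * (r1 - r0) / KT1`.
#'
#' @param bond A `bond_params` object (the `r1bar` field is ignored).
#' @return The continuity-consistent `r1bar`, Angstrom.
#' @export
#' @examples
#' # collagen: 18.20 - 17.13 * 4.20 / 97.66 = 17.4633 A
#' derive_r1bar(collagen_bond())
derive_r1bar <- function(bond) {
  if (!is.finite(bond$KT1) || bond$KT1 == 0)
    stop("derive_r1bar: KT1 must be nonzero")
  if (!(bond$r0 < bond$r1))
    stop("derive_r1bar: need r0 < r1")
  bond$r1 - bond$KT0 * (bond$r1 - bond$r0) / bond$KT1
}

#' Harmonic angle parameters
#'
#' Three consecutive beads of a chain resist bending through
#' \eqn{E(\theta) = K_\theta (\theta - \theta_0)^2} with \eqn{\theta}
#' in radians. `theta0` is stored in degrees, the field convention.
#'
#' @param ktheta Bending stiffness, kcal/mol/rad^2.
#' @param theta0 Equilibrium angle, degrees (default 180: straight chains).
#' @return Object of class `angle_params`.
#' @export
angle_params <- function(ktheta, theta0 = 180) {
  if (ktheta <= 0) stop("angle_params: ktheta must be positive")
  structure(list(ktheta = ktheta, theta0 = theta0), class = "angle_params")
}

#' Bond force magnitude
#'
#' Evaluates the bilinear bond force law: `KT0 * (r - r0)` below
#' `r1`, `KT1 * (r - r1bar)` between `r1` and `rb`, and 0 at or
#' beyond the breaking distance `rb` (a broken bond; permanence is
#' enforced by the simulation engine). Positive values pull the beads
#' together (restoring force under extension).
#'
#' @param r Distance(s), Angstrom (> 0). Vectorized.
#' @param bond A `bond_params` object.
#' @return Force magnitude(s), kcal/mol/A.
#' @export
bond_force <- function(r, bond) {
  stopifnot(all(r > 0))
  ifelse(r >= bond$rb, 0,
         ifelse(r < bond$r1,
                bond$KT0 * (r - bond$r0),
                bond$KT1 * (r - bond$r1bar)))
}

#' Bond energy and rupture energy
#'
#' `bond_energy()` integrates the bond force with reference `E(r0) = 0`;
#' it is continuous at `r1` and constant beyond `rb`.
#' `rupture_energy()` is the elastic energy stored in the hyperelastic
#' branch at the breaking distance, `0.5 * KT1 * (rb - r1bar)^2` — the
#' maximum energy a single bond can hold before rupture.
#'
#' @param r Distance(s), Angstrom. Vectorized.
#' @param bond A `bond_params` object.
#' @return Energy, kcal/mol.
#' @export
#' @examples
#' rupture_energy(collagen_bond()) # ~611 kcal/mol
bond_energy <- function(r, bond) {
  stopifnot(all(r > 0))
  e_harm <- function(x) 0.5 * bond$KT0 * (x - bond$r0)^2
  # offset keeps the integral continuous at r1
  c1 <- e_harm(bond$r1) - 0.5 * bond$KT1 * (bond$r1 - bond$r1bar)^2
  e_hyper <- function(x) 0.5 * bond$KT1 * (x - bond$r1bar)^2 + c1
  ifelse(r < bond$r1, e_harm(r),
         ifelse(r < bond$rb, e_hyper(r), e_hyper(bond$rb)))
}

#' @rdname bond_energy
#' @export
rupture_energy <- function(bond) {
  0.5 * bond$KT1 * (bond$rb - bond$r1bar)^2
}

#' Lennard-Jones energy and force
#'
#' Truncated-and-shifted 12-6 Lennard-Jones potential. The energy is
#' shifted so that `lj_energy(cutoff) = 0`; both energy and force
#' vanish beyond the cutoff. Distances below `0.5 * sigma` are clamped
#' to `0.5 * sigma` before evaluation as a safety net against overlap
#' blow-ups (placement rejection should prevent them arising).
#'
#' `lj_force()` returns \eqn{-dE/dr} of the unshifted potential:
#' positive = repulsive (pushes the pair apart).
#'
#' @param r Distance(s), Angstrom (> 0). Vectorized.
#' @param pair A `pair_params` object.
#' @return Energy (kcal/mol) or force magnitude (kcal/mol/A).
#' @export
lj_energy <- function(r, pair) {
  stopifnot(all(r > 0))
  r <- pmax(r, 0.5 * pair$sigma)
  s6 <- (pair$sigma / r)^6
  sc6 <- (pair$sigma / pair$cutoff)^6
  shift <- 4 * pair$epsilon * (sc6^2 - sc6)
  ifelse(r >= pair$cutoff, 0, 4 * pair$epsilon * (s6^2 - s6) - shift)
}

#' @rdname lj_energy
#' @export
lj_force <- function(r, pair) {
  stopifnot(all(r > 0))
  rc <- pmax(r, 0.5 * pair$sigma)
  s6 <- (pair$sigma / rc)^6
  ifelse(r >= pair$cutoff, 0, 24 * pair$epsilon * (2 * s6^2 - s6) / rc)
}

#' Angle bending energy
#'
#' \eqn{E(\theta) = K_\theta (\theta - \theta_0)^2} with the deviation
#' taken in radians. `theta` is given in degrees for consistency with
#' `angle_params`.
#'
#' @param theta Angle(s), degrees, in (0, 180]. Vectorized.
#' @param angle An `angle_params` object.
#' @return Energy, kcal/mol.
#' @export
angle_energy <- function(theta, angle) {
  stopifnot(all(theta > 0), all(theta <= 180))
  d <- (theta - angle$theta0) * pi / 180
  angle$ktheta * d^2
}

#' Default collagen / hydroxyapatite parameter sets
#'
#' Mesoscopic two-species force field for mineralized collagen fibrils:
#' collagen (Col) bead chains and hydroxyapatite (HAp) bead clusters.
#' Bonded interactions exist within a species (Col-Col chain bonds,
#' HAp-HAp cluster bonds); Col-HAp adhesion is nonbonded (LJ) only.
#' Angles apply to collagen triplets.
#'
#' @return `collagen_bond()`/`hap_bond()` return `bond_params`;
#'   `default_forcefield()` returns a `forcefield` object with
#'   components `pair` (named list `col_col`, `hap_hap`, `col_hap`),
#'   `bond` (named list `col_col`, `hap_hap`) and `angle` (named list
#'   `col`).
#' @export
default_forcefield <- function() {
  ff <- list(
    pair = list(
      col_col = pair_params(epsilon = 6.87, sigma = 14.72),
      hap_hap = pair_params(epsilon = 137.1, sigma = 9.88),
      col_hap = pair_params(epsilon = 106.7, sigma = 10.28)
    ),
    bond = list(
      col_col = collagen_bond(),
      hap_hap = hap_bond()
    ),
    angle = list(
      col = angle_params(ktheta = 14.98, theta0 = 180)
    )
  )
  structure(ff, class = "forcefield")
}

#' @rdname default_forcefield
#' @export
collagen_bond <- function() {
  bond_params(r0 = 14.00, r1 = 18.20, rb = 21.00, KT0 = 17.13, KT1 = 97.66)
}

#' @rdname default_forcefield
#' @export
hap_bond <- function() {
  bond_params(r0 = 10.00, r1 = 12.00, rb = 14.89, KT0 = 200.00, KT1 = 418.40)
}

#' Read / write a force field as a human-editable JSON file
#'
#' The file mirrors the parameter-table key names (`r0`, `r1`, `rb`,
#' `KT0`, `KT1`, `epsilon`, `sigma`, `cutoff`, `theta0`, `ktheta`).
#' `read_forcefield()` revalidates every block and rederives `r1bar`,
#' so hand edits cannot produce a force-discontinuous field.
#'
#' @param ff A `forcefield` object.
#' @param path File path.
#' @return `read_forcefield()` returns a `forcefield`;
#'   `write_forcefield()` returns `path` invisibly.
#' @export
write_forcefield <- function(ff, path) {
  strip <- function(x) lapply(unclass(x), function(v) v)
  out <- list(
    pair = lapply(ff$pair, strip),
    bond = lapply(ff$bond, function(b) strip(b)[c("r0", "r1", "rb", "KT0", "KT1")]),
    angle = lapply(ff$angle, strip)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_forcefield
#' @export
read_forcefield <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ff <- list(
    pair = lapply(raw$pair, function(p)
      pair_params(p$epsilon, p$sigma, p$cutoff)),
    bond = lapply(raw$bond, function(b)
      bond_params(b$r0, b$r1, b$rb, b$KT0, b$KT1)),
    angle = lapply(raw$angle, function(a)
      angle_params(a$ktheta, a$theta0))
  )
  structure(ff, class = "forcefield")
}
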