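# Shared fixtures and independent oracles for the test suite.

# Raw model constructor for hand-built bead systems (bypasses build_fibril).
raw_model <- function(positions, species, bonds, bond_type, angles = NULL,
                      Lz, mass = 1316, lattice_constant = 16.52,
                      n_sites = 1L) {
  n <- nrow(positions)
  structure(list(
    positions = positions,
    species = as.integer(species),
    molecule = rep(1L, n),
    mass = rep(mass, n),
    bonds = if (is.null(bonds)) matrix(0L, 0, 2) else bonds,
    bond_type = as.integer(bond_type),
    angles = if (is.null(angles)) matrix(0L, 0, 3) else angles,
    cell = list(Lz = Lz, periodic_z = TRUE),
    sites = data.frame(i = seq_len(n_sites), j = 0),
    config = geometry_config(lattice_constant = lattice_constant),
    inclusion_log = NULL
  ), class = "fibril_model")
}

# O(N^2) all-pairs force/energy oracle, no neighbour lists. Pair and bond
# terms are analytic; angle forces use central differences on the energy.
brute_forces <- function(model, ff = default_forcefield()) {
  pos <- model$positions
  n <- nrow(pos)
  Lz <- model$cell$Lz
  sp <- model$species
  mi <- function(d) d - Lz * round(d / Lz)
  FF <- matrix(0, n, 3)
  ep <- 0
  wzz <- 0
  bonded <- matrix(FALSE, n, n)
  if (nrow(model$bonds) > 0)
    for (b in seq_len(nrow(model$bonds))) {
      bonded[model$bonds[b, 1], model$bonds[b, 2]] <- TRUE
      bonded[model$bonds[b, 2], model$bonds[b, 1]] <- TRUE
    }
  pr <- list(ff$pair$col_col, ff$pair$col_hap, ff$pair$hap_hap)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bonded[i, j]) next
    d <- pos[i, ] - pos[j, ]
    d[3] <- mi(d[3])
    r <- sqrt(sum(d^2))
    p <- pr[[sp[i] + sp[j] + 1]]
    if (r < p$cutoff) {
      ep <- ep + lj_energy(r, p)
      fv <- lj_force(r, p) * d / max(r, 0.5 * p$sigma)
      FF[i, ] <- FF[i, ] + fv
      FF[j, ] <- FF[j, ] - fv
      wzz <- wzz + d[3] * fv[3]
    }
  }
  bl <- list(ff$bond$col_col, ff$bond$hap_hap)
  if (nrow(model$bonds) > 0)
    for (b in seq_len(nrow(model$bonds))) {
      i <- model$bonds[b, 1]; j <- model$bonds[b, 2]
      bp <- bl[[model$bond_type[b] + 1]]
      d <- pos[i, ] - pos[j, ]
      d[3] <- mi(d[3])
      r <- sqrt(sum(d^2))
      if (r >= bp$rb) next
      ep <- ep + bond_energy(r, bp)
      fv <- -bond_force(r, bp) * d / r
      FF[i, ] <- FF[i, ] + fv
      FF[j, ] <- FF[j, ] - fv
      wzz <- wzz + d[3] * fv[3]
    }
  angle_E <- function(p) {
    e <- 0
    if (nrow(model$angles) > 0)
      for (a in seq_len(nrow(model$angles))) {
        d1 <- p[model$angles[a, 1], ] - p[model$angles[a, 2], ]
        d2 <- p[model$angles[a, 3], ] - p[model$angles[a, 2], ]
        d1[3] <- mi(d1[3]); d2[3] <- mi(d2[3])
        cth <- sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2))
        e <- e + ff$angle$col$ktheta * (acos(max(-1, min(1, cth))) - pi)^2
      }
    e
  }
  ep <- ep + angle_E(pos)
  if (nrow(model$angles) > 0) {
    h <- 1e-6
    touched <- unique(as.vector(model$angles))
    for (bead in touched) for (dim in 1:3) {
      pp <- pos; pm <- pos
      pp[bead, dim] <- pp[bead, dim] + h
      pm[bead, dim] <- pm[bead, dim] - h
      FF[bead, dim] <- FF[bead, dim] - (angle_E(pp) - angle_E(pm)) / (2 * h)
    }
  }
  list(forces = FF, epot = ep, wzz = wzz)
}

# random sprinkled two-species system, no catastrophic overlaps
random_system <- function(n, Lz = 120, seed = 1, with_angles = FALSE) {
  set.seed(seed)
  pos <- matrix(0, n, 3)
  k <- 0
  while (k < n) {
    cand <- c(runif(1, 0, 150), runif(1, 0, 150), runif(1, 0, Lz))
    ok <- TRUE
    if (k > 0) {
      d <- sweep(pos[seq_len(k), , drop = FALSE], 2, cand)
      d[, 3] <- d[, 3] - Lz * round(d[, 3] / Lz)
      ok <- min(sqrt(rowSums(d^2))) > 9
    }
    if (ok) { k <- k + 1; pos[k, ] <- cand }
  }
  sp <- rep(c(0L, 1L), length.out = n)
  bonds <- cbind(seq(1, n - 2, by = 3), seq(2, n - 1, by = 3))
  bt <- ifelse(sp[bonds[, 1]] == 0 & sp[bonds[, 2]] == 0, 0L, 1L)
  ang <- if (with_angles)
    cbind(seq(1, n - 2, by = 3), seq(2, n - 1, by = 3), seq(3, n, by = 3))
  else NULL
  raw_model(pos, sp, bonds, bt, ang, Lz = Lz)
}

# short, fast protocol for desk-scale engine tests
fast_protocol <- function(...) {
  protocol_config(relax_steps = 2000, record_interval = 10L, ...)
}
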