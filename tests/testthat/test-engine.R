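test_that("neighbor-listed forces equal the all-pairs oracle", {
  # analytic pair+bond system (no angles): agreement to 1e-10
  m <- random_system(200, Lz = 150, seed = 4)
  st <- simulation_state(m, temperature = 0)
  res <- compute_forces(st)
  ora <- brute_forces(m)
  expect_lt(max(abs(res$forces - ora$forces)), 1e-10)
  expect_equal(res$epot, ora$epot, tolerance = 1e-12)
  expect_lt(abs(res$virial[3] - ora$wzz), 1e-8)
  # Newton's third law on the isolated system
  expect_lt(max(abs(colSums(res$forces))), 1e-9)
  # with angles: oracle gradient is numeric, so looser
  ma <- random_system(60, Lz = 120, seed = 9, with_angles = TRUE)
  sta <- simulation_state(ma, temperature = 0)
  resa <- compute_forces(sta)
  oraa <- brute_forces(ma)
  expect_lt(max(abs(resa$forces - oraa$forces)), 1e-4)
  expect_equal(resa$epot, oraa$epot, tolerance = 1e-10)
})

test_that("bonded equilibrium pairs feel no force; LJ minimum pairs neither", {
  ff <- default_forcefield()
  m <- raw_model(rbind(c(0, 0, 50), c(0, 0, 64)), c(0L, 0L),
                 matrix(c(1L, 2L), 1), 0L, Lz = 500)
  st <- simulation_state(m, temperature = 0)
  expect_lt(max(abs(compute_forces(st)$forces)), 1e-12)
  rmin <- 2^(1 / 6) * ff$pair$col_col$sigma
  m2 <- raw_model(rbind(c(0, 0, 50), c(0, 0, 50 + rmin)), c(0L, 0L),
                  NULL, integer(0), Lz = 500)
  st2 <- simulation_state(m2, temperature = 0)
  expect_lt(max(abs(compute_forces(st2)$forces)), 1e-10)
})

test_that("velocity Verlet conserves energy and reverses in time", {
  # harmonic dimer started off equilibrium
  m <- raw_model(rbind(c(0, 0, 100), c(0, 0, 115.5)), c(0L, 0L),
                 matrix(c(1L, 2L), 1), 0L, Lz = 400)
  st <- simulation_state(m, temperature = 0)
  p <- protocol_config(record_interval = 10L)
  r <- run_md(st, 1e4, p, thermostat = FALSE)
  E <- r$records$epot + r$records$ekin
  # secular drift (Verlet has bounded oscillation, no trend)
  n <- length(E)
  drift <- abs(mean(E[(n - 99):n]) - mean(E[1:100])) / abs(mean(E))
  expect_lt(drift, 1e-4)
  # zero force + zero velocity: nothing moves
  m0 <- raw_model(rbind(c(0, 0, 100), c(0, 0, 114)), c(0L, 0L),
                  matrix(c(1L, 2L), 1), 0L, Lz = 400)
  st0 <- simulation_state(m0, temperature = 0)
  r0 <- run_md(st0, 100, p, thermostat = FALSE)
  expect_equal(r0$state$positions, st0$positions, tolerance = 1e-14)
  # time reversal: integrate, flip velocities, integrate back
  fwd <- run_md(st, 500, p, thermostat = FALSE)
  rev <- fwd$state
  rev$velocities <- -rev$velocities
  back <- run_md(rev, 500, p, thermostat = FALSE)
  expect_equal(back$state$positions, st$positions, tolerance = 1e-8)
})

test_that("Langevin thermostat holds the target temperature and reproduces", {
  m <- build_fibril(microfibril_preset(7))
  st <- simulation_state(m, temperature = 300, seed = 7)
  p <- protocol_config(record_interval = 100L)
  r <- run_md(st, 15000, p, thermostat = TRUE, seed = 13)
  Ts <- utils::tail(r$records$temperature, 80)
  expect_equal(mean(Ts), 300, tolerance = 10 / 300)
  r2 <- run_md(st, 2000, p, thermostat = TRUE, seed = 13)
  r3 <- run_md(st, 2000, p, thermostat = TRUE, seed = 13)
  expect_identical(r2$records, r3$records)
  expect_identical(r2$state$positions, r3$state$positions)
})

test_that("NVE drift on the microfibril stays below 1e-3 over 1e4 steps", {
  m <- build_fibril(microfibril_preset(7))
  st <- simulation_state(m, temperature = 300, seed = 7)
  p <- protocol_config(record_interval = 100L)
  r <- run_md(st, 1e4, p, thermostat = FALSE)
  E <- r$records$epot + r$records$ekin
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-3)
})

test_that("virial stress matches dE/dstrain on a quasi-static stretched chain", {
  # straight bonded chain along z, statically strained
  nb <- 40
  z <- (0:(nb - 1)) * 14.0
  Lz <- nb * 14.0
  m <- raw_model(cbind(0, 0, z), rep(0L, nb),
                 cbind(1:(nb - 1), 2:nb), rep(0L, nb - 1), Lz = Lz)
  # close the ring across the boundary so strain loads every bond
  m$bonds <- rbind(m$bonds, c(nb, 1L))
  m$bond_type <- c(m$bond_type, 0L)
  strain_energy <- function(eps) {
    mm <- m
    mm$positions[, 3] <- mm$positions[, 3] * (1 + eps)
    mm$cell$Lz <- Lz * (1 + eps)
    st <- simulation_state(mm, temperature = 0)
    compute_forces(st)$epot
  }
  eps0 <- 0.05
  h <- 1e-5
  dE <- (strain_energy(eps0 + h) - strain_energy(eps0 - h)) / (2 * h)
  mm <- m
  mm$positions[, 3] <- mm$positions[, 3] * (1 + eps0)
  mm$cell$Lz <- Lz * (1 + eps0)
  st <- simulation_state(mm, temperature = 0)
  wzz <- compute_forces(st)$virial[3]
  # dE/deps = -W_zz / (1 + eps) for affine axial scaling
  expect_equal(-wzz / (1 + eps0), dE, tolerance = 0.02)
})

test_that("relaxation releases the built-in axial pre-strain", {
  m <- build_fibril(microfibril_preset(7))
  st <- simulation_state(m, temperature = 300, seed = 5)
  p <- protocol_config(relax_steps = 6000, record_interval = 50L,
                       stress_tolerance = 60)
  rx <- relax(st, p, seed = 5)
  # 13.88 A spacing vs r0 = 14.0: compressed springs push the box longer
  stage1 <- rx$records$Lz[seq_len(nrow(rx$records) / 2)]
  expect_gt(max(stage1), 3410)
  expect_lte(abs(rx$residual_stress_MPa), 60)
  # already-relaxed state: box length barely moves
  rx2 <- relax(rx$state, p, seed = 6)
  expect_lt(abs(rx2$state$cell$Lz - rx$state$cell$Lz) / rx$state$cell$Lz,
            0.005)
})

test_that("box-strain bookkeeping ties strain to rate and time", {
  m <- build_fibril(microfibril_preset(7))
  st <- simulation_state(m, temperature = 300, seed = 2)
  p <- protocol_config(strain_rate = 1e-5, max_strain = 0.02,
                       record_interval = 50L)
  cv <- tensile_run(st, p, seed = 2)
  steps <- seq(50, by = 50, length.out = nrow(cv))
  expect_equal(cv$strain, 1e-5 * p$timestep * steps, tolerance = 1e-9)
  expect_true(!is.unsorted(cv$strain))
  expect_true(all(diff(cv$broken_bonds) >= 0))
})

test_that("a clamped single chain pulls at the spring-chain modulus", {
  # short chain nearly spanning the cell, one bead clamped at each end,
  # low temperature, pulled slowly enough that loading is quasi-static
  # (several stress-wave traversals within the run)
  nb <- 61
  z <- (0:(nb - 1)) * 14.0 # 840 A chain in a 900 A cell
  m <- raw_model(cbind(0, 0, z), rep(0L, nb),
                 cbind(1:(nb - 1), 2:nb), rep(0L, nb - 1), Lz = 900)
  st <- simulation_state(m, temperature = 0)
  p <- protocol_config(temperature = 5, strain_rate = 1e-6,
                       max_strain = 0.02, record_interval = 50L,
                       deformation_mode = "END_CLAMP", clamp_width = 10)
  cv <- tensile_run(st, p, seed = 3)
  fit <- stats::lm(stress_MPa ~ strain, data = cv[cv$strain > 0.004, ])
  slope_GPa <- unname(stats::coef(fit)[2]) / 1000
  # analytic spring-chain modulus KT0 * r0 / hexagonal cell area
  E_chain <- 17.13 * 14.0 / (sqrt(3) / 2 * 16.52^2) * mcf_constants()$stress_GPa
  expect_equal(slope_GPa, E_chain, tolerance = 0.10)
})

test_that("fibril volume recovers a known cylinder and the nominal radius", {
  # beads on a cylinder surface of radius 50
  set.seed(1)
  n <- 20000 # enough beads that the centroid estimate is tight
  th <- runif(n, 0, 2 * pi)
  pos <- cbind(50 * cos(th), 50 * sin(th), runif(n, 0, 1000))
  m <- raw_model(pos, rep(0L, n), NULL, integer(0), Lz = 1000)
  st <- simulation_state(m, temperature = 0)
  st$area_hex <- 0
  v <- fibril_volume(st)
  expect_equal(as.numeric(v), pi * 50^2 * 1000, tolerance = 0.05)
  # mineral-free full fibril: effective radius ~ the nominal 107.5 A
  stf <- simulation_state(build_fibril(geometry_config()), temperature = 0)
  vf <- fibril_volume(stf)
  expect_equal(sqrt(as.numeric(vf) / 3410 / pi), 107.5, tolerance = 0.05)
})

test_that("trajectory and curve writers round-trip their own output", {
  m <- build_fibril(microfibril_preset(7))
  dir <- withr::local_tempdir()
  dpath <- file.path(dir, "model.data")
  write_lammps_data(m, dpath)
  m2 <- read_lammps_data(dpath)
  expect_equal(nrow(m2$positions), nrow(m$positions))
  expect_equal(m2$bonds, unname(m$bonds))
  expect_equal(m2$angles, unname(m$angles))
  expect_equal(m2$species, m$species)
  expect_equal(m2$cell$Lz, m$cell$Lz)
  expect_equal(m2$positions, unname(m$positions), tolerance = 1e-7)
  # dump: one frame per snapshot
  dump <- file.path(dir, "traj.dump")
  write_dump(list(m$positions, m$positions), m$species, m$cell$Lz, dump)
  expect_equal(sum(grepl("^ITEM: TIMESTEP", readLines(dump))), 2)
  # curve CSV has monotone strain
  st <- simulation_state(m, temperature = 300, seed = 1)
  p <- protocol_config(strain_rate = 1e-5, max_strain = 0.01,
                       record_interval = 20L)
  cv <- tensile_run(st, p, seed = 1)
  cpath <- file.path(dir, "curve.csv")
  write_curve_csv(cv, cpath)
  back <- utils::read.csv(cpath)
  expect_true(!is.unsorted(back$strain))
  expect_equal(nrow(back), nrow(cv))
})
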