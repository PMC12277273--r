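make_curve <- function(strain, stress) {
  data.frame(strain = strain, stress_MPa = stress)
}

test_that("smoothing preserves the grid and suppresses noise as 1/sqrt(window)", {
  eps <- seq(0, 0.5, length.out = 2001)
  flat <- make_curve(eps, rep(100, 2001))
  sm <- smooth_curve(flat, 51)
  expect_equal(sm$stress_MPa, flat$stress_MPa)
  expect_equal(sm$strain, flat$strain)
  # window 1 is the identity
  noisy <- make_curve(eps, 100 + rnorm(2001, sd = 5))
  expect_equal(smooth_curve(noisy, 1)$stress_MPa, noisy$stress_MPa)
  set.seed(2)
  a <- 8
  wn <- make_curve(eps, rnorm(2001, sd = a))
  sm2 <- smooth_curve(wn, 101)
  core <- sm2$stress_MPa[101:1901] # full windows only
  expect_lt(stats::sd(core), 2 * a / sqrt(101))
  expect_gt(stats::sd(core), 0.5 * a / sqrt(101))
  expect_error(smooth_curve(make_curve(eps[1:10], rep(1, 10)), 51), "window")
})

test_that("modulus fit is confined to the 0-10% strain window", {
  eps <- seq(0, 0.3, length.out = 601)
  lin <- make_curve(eps, 4500 * eps)
  expect_equal(youngs_modulus(lin), 4500, tolerance = 1e-9)
  # bilinear knee beyond the window leaves the fit untouched
  knee <- make_curve(eps, ifelse(eps < 0.15, 3000 * eps,
                                 3000 * 0.15 + 800 * (eps - 0.15)))
  expect_equal(youngs_modulus(knee), 3000, tolerance = 1e-9)
  expect_error(youngs_modulus(make_curve(seq(0, 0.05, 0.01), 1:6)), "window")
})

test_that("offset yield classifies drop, lift and none correctly", {
  E <- 5000
  eps <- seq(0, 0.4, length.out = 4001)
  # elastic-perfectly-plastic: drop yield at sy/E + offset with stress sy
  sy <- 400
  epp <- make_curve(eps, pmin(E * eps, sy))
  yp <- yield_point(epp, offset = 0.01, modulus = E)
  expect_equal(yp$mode, "DROP")
  expect_equal(yp$strain, sy / E + 0.01, tolerance = 1e-3)
  expect_equal(yp$stress, sy, tolerance = 1)
  # purely linear to failure: no yield
  lin <- make_curve(eps, E * eps)
  expect_equal(yield_point(lin, modulus = E)$mode, "NONE")
  # upward hardening knee: lift at knee + offset/(slope ratio - 1)
  estar <- 0.1
  hard <- make_curve(eps, E * eps + ifelse(eps > estar,
                                           3 * E * (eps - estar), 0))
  yl <- yield_point(hard, offset = 0.01, modulus = E)
  expect_equal(yl$mode, "LIFT")
  expect_equal(yl$strain, estar + 0.01 / 3, tolerance = 1e-3)
  # drop-mode yield strain is invariant under uniform stress rescaling
  # when the modulus is rescaled with the curve
  sc <- 3.7
  ys <- yield_point(make_curve(eps, sc * pmin(E * eps, sy)),
                    offset = 0.01, modulus = sc * E)
  expect_equal(ys$strain, yp$strain, tolerance = 1e-9)
  expect_equal(ys$stress, sc * yp$stress, tolerance = 1e-6)
})

test_that("ultimate point is the stress argmax with ties to smaller strain", {
  eps <- seq(0, 0.4, length.out = 401)
  mono <- make_curve(eps, 100 * eps)
  expect_equal(ultimate_point(mono)$strain, 0.4)
  uni <- make_curve(eps, -(eps - 0.25)^2)
  expect_equal(ultimate_point(uni)$strain, 0.25, tolerance = 1e-9)
  flat <- make_curve(c(0, 0.1, 0.2, 0.3), c(0, 5, 5, 1))
  expect_equal(ultimate_point(flat)$strain, 0.1)
})

test_that("replicate aggregation is permutation-invariant with a mode tally", {
  mk <- function(E, mode = "DROP") structure(list(
    youngs_modulus = E, yield_strain = E / 1e5, yield_stress = E / 10,
    ultimate_strain = 0.4, ultimate_stress = E / 2, yield_mode = mode),
    class = "mechanical_properties")
  props <- lapply(1:5, mk)
  ag <- aggregate_replicates(props)
  expect_equal(unname(ag$youngs_modulus), c(1, 5, 3))
  ag2 <- aggregate_replicates(props[c(3, 5, 1, 4, 2)])
  expect_equal(ag, ag2)
  same <- aggregate_replicates(lapply(c(2, 2, 2), mk))
  expect_equal(unname(same$youngs_modulus), c(2, 2, 2))
  mixed <- aggregate_replicates(list(mk(1), mk(2, "LIFT"), mk(3, "NONE")))
  expect_equal(as.integer(mixed$mode_tally), c(1L, 1L, 1L))
})

test_that("extract_properties reads off a constructed elastic-plastic curve", {
  E <- 4500
  eps <- seq(0, 0.45, length.out = 4501)
  sy <- 550
  set.seed(4)
  stress <- pmin(E * eps, sy + 40 * (eps - sy / E)) # mild hardening plateau
  stress[eps > 0.42] <- sy - 2000 * (eps[eps > 0.42] - 0.42) # failure
  cv <- make_curve(eps, stress + rnorm(4501, sd = 3))
  pr <- extract_properties(cv, window = 51, offset = 0.01)
  expect_equal(pr$youngs_modulus, E, tolerance = 0.02)
  expect_equal(pr$yield_mode, "DROP")
  expect_equal(pr$yield_strain, sy / E + 0.01, tolerance = 0.05)
  expect_equal(pr$ultimate_strain, 0.42, tolerance = 0.03)
  expect_lte(pr$yield_strain, pr$ultimate_strain)
})

test_that("the insertion study contract: complete rows, determinism", {
  # desk-scale smoke: one position, one replicate, short fast protocol
  geom <- microfibril_preset(7)
  p <- protocol_config(relax_steps = 1500, strain_rate = 2e-6,
                       max_strain = 0.35, record_interval = 50L,
                       stress_tolerance = 100)
  s1 <- run_insertion_study(geom, p, positions = 0, n_replicates = 1,
                            base_seed = 4, window = 21,
                            mineralization = list(shell_width = c(0, 100),
                                                  shell_length = c(100, 300)))
  expect_s3_class(s1, "insertion_study")
  expect_equal(nrow(s1$summary), 1)
  expect_equal(s1$summary$target_mvf, 0.094)
  expect_gte(s1$summary$achieved_mvf, 0.094)
  num <- unlist(s1$summary[, c("E_MPa", "ultimate_strain",
                               "ultimate_stress_MPa")])
  expect_true(all(is.finite(num)))
  expect_equal(s1$summary$n_ok, 1)
  # identical seeds reproduce the study bit-for-bit
  s2 <- run_insertion_study(geom, p, positions = 0, n_replicates = 1,
                            base_seed = 4, window = 21,
                            mineralization = list(shell_width = c(0, 100),
                                                  shell_length = c(100, 300)))
  expect_identical(s1$summary, s2$summary)
})
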