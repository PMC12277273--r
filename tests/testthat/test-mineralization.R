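test_that("insertion MVF gradient is linear between the measured endpoints", {
  expect_equal(mvf_at_position(0), 0.094)
  expect_equal(mvf_at_position(1), 0.652)
  expect_equal(mvf_at_position(0.5), 0.373)
  expect_equal(mvf_at_position(0.25), 0.2335) # linear rule
  xs <- seq(0, 1, by = 0.05)
  expect_equal(diff(mvf_at_position(xs)), rep(0.558 * 0.05, 20))
  expect_error(mvf_at_position(1.2), "\\[0, 1\\]")
})

test_that("sampled inclusions respect their size ranges and admissible regions", {
  mc <- mineralization_config(target_mvf = 0.2)
  geom <- geometry_config()
  bands <- gap_bands(geom)
  set.seed(99)
  in_band <- function(z) any(z >= bands$zlo & z <= bands$zhi)
  for (k in 1:300) {
    e <- sample_inclusion("GAP_ELLIPSOID", mc, geom)
    expect_true(e$dimensions[["long"]] >= 20 && e$dimensions[["long"]] <= 340)
    expect_true(e$dimensions[["short"]] >= 20 && e$dimensions[["short"]] <= 40)
    expect_true(in_band(e$center[["z"]]))
    expect_lte(sqrt(e$center[["x"]]^2 + e$center[["y"]]^2), 107.5)
  }
  for (k in 1:100) {
    s <- sample_inclusion("EXTRA_SHELL", mc, geom)
    expect_true(s$dimensions[["thickness"]] >= 20 && s$dimensions[["thickness"]] <= 40)
    expect_true(s$dimensions[["length"]] >= 150 && s$dimensions[["length"]] <= 1000)
    expect_gte(s$center[["r"]], 107.5) # annulus outside the fibril surface
    p <- sample_inclusion("INTRA_PLATELET", mc, geom)
    expect_true(p$plane_angle %in% (c(0, 60, 120) * pi / 180))
  }
  # fixed seed reproduces the same inclusion sequence
  set.seed(5); a <- replicate(5, sample_inclusion("GAP_ELLIPSOID", mc, geom),
                              simplify = FALSE)
  set.seed(5); b <- replicate(5, sample_inclusion("GAP_ELLIPSOID", mc, geom),
                              simplify = FALSE)
  expect_identical(a, b)
})

test_that("ellipsoid realization matches the lattice-point enumeration oracle", {
  mc <- mineralization_config(target_mvf = 0.2)
  # empty space: no rejection, bead count = cubic lattice points in ellipsoid
  empty <- raw_model(matrix(0, 0, 3), integer(0), NULL, integer(0),
                     Lz = 3410)
  spec <- structure(list(kind = "GAP_ELLIPSOID",
                         dimensions = c(long = 40, short = 20),
                         center = c(x = 50, y = 50, z = 1000), axis = "z"),
                    class = "inclusion_spec")
  real <- realize_inclusion(spec, empty, mc)
  # independent enumeration over the bounding grid
  cnt <- 0
  for (dx in seq(-20, 20, by = 10)) for (dy in seq(-20, 20, by = 10))
    for (dz in seq(-20, 20, by = 10))
      if ((dx / 10)^2 + (dy / 10)^2 + (dz / 20)^2 <= 1) cnt <- cnt + 1
  expect_equal(nrow(real$positions), cnt)
  expect_equal(cnt, 9)
  # bonds connect nearest lattice neighbours only
  expect_true(all(real$bonds >= 1 & real$bonds <= 9))
})

test_that("placement rejection keeps minerals clear of existing beads", {
  fib <- build_fibril(microfibril_preset(7))
  mc <- mineralization_config(target_mvf = 0.2)
  # drop an ellipsoid into the crowded overlap region near the axis
  spec <- structure(list(kind = "GAP_ELLIPSOID",
                         dimensions = c(long = 100, short = 40),
                         center = c(x = 0, y = 0, z = 100), axis = "z"),
                    class = "inclusion_spec")
  real <- realize_inclusion(spec, fib, mc)
  if (nrow(real$positions) > 0) {
    pr <- .close_pairs_cpp(real$positions, fib$positions,
                           mc$rejection_distance, fib$cell$Lz)
    expect_equal(nrow(pr), 0)
  }
  # the crowded interior admits far fewer beads than free space does:
  # only the interstitial channels of the molecule lattice survive
  free <- realize_inclusion(spec, raw_model(matrix(0, 0, 3), integer(0),
                                            NULL, integer(0), Lz = 3410),
                            mc)
  expect_lt(nrow(real$positions), 0.6 * nrow(free$positions))
})

test_that("computed MVF follows the per-bead volume convention", {
  fib <- build_fibril(microfibril_preset(7))
  expect_equal(compute_mvf(fib), 0)
  n_col <- nrow(fib$positions)
  # closed-form ratio after appending n mineral beads
  n_hap <- 500
  m <- fib
  m$species <- c(m$species, rep(1L, n_hap))
  m$positions <- rbind(m$positions, matrix(runif(3 * n_hap, 0, 100), ncol = 3))
  m$mass <- c(m$mass, rep(1316, n_hap))
  v_col <- n_col * pi / 6 * 14^3
  v_hap <- n_hap * pi / 6 * 10^3
  expect_equal(compute_mvf(m), v_hap / (v_hap + v_col), tolerance = 1e-12)
})

test_that("mineralization reaches the target, logs inclusions, and is reproducible", {
  fib <- build_fibril(microfibril_preset(7))
  mc <- mineralization_config(target_mvf = 0.094)
  m1 <- mineralize(fib, mc, seed = 21)
  m2 <- mineralize(fib, mc, seed = 21)
  expect_identical(m1$positions, m2$positions)
  expect_identical(m1$inclusion_log, m2$inclusion_log)
  got <- compute_mvf(m1)
  expect_gte(got, 0.094)
  # overshoot bounded by the final inclusion's bead volume
  last_v <- utils::tail(m1$inclusion_log$beads, 1) * pi / 6 * 10^3
  v_col <- sum(fib$species == 0L) * pi / 6 * 14^3
  vh <- got / (1 - got) * v_col
  vh_target <- 0.094 / (1 - 0.094) * v_col
  expect_lte(vh - vh_target, last_v + 1e-9)
  # all mineral beads clear of collagen by the rejection distance
  hap <- m1$positions[m1$species == 1L, , drop = FALSE]
  col <- m1$positions[m1$species == 0L, , drop = FALSE]
  pr <- .close_pairs_cpp(hap, col, mc$rejection_distance, m1$cell$Lz)
  expect_equal(nrow(pr), 0)
  # zero target is a no-op
  m0 <- mineralize(fib, mineralization_config(target_mvf = 0), seed = 1)
  expect_equal(sum(m0$species == 1L), 0)
})

test_that("higher targets extend the same inclusion sequence (same seed)", {
  fib <- build_fibril(microfibril_preset(7))
  lo <- mineralize(fib, mineralization_config(target_mvf = 0.05), seed = 3)
  hi <- mineralize(fib, mineralization_config(target_mvf = 0.12), seed = 3)
  n <- nrow(lo$inclusion_log)
  expect_gte(nrow(hi$inclusion_log), n)
  expect_equal(hi$inclusion_log[seq_len(n), ], lo$inclusion_log[seq_len(n), ])
})

test_that("intra/extra partition respects the fibril surface", {
  fib <- build_fibril(microfibril_preset(19))
  mc <- mineralization_config(target_mvf = 0.25)
  m <- mineralize(fib, mc, seed = 8)
  R <- fib$config$fibril_diameter / 2
  log <- m$inclusion_log
  # reconstruct per-kind bead radial positions from the log order
  hap <- m$positions[m$species == 1L, , drop = FALSE]
  kinds <- rep(log$kind, log$beads)
  r <- sqrt(hap[, 1]^2 + hap[, 2]^2)
  expect_true(all(r[kinds == "EXTRA_SHELL"] >= R - mc$rejection_distance))
  expect_true(all(r[kinds != "EXTRA_SHELL"] <= R + mc$rejection_distance))
  # at this reduced scale single inclusions are large relative to the
  # mineral budget, so only the radial partition is asserted here; the
  # 75/25 share invariant is checked at full scale below
  expect_true(is.finite(m$extrafibrillar_share_realized))
})

test_that("extrafibrillar share honors the 75/25 split at full scale", {
  fib <- build_fibril(geometry_config())
  m <- mineralize(fib, mineralization_config(target_mvf = 0.22), seed = 12)
  expect_gte(compute_mvf(m), 0.22)
  expect_lte(abs(m$extrafibrillar_share_realized - 0.75), 0.05)
})
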