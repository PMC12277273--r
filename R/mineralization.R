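#' Mineralization configuration
#'
#' Controls the stochastic hydroxyapatite deposition: three inclusion
#' kinds (gap-zone ellipsoids, intrafibrillar lattice-plane platelets,
#' extrafibrillar shell blocks), their size ranges, the target mineral
#' volume fraction and the ~75/25 extrafibrillar/intrafibrillar split.
#' Dimension ranges follow reported hydroxyapatite morphologies in
#' collagenous tissue (all in Angstrom).
#'
#' @param target_mvf Target mineral volume fraction in `[0, 1)`.
#' @param extrafibrillar_share Target share of mineral volume outside
#'   the fibril (default 0.75).
#' @param ellipsoid_long,ellipsoid_short Gap ellipsoid diameter ranges.
#' @param platelet_thickness,platelet_width,platelet_length
#'   Intrafibrillar platelet ranges.
#' @param shell_thickness,shell_width,shell_length Extrafibrillar
#'   shell block ranges (thickness radial, width = arc length, length
#'   axial).
#' @param hap_bead_spacing Mineral bead lattice spacing, Angstrom
#'   (the HAp equilibrium bond distance).
#' @param rejection_distance Minimum distance of a new mineral bead to
#'   any existing bead; default `0.8 * 10.28` (Col-HAp sigma), keeping
#'   placements out of the repulsive core but inside the adhesive well.
#' @param share_tolerance Allowed drift of the realized extrafibrillar
#'   share before corrective kind resampling (default 0.05).
#' @param max_consecutive_rejects Consecutive fully-rejected inclusions
#'   tolerated before `mineralize()` fails (default 200).
#' @return Object of class `mineralization_config`.
#' @export
mineralization_config <- function(target_mvf,
                                  extrafibrillar_share = 0.75,
                                  ellipsoid_long = c(20, 340),
                                  ellipsoid_short = c(20, 40),
                                  platelet_thickness = c(20, 40),
                                  platelet_width = c(50, 100),
                                  platelet_length = c(50, 400),
                                  shell_thickness = c(20, 40),
                                  shell_width = c(0, 400),
                                  shell_length = c(150, 1000),
                                  hap_bead_spacing = 10.00,
                                  rejection_distance = 0.8 * 10.28,
                                  share_tolerance = 0.05,
                                  max_consecutive_rejects = 200L) {
  if (target_mvf < 0 || target_mvf >= 1)
    stop("target_mvf must be in [0, 1)")
  rng_ok <- function(r) length(r) == 2 && all(r >= 0) && r[1] <= r[2]
  for (r in list(ellipsoid_long, ellipsoid_short, platelet_thickness,
                 platelet_width, platelet_length, shell_thickness,
                 shell_width, shell_length))
    if (!rng_ok(r)) stop("size ranges must be nonnegative and ordered")
  structure(list(target_mvf = target_mvf,
                 extrafibrillar_share = extrafibrillar_share,
                 ellipsoid_long = ellipsoid_long,
                 ellipsoid_short = ellipsoid_short,
                 platelet_thickness = platelet_thickness,
                 platelet_width = platelet_width,
                 platelet_length = platelet_length,
                 shell_thickness = shell_thickness,
                 shell_width = shell_width,
                 shell_length = shell_length,
                 hap_bead_spacing = hap_bead_spacing,
                 rejection_distance = rejection_distance,
                 share_tolerance = share_tolerance,
                 max_consecutive_rejects = as.integer(max_consecutive_rejects)),
            class = "mineralization_config")
}

#' Mineral volume fraction across the ligament insertion
#'
#' The mineral volume fraction rises linearly through the insertion,
#' from 9.4% at the ligament limit (`x = 0`) to 65.2% at the bone
#' limit (`x = 1`).
#'
#' @param x Relative insertion position in `[0, 1]` (vectorized).
#' @return Mineral volume fraction (fraction, not percent).
#' @export
#' @examples
#' mvf_at_position(c(0, 0.5, 1)) # 0.094 0.373 0.652
mvf_at_position <- function(x) {
  if (any(x < 0 | x > 1)) stop("mvf_at_position: x must lie in [0, 1]")
  0.094 + x * (0.652 - 0.094)
}

#' Sample one mineral inclusion
#'
#' Draws dimensions uniformly from the kind's configured ranges and a
#' placement uniformly from the kind's admissible region: gap-zone
#' axial bands (ellipsoids), lattice planes through the fibril
#' cross-section (platelets), or the annulus just outside the fibril
#' surface (shell blocks). The crystal c-axis (long axis) is aligned
#' with the fibril axis for every kind. Draws come from R's RNG; seed
#' it (or call through [mineralize()]) for reproducibility.
#'
#' @param kind One of `"GAP_ELLIPSOID"`, `"INTRA_PLATELET"`,
#'   `"EXTRA_SHELL"`.
#' @param config A `mineralization_config`.
#' @param geom The `geometry_config` of the fibril being mineralized.
#' @return Object of class `inclusion_spec`: list with `kind`,
#'   `dimensions` (named), `center` (x, y, z or r, theta, z for
#'   shells) and `axis = "z"`.
#' @export
sample_inclusion <- function(kind, config, geom) {
  kind <- match.arg(kind, c("GAP_ELLIPSOID", "INTRA_PLATELET", "EXTRA_SHELL"))
  R <- geom$fibril_diameter / 2
  Lz <- geom$cell_length
  spec <- switch(kind,
    GAP_ELLIPSOID = {
      bands <- gap_bands(geom)
      b <- sample.int(nrow(bands), 1)
      # uniform over the fibril cross-section disk
      rr <- R * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      list(kind = kind,
           dimensions = c(long = stats::runif(1, config$ellipsoid_long[1],
                                              config$ellipsoid_long[2]),
                          short = stats::runif(1, config$ellipsoid_short[1],
                                               config$ellipsoid_short[2])),
           center = c(x = rr * cos(th), y = rr * sin(th),
                      z = stats::runif(1, bands$zlo[b], bands$zhi[b])))
    },
    INTRA_PLATELET = {
      # lattice-plane families containing the fibril axis: 0, 60, 120 deg
      phi <- sample(c(0, 60, 120), 1) * pi / 180
      rr <- R * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      list(kind = kind,
           dimensions = c(thickness = stats::runif(1, config$platelet_thickness[1],
                                                   config$platelet_thickness[2]),
                          width = stats::runif(1, config$platelet_width[1],
                                               config$platelet_width[2]),
                          length = stats::runif(1, config$platelet_length[1],
                                                config$platelet_length[2])),
           center = c(x = rr * cos(th), y = rr * sin(th),
                      z = stats::runif(1, 0, Lz)),
           plane_angle = phi)
    },
    EXTRA_SHELL = {
      list(kind = kind,
           dimensions = c(thickness = stats::runif(1, config$shell_thickness[1],
                                                   config$shell_thickness[2]),
                          width = stats::runif(1, config$shell_width[1],
                                               config$shell_width[2]),
                          length = stats::runif(1, config$shell_length[1],
                                                config$shell_length[2])),
           center = c(r = R + config$rejection_distance,
                      theta = stats::runif(1, 0, 2 * pi),
                      z = stats::runif(1, 0, Lz)))
    })
  spec$axis <- "z"
  structure(spec, class = "inclusion_spec")
}

# cubic bead lattice covering [lo, hi] in each of three basis directions,
# centered on `center` expressed in that basis
.hap_lattice <- function(center, half, spacing) {
  ax <- lapply(1:3, function(d) {
    n <- floor(half[d] / spacing)
    center[d] + spacing * (-n:n)
  })
  as.matrix(expand.grid(u = ax[[1]], v = ax[[2]], w = ax[[3]]))
}

#' Realize an inclusion as mineral beads and bonds
#'
#' Fills the inclusion solid with hydroxyapatite beads on a simple
#' cubic lattice (spacing `hap_bead_spacing`, axes aligned with the
#' crystal c-axis = fibril axis), discards beads closer than
#' `rejection_distance` to any existing bead, and bonds surviving
#' bead pairs within `1.2 * hap_bead_spacing` (within the inclusion
#' and to previously placed mineral). Collagen-mineral contact stays
#' nonbonded.
#'
#' @param spec An `inclusion_spec`.
#' @param model A `fibril_model`.
#' @param config A `mineralization_config`.
#' @return List: `positions` (k x 3, possibly 0-row), `bonds`
#'   (1-based into the model grown by these beads), `n_candidates`.
#' @export
realize_inclusion <- function(spec, model, config) {
  sp <- config$hap_bead_spacing
  d <- spec$dimensions
  pts <- switch(spec$kind,
    GAP_ELLIPSOID = {
      ce <- spec$center
      half <- c(d[["short"]] / 2, d[["short"]] / 2, d[["long"]] / 2)
      g <- .hap_lattice(c(ce[["x"]], ce[["y"]], ce[["z"]]), half, sp)
      u <- (g[, 1] - ce[["x"]]) / half[1]
      v <- (g[, 2] - ce[["y"]]) / half[2]
      w <- (g[, 3] - ce[["z"]]) / half[3]
      g[u^2 + v^2 + w^2 <= 1, , drop = FALSE]
    },
    INTRA_PLATELET = {
      ce <- spec$center
      phi <- spec$plane_angle
      uvec <- c(cos(phi), sin(phi))   # in-plane width direction
      nvec <- c(-sin(phi), cos(phi))  # plane normal (thickness)
      half <- c(d[["width"]] / 2, d[["thickness"]] / 2, d[["length"]] / 2)
      g <- .hap_lattice(c(0, 0, ce[["z"]]), half, sp)
      # map (u, n, z) lattice coordinates back to cartesian
      x <- ce[["x"]] + g[, 1] * uvec[1] + g[, 2] * nvec[1]
      y <- ce[["y"]] + g[, 1] * uvec[2] + g[, 2] * nvec[2]
      cbind(x, y, g[, 3])
    },
    EXTRA_SHELL = {
      ce <- spec$center
      r0 <- ce[["r"]]
      rmid <- r0 + d[["thickness"]] / 2
      half_arc <- d[["width"]] / 2
      nr <- floor(d[["thickness"]] / sp)
      radii <- r0 + sp * (0:nr)
      nth <- floor(half_arc / sp)
      dth <- sp / rmid # arc step ~ bead spacing at mid-thickness
      nz <- floor(d[["length"]] / 2 / sp)
      do.call(rbind, lapply(radii, function(rr) {
        gg <- expand.grid(th = ce[["theta"]] + dth * seq(-nth, nth),
                          z = ce[["z"]] + sp * seq(-nz, nz))
        cbind(rr * cos(gg$th), rr * sin(gg$th), gg$z)
      }))
    })
  # intrafibrillar mineral stays inside the fibril surface
  if (spec$kind != "EXTRA_SHELL" && !is.null(model$config)) {
    R_fib <- model$config$fibril_diameter / 2
    pts <- pts[pts[, 1]^2 + pts[, 2]^2 <= R_fib^2, , drop = FALSE]
  }
  if (is.null(pts) || nrow(pts) == 0)
    return(list(positions = matrix(0, 0, 3), bonds = matrix(0L, 0, 2),
                n_candidates = 0L))
  pts <- wrap_positions(pts, model$cell$Lz)
  keep <- .min_dist_keep_cpp(pts, model$positions, config$rejection_distance,
                             model$cell$Lz)
  pts <- pts[keep, , drop = FALSE]
  n_new <- nrow(pts)
  if (n_new == 0)
    return(list(positions = matrix(0, 0, 3), bonds = matrix(0L, 0, 2),
                n_candidates = length(keep)))
  n0 <- nrow(model$positions)
  rbond <- 1.2 * sp
  self_pairs <- .close_pairs_cpp(pts, matrix(0, 0, 3), rbond, model$cell$Lz)
  bonds <- self_pairs + n0
  hap_idx <- which(model$species == 1L)
  if (length(hap_idx) > 0) {
    cross <- .close_pairs_cpp(pts, model$positions[hap_idx, , drop = FALSE],
                              rbond, model$cell$Lz)
    if (nrow(cross) > 0)
      bonds <- rbind(bonds, cbind(cross[, 1] + n0, hap_idx[cross[, 2]]))
  }
  list(positions = pts, bonds = bonds, n_candidates = length(keep))
}

# per-bead volumes: spheres at the species' equilibrium spacing
.bead_volume <- function(species) {
  d <- ifelse(species == 0L, 14.00, 10.00)
  pi / 6 * d^3
}

#' Mineral volume fraction of a model
#'
#' `V_hap / (V_hap + V_col)` with each bead contributing a fixed
#' spherical volume of diameter equal to its species' equilibrium
#' spacing (14.00 A collagen, 10.00 A hydroxyapatite). A convention
#' choice: cheap, monotone in bead count, and consistent across
#' models.
#'
#' @param model A `fibril_model`.
#' @return Fraction in `[0, 1)`.
#' @export
compute_mvf <- function(model) {
  v <- .bead_volume(model$species)
  vh <- sum(v[model$species == 1L])
  vh / (vh + sum(v[model$species == 0L]))
}

# append realized mineral beads/bonds to a model
.add_mineral <- function(model, real) {
  n_new <- nrow(real$positions)
  if (n_new == 0) return(model)
  model$positions <- rbind(model$positions, real$positions)
  model$species <- c(model$species, rep(1L, n_new))
  model$molecule <- c(model$molecule, rep(max(model$molecule) + 1L, n_new))
  model$mass <- c(model$mass, rep(1316, n_new))
  if (nrow(real$bonds) > 0) {
    model$bonds <- rbind(model$bonds, real$bonds)
    model$bond_type <- c(model$bond_type, rep(1L, nrow(real$bonds)))
  }
  model
}

#' Mineralize a fibril to a target volume fraction
#'
#' Samples and realizes inclusions one by one, alternating kinds to
#' hold the realized extrafibrillar share near
#' `extrafibrillar_share`, until the computed mineral volume fraction
#' first reaches `target_mvf`. Mineral beads take the collagen bead
#' mass (the mesoscopic masses are set per bead, not per species).
#'
#' @param model A mineral-free (or partially mineralized) `fibril_model`.
#' @param config A `mineralization_config`.
#' @param seed Integer seed; the function uses an isolated RNG stream
#'   and restores the caller's RNG state.
#' @return The mineralized `fibril_model`, with `inclusion_log`
#'   (data.frame: kind, dimensions, placement, beads added, MVF after)
#'   attached.
#' @export
mineralize <- function(model, config, seed = 1L) {
  local_seed(seed)
  target <- config$target_mvf
  if (compute_mvf(model) > target && target > 0)
    stop("mineralize: model already above target MVF")
  log_rows <- list()
  consecutive_rejects <- 0L
  vol_extra <- 0; vol_intra <- 0
  R_fib <- model$config$fibril_diameter / 2
  while (compute_mvf(model) < target) {
    # volume-deficit scheduling: pick the compartment lagging its target
    # share (count-probability draws cannot hold a volume split when shell
    # blocks dwarf the intrafibrillar inclusions). Endgame: once less than
    # a typical shell volume is missing, fill with the small intrafibrillar
    # kinds so the closing inclusion cannot blow the share or the target.
    share <- if (vol_extra + vol_intra > 0) vol_extra / (vol_extra + vol_intra) else NA
    v_col_now <- sum(.bead_volume(model$species)[model$species == 0L])
    v_target <- target / (1 - target) * v_col_now
    remaining <- v_target - (vol_extra + vol_intra)
    shell_typ <- mean(config$shell_thickness) * mean(config$shell_width) *
      mean(config$shell_length) / config$hap_bead_spacing^3 * pi / 6 * 10^3
    kind <- if (is.na(share)) {
      "EXTRA_SHELL"
    } else if (share > config$extrafibrillar_share ||
               (remaining < shell_typ &&
                share >= config$extrafibrillar_share - config$share_tolerance)) {
      sample(c("GAP_ELLIPSOID", "INTRA_PLATELET"), 1)
    } else {
      "EXTRA_SHELL"
    }
    spec <- sample_inclusion(kind, config, model$config)
    real <- realize_inclusion(spec, model, config)
    n_new <- nrow(real$positions)
    if (n_new == 0) {
      consecutive_rejects <- consecutive_rejects + 1L
      if (consecutive_rejects >= config$max_consecutive_rejects)
        stop(sprintf(
          "mineralize: %d consecutive fully-rejected inclusions; achieved MVF %.4f of target %.4f",
          consecutive_rejects, compute_mvf(model), target))
      next
    }
    consecutive_rejects <- 0L
    model <- .add_mineral(model, real)
    vnew <- n_new * pi / 6 * 10^3
    if (kind == "EXTRA_SHELL") vol_extra <- vol_extra + vnew
    else vol_intra <- vol_intra + vnew
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      kind = kind,
      dim1 = spec$dimensions[[1]], dim2 = spec$dimensions[[2]],
      dim3 = if (length(spec$dimensions) > 2) spec$dimensions[[3]] else NA_real_,
      c1 = spec$center[[1]], c2 = spec$center[[2]], c3 = spec$center[[3]],
      beads = n_new, mvf_after = compute_mvf(model))
  }
  model$inclusion_log <- if (length(log_rows)) do.call(rbind, log_rows)
                         else data.frame()
  model$extrafibrillar_share_realized <-
    if (vol_extra + vol_intra > 0) vol_extra / (vol_extra + vol_intra) else NA_real_
  model$fibril_radius_build <- R_fib
  model
}
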