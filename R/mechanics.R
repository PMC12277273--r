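#' Moving-average smoothing of a stress-strain curve
#'
#' Centered moving average over the strain-ordered records; the strain
#' grid is unchanged and the window shrinks symmetrically near the
#' ends (partial windows). MD stress fluctuations of a few megapascals
#' would otherwise trigger spurious yield detection.
#'
#' @param curve A `stress_strain` data.frame (or any data.frame with
#'   `strain` and `stress_MPa`).
#' @param window Odd window length in records (default 51); 1 is the
#'   identity.
#' @return The curve with `stress_MPa` replaced by its smoothed value
#'   and the raw series kept as `stress_raw_MPa`.
#' @export
smooth_curve <- function(curve, window = 51L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  n <- nrow(curve)
  if (n < window) stop("smooth_curve: fewer records than the window")
  if (is.unsorted(curve$strain)) stop("smooth_curve: strain must be ordered")
  y <- curve$stress_MPa
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  # symmetric partial windows at the edges
  half <- pmin(seq_len(n) - lo, hi - seq_len(n))
  lo <- seq_len(n) - half
  hi <- seq_len(n) + half
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out <- curve
  out$stress_raw_MPa <- y
  out$stress_MPa <- sm
  out
}

#' Young's modulus from the initial slope
#'
#' Ordinary least-squares slope of stress versus strain restricted to
#' the 0-10% strain window.
#'
#' @param curve Data.frame with `strain` and `stress_MPa`.
#' @param strain_window Fit window, fractions (default `c(0, 0.10)`).
#' @return Modulus, MPa.
#' @export
youngs_modulus <- function(curve, strain_window = c(0, 0.10)) {
  sel <- curve$strain >= strain_window[1] & curve$strain <= strain_window[2]
  if (sum(sel) < 2 || max(curve$strain) < strain_window[2])
    stop("youngs_modulus: curve does not span the fit window")
  unname(stats::coef(stats::lm(stress_MPa ~ strain, data = curve[sel, ]))[2])
}

#' Offset yield point with drop/lift classification
#'
#' Constructs the elastic line `sigma = E * eps` and the 1% offset
#' line `sigma = E * (eps - offset)`. DROP yield: the first crossing
#' (before the ultimate strain) where the curve falls onto the offset
#' line from above — the onset of intermolecular sliding. If no such
#' crossing exists, LIFT yield: the first strain where the curve rises
#' above the elastic line by `E * offset` — strain hardening departure,
#' seen at high mineral fractions where sliding is blocked. NONE if
#' neither occurs.
#'
#' @param curve Data.frame with `strain` and `stress_MPa` (smooth it
#'   first; see [smooth_curve()]).
#' @param offset Offset strain (default 0.01).
#' @param modulus Elastic modulus, MPa; computed from the curve when
#'   omitted.
#' @return List: `strain`, `stress` (MPa), `mode` ("DROP", "LIFT" or
#'   "NONE"; strain/stress are `NA` for NONE).
#' @export
yield_point <- function(curve, offset = 0.01, modulus = NULL) {
  if (is.unsorted(curve$strain)) stop("yield_point: strain must be ordered")
  E <- if (is.null(modulus)) youngs_modulus(curve) else modulus
  eps <- curve$strain
  sig <- curve$stress_MPa
  # yield must precede the ultimate point; on a stress plateau the whole
  # plateau counts, so the cutoff is the last point of maximal stress
  pre <- eps <= eps[max(which(sig >= max(sig) - 1e-9 * abs(max(sig))))]
  # DROP: curve meets the offset line from above
  gap <- sig - E * (eps - offset)
  cross <- which(pre & eps > offset & gap <= 0 &
                   c(Inf, utils::head(gap, -1)) > 0)
  if (length(cross) > 0) {
    i <- cross[1]
    # linear interpolation of the crossing
    f <- gap[i - 1] / (gap[i - 1] - gap[i])
    e_y <- eps[i - 1] + f * (eps[i] - eps[i - 1])
    return(list(strain = e_y, stress = E * (e_y - offset), mode = "DROP"))
  }
  # LIFT: departure above the elastic line by E * offset
  lift <- which(pre & sig - E * eps >= E * offset)
  if (length(lift) > 0) {
    i <- lift[1]
    return(list(strain = eps[i], stress = sig[i], mode = "LIFT"))
  }
  list(strain = NA_real_, stress = NA_real_, mode = "NONE")
}

#' Ultimate tensile point
#'
#' Argmax of the (smoothed) stress; ties go to the smaller strain.
#'
#' @param curve Data.frame with `strain` and `stress_MPa`.
#' @return List `strain`, `stress` (MPa).
#' @export
ultimate_point <- function(curve) {
  if (nrow(curve) == 0) stop("ultimate_point: empty curve")
  i <- which.max(curve$stress_MPa) # first maximum on ties
  list(strain = curve$strain[i], stress = curve$stress_MPa[i])
}

#' Extract the five mechanical properties from a tensile record
#'
#' Smooths the curve, fits the 0-10% modulus, locates the 1% offset
#' yield (drop or lift mode) and the ultimate point.
#'
#' @param curve A `stress_strain` data.frame from [tensile_run()].
#' @param window Smoothing window (records).
#' @param offset Yield offset strain.
#' @return Object of class `mechanical_properties`: list with
#'   `youngs_modulus` (MPa), `yield_strain`, `yield_stress` (MPa),
#'   `ultimate_strain`, `ultimate_stress` (MPa), `yield_mode`, and
#'   `ultimate_unsmoothed` (strain/stress of the raw-series peak).
#' @export
extract_properties <- function(curve, window = 51L, offset = 0.01) {
  sm <- smooth_curve(curve, window)
  E <- youngs_modulus(sm)
  yp <- yield_point(sm, offset = offset, modulus = E)
  up <- ultimate_point(sm)
  iraw <- which.max(sm$stress_raw_MPa)
  structure(list(
    youngs_modulus = E,
    yield_strain = yp$strain, yield_stress = yp$stress,
    ultimate_strain = up$strain, ultimate_stress = up$stress,
    yield_mode = yp$mode,
    ultimate_unsmoothed = list(strain = sm$strain[iraw],
                               stress = sm$stress_raw_MPa[iraw])
  ), class = "mechanical_properties")
}

#' @export
print.mechanical_properties <- function(x, ...) {
  cat(sprintf(
    "<mechanical_properties> E = %.0f MPa | yield (%s): %.2f%% / %.0f MPa | ultimate: %.2f%% / %.0f MPa\n",
    x$youngs_modulus, x$yield_mode, 100 * x$yield_strain, x$yield_stress,
    100 * x$ultimate_strain, x$ultimate_stress))
  invisible(x)
}

#' Aggregate replicate property sets
#'
#' Elementwise minimum, maximum and arithmetic mean of each numeric
#' property over replicates, plus a tally of yield modes (replicate
#' curves at high mineral fraction mix drop- and lift-mode yields).
#'
#' @param props List of `mechanical_properties`.
#' @return List with one `c(min, max, mean)` vector per property
#'   (NA yields excluded with `na.rm`), `n`, and `mode_tally`.
#' @export
aggregate_replicates <- function(props) {
  if (length(props) == 0) stop("aggregate_replicates: no replicates")
  fields <- c("youngs_modulus", "yield_strain", "yield_stress",
              "ultimate_strain", "ultimate_stress")
  out <- lapply(fields, function(f) {
    v <- vapply(props, function(p) as.numeric(p[[f]]), numeric(1))
    c(min = suppressWarnings(min(v, na.rm = TRUE)),
      max = suppressWarnings(max(v, na.rm = TRUE)),
      mean = mean(v, na.rm = TRUE))
  })
  names(out) <- fields
  modes <- vapply(props, function(p) p$yield_mode, character(1))
  out$n <- length(props)
  out$mode_tally <- table(factor(modes, levels = c("DROP", "LIFT", "NONE")))
  out
}

#' Five-position insertion study
#'
#' For each relative insertion position: set the target mineral volume
#' fraction from the linear gradient, mineralize with a fresh seed per
#' replicate, relax, run the tensile test and extract properties.
#' Replicate seeds are `base_seed + replicate index`; mineralization,
#' velocity initialization and thermostat noise consume independent
#' derived streams.
#'
#' @param geom A `geometry_config` (use [microfibril_preset()] for
#'   desk-scale studies).
#' @param protocol A `protocol_config`.
#' @param positions Relative insertion positions in `[0, 1]`.
#' @param n_replicates Replicates per position (default 5).
#' @param base_seed Base seed.
#' @param window,offset Property-extraction settings.
#' @param mineralization Named list of [mineralization_config()] overrides
#'   (everything but `target_mvf`). Desk-scale studies should scale the
#'   extrafibrillar shell ranges down with the cross-section: full-size
#'   shell blocks hold more mineral than a microfibril's whole budget, so
#'   one inclusion would saturate every position identically.
#' @return Object of class `insertion_study`: list with `summary`
#'   (data.frame: x, target and achieved MVF, min/max/mean of each
#'   property, lift/drop tally), `replicates` (nested detail), and
#'   `seeds`.
#' @export
run_insertion_study <- function(geom, protocol = protocol_config(),
                                positions = c(0, 0.25, 0.5, 0.75, 1),
                                n_replicates = 5L,
                                base_seed = 1L,
                                window = 51L, offset = 0.01,
                                mineralization = list()) {
  base <- build_fibril(geom)
  reps <- list()
  rows <- list()
  for (x in positions) {
    target <- mvf_at_position(x)
    detail <- list()
    props <- list()
    for (r in seq_len(n_replicates)) {
      # a fresh stream per replicate AND per position
      seed <- derive_seed(base_seed + r, paste0("x", format(x)))
      res <- tryCatch({
        mc <- do.call(mineralization_config,
                      c(list(target_mvf = target), mineralization))
        model <- mineralize(base, mc, seed = derive_seed(seed, "mineralize"))
        st <- simulation_state(model, temperature = protocol$temperature,
                               seed = seed)
        rx <- suppressWarnings(relax(st, protocol, seed = seed))
        curve <- tensile_run(rx$state, protocol, seed = seed)
        list(curve = curve, props = extract_properties(curve, window, offset),
             mvf = compute_mvf(model), seed = seed,
             residual_stress_MPa = rx$residual_stress_MPa)
      }, error = function(e) {
        warning(sprintf("replicate x=%.2f r=%d failed: %s", x, r,
                        conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) {
        detail[[length(detail) + 1L]] <- res
        props[[length(props) + 1L]] <- res$props
        message(sprintf(
          "x = %.2f replicate %d/%d: MVF %.3f, E %.0f MPa, UTS %.0f MPa (%s)",
          x, r, n_replicates, res$mvf, res$props$youngs_modulus,
          res$props$ultimate_stress, res$props$yield_mode))
      }
    }
    if (length(props) == 0)
      stop(sprintf("run_insertion_study: all replicates failed at x = %.2f", x))
    ag <- aggregate_replicates(props)
    rows[[length(rows) + 1L]] <- data.frame(
      x = x, target_mvf = target,
      achieved_mvf = mean(vapply(detail, `[[`, 0, "mvf")),
      E_MPa = ag$youngs_modulus[["mean"]],
      E_min = ag$youngs_modulus[["min"]], E_max = ag$youngs_modulus[["max"]],
      yield_strain = ag$yield_strain[["mean"]],
      yield_stress_MPa = ag$yield_stress[["mean"]],
      ultimate_strain = ag$ultimate_strain[["mean"]],
      ultimate_stress_MPa = ag$ultimate_stress[["mean"]],
      n_drop = unname(ag$mode_tally["DROP"]),
      n_lift = unname(ag$mode_tally["LIFT"]),
      n_none = unname(ag$mode_tally["NONE"]),
      n_ok = length(props))
    reps[[as.character(x)]] <- detail
  }
  structure(list(summary = do.call(rbind, rows), replicates = reps,
                 seeds = base_seed + seq_len(n_replicates),
                 positions = positions),
            class = "insertion_study")
}

#' @export
print.insertion_study <- function(x, ...) {
  cat("<insertion_study>\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Plot a stress-strain curve
#'
#' @param x A `stress_strain` data.frame.
#' @param window Smoothing window overlay (0 = raw only).
#' @param ... Passed to [plot()].
#' @export
plot.stress_strain <- function(x, window = 51L, ...) {
  plot(x$strain, x$stress_MPa, type = "l", col = "grey60",
       xlab = "engineering strain", ylab = "axial stress (MPa)", ...)
  if (window > 1 && nrow(x) >= window)
    graphics::lines(smooth_curve(x, window)$strain,
                    smooth_curve(x, window)$stress_MPa, col = "red3", lwd = 2)
  invisible(x)
}
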