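#' LED-type source specification
#'
#' Square emitter centered on the origin of the tissue surface with a top-hat
#' near field and a Lambertian far field restricted to a half angle. Half
#' angles above pi/2 are clamped to pi/2 with a warning, since a Lambertian
#' far field cannot exceed the forward hemisphere -- the nominal
#' device-datasheet half angle of 2.4 rad is therefore equivalent to the
#' default pi/2.
#'
#' @param side Side length of the square emitter, mm.
#' @param half_angle Emission half angle, radians.
#' @return An object of class `mc_source`.
#' @export
mc_source <- function(side = 1.0, half_angle = pi / 2) {
  stopifnot(side >= 0, half_angle > 0)
  if (half_angle > pi / 2) {
    warning("source half angle ", signif(half_angle, 3),
            " rad exceeds pi/2; clamping to pi/2")
    half_angle <- pi / 2
  }
  structure(list(side = side, half_angle = half_angle), class = "mc_source")
}

#' Annular detector specification
#'
#' Donut-shaped detector concentric with the emitter. The default radii are
#' the device-datasheet values (0.0071/0.0091 mm); because they lie well
#' inside the 1 mm emitter footprint and subtend a near-zero area, grid
#' simulations normally use [mc_detector_annulus()], the physically
#' consistent ring just outside the source footprint.
#'
#' @param inner,outer Annulus radii in mm (`0 <= inner < outer`).
#' @param surface `"top"` (reflectance, default) or `"bottom"`
#'   (transmittance; mainly for closed-form validation set-ups).
#' @return An object of class `mc_detector`.
#' @export
mc_detector <- function(inner = 0.0071, outer = 0.0091,
                        surface = c("top", "bottom")) {
  surface <- match.arg(surface)
  stopifnot(inner >= 0, outer > inner)
  structure(list(inner = inner, outer = outer, surface = surface),
            class = "mc_detector")
}

#' Annular detector hugging the emitter footprint
#'
#' A 0.2 mm wide ring starting at the circumscribed radius of the default
#' 1 mm square emitter (`sqrt(2)/2` mm), i.e. the closest ring that does not
#' overlap the source.
#'
#' @param source An [mc_source()]; its side sets the inner radius.
#' @param width Ring width, mm.
#' @return An object of class `mc_detector`.
#' @export
mc_detector_annulus <- function(source = mc_source(), width = 0.2) {
  inner <- source$side * sqrt(2) / 2
  mc_detector(inner = inner, outer = inner + width)
}

#' Detector active area in cm^2
#' @param detector An [mc_detector()].
#' @export
detector_area_cm2 <- function(detector) {
  pi * (detector$outer^2 - detector$inner^2) / 100  # mm^2 -> cm^2
}

#' Derive a reproducible substream seed from a master seed
#'
#' Seeds are expanded with a splitmix64 walk so that runs (and triplicates)
#' use independent, reproducible streams. Returned seeds are 53-bit integers
#' stored exactly in doubles.
#'
#' @param master Master seed (non-negative integer-valued scalar).
#' @param k Substream index (0, 1, 2, ...).
#' @export
mc_substream_seed <- function(master, k) {
  vapply(k, function(kk) .mc_derive_seed(as.double(master), as.double(kk)),
         numeric(1))
}

#' Raw uniforms of the photon-transport random stream
#'
#' Exposes the exact `(0, 1]` uniform sequence the compiled engine consumes
#' for a given seed, enabling independently coded reference loops to replay
#' a simulation number for number.
#'
#' @param seed Stream seed.
#' @param n Number of uniforms.
#' @export
mc_rng_stream <- function(seed, n) .mc_rng_stream(as.double(seed), as.double(n))

#' Monte Carlo photon transport through a layered tissue model
#'
#' Weighted photon transport in laterally infinite layers: optical-path step
#' sampling, Henyey-Greenstein scattering, absorption weighting, Fresnel
#' splitting at the top tissue/ambient interface, an absorbing bottom
#' boundary, and Russian roulette termination. Deterministic for a fixed
#' seed.
#'
#' The absorbed fraction reported includes the net weight retired by Russian
#' roulette (a zero-mean correction), so that
#' `detected + escaped + absorbed = 1` holds to floating-point accuracy on
#' every run, not just in expectation.
#'
#' @param model A [build_tissue_model()] result (or any data frame with
#'   columns `thickness`, `mua`, `mus`, `g`, `n` in mm and cm^-1).
#' @param source An [mc_source()].
#' @param detector An [mc_detector()].
#' @param n_photons Number of photons (>= 1).
#' @param seed Stream seed (see [mc_substream_seed()]).
#' @param w_threshold,p_survive Russian roulette weight threshold and
#'   survival probability.
#' @param max_steps Safety cap on propagation steps per photon.
#' @param perturb_model Optional second tissue model differing from `model`
#'   only in absorption (same geometry, scattering and anisotropy). The
#'   photon paths of the main simulation are reweighted exactly by
#'   `exp(-sum_layers dmua * pathlength)` (correlated/perturbation
#'   sampling), yielding `detected_fraction_perturbed`: the detected
#'   fraction the perturbed model would give from the very same random
#'   stream. This is the strongest form of common-random-number pairing
#'   and the default route to pulsatile amplitudes.
#' @return An object of class `mc_result` with elements `detected_fraction`,
#'   `escaped_fraction`, `absorbed_fraction`, `n_photons`, `seed`,
#'   `n_detected_photons`, `roulette_net`, `mean_steps` (and
#'   `detected_fraction_perturbed` when `perturb_model` is given).
#' @export
mc_simulate <- function(model, source = mc_source(),
                        detector = mc_detector_annulus(source),
                        n_photons, seed,
                        w_threshold = 1e-4, p_survive = 0.1,
                        max_steps = 1e6, perturb_model = NULL) {
  stopifnot(n_photons >= 1)
  df <- as.data.frame(model)
  if (any(df$thickness <= 0)) stop("all layer thicknesses must be positive")
  if (any(df$mua < 0) || any(df$mus < 0)) stop("negative optical coefficients")
  if (length(unique(df$n)) != 1L)
    stop("internal layers must share one refractive index")
  z0 <- cumsum(c(0, df$thickness[-nrow(df)])) / 10  # mm -> cm
  z1 <- z0 + df$thickness / 10
  layers <- cbind(z0, z1, df$mua, df$mus, df$g)
  n_amb <- attr(model, "n_ambient")
  if (is.null(n_amb)) n_amb <- tissue_optics()$n_ambient
  mua_pert <- numeric(0)
  if (!is.null(perturb_model)) {
    pdf <- as.data.frame(perturb_model)
    if (nrow(pdf) != nrow(df) ||
        max(abs(pdf$thickness - df$thickness)) > 1e-12 ||
        max(abs(pdf$mus - df$mus)) > 1e-12 ||
        max(abs(pdf$g - df$g)) > 1e-12)
      stop("perturb_model must differ from model only in absorption")
    mua_pert <- pdf$mua
  }
  # detector/source lengths are mm; engine works in cm
  res <- .mc_engine(layers, df$n[1], n_amb,
                    source$side / 10, source$half_angle,
                    detector$inner / 10, detector$outer / 10,
                    as.integer(detector$surface == "bottom"),
                    as.double(n_photons), as.double(seed),
                    w_threshold, p_survive, as.double(max_steps),
                    mua_pert)
  absorbed <- res$absorbed_interior + res$absorbed_bottom - res$roulette_net
  structure(list(
    detected_fraction = res$detected,
    escaped_fraction = res$escaped,
    absorbed_fraction = absorbed,
    roulette_net = res$roulette_net,
    n_detected_photons = res$n_detected_photons,
    detected_fraction_perturbed =
      if (length(mua_pert)) res$detected_perturbed else NULL,
    mean_steps = res$mean_steps,
    n_photons = n_photons, seed = seed
  ), class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "MC result: %.3g photons, detected %.4g (%d photons), escaped %.4g, absorbed %.4g\n",
    x$n_photons, x$detected_fraction, x$n_detected_photons,
    x$escaped_fraction, x$absorbed_fraction))
  invisible(x)
}

#' Paired rest/pulse simulation at one grid point
#'
#' Estimates the rest (DC) and pulsatile (AC) detected amplitudes in
#' triplicate with common random numbers. DC is the rest detected
#' fraction; AC is rest minus pulse (the pulse state absorbs more, so this
#' magnitude convention keeps AC positive). Two pairing methods:
#' \describe{
#'   \item{`correlated`}{(default) one simulation per replicate; the pulse
#'     detected fraction is obtained by exact path reweighting of the rest
#'     simulation (see `perturb_model` in [mc_simulate()]). Same random
#'     stream by construction, lowest AC variance, half the cost.}
#'   \item{`paired`}{two simulations per replicate sharing a substream
#'     seed.}
#' }
#'
#' @param age,vfm,wavelength Grid point.
#' @param n_photons Photons per individual simulation.
#' @param seeds Three substream seeds (one per replicate); see
#'   [mc_substream_seed()].
#' @param source,detector Geometry (defaults: 1 mm square emitter,
#'   footprint-hugging annulus).
#' @param method Common-random-number pairing method (see above).
#' @param ... Passed on to [mc_simulate()] and [build_tissue_model()].
#' @return An object of class `pulse_pair` with mean `ac`, `dc`, the
#'   triplicate coefficient of variation `cv_ac`, per-replicate values, and
#'   a `converged` flag (FALSE when the mean AC is not positive at this
#'   photon count).
#' @export
run_pulse_pair <- function(age, vfm, wavelength, n_photons, seeds,
                           source = mc_source(),
                           detector = mc_detector_annulus(source),
                           method = c("correlated", "paired"), ...) {
  method <- match.arg(method)
  stopifnot(length(seeds) >= 1)
  rest_m <- build_tissue_model(age, vfm, wavelength, "rest", ...)
  pulse_m <- build_tissue_model(age, vfm, wavelength, "pulse", ...)
  acs <- numeric(length(seeds)); dcs <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    if (method == "correlated") {
      r <- mc_simulate(rest_m, source, detector, n_photons, seeds[i],
                       perturb_model = pulse_m)
      dcs[i] <- r$detected_fraction
      acs[i] <- r$detected_fraction - r$detected_fraction_perturbed
    } else {
      r <- mc_simulate(rest_m, source, detector, n_photons, seeds[i])
      p <- mc_simulate(pulse_m, source, detector, n_photons, seeds[i])
      dcs[i] <- r$detected_fraction
      acs[i] <- r$detected_fraction - p$detected_fraction
    }
  }
  ac <- mean(acs); dc <- mean(dcs)
  cv <- if (length(acs) > 1 && ac != 0) stats::sd(acs) / abs(ac) else NA_real_
  structure(list(
    age = age, vfm = vfm, wavelength = wavelength,
    ac = ac, dc = dc, cv_ac = cv, ac_replicates = acs, dc_replicates = dcs,
    n_photons = n_photons, seeds = seeds,
    converged = is.finite(ac) && ac > 0
  ), class = "pulse_pair")
}

#' @export
print.pulse_pair <- function(x, ...) {
  cat(sprintf(
    "Pulse pair (age %.1f, VFM %.2f, %g nm): AC %.4g, DC %.4g, CV(AC) %.3g [n=%.3g%s]\n",
    x$age, x$vfm, x$wavelength, x$ac, x$dc, x$cv_ac, x$n_photons,
    if (isTRUE(x$converged)) "" else ", UNCONVERGED"))
  invisible(x)
}

#' Grow the photon count until the triplicate AC coefficient of variation
#' converges
#'
#' Repeats triplicate rest/pulse pairs with a geometrically increasing
#' photon count until `cv_ac < target_cv`, or the photon budget is
#' exhausted (the best attempt is then returned flagged unconverged).
#'
#' @param age,vfm,wavelength Grid point.
#' @param target_cv Convergence threshold on the triplicate CV of AC
#'   (default 0.10).
#' @param start_n Photons per simulation for the first triplicate (>= 1e3).
#' @param growth_factor Photon-count multiplier between attempts.
#' @param max_photons Per-simulation photon budget cap.
#' @param master_seed Master seed; each simulation uses a distinct
#'   substream.
#' @param pair_fn Pair-generating function `(n_photons, seeds) ->
#'   pulse_pair`; replaceable by a stub for scaling-law tests. Defaults to
#'   [run_pulse_pair()] at the requested grid point.
#' @param ... Passed to [run_pulse_pair()].
#' @return The first converged `pulse_pair` (or the last attempt, flagged),
#'   with the photon count used recorded in `n_photons` and the attempt
#'   history in `attempts`.
#' @export
converge_pulse_pair <- function(age, vfm, wavelength, target_cv = 0.10,
                                start_n = 1e3, growth_factor = 4,
                                max_photons = 1e8, master_seed = 1,
                                pair_fn = NULL, ...) {
  stopifnot(start_n >= 1e3, growth_factor > 1)
  if (is.null(pair_fn))
    pair_fn <- function(n_photons, seeds)
      run_pulse_pair(age, vfm, wavelength, n_photons, seeds, ...)
  n <- start_n
  k <- 0
  history <- list()
  repeat {
    seeds <- mc_substream_seed(master_seed, k + 0:2)
    k <- k + 3
    pair <- pair_fn(n, seeds)
    history[[length(history) + 1L]] <-
      list(n_photons = n, cv_ac = pair$cv_ac)
    if (is.infinite(target_cv) ||
        (is.finite(pair$cv_ac) && pair$cv_ac < target_cv && pair$ac > 0)) {
      pair$converged <- TRUE
      break
    }
    if (n * growth_factor > max_photons) {
      pair$converged <- FALSE
      break
    }
    n <- n * growth_factor
  }
  pair$attempts <- history
  pair$target_cv <- target_cv
  pair
}

#' Assemble pulse pairs into an amplitude grid
#'
#' @param pairs A list of `pulse_pair` objects.
#' @return An object of class `amplitude_grid`: a data frame with columns
#'   `age`, `vfm`, `wavelength`, `ac`, `dc`, `cv_ac`, `n_photons`,
#'   `converged`.
#' @export
amplitude_grid <- function(pairs) {
  df <- do.call(rbind, lapply(pairs, function(p)
    data.frame(age = p$age, vfm = p$vfm, wavelength = p$wavelength,
               ac = p$ac, dc = p$dc, cv_ac = p$cv_ac,
               n_photons = p$n_photons, converged = p$converged)))
  structure(df, class = c("amplitude_grid", "data.frame"))
}

#' Normalize an amplitude grid to its maxima
#'
#' Scales the AC and DC maps so the largest value of each is exactly 1 and
#' records the argmax grid point of each map.
#'
#' @param grid An [amplitude_grid()] (or compatible data frame).
#' @return The grid with added columns `ac_norm`, `dc_norm` and attributes
#'   `ac_argmax` / `dc_argmax` (single-row data frames).
#' @export
normalize_grid <- function(grid) {
  if (nrow(grid) == 0) stop("empty amplitude grid")
  if (max(grid$ac) <= 0 || max(grid$dc) <= 0)
    stop("cannot normalize an all-zero amplitude grid")
  grid$ac_norm <- grid$ac / max(grid$ac)
  grid$dc_norm <- grid$dc / max(grid$dc)
  attr(grid, "ac_argmax") <- grid[which.max(grid$ac),
                                  c("age", "vfm", "wavelength")]
  attr(grid, "dc_argmax") <- grid[which.max(grid$dc),
                                  c("age", "vfm", "wavelength")]
  grid
}
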