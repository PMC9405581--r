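#' Device filter specification
#'
#' The three device filter chains plus a pass-through control:
#' \describe{
#'   \item{`butter_bp`}{0.1--7 Hz Butterworth bandpass.}
#'   \item{`cheby2_bp_ma`}{0.1--7 Hz inverse Chebyshev (type II) bandpass
#'     followed by a 10-sample trailing moving average.}
#'   \item{`cheby2_lp_ma`}{7 Hz inverse Chebyshev lowpass followed by a
#'     10-sample trailing moving average.}
#'   \item{`none`}{identity (control).}
#' }
#' All IIR stages are applied causally (forward only), matching on-device
#' processing. The type II stopband attenuation defaults to 40 dB.
#'
#' @param id Filter chain identifier (see above), or 1--4 as an index into
#'   `c("butter_bp", "cheby2_bp_ma", "cheby2_lp_ma", "none")`.
#' @param order IIR design order passed to the designer (the bandpass
#'   transfer functions are of twice this order).
#' @param band Passband edges in Hz (bandpass) or cutoff (lowpass).
#' @param ma_window Moving-average length in samples.
#' @param stopband_db Type II stopband attenuation.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(id = c("butter_bp", "cheby2_bp_ma", "cheby2_lp_ma",
                               "none"),
                        order = 4, band = NULL, ma_window = 10,
                        stopband_db = 40) {
  if (is.numeric(id))
    id <- c("butter_bp", "cheby2_bp_ma", "cheby2_lp_ma", "none")[id]
  id <- match.arg(id)
  if (is.null(band))
    band <- if (id == "cheby2_lp_ma") 7 else c(0.1, 7)
  if (length(band) == 2 && band[1] >= band[2])
    stop("bandpass edges must satisfy low < high")
  if (ma_window < 1) stop("ma_window must be >= 1")
  structure(list(id = id, order = order, band = band, ma_window = ma_window,
                 stopband_db = stopband_db),
            class = "filter_spec")
}

# Factor a transfer function into second-order sections. Direct
# high-order recursions at the narrow 0.1 Hz band edge are too
# ill-conditioned in double precision; cascaded biquads (conjugate
# pole/zero pairs, nearest-neighbour pairing) keep the filter numerically
# clean, as device DSP implementations do.
.tf_to_sos <- function(b, a) {
  pair_up <- function(r) {
    # group complex-conjugate (and leftover real) roots into pairs
    r <- r[order(-Mod(r))]
    cplx <- r[Im(r) > 1e-8]
    real <- Re(r[abs(Im(r)) <= 1e-8])
    sects <- lapply(cplx, function(p) c(p, Conj(p)))
    while (length(real) >= 2) {
      sects[[length(sects) + 1]] <- real[1:2]
      real <- real[-(1:2)]
    }
    if (length(real) == 1) sects[[length(sects) + 1]] <- real[1]
    sects
  }
  poly2 <- function(roots) {
    if (length(roots) == 1) return(Re(c(1, -roots)))
    Re(c(1, -(roots[1] + roots[2]), roots[1] * roots[2]))
  }
  zs <- pair_up(polyroot(rev(b)))
  ps <- pair_up(polyroot(rev(a)))
  # pair each pole section with the nearest remaining zero section
  sos <- vector("list", length(ps))
  used <- logical(length(zs))
  for (i in seq_along(ps)) {
    pc <- mean(ps[[i]])
    j <- which.min(ifelse(used, Inf,
                          vapply(zs, function(z) Mod(mean(z) - pc),
                                 numeric(1))))
    if (length(zs) && is.finite(j) && j <= length(zs) && !used[j]) {
      used[j] <- TRUE
      sos[[i]] <- list(b = poly2(zs[[j]]), a = poly2(ps[[i]]))
    } else {
      sos[[i]] <- list(b = 1, a = poly2(ps[[i]]))
    }
  }
  list(gain = b[1] / a[1], sections = sos)
}

.apply_sos <- function(sos, x) {
  y <- x * sos$gain
  for (s in sos$sections)
    y <- as.numeric(signal::filter(signal::Arma(b = s$b, a = s$a), y))
  y
}

#' Apply a device filter chain to a record
#'
#' Causal IIR filtering implemented as a cascade of second-order sections;
#' for the `*_ma` chains the trailing moving average is applied after the
#' IIR stage.
#'
#' @param record A [ppg_record()].
#' @param spec A [filter_spec()].
#' @return The filtered record (filter id recorded in metadata).
#' @export
apply_ppg_filter <- function(record, spec = filter_spec()) {
  fs <- record$fs
  y <- record$samples
  if (spec$id != "none") {
    if (any(spec$band >= fs / 2))
      stop("filter band edge at or above Nyquist (", fs / 2, " Hz)")
    w <- spec$band / (fs / 2)
    flt <- switch(spec$id,
      butter_bp = signal::butter(spec$order, w, type = "pass"),
      cheby2_bp_ma = signal::cheby2(spec$order, spec$stopband_db, w,
                                    type = "pass"),
      cheby2_lp_ma = signal::cheby2(spec$order, spec$stopband_db, w,
                                    type = "low"))
    y <- .apply_sos(.tf_to_sos(flt$b, flt$a), y)
    if (spec$id %in% c("cheby2_bp_ma", "cheby2_lp_ma")) {
      k <- spec$ma_window
      y <- as.numeric(stats::filter(y, rep(1 / k, k), method = "convolution",
                                    sides = 1))
      y[seq_len(k - 1)] <- y[k]  # warm-up: hold the first full average
    }
  }
  out <- record
  out$samples <- y
  out$meta$filter <- spec$id
  out
}

#' ADC specification
#'
#' @param bits ADC resolution in bits (1--32).
#' @param reference_current Full-scale reference current, amperes.
#' @param led_power LED optical power, watts.
#' @param photodiode_area Photodiode active area, cm^2; defaults to the
#'   area of the footprint-hugging detector annulus.
#' @return An object of class `adc_spec`.
#' @export
adc_spec <- function(bits = 10, reference_current = 32e-6, led_power = 0.05,
                     photodiode_area = detector_area_cm2(mc_detector_annulus())) {
  stopifnot(bits >= 1, bits <= 32, reference_current > 0, led_power > 0,
            photodiode_area > 0)
  structure(list(bits = bits, reference_current = reference_current,
                 led_power = led_power, photodiode_area = photodiode_area),
            class = "adc_spec")
}

#' Quantize a record through the simulated ADC
#'
#' Each sample (in detected-fraction units) maps to a photocurrent
#' `i = 10 * value * led_power * photodiode_area`, then to an integer code
#' `floor(i * 2^bits / reference_current)` saturated to
#' `[0, 2^bits - 1]`. The reconstructed sample is the code mapped back to
#' input units, so quantization error is at most one least significant bit
#' for unsaturated samples.
#'
#' @param record A [ppg_record()].
#' @param spec An [adc_spec()].
#' @return The quantized record; `samples` holds the reconstruction in
#'   input units, `meta$adc_codes` the integer codes, `meta$adc` the spec,
#'   and `meta$adc_saturated` whether any sample exceeded the reference
#'   current.
#' @export
adc_convert <- function(record, spec = adc_spec()) {
  scale <- 10 * spec$led_power * spec$photodiode_area
  i <- record$samples * scale
  full <- 2^spec$bits
  code <- floor(i * full / spec$reference_current)
  saturated <- any(code >= full) || any(code < 0)
  code <- pmin(pmax(code, 0), full - 1)
  out <- record
  out$samples <- code * spec$reference_current / full / scale
  out$meta$adc_codes <- code
  out$meta$adc <- spec
  out$meta$adc_saturated <- saturated
  out
}

#' Median percent difference across ADC resolutions
#'
#' Quantizes a record at each requested resolution and compares, sample by
#' sample, against the same record quantized at a high reference resolution:
#' `median(|x_b - x_ref| / |x_ref|) * 100`. By default both signals are
#' filtered (same chain) before comparison, mirroring a
#' filter-then-digitize device chain; set `order = "adc_first"` to quantize
#' the raw record and filter afterwards.
#'
#' @param record A [ppg_record()] in detected-fraction units.
#' @param bits_range Integer vector of resolutions to sweep (subset of
#'   1..reference_bits).
#' @param reference_bits Reference resolution (default 25).
#' @param filter A [filter_spec()] applied identically to both signals
#'   (default: none).
#' @param adc Template [adc_spec()]; its `bits` field is overridden.
#' @param order `"filter_first"` (default) or `"adc_first"`.
#' @return Named numeric vector: median percent difference per bit depth.
#' @export
resolution_sweep <- function(record, bits_range = 1:25, reference_bits = 25,
                             filter = filter_spec("none"), adc = adc_spec(),
                             order = c("filter_first", "adc_first")) {
  order <- match.arg(order)
  stopifnot(all(bits_range >= 1), all(bits_range <= reference_bits))
  chain <- function(bits) {
    a <- adc
    a$bits <- bits
    if (order == "filter_first")
      adc_convert(apply_ppg_filter(record, filter), a)$samples
    else
      apply_ppg_filter(adc_convert(record, a), filter)$samples
  }
  ref <- chain(reference_bits)
  nz <- abs(ref) > 0
  if (!any(nz)) stop("reference-resolution signal is identically zero")
  out <- vapply(bits_range, function(b) {
    x <- chain(b)
    median(abs(x[nz] - ref[nz]) / abs(ref[nz])) * 100
  }, numeric(1))
  names(out) <- as.character(bits_range)
  out
}

#' Jointly rescale a group of records to the range 0.5--2.7
#'
#' All records from one parameter combination are rescaled with a single
#' affine map taking the group minimum to 0.5 and the group maximum to 2.7,
#' matching the amplitude range of typical feature-extraction training
#' data. Rank order of samples is preserved.
#'
#' @param records A list of [ppg_record()]s (or a single record).
#' @param lower,upper Target range.
#' @return The rescaled records (a list, or a single record if a single
#'   record was given).
#' @export
rescale_group <- function(records, lower = 0.5, upper = 2.7) {
  single <- inherits(records, "ppg_record")
  if (single) records <- list(records)
  if (length(records) == 0) stop("empty record group")
  all_vals <- unlist(lapply(records, function(r) r$samples))
  rng <- range(all_vals)
  if (diff(rng) <= 0) stop("constant record group cannot be rescaled")
  out <- lapply(records, function(r) {
    r$samples <- lower + (r$samples - rng[1]) * (upper - lower) / diff(rng)
    r$meta$rescaled <- c(lower, upper)
    r
  })
  if (single) out[[1]] else out
}
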