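#' Detect fiducial points in a PPG record
#'
#' Systolic peaks are found with an adaptive-threshold rolling-mean
#' detector (a documented re-implementation of the common rolling-mean
#' approach): the signal is compared against its rolling mean raised by a
#' percentage, contiguous supra-threshold runs become candidate beats, and
#' the raise percentage is chosen from a candidate ladder by minimizing the
#' beat-interval standard deviation among settings that give a plausible
#' pulse rate (30--220 bpm). Peak times and values are refined to
#' sub-sample precision by parabolic interpolation; onsets are the
#' preceding local minima (also refined); the dicrotic notch is the "c"
#' peak -- the first local maximum after the systolic peak -- of a
#' Savitzky-Golay-smoothed, rescaled second derivative.
#'
#' Peaks whose neighboring beat intervals deviate more than 30% from the
#' median interval are marked rejected.
#'
#' @param record A [ppg_record()].
#' @param expected_hr Optional expected heart rate (bpm); used only to
#'   center the plausibility band.
#' @param ma_window Rolling-mean window, seconds.
#' @param ma_perc_candidates Threshold-raise percentages to try.
#' @param sg_window,sg_order Savitzky-Golay smoothing window (samples, odd)
#'   and polynomial order for the second derivative.
#' @return An object of class `fiducial_set`: lists of systolic peaks,
#'   onsets and dicrotic notches (sample indices plus refined times/values)
#'   and rejected peak indices. Empty (zero peaks) when nothing is found.
#' @export
detect_fiducials <- function(record, expected_hr = NULL, ma_window = 0.75,
                             ma_perc_candidates = c(0, 2, 5, 10, 15, 20,
                                                    25, 30, 40),
                             sg_window = 11, sg_order = 3) {
  y <- record$samples
  fs <- record$fs
  n <- length(y)
  empty <- structure(list(peaks = integer(0), onsets = integer(0),
                          notches = integer(0), rejected = integer(0),
                          peak_time = numeric(0), peak_value = numeric(0),
                          onset_time = numeric(0), onset_value = numeric(0),
                          notch_time = numeric(0), notch_value = numeric(0),
                          fs = fs, n = n),
                     class = "fiducial_set")
  if (n < 3 || diff(range(y)) == 0) return(empty)

  w <- max(1L, round(ma_window * fs))
  rol <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
  rol[is.na(rol)] <- mean(y)
  # positive offset scale so the percentage raise works for any baseline
  amp_scale <- mean(abs(y - rol)) * 2 + .Machine$double.eps

  peaks_for <- function(perc) {
    thr <- rol + perc / 100 * amp_scale
    above <- y > thr
    if (!any(above)) return(integer(0))
    d <- diff(c(FALSE, above, FALSE))
    starts <- which(d == 1)
    ends <- which(d == -1) - 1L
    vapply(seq_along(starts), function(i) {
      seg <- starts[i]:ends[i]
      seg[which.max(y[seg])]
    }, integer(1))
  }

  lo_bpm <- 30; hi_bpm <- 220
  if (!is.null(expected_hr)) {
    lo_bpm <- max(30, expected_hr / 2)
    hi_bpm <- min(220, expected_hr * 2)
  }
  best <- NULL; best_sd <- Inf
  for (perc in ma_perc_candidates) {
    pk <- peaks_for(perc)
    if (length(pk) < 2) next
    rr <- diff(pk) / fs
    bpm <- 60 / mean(rr)
    if (bpm < lo_bpm || bpm > hi_bpm) next
    s <- stats::sd(rr)
    if (s < best_sd) { best_sd <- s; best <- pk }
  }
  if (is.null(best)) {
    # fall back to the raise giving the most plausible count
    for (perc in ma_perc_candidates) {
      pk <- peaks_for(perc)
      if (length(pk) >= 1) { best <- pk; break }
    }
    if (is.null(best)) return(empty)
  }
  peaks <- best

  refine <- function(i, maximum = TRUE) {
    # parabolic refinement through (i-1, i, i+1); returns c(time, value)
    if (i <= 1L || i >= n) return(c((i - 1) / fs, y[i]))
    y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den == 0) return(c((i - 1) / fs, y2))
    off <- 0.5 * (y1 - y3) / den
    off <- max(-0.5, min(0.5, off))
    val <- y2 - 0.25 * (y1 - y3) * off
    c((i - 1 + off) / fs, val)
  }

  # onsets: minimum between the previous peak (or window start) and the peak
  onsets <- integer(length(peaks))
  for (k in seq_along(peaks)) {
    from <- if (k == 1) 1L else peaks[k - 1]
    seg <- from:peaks[k]
    onsets[k] <- seg[which.min(y[seg])]
  }

  # rejected peaks: neighboring beat interval deviates > 30% from median
  rejected <- integer(0)
  if (length(peaks) >= 3) {
    rr <- diff(peaks)
    med <- median(rr)
    bad <- abs(rr - med) > 0.3 * med
    rejected <- unique(peaks[c(which(bad), which(bad) + 1L)])
  }

  # dicrotic notch: "c" peak of the smoothed, rescaled second derivative
  d2 <- c(NA, diff(diff(y)), NA) * fs^2
  d2[is.na(d2)] <- 0
  sgw <- min(sg_window, if (n %% 2 == 1) n else n - 1)
  if (sgw >= sg_order + 2 && sgw %% 2 == 1)
    d2 <- as.numeric(signal::sgolayfilt(d2, p = sg_order, n = sgw))
  if (diff(range(d2)) > 0)
    d2 <- 2 * (d2 - min(d2)) / diff(range(d2)) - 1
  notches <- rep(NA_integer_, length(peaks))
  for (k in seq_along(peaks)) {
    upto <- if (k < length(peaks)) onsets[k + 1] else n
    # exclude the foot of the next pulse, whose upstroke curvature would
    # otherwise dominate the search
    upto <- upto - max(1L, round(0.15 * (upto - peaks[k])))
    seg <- (peaks[k] + 1L):max(peaks[k] + 1L, upto)
    seg <- seg[seg > 1 & seg < n]
    if (length(seg) < 3) next
    is_max <- d2[seg] > d2[seg - 1L] & d2[seg] >= d2[seg + 1L]
    cand <- seg[is_max]
    if (length(cand)) notches[k] <- cand[which.max(d2[cand])]
  }

  pk_ref <- t(vapply(peaks, refine, numeric(2)))
  on_ref <- t(vapply(onsets, function(i) {
    if (i <= 1L || i >= n) return(c((i - 1) / fs, y[i]))
    y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den == 0) return(c((i - 1) / fs, y2))
    off <- max(-0.5, min(0.5, 0.5 * (y1 - y3) / den))
    c((i - 1 + off) / fs, y2 - 0.25 * (y1 - y3) * off)
  }, numeric(2)))

  structure(list(
    peaks = peaks, onsets = onsets, notches = notches, rejected = rejected,
    peak_time = pk_ref[, 1], peak_value = pk_ref[, 2],
    onset_time = on_ref[, 1], onset_value = on_ref[, 2],
    notch_time = ifelse(is.na(notches), NA_real_, (notches - 1) / fs),
    notch_value = ifelse(is.na(notches), NA_real_, y[notches]),
    fs = fs, n = n
  ), class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf(
    "Fiducials: %d systolic peaks (%d rejected), %d notches found, %d samples @ %g Hz\n",
    length(x$peaks), length(x$rejected), sum(!is.na(x$notches)), x$n, x$fs))
  invisible(x)
}

#' Window acceptance check
#'
#' A window is accepted when more than 90% of the expected number of
#' systolic peaks (`duration * hr / 60`) were found and fewer than 10% were
#' rejected.
#'
#' @param fiducials A [detect_fiducials()] result.
#' @param duration Window length, seconds.
#' @param hr Expected heart rate, bpm.
#' @return An object of class `window_qc` with fields `expected`, `found`,
#'   `rejected`, `accepted`.
#' @export
window_qc <- function(fiducials, duration, hr) {
  expected <- duration * hr / 60
  found <- length(fiducials$peaks)
  rejected <- length(fiducials$rejected)
  structure(list(expected = expected, found = found, rejected = rejected,
                 accepted = found > 0.9 * expected &&
                   rejected < 0.1 * expected),
            class = "window_qc")
}

#' @export
print.window_qc <- function(x, ...) {
  cat(sprintf("Window QC: found %d of %.1f expected peaks, %d rejected -> %s\n",
              x$found, x$expected, x$rejected,
              if (x$accepted) "ACCEPTED" else "REJECTED"))
  invisible(x)
}

#' Default percentage grid for width features
#' @export
width_p_grid <- function() c(10, 25, 33, 50, 66, 75)

.crossing_time <- function(tt, y, level, from, to, rising) {
  # first (falling) / last (rising) linear-interpolated crossing of `level`
  idx <- from:to
  below <- y[idx] < level
  if (rising) {
    w <- which(below)
    if (!length(w)) return(NA_real_)
    i <- idx[w[length(w)]]
    if (i >= to) return(NA_real_)
    tt[i] + (level - y[i]) / (y[i + 1] - y[i]) * (tt[i + 1] - tt[i])
  } else {
    w <- which(below)
    if (!length(w)) return(NA_real_)
    i <- idx[w[1]]
    if (i <= from) return(NA_real_)
    tt[i - 1] + (y[i - 1] - level) / (y[i - 1] - y[i]) * (tt[i] - tt[i - 1])
  }
}

#' Compute pulse-wave-analysis features for an accepted window
#'
#' Per accepted beat (consecutive onset/peak/next-onset triplets with the
#' peak not rejected), the onset-referenced pulse amplitude is
#' `peak - onset`; the systolic width at p% is the time from the rising
#' p%-amplitude crossing to the (refined) peak, the diastolic width the
#' time from the peak to the falling crossing, `x{p}WidthTime` their sum
#' and `X{p}DivWidthTime` the diastolic/systolic ratio. Crossings use
#' linear interpolation between samples. Notch-dependent features are `NA`
#' for beats without a detected notch. Per-window feature values are means
#' across accepted beats.
#'
#' @param record A [ppg_record()].
#' @param fiducials A [detect_fiducials()] result for the same record.
#' @param p_grid Percentage grid for width features.
#' @return An object of class `feature_set`: a named list of feature values
#'   with the per-beat table in `attr(, "beats")`.
#' @export
compute_ppg_features <- function(record, fiducials,
                                 p_grid = width_p_grid()) {
  y <- record$samples
  tt <- record_time(record)
  f <- fiducials
  np <- length(f$peaks)
  if (np < 2) stop("need at least two detected peaks to delimit beats")
  beats <- list()
  for (k in seq_len(np - 1)) {
    if (f$peaks[k] %in% f$rejected) next
    on_i <- f$onsets[k]
    pk_i <- f$peaks[k]
    nxt_i <- f$onsets[k + 1]
    if (!(on_i < pk_i && pk_i < nxt_i)) next
    tpk <- f$peak_time[k]; vpk <- f$peak_value[k]
    von <- f$onset_value[k]; ton <- f$onset_time[k]
    amp <- vpk - von
    if (amp <= 0) next
    b <- list(onset_i = on_i, peak_i = pk_i, next_i = nxt_i,
              t_on = ton, t_pk = tpk, v_on = von, v_pk = vpk, amp = amp,
              notch_i = f$notches[k],
              t_notch = f$notch_time[k], v_notch = f$notch_value[k],
              period = f$onset_time[k + 1] - ton)
    for (p in p_grid) {
      lev <- von + p / 100 * amp
      tr <- .crossing_time(tt, y, lev, on_i, pk_i, rising = TRUE)
      tf <- .crossing_time(tt, y, lev, pk_i, nxt_i, rising = FALSE)
      b[[sprintf("sys%d", p)]] <- tpk - tr
      b[[sprintf("dia%d", p)]] <- tf - tpk
    }
    # areas above the onset value, split at the notch
    if (!is.na(b$notch_i)) {
      seg1 <- on_i:b$notch_i
      seg2 <- b$notch_i:nxt_i
      trapz <- function(i) sum(diff(tt[i]) *
                                 (head(y[i] - von, -1) + (y[i] - von)[-1]) / 2)
      b$a1 <- trapz(seg1)
      b$a2 <- trapz(seg2)
    } else {
      b$a1 <- NA_real_; b$a2 <- NA_real_
    }
    beats[[length(beats) + 1L]] <- b
  }
  if (!length(beats)) stop("no usable beats in this window")
  g <- function(field) vapply(beats, function(b) {
    v <- b[[field]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  mn <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)

  feats <- list()
  for (p in p_grid) {
    sys <- g(sprintf("sys%d", p)); dia <- g(sprintf("dia%d", p))
    feats[[sprintf("x%dSysWidthTime", p)]] <- mn(sys)
    feats[[sprintf("x%dDiaWidthTime", p)]] <- mn(dia)
    feats[[sprintf("x%dWidthTime", p)]] <- mn(sys + dia)
    feats[[sprintf("X%dDivWidthTime", p)]] <- mn(dia / sys)
  }
  rr <- diff(g("t_pk"))
  feats$pulseRiseTime <- mn(g("t_pk") - g("t_on"))
  feats$peakAmplitude <- mn(g("amp"))
  feats$pulseRate <- 60 / mean(diff(vapply(seq_len(np),
                                           function(k) f$peak_time[k],
                                           numeric(1))))
  feats$beatPeriod <- mn(g("period"))
  feats$decayTime <- mn(g("period") - (g("t_pk") - g("t_on")))
  feats$riseFraction <- mn((g("t_pk") - g("t_on")) / g("period"))
  feats$notchTime <- mn(g("t_notch") - g("t_pk"))
  feats$notchHeight <- mn(g("v_notch") - g("v_on"))
  feats$notchHeightFraction <- mn((g("v_notch") - g("v_on")) / g("amp"))
  feats$inflectionPointAreaRatio <- mn(g("a2") / g("a1"))
  feats$areaSystolic <- mn(g("a1"))
  feats$areaDiastolic <- mn(g("a2"))
  feats$areaTotal <- mn(g("a1") + g("a2"))
  feats$onsetValue <- mn(g("v_on"))

  structure(feats, class = "feature_set", n_beats = length(beats),
            beats = beats, p_grid = p_grid)
}

#' @export
print.feature_set <- function(x, digits = 4, ...) {
  cat(sprintf("PPG feature set (%d features, mean over %d beats)\n",
              length(x), attr(x, "n_beats")))
  v <- unlist(x)
  print(round(v, digits))
  invisible(x)
}

#' Feature names of the default registry
#' @export
feature_names <- function() {
  ps <- width_p_grid()
  c(as.vector(t(cbind(sprintf("x%dSysWidthTime", ps),
                      sprintf("x%dDiaWidthTime", ps),
                      sprintf("x%dWidthTime", ps),
                      sprintf("X%dDivWidthTime", ps)))),
    "pulseRiseTime", "peakAmplitude", "pulseRate", "beatPeriod",
    "decayTime", "riseFraction", "notchTime", "notchHeight",
    "notchHeightFraction", "inflectionPointAreaRatio", "areaSystolic",
    "areaDiastolic", "areaTotal", "onsetValue")
}

#' Mean/sd of each feature across the levels of a factor
#'
#' @param features A data frame of feature values with metadata columns
#'   (e.g. the output of the pipeline: one row per record).
#' @param factor Name of the metadata column to summarize over (e.g.
#'   `"age"`, `"vfm"`, `"wavelength"`, `"filter"`).
#' @param feature_cols Which columns are features; defaults to every
#'   numeric column except the factor.
#' @return An object of class `factor_summary`: matrices `mean`, `sd` and
#'   `normalized` (rows = features, columns = factor levels; `normalized`
#'   is a min-max row normalization of the means to `[0, 1]` for display,
#'   constant rows mapping to 0.5).
#' @export
summarize_by_factor <- function(features, factor, feature_cols = NULL) {
  if (!factor %in% names(features)) stop("no column '", factor, "'")
  lv <- unique(features[[factor]])
  if (length(lv) < 2) stop("need at least two levels of '", factor, "'")
  keep <- !vapply(lv, function(l) sum(features[[factor]] == l) == 0,
                  logical(1))
  lv <- lv[keep]
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                                   logical(1))], factor)
  }
  mea <- sapply(lv, function(l) {
    sub <- features[features[[factor]] == l, feature_cols, drop = FALSE]
    vapply(sub, function(col) mean(col, na.rm = TRUE), numeric(1))
  })
  sds <- sapply(lv, function(l) {
    sub <- features[features[[factor]] == l, feature_cols, drop = FALSE]
    vapply(sub, function(col) if (sum(!is.na(col)) > 1) sd(col, na.rm = TRUE)
           else 0, numeric(1))
  })
  colnames(mea) <- colnames(sds) <- as.character(lv)
  norm <- t(apply(mea, 1, function(r) {
    if (diff(range(r, na.rm = TRUE)) == 0) return(rep(0.5, length(r)))
    (r - min(r, na.rm = TRUE)) / diff(range(r, na.rm = TRUE))
  }))
  colnames(norm) <- colnames(mea)
  structure(list(mean = mea, sd = sds, normalized = norm, factor = factor),
            class = "factor_summary")
}

#' @export
print.factor_summary <- function(x, digits = 3, ...) {
  cat("Feature means by", x$factor, "level:\n")
  print(round(x$mean, digits))
  invisible(x)
}
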