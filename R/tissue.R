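#' @useDynLib ppgsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx median sd quantile coef predict fitted residuals
#' @importFrom utils head modifyList read.csv write.csv
NULL

.ppgsim_env <- new.env(parent = emptyenv())

#' Tissue optical and geometric constants
#'
#' Loads (and caches) the structured constants file shipped with the package:
#' layer scattering/absorption coefficients per wavelength, the age-dependent
#' dermal thickness model, melanin mixing constants, and the pulse
#' blood-volume factors.
#'
#' @param path Optional path to an alternative constants file (JSON).
#' @return A nested list of constants.
#' @export
tissue_optics <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ppgsim_env$optics)) return(.ppgsim_env$optics)
    path <- system.file("extdata", "tissue_optics.json", package = "ppgsim")
    opt <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    .ppgsim_env$optics <- opt
    return(opt)
  }
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Layer names of the six-layer fingertip model, in depth order
#' @export
ppg_layer_names <- function() {
  c("epidermis", "papillary_dermis", "upper_blood_net",
    "reticular_dermis", "deep_blood_net", "subcutis")
}

.dermal_sublayers <- c("papillary_dermis", "upper_blood_net",
                       "reticular_dermis", "deep_blood_net")

#' Age-dependent dermal sublayer thicknesses
#'
#' Total dermal thickness follows a linear thinning model anchored at 0.75 mm
#' for a 61-year-old with an annual decrease of 0.0044 mm; the four dermal
#' sublayers are fixed fractions of the total (papillary 8.2%, upper blood
#' net 4.37%, reticular 81.97%, deep blood net 5.46%).
#'
#' @param age Subject age in years (18--80).
#' @return Named numeric vector of sublayer thicknesses in mm, plus the total
#'   as attribute `"total"`.
#' @export
dermal_sublayer_thicknesses <- function(age) {
  stopifnot(is.numeric(age), length(age) == 1L, is.finite(age))
  if (age < 18 || age > 80)
    stop("age must be within [18, 80] years, got ", age)
  opt <- tissue_optics()$dermis
  total <- opt$total_anchor_mm + (opt$anchor_age - age) * opt$thinning_mm_per_year
  th <- vapply(.dermal_sublayers, function(nm) total * opt$fractions[[nm]],
               numeric(1))
  attr(th, "total") <- total
  th
}

#' Epidermal absorption coefficient under melanin volume-fraction mixing
#'
#' Linear mixture `mua = vfm * mua_mel(lambda) + (1 - vfm) * mua_base(lambda)`
#' where the melanosome coefficient follows the power law
#' `mua_mel = 6.6e10 * lambda^-3.33` (cm^-1, lambda in nm) and the baseline
#' is back-solved per wavelength from the tabulated VFM = 0.03 value, so that
#' the shipped table is the calibration authority.
#'
#' @param wavelength Wavelength in nm. One of 515/660/880 unless
#'   `extrapolate = TRUE` (the melanin power law is evaluated at any
#'   wavelength; the baseline is interpolated on log-wavelength).
#' @param vfm Volume fraction of melanosomes in `[0, 1]`.
#' @param extrapolate Allow wavelengths off the calibrated grid.
#' @return Absorption coefficient in cm^-1.
#' @export
epidermal_mua <- function(wavelength, vfm, extrapolate = FALSE) {
  stopifnot(is.numeric(wavelength), is.numeric(vfm))
  if (any(vfm < 0 | vfm > 1)) stop("vfm must lie in [0, 1]")
  opt <- tissue_optics()
  mel <- opt$melanin$scale * wavelength^opt$melanin$exponent
  lams <- opt$wavelengths
  base_tab <- vapply(as.character(lams), function(l) {
    printed <- opt$epidermis$mua_printed_by_vfm[[l]][["0.03"]]
    mel_l <- opt$melanin$scale * as.numeric(l)^opt$melanin$exponent
    (printed - 0.03 * mel_l) / (1 - 0.03)
  }, numeric(1))
  if (all(wavelength %in% lams)) {
    base <- base_tab[as.character(wavelength)]
  } else if (extrapolate) {
    base <- exp(approx(log(lams), log(base_tab), xout = log(wavelength),
                       rule = 2)$y)
  } else {
    stop("wavelength ", paste(setdiff(wavelength, lams), collapse = ", "),
         " nm is off the calibrated grid; set extrapolate = TRUE")
  }
  unname(vfm * mel + (1 - vfm) * base)
}

#' Systolic blood-volume multiplier as a function of age
#'
#' Tabulated vessel-compliance-derived multipliers (1.124 at 23 y down to
#' 1.073 at 55 y) with linear interpolation between the anchors. Ages beyond
#' the anchors are clamped with a warning.
#'
#' @param age Age in years.
#' @return Dimensionless blood-volume multiplier (>= 1).
#' @export
pulse_blood_factor <- function(age) {
  tab <- tissue_optics()$pulse_blood_factor
  ages <- as.numeric(names(tab))
  vals <- unlist(tab, use.names = FALSE)
  o <- order(ages)
  ages <- ages[o]; vals <- vals[o]
  if (any(age < min(ages) | age > max(ages))) {
    warning("age outside tabulated span [", min(ages), ", ", max(ages),
            "]; clamping")
    age <- pmin(pmax(age, min(ages)), max(ages))
  }
  approx(ages, vals, xout = age)$y
}

#' Build the six-layer fingertip optical model
#'
#' Assembles the ordered layer stack (epidermis, four dermal sublayers,
#' subcutis) for one combination of age, melanosome volume fraction,
#' wavelength and hemodynamic state. The `"pulse"` state differs from
#' `"rest"` only in the dermal sublayers' absorption: at the tabulated ages
#' the printed pulsed values are used directly; at intermediate ages the
#' blood-borne share of the rest absorption (calibrated from the printed
#' rest/pulsed pair at the youngest tabulated age) is scaled by
#' [pulse_blood_factor()].
#'
#' @param age Age in years.
#' @param vfm Volume fraction melanosomes in `[0, 1]`.
#' @param wavelength Device wavelength in nm (515/660/880 unless
#'   `extrapolate = TRUE`).
#' @param state `"rest"` or `"pulse"`.
#' @param g Scattering anisotropy applied to all layers.
#' @param n Tissue refractive index (ambient side is
#'   `tissue_optics()$n_ambient`).
#' @param extrapolate Allow off-grid wavelengths (melanin law + log-log
#'   interpolated baselines/scattering).
#' @return An object of class `tissue_model`: a data frame of layers with
#'   columns `name`, `thickness`, `start_depth` (mm), `mua`, `mus` (cm^-1),
#'   `g`, `n`, and metadata attributes.
#' @export
build_tissue_model <- function(age, vfm, wavelength,
                               state = c("rest", "pulse"),
                               g = NULL, n = NULL, extrapolate = FALSE) {
  state <- match.arg(state)
  stopifnot(length(age) == 1L, length(vfm) == 1L, length(wavelength) == 1L)
  if (vfm < 0 || vfm > 1) stop("vfm must lie in [0, 1]")
  opt <- tissue_optics()
  if (is.null(g)) g <- opt$anisotropy_g
  if (is.null(n)) n <- opt$n_tissue
  lam <- as.character(wavelength)
  on_grid <- wavelength %in% opt$wavelengths
  if (!on_grid && !extrapolate)
    stop("wavelength ", wavelength, " nm unsupported without extrapolate = TRUE")

  interp_lam <- function(tab) {
    # log-log interpolation across the three calibrated wavelengths
    v <- vapply(as.character(opt$wavelengths), function(l) tab[[l]], numeric(1))
    exp(approx(log(opt$wavelengths), log(v), xout = log(wavelength),
               rule = 2)$y)
  }
  get_lam <- function(tab) if (on_grid) tab[[lam]] else interp_lam(tab)

  th <- dermal_sublayer_thicknesses(age)
  ages_tab <- opt$ages
  dermal_mua <- vapply(.dermal_sublayers, function(nm) {
    rest <- get_lam(opt$dermis$mua[[nm]]$rest)
    if (state == "rest") return(rest)
    pulse_ref <- get_lam(opt$dermis$mua[[nm]]$pulse)
    if (age %in% ages_tab && age == min(ages_tab)) return(pulse_ref)
    # blood-borne share calibrated from the youngest-age printed pair
    f_ref <- pulse_blood_factor(min(ages_tab))
    blood <- (pulse_ref - rest) / (f_ref - 1)
    rest + (pulse_blood_factor(age) - 1) * blood
  }, numeric(1))

  layers <- data.frame(
    name = ppg_layer_names(),
    thickness = c(opt$epidermis$thickness_mm, unname(th),
                  opt$subcutis$thickness_mm),
    mua = c(epidermal_mua(wavelength, vfm, extrapolate = extrapolate),
            unname(dermal_mua), get_lam(opt$subcutis$mua)),
    mus = c(get_lam(opt$epidermis$mus),
            rep(get_lam(opt$dermis$mus), 4L),
            get_lam(opt$subcutis$mus)),
    stringsAsFactors = FALSE
  )
  layers$start_depth <- cumsum(c(0, layers$thickness[-nrow(layers)]))
  layers$g <- g
  layers$n <- n
  layers <- layers[, c("name", "thickness", "start_depth", "mua", "mus",
                       "g", "n")]
  structure(layers,
            class = c("tissue_model", "data.frame"),
            age = age, vfm = vfm, wavelength = wavelength, state = state,
            n_ambient = opt$n_ambient)
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf(
    "Six-layer fingertip model: age %.1f y, VFM %.2f, %g nm, state '%s'\n",
    attr(x, "age"), attr(x, "vfm"), attr(x, "wavelength"), attr(x, "state")))
  df <- as.data.frame(x)
  df$thickness <- round(df$thickness, 4)
  df$start_depth <- round(df$start_depth, 4)
  df$mua <- signif(df$mua, 5)
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}
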