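#' Write a PPG record as CSV with a JSON metadata sidecar
#'
#' Samples are written in full binary precision (`%.17g`) so a write/read
#' round trip is bitwise exact; all metadata go to `<path>.json`.
#'
#' @param record A [ppg_record()].
#' @param path Output CSV path (columns `time_s`, `value`).
#' @return `path`, invisibly.
#' @export
write_ppg_record <- function(record, path) {
  tt <- record_time(record)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,value", con)
  writeLines(sprintf("%.17g,%.17g", tt, record$samples), con)
  meta <- record$meta
  meta$fs <- record$fs
  # data-frame metadata (e.g. a noise spec) serializes naturally to JSON
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a PPG record written by [write_ppg_record()]
#'
#' @param path CSV path; the `<path>.json` sidecar must be present.
#' @return A [ppg_record()].
#' @export
read_ppg_record <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("no such record file: ", path)
  if (!file.exists(sidecar))
    stop("missing metadata sidecar: ", sidecar)
  df <- tryCatch(read.csv(path), error = function(e)
    stop("malformed record file ", path, ": ", conditionMessage(e)))
  if (!all(c("time_s", "value") %in% names(df)))
    stop("malformed record file ", path, ": need columns time_s, value")
  meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  fs <- meta$fs
  if (is.null(fs)) stop("sidecar lacks the sampling frequency 'fs'")
  meta$fs <- NULL
  if (!is.null(meta$noise)) meta$noise <- as.data.frame(meta$noise)
  ppg_record(df$value, fs, meta)
}

#' Write / read a feature table (tidy CSV)
#'
#' One row per record; metadata columns (age, vfm, wavelength, filter, ...)
#' next to feature columns.
#'
#' @param features A data frame.
#' @param path CSV path.
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such feature table: ", path)
  read.csv(path, check.names = FALSE)
}

#' Load a run configuration
#'
#' YAML configuration describing the simulation grids and processing
#' options. A seed is mandatory: nothing in the pipeline is allowed to be
#' silently nondeterministic.
#'
#' @param path YAML file; `NULL` returns the default configuration.
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  default <- list(
    ages = c(23, 34.4, 44.8, 55),
    vfms = c(0.03, 0.10, 0.20, 0.30),
    wavelengths = c(515, 660, 880),
    mc = list(n_photons = 1e6, target_cv = 0.10, seed = NULL,
              detector = "annulus"),
    waveform = list(hr = 75, fs = 120, duration = 30,
                    noise = list(frequency = c(20, 40, 60),
                                 fraction = c(0.38, 0.59, 0.59),
                                 phase = c(0, 0, pi / 2))),
    device = list(filter = "none", adc_bits = 25,
                  reference_current = 32e-6, led_power = 0.05),
    feature = list(p_grid = width_p_grid(), sg_window = 11, sg_order = 3)
  )
  cfg <- if (is.null(path)) default else
    modifyList(default, yaml::read_yaml(path))
  for (f in c("ages", "vfms", "wavelengths"))
    if (!length(cfg[[f]])) stop("empty factor list: ", f)
  if (is.null(cfg$mc$seed))
    stop("configuration must set mc.seed (no silent nondeterminism)")
  structure(cfg, class = c("run_config", "list"))
}

#' Expand the configured factorial grid into a run plan
#'
#' @param config A [read_run_config()] result (or compatible list with
#'   `ages`, `vfms`, `wavelengths`).
#' @return A data frame of all (age, vfm, wavelength) combinations with
#'   attributes `n_combinations` and `n_mc_runs` (two hemodynamic states
#'   per combination).
#' @export
expand_run_grid <- function(config) {
  for (f in c("ages", "vfms", "wavelengths"))
    if (!length(config[[f]])) stop("empty factor list: ", f)
  grid <- expand.grid(age = config$ages, vfm = config$vfms,
                      wavelength = config$wavelengths,
                      KEEP.OUT.ATTRS = FALSE)
  attr(grid, "n_combinations") <- nrow(grid)
  attr(grid, "n_mc_runs") <- 2L * nrow(grid)
  grid
}

#' Hash of a configuration for reproducibility logging
#'
#' A short deterministic digest of the serialized configuration, recorded
#' by pipeline stages so identical config + seed implies identical outputs.
#'
#' @param config Any R object.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  # FNV-1a over the serialized bytes; 32-bit arithmetic kept exact in
  # doubles by splitting the multiply into 16-bit halves
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(h %% 256, b)  # xor of the low byte
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 2^32
  }
  sprintf("%08x", h)
}
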