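#' Read a device configuration JSON
#'
#' The configuration names the device, its primaries (label, colour,
#' resolution), the calibration CSV, and the measurement units. Schema:
#' `{name, primaries: [{label, color, resolution}], calibration_path,
#' units: "radiance"|"irradiance", notes}`.
#'
#' @param path Path to the JSON file.
#' @return A validated config list of class `silsub_device_config`.
#' @export
read_device_config <- function(path) {
  if (!file.exists(path)) {
    stop_validation(sprintf("Device config file not found: '%s'.", path))
  }
  cfg <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop_format(sprintf(
      "Device config '%s' is not valid JSON: %s", path, conditionMessage(e)
    ))
  )
  cfg$.dir <- dirname(path)
  validate_device_config(cfg)
}

validate_device_config <- function(cfg) {
  for (field in c("name", "primaries", "calibration_path", "units")) {
    if (is.null(cfg[[field]])) {
      stop_format(sprintf("Device config is missing required field '%s'.", field))
    }
  }
  if (!cfg$units %in% c("radiance", "irradiance")) {
    stop_format(sprintf(
      "Device config field 'units' must be 'radiance' or 'irradiance' (energy units; convert photon-unit measurements before use), got '%s'.",
      cfg$units
    ))
  }
  if (length(cfg$primaries) < 1) {
    stop_format("Device config field 'primaries' must list at least one primary.")
  }
  labels <- vapply(cfg$primaries, function(p) {
    if (is.null(p$label)) stop_format("Each primary needs a 'label' field.")
    as.character(p$label)
  }, character(1))
  if (anyDuplicated(labels)) {
    stop_format("Primary labels must be unique.")
  }
  resolutions <- vapply(cfg$primaries, function(p) {
    if (is.null(p$resolution)) stop_format("Each primary needs a 'resolution' field.")
    r <- as.numeric(p$resolution)
    if (!is.finite(r) || r < 1) stop_format("Primary resolutions must be >= 1.")
    r
  }, numeric(1))
  colors <- vapply(cfg$primaries, function(p) {
    if (is.null(p$color)) NA_character_ else as.character(p$color)
  }, character(1))
  structure(
    list(name = as.character(cfg$name), labels = labels, colors = colors,
         resolutions = resolutions,
         calibration_path = as.character(cfg$calibration_path),
         units = cfg$units, notes = cfg$notes, .dir = cfg$.dir),
    class = "silsub_device_config"
  )
}

#' Read a device calibration table
#'
#' Parses the calibration CSV dialect: header `Primary,Setting,380,381,...,780`
#' where `Primary` is a zero-based ordinal, `Setting` a native input setting,
#' and each remaining column one wavelength sample; one spectral measurement
#' per row in energy units. Every primary must include measurements at its
#' minimum (0) and maximum (resolution) settings; the minimum-setting rows
#' represent the ambient spectral power distribution and must agree across
#' primaries within `ambient_tol`. Inputs sampled more finely than 1 nm (or at
#' up to 5 nm steps) are linearly resampled onto the canonical grid; sampling
#' coarser than 5 nm is rejected. Negative spectral values (spectrometer noise
#' floor) are clipped to zero with a notice.
#'
#' @param x CSV path or data frame in the calibration dialect.
#' @param config A `silsub_device_config` (see [read_device_config()]).
#' @param ambient_tol Relative tolerance for agreement of the setting-0 rows,
#'   as a fraction of the peak ambient value (default 0.05).
#' @return A list of class `silsub_calibration` with per-primary setting
#'   ladders and measurement matrices on the canonical grid.
#' @export
read_calibration <- function(x, config, ambient_tol = 0.05) {
  if (is.character(x)) {
    if (!file.exists(x)) {
      stop_validation(sprintf("Calibration file not found: '%s'.", x))
    }
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  x <- tibble::as_tibble(x)
  for (col in c("Primary", "Setting")) {
    if (!col %in% names(x)) {
      stop_format(sprintf("Calibration table is missing the '%s' column.", col))
    }
  }
  wl_cols <- setdiff(names(x), c("Primary", "Setting"))
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (any(!is.finite(wl))) {
    stop_format("Calibration header must contain numeric wavelength columns after 'Primary' and 'Setting'.")
  }
  if (is.unsorted(wl, strictly = TRUE)) {
    stop_format("Calibration wavelength columns must be strictly increasing.")
  }
  grid <- silsub_grid()
  n_primaries <- length(config$labels)

  vals <- as.matrix(x[wl_cols])
  dimnames(vals) <- NULL
  if (any(!is.finite(vals))) {
    stop_format("Calibration table contains non-finite spectral values.")
  }
  n_neg <- sum(vals < 0)
  if (n_neg > 0) {
    rlang::inform(sprintf(
      "Clipped %d negative spectral value(s) to zero (spectrometer noise floor).",
      n_neg
    ), class = "silsub_clip_notice")
    vals[vals < 0] <- 0
  }
  # resample rows onto the canonical grid if needed
  if (!(length(wl) == length(grid) && all(wl == grid))) {
    vals <- t(apply(vals, 1, function(row) {
      resample_to_grid(wl, row, grid, what = "calibration spectrum")
    }))
  }

  primary_idx <- as.numeric(x$Primary)
  setting <- as.numeric(x$Setting)
  if (any(!is.finite(primary_idx)) || any(!is.finite(setting))) {
    stop_format("'Primary' and 'Setting' columns must be finite numbers.")
  }
  if (any(!primary_idx %in% (seq_len(n_primaries) - 1))) {
    stop_format(sprintf(
      "Calibration 'Primary' values must be zero-based ordinals 0..%d matching the config's %d primaries.",
      n_primaries - 1, n_primaries
    ))
  }

  settings <- vector("list", n_primaries)
  spd <- vector("list", n_primaries)
  for (p in seq_len(n_primaries)) {
    rows <- which(primary_idx == p - 1)
    if (length(rows) == 0) {
      stop_format(sprintf("No calibration rows for primary %d ('%s').",
                          p - 1, config$labels[p]))
    }
    s <- setting[rows]
    if (anyDuplicated(s)) {
      stop_format(sprintf(
        "Duplicate (Primary, Setting) rows for primary %d at setting(s) %s.",
        p - 1, paste(unique(s[duplicated(s)]), collapse = ", ")
      ))
    }
    ord <- order(s)
    s <- s[ord]
    m <- vals[rows[ord], , drop = FALSE]
    res <- config$resolutions[p]
    if (s[1] != 0 || s[length(s)] != res) {
      stop_format(sprintf(
        "Incomplete calibration for primary %d ('%s'): measurements at settings 0 and %g are required (found %g-%g).",
        p - 1, config$labels[p], res, s[1], s[length(s)]
      ))
    }
    if (any(s < 0 | s > res)) {
      stop_format(sprintf("Settings for primary %d outside [0, %g].", p - 1, res))
    }
    settings[[p]] <- s
    spd[[p]] <- m
  }

  # ambient consistency: the setting-0 rows of all primaries measure the same
  # ambient light and must agree within tolerance (relative to peak ambient)
  amb <- t(vapply(spd, function(m) m[1, ], numeric(length(grid))))
  amb_mean <- colMeans(amb)
  scale <- max(amb_mean)
  dev_max <- max(abs(sweep(amb, 2, amb_mean)))
  if (dev_max > ambient_tol * max(scale, .Machine$double.eps)) {
    stop_format(sprintf(
      "Setting-0 (ambient) rows disagree across primaries: max deviation %.3g exceeds %g%% of the peak ambient value %.3g.",
      dev_max, 100 * ambient_tol, scale
    ))
  }

  structure(
    list(grid = grid, settings = settings, spd = spd, ambient = amb_mean,
         n_primaries = n_primaries, resolutions = config$resolutions),
    class = "silsub_calibration"
  )
}

#' Assemble a multiprimary stimulation device
#'
#' Binds a validated calibration to a device configuration, yielding the
#' forward model used by all prediction and solver functions.
#'
#' @param calibration A `silsub_calibration` (see [read_calibration()]).
#' @param config A `silsub_device_config`.
#' @return An object of class `silsub_device`.
#' @export
silsub_device <- function(calibration, config) {
  stopifnot(inherits(calibration, "silsub_calibration"),
            inherits(config, "silsub_device_config"))
  structure(
    list(name = config$name, labels = config$labels, colors = config$colors,
         resolutions = config$resolutions, units = config$units,
         grid = calibration$grid, settings = calibration$settings,
         spd = calibration$spd, ambient = calibration$ambient),
    class = "silsub_device"
  )
}

#' Load a device from a configuration JSON
#'
#' Reads the config, then the calibration CSV it names (resolved relative to
#' the config file's directory if not absolute), and assembles the device.
#'
#' @param config_path Path to the device config JSON.
#' @param ambient_tol Passed to [read_calibration()].
#' @return A `silsub_device`.
#' @export
load_device <- function(config_path, ambient_tol = 0.05) {
  cfg <- read_device_config(config_path)
  cal_path <- cfg$calibration_path
  if (!file.exists(cal_path) && !is.null(cfg$.dir)) {
    cal_path <- file.path(cfg$.dir, cfg$calibration_path)
  }
  silsub_device(read_calibration(cal_path, cfg, ambient_tol), cfg)
}

#' @export
print.silsub_device <- function(x, ...) {
  n_meas <- sum(vapply(x$settings, length, integer(1)))
  cat(sprintf(
    "<multiprimary device '%s': %d primaries (%s), %d calibration spectra, %s units, %g-%g nm>\n",
    x$name, length(x$labels), paste(x$labels, collapse = ", "),
    n_meas, x$units, min(x$grid), max(x$grid)
  ))
  invisible(x)
}

#' Calibration table of a device as a tibble
#'
#' Returns the device's calibration in the CSV dialect layout: columns
#' `Primary` (zero-based), `Setting`, then one column per wavelength.
#'
#' @param device A `silsub_device`.
#' @return A tibble.
#' @export
calibration_table <- function(device) {
  rows <- purrr::map_dfr(seq_along(device$settings), function(p) {
    m <- device$spd[[p]]
    out <- tibble::as_tibble(m, .name_repair = ~ as.character(device$grid))
    dplyr::bind_cols(
      tibble::tibble(Primary = p - 1, Setting = device$settings[[p]]),
      out
    )
  })
  rows
}

#' Write a device calibration CSV
#'
#' @param device A `silsub_device`.
#' @param path Output CSV path (Table-dialect: `Primary,Setting,380,...,780`).
#' @return `path`, invisibly.
#' @export
write_calibration <- function(device, path) {
  readr::write_csv(calibration_table(device), path, progress = FALSE)
  invisible(path)
}

n_primaries <- function(device) length(device$labels)

check_n_primaries <- function(device, v, what) {
  if (length(v) != n_primaries(device)) {
    stop_validation(sprintf(
      "%s must have one value per primary (%d), got %d.",
      what, n_primaries(device), length(v)
    ))
  }
  invisible(TRUE)
}

#' Convert between native settings and unit-interval weights
#'
#' Weights are settings divided by each primary's resolution; the inverse
#' multiplies by the resolution and rounds half away from zero (so weight 0.5
#' on an 8-bit primary gives setting 128). The settings -> weights -> settings
#' round trip is the identity.
#'
#' @param device A `silsub_device`.
#' @param settings Numeric vector of native settings, one per primary, each in
#'   `[0, resolution]`.
#' @param weights Numeric vector of weights in `[0, 1]`, one per primary.
#' @return `settings_to_weights`: weights; `weights_to_settings`: integer-valued
#'   native settings.
#' @export
settings_to_weights <- function(device, settings) {
  check_n_primaries(device, settings, "settings")
  if (any(!is.finite(settings)) || any(settings < 0) ||
      any(settings > device$resolutions)) {
    stop_validation("Settings must be finite and within [0, resolution] per primary.")
  }
  settings / device$resolutions
}

#' @rdname settings_to_weights
#' @export
weights_to_settings <- function(device, weights) {
  check_n_primaries(device, weights, "weights")
  if (any(!is.finite(weights)) || any(weights < -1e-9) || any(weights > 1 + 1e-9)) {
    stop_validation("Weights must be finite and within [0, 1] per primary.")
  }
  w <- pmin(pmax(weights, 0), 1)
  round_half_away(w * device$resolutions)
}

#' Gamut check
#'
#' A weights vector is in gamut iff every weight lies in `[0, 1]` within a
#' `1e-9` numerical slack.
#'
#' @param device A `silsub_device`.
#' @param weights Numeric weights vector, one per primary.
#' @param slack Numerical slack (default `1e-9`).
#' @return List with `in_gamut` (logical) and `violations` (tibble with columns
#'   `primary`, `label`, `weight`, `overshoot`; empty when in gamut).
#' @export
in_gamut <- function(device, weights, slack = 1e-9) {
  check_n_primaries(device, weights, "weights")
  over <- pmax(weights - 1, -weights, 0)
  bad <- which(over > slack | !is.finite(weights))
  list(
    in_gamut = length(bad) == 0,
    violations = tibble::tibble(
      primary = bad,
      label = device$labels[bad],
      weight = weights[bad],
      overshoot = over[bad]
    )
  )
}

require_in_gamut <- function(device, weights, what = "weights") {
  g <- in_gamut(device, weights)
  if (!g$in_gamut) {
    v <- g$violations
    stop_gamut(sprintf(
      "%s out of gamut: %s.",
      what,
      paste(sprintf("primary %d ('%s') weight %.6g (overshoot %.3g)",
                    v$primary, v$label, v$weight, v$overshoot), collapse = "; ")
    ))
  }
  invisible(pmin(pmax(weights, 0), 1))
}

# ---- spectral prediction -----------------------------------------------------

# numeric spectrum of one primary at a continuous native setting; exact at
# calibration nodes, wavelength-wise linear interpolation between bracketing
# measurements otherwise; never extrapolates
primary_spd_values <- function(device, primary, setting) {
  s <- device$settings[[primary]]
  m <- device$spd[[primary]]
  if (!is.finite(setting) || setting < s[1] || setting > s[length(s)]) {
    stop_gamut(sprintf(
      "Setting %.6g for primary %d ('%s') is outside the calibrated range [%g, %g].",
      setting, primary, device$labels[primary], s[1], s[length(s)]
    ))
  }
  hit <- which(s == setting)
  if (length(hit) == 1) {
    return(m[hit, ])
  }
  i <- findInterval(setting, s)
  t <- (setting - s[i]) / (s[i + 1] - s[i])
  (1 - t) * m[i, ] + t * m[i + 1, ]
}

weights_from_args <- function(device, settings, weights) {
  if (is.null(settings) == is.null(weights)) {
    stop_validation("Supply exactly one of 'settings' (native) or 'weights' ([0,1]).")
  }
  if (!is.null(settings)) {
    check_n_primaries(device, settings, "settings")
    settings / device$resolutions
  } else {
    check_n_primaries(device, weights, "weights")
    weights
  }
}

multi_spd_values <- function(device, w) {
  w <- require_in_gamut(device, w)
  amb <- device$ambient
  total <- amb
  for (p in seq_len(n_primaries(device))) {
    total <- total + (primary_spd_values(device, p, w[p] * device$resolutions[p]) - amb)
  }
  pmax(total, 0)
}

aopic_values <- function(device, w, smat) {
  spd <- multi_spd_values(device, w)
  drop(crossprod(smat, spd)) * grid_step(device$grid)
}

#' Predict the spectral output of a single primary
#'
#' Wavelength-wise linear interpolation between the bracketing calibration
#' measurements; exact (bitwise) at calibrated settings; never extrapolates
#' beyond the calibrated range.
#'
#' @param device A `silsub_device`.
#' @param primary Primary index (1-based, matching the order in the config;
#'   the calibration CSV dialect numbers primaries from 0).
#' @param setting Native setting in `[0, resolution]` (may be fractional), or
#' @param weight a weight in `[0, 1]` instead.
#' @return Tibble with columns `wavelength`, `value`.
#' @export
predict_primary_spd <- function(device, primary, setting = NULL, weight = NULL) {
  if (is.null(setting) == is.null(weight)) {
    stop_validation("Supply exactly one of 'setting' or 'weight'.")
  }
  if (!is.null(weight)) setting <- weight * device$resolutions[primary]
  tibble::tibble(
    wavelength = device$grid,
    value = primary_spd_values(device, primary, setting)
  )
}

#' Predict the spectral output of the full device
#'
#' Sums the ambient-subtracted per-primary predictions and adds the ambient
#' spectrum back once (so the all-zeros prediction is the ambient measurement,
#' not n-times it); output is clipped at zero.
#'
#' @param device A `silsub_device`.
#' @param settings Native settings vector (one per primary), or
#' @param weights weights vector in `[0, 1]` instead.
#' @return Tibble with columns `wavelength`, `value`.
#' @export
predict_multiprimary_spd <- function(device, settings = NULL, weights = NULL) {
  w <- weights_from_args(device, settings, weights)
  tibble::tibble(wavelength = device$grid, value = multi_spd_values(device, w))
}

#' Predict alpha-opic irradiances
#'
#' Projects the predicted device spectrum onto each receptor's action spectrum:
#' `E_alpha = sum_lambda E(lambda) * S_alpha(lambda) * delta_lambda`, the
#' alpha-opic irradiance (units: the calibration's energy units weighted by
#' dimensionless sensitivity).
#'
#' @param device A `silsub_device`.
#' @param observer An [action_spectra()] set on the device grid (grid mismatch
#'   raises an alignment error; no silent resampling).
#' @param settings,weights Exactly one of native settings or weights.
#' @return Tibble with columns `receptor`, `irradiance`.
#' @export
predict_aopic <- function(device, observer, settings = NULL, weights = NULL) {
  check_same_grid(device$grid, observer$wavelength, "device and observer")
  w <- weights_from_args(device, settings, weights)
  e <- aopic_values(device, w, sensitivity_matrix(observer))
  tibble::tibble(receptor = receptor_labels(observer), irradiance = unname(e))
}

# ---- gamma -------------------------------------------------------------------

#' Gamma (input-output) table of a primary
#'
#' The input-output map of a primary: native setting versus integrated
#' ambient-subtracted output (summed over wavelength times the grid step).
#' Integrated rather than per-wavelength output is used because primaries may
#' shift spectrally with drive level. Requires at least 3 calibrated settings.
#' The map must be non-decreasing; dips beyond 1% of the output range raise a
#' calibration-quality error, smaller dips are flattened monotone.
#'
#' @param device A `silsub_device`.
#' @param primary Primary index (1-based).
#' @param tol Monotonicity tolerance as a fraction of the output range.
#' @return Tibble with columns `setting`, `output`, `output_norm`.
#' @export
gamma_table <- function(device, primary, tol = 0.01) {
  s <- device$settings[[primary]]
  if (length(s) < 3) {
    stop_validation(sprintf(
      "Gamma correction for primary %d needs >= 3 calibrated settings, found %d.",
      primary, length(s)
    ))
  }
  m <- device$spd[[primary]]
  out <- as.numeric(m %*% rep(grid_step(device$grid), ncol(m))) -
    sum(device$ambient) * grid_step(device$grid)
  rng <- max(out) - min(out)
  dips <- -pmin(diff(out), 0)
  if (any(dips > tol * max(rng, .Machine$double.eps))) {
    stop_validation(sprintf(
      "Calibration ladder of primary %d is non-monotone beyond %g%% of its output range; gamma correction is unreliable.",
      primary, 100 * tol
    ))
  }
  out <- cummax(out)
  tibble::tibble(setting = s, output = out,
                 output_norm = if (max(out) > 0) out / max(out) else out)
}

#' Gamma-correct weights to native settings
#'
#' For each primary, finds the native setting whose predicted integrated
#' (ambient-subtracted) output is closest to `weight x maximum output`, by
#' monotone piecewise-linear inversion of the gamma table followed by
#' round-half-away-from-zero. On a linear device this reduces to
#' `round(weight x resolution)`.
#'
#' @param device A `silsub_device`.
#' @param weights Weights vector in `[0, 1]`.
#' @return Integer-valued native settings vector.
#' @export
gamma_correct <- function(device, weights) {
  check_n_primaries(device, weights, "weights")
  w <- require_in_gamut(device, weights, "weights for gamma correction")
  vapply(seq_len(n_primaries(device)), function(p) {
    gt <- gamma_table(device, p)
    target <- w[p] * max(gt$output)
    # invert the monotone map output -> setting; ties.ordered handles flats
    s <- stats::approx(gt$output, gt$setting, xout = target,
                       method = "linear", ties = "ordered")$y
    # snap float jitter at half-integer counts so rounding is reproducible
    half <- round(s * 2) / 2
    if (abs(s - half) < 1e-6 * max(1, device$resolutions[p])) s <- half
    min(max(round_half_away(s), 0), device$resolutions[p])
  }, numeric(1))
}
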