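#' Recipe for a synthetic Gaussian-primary device
#'
#' Describes a synthetic multiprimary device whose primaries are Gaussian
#' spectral bands with controllable nonlinearities, used to exercise the whole
#' pipeline without calibration hardware: a gamma exponent per primary (1 =
#' linear drive), an optional spectral peak shift with drive level (the classic
#' LED nonlinearity that defeats purely linear solvers), an ambient floor, and
#' seeded multiplicative measurement noise.
#'
#' @param n_primaries Number of primaries.
#' @param peaks Peak wavelengths (nm); default equally spaced 430-630 nm.
#' @param fwhm Full width at half maximum of each primary (nm).
#' @param max_output Peak spectral output of each primary at full drive
#'   (energy units).
#' @param resolution Native resolution (maximum setting) per primary.
#' @param levels Native settings measured during calibration; must include 0
#'   and the resolution.
#' @param gamma Drive exponent per primary: output scales with
#'   `(setting/resolution)^gamma`.
#' @param shift Spectral peak shift at full drive (nm); the peak moves linearly
#'   with drive level.
#' @param ambient_scale Flat ambient spectral floor (energy units).
#' @param noise_sd Relative standard deviation of multiplicative log-normal
#'   measurement noise (0 = noiseless); log-normal keeps measurements
#'   nonnegative, matching signal-proportional spectrometer noise.
#' @param seed Integer seed making generation deterministic.
#' @param units `"radiance"` or `"irradiance"`.
#' @return List of class `silsub_fixture_recipe`.
#' @export
fixture_recipe <- function(n_primaries = 5,
                           peaks = seq(430, 630, length.out = n_primaries),
                           fwhm = 35,
                           max_output = 1,
                           resolution = 255,
                           levels = round(seq(0, resolution, length.out = 6)),
                           gamma = 1,
                           shift = 0,
                           ambient_scale = 0,
                           noise_sd = 0,
                           seed = 1L,
                           units = "radiance") {
  grid <- silsub_grid()
  if (length(peaks) != n_primaries) {
    stop_validation("peaks must have one value per primary.")
  }
  if (any(peaks < min(grid)) || any(peaks > max(grid))) {
    stop_validation("Fixture peaks must lie within the wavelength grid.")
  }
  if (!0 %in% levels || !resolution %in% levels) {
    stop_validation("Calibration levels must include 0 and the resolution.")
  }
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0.")
  rec <- list(
    n_primaries = n_primaries, peaks = peaks,
    fwhm = rep_len(fwhm, n_primaries),
    max_output = rep_len(max_output, n_primaries),
    resolution = resolution,
    levels = sort(unique(levels)),
    gamma = rep_len(gamma, n_primaries),
    shift = rep_len(shift, n_primaries),
    ambient_scale = ambient_scale,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    units = units
  )
  structure(rec, class = "silsub_fixture_recipe")
}

# noiseless generator: the closed-form measurement of primary p at setting s
fixture_spd <- function(recipe, p, s, grid = silsub_grid()) {
  drive <- s / recipe$resolution
  sigma <- recipe$fwhm[p] / (2 * sqrt(2 * log(2)))
  mu <- recipe$peaks[p] + recipe$shift[p] * drive
  band <- drive^recipe$gamma[p] * recipe$max_output[p] *
    exp(-0.5 * ((grid - mu) / sigma)^2)
  recipe$ambient_scale + band
}

#' Generate a synthetic calibrated device
#'
#' Builds the calibration ladder of a Gaussian-primary device from a
#' [fixture_recipe()] and assembles a ready-to-use `silsub_device`. The
#' measurement of primary `p` at setting `s` is
#' `ambient + (s/resolution)^gamma * max_output * Gaussian(peak + shift *
#' s/resolution, fwhm)`, optionally perturbed by seeded multiplicative
#' log-normal noise. Deterministic given the recipe's seed.
#'
#' @param recipe A [fixture_recipe()].
#' @return A `silsub_device` with attributes `recipe` and `config`.
#' @export
make_gaussian_device <- function(recipe) {
  stopifnot(inherits(recipe, "silsub_fixture_recipe"))
  grid <- silsub_grid()
  rows <- withr::with_seed(recipe$seed, {
    purrr::map(seq_len(recipe$n_primaries), function(p) {
      m <- t(vapply(recipe$levels, function(s) {
        v <- fixture_spd(recipe, p, s, grid)
        if (recipe$noise_sd > 0) {
          v <- v * stats::rlnorm(length(grid), meanlog = 0, sdlog = recipe$noise_sd)
        }
        v
      }, numeric(length(grid))))
      m
    })
  })
  cfg <- fixture_config(recipe)
  cal <- structure(
    list(grid = grid,
         settings = rep(list(as.numeric(recipe$levels)), recipe$n_primaries),
         spd = rows,
         ambient = colMeans(do.call(rbind, lapply(rows, function(m) m[1, ]))),
         n_primaries = recipe$n_primaries,
         resolutions = cfg$resolutions),
    class = "silsub_calibration"
  )
  dev <- silsub_device(cal, cfg)
  attr(dev, "recipe") <- recipe
  dev
}

fixture_config <- function(recipe, calibration_path = "calibration.csv") {
  validate_device_config(list(
    name = sprintf("synthetic %d-primary gaussian device", recipe$n_primaries),
    primaries = purrr::map(seq_len(recipe$n_primaries), function(p) {
      list(label = sprintf("P%d", p), color = NA,
           resolution = recipe$resolution)
    }),
    calibration_path = calibration_path,
    units = recipe$units,
    notes = "synthetic fixture",
    .dir = NULL
  ))
}

#' Build a template observer from pigment peaks
#'
#' One peak-normalised pigment template per label, with optional prereceptoral
#' filters applied to every member. Supports human-like five-receptor sets and
#' reduced sets such as a mouse-like observer (near-UV S cone, no third cone).
#'
#' @param peaks Numeric vector of peak wavelengths (nm).
#' @param labels Receptor labels, one per peak (defaults to `names(peaks)`).
#' @param filters Optional [prereceptoral_filter()] or list of filters applied
#'   to every member.
#' @param log_width Template width(s) in log-wavelength units, recycled over
#'   receptors (see [make_template_pigment()]). Narrower templates make the
#'   receptors more linearly independent, enlarging the contrast available on
#'   a given device.
#' @return An [action_spectra()] set.
#' @export
#' @examples
#' mouse <- make_template_observer(c(sc = 360, mc = 510, rh = 500, mel = 480))
#' receptor_labels(mouse)
make_template_observer <- function(peaks, labels = names(peaks), filters = NULL,
                                   log_width = 0.08) {
  if (is.null(labels) || any(!nzchar(labels))) {
    stop_validation("Each peak needs a receptor label (names(peaks) or labels=).")
  }
  if (anyDuplicated(labels)) {
    stop_validation(sprintf(
      "Duplicate receptor labels: %s.",
      paste(unique(labels[duplicated(labels)]), collapse = ", ")
    ))
  }
  grid <- silsub_grid()
  log_width <- rep_len(log_width, length(peaks))
  out <- tibble::tibble(wavelength = grid)
  for (i in seq_along(peaks)) {
    pig <- make_template_pigment(peaks[i], grid, log_width = log_width[i])
    if (!is.null(filters)) pig <- apply_prereceptoral_filters(pig, filters)
    out[[labels[i]]] <- pig$value
  }
  action_spectra(out, normalize = TRUE)
}

#' Draw a random solvable silent substitution problem
#'
#' Generates a matched (device, observer, problem) triple for property-style
#' testing of the solvers: a linear zero-ambient Gaussian device with 5-7
#' primaries, a five-receptor template observer whose peaks are spread across
#' the device's spectral span (so the receptors are well separated and the
#' A-matrix is well conditioned), a random target/silence/ignore partition
#' with at least one target and one silenced receptor, a random mid-gamut
#' background, and a Weber contrast drawn safely inside the gamut (a fixed
#' fraction of the maximum feasible contrast along the solution direction).
#' Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param n_targets Number of targeted receptors (1 or 2).
#' @return List with elements `device`, `observer`, `spec`.
#' @export
sample_problem_fixture <- function(seed, n_targets = 1) {
  withr::with_seed(seed, {
    np <- sample(5:7, 1)
    peaks <- seq(430, 630, length.out = np) + stats::runif(np, -8, 8)
    rec <- fixture_recipe(
      n_primaries = np, peaks = peaks, fwhm = stats::runif(1, 25, 45),
      seed = seed
    )
    device <- make_gaussian_device(rec)
    labels <- c("sc", "mel", "rh", "mc", "lc")
    obs_peaks <- stats::setNames(
      seq(min(peaks) - 5, max(peaks) + 5, length.out = 5) +
        stats::runif(5, -5, 5),
      labels
    )
    observer <- make_template_observer(obs_peaks,
                                       log_width = stats::runif(1, 0.04, 0.06))
    shuffled <- sample(labels)
    target <- shuffled[seq_len(n_targets)]
    n_ignore <- sample(0:2, 1)
    ignore <- if (n_ignore > 0) shuffled[n_targets + seq_len(n_ignore)] else character()
    silence <- setdiff(shuffled, c(target, ignore))
    background <- stats::runif(np, 0.3, 0.7)
    # probe the solution direction at a tiny contrast, then request a fixed
    # fraction of the largest in-gamut contrast along it
    probe <- problem_spec(target, silence, ignore, contrast = 1e-3,
                          mode = "weber", background = background)
    sol <- linalg_solve(device, observer, probe)
    dir <- (sol$modulation$weights - background) / 1e-3
    kappa_max <- max_feasible_scale(background, dir)
    contrast <- 1e-3 * kappa_max * stats::runif(1, 0.2, 0.7)
    spec <- problem_spec(target, silence, ignore, contrast = contrast,
                         mode = "weber", background = background)
    list(device = device, observer = observer, spec = spec)
  })
}

#' Write a fixture bundle to disk
#'
#' Emits a calibration CSV (dialect `Primary,Setting,380,...,780`), a device
#' config JSON, and an observer action-spectra CSV into `directory`, all
#' re-loadable by [load_device()] and [load_action_spectra()] with values equal
#' to the in-memory originals. Deterministic: equal recipes (and seeds) give
#' byte-identical files.
#'
#' @param recipe A [fixture_recipe()].
#' @param directory Output directory (created if missing).
#' @param observer Observer to write; default a human-like template observer.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture_bundle <- function(recipe, directory,
                                 observer = make_template_observer(
                                   c(sc = 420, mc = 530, lc = 560, rh = 500, mel = 480)
                                 )) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  dev <- make_gaussian_device(recipe)
  cal_path <- file.path(directory, "calibration.csv")
  cfg_path <- file.path(directory, "device.json")
  obs_path <- file.path(directory, "observer.csv")
  write_calibration(dev, cal_path)
  cfg <- list(
    name = dev$name,
    primaries = purrr::map(seq_along(dev$labels), function(p) {
      list(label = dev$labels[p], color = dev$colors[p],
           resolution = dev$resolutions[p])
    }),
    calibration_path = "calibration.csv",
    units = dev$units,
    notes = "synthetic fixture"
  )
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  write_action_spectra(observer, obs_path)
  invisible(c(calibration = cal_path, config = cfg_path, observer = obs_path))
}
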