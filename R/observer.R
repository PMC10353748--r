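#' Action spectra sets
#'
#' A set of photoreceptor action spectra is represented as a tibble with a
#' `wavelength` column (the canonical grid, nm) and one column per receptor
#' label (dimensionless sensitivity, peak-normalised to 1). Human observers
#' built with [build_observer()] carry the five labels `sc`, `mc`, `lc`, `rh`,
#' `mel`; custom observers (nonhuman animals, vessel-shadowed cone variants)
#' may carry any labels.
#'
#' @param x A data frame with a `wavelength` column and one numeric column per
#'   receptor.
#' @param normalize Peak-normalise each member to a maximum of 1 (the package
#'   convention; all solver maths is invariant to per-receptor scaling).
#' @return A tibble of class `silsub_action_spectra`.
#' @export
action_spectra <- function(x, normalize = TRUE) {
  x <- tibble::as_tibble(x)
  if (!"wavelength" %in% names(x)) {
    stop_format("Action spectra table must have a 'wavelength' column.")
  }
  labels <- setdiff(names(x), "wavelength")
  if (length(labels) == 0) {
    stop_validation("Action spectra table has no receptor columns.")
  }
  for (lab in labels) {
    v <- x[[lab]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop_validation(sprintf("Receptor column '%s' must be finite numeric.", lab))
    }
    if (any(v < 0)) {
      stop_validation(sprintf("Receptor column '%s' has negative sensitivities.", lab))
    }
    if (normalize) x[[lab]] <- v / max(v)
  }
  x <- x[, c("wavelength", labels)]
  class(x) <- c("silsub_action_spectra", class(tibble::tibble()))
  x
}

#' @export
print.silsub_action_spectra <- function(x, ...) {
  labels <- receptor_labels(x)
  cat(sprintf(
    "<action spectra: %d receptors (%s) on %g-%g nm grid>\n",
    length(labels), paste(labels, collapse = ", "),
    min(x$wavelength), max(x$wavelength)
  ))
  NextMethod()
}

#' Receptor labels of an action spectra set
#' @param observer An action spectra set.
#' @return Character vector of receptor labels in column order.
#' @export
receptor_labels <- function(observer) {
  setdiff(names(observer), "wavelength")
}

# 401 x n_receptors sensitivity matrix
sensitivity_matrix <- function(observer) {
  labels <- receptor_labels(observer)
  m <- as.matrix(observer[labels])
  rownames(m) <- NULL
  m
}

#' Unimodal pigment template
#'
#' An analytic stand-in for tabulated visual pigment sensitivity: a Gaussian in
#' log wavelength, peak-normalised so the maximum is exactly 1 at the grid
#' point nearest `peak_wavelength`. Used by the template observer backend and
#' by custom/nonhuman fixture observers. The log-wavelength parameterisation
#' makes the pointwise ratio of two shifted templates monotone in wavelength
#' (the ordering that univariance-style arguments rely on).
#'
#' @param peak_wavelength Peak sensitivity, nm; must lie inside the grid range.
#' @param grid Wavelength grid (default [silsub_grid()]).
#' @param log_width Gaussian width in log-wavelength units. The default 0.08
#'   gives a full width at half maximum of roughly 0.19 x peak (about 100 nm
#'   for a mid-wave pigment), comparable to cone fundamentals.
#' @return Tibble with columns `wavelength`, `value` (max exactly 1).
#' @export
#' @examples
#' p <- make_template_pigment(555)
#' p$wavelength[which.max(p$value)] # 555
make_template_pigment <- function(peak_wavelength, grid = silsub_grid(),
                                  log_width = 0.08) {
  if (length(peak_wavelength) != 1 || !is.finite(peak_wavelength)) {
    stop_validation("peak_wavelength must be a single finite number.")
  }
  if (peak_wavelength < min(grid) || peak_wavelength > max(grid)) {
    stop_validation(sprintf(
      "peak_wavelength %g nm is outside the grid range %g-%g nm.",
      peak_wavelength, min(grid), max(grid)
    ))
  }
  v <- exp(-0.5 * ((log(grid) - log(peak_wavelength)) / log_width)^2)
  v <- v / max(v)
  tibble::tibble(wavelength = grid, value = v)
}

#' Lens optical density
#'
#' Spectral optical density of the crystalline lens (plus ocular media) for an
#' observer of a given age. The lens accumulates yellow pigment with age, so
#' density increases with age and is concentrated at short wavelengths: older
#' lenses transmit less short-wavelength light.
#'
#' Two backends are available. `"template"` is a fully analytic surrogate (a
#' short-wavelength-decaying profile scaled linearly in age) satisfying the
#' same monotonicity contracts as the standard formulation. `"cie-tables"`
#' evaluates the CIEPO06 two-component formulation from user-supplied base
#' tables (see Details); no standard tables are bundled.
#'
#' @details For `backend = "cie-tables"`, `tables$lens` must be a data frame
#'   with columns `wavelength`, `TL1` (age-dependent component) and `TL2`
#'   (stable component). Density is `TL1 * (1 + 0.02 * (age - 32)) + TL2` for
#'   ages up to 60 and `TL1 * (1.56 + 0.0667 * (age - 60)) + TL2` above 60.
#'
#' @param age Observer age in years, 20-80.
#' @param grid Wavelength grid.
#' @param backend `"template"` or `"cie-tables"`.
#' @param tables For the cie-tables backend, a list with element `lens`.
#' @return Tibble with columns `wavelength`, `density` (optical density, >= 0).
#' @export
lens_density <- function(age, grid = silsub_grid(),
                         backend = c("template", "cie-tables"), tables = NULL) {
  backend <- match.arg(backend)
  if (length(age) != 1 || !is.finite(age) || age < 20 || age > 80) {
    stop_validation(sprintf(
      "age must be between 20 and 80 years (got %s); no extrapolation rule is defined outside that range.",
      format(age)
    ))
  }
  if (backend == "template") {
    # analytic surrogate: separable age scale x short-wavelength profile;
    # non-increasing in wavelength over the whole grid, non-decreasing in age
    profile <- 1.6 * exp(-((grid - 330) / 90)^2)
    density <- (1 + 0.015 * (age - 20)) * profile
  } else {
    if (is.null(tables$lens)) {
      stop_validation(paste(
        "cie-tables backend requested but no lens base table supplied;",
        "pass tables = list(lens = <data frame with wavelength, TL1, TL2>)",
        "or use backend = 'template'."
      ))
    }
    lt <- tables$lens
    for (col in c("wavelength", "TL1", "TL2")) {
      if (!col %in% names(lt)) {
        stop_format(sprintf("Lens base table is missing column '%s'.", col))
      }
    }
    tl1 <- resample_to_grid(lt$wavelength, lt$TL1, grid, what = "lens base table")
    tl2 <- resample_to_grid(lt$wavelength, lt$TL2, grid, what = "lens base table")
    scale <- if (age <= 60) 1 + 0.02 * (age - 32) else 1.56 + 0.0667 * (age - 60)
    density <- tl1 * scale + tl2
  }
  tibble::tibble(wavelength = grid, density = pmax(density, 0))
}

#' Macular pigment optical density
#'
#' Spectral optical density of the macular pigment, a yellow carotenoid spot
#' above the foveal photoreceptors. Its effect is strongest for small stimulus
#' fields: the peak density decreases with field size following
#' `0.485 * exp(-field_size / 6.132)` and is taken as negligible beyond 10
#' degrees, so larger field sizes are clamped to 10 (with a notice).
#'
#' @param field_size Stimulus field size in degrees of visual angle (> 0;
#'   values above 10 are clamped to 10).
#' @param grid Wavelength grid.
#' @param backend `"template"` (analytic: Gaussian profile peaking at 460 nm)
#'   or `"cie-tables"` (user-supplied relative density template in
#'   `tables$macular`, columns `wavelength`, `density`).
#' @param tables For the cie-tables backend, a list with element `macular`.
#' @return Tibble with columns `wavelength`, `density`.
#' @export
macular_density <- function(field_size, grid = silsub_grid(),
                            backend = c("template", "cie-tables"),
                            tables = NULL) {
  backend <- match.arg(backend)
  if (length(field_size) != 1 || !is.finite(field_size) || field_size <= 0) {
    stop_validation("field_size must be a single positive number of degrees.")
  }
  field_size <- clamp_field_size(field_size)
  peak <- 0.485 * exp(-field_size / 6.132)
  if (backend == "template") {
    shape <- exp(-((grid - 460) / 38)^2)
  } else {
    if (is.null(tables$macular)) {
      stop_validation(paste(
        "cie-tables backend requested but no macular base table supplied;",
        "pass tables = list(macular = <data frame with wavelength, density>)",
        "or use backend = 'template'."
      ))
    }
    mt <- tables$macular
    for (col in c("wavelength", "density")) {
      if (!col %in% names(mt)) {
        stop_format(sprintf("Macular base table is missing column '%s'.", col))
      }
    }
    shape <- resample_to_grid(mt$wavelength, mt$density, grid,
                              what = "macular base table")
    shape <- shape / max(shape)
  }
  tibble::tibble(wavelength = grid, density = pmax(peak * shape, 0))
}

clamp_field_size <- function(field_size) {
  if (field_size > 10) {
    rlang::inform(sprintf(
      "field_size %g clamped to 10 degrees (macular pigment negligible beyond 10).",
      field_size
    ), class = "silsub_clamp_notice")
    field_size <- 10
  }
  field_size
}

#' Prereceptoral filter
#'
#' A named spectral transmittance applied multiplicatively in front of a
#' photopigment (lens, macular pigment, or custom filters such as haemoglobin
#' for vessel-shadowed cones).
#'
#' @param transmittance Data frame with columns `wavelength`, `value`; values
#'   in `[0, 1]`.
#' @param kind Label: `"lens"`, `"macular"`, or any custom string.
#' @return List of class `silsub_filter`.
#' @export
prereceptoral_filter <- function(transmittance, kind = "custom") {
  transmittance <- tibble::as_tibble(transmittance)
  if (!all(c("wavelength", "value") %in% names(transmittance))) {
    stop_format("Filter transmittance needs columns 'wavelength' and 'value'.")
  }
  v <- transmittance$value
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1 + 1e-12)) {
    stop_validation("Filter transmittance must lie in [0, 1].")
  }
  structure(list(kind = kind, transmittance = transmittance),
            class = "silsub_filter")
}

#' Convert optical density to transmittance
#'
#' @param density Tibble with columns `wavelength`, `density`.
#' @param kind Filter label for the result.
#' @return A [prereceptoral_filter()] with transmittance `10^(-density)`.
#' @export
density_to_filter <- function(density, kind = "custom") {
  prereceptoral_filter(
    tibble::tibble(wavelength = density$wavelength,
                   value = 10^(-density$density)),
    kind = kind
  )
}

#' Apply prereceptoral filters to a pigment template
#'
#' Multiplies a pigment sensitivity pointwise by each filter's transmittance,
#' then re-peak-normalises to 1. Grids must match exactly; mismatches raise an
#' alignment error rather than resampling silently.
#'
#' @param pigment Tibble with columns `wavelength`, `value`.
#' @param filters A single [prereceptoral_filter()] or a list of them.
#' @return Filtered, peak-normalised pigment tibble.
#' @export
apply_prereceptoral_filters <- function(pigment, filters) {
  if (inherits(filters, "silsub_filter")) filters <- list(filters)
  v <- pigment$value
  for (f in filters) {
    check_same_grid(pigment$wavelength, f$transmittance$wavelength,
                    what = sprintf("pigment and '%s' filter", f$kind))
    v <- v * f$transmittance$value
  }
  if (max(v) <= 0) {
    stop_validation("Filtered pigment is identically zero; cannot peak-normalise.")
  }
  tibble::tibble(wavelength = pigment$wavelength, value = v / max(v))
}

#' Build a colorimetric observer
#'
#' Constructs the five photoreceptor action spectra (`sc`, `mc`, `lc`, `rh`,
#' `mel`) appropriate to an observer's age and stimulus field size. Cones
#' receive both lens and macular pigment filtering; the rhodopic and melanopic
#' members receive the lens correction only -- macular pigment correction is
#' not applied to them because rods are absent from the fovea and ipRGCs sit
#' above the retinal pigment layer. All members are peak-normalised.
#'
#' @param age Observer age in years (20-80).
#' @param field_size Stimulus field size in degrees (> 0; > 10 clamps to 10).
#' @param backend `"template"` (self-contained analytic backend) or
#'   `"cie-tables"` (evaluates CIEPO06/CIE S 026-style computations from
#'   user-supplied base tables; see [lens_density()] and Details).
#' @param tables For the cie-tables backend: a list with elements `lens`,
#'   `macular`, `absorbance` (columns `wavelength`, `sc`, `mc`, `lc`:
#'   low-density photopigment absorbance) and `rod_mel` (columns `wavelength`,
#'   `rh`, `mel`: standard-observer action spectra to be lens-adjusted).
#' @param cone_peaks,rod_peak,mel_peak Template-backend pigment peaks (nm).
#' @param mel_lens_fn Optional function `(age, grid) -> density tibble` used to
#'   lens-correct the rhodopic and melanopic members. The reference standard
#'   uses a slightly different lens density function for these members; it is
#'   exposed here as a swappable component. Default: the same lens function as
#'   the cones.
#' @return A [action_spectra()] set on the canonical grid with attributes
#'   `age`, `field_size`, `backend`.
#' @export
#' @examples
#' obs <- build_observer(32, 10)
#' receptor_labels(obs)
build_observer <- function(age = 32, field_size = 10,
                           backend = c("template", "cie-tables"),
                           tables = NULL,
                           cone_peaks = c(sc = 419, mc = 530, lc = 558),
                           rod_peak = 498, mel_peak = 480,
                           mel_lens_fn = NULL) {
  backend <- match.arg(backend)
  grid <- silsub_grid()
  field_size <- {
    if (length(field_size) != 1 || !is.finite(field_size) || field_size <= 0) {
      stop_validation("field_size must be a single positive number of degrees.")
    }
    clamp_field_size(field_size)
  }

  lens <- lens_density(age, grid, backend = backend, tables = tables)
  mac <- macular_density(field_size, grid, backend = backend, tables = tables)
  lens_f <- density_to_filter(lens, "lens")
  mac_f <- density_to_filter(mac, "macular")
  if (is.null(mel_lens_fn)) {
    mel_lens_f <- lens_f
  } else {
    mel_lens_f <- density_to_filter(mel_lens_fn(age, grid), "lens-rh-mel")
  }

  if (backend == "template") {
    if (is.null(names(cone_peaks)) || !all(c("sc", "mc", "lc") %in% names(cone_peaks))) {
      stop_validation("cone_peaks must be named with sc, mc, lc.")
    }
    cones <- lapply(c("sc", "mc", "lc"), function(lab) {
      pig <- make_template_pigment(cone_peaks[[lab]], grid)
      apply_prereceptoral_filters(pig, list(lens_f, mac_f))$value
    })
    rh <- apply_prereceptoral_filters(make_template_pigment(rod_peak, grid),
                                      list(mel_lens_f))$value
    mel <- apply_prereceptoral_filters(make_template_pigment(mel_peak, grid),
                                       list(mel_lens_f))$value
    out <- tibble::tibble(
      wavelength = grid,
      sc = cones[[1]], mc = cones[[2]], lc = cones[[3]],
      rh = rh, mel = mel
    )
  } else {
    need <- c("absorbance", "rod_mel")
    missing <- need[vapply(need, function(n) is.null(tables[[n]]), logical(1))]
    if (length(missing) > 0) {
      stop_validation(sprintf(
        "cie-tables backend needs user-supplied base tables %s; none are bundled. Use backend = 'template' for the self-contained observer.",
        paste(sprintf("'%s'", missing), collapse = ", ")
      ))
    }
    ab <- tables$absorbance
    for (col in c("wavelength", "sc", "mc", "lc")) {
      if (!col %in% names(ab)) {
        stop_format(sprintf("Absorbance base table is missing column '%s'.", col))
      }
    }
    # field-size-dependent peak axial optical densities of the photopigments
    d_lm <- 0.38 + 0.54 * exp(-field_size / 1.333)
    d_s <- 0.30 + 0.45 * exp(-field_size / 1.333)
    t_pre <- 10^(-(lens$density + mac$density))
    cone <- function(lab, dmax) {
      a <- resample_to_grid(ab$wavelength, ab[[lab]], grid,
                            what = "absorbance table")
      a <- a / max(a)
      (1 - 10^(-dmax * a)) * t_pre
    }
    rm_tab <- tables$rod_mel
    for (col in c("wavelength", "rh", "mel")) {
      if (!col %in% names(rm_tab)) {
        stop_format(sprintf("rod_mel base table is missing column '%s'.", col))
      }
    }
    # lens-adjust standard-observer rod/mel spectra: divide out the reference
    # (age 32) lens and apply the requested observer's lens
    ref_lens <- if (is.null(mel_lens_fn)) {
      lens_density(32, grid, backend = backend, tables = tables)
    } else {
      mel_lens_fn(32, grid)
    }
    obs_lens <- if (is.null(mel_lens_fn)) {
      lens_density(age, grid, backend = backend, tables = tables)
    } else {
      mel_lens_fn(age, grid)
    }
    adj <- 10^(ref_lens$density - obs_lens$density)
    out <- tibble::tibble(
      wavelength = grid,
      sc = cone("sc", d_s), mc = cone("mc", d_lm), lc = cone("lc", d_lm),
      rh = resample_to_grid(rm_tab$wavelength, rm_tab$rh, grid,
                            what = "rod_mel table") * adj,
      mel = resample_to_grid(rm_tab$wavelength, rm_tab$mel, grid,
                             what = "rod_mel table") * adj
    )
  }
  out <- action_spectra(out, normalize = TRUE)
  attr(out, "age") <- age
  attr(out, "field_size") <- field_size
  attr(out, "backend") <- backend
  out
}

#' Load action spectra from a table or CSV file
#'
#' Reads a table whose first column is `wavelength` (nm) and whose remaining
#' columns are receptor labels (arbitrary labels are allowed, supporting
#' nonhuman observers and vessel-shadowed cone variants). Values must be
#' nonnegative energy-unit sensitivities; tables sampled more finely than the
#' canonical grid, or at up to 5 nm steps, are linearly resampled onto it.
#' Members are peak-normalised on load.
#'
#' @param x A CSV path or a data frame.
#' @return A [action_spectra()] set on the canonical grid.
#' @export
load_action_spectra <- function(x) {
  if (is.character(x)) {
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!"wavelength" %in% names(x)) {
    stop_format("Action spectra table must have a 'wavelength' column first.")
  }
  grid <- silsub_grid()
  labels <- setdiff(names(x), "wavelength")
  wl <- x$wavelength
  if (is.unsorted(wl, strictly = TRUE)) {
    stop_format("Action spectra wavelengths must be strictly increasing.")
  }
  if (min(wl) > min(grid) || max(wl) < max(grid)) {
    stop_format(sprintf(
      "Action spectra cover %g-%g nm but must cover 380-780 nm.", min(wl), max(wl)
    ))
  }
  out <- tibble::tibble(wavelength = grid)
  for (lab in labels) {
    v <- x[[lab]]
    if (any(!is.finite(v))) {
      stop_validation(sprintf("Receptor column '%s' has non-finite values.", lab))
    }
    if (any(v < 0)) {
      stop_validation(sprintf("Receptor column '%s' has negative sensitivities.", lab))
    }
    out[[lab]] <- resample_to_grid(wl, v, grid, what = sprintf("column '%s'", lab))
  }
  action_spectra(out, normalize = TRUE)
}

#' Write action spectra to CSV
#'
#' The inverse of [load_action_spectra()]: first column `wavelength`, one
#' column per receptor label, UTF-8, comma-delimited. Values round-trip
#' exactly (shortest round-trip decimal representation).
#'
#' @param observer An action spectra set.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_action_spectra <- function(observer, path) {
  readr::write_csv(tibble::as_tibble(unclass_tbl(observer)), path, progress = FALSE)
  invisible(path)
}

unclass_tbl <- function(x) {
  class(x) <- class(tibble::tibble())
  x
}
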