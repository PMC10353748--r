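#' Canonical wavelength grid
#'
#' All internal computation happens on a shared wavelength grid of 380-780 nm
#' in 1 nm steps (401 samples). Loaders resample finer-sampled inputs onto this
#' grid; no other operation ever resamples silently -- mismatched grids raise
#' an alignment error.
#'
#' @return Integer vector of wavelengths in nm.
#' @export
#' @examples
#' length(silsub_grid()) # 401
silsub_grid <- function() {
  380:780
}

# Grid step in nm (the Delta-lambda of the alpha-opic quadrature).
grid_step <- function(grid) {
  steps <- diff(grid)
  steps[1]
}

# ---- condition helpers -------------------------------------------------------
# All package errors carry class "silsub_error" plus a specific subclass:
#   silsub_validation_error  - bad arguments, formats, ranges (CLI exit 2)
#   silsub_alignment_error   - wavelength-grid mismatch (CLI exit 2)
#   silsub_format_error      - malformed files (CLI exit 2)
#   silsub_gamut_error       - physically unrealisable settings (CLI exit 3)
#   silsub_infeasibility_error - no feasible solution found (CLI exit 3)
#   silsub_degenerate_error  - singular/ill-conditioned system (CLI exit 3)

abort_silsub <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "silsub_error"), ...)
}

stop_validation <- function(message, ...) {
  abort_silsub(message, "silsub_validation_error", ...)
}

stop_alignment <- function(message, ...) {
  abort_silsub(message, c("silsub_alignment_error", "silsub_validation_error"), ...)
}

stop_format <- function(message, ...) {
  abort_silsub(message, c("silsub_format_error", "silsub_validation_error"), ...)
}

stop_gamut <- function(message, ...) {
  abort_silsub(message, "silsub_gamut_error", ...)
}

stop_infeasible <- function(message, ...) {
  abort_silsub(message, "silsub_infeasibility_error", ...)
}

stop_degenerate <- function(message, ...) {
  abort_silsub(message, "silsub_degenerate_error", ...)
}

# Check that two wavelength grids are identical; raise alignment error if not.
check_same_grid <- function(a, b, what = "inputs") {
  if (length(a) != length(b) || any(a != b)) {
    stop_alignment(sprintf(
      "Wavelength grids of %s differ (%d vs %d samples, %g-%g vs %g-%g nm); resample explicitly, no silent resampling is performed.",
      what, length(a), length(b), min(a), max(a), min(b), max(b)
    ))
  }
  invisible(TRUE)
}

# Linear resampling of spectral values onto the canonical grid.
# `wl` must cover the target grid fully (no extrapolation) and must not be
# coarser than `max_step` nm.
resample_to_grid <- function(wl, values, grid = silsub_grid(), max_step = 5,
                             what = "spectral table") {
  if (min(wl) > min(grid) || max(wl) < max(grid)) {
    stop_format(sprintf(
      "%s covers %g-%g nm but must cover the full %g-%g nm grid.",
      what, min(wl), max(wl), min(grid), max(grid)
    ))
  }
  step <- max(diff(wl))
  if (step > max_step) {
    stop_format(sprintf(
      "%s is sampled at %g nm steps; sampling coarser than %g nm is rejected (quadrature error unbounded).",
      what, step, max_step
    ))
  }
  if (length(wl) == length(grid) && all(wl == grid)) {
    return(values)
  }
  stats::approx(wl, values, xout = grid, method = "linear")$y
}

# round half away from zero (weight -> setting quantisation; documented because
# half-even vs half-up changes settings by one count)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
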