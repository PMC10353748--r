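# Shared fixtures: all synthetic, generated in code at test time.

round_half_away <- silsub:::round_half_away

# column-wise comparison ignoring classes/attributes beyond the values
plain_cols <- function(x) as.data.frame(lapply(x, unname))

# linear, zero-ambient, 5-primary Gaussian device (default study device)
linear_device <- function(n_primaries = 5, seed = 42, ...) {
  make_gaussian_device(fixture_recipe(n_primaries = n_primaries, seed = seed, ...))
}

# five-receptor template observer with peaks spread across the device span:
# well separated receptors, so sizeable target contrasts are in gamut
separable_observer <- function(log_width = 0.05) {
  make_template_observer(
    c(sc = 425, mel = 475, rh = 525, mc = 575, lc = 625),
    log_width = log_width
  )
}

# human-like template observer (realistic peak layout; heavily overlapping)
human_observer <- function() {
  make_template_observer(c(sc = 420, mc = 530, lc = 560, rh = 500, mel = 480))
}

# independent quadrature oracle for the alpha-opic projection: explicit loop,
# no matrix algebra shared with the implementation
quadrature_oracle <- function(spd_values, observer, step = 1) {
  labels <- receptor_labels(observer)
  out <- numeric(length(labels))
  names(out) <- labels
  for (lab in labels) {
    s <- observer[[lab]]
    acc <- 0
    for (i in seq_along(spd_values)) acc <- acc + spd_values[i] * s[i] * step
    out[lab] <- acc
  }
  out
}

# minimal calibration table in the CSV dialect (wide data frame)
minimal_calibration_df <- function(n_primaries = 4, resolution = 255,
                                   grid = silsub_grid(),
                                   value_fn = function(p, s) {
                                     rep(s / resolution * p, length(grid))
                                   }) {
  rows <- list()
  for (p in seq_len(n_primaries) - 1) {
    for (s in c(0, resolution)) {
      rows[[length(rows) + 1]] <- c(Primary = p, Setting = s,
                                    stats::setNames(value_fn(p + 1, s),
                                                    as.character(grid)))
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

simple_config <- function(n_primaries = 4, resolution = 255) {
  silsub:::validate_device_config(list(
    name = "test device",
    primaries = lapply(seq_len(n_primaries), function(p) {
      list(label = paste0("P", p), color = NA, resolution = resolution)
    }),
    calibration_path = "calibration.csv",
    units = "radiance",
    .dir = NULL
  ))
}
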