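#' Contrast metrics
#'
#' Michelson contrast `(e_max - e_min) / (e_max + e_min)` describes bipolar
#' modulations about a mean background; Weber contrast `(e_mod - e_bg) / e_bg`
#' describes unipolar pulses against a background and may be negative
#' (decrements). Both are dimensionless ratios of alpha-opic quantities.
#'
#' @param e_max,e_min Alpha-opic irradiances at the modulation extremes.
#' @param e_mod,e_bg Alpha-opic irradiance of the modulation and background.
#' @return Contrast value(s).
#' @export
michelson_contrast <- function(e_max, e_min) {
  denom <- e_max + e_min
  if (any(denom <= 0)) {
    stop_validation("Michelson contrast undefined: e_max + e_min must be > 0.")
  }
  (e_max - e_min) / denom
}

#' @rdname michelson_contrast
#' @export
weber_contrast <- function(e_mod, e_bg) {
  if (any(e_bg <= 0)) {
    stop_validation("Weber contrast undefined: background irradiance must be > 0.")
  }
  (e_mod - e_bg) / e_bg
}

#' Specify a silent substitution problem
#'
#' Partitions the observer's receptors into targeted, silenced, and ignored
#' sets, and fixes the contrast request. The three sets must be pairwise
#' disjoint and together cover every receptor label of the observer the
#' problem is solved for (checked at solve time). Ignored receptors are
#' dropped from the equations -- freeing contrast for the targets -- but their
#' achieved contrasts are still reported for transparency.
#'
#' @param target Receptor labels to modulate (nonempty).
#' @param silence Receptor labels to hold constant (nonempty).
#' @param ignore Receptor labels to leave unconstrained (possibly empty).
#' @param contrast Requested contrast (in the units of `mode`), or `"max"` to
#'   maximise target contrast (optimisation solver only).
#' @param mode `"weber"` (unipolar pulse) or `"michelson"` (bipolar modulation
#'   about the background; the stored modulation is the positive arm, the
#'   negative arm is its reflection through the background).
#' @param background Optional background weights vector. Required by
#'   [linalg_solve()]; when omitted, [optim_solve()] treats the background as
#'   free variables.
#' @param bounds Optional per-primary weight bounds: a 2-column matrix (or
#'   list of `c(lo, hi)`) within `[0, 1]`, `lo < hi`. Useful to keep solutions
#'   away from the hard edges of the gamut.
#' @return List of class `silsub_problem`.
#' @export
problem_spec <- function(target, silence, ignore = character(),
                         contrast = 0.2, mode = c("weber", "michelson"),
                         background = NULL, bounds = NULL) {
  mode <- match.arg(mode)
  target <- as.character(target); silence <- as.character(silence)
  ignore <- as.character(ignore)
  if (length(target) == 0) stop_validation("target must name at least one receptor.")
  if (length(silence) == 0) stop_validation("silence must name at least one receptor.")
  overlap <- c(intersect(target, silence), intersect(target, ignore),
               intersect(silence, ignore))
  if (length(overlap) > 0) {
    stop_validation(sprintf(
      "target/silence/ignore must be disjoint; overlapping label(s): %s.",
      paste(unique(overlap), collapse = ", ")
    ))
  }
  if (is.character(contrast)) {
    if (!identical(contrast, "max")) {
      stop_validation("contrast must be a number or the string 'max'.")
    }
  } else if (length(contrast) != 1 || !is.finite(contrast)) {
    stop_validation("contrast must be a single finite number or 'max'.")
  }
  if (!is.null(bounds)) {
    if (is.list(bounds)) bounds <- do.call(rbind, bounds)
    bounds <- as.matrix(bounds)
    if (ncol(bounds) != 2 || any(!is.finite(bounds)) ||
        any(bounds < 0) || any(bounds > 1) || any(bounds[, 1] >= bounds[, 2])) {
      stop_validation("bounds must be rows of c(lo, hi) with 0 <= lo < hi <= 1.")
    }
  }
  structure(
    list(target = target, silence = silence, ignore = ignore,
         contrast = contrast, mode = mode, background = background,
         bounds = bounds),
    class = "silsub_problem"
  )
}

check_partition <- function(spec, labels) {
  all_named <- c(spec$target, spec$silence, spec$ignore)
  unknown <- setdiff(all_named, labels)
  if (length(unknown) > 0) {
    stop_validation(sprintf(
      "Unknown receptor label(s) %s; observer has: %s.",
      paste(unknown, collapse = ", "), paste(labels, collapse = ", ")
    ))
  }
  missing <- setdiff(labels, all_named)
  if (length(missing) > 0) {
    stop_validation(sprintf(
      "Receptor(s) %s are not assigned to target, silence, or ignore; the three sets must cover every receptor.",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

spec_bounds <- function(spec, n) {
  if (is.null(spec$bounds)) {
    cbind(rep(0, n), rep(1, n))
  } else {
    b <- spec$bounds
    if (nrow(b) == 1) b <- b[rep(1, n), , drop = FALSE]
    if (nrow(b) != n) {
      stop_validation(sprintf("bounds must have 1 or %d rows.", n))
    }
    b
  }
}

# named contrast vector from weights through the forward model.
# clip_reflection: clip the bipolar negative arm into gamut (optimiser path)
# instead of raising.
contrast_values <- function(device, smat, labels, bg_w, mod_w, mode,
                            clip_reflection = FALSE, floor_bg = FALSE) {
  e_bg <- aopic_values(device, bg_w, smat)
  if (mode == "weber") {
    if (floor_bg) e_bg <- pmax(e_bg, .Machine$double.xmin)
    if (any(e_bg <= 0)) {
      stop_validation("Weber contrast undefined: background alpha-opic irradiance is zero for at least one receptor.")
    }
    e_mod <- aopic_values(device, mod_w, smat)
    out <- (e_mod - e_bg) / e_bg
  } else {
    neg <- 2 * bg_w - mod_w
    g <- in_gamut_weights(neg)
    if (!g && !clip_reflection) {
      stop_gamut(paste(
        "Bipolar reflection out of gamut: the negative arm 2*background - modulation",
        "has weights outside [0, 1]; reduce contrast or move the background toward mid-gamut."
      ))
    }
    neg <- pmin(pmax(neg, 0), 1)
    e_pos <- aopic_values(device, mod_w, smat)
    e_neg <- aopic_values(device, neg, smat)
    denom <- e_pos + e_neg
    if (floor_bg) denom <- pmax(denom, .Machine$double.xmin)
    if (any(denom <= 0)) {
      stop_validation("Michelson contrast undefined: arm irradiances sum to zero for at least one receptor.")
    }
    out <- (e_pos - e_neg) / denom
  }
  if (floor_bg) {
    # optimiser path: keep the landscape finite near degenerate (dark)
    # backgrounds so the search can move away instead of aborting
    out[!is.finite(out)] <- 1e6
    out <- pmin(pmax(out, -1e6), 1e6)
  }
  names(out) <- labels
  out
}

in_gamut_weights <- function(w, slack = 1e-9) {
  all(is.finite(w)) && all(w >= -slack) && all(w <= 1 + slack)
}

#' Per-receptor contrasts of a background/modulation pair
#'
#' Forward-models both arms through the device and applies the chosen contrast
#' metric per receptor. For `"michelson"` the extremes are the modulation and
#' its reflection through the background (`2*bg - mod` in weight space); a
#' reflection outside the gamut raises a gamut error. Contrasts are signed:
#' positive when the (positive-arm) modulation increases the receptor's
#' alpha-opic irradiance.
#'
#' @param device A `silsub_device`.
#' @param observer An [action_spectra()] set on the device grid.
#' @param background,modulation Weights vectors (both must be in gamut).
#' @param mode `"weber"` or `"michelson"`.
#' @return Tibble with columns `receptor`, `contrast`.
#' @export
receptor_contrasts <- function(device, observer, background, modulation,
                               mode = c("weber", "michelson")) {
  mode <- match.arg(mode)
  check_same_grid(device$grid, observer$wavelength, "device and observer")
  require_in_gamut(device, background, "background weights")
  require_in_gamut(device, modulation, "modulation weights")
  v <- contrast_values(device, sensitivity_matrix(observer),
                       receptor_labels(observer), background, modulation, mode)
  tibble::tibble(receptor = names(v), contrast = unname(v))
}

# ---- solution object ---------------------------------------------------------

new_solution <- function(device, observer, spec, bg_w, mod_w, method, meta) {
  labels <- receptor_labels(observer)
  smat <- sensitivity_matrix(observer)
  contrasts <- contrast_values(device, smat, labels, bg_w, mod_w, spec$mode)
  role <- ifelse(labels %in% spec$target, "target",
                 ifelse(labels %in% spec$silence, "silence", "ignore"))
  e_bg <- aopic_values(device, bg_w, smat)
  e_mod <- aopic_values(device, mod_w, smat)
  meta$constraint_residual <- max(abs(contrasts[role == "silence"]))
  structure(
    list(
      background = list(weights = bg_w,
                        settings = weights_to_settings(device, bg_w)),
      modulation = list(weights = mod_w,
                        settings = weights_to_settings(device, mod_w)),
      spectra = tibble::tibble(
        wavelength = device$grid,
        background = multi_spd_values(device, bg_w),
        modulation = multi_spd_values(device, mod_w)
      ),
      aopic = tibble::tibble(receptor = labels,
                             background = unname(e_bg),
                             modulation = unname(e_mod)),
      contrasts = tibble::tibble(receptor = labels, role = role,
                                 contrast = unname(contrasts)),
      mode = spec$mode,
      spec = spec,
      device_name = device$name,
      method = method,
      meta = meta
    ),
    class = "silsub_solution"
  )
}

#' @export
print.silsub_solution <- function(x, ...) {
  cat(sprintf("<silent substitution solution (%s, %s contrast) on '%s'>\n",
              x$method, x$mode, x$device_name))
  cat("background weights: ", paste(sprintf("%.4f", x$background$weights),
                                    collapse = " "), "\n")
  cat("modulation weights: ", paste(sprintf("%.4f", x$modulation$weights),
                                    collapse = " "), "\n")
  print(x$contrasts)
  cat(sprintf("max |silenced contrast| = %.3g\n", x$meta$constraint_residual))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a silent substitution solution
#'
#' `tidy()` returns the per-receptor table (role, achieved contrast, alpha-opic
#' irradiances of both arms); `glance()` returns a one-row summary.
#'
#' @param x A `silsub_solution`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.silsub_solution <- function(x, ...) {
  dplyr::left_join(x$contrasts, x$aopic, by = "receptor")
}

#' @rdname tidy.silsub_solution
#' @export
glance.silsub_solution <- function(x, ...) {
  targeted <- x$contrasts$contrast[x$contrasts$role == "target"]
  tibble::tibble(
    method = x$method,
    mode = x$mode,
    requested_contrast = if (is.character(x$spec$contrast)) NA_real_ else x$spec$contrast,
    achieved_target_contrast = mean(targeted),
    max_silenced_contrast = x$meta$constraint_residual,
    seed = x$meta$seed %||% NA_integer_,
    iterations = x$meta$iterations %||% NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- linear-algebra solver ---------------------------------------------------

# local linear model of the device about a background: one row per primary,
# the d(spd)/d(weight) slope through the calibration interpolant (central
# finite difference, one-sided at the gamut edges). On a linear device this is
# exactly the ambient-subtracted full-drive spectrum.
primary_slopes <- function(device, bg_w, delta = 1e-3) {
  t(vapply(seq_len(n_primaries(device)), function(p) {
    res <- device$resolutions[p]
    lo <- max(bg_w[p] - delta, 0)
    hi <- min(bg_w[p] + delta, 1)
    (primary_spd_values(device, p, hi * res) -
       primary_spd_values(device, p, lo * res)) / (hi - lo)
  }, numeric(length(device$grid))))
}

#' Solve a silent substitution problem by linear algebra
#'
#' For a known background and a numeric target contrast, builds the A-matrix
#' mapping primary weight increments to alpha-opic increments about the
#' background (`A = P_bg . S_alpha` over the non-ignored receptors, where the
#' rows of `P_bg` are the per-primary spectral slopes at the background), forms
#' the requested modulation `beta` (zero for silenced receptors,
#' `contrast x E_alpha(background)` for targets), and solves
#' `alpha_sc = beta A^-1` -- by exact inversion for square systems, by the
#' Moore-Penrose pseudo-inverse (least-squares / minimum-norm) otherwise. The
#' modulation weights are `background + alpha_sc`. Reported contrasts are
#' recomputed through the forward model, never echoed from the solver.
#'
#' For `"michelson"` mode the request is converted to a positive Weber arm of
#' the same magnitude; the negative arm is the reflection through the
#' background, and the Michelson contrast of the two arms equals the request
#' exactly on a linear device.
#'
#' @param device A `silsub_device`.
#' @param observer An [action_spectra()] set on the device grid.
#' @param spec A [problem_spec()] with a `background` and a numeric `contrast`.
#' @param cond_tol Condition-number threshold above which the system is
#'   treated as singular (default `1e10`).
#' @return A `silsub_solution`.
#' @export
linalg_solve <- function(device, observer, spec, cond_tol = 1e10) {
  stopifnot(inherits(spec, "silsub_problem"))
  labels <- receptor_labels(observer)
  check_partition(spec, labels)
  check_same_grid(device$grid, observer$wavelength, "device and observer")
  if (is.null(spec$background)) {
    stop_validation("linalg_solve requires a known background; use optim_solve to optimise the background as well.")
  }
  if (is.character(spec$contrast)) {
    stop_validation("linalg_solve requires a numeric target contrast; use optim_solve for contrast = 'max'.")
  }
  bg_w <- require_in_gamut(device, spec$background, "background weights")
  smat <- sensitivity_matrix(observer)
  considered <- labels[!labels %in% spec$ignore]
  smat_c <- smat[, match(considered, labels), drop = FALSE]

  P <- primary_slopes(device, bg_w)             # n_primaries x n_wavelengths
  A <- P %*% smat_c * grid_step(device$grid)    # n_primaries x n_considered

  sv <- svd(A)$d
  cond <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  if (cond > cond_tol) {
    stop_degenerate(sprintf(
      "A-matrix is singular or ill-conditioned (condition number %.3g > %.3g); try a different background, or primaries with more distinct spectra.",
      cond, cond_tol
    ))
  }

  e_bg <- aopic_values(device, bg_w, smat_c)
  beta <- numeric(length(considered))
  names(beta) <- considered
  beta[spec$target] <- spec$contrast * e_bg[spec$target]

  # alpha_sc . A = beta  <=>  t(A) alpha_sc = beta
  alpha_sc <- if (nrow(A) == ncol(A)) {
    as.numeric(solve(t(A), beta))
  } else {
    as.numeric(MASS::ginv(t(A)) %*% beta)
  }

  mod_w <- bg_w + alpha_sc
  arms <- list(mod_w)
  if (spec$mode == "michelson") arms <- c(arms, list(bg_w - alpha_sc))
  for (arm in arms) {
    g <- in_gamut(device, arm)
    if (!g$in_gamut) {
      kappa <- max_feasible_scale(bg_w, alpha_sc, bipolar = spec$mode == "michelson")
      stop_gamut(sprintf(
        paste("Requested contrast %.4g drives the solution out of gamut",
              "(primary %s); the largest in-gamut contrast along this direction is about %.4g."),
        spec$contrast,
        paste(g$violations$label, collapse = ", "),
        kappa * spec$contrast
      ))
    }
  }

  new_solution(device, observer, spec, bg_w, mod_w, "linalg",
               meta = list(condition_number = cond))
}

# largest kappa in [0,1] keeping bg + kappa*d (and, bipolar, bg - kappa*d)
# inside [0,1] per primary
max_feasible_scale <- function(bg, d, bipolar = FALSE) {
  lim <- function(dir) {
    k <- rep(Inf, length(d))
    up <- dir > 0
    k[up] <- (1 - bg[up]) / dir[up]
    dn <- dir < 0
    k[dn] <- bg[dn] / -dir[dn]
    min(k)
  }
  k <- lim(d)
  if (bipolar) k <- min(k, lim(-d))
  k
}

# ---- constrained-optimisation solver ------------------------------------------

#' Options for the optimisation solver
#'
#' @param constraint_tol Largest acceptable absolute contrast on any silenced
#'   receptor, recomputed through the forward model (contrast units).
#' @param obj_tol Objective tolerance for early stopping in global mode.
#' @param maxiter Iteration cap per local solve.
#' @param restarts Number of stepped local solves in global mode (and the
#'   retry cap before declaring infeasibility).
#' @param step Step size of the global perturbation, in weight units.
#' @param ridge Tiny penalty on the squared modulation excursion
#'   `||mod - bg||^2` added to the objective. Silent substitution problems
#'   with more primaries than constrained receptors have a null space (a
#'   family of metameric solutions); the ridge selects the minimum-excursion
#'   member, matching the minimum-norm semantics of the pseudo-inverse in
#'   [linalg_solve()] while perturbing the achieved contrasts by a negligible
#'   amount.
#' @param target_tol Largest acceptable miss of a numeric target contrast;
#'   beyond it the request is declared infeasible rather than silently
#'   clipped.
#' @param seed Integer seed for the starting points (recorded in the
#'   solution's metadata; fixed seed gives bit-reproducible solutions).
#' @return A list of options.
#' @export
optim_options <- function(constraint_tol = 1e-4, obj_tol = 1e-8,
                          maxiter = 100, restarts = 30, step = 0.3,
                          ridge = 1e-6, target_tol = 1e-3, seed = 1L) {
  list(constraint_tol = constraint_tol, obj_tol = obj_tol, maxiter = maxiter,
       restarts = restarts, step = step, ridge = ridge,
       target_tol = target_tol, seed = as.integer(seed))
}

#' Solve a silent substitution problem by constrained optimisation
#'
#' Minimises the deviation of the targeted receptors' contrast from the
#' request (or maximises the absolute targeted contrast for
#' `contrast = "max"`) subject to equality constraints holding every silenced
#' receptor's contrast at zero, with the primary weights bounded to the
#' problem's gamut bounds. The optimisation variables are the modulation
#' weights, plus the background weights when no background is specified. Local
#' solves use SLSQP (sequential least-squares quadratic programming); in
#' global mode a seeded basin-hopping-style loop reruns SLSQP from perturbed
#' and fresh random starts, keeping the best feasible solution. Because the
#' contrasts are evaluated through the calibration interpolant itself, this
#' solver remains valid where the device is nonlinear (gamma, spectral shift
#' with drive) and the linear-algebra solution breaks down.
#'
#' The returned solution's contrasts are recomputed through the forward model;
#' if after all restarts no point keeps every silenced contrast within
#' `options$constraint_tol`, an infeasibility error reports the best residual
#' found.
#'
#' @param device A `silsub_device`.
#' @param observer An [action_spectra()] set on the device grid.
#' @param spec A [problem_spec()]; `background` optional, `contrast` numeric or
#'   `"max"`.
#' @param global Run the global stepping loop instead of a single local solve.
#' @param options See [optim_options()].
#' @return A `silsub_solution` with solver metadata (iterations, residuals,
#'   seed).
#' @export
optim_solve <- function(device, observer, spec, global = FALSE,
                        options = optim_options()) {
  stopifnot(inherits(spec, "silsub_problem"))
  options <- utils::modifyList(optim_options(), options)
  labels <- receptor_labels(observer)
  check_partition(spec, labels)
  check_same_grid(device$grid, observer$wavelength, "device and observer")
  smat <- sensitivity_matrix(observer)
  np <- n_primaries(device)
  free_bg <- is.null(spec$background)
  if (!free_bg) {
    bg_fixed <- require_in_gamut(device, spec$background, "background weights")
  }

  bounds <- spec_bounds(spec, np)
  if (free_bg) {
    lower <- c(bounds[, 1], bounds[, 1])
    upper <- c(bounds[, 2], bounds[, 2])
  } else {
    lower <- bounds[, 1]
    upper <- bounds[, 2]
    if (spec$mode == "michelson") {
      # keep the reflected arm in gamut by tightening the modulation bounds
      lower <- pmax(lower, 2 * bg_fixed - 1)
      upper <- pmin(upper, 2 * bg_fixed)
    }
  }

  split_x <- function(x) {
    if (free_bg) list(bg = x[seq_len(np)], mod = x[np + seq_len(np)])
    else list(bg = bg_fixed, mod = x)
  }
  clip01 <- function(w) pmin(pmax(w, 0), 1)

  contrasts_of <- function(x) {
    parts <- split_x(x)
    contrast_values(device, smat, labels, clip01(parts$bg), clip01(parts$mod),
                    spec$mode, clip_reflection = TRUE, floor_bg = TRUE)
  }

  is_max <- is.character(spec$contrast)
  objective <- function(x) {
    cv <- contrasts_of(x)
    if (any(!is.finite(cv))) {
      stop_validation(sprintf(
        "Objective is not finite at weights [%s]; the forward model degenerated (zero background irradiance?).",
        paste(sprintf("%.4f", x), collapse = ", ")
      ))
    }
    ct <- cv[spec$target]
    parts <- split_x(x)
    penalty <- options$ridge * sum((parts$mod - parts$bg)^2)
    (if (is_max) -abs(mean(ct)) else sum((ct - spec$contrast)^2)) + penalty
  }
  heq <- function(x) unname(contrasts_of(x)[spec$silence])
  hin <- if (free_bg && spec$mode == "michelson") {
    function(x) {
      parts <- split_x(x)
      neg <- 2 * parts$bg - parts$mod
      c(neg, 1 - neg)
    }
  } else {
    NULL
  }

  n_var <- length(lower)
  maxeval <- options$maxiter * (n_var + 2)

  local_solve <- function(x0) {
    res <- tryCatch(
      nloptr::slsqp(x0, fn = objective, lower = lower, upper = upper,
                    hin = hin, heq = heq,
                    control = list(maxeval = maxeval, xtol_rel = 1e-12,
                                   ftol_rel = 0, ftol_abs = 0)),
      error = function(e) {
        if (inherits(e, "silsub_error")) rlang::cnd_signal(e)
        NULL
      }
    )
    if (is.null(res)) return(NULL)
    x <- pmin(pmax(res$par, lower), upper)
    cv <- contrasts_of(x)
    target_err <- if (is_max) NA_real_ else sum((cv[spec$target] - spec$contrast)^2)
    list(x = x, value = objective(x), target_err = target_err,
         residual = max(abs(cv[spec$silence])),
         iterations = res$iter %||% NA_integer_)
  }

  n_starts <- if (global) options$restarts else 1L
  best <- NULL
  best_any <- NULL
  total_iter <- 0L
  withr::with_seed(options$seed, {
    for (k in seq_len(n_starts)) {
      x0 <- if (k == 1 && global && !free_bg) {
        # anchor the first global start near the background: the desired
        # modulation is a (often small) excursion about it
        pmin(pmax(bg_fixed + stats::rnorm(n_var, 0, 0.02), lower), upper)
      } else if (k == 1 || is.null(best)) {
        stats::runif(n_var, lower, upper)
      } else {
        # basin-hopping-style step from the incumbent
        pmin(pmax(best$x + stats::rnorm(n_var, 0, options$step), lower), upper)
      }
      cand <- local_solve(x0)
      if (is.null(cand)) next
      total_iter <- total_iter + (if (is.na(cand$iterations)) 0L else cand$iterations)
      if (is.null(best_any) || cand$residual < best_any$residual) best_any <- cand
      feasible <- cand$residual <= options$constraint_tol
      if (feasible && (is.null(best) || cand$value < best$value)) best <- cand
      if (!is.null(best) && !is_max && best$target_err <= options$obj_tol) break
    }
  })

  if (is.null(best)) {
    stop_infeasible(sprintf(
      "No feasible solution after %d start(s): best silenced-contrast residual %.3g exceeds the constraint tolerance %.3g. Consider fewer silenced receptors, ignoring saturated receptors, a different background, or a smaller contrast.",
      n_starts, if (is.null(best_any)) NA_real_ else best_any$residual,
      options$constraint_tol
    ))
  }

  if (!is_max && sqrt(best$target_err) > options$target_tol) {
    stop_infeasible(sprintf(
      "Requested target contrast %.4g is not attainable: best feasible point misses it by %.4g (> target_tol %.3g). The request likely exceeds the device's gamut for this partition; try contrast = 'max' to find the attainable maximum.",
      spec$contrast, sqrt(best$target_err), options$target_tol
    ))
  }

  parts <- split_x(best$x)
  new_solution(device, observer, spec, clip01(parts$bg), clip01(parts$mod),
               if (global) "optim-global" else "optim",
               meta = list(seed = options$seed, iterations = total_iter,
                           objective = best$value,
                           solver = "SLSQP",
                           starts = n_starts))
}

# ---- waveforms ---------------------------------------------------------------

#' Sinusoidal modulation waveform
#'
#' Time series of device settings for a sinusoidal photoreceptor-directed
#' modulation about the solution's background:
#' `w(t) = bg + sin(2 pi f t) (mod - bg)`, each sample converted to native
#' settings by gamma correction. Requires a bipolar (`"michelson"`) solution;
#' the first and last samples equal the background exactly.
#'
#' @param solution A `silsub_solution` in michelson mode.
#' @param device The device the solution was solved on.
#' @param frequency Modulation frequency, Hz.
#' @param sample_rate Sampling rate, Hz.
#' @param n_cycles Number of cycles.
#' @return Tibble with columns `time` (s) and one settings column per primary
#'   label; the continuous weights are attached as attribute `"weights"`.
#' @export
make_sinusoidal_waveform <- function(solution, device, frequency, sample_rate,
                                     n_cycles = 1) {
  if (!identical(solution$mode, "michelson")) {
    stop_validation("Sinusoidal waveforms require a bipolar (michelson-mode) solution.")
  }
  bg <- solution$background$weights
  amp <- solution$modulation$weights - bg
  require_in_gamut(device, bg + amp, "positive arm")
  require_in_gamut(device, bg - amp, "negative arm")
  times <- seq(0, n_cycles / frequency, by = 1 / sample_rate)
  w <- t(vapply(times, function(t) bg + sinpi(2 * frequency * t) * amp,
                numeric(length(bg))))
  settings <- t(apply(w, 1, function(wi) {
    g <- in_gamut(device, wi)
    if (!g$in_gamut) {
      stop_gamut("Waveform sample out of gamut (should be impossible for in-gamut arms and a convex gamut).")
    }
    gamma_correct(device, pmin(pmax(wi, 0), 1))
  }))
  colnames(settings) <- device$labels
  out <- dplyr::bind_cols(tibble::tibble(time = times),
                          tibble::as_tibble(settings))
  attr(out, "weights") <- w
  out
}

# ---- validation --------------------------------------------------------------

#' Validate a solution after quantisation
#'
#' Recomputes everything from the solution's *native settings* (i.e., after
#' quantisation to integer counts) and reports, per receptor, the achieved
#' contrast, the quantisation-induced error relative to the nominal
#' (weight-space) contrast, and the gamut margins. Report-only: a hand-made
#' out-of-gamut solution is flagged, not rejected.
#'
#' @param solution A `silsub_solution`.
#' @param device The device the solution was solved on.
#' @param observer The observer the solution was solved for.
#' @return List of class `silsub_validation_report` with elements `contrasts`
#'   (tibble: receptor, role, nominal, achieved, quantization_error),
#'   `gamut_margin` (smallest distance of any arm weight to the gamut edge,
#'   negative if out of gamut), and `in_gamut`.
#' @export
validate_solution <- function(solution, device, observer) {
  labels <- receptor_labels(observer)
  smat <- sensitivity_matrix(observer)
  bg_q <- solution$background$settings / device$resolutions
  mod_q <- solution$modulation$settings / device$resolutions
  arms <- list(bg_q, mod_q)
  if (solution$mode == "michelson") arms <- c(arms, list(2 * bg_q - mod_q))
  margins <- vapply(arms, function(w) min(w, 1 - w), numeric(1))
  gamut_margin <- min(margins)
  ok <- gamut_margin >= -1e-9
  achieved <- contrast_values(device, smat, labels,
                              pmin(pmax(bg_q, 0), 1), pmin(pmax(mod_q, 0), 1),
                              solution$mode, clip_reflection = TRUE)
  nominal <- solution$contrasts$contrast
  achieved_v <- unname(achieved[labels])
  structure(
    list(
      contrasts = tibble::tibble(
        receptor = labels,
        role = solution$contrasts$role,
        nominal = nominal,
        achieved = achieved_v,
        quantization_error = abs(achieved_v - nominal)
      ),
      gamut_margin = gamut_margin,
      in_gamut = ok
    ),
    class = "silsub_validation_report"
  )
}

#' @export
print.silsub_validation_report <- function(x, ...) {
  cat(sprintf("<solution validation: %s, gamut margin %.4g>\n",
              if (x$in_gamut) "in gamut" else "OUT OF GAMUT", x$gamut_margin))
  print(x$contrasts)
  invisible(x)
}
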