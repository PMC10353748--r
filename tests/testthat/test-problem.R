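test_that("contrast metrics follow their definitions", {
  expect_equal(michelson_contrast(1, 1), 0)
  expect_equal(michelson_contrast(1.2, 0.8), 0.2)
  expect_equal(michelson_contrast(3.7, 0), 1)
  expect_error(michelson_contrast(0, 0), class = "silsub_validation_error")
  expect_equal(weber_contrast(1.2, 1), 0.2)
  expect_equal(weber_contrast(1, 1), 0)
  expect_equal(weber_contrast(0.5, 1), -0.5)
  expect_error(weber_contrast(1, 0), class = "silsub_validation_error")
})

test_that("problem specifications are validated", {
  expect_error(problem_spec(character(), "rh"), class = "silsub_validation_error")
  expect_error(problem_spec("mel", character()), class = "silsub_validation_error")
  expect_error(problem_spec("mel", c("mel", "rh")),
               class = "silsub_validation_error")
  expect_error(problem_spec("mel", "rh", contrast = "huge"),
               class = "silsub_validation_error")
  expect_error(problem_spec("mel", "rh", bounds = c(0.5, 0.2)),
               class = "silsub_validation_error")
  # unassigned receptors are rejected at solve time
  dev <- linear_device()
  obs <- separable_observer()
  sp <- problem_spec("mel", c("sc", "mc"), background = rep(0.5, 5))
  expect_error(linalg_solve(dev, obs, sp), regexp = "not assigned",
               class = "silsub_validation_error")
})

test_that("receptor contrasts are forward-modelled, linear, and complete", {
  dev <- linear_device()
  obs <- separable_observer()
  bg <- rep(0.5, 5)
  same <- receptor_contrasts(dev, obs, bg, bg, "weber")
  expect_equal(same$contrast, rep(0, 5))

  withr::with_seed(17, {
    d <- runif(5, -0.1, 0.1)
    full <- receptor_contrasts(dev, obs, bg, bg + d, "weber")$contrast
    half <- receptor_contrasts(dev, obs, bg, bg + d / 2, "weber")$contrast
    expect_equal(half, full / 2, tolerance = 1e-9)
  })

  # every receptor is reported, including ones a problem would ignore
  expect_setequal(same$receptor, receptor_labels(obs))

  # bipolar reflection outside the gamut is a gamut error naming the reflection
  expect_error(
    receptor_contrasts(dev, obs, rep(0.1, 5), rep(0.6, 5), "michelson"),
    regexp = "reflection", class = "silsub_gamut_error"
  )
})

test_that("linalg_solve with zero contrast returns the background", {
  dev <- linear_device()
  obs <- separable_observer()
  sp <- problem_spec("mel", c("sc", "mc", "lc", "rh"), contrast = 0,
                     background = rep(0.5, 5))
  sol <- linalg_solve(dev, obs, sp)
  expect_equal(sol$modulation$weights, sol$background$weights, tolerance = 1e-12)
  expect_equal(sol$contrasts$contrast, rep(0, 5), tolerance = 1e-12)
})

test_that("linalg_solve silences and targets exactly on a linear device", {
  dev <- linear_device()
  obs <- separable_observer()
  sp <- problem_spec("mel", c("sc", "mc", "lc", "rh"), contrast = 0.2,
                     mode = "weber", background = rep(0.5, 5))
  sol <- linalg_solve(dev, obs, sp)
  sil <- sol$contrasts$contrast[sol$contrasts$role == "silence"]
  tgt <- sol$contrasts$contrast[sol$contrasts$role == "target"]
  expect_lte(max(abs(sil)), 1e-8)
  expect_equal(tgt, 0.2, tolerance = 1e-6)

  # michelson request: the two arms realise the requested contrast exactly
  spm <- problem_spec("mel", c("sc", "mc", "lc", "rh"), contrast = 0.2,
                      mode = "michelson", background = rep(0.5, 5))
  solm <- linalg_solve(dev, obs, spm)
  tgtm <- solm$contrasts$contrast[solm$contrasts$role == "target"]
  expect_equal(tgtm, 0.2, tolerance = 1e-6)
  expect_lte(max(abs(solm$contrasts$contrast[solm$contrasts$role == "silence"])),
             1e-8)
})

test_that("ignored receptors are unconstrained but still reported", {
  dev <- linear_device(n_primaries = 3, seed = 13)
  obs <- separable_observer()
  sp <- problem_spec("sc", c("mc", "lc"), ignore = c("rh", "mel"),
                     contrast = 0.1, background = rep(0.5, 3))
  sol <- linalg_solve(dev, obs, sp)
  cs <- sol$contrasts
  expect_lte(max(abs(cs$contrast[cs$role == "silence"])), 1e-8)
  expect_equal(cs$contrast[cs$role == "target"], 0.1, tolerance = 1e-6)
  ign <- cs$contrast[cs$role == "ignore"]
  expect_length(ign, 2)
  expect_true(all(abs(ign) > 1e-6))  # contrast redirected onto ignored receptors
})

test_that("linalg_solve guards its preconditions and the gamut frontier", {
  dev <- linear_device()
  obs <- separable_observer()
  no_bg <- problem_spec("mel", c("sc", "mc", "lc", "rh"), contrast = 0.1)
  expect_error(linalg_solve(dev, obs, no_bg), class = "silsub_validation_error")
  maxreq <- problem_spec("mel", c("sc", "mc", "lc", "rh"), contrast = "max",
                         background = rep(0.5, 5))
  expect_error(linalg_solve(dev, obs, maxreq), class = "silsub_validation_error")

  # contrast above the feasible maximum raises, never silently clips
  for (c_req in c(0.7, 1.5, 50)) {
    sp <- problem_spec("mel", c("sc", "mc", "lc", "rh"), contrast = c_req,
                       background = rep(0.5, 5))
    expect_error(linalg_solve(dev, obs, sp), regexp = "gamut",
                 class = "silsub_gamut_error")
  }

  # near-identical primaries give a degenerate system
  dup <- make_gaussian_device(fixture_recipe(
    peaks = c(530, 530.0001, 530.0002, 530.0003, 530.0004), seed = 5
  ))
  sp <- problem_spec("mel", c("sc", "mc", "lc", "rh"), contrast = 0.01,
                     background = rep(0.5, 5))
  expect_error(linalg_solve(dup, obs, sp), class = "silsub_degenerate_error")
})

test_that("non-square systems use least-squares pseudo-inverse semantics", {
  dev <- linear_device(n_primaries = 3, seed = 19)
  obs4 <- make_template_observer(
    c(sc = 430, mel = 490, rh = 550, mc = 610), log_width = 0.05
  )
  sp <- problem_spec("mel", c("sc", "rh", "mc"), contrast = 0.05,
                     background = rep(0.5, 3))
  sol <- linalg_solve(dev, obs4, sp)
  alpha <- sol$modulation$weights - sol$background$weights

  # brute-force normal equations on the same small system
  smat <- silsub:::sensitivity_matrix(obs4)
  A <- silsub:::primary_slopes(dev, rep(0.5, 3)) %*% smat   # 3 x 4
  e_bg <- silsub:::aopic_values(dev, rep(0.5, 3), smat)
  names(e_bg) <- receptor_labels(obs4)
  beta <- stats::setNames(numeric(4), receptor_labels(obs4))
  beta["mel"] <- 0.05 * e_bg[["mel"]]
  M <- t(A)                                  # 4 x 3: overdetermined in alpha
  oracle <- solve(t(M) %*% M, t(M) %*% beta) # normal equations
  expect_equal(alpha, as.numeric(oracle), tolerance = 1e-10)
})

test_that("optim_solve agrees with linalg_solve on linear problems", {
  for (i in 1:6) {
    prob <- sample_problem_fixture(100 + i)
    sl <- linalg_solve(prob$device, prob$observer, prob$spec)
    so <- optim_solve(prob$device, prob$observer, prob$spec, global = TRUE,
                      options = optim_options(seed = i))
    expect_lte(max(abs(so$contrasts$contrast - sl$contrasts$contrast)), 1e-4)
    expect_lte(so$meta$constraint_residual, 1e-4)
  }
})

test_that("optim_solve is bit-reproducible under a fixed seed", {
  prob <- sample_problem_fixture(55)
  s1 <- optim_solve(prob$device, prob$observer, prob$spec,
                    options = optim_options(seed = 9))
  s2 <- optim_solve(prob$device, prob$observer, prob$spec,
                    options = optim_options(seed = 9))
  expect_identical(s1$modulation$weights, s2$modulation$weights)
  expect_identical(s1$background$weights, s2$background$weights)
  expect_equal(s1$meta$seed, 9)
})

test_that("optim_solve handles nonlinear devices where linalg fails", {
  rec <- fixture_recipe(n_primaries = 5, shift = 20,
                        levels = round(seq(0, 255, length.out = 12)), seed = 7)
  dev <- make_gaussian_device(rec)
  obs <- separable_observer()
  sp <- problem_spec("mel", c("sc", "mc", "lc", "rh"), contrast = 0.15,
                     background = rep(0.5, 5))
  sl <- linalg_solve(dev, obs, sp)
  # the linear solution, pushed through the true forward model, leaks contrast
  expect_gt(sl$meta$constraint_residual, 1e-4)
  so <- optim_solve(dev, obs, sp, global = TRUE,
                    options = optim_options(seed = 3))
  expect_lte(so$meta$constraint_residual, 1e-4)
  expect_equal(so$contrasts$contrast[so$contrasts$role == "target"], 0.15,
               tolerance = 1e-3)
})

test_that("optim_solve maximises target contrast beyond random feasible probes", {
  dev <- linear_device()
  obs <- separable_observer()
  bg <- rep(0.5, 5)
  sp <- problem_spec("mel", c("sc", "mc", "lc"), ignore = "rh",
                     contrast = "max", background = bg)
  sol <- optim_solve(dev, obs, sp, global = TRUE,
                     options = optim_options(seed = 2, restarts = 5))
  best <- abs(sol$contrasts$contrast[sol$contrasts$receptor == "mel"])

  # independent probes: random in-gamut points on the silencing null space
  # (on a linear device the silencing constraints are linear in the weights)
  smat <- silsub:::sensitivity_matrix(obs)
  A <- silsub:::primary_slopes(dev, bg) %*% smat   # 5 x 5
  A_sil <- A[, match(c("sc", "mc", "lc"), receptor_labels(obs))]
  ns <- MASS::Null(A_sil)                          # basis of silenced directions
  withr::with_seed(10, {
    probe_best <- 0
    for (k in 1:1000) {
      d <- as.numeric(ns %*% rnorm(ncol(ns)))
      kmax <- silsub:::max_feasible_scale(bg, d)
      mod <- bg + runif(1) * kmax * d
      cv <- receptor_contrasts(dev, obs, bg, mod, "weber")
      expect_lte(max(abs(cv$contrast[cv$receptor %in% c("sc", "mc", "lc")])), 1e-6)
      probe_best <- max(probe_best, abs(cv$contrast[cv$receptor == "mel"]))
    }
  })
  expect_gte(best, probe_best)
})

test_that("optim_solve raises on unattainable targets and infeasible problems", {
  dev <- linear_device()
  obs <- separable_observer()
  sp <- problem_spec("mel", c("sc", "mc", "lc", "rh"), contrast = 5,
                     background = rep(0.5, 5))
  expect_error(
    optim_solve(dev, obs, sp, options = optim_options(seed = 1)),
    class = "silsub_infeasibility_error"
  )
})

test_that("sinusoidal waveforms sample the modulation at quarter phases", {
  dev <- linear_device()
  obs <- separable_observer()
  sp <- problem_spec("mel", c("sc", "mc", "lc", "rh"), contrast = 0.2,
                     mode = "michelson", background = rep(0.5, 5))
  sol <- linalg_solve(dev, obs, sp)
  wf <- make_sinusoidal_waveform(sol, dev, frequency = 1, sample_rate = 4,
                                 n_cycles = 1)
  expect_equal(nrow(wf), 5)
  stg <- as.matrix(wf[, -1])
  bg_s <- sol$background$settings
  mod_s <- sol$modulation$settings
  expect_equal(unname(stg[1, ]), bg_s)
  expect_equal(unname(stg[3, ]), bg_s)
  expect_equal(unname(stg[5, ]), bg_s)
  expect_equal(unname(stg[2, ]), mod_s)
  refl <- gamma_correct(dev, 2 * sol$background$weights - sol$modulation$weights)
  expect_equal(unname(stg[4, ]), refl)

  # the peak sample realises the solution's quantised contrast exactly
  peak_w <- stg[2, ] / dev$resolutions
  achieved <- receptor_contrasts(dev, obs, bg_s / dev$resolutions, peak_w,
                                 "michelson")
  vr <- validate_solution(sol, dev, obs)
  expect_equal(achieved$contrast, vr$contrasts$achieved, tolerance = 1e-12)

  # zero amplitude gives a constant series
  sp0 <- problem_spec("mel", c("sc", "mc", "lc", "rh"), contrast = 0,
                      mode = "michelson", background = rep(0.5, 5))
  wf0 <- make_sinusoidal_waveform(linalg_solve(dev, obs, sp0), dev, 1, 8, 2)
  expect_true(all(apply(as.matrix(wf0[, -1]), 2, function(col) {
    all(col == col[1])
  })))

  # unipolar solutions cannot be turned into bipolar sinusoids
  spw <- problem_spec("mel", c("sc", "mc", "lc", "rh"), contrast = 0.2,
                      mode = "weber", background = rep(0.5, 5))
  expect_error(make_sinusoidal_waveform(linalg_solve(dev, obs, spw), dev, 1, 4),
               class = "silsub_validation_error")
})

test_that("validate_solution reports quantisation error and gamut margins", {
  dev <- linear_device()
  obs <- separable_observer()
  sp <- problem_spec("mel", c("sc", "mc", "lc", "rh"), contrast = 0.2,
                     background = rep(0.5, 5))
  sol <- linalg_solve(dev, obs, sp)
  vr <- validate_solution(sol, dev, obs)
  expect_true(vr$in_gamut)
  expect_true(all(is.finite(vr$contrasts$quantization_error)))

  # identical background and modulation: zero achieved contrast
  sp0 <- problem_spec("mel", c("sc", "mc", "lc", "rh"), contrast = 0,
                      background = rep(0.5, 5))
  vr0 <- validate_solution(linalg_solve(dev, obs, sp0), dev, obs)
  expect_equal(vr0$contrasts$achieved, rep(0, 5), tolerance = 1e-12)

  # a hand-made out-of-gamut solution is flagged, not rejected
  bad <- sol
  bad$modulation$settings <- bad$modulation$settings + 200
  expect_no_error(vrb <- validate_solution(bad, dev, obs))
  expect_false(vrb$in_gamut)
  expect_lt(vrb$gamut_margin, 0)
})

test_that("solutions tidy and glance like fitted objects", {
  dev <- linear_device()
  obs <- separable_observer()
  sp <- problem_spec("mel", c("sc", "mc", "lc", "rh"), contrast = 0.1,
                     background = rep(0.5, 5))
  sol <- linalg_solve(dev, obs, sp)
  td <- generics::tidy(sol)
  expect_setequal(names(td),
                  c("receptor", "role", "contrast", "background", "modulation"))
  gl <- generics::glance(sol)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$requested_contrast, 0.1)
  expect_lte(gl$max_silenced_contrast, 1e-8)
})
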