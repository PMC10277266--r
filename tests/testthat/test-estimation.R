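test_that("rmse_objective: zero at truth, hand value, homogeneity", {
  np <- noiseless_patient()
  truth_theta <- c(Ks = 5, Kb = 8, Vb0 = 15, z0 = 1.8, x0 = 1.8)
  expect_lt(rmse_objective(truth_theta, np$data, "CP"), 1e-12)
  expect_lt(rmse_objective(truth_theta[c("Ks", "Kb", "Vb0", "x0")],
                           np$data, "MP"), 1e-12)

  # two residuals (0.1, -0.1) -> RMSE 0.1, by constructing data offset from
  # the model curve by exactly those residuals
  theta <- c(Ks = 5, Kb = 8, z0 = 1.8)
  p <- sp_params(Ks = 5, Kb = 8, Q = 0, Cs = 1.8, Cd0 = 0.15, Vb0 = 15, x0 = 1.8)
  z <- sp_concentration(p, c(0, 1))
  for (cc in c(1, 3)) {
    ms <- measurement_set("toy",
                          sp = data.frame(time = c(0, 1),
                                          conc = z - cc * c(0.1, -0.1)),
                          Cd0 = 0.15, Vb0_clinical = 15)
    expect_equal(rmse_objective(theta, ms, "SP"), cc * 0.1)
  }
  expect_error(rmse_objective(c(Ks = 5), np$data, "SP"), "lacks")
})

test_that("linear pre-estimate recovers rates from noiseless data and flags
           a zero-information design", {
  # moderate-rate patient ((Ks+Kb)/Vb0 ~ 0.5/h): hourly trapezoidal bias < 5%.
  # The bias grows as ((Ks+Kb)/Vb0 * dt)^2 and can exceed 5% for the fastest
  # patients, hence the second-order convergence check below.
  np <- noiseless_patient(Ks = 3.58, Kb = 7.88, Cs = 1.9, Vb0 = 22.7)
  pre_sp <- linear_preestimate(np$data, "SP")
  pre_mp <- linear_preestimate(np$data, "MP")
  pre_cp <- linear_preestimate(np$data, "CP")
  for (pre in list(pre_sp, pre_mp, pre_cp)) {
    expect_lt(abs(pre[["Ks"]] - 3.58) / 3.58, 0.05)   # trapezoidal bias only
    expect_lt(abs(pre[["Kb"]] - 7.88) / 7.88, 0.05)
  }

  # second-order scheme: halving the sampling interval cuts the bias ~4x
  truth <- mp_params(Ks = 5, Kb = 8, Q = 0, Cs = 1.8, Vb0 = 15, Vd0 = 25)
  err_kb <- vapply(c(1, 0.5), function(dt) {
    ms <- simulate_patient(truth, Cd0 = 0.15, mp_times = seq(0, 8, by = dt),
                           noise_sd = 0, seed = 1)
    abs(linear_preestimate(ms, "MP")[["Kb"]] - 8) / 8
  }, numeric(1))
  expect_gt(err_kb[1] / err_kb[2], 3)
  expect_lt(err_kb[1] / err_kb[2], 5.5)

  # constant series at the steady state: design matrix rank deficient
  flat <- measurement_set("flat",
                          sp = data.frame(time = 0:4, conc = rep(1.8, 5)),
                          Cd0 = 1.8, Vb0_clinical = 15)
  expect_error(linear_preestimate(flat, "SP"), "rank")
})

test_that("linear pre-estimate equals a hand-solved normal-equations solution", {
  # two-interval SP toy: assemble the trapezoidal design by hand
  z <- c(2.0, 1.6, 1.4); times <- 0:2
  Cs <- 2.0; Cd0 <- 0.1; Vb0 <- 12
  ms <- measurement_set("toy", sp = data.frame(time = times, conc = z),
                        Cd0 = Cd0, Vb0_clinical = Vb0)
  zbar <- c((z[1] + z[2]) / 2, (z[2] + z[3]) / 2)
  A <- cbind(Cs - zbar, Cd0 - zbar)
  rhs <- Vb0 * diff(z) / diff(times)
  oracle <- solve(t(A) %*% A, t(A) %*% rhs)
  pre <- linear_preestimate(ms, "SP")
  expect_equal(unname(pre), as.vector(oracle), tolerance = 1e-12)
})

test_that("noiseless MP and CP fits recover the generating parameters to 1%", {
  np <- noiseless_patient(Ks = 5, Kb = 8, Cs = 1.8, Vb0 = 15)
  fmp <- fit(np$data, fit_spec("MP"))
  fcp <- fit(np$data, fit_spec("CP"))
  truth <- c(Ks = 5, Kb = 8, Vb0 = 15)
  for (f in list(fmp, fcp)) {
    expect_true(f$converged)
    for (nm in names(truth))
      expect_lt(abs(f$estimates[[nm]] - truth[[nm]]) / truth[[nm]], 0.01)
    expect_lt(f$rmse, 1e-6)
  }
  # pooled CP residuals cannot beat both single-modality fits
  fsp <- fit(np$data, fit_spec("SP"))
  expect_lte(fcp$rmse, max(fsp$rmse, fmp$rmse) + 1e-9)
  # objective identity: reported rmse is the objective at the optimum
  expect_equal(fcp$rmse, rmse_objective(fcp$estimates[fcp$free], np$data, "CP"))
})

test_that("estimates respect the physiological bounds on noisy data", {
  set.seed(61)
  for (i in 1:3) {
    truth <- draw_mp()
    ms <- simulate_patient(truth, Cd0 = 0.15, noise_sd = 0.15, seed = 100 + i)
    f <- fit(ms, fit_spec("CP"))
    b <- default_bounds()
    expect_true(all(f$estimates[f$free] >= b$lower[f$free] - 1e-9))
    expect_true(all(f$estimates[f$free] <= b$upper[f$free] + 1e-9))
  }
})

test_that("starting from the pre-estimate is no slower than bound midpoints", {
  np <- noiseless_patient()
  f_pre <- fit(np$data, fit_spec("MP"))
  b <- default_bounds()
  mid <- (b$lower + b$upper)[free_params_mid <- c("Ks", "Kb", "Vb0", "x0")] / 2
  f_mid <- fit(np$data, fit_spec("MP"), start = mid)
  # smoke property: the informed start should not cost more gradient-stage
  # evaluations than the uninformed one (polish stages excluded)
  expect_lte(f_pre$stage1_evals, f_mid$stage1_evals)
})

test_that("confidence half-widths: ~0 for noiseless data, match the
           Jacobian-linearization oracle on low-noise data", {
  np <- noiseless_patient()
  f0 <- fit(np$data, fit_spec("MP"))
  expect_true(all(f0$ci_halfwidth < 1e-4))

  truth <- mp_params(Ks = 5, Kb = 8, Q = 0, Cs = 1.8, Vb0 = 15, Vd0 = 25)
  ms <- simulate_patient(truth, Cd0 = 0.15, noise_sd = 0.02, seed = 7)
  f <- fit(ms, fit_spec("MP"))
  # oracle: 1.96 * sqrt(s2 * diag((J'J)^-1)) with a finite-difference Jacobian
  # of the model curve (independent of the package's RSS-Hessian route)
  theta <- f$estimates[f$free]
  model_vec <- function(th) {
    p <- mp_params(Ks = th[["Ks"]], Kb = th[["Kb"]], Q = 0, Cs = th[["x0"]],
                   Vb0 = th[["Vb0"]], Vd0 = 25, x0 = th[["x0"]], y0 = 0)
    v <- closed_form_Q0(p, ms$mp$time)
    c(v$x, v$y)
  }
  J <- sapply(seq_along(theta), function(i) {
    h <- 1e-6 * (abs(theta[i]) + 1e-3)
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (model_vec(tp) - model_vec(tm)) / (2 * h)
  })
  r <- model_vec(theta) - c(ms$mp$x, ms$mp$y)
  s2 <- sum(r^2) / (length(r) - length(theta))
  hw_oracle <- 1.96 * sqrt(s2 * diag(solve(t(J) %*% J)))
  expect_equal(unname(f$ci_halfwidth), unname(hw_oracle), tolerance = 0.1)
})

test_that("Vb0 is not identifiable from SP data alone: freeing it inflates
           the uncertainties", {
  np <- noiseless_patient(Ks = 5, Kb = 8, Cs = 1.8, Vb0 = 15)
  ms <- simulate_patient(np$truth, Cd0 = 0.15, noise_sd = 0.03, seed = 5)
  spec <- fit_spec("SP")
  f_fixed <- fit(ms, spec)

  # same data, Vb0 freed: optimize the 4-parameter SP problem directly
  fp <- c("Ks", "Kb", "Vb0", "z0")
  b <- default_bounds()
  obj <- function(v) {
    th <- stats::setNames(v, fp)
    tryCatch(rmse_objective(th, ms, "SP")^2 * nrow(ms$sp),
             error = function(e) 1e10)
  }
  opt <- nlminb(c(f_fixed$estimates[c("Ks", "Kb")], Vb0 = 15,
                  z0 = f_fixed$estimates[["z0"]]),
                obj, lower = b$lower[fp], upper = b$upper[fp])
  free_res <- structure(list(mode = "SP", patient_id = "x",
                             estimates = c(stats::setNames(opt$par, fp),
                                           Cs = opt$par[[4]]),
                             free = fp, rmse = sqrt(opt$objective / nrow(ms$sp)),
                             d = 1L, n_total = nrow(ms$sp), converged = TRUE),
                        class = "fit_result")
  hw_free <- suppressWarnings(confidence_intervals(free_res, ms, spec))
  # the freed problem has a flat direction: Vb0's half-width blows up
  expect_true(!is.finite(hw_free[["Vb0"]]) ||
                hw_free[["Vb0"]] > 100 * f_fixed$ci_halfwidth[["Ks"]])
  expect_true(!is.finite(hw_free[["Ks"]]) ||
                hw_free[["Ks"]] > 5 * f_fixed$ci_halfwidth[["Ks"]])
})

test_that("multistart: deterministic, collapses to one optimum, n_starts = 1
           equals the plain fit", {
  np <- noiseless_patient()
  spec <- fit_spec("MP")
  r1 <- multistart_robustness(np$data, spec, n_starts = 1, seed = 3)
  expect_identical(r1$best$estimates, fit(np$data, spec)$estimates)

  r <- multistart_robustness(np$data, spec, n_starts = 6, seed = 3)
  r_again <- multistart_robustness(np$data, spec, n_starts = 6, seed = 3)
  expect_identical(r$optima, r_again$optima)
  expect_identical(r$n_clusters, 1L)
  expect_lt(r$relative_spread, 1e-4)
})

test_that("mode/data consistency is enforced", {
  np <- noiseless_patient()
  mp_only <- measurement_set("m", mp = np$data$mp, Vd0 = 25, Vb0_clinical = 15)
  expect_error(fit(mp_only, fit_spec("SP")), "requires SP data")
  expect_error(fit(mp_only, fit_spec("CP")), "requires SP data")
  sp_only <- measurement_set("s", sp = np$data$sp, Cd0 = 0.15)
  expect_error(fit(sp_only, fit_spec("SP")), "Vb0")
  expect_error(fit_spec("MP", bounds = list(lower = c(Ks = 1), upper = c(Ks = 0))),
               "bounds")
})
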