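test_that("series coefficients satisfy the recursion's anchor values", {
  p <- fig_mp()
  s <- series_coefficients(p, 5)
  expect_identical(s$alpha[1], 2.9)
  expect_identical(s$beta[1], 0)
  # first-order blood coefficient by hand: (KsCs - (Ks+Kb)x0)/Vb0
  expect_equal(s$alpha[2], (2.6 * 2.9 - 9.5 * 2.9) / 10)
  expect_equal(s$alpha[2], -2.001, tolerance = 1e-12)
  # equal starting concentrations: no initial dialysate flux
  s2 <- series_coefficients(fig_mp(y0 = 2.9), 3)
  expect_identical(s2$beta[2], 0)
  expect_error(series_coefficients(p, -1), "N")
})

test_that("series evaluation: initial condition, oracle match, domain", {
  p <- fig_mp()
  s <- series_coefficients(p, 40)
  v0 <- series_eval(s, 0)
  expect_equal(c(v0$x, v0$y), c(2.9, 0))

  tr <- reference_integrate("MP", p, 1:8)
  v <- series_eval(s, 1:8)
  b <- truncation_bound(s, 1:8)
  expect_true(all(abs(v$x - tr$x) <= b$bound_x + 1e-7))
  expect_true(all(abs(v$y - tr$y) <= b$bound_y + 1e-7))

  # t_valid = min(Vb0, Vd0)/Q = 10/0.23 = 43.5 h
  expect_equal(s$t_valid, 10 / 0.23)
  expect_error(series_eval(s, 50), "t_valid")
})

test_that("Lagrange bound: zero at t=0, certifies 0.01 at N=27, dominates error", {
  p <- fig_mp()
  s27 <- series_coefficients(p, 27)
  b <- truncation_bound(s27, 8)
  expect_lte(b$bound_x, 0.01)
  expect_lte(b$bound_y, 0.01)
  b0 <- truncation_bound(s27, 0)
  expect_identical(c(b0$bound_x, b0$bound_y), c(0, 0))

  # observed truncation error vs a much higher-order self-oracle
  s200 <- series_coefficients(p, 200)
  ts <- seq(0.4, 8, length.out = 20)
  v27 <- series_eval(s27, ts); v200 <- series_eval(s200, ts)
  bb <- truncation_bound(s27, ts)
  expect_true(all(abs(v27$x - v200$x) <= bb$bound_x + 1e-12))
  expect_true(all(abs(v27$y - v200$y) <= bb$bound_y + 1e-12))
})

test_that("terms_for_tolerance finds the smallest certified order", {
  p <- fig_mp()
  N <- terms_for_tolerance(p, 8, 0.01)
  expect_lte(N, 27)
  b <- truncation_bound(series_coefficients(p, N), 8)
  expect_true(b$bound_x <= 0.01 && b$bound_y <= 0.01)
  if (N > 0) {
    bprev <- truncation_bound(series_coefficients(p, N - 1L), 8)
    expect_true(bprev$bound_x > 0.01 || bprev$bound_y > 0.01)
  }
  expect_identical(terms_for_tolerance(p, 8, 1e9), 0L)
  # non-increasing in the tolerance
  tols <- 10^seq(-6, 0, by = 1)
  Ns <- vapply(tols, function(tl) terms_for_tolerance(p, 8, tl), integer(1))
  expect_true(all(diff(Ns) <= 0))
  expect_error(terms_for_tolerance(p, 8, 1e-30, N_max = 10), "N_max|no N")
})

test_that("eigenvalues of the Q=0 system matrix", {
  p <- fig_mp(Q = 0)
  ev <- eigenvalues_A(p)
  # independent oracle: roots of the characteristic polynomial
  A <- matrix(c(-(2.6 + 6.9) / 10, 6.9 / 25, 6.9 / 10, -6.9 / 25), 2, 2)
  r <- sort(Re(polyroot(c(det(A), -sum(diag(A)), 1))))
  expect_equal(ev$lambda2, r[1], tolerance = 1e-12)
  expect_equal(ev$lambda1, r[2], tolerance = 1e-12)
  expect_true(ev$lambda1 < 0 && ev$lambda2 < 0)

  # Ks = 0: conservation mode, lambda1 = 0, lambda2 = trace
  p0 <- mp_params(Ks = 0, Kb = 6.9, Cs = 2.9, Vb0 = 10, Vd0 = 25)
  ev0 <- eigenvalues_A(p0)
  expect_equal(ev0$lambda1, 0, tolerance = 1e-14)
  expect_equal(ev0$lambda2, -6.9 * (1 / 10 + 1 / 25))
})

test_that("closed form: initial value, long-time limit, oracle, normalization", {
  p <- fig_mp(Q = 0)
  v0 <- closed_form_Q0(p, 0)
  expect_equal(c(v0$x, v0$y), c(2.9, 0))
  vinf <- closed_form_Q0(p, 500)
  expect_equal(c(vinf$x, vinf$y), c(2.9, 2.9), tolerance = 1e-9)

  tr <- reference_integrate("MP", p, 1:8)
  v <- closed_form_Q0(p, 1:8)
  expect_lt(max(abs(v$x - tr$x), abs(v$y - tr$y)), 1e-9)

  # explicit formula == matrix-exponential route with unit-norm eigenvectors
  ve <- closed_form_Q0(p, seq(0, 8, by = 0.5), method = "eigen")
  vx <- closed_form_Q0(p, seq(0, 8, by = 0.5))
  expect_lt(max(abs(ve$x - vx$x), abs(ve$y - vx$y)), 1e-10)

  expect_error(closed_form_Q0(fig_mp(Q = 0.23), 1), "Q = 0")
})

test_that("mass is conserved when there is no source and no ultrafiltration", {
  p <- mp_params(Ks = 0, Kb = 6.9, Cs = 2.9, Vb0 = 10, Vd0 = 25, x0 = 2.9, y0 = 0)
  m0 <- 10 * 2.9
  ts <- seq(0.5, 8, by = 0.5)
  for (v in list(closed_form_Q0(p, ts),
                 series_eval(series_coefficients(p, 60), ts),
                 reference_integrate("MP", p, ts))) {
    expect_lt(max(abs(10 * v$x + 25 * v$y - m0)) / m0, 1e-9)
  }
})

test_that("blood stays above dialysate when it starts above and Cs >= x0", {
  set.seed(31)
  ts <- seq(0, 8, by = 0.25)
  for (i in 1:25) {
    pr <- draw_mp()                       # x0 = Cs >= y0 = 0 by construction
    v <- closed_form_Q0(pr, ts)
    expect_true(all(v$x >= v$y - 1e-10))
  }
})

test_that("consistency triangle at certified order (Q = 0)", {
  set.seed(41)
  ts <- seq(1, 8, by = 1)
  for (i in 1:10) {
    pr <- draw_mp()
    N <- terms_for_tolerance(pr, 8, 1e-8)
    sv <- series_eval(series_coefficients(pr, N), ts)
    cv <- closed_form_Q0(pr, ts)
    nv <- reference_integrate("MP", pr, ts)
    expect_lt(max(abs(cv$x - nv$x), abs(cv$y - nv$y)), 1e-7)
    expect_lt(max(abs(sv$x - cv$x), abs(sv$y - cv$y)), 1e-8 + 1e-7)
  }
})

test_that("MP approaches the SP exponential as the dialysate volume grows", {
  pmp <- fig_mp(Q = 0, Vd0 = 1e6)
  psp <- fig_sp(Q = 0, Cd0 = 0)
  v <- closed_form_Q0(pmp, 0:8)
  expect_lt(max(abs(v$x - sp_concentration(psp, 0:8))), 1e-3)
})

test_that("both concentrations approach Cs for long Q = 0 sessions", {
  set.seed(51)
  for (i in 1:5) {
    pr <- draw_mp()
    v <- closed_form_Q0(pr, 2000)
    expect_equal(c(v$x, v$y), c(pr$Cs, pr$Cs), tolerance = 1e-6)
  }
})

test_that("reference integrator: degenerate RHS, closed-form check, self-convergence", {
  pz <- mp_params(Ks = 0, Kb = 0, Q = 0, Cs = 1, Vb0 = 10, Vd0 = 25,
                  x0 = 2, y0 = 0.5)
  tr <- reference_integrate("MP", pz, 1:5)
  expect_equal(tr$x, rep(2, 5))
  expect_equal(tr$y, rep(0.5, 5))

  p <- fig_sp()
  tr1 <- reference_integrate("SP", p, 1:4, tol = 1e-8)
  tr2 <- reference_integrate("SP", p, 1:4, tol = 1e-10)
  expect_lt(max(abs(tr1$x - tr2$x)), 1e-8)
  expect_lt(max(abs(tr2$x - sp_concentration(p, 1:4))), 1e-8)

  expect_error(reference_integrate("SP", p, c(2, 1)), "increasing")
  expect_error(reference_integrate("SP", p, 50), "validity")
})

test_that("trajectories carry masses and provenance", {
  p <- fig_mp()
  tr <- mp_trajectory(p, 0:8, method = "series")
  expect_s3_class(tr, "trajectory")
  expect_identical(attr(tr, "provenance"), "series")
  expect_equal(tr$mass_b, tr$x * (10 - 0.23 * tr$time))
  expect_equal(tr$mass_d, tr$y * (25 + 0.23 * tr$time))
  tr2 <- mp_trajectory(fig_mp(Q = 0), 0:8, method = "closed_form")
  expect_identical(attr(tr2, "provenance"), "closed_form")
})
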