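# Adaptive Dormand-Prince RK45 integrator. Implemented here because no ODE
# solver package is assumed; it serves as the package's independent numerical
# oracle for every analytic solver and must therefore not share code with
# them. Classic embedded 5(4) pair with PI-free step control (Hairer et al.).

.DP <- local({
  c_ <- c(0, 1/5, 3/10, 4/5, 8/9, 1, 1)
  A <- matrix(0, 7, 7)
  A[2, 1] <- 1/5
  A[3, 1:2] <- c(3/40, 9/40)
  A[4, 1:3] <- c(44/45, -56/15, 32/9)
  A[5, 1:4] <- c(19372/6561, -25360/2187, 64448/6561, -212/729)
  A[6, 1:5] <- c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656)
  A[7, 1:6] <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)
  b5 <- A[7, ]                                   # 5th-order weights
  b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)
  list(c = c_, A = A, b5 = b5, e = b5 - b4)
})

# Integrate dy/dt = f(t, y) from times[1] through all grid points, returning
# the solution at each grid time. Local error controlled against
# atol + rtol * |y| componentwise.
rk45 <- function(f, y0, times, rtol = 1e-10, atol = 1e-10, max_steps = 1e6) {
  stopifnot(length(times) >= 1, !is.unsorted(times, strictly = TRUE))
  d <- length(y0)
  out <- matrix(NA_real_, length(times), d)
  out[1, ] <- y0
  t <- times[1]; y <- y0
  h <- diff(range(times)) / 100 + 1e-12
  k <- matrix(0, 7, d)
  k[1, ] <- f(t, y)
  steps <- 0L
  for (i in seq_along(times)[-1]) {
    target <- times[i]
    while (t < target) {
      h <- min(h, target - t)
      repeat {
        steps <- steps + 1L
        if (steps > max_steps)
          stop("rk45: step limit exceeded (stiff or invalid problem?)",
               call. = FALSE)
        for (s in 2:7)
          k[s, ] <- f(t + .DP$c[s] * h, y + h * drop(.DP$A[s, 1:(s - 1)] %*%
                                                       k[1:(s - 1), , drop = FALSE]))
        ynew <- y + h * drop(.DP$b5 %*% k)
        err <- h * drop(.DP$e %*% k)
        sc <- atol + rtol * pmax(abs(y), abs(ynew))
        errnorm <- sqrt(mean((err / sc)^2))
        if (errnorm <= 1 || h < 1e-14) {
          t <- t + h
          y <- ynew
          k[1, ] <- k[7, ]                       # FSAL
          h <- h * min(5, max(0.2, 0.9 * errnorm^-0.2))
          break
        }
        h <- h * max(0.2, 0.9 * errnorm^-0.2)
      }
    }
    out[i, ] <- y
  }
  out
}

#' Reference numerical integration of the SP or MP model
#'
#' Adaptive Runge-Kutta 4(5) (Dormand-Prince) integration of the governing
#' differential equations at local tolerance `tol` (default 1e-10). This is
#' the package's independent oracle: every analytic solver
#' ([sp_concentration()], [series_eval()], [closed_form_Q0()]) is validated
#' against it, so it deliberately shares no code with them and integrates
#' the time-varying-volume equations directly.
#'
#' @param model `"SP"` or `"MP"`.
#' @param params an [sp_params()] (SP) or [mp_params()] (MP) object.
#' @param t_grid strictly increasing times (h) starting at `t >= 0`; must
#'   stay inside the validity domain `t < Vb0/Q` (and `t < Vd0/Q` would
#'   never bind since `Vd` grows).
#' @param tol local relative and absolute tolerance.
#' @return A `"trajectory"` data frame with columns `time`, `x`, (`y` for
#'   MP), `mass_b` (= `x * Vb(t)`), (`mass_d` = `y * Vd(t)`) and attribute
#'   `provenance = "numeric"`.
#' @export
reference_integrate <- function(model = c("SP", "MP"), params, t_grid,
                                tol = 1e-10) {
  model <- match.arg(model)
  if (any(!is.finite(t_grid)) || any(t_grid < 0) ||
      is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be finite, nonnegative and strictly increasing",
         call. = FALSE)
  if (t_grid[1] > 0) t_grid0 <- c(0, t_grid) else t_grid0 <- t_grid
  if (model == "SP") {
    stopifnot(inherits(params, "sp_params"))
    validate_sp_params(params)
    with(params, {
      if (!is_q_zero(Q) && any(t_grid0 >= Vb0 / Q))
        stop("t_grid leaves the validity domain t < Vb0/Q", call. = FALSE)
      f <- function(t, y)
        (Ks * Cs - (Ks + Kb) * y + Kb * Cd0) / (Vb0 - Q * t)
      sol <- tryCatch(rk45(f, x0, t_grid0, rtol = tol, atol = tol),
                      error = function(e)
                        stop("integrator failure: ", conditionMessage(e),
                             call. = FALSE))
      keep <- match(t_grid, t_grid0)
      trajectory(t_grid, x = sol[keep, 1], params = params,
                 provenance = "numeric")
    })
  } else {
    stopifnot(inherits(params, "mp_params"))
    with(params, {
      if (!is_q_zero(Q) && any(t_grid0 >= Vb0 / Q))
        stop("t_grid leaves the validity domain t < Vb0/Q", call. = FALSE)
      f <- function(t, s)
        c((Ks * Cs - (Ks + Kb) * s[1] + Kb * s[2]) / (Vb0 - Q * t),
          (Kb + Q) * (s[1] - s[2]) / (Vd0 + Q * t))
      sol <- tryCatch(rk45(f, c(x0, y0), t_grid0, rtol = tol, atol = tol),
                      error = function(e)
                        stop("integrator failure: ", conditionMessage(e),
                             call. = FALSE))
      keep <- match(t_grid, t_grid0)
      trajectory(t_grid, x = sol[keep, 1], y = sol[keep, 2], params = params,
                 provenance = "numeric")
    })
  }
}

#' Assemble a trajectory with derived compartment masses
#'
#' Packs a time grid and concentration series into a data frame, adding the
#' compartment masses `mass_b = x * (Vb0 - Q t)` and, for MP,
#' `mass_d = y * (Vd0 + Q t)` (mmol). The solver of origin is recorded in
#' the `provenance` attribute (`"series"`, `"closed_form"` or `"numeric"`).
#'
#' @param times strictly increasing time grid (h).
#' @param x serum concentrations (mmol/L).
#' @param y dialysate concentrations (mmol/L), or `NULL` for SP.
#' @param params the generating parameter object (for the volumes).
#' @param provenance solver tag.
#' @return A data frame of class `"trajectory"`.
#' @export
trajectory <- function(times, x, y = NULL, params,
                       provenance = c("numeric", "series", "closed_form")) {
  provenance <- match.arg(provenance)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  stopifnot(length(x) == length(times), is.null(y) || length(y) == length(times))
  df <- data.frame(time = times, x = x)
  df$mass_b <- x * (params$Vb0 - params$Q * times)
  if (!is.null(y)) {
    df$y <- y
    df$mass_d <- y * (params$Vd0 + params$Q * times)
    df <- df[, c("time", "x", "y", "mass_b", "mass_d")]
  }
  structure(df, class = c("trajectory", "data.frame"), provenance = provenance)
}

#' Analytic MP trajectory on a grid
#'
#' Convenience wrapper producing a [trajectory()] from either the certified
#' power series (with `N` from [terms_for_tolerance()] when not given) or
#' the Q = 0 closed form.
#'
#' @inheritParams series_coefficients
#' @param times strictly increasing time grid (h).
#' @param method `"series"` or `"closed_form"`.
#' @param N series order; default certifies 1e-8 mmol/L at `max(times)`.
#' @return A `"trajectory"` data frame.
#' @export
mp_trajectory <- function(params, times, method = c("series", "closed_form"),
                          N = NULL) {
  method <- match.arg(method)
  if (method == "series") {
    if (is.null(N)) N <- terms_for_tolerance(params, max(times), 1e-8)
    s <- series_coefficients(params, N)
    v <- series_eval(s, times)
  } else {
    v <- closed_form_Q0(params, times)
  }
  trajectory(times, x = v$x, y = v$y, params = params,
             provenance = if (method == "series") "series" else "closed_form")
}
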