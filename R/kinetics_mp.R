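#' Power-series coefficients of the multi-pass solution
#'
#' The MP model
#' \deqn{(V_{b0} - Qt)\,x' = K_s C_s - (K_s+K_b)x + K_b y, \qquad
#'       (V_{d0} + Qt)\,y' = (K_b + Q)(x - y)}
#' admits a power-series solution \eqn{x(t) = \sum \alpha_k t^k},
#' \eqn{y(t) = \sum \beta_k t^k}. Matching coefficients gives
#' \eqn{\alpha_0 = x_0}, \eqn{\beta_0 = y_0},
#' \deqn{\alpha_1 = \frac{K_s C_s - (K_s+K_b)\alpha_0 + K_b\beta_0}{V_{b0}},}
#' and for \eqn{k \ge 1} (the dialysate recursion also holds at \eqn{k = 0})
#' \deqn{\alpha_{k+1} = \frac{Qk\alpha_k - (K_s+K_b)\alpha_k + K_b\beta_k}
#'   {V_{b0}(k+1)}, \qquad
#'   \beta_{k+1} = \frac{-Qk\beta_k + (K_b+Q)(\alpha_k-\beta_k)}{V_{d0}(k+1)}.}
#' The series converges uniformly for \eqn{t < \min(V_{b0}, V_{d0})/Q}
#' (all \eqn{t \ge 0} when `Q = 0`), i.e. until one compartment would be
#' depleted. One extra order (`N + 1`) is always computed so that the
#' Lagrange truncation bound of [truncation_bound()] is available.
#'
#' @param params an [mp_params()] object.
#' @param N highest retained order (`N >= 0`).
#' @return An object of class `"series_solution"`: list with `alpha`, `beta`
#'   (numeric vectors of orders `0..N+1`, units mmol/L/h^k), `N`,
#'   `lambda_tilde` (uniform bound on the recursion-matrix eigenvalues,
#'   1/h), `t_valid` (validity horizon, h) and the generating `params`.
#' @examples
#' p <- mp_params(Ks = 2.6, Kb = 6.9, Q = 0.23, Cs = 2.9, Vb0 = 10, Vd0 = 25)
#' s <- series_coefficients(p, 27)
#' series_eval(s, 0:8)
#' @export
series_coefficients <- function(params, N) {
  stopifnot(inherits(params, "mp_params"))
  if (!is.numeric(N) || length(N) != 1L || N < 0 || N != round(N))
    stop("N must be a single nonnegative integer", call. = FALSE)
  N <- as.integer(N)
  with(params, {
    a <- b <- numeric(N + 2L)             # orders 0 .. N+1
    a[1L] <- x0
    b[1L] <- y0
    a[2L] <- (Ks * Cs - (Ks + Kb) * a[1L] + Kb * b[1L]) / Vb0
    b[2L] <- (Kb + Q) * (a[1L] - b[1L]) / Vd0
    if (N >= 1L) for (k in seq_len(N)) {
      a[k + 2L] <- (Q * k * a[k + 1L] - (Ks + Kb) * a[k + 1L] + Kb * b[k + 1L]) /
        (Vb0 * (k + 1))
      b[k + 2L] <- (-Q * k * b[k + 1L] + (Kb + Q) * (a[k + 1L] - b[k + 1L])) /
        (Vd0 * (k + 1))
    }
    if (!all(is.finite(a)) || !all(is.finite(b)))
      stop("series coefficients overflow double precision at order ",
           max(which(!is.finite(a) | !is.finite(b))) - 1L, call. = FALSE)
    structure(list(
      alpha = a, beta = b, N = N,
      lambda_tilde = max(Q / Vb0, Q / Vd0) + 1e-6,
      t_valid = if (is_q_zero(Q)) Inf else min(Vb0, Vd0) / Q,
      params = params), class = "series_solution")
  })
}

#' Evaluate the truncated multi-pass power series
#'
#' Partial sums \eqn{\sum_{k=0}^N \alpha_k t^k} and
#' \eqn{\sum_{k=0}^N \beta_k t^k}, evaluated in Horner order for stability
#' (avoids forming large `t^k` explicitly). Evaluation is refused outside
#' the proven convergence region `t < t_valid`.
#'
#' @param series a `"series_solution"` from [series_coefficients()].
#' @param t time (h); vectorized, `0 <= t < t_valid`.
#' @return List with numeric vectors `x` (serum) and `y` (dialysate), mmol/L.
#' @export
series_eval <- function(series, t) {
  stopifnot(inherits(series, "series_solution"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  if (any(t >= series$t_valid))
    stop("t >= t_valid (", format(series$t_valid),
         " h): outside the proven convergence region of the series",
         call. = FALSE)
  horner <- function(cf, t) {
    acc <- rep(cf[length(cf)], length(t))
    for (k in rev(seq_len(length(cf) - 1L))) acc <- acc * t + cf[k]
    acc
  }
  n <- series$N + 1L                      # retain orders 0..N only
  list(x = horner(series$alpha[seq_len(n)], t),
       y = horner(series$beta[seq_len(n)], t))
}

#' Lagrange truncation-error bound of the series solution
#'
#' Upper bound on the error committed by keeping only orders `0..N`:
#' \eqn{|x(t) - x_N(t)| \le |\alpha_{N+1}| t^{N+1}} and likewise
#' \eqn{|\beta_{N+1}| t^{N+1}} for the dialysate series (Lagrange remainder
#' applied to the truncated Taylor series). This certifies the analytic
#' solution with an a-priori error that direct numerical integration cannot
#' provide.
#'
#' @inheritParams series_eval
#' @return List with nonnegative `bound_x`, `bound_y` (mmol/L); both zero at
#'   `t = 0`.
#' @export
truncation_bound <- function(series, t) {
  stopifnot(inherits(series, "series_solution"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  k <- series$N + 2L                      # stored order N+1
  list(bound_x = abs(series$alpha[k]) * t^(series$N + 1L),
       bound_y = abs(series$beta[k]) * t^(series$N + 1L))
}

#' Number of series terms guaranteeing a tolerance
#'
#' Smallest order `N` such that both components of [truncation_bound()] at
#' `t_max` are at or below `tol`. For a typical 8-hour MP session and
#' tolerance 0.01 mmol/L this is a few dozen terms.
#'
#' @inheritParams series_coefficients
#' @param t_max largest time of interest (h), must lie inside the validity
#'   horizon.
#' @param tol guaranteed accuracy (mmol/L), `tol > 0`.
#' @param N_max give up beyond this order.
#' @return The smallest such `N` (integer).
#' @export
terms_for_tolerance <- function(params, t_max, tol, N_max = 500L) {
  stopifnot(inherits(params, "mp_params"))
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0)
    stop("tol must be a single positive number", call. = FALSE)
  if (!is.numeric(t_max) || length(t_max) != 1L || t_max < 0)
    stop("t_max must be a single nonnegative time", call. = FALSE)
  if (!is_q_zero(params$Q) && t_max >= min(params$Vb0, params$Vd0) / params$Q)
    stop("t_max lies outside the series validity horizon", call. = FALSE)
  # One pass to N_max; the bound at order N only needs coefficient N+1.
  s <- series_coefficients(params, N_max)
  for (N in 0:N_max) {
    if (abs(s$alpha[N + 2L]) * t_max^(N + 1) <= tol &&
        abs(s$beta[N + 2L])  * t_max^(N + 1) <= tol)
      return(N)
  }
  stop("no N <= ", N_max, " certifies tolerance ", tol, " mmol/L at t = ",
       t_max, " h", call. = FALSE)
}

#' Eigenvalues of the Q = 0 multi-pass system matrix
#'
#' For negligible ultrafiltration the MP model is the constant-coefficient
#' linear system \eqn{d\mathbf{x}/dt = A\mathbf{x} + \mathbf{b}} with
#' \deqn{A = \begin{pmatrix} -(K_s+K_b)/V_{b0} & K_b/V_{b0} \\
#'   K_b/V_{d0} & -K_b/V_{d0} \end{pmatrix}.}
#' Its eigenvalues are real (the discriminant is a sum of squares) and both
#' negative whenever `Ks > 0` and `Kb > 0` (negative trace, positive
#' determinant):
#' \deqn{\lambda_{1,2} = \tfrac12\Big(-\tfrac{K_s+K_b}{V_{b0}}
#'   - \tfrac{K_b}{V_{d0}} \pm \sqrt{\big(\tfrac{K_b}{V_{d0}}
#'   - \tfrac{K_s+K_b}{V_{b0}}\big)^2 + \tfrac{4K_b^2}{V_{b0}V_{d0}}}\Big).}
#'
#' @inheritParams series_coefficients
#' @return List with `lambda1 > lambda2` (1/h), both real.
#' @export
eigenvalues_A <- function(params) {
  stopifnot(inherits(params, "mp_params"))
  with(params, {
    s <- -(Ks + Kb) / Vb0 - Kb / Vd0
    disc <- (-(Ks + Kb) / Vb0 + Kb / Vd0)^2 + 4 * Kb^2 / (Vb0 * Vd0)
    d <- sqrt(disc)
    list(lambda1 = (s + d) / 2, lambda2 = (s - d) / 2)
  })
}

# System matrix A of the Q=0 MP model (internal).
mp_matrix_A <- function(params) {
  with(params, matrix(c(-(Ks + Kb) / Vb0, Kb / Vd0,
                        Kb / Vb0, -Kb / Vd0), 2L, 2L))
}

#' Closed-form multi-pass solution for negligible ultrafiltration
#'
#' Bi-exponential explicit solution of the Q = 0 MP model. With
#' \eqn{u = x_0 - C_s}, \eqn{v = y_0 - C_s}, eigenvalues \eqn{\lambda_1 >
#' \lambda_2} of [eigenvalues_A()] and \eqn{a_i = V_{d0}\lambda_i + K_b}:
#' \deqn{x(t) = \frac{a_1 (K_b u - a_2 v)}{K_b V_{d0} (\lambda_1-\lambda_2)}
#'   e^{\lambda_1 t} + \frac{a_2 (-K_b u + a_1 v)}
#'   {K_b V_{d0} (\lambda_1-\lambda_2)} e^{\lambda_2 t} + C_s,}
#' \deqn{y(t) = \frac{K_b u - a_2 v}{V_{d0} (\lambda_1-\lambda_2)}
#'   e^{\lambda_1 t} + \frac{-K_b u + a_1 v}{V_{d0} (\lambda_1-\lambda_2)}
#'   e^{\lambda_2 t} + C_s.}
#' Both concentrations relax bi-exponentially to the source level `Cs`.
#' The result agrees with the matrix-exponential route
#' \eqn{P e^{Dt} P^{-1}(x_0-C_s, y_0-C_s)^T + C_s} to better than 1e-10
#' for any consistent eigenvector normalization (see `method`).
#'
#' @inheritParams series_coefficients
#' @param t time (h); vectorized, `t >= 0`.
#' @param method `"explicit"` (the formulas above) or `"eigen"` (matrix
#'   route with unit-norm eigenvector columns); both give identical output
#'   and the second exists mainly as an internal cross-check.
#' @return List with numeric vectors `x`, `y` (mmol/L).
#' @export
closed_form_Q0 <- function(params, t, method = c("explicit", "eigen")) {
  stopifnot(inherits(params, "mp_params"))
  method <- match.arg(method)
  if (!is_q_zero(params$Q))
    stop("closed_form_Q0 requires Q = 0 (got Q = ", params$Q,
         " L/h); use series_coefficients() or reference_integrate()",
         call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  if (params$Kb <= 0)
    stop("closed_form_Q0 requires Kb > 0", call. = FALSE)
  ev <- eigenvalues_A(params)
  l1 <- ev$lambda1; l2 <- ev$lambda2
  if (abs(l1 - l2) < 1e-12)
    stop("degenerate eigenvalues (|lambda1 - lambda2| < 1e-12)", call. = FALSE)
  with(params, {
    u <- x0 - Cs; v <- y0 - Cs
    if (method == "explicit") {
      a1 <- Vd0 * l1 + Kb; a2 <- Vd0 * l2 + Kb
      D <- Vd0 * (l1 - l2)
      c1 <- (Kb * u - a2 * v) / D          # lambda1 weight of y(t)
      c2 <- (-Kb * u + a1 * v) / D         # lambda2 weight of y(t)
      list(x = a1 / Kb * c1 * exp(l1 * t) + a2 / Kb * c2 * exp(l2 * t) + Cs,
           y = c1 * exp(l1 * t) + c2 * exp(l2 * t) + Cs)
    } else {
      A <- mp_matrix_A(params)
      e1 <- c(Vd0 * l1 + Kb, Kb); e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(Vd0 * l2 + Kb, Kb); e2 <- e2 / sqrt(sum(e2^2))
      P <- cbind(e1, e2)
      w <- solve(P, c(u, v))
      list(x = P[1, 1] * w[1] * exp(l1 * t) + P[1, 2] * w[2] * exp(l2 * t) + Cs,
           y = P[2, 1] * w[1] * exp(l1 * t) + P[2, 2] * w[2] * exp(l2 * t) + Cs)
    }
  })
}
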