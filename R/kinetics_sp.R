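#' Serum phosphate concentration during single-pass dialysis
#'
#' Exact analytical solution of the SP model
#' \deqn{(V_{b0} - Qt)\, x'(t) = K_s C_s - (K_s + K_b)\, x(t) + K_b C_{d0}.}
#' With ultrafiltration (`Q > 0`) the solution is
#' \deqn{x(t) = x^* + (x_0 - x^*)\,(1 - Qt/V_{b0})^{(K_s+K_b)/Q},}
#' where \eqn{x^* = (K_s C_s + K_b C_{d0})/(K_s + K_b)} is the plateau level;
#' for `Q = 0` the power collapses to the exponential
#' \eqn{x(t) = x^* + (x_0 - x^*) e^{-(K_s+K_b)t/V_{b0}}}. The `Q = 0` branch
#' is also used whenever `Q < 1e-10` L/h, where the finite-Q exponent would
#' overflow while the limit is exact.
#'
#' @param params an [sp_params()] object.
#' @param t time since session start (h); vectorized. Must satisfy
#'   `0 <= t < Vb0/Q` when `Q > 0` (beyond that the serum + extracellular
#'   volume would be completely depleted); any `t >= 0` when `Q = 0`.
#' @return Serum concentration `x(t)` in mmol/L, same length as `t`.
#' @seealso [sp_steady_state()], [sp_reduction_ratio()]
#' @examples
#' p <- sp_params(Ks = 2.6, Kb = 6.9, Q = 0.23, Cs = 2.9, Vb0 = 10)
#' sp_concentration(p, c(0, 2, 4))
#' @export
sp_concentration <- function(params, t) {
  stopifnot(inherits(params, "sp_params"))
  validate_sp_params(params)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  xss <- sp_steady_state(params)
  with(params, {
    if (is_q_zero(Q)) {
      xss + (x0 - xss) * exp(-(Ks + Kb) / Vb0 * t)
    } else {
      if (any(t >= Vb0 / Q))
        stop("t >= Vb0/Q: complete depletion of the plasma and extracellular ",
             "volume; the SP solution is valid only for t < ",
             format(Vb0 / Q), " h", call. = FALSE)
      xss + (x0 - xss) * (1 - Q / Vb0 * t)^((Ks + Kb) / Q)
    }
  })
}

#' Single-pass steady-state (plateau) concentration
#'
#' The level \eqn{(K_s C_s + K_b C_{d0})/(K_s + K_b)} that the serum
#' concentration approaches exponentially during a long SP session: the
#' balance point between source influx and dialyzer clearance.
#'
#' @inheritParams sp_concentration
#' @return Plateau concentration (mmol/L).
#' @export
sp_steady_state <- function(params) {
  stopifnot(inherits(params, "sp_params"))
  with(params, {
    if (Ks + Kb <= 0)
      stop("steady state undefined: Ks + Kb must be > 0", call. = FALSE)
    (Ks * Cs + Kb * Cd0) / (Ks + Kb)
  })
}

#' Phosphate reduction ratio of an SP session
#'
#' Ratio `x(T)/x(0)` for a session of duration `T` under the conventions of
#' the bi-linear correlation analysis: no ultrafiltration, steady state
#' before the session (`x(0) = Cs`), and phosphate-free dialysate
#' (`Cd0 = 0`). Exactly,
#' \deqn{\frac{x(T)}{x(0)} = \frac{K_b}{K_s+K_b} e^{-(K_s+K_b)T/V_{b0}}
#'   + \frac{K_s}{K_s+K_b},}
#' and a second-order Taylor expansion of the exponential gives
#' \deqn{\frac{x(T)}{x(0)} \approx 1 - \frac{K_b T}{V_{b0}}
#'   + \frac12\Big(\frac{K_b T}{V_{b0}}\Big)^2
#'   + \frac12 K_b \Big(\frac{T}{V_{b0}}\Big)^2 K_s,}
#' which is linear in `Ks` with positive slope — the analytic form of the
#' observed positive correlation between reduction ratio and transfer rate.
#' Only `Ks`, `Kb`, `Vb0` of `params` are used; the `Cd0 = 0`, steady-start
#' convention is enforced rather than generalized.
#'
#' @inheritParams sp_concentration
#' @param T session duration (h), `T >= 0`; vectorized.
#' @return A list with components `exact` and `approx`, both in `(0, 1]` for
#'   `T >= 0`.
#' @export
sp_reduction_ratio <- function(params, T) {
  stopifnot(inherits(params, "sp_params"))
  validate_sp_params(params)
  if (any(!is.finite(T)) || any(T < 0))
    stop("T must be finite and >= 0", call. = FALSE)
  with(params, {
    r <- Kb * T / Vb0
    list(exact  = Kb / (Ks + Kb) * exp(-(Ks + Kb) * T / Vb0) + Ks / (Ks + Kb),
         approx = 1 - r + r^2 / 2 + Kb * (T / Vb0)^2 / 2 * Ks)
  })
}
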