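#' Post-dialysis rebound state
#'
#' After a session of duration `T` the dialyzer is disconnected and serum
#' phosphate is governed solely by diffusion from the intracellular source:
#' \eqn{V_{b0}\,x'(t) = K_s(C_s - x(t))} for \eqn{t \ge T}, with
#' \eqn{x(T) = x_T}. This object holds the quantities needed by the rebound
#' formulas.
#'
#' @param Cs source concentration (mmol/L).
#' @param xT serum concentration at end of session (mmol/L); for a
#'   phosphate-lowering session `0 <= xT <= Cs`.
#' @param Ks source-to-serum transfer rate (L/h), `Ks > 0` for a nontrivial
#'   rebound.
#' @param Vb0 serum + extracellular volume (L).
#' @param T session duration (h), `T > 0`.
#' @param Kb dialyzer clearance (L/h); needed only by the plateau formula.
#' @return An object of class `"rebound_state"`.
#' @examples
#' st <- rebound_state(Cs = 2.9, xT = 1.2, Ks = 2.6, Vb0 = 10, T = 4)
#' rebound_concentration(st, c(4, 5, 6))
#' rebound_percent(st, c(0, 1, 2))
#' @export
rebound_state <- function(Cs, xT, Ks, Vb0, T, Kb = NA_real_) {
  if (!is.numeric(T) || length(T) != 1L || T <= 0)
    stop("T must be a single positive duration (h)", call. = FALSE)
  if (Vb0 <= 0) stop("Vb0 must be > 0", call. = FALSE)
  if (Ks < 0) stop("Ks must be >= 0", call. = FALSE)
  if (xT < 0) stop("xT must be >= 0", call. = FALSE)
  if (xT > Cs)
    warning("xT > Cs: not a phosphate-lowering session; the 'rebound' decays")
  structure(list(Cs = Cs, xT = xT, Ks = Ks, Kb = Kb, Vb0 = Vb0, T = T),
            class = "rebound_state")
}

#' Serum concentration during the post-dialysis rebound
#'
#' Solution of the rebound equation in absolute time:
#' \deqn{x(t) = (x_T - C_s)\,e^{-K_s (t - T)/V_{b0}} + C_s, \quad t \ge T,}
#' a monotone exponential relaxation from the end-of-session level `xT`
#' back to the source level `Cs` with rate `Ks/Vb0`. Note the absolute-time
#' convention: `t` is hours since session *start*; see [rebound_percent()]
#' for the time-since-end convention.
#'
#' @param state a [rebound_state()].
#' @param t absolute time (h), `t >= T`; vectorized.
#' @return Concentration (mmol/L).
#' @export
rebound_concentration <- function(state, t) {
  stopifnot(inherits(state, "rebound_state"))
  if (any(!is.finite(t)) || any(t < state$T))
    stop("t must be >= T (absolute time, h); rebound starts at end of session",
         call. = FALSE)
  with(state, (xT - Cs) * exp(-Ks / Vb0 * (t - T)) + Cs)
}

#' Percentage rebound after treatment
#'
#' The rebound measure \eqn{(x(t+T) - x(T))/x(T)\cdot 100\%} in explicit
#' form:
#' \deqn{\mathrm{rebound}(t) = \frac{C_s - x_T}{x_T}
#'   \big(1 - e^{-K_s t / V_{b0}}\big) \cdot 100\%,}
#' where `t` here is time *since the end* of the session. It increases
#' monotonically from 0 to its plateau \eqn{(C_s - x_T)/x_T \cdot 100\%}.
#'
#' @param state a [rebound_state()] with `xT > 0`.
#' @param t time since end of session (h), `t >= 0`; vectorized.
#' @return Rebound in percent.
#' @export
rebound_percent <- function(state, t) {
  stopifnot(inherits(state, "rebound_state"))
  if (state$xT == 0)
    stop("rebound percent undefined for xT = 0", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t is time since end of session and must be >= 0", call. = FALSE)
  with(state, (Cs - xT) / xT * (1 - exp(-Ks / Vb0 * t)) * 100)
}

#' Percentage rebound from the single-pass plateau
#'
#' When the session is long enough that `xT` has reached the SP plateau
#' \eqn{K_s C_s/(K_s + K_b)} (phosphate-free dialysate), the rebound
#' becomes independent of both `Cs` and the session duration `T`:
#' \deqn{\mathrm{rebound}(t) = \frac{K_b}{K_s}
#'   \big(1 - e^{-K_s t / V_{b0}}\big)\cdot 100\%.}
#' This explains the clinical observation that 2 h, 4 h and 8 h sessions
#' produce the same rebound curve. Plateau attainment depends on the rates;
#' sessions much shorter than about 2 h may not have reached it, in which
#' case a warning is issued (use [rebound_percent()] with the actual `xT`
#' instead).
#'
#' @param Ks source-to-serum transfer rate (L/h), `Ks > 0`.
#' @param Kb dialyzer clearance (L/h).
#' @param Vb0 serum + extracellular volume (L).
#' @param t time since end of session (h), `t >= 0`; vectorized.
#' @param T session duration (h); advisory only — a warning (not an error)
#'   is given when `T < 2` h.
#' @return Rebound in percent, approaching `Kb/Ks * 100` as `t` grows.
#' @export
plateau_rebound_percent <- function(Ks, Kb, Vb0, t, T = NULL) {
  if (Ks <= 0)
    stop("plateau rebound undefined for Ks = 0", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t is time since end of session and must be >= 0", call. = FALSE)
  if (!is.null(T) && T < 2)
    warning("plateau formula assumes the session reached the SP plateau; ",
            "T < 2 h may be too short")
  Kb / Ks * (1 - exp(-Ks / Vb0 * t)) * 100
}
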