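# Units used throughout the package: hours (h), litres (L), mmol/L, L/h.
# No unit-conversion layer is provided.

# Threshold below which ultrafiltration Q is treated as exactly zero.  The
# exponent (Ks+Kb)/Q in the finite-Q solution overflows as Q -> 0 while the
# limit is exact, so dispatching to the Q = 0 branch preserves continuity.
.Q_ZERO <- 1e-10

#' Single-pass model parameters
#'
#' Bundles the kinetic constants, volumes and concentrations that define one
#' patient-session single-pass (SP) hemodialysis model: a constant
#' intracellular source at concentration `Cs` feeds the serum + extracellular
#' compartment (initial volume `Vb0`, concentration `x(t)`) at rate `Ks`;
#' the dialyzer removes phosphate by diffusion at rate `Kb` against a fixed
#' dialysate concentration `Cd0`, and by ultrafiltration at flow `Q`, which
#' shrinks the compartment as `Vb(t) = Vb0 - Q t`.
#'
#' @param Ks source-to-serum transfer rate (L/h), `Ks >= 0`.
#' @param Kb dialyzer diffusion clearance (L/h), `Kb >= 0` (`Kb > 0` is
#'   required by the closed-form MP solution).
#' @param Q ultrafiltration flow (L/h), `Q >= 0`. Values below `1e-10` are
#'   treated as exactly zero by the solvers.
#' @param Cs source (steady-state) phosphate concentration (mmol/L).
#' @param Cd0 fixed dialysate phosphate concentration (mmol/L). Zero for a
#'   phosphate-free dialysate.
#' @param Vb0 initial serum + extracellular volume (L), `Vb0 > 0`.
#' @param x0 initial serum concentration (mmol/L); defaults to `Cs`
#'   (equilibrium before the session).
#'
#' @return An object of class `"sp_params"`: a named list of the validated
#'   fields.
#' @examples
#' p <- sp_params(Ks = 2.6, Kb = 6.9, Q = 0.23, Cs = 2.9, Cd0 = 0, Vb0 = 10)
#' sp_concentration(p, 0:4)
#' @export
sp_params <- function(Ks, Kb, Q = 0, Cs, Cd0 = 0, Vb0, x0 = Cs) {
  p <- list(Ks = Ks, Kb = Kb, Q = Q, Cs = Cs, Cd0 = Cd0, Vb0 = Vb0, x0 = x0)
  validate_sp_params(p)
  structure(p, class = "sp_params")
}

#' Multi-pass model parameters
#'
#' Extends [sp_params()] with the recirculating-dialysate compartment of the
#' multi-pass (MP) model: initial dialysate volume `Vd0` (growing as
#' `Vd(t) = Vd0 + Q t`) and initial dialysate concentration `y0`. In MP the
#' dialysate concentration `y(t)` evolves; the fixed `Cd0` of SP is unused.
#'
#' @inheritParams sp_params
#' @param Vd0 initial dialysate volume (L), `Vd0 > 0`.
#' @param y0 initial dialysate concentration (mmol/L), usually 0.
#'
#' @return An object of class `c("mp_params", "sp_params")`.
#' @examples
#' p <- mp_params(Ks = 2.6, Kb = 6.9, Q = 0.23, Cs = 2.9, Vb0 = 10,
#'                Vd0 = 25, x0 = 2.9, y0 = 0)
#' closed_form_Q0(mp_params(Ks = 2.6, Kb = 6.9, Cs = 2.9, Vb0 = 10, Vd0 = 25), 0:8)
#' @export
mp_params <- function(Ks, Kb, Q = 0, Cs, Cd0 = 0, Vb0, Vd0, x0 = Cs, y0 = 0) {
  p <- list(Ks = Ks, Kb = Kb, Q = Q, Cs = Cs, Cd0 = Cd0, Vb0 = Vb0,
            Vd0 = Vd0, x0 = x0, y0 = y0)
  validate_sp_params(p)
  if (!is.numeric(p$Vd0) || length(p$Vd0) != 1L || !is.finite(p$Vd0) || p$Vd0 <= 0)
    stop("Vd0 must be a single positive number (L)", call. = FALSE)
  if (!is.numeric(p$y0) || length(p$y0) != 1L || !is.finite(p$y0) || p$y0 < 0)
    stop("y0 must be a single nonnegative concentration (mmol/L)", call. = FALSE)
  structure(p, class = c("mp_params", "sp_params"))
}

validate_sp_params <- function(p) {
  chk <- function(v, nm, lower = 0, strict = FALSE) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(nm, " must be a single finite number", call. = FALSE)
    if (if (strict) v <= lower else v < lower)
      stop(nm, " must be ", if (strict) "> " else ">= ", lower, call. = FALSE)
  }
  chk(p$Ks, "Ks")
  chk(p$Kb, "Kb")
  chk(p$Q, "Q")
  chk(p$Cs, "Cs")
  chk(p$Cd0, "Cd0")
  chk(p$Vb0, "Vb0", strict = TRUE)
  chk(p$x0, "x0")
  invisible(p)
}

#' @export
print.sp_params <- function(x, ...) {
  kind <- if (inherits(x, "mp_params")) "Multi-pass" else "Single-pass"
  cat(kind, "model parameters (h, L, mmol/L, L/h):\n")
  fields <- unlist(x)
  cat(paste0("  ", format(names(fields), width = 4), " = ", fields,
             collapse = "\n"), "\n")
  invisible(x)
}

is_q_zero <- function(Q) Q < .Q_ZERO
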