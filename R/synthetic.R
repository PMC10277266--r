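# Synthetic patients and cohorts emulating the clinical study design:
# ten patients, each with an SP session sampled at baseline + hourly to 4 h
# (blood only) and an MP session sampled at baseline + hourly to 8 h (blood
# and dialysate). Parameter ranges default to the spans of the published
# per-patient estimates; measurement noise is additive Gaussian (sd 0.05
# mmol/L, consistent with the published fit RMSEs of 0.01-0.08), truncated
# at zero. The noise model itself is a package choice: the study does not
# state one.

#' Cohort design
#'
#' Sampling schedule, parameter ranges and noise level for a synthetic
#' cohort. Defaults emulate the published 10-patient study: uniform
#' per-patient draws of `Ks` in \[2.4, 11\] L/h, `Kb` in \[3.9, 17.4\] L/h,
#' `Vb0` in \[8, 23\] L, `Cs` in \[1.0, 2.9\] mmol/L, `Cd0` in
#' \[0.09, 0.21\] mmol/L, `Vd0` in \[14.24, 31.93\] L; SP sampled hourly
#' 0-4 h, MP hourly 0-8 h; additive Gaussian noise sd 0.05 mmol/L.
#'
#' @param n_patients number of patients (`>= 0`).
#' @param ranges named list of `c(lower, upper)` ranges for `Ks`, `Kb`,
#'   `Vb0`, `Cs`, `Cd0`, `Vd0`; must sit inside the physiological fitting
#'   bounds of [default_bounds()].
#' @param sp_times,mp_times sampling schedules (h), starting at 0.
#' @param noise_sd additive Gaussian measurement noise (mmol/L), `>= 0`.
#' @param seed integer seed making the cohort reproducible.
#' @param Q ultrafiltration flow used in the generating (truth) model; 0 by
#'   default to match the estimation assumption. A nonzero value (e.g.
#'   0.1-0.3 L/h) injects the model misspecification argued to be
#'   negligible.
#' @return An object of class `"cohort_design"`.
#' @export
cohort_design <- function(n_patients = 10L,
                          ranges = list(Ks = c(2.4, 11), Kb = c(3.9, 17.4),
                                        Vb0 = c(8, 23), Cs = c(1.0, 2.9),
                                        Cd0 = c(0.09, 0.21),
                                        Vd0 = c(14.24, 31.93)),
                          sp_times = 0:4, mp_times = 0:8,
                          noise_sd = 0.05, seed = 1L, Q = 0) {
  if (n_patients < 0) stop("n_patients must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  need <- c("Ks", "Kb", "Vb0", "Cs", "Cd0", "Vd0")
  if (!all(need %in% names(ranges)))
    stop("ranges must name ", paste(need, collapse = ", "), call. = FALSE)
  b <- default_bounds()
  for (nm in c("Ks", "Kb", "Vb0")) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < b$lower[[nm]] || r[2] > b$upper[[nm]])
      stop("range for ", nm, " must lie inside the physiological bounds [",
           b$lower[[nm]], ", ", b$upper[[nm]], "]", call. = FALSE)
  }
  if (ranges$Cs[1] < 0 || ranges$Cs[2] > b$upper[["x0"]])
    stop("Cs range must lie inside [0, ", b$upper[["x0"]], "]", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), ranges = ranges,
                 sp_times = as.numeric(sp_times), mp_times = as.numeric(mp_times),
                 noise_sd = noise_sd, seed = as.integer(seed), Q = Q),
            class = "cohort_design")
}

#' Simulate one patient's SP and MP sessions
#'
#' Forward-simulates both modalities from the SAME physiological parameters
#' (`Ks`, `Kb`, `Vb0`, `Cs`) — the premise that makes coupled (CP) fitting
#' well posed — and adds independent additive Gaussian noise truncated at
#' zero. SP starts at equilibrium (`z0 = Cs`) against the fixed dialysate
#' concentration `Cd0`; MP starts at `x0 = Cs`, `y0 = 0`.
#'
#' @param params an [mp_params()] object: truth for both sessions (its
#'   `Vd0`, `x0`, `y0` apply to MP; its `Q` to both).
#' @param Cd0 fixed SP dialysate concentration (mmol/L).
#' @param sp_times,mp_times sampling schedules (h) including baseline 0.
#' @param noise_sd additive Gaussian noise sd (mmol/L).
#' @param seed integer seed; the measurement set is a pure function of
#'   (params, schedule, noise_sd, seed).
#' @param Vb0_clinical the "clinical" volume carried by the measurement
#'   set; defaults to the truth (the study's clinical values are
#'   themselves noisy initial estimates).
#' @return A [measurement_set()] with both modalities.
#' @export
simulate_patient <- function(params, Cd0, sp_times = 0:4, mp_times = 0:8,
                             noise_sd = 0.05, seed = 1L,
                             Vb0_clinical = params$Vb0) {
  stopifnot(inherits(params, "mp_params"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  sp_times <- as.numeric(sp_times)
  mp_times <- as.numeric(mp_times)
  sp_p <- sp_params(Ks = params$Ks, Kb = params$Kb, Q = params$Q,
                    Cs = params$Cs, Cd0 = Cd0, Vb0 = params$Vb0,
                    x0 = params$Cs)
  z <- sp_concentration(sp_p, sp_times)
  v <- if (is_q_zero(params$Q)) closed_form_Q0(params, mp_times)
       else {
         tr <- reference_integrate("MP", params, mp_times)
         list(x = tr$x, y = tr$y)
       }
  set.seed(seed)
  jitter <- function(mu) pmax(mu + stats::rnorm(length(mu), 0, noise_sd), 0)
  measurement_set(patient_id = "synthetic",
                  sp = data.frame(time = sp_times, conc = jitter(z)),
                  mp = data.frame(time = mp_times, x = jitter(v$x),
                                  y = jitter(v$y)),
                  Cd0 = Cd0, Vd0 = params$Vd0, Vb0_clinical = Vb0_clinical)
}

#' Generate a synthetic cohort with known truth
#'
#' Draws per-patient parameters uniformly within the design ranges (no
#' correlation structure) and simulates each patient with
#' [simulate_patient()]. The generating truth is returned alongside the
#' data for parameter-recovery studies.
#'
#' @param design a [cohort_design()].
#' @return A list of length `n_patients`; each element has `$truth` (an
#'   [mp_params()] plus `Cd0`) and `$data` (a [measurement_set()]).
#' @examples
#' coh <- generate_cohort(cohort_design(n_patients = 2, seed = 7))
#' coh[[1]]$truth$Ks
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  if (design$n_patients == 0L) return(list())
  set.seed(design$seed)
  draw <- function(r) stats::runif(1, r[1], r[2])
  # per-patient seeds drawn up front so patients are independent of order
  seeds <- sample.int(.Machine$integer.max, design$n_patients)
  out <- vector("list", design$n_patients)
  for (i in seq_len(design$n_patients)) {
    r <- design$ranges
    truth <- mp_params(Ks = draw(r$Ks), Kb = draw(r$Kb), Q = design$Q,
                       Cs = draw(r$Cs), Vb0 = draw(r$Vb0),
                       Vd0 = draw(r$Vd0), y0 = 0)
    Cd0 <- draw(r$Cd0)
    ms <- simulate_patient(truth, Cd0 = Cd0,
                           sp_times = design$sp_times,
                           mp_times = design$mp_times,
                           noise_sd = design$noise_sd, seed = seeds[i])
    ms$patient_id <- as.character(i)
    truth_fields <- unclass(truth)
    truth_fields$Cd0 <- Cd0            # the SP fixed dialysate concentration
    out[[i]] <- list(truth = truth_fields, data = ms)
  }
  out
}
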