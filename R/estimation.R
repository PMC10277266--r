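# Parameter estimation for SP / MP / CP dialysis data.
#
# All fitting assumes Q = 0 (ultrafiltration shown negligible for phosphate),
# so the SP model is a single exponential and the MP model the bi-exponential
# closed form. Modes:
#   SP: free (Ks, Kb, z0);          Vb0 fixed at the clinical value, Cs = z0
#   MP: free (Ks, Kb, Vb0, x0);     Cs = x0, y0 = 0
#   CP: free (Ks, Kb, Vb0, z0, x0); Cs = max(z0, x0), y0 = 0, shared rates
# Initial conditions are free parameters because they carry the same
# measurement noise as later samples.

#' One patient's measurement set
#'
#' Holds the sampled phosphate concentrations for one patient for one or
#' both treatment modalities, plus the per-patient fixed quantities that are
#' estimated independently beforehand: the constant SP dialysate
#' concentration `Cd0`, the MP dialysate volume `Vd0`, and the (clinically
#' measured, less accurate) extracellular volume `Vb0_clinical`.
#'
#' @param patient_id label.
#' @param sp `NULL`, or a data frame with columns `time` (h) and `conc`
#'   (blood phosphate, mmol/L) for the single-pass session.
#' @param mp `NULL`, or a data frame with columns `time` (h), `x` (blood)
#'   and `y` (dialysate) for the multi-pass session.
#' @param Cd0 fixed SP dialysate concentration (mmol/L).
#' @param Vd0 fixed MP dialysate volume (L).
#' @param Vb0_clinical clinical estimate of the serum + extracellular
#'   volume (L); fixed in SP fits, initial guess otherwise.
#' @return An object of class `"measurement_set"`. Series are sorted by
#'   time; each supplied series must include a baseline sample at `t = 0`
#'   and nonnegative concentrations.
#' @export
measurement_set <- function(patient_id, sp = NULL, mp = NULL,
                            Cd0 = NA_real_, Vd0 = NA_real_,
                            Vb0_clinical = NA_real_) {
  chk_series <- function(df, cols, what) {
    if (!is.data.frame(df) || !all(cols %in% names(df)))
      stop(what, " must be a data frame with columns ",
           paste(cols, collapse = ", "), call. = FALSE)
    df <- df[order(df$time), cols, drop = FALSE]
    if (anyDuplicated(df$time))
      stop(what, ": duplicated times", call. = FALSE)
    if (df$time[1] != 0)
      stop(what, ": missing baseline sample at t = 0", call. = FALSE)
    vals <- unlist(df[setdiff(cols, "time")])
    if (any(!is.finite(vals)) || any(vals < 0))
      stop(what, ": concentrations must be finite and >= 0", call. = FALSE)
    df
  }
  if (!is.null(sp)) sp <- chk_series(sp, c("time", "conc"), "sp")
  if (!is.null(mp)) mp <- chk_series(mp, c("time", "x", "y"), "mp")
  if (is.null(sp) && is.null(mp))
    stop("at least one of sp, mp must be supplied", call. = FALSE)
  # the fixed constants may be joined later (read_measurements without a
  # constants table); fitting checks their presence per mode
  if (is.finite(Vd0) && Vd0 <= 0)
    stop("Vd0 must be positive", call. = FALSE)
  structure(list(patient_id = as.character(patient_id), sp = sp, mp = mp,
                 Cd0 = Cd0, Vd0 = Vd0, Vb0_clinical = Vb0_clinical),
            class = "measurement_set")
}

#' Default physiological bounds for the nonlinear fit
#'
#' The box constraints used in the bounded least-squares stage: transfer
#' rates in `[0, 30]` L/h, volume in `[0, 60]` L, initial concentrations in
#' `[0, 5]` mmol/L.
#'
#' @return List with named numeric vectors `lower` and `upper` over
#'   `Ks, Kb, Vb0, z0, x0`.
#' @export
default_bounds <- function() {
  list(lower = c(Ks = 0, Kb = 0, Vb0 = 0, z0 = 0, x0 = 0),
       upper = c(Ks = 30, Kb = 30, Vb0 = 60, z0 = 5, x0 = 5))
}

#' Fit specification
#'
#' @param mode `"SP"`, `"MP"` or `"CP"` (coupled: SP and MP jointly with
#'   shared `Ks`, `Kb`, `Vb0` and `Cs = max(z0, x0)`).
#' @param bounds as [default_bounds()]; only entries for the mode's free
#'   parameters are used.
#' @param multistart number of additional uniform random starts (1 = just
#'   the deterministic two-stage start).
#' @param seed integer seed for the random starts.
#' @param rel_tol,x_tol optimizer convergence tolerances (objective,
#'   parameters).
#' @return An object of class `"fit_spec"`.
#' @export
fit_spec <- function(mode = c("SP", "MP", "CP"), bounds = default_bounds(),
                     multistart = 1L, seed = 1L,
                     rel_tol = 1e-10, x_tol = 1e-8) {
  mode <- match.arg(mode)
  if (!all(c("lower", "upper") %in% names(bounds)) ||
      any(bounds$lower > bounds$upper) ||
      any(!is.finite(c(bounds$lower, bounds$upper))))
    stop("bounds must be finite with lower <= upper", call. = FALSE)
  structure(list(mode = mode, bounds = bounds,
                 multistart = as.integer(multistart), seed = as.integer(seed),
                 rel_tol = rel_tol, x_tol = x_tol),
            class = "fit_spec")
}

free_params <- function(mode) {
  switch(mode,
         SP = c("Ks", "Kb", "z0"),
         MP = c("Ks", "Kb", "Vb0", "x0"),
         CP = c("Ks", "Kb", "Vb0", "z0", "x0"))
}

check_mode_data <- function(data, mode) {
  if (mode %in% c("SP", "CP") && is.null(data$sp))
    stop("mode ", mode, " requires SP data", call. = FALSE)
  if (mode %in% c("MP", "CP") && is.null(data$mp))
    stop("mode ", mode, " requires MP data", call. = FALSE)
  if (mode == "SP" && !is.finite(data$Vb0_clinical))
    stop("SP fits fix Vb0 at Vb0_clinical, which is missing", call. = FALSE)
  if (mode %in% c("SP", "CP") && !is.finite(data$Cd0))
    stop("fitting the SP series requires the fixed Cd0 (join a constants table)",
         call. = FALSE)
  if (mode %in% c("MP", "CP") && !is.finite(data$Vd0))
    stop("fitting the MP series requires the fixed Vd0 (join a constants table)",
         call. = FALSE)
}

# Residuals (model - data) stacked over all series of the mode.
mode_residuals <- function(theta, data, mode) {
  res <- numeric(0)
  Cs <- switch(mode, SP = theta[["z0"]], MP = theta[["x0"]],
               CP = max(theta[["z0"]], theta[["x0"]]))
  if (mode %in% c("SP", "CP")) {
    # SP fixes Vb0 at the clinical value unless a free Vb0 is supplied
    # (used to demonstrate its non-identifiability from SP data alone)
    Vb0 <- if (mode == "SP") {
      if ("Vb0" %in% names(theta)) theta[["Vb0"]] else data$Vb0_clinical
    } else theta[["Vb0"]]
    p <- sp_params(Ks = theta[["Ks"]], Kb = theta[["Kb"]], Q = 0, Cs = Cs,
                   Cd0 = data$Cd0, Vb0 = Vb0, x0 = theta[["z0"]])
    res <- c(res, sp_concentration(p, data$sp$time) - data$sp$conc)
  }
  if (mode %in% c("MP", "CP")) {
    p <- mp_params(Ks = theta[["Ks"]], Kb = theta[["Kb"]], Q = 0, Cs = Cs,
                   Vb0 = theta[["Vb0"]], Vd0 = data$Vd0,
                   x0 = theta[["x0"]], y0 = 0)
    v <- closed_form_Q0(p, data$mp$time)
    res <- c(res, v$x - data$mp$x, v$y - data$mp$y)
  }
  res
}

n_residuals <- function(data, mode) {
  (if (mode %in% c("SP", "CP")) nrow(data$sp) else 0L) +
    (if (mode %in% c("MP", "CP")) 2L * nrow(data$mp) else 0L)
}

#' Root-mean-square-error objective
#'
#' The fitting objective: the square root of the mean squared residual over
#' all residuals of all series used by the mode (`d` = 1 series for SP, 2
#' for MP, 3 for CP). With unequal series lengths the mean is taken over
#' the total residual count, which reduces to the equal-length `1/(dn)`
#' normalization when lengths agree.
#'
#' @param theta named numeric vector of the mode's free parameters (see
#'   [fit_spec()]): always `Ks`, `Kb`; plus `z0` (SP, CP), `x0` (MP, CP)
#'   and `Vb0` (MP, CP; SP uses the fixed clinical value).
#' @param data a [measurement_set()].
#' @param mode `"SP"`, `"MP"` or `"CP"`.
#' @return RMSE in mmol/L.
#' @export
rmse_objective <- function(theta, data, mode = c("SP", "MP", "CP")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "measurement_set"))
  check_mode_data(data, mode)
  theta <- unlist(theta)
  missing <- setdiff(free_params(mode), names(theta))
  if (length(missing))
    stop("theta lacks parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  r <- mode_residuals(theta, data, mode)
  sqrt(mean(r^2))
}

#' Linearized pre-estimate of the transfer rates
#'
#' First stage of the estimation pipeline. With the volumes, `Cs` and the
#' initial conditions held fixed, the governing equations are linear in
#' `(Ks, Kb)`. Each consecutive sampling interval is discretized by the
#' trapezoidal rule, giving one linear equation per interval per series,
#' e.g. for the SP series
#' \deqn{\big(C_s - \bar z_i\big) K_s + \big(C_{d0} - \bar z_i\big) K_b
#'   = V_{b0} (z_{i+1} - z_i)/\Delta t_i,}
#' with \eqn{\bar z_i = (z_{i+1} + z_i)/2}, and analogously for the MP
#' blood row (`Cs - x̄`, `ȳ - x̄`) and dialysate row (`0`, `x̄ - ȳ`). The
#' stacked system over all intervals of all series in the mode is solved by
#' global linear least squares and the solution seeds the nonlinear stage.
#'
#' @inheritParams rmse_objective
#' @param fixed optional named list overriding the fixed quantities
#'   (`Vb0`, `Vd0`, `Cs`, `Cd0`); defaults come from the measurement set
#'   (clinical `Vb0`, first blood measurement(s) for `Cs`).
#' @return Named vector `c(Ks, Kb)` (L/h); possibly outside the
#'   physiological bounds (the caller clips).
#' @export
linear_preestimate <- function(data, mode = c("SP", "MP", "CP"), fixed = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "measurement_set"))
  check_mode_data(data, mode)
  Cs <- fixed$Cs %||% switch(mode,
                             SP = data$sp$conc[1],
                             MP = data$mp$x[1],
                             CP = max(data$sp$conc[1], data$mp$x[1]))
  Vb0 <- fixed$Vb0 %||% data$Vb0_clinical
  Vd0 <- fixed$Vd0 %||% data$Vd0
  Cd0 <- fixed$Cd0 %||% data$Cd0
  if (!is.finite(Vb0))
    stop("linear pre-estimate needs a fixed Vb0 (clinical value missing)",
         call. = FALSE)
  A <- NULL; rhs <- NULL
  if (mode %in% c("SP", "CP")) {
    if (nrow(data$sp) < 2) stop("need >= 2 SP time points", call. = FALSE)
    z <- data$sp$conc; dt <- diff(data$sp$time); zbar <- (z[-1] + z[-length(z)]) / 2
    A <- rbind(A, cbind(Cs - zbar, Cd0 - zbar))
    rhs <- c(rhs, Vb0 * diff(z) / dt)
  }
  if (mode %in% c("MP", "CP")) {
    if (nrow(data$mp) < 2) stop("need >= 2 MP time points", call. = FALSE)
    x <- data$mp$x; y <- data$mp$y; dt <- diff(data$mp$time)
    xbar <- (x[-1] + x[-length(x)]) / 2
    ybar <- (y[-1] + y[-length(y)]) / 2
    A <- rbind(A, cbind(Cs - xbar, ybar - xbar), cbind(0, xbar - ybar))
    rhs <- c(rhs, Vb0 * diff(x) / dt, Vd0 * diff(y) / dt)
  }
  qrA <- qr(A)
  if (qrA$rank < 2L)
    stop("rank-deficient design: the measurements carry no information on ",
         "(Ks, Kb) (e.g. all samples at steady state)", call. = FALSE)
  est <- qr.coef(qrA, rhs)
  c(Ks = est[1], Kb = est[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# RSS with a large finite penalty where the model is unevaluable (e.g. the
# optimizer probing Kb = 0); keeps bounded quasi-Newton search well defined.
rss_safe <- function(theta_vec, names_, data, mode) {
  theta <- stats::setNames(theta_vec, names_)
  r <- tryCatch(mode_residuals(theta, data, mode), error = function(e) NULL)
  if (is.null(r) || any(!is.finite(r))) return(1e10)
  sum(r^2)
}

#' Bounded nonlinear least-squares fit
#'
#' Second stage of the pipeline: bounded local minimization (`nlminb`, a
#' quasi-Newton method with box constraints) of the residual sum of squares,
#' started from the [linear_preestimate()] rates, the first blood
#' measurement(s) for the initial concentrations, and the clinical volume
#' for `Vb0`. In CP mode `Ks`, `Kb`, `Vb0` are shared between both sessions
#' and `Cs = max(z0, x0)` is re-evaluated (exact, unsmoothed) at every
#' objective call. With `spec$multistart > 1` additional uniform random
#' starts inside the bounds are tried and the best optimum kept.
#' 95% confidence half-widths are attached via [confidence_intervals()].
#'
#' @inheritParams rmse_objective
#' @param spec a [fit_spec()].
#' @param start optional named start vector overriding the two-stage start
#'   (used by [multistart_robustness()]).
#' @return An object of class `"fit_result"`: estimates (including the
#'   implied `Cs`), `ci_halfwidth`, `rmse` (mmol/L), `d` (number of series),
#'   `n_total` residuals, `converged`, the `preestimate`, and optimizer
#'   diagnostics. Non-convergence is reported, not raised.
#' @examples
#' set.seed(1)
#' truth <- mp_params(Ks = 5, Kb = 8, Cs = 1.8, Vb0 = 15, Vd0 = 25)
#' ms <- simulate_patient(truth, Cd0 = 0.15, noise_sd = 0, seed = 1)
#' fit(ms, fit_spec("MP"))
#' @export
fit <- function(data, spec, start = NULL) {
  stopifnot(inherits(data, "measurement_set"), inherits(spec, "fit_spec"))
  mode <- spec$mode
  check_mode_data(data, mode)
  fp <- free_params(mode)
  lb <- spec$bounds$lower[fp]; ub <- spec$bounds$upper[fp]

  pre <- tryCatch(linear_preestimate(data, mode), error = function(e) NULL)
  start0 <- c(Ks = if (!is.null(pre)) pre[["Ks"]] else mean(c(lb["Ks"], ub["Ks"])),
              Kb = if (!is.null(pre)) pre[["Kb"]] else mean(c(lb["Kb"], ub["Kb"])))
  if ("Vb0" %in% fp)
    start0["Vb0"] <- if (is.finite(data$Vb0_clinical)) data$Vb0_clinical
                     else mean(c(lb["Vb0"], ub["Vb0"]))
  if ("z0" %in% fp) start0["z0"] <- data$sp$conc[1]
  if ("x0" %in% fp) start0["x0"] <- data$mp$x[1]
  start0 <- pmin(pmax(start0[fp], lb + 1e-8), ub - 1e-8)
  if (!is.null(start)) start0 <- pmin(pmax(unlist(start)[fp], lb), ub)

  evals_total <- 0L
  run1 <- function(s0) {
    r <- stats::nlminb(s0, rss_safe, lower = lb, upper = ub,
                       names_ = fp, data = data, mode = mode,
                       control = list(eval.max = 2000, iter.max = 1000,
                                      rel.tol = spec$rel_tol,
                                      x.tol = spec$x_tol, abs.tol = 0))
    evals_total <<- evals_total + r$evaluations[["function"]]
    r
  }
  best <- run1(start0)
  stage1_evals <- evals_total            # cost attributable to the start
  # polish: a restart at the optimum recovers the last digits the line search
  # leaves on the table (matters on (near-)zero-residual data)
  polish <- tryCatch(run1(best$par), error = function(e) NULL)
  if (!is.null(polish) && polish$objective <= best$objective) best <- polish
  # derivative-free polish: the CP objective is non-smooth on the z0 = x0
  # ridge (Cs = max(z0, x0), kept exact), where finite-difference gradients
  # stall; a short Nelder-Mead pass is kink-safe. Bounds enforced by clipping.
  nm_obj <- function(v) rss_safe(pmin(pmax(v, lb), ub), fp, data, mode)
  nm <- tryCatch(stats::optim(best$par, nm_obj, method = "Nelder-Mead",
                              control = list(maxit = 500, reltol = 1e-14)),
                 error = function(e) NULL)
  if (!is.null(nm) && nm$value <= best$objective) {
    best$par <- pmin(pmax(nm$par, lb), ub)
    best$objective <- nm$value
    evals_total <- evals_total + nm$counts[["function"]]
  }
  n_extra <- max(0L, spec$multistart - 1L)
  if (n_extra > 0L) {
    set.seed(spec$seed)
    for (i in seq_len(n_extra)) {
      s <- stats::setNames(stats::runif(length(fp), lb, ub), fp)
      cand <- tryCatch(run1(s), error = function(e) NULL)
      if (!is.null(cand) && cand$objective < best$objective) best <- cand
    }
  }

  theta <- stats::setNames(best$par, fp)
  n_tot <- n_residuals(data, mode)
  d <- switch(mode, SP = 1L, MP = 2L, CP = 3L)
  Cs <- switch(mode, SP = theta[["z0"]], MP = theta[["x0"]],
               CP = max(theta[["z0"]], theta[["x0"]]))
  res <- structure(list(
    mode = mode, patient_id = data$patient_id,
    estimates = c(theta, Cs = Cs),
    free = fp,
    ci_halfwidth = stats::setNames(rep(NA_real_, length(fp)), fp),
    rmse = sqrt(best$objective / n_tot),
    d = d, n_total = n_tot,
    converged = best$convergence == 0,
    message = best$message,
    preestimate = pre,
    objective_evals = evals_total,
    stage1_evals = stage1_evals),
    class = "fit_result")
  res$ci_halfwidth <- confidence_intervals(res, data, spec)
  res
}

# Central finite-difference Hessian of fn at x (O(h^2) stencil).
fd_hessian <- function(fn, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- 1e-4 * (abs(x) + 1e-2)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Hessian-based 95% confidence half-widths
#'
#' Gauss-Markov linearization at the optimum: with `H` the (finite
#' difference) Hessian of the residual sum of squares and
#' \eqn{s^2 = RSS/(n - p)} the residual-variance estimate, the parameter
#' covariance is \eqn{2 s^2 H^{-1}} (for RSS, \eqn{H \approx 2 J^T J}, so
#' this is the familiar \eqn{s^2 (J^T J)^{-1}}), and the half-widths are
#' \eqn{1.96\sqrt{\mathrm{diag}}}. A singular or indefinite Hessian —
#' the signature of a practically non-identifiable parameter, as happens
#' for `Vb0` in SP-only fits — yields `Inf` half-widths with a warning.
#'
#' @param result a `"fit_result"`.
#' @inheritParams rmse_objective
#' @param spec the [fit_spec()] used.
#' @return Named vector of 95% half-widths for the free parameters.
#' @export
confidence_intervals <- function(result, data, spec) {
  stopifnot(inherits(result, "fit_result"))
  fp <- result$free
  theta <- result$estimates[fp]
  rss_fn <- function(v) rss_safe(v, fp, data, spec$mode)
  rss <- rss_fn(theta)
  dof <- result$n_total - length(fp)
  if (dof <= 0) {
    warning("no residual degrees of freedom; CIs undefined")
    return(stats::setNames(rep(Inf, length(fp)), fp))
  }
  s2 <- rss / dof
  H <- fd_hessian(rss_fn, theta)
  cov <- tryCatch(2 * s2 * solve(H), error = function(e) NULL)
  if (is.null(cov)) {
    warning("singular Hessian: parameters not practically identifiable; ",
            "half-widths reported as Inf")
    return(stats::setNames(rep(Inf, length(fp)), fp))
  }
  v <- diag(cov)
  bad <- !is.finite(v) | v < 0
  if (any(bad))
    warning("non-positive Hessian curvature for ",
            paste(fp[bad], collapse = ", "),
            ": half-widths reported as Inf")
  hw <- ifelse(bad, Inf, 1.96 * sqrt(pmax(v, 0)))
  stats::setNames(hw, fp)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit, patient %s: %s (RMSE %.4g mmol/L, %d residuals in %d series)\n",
              x$mode, x$patient_id,
              if (x$converged) "converged" else "NOT converged",
              x$rmse, x$n_total, x$d))
  est <- x$estimates[x$free]
  ci <- x$ci_halfwidth[x$free]
  for (nm in x$free)
    cat(sprintf("  %-4s = %8.4f +/- %.4f\n", nm, est[[nm]], ci[[nm]]))
  cat(sprintf("  Cs   = %8.4f (implied)\n", x$estimates[["Cs"]]))
  invisible(x)
}

#' Multistart robustness report
#'
#' Runs [fit()] from `n_starts` independent uniform draws inside the
#' physiological bounds and clusters the resulting optima at relative
#' tolerance 1e-4 (on the free-parameter vectors). A single cluster
#' indicates the two-stage estimate is a robust (practically global)
#' optimum.
#'
#' @inheritParams rmse_objective
#' @param spec a [fit_spec()].
#' @param n_starts number of random starts (`>= 1`).
#' @param seed integer seed for the draws.
#' @return List: `best` fit, `n_clusters`, `relative_spread` (max relative
#'   deviation of any optimum from the best), `n_failed`, and the matrix
#'   `optima` (one row per successful start).
#' @export
multistart_robustness <- function(data, spec, n_starts = 20L, seed = 1L) {
  stopifnot(n_starts >= 1)
  fp <- free_params(spec$mode)
  lb <- spec$bounds$lower[fp]; ub <- spec$bounds$upper[fp]
  set.seed(seed)
  # start 1 is the deterministic two-stage start (n_starts = 1 == plain fit);
  # the remainder are uniform draws inside the bounds
  starts <- c(list(NULL),
              lapply(seq_len(n_starts - 1L), function(i)
                stats::setNames(stats::runif(length(fp), lb, ub), fp)))
  fits <- lapply(starts, function(s)
    tryCatch(fit(data, spec, start = s), error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all multistart fits failed", call. = FALSE)
  optima <- t(vapply(fits[ok], function(f) f$estimates[fp], numeric(length(fp))))
  objs <- vapply(fits[ok], function(f) f$rmse, numeric(1))
  best <- fits[ok][[which.min(objs)]]
  ref <- best$estimates[fp]
  reldist <- apply(optima, 1L, function(r) max(abs(r - ref) / (abs(ref) + 1e-8)))
  # single-linkage-lite: optima within 1e-4 of an existing representative join it
  reps <- list()
  for (i in seq_len(nrow(optima))) {
    hit <- FALSE
    for (r in reps)
      if (max(abs(optima[i, ] - r) / (abs(r) + 1e-8)) < 1e-4) { hit <- TRUE; break }
    if (!hit) reps[[length(reps) + 1L]] <- optima[i, ]
  }
  list(best = best, n_clusters = length(reps),
       relative_spread = max(reldist), n_failed = sum(!ok),
       optima = optima)
}
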