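# CSV schemas (comma separator, UTF-8, period decimal, header required):
#
# measurements: patient_id, modality (SP|MP), series (blood|dialysate),
#               time_h, concentration_mmol_L  -- one row per sample
# constants:    patient_id, Cd0_mmol_L, Vd0_L, Vb0_L -- one row per patient

#' Read a measurement table into per-patient measurement sets
#'
#' Parses and validates the measurement CSV schema (columns `patient_id`,
#' `modality` in SP/MP, `series` in blood/dialysate, `time_h`,
#' `concentration_mmol_L`), optionally joins a per-patient constants table
#' (`patient_id`, `Cd0_mmol_L`, `Vd0_L`, `Vb0_L`), and returns validated,
#' time-sorted [measurement_set()]s. Parsing is order independent; schema
#' violations are reported with the offending row.
#'
#' @param path measurement CSV.
#' @param constants_path optional constants CSV; required for fitting (it
#'   carries `Cd0`, `Vd0`, `Vb0_clinical`).
#' @return Named list of [measurement_set()], one per patient.
#' @export
read_measurements <- function(path, constants_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "modality", "series", "time_h", "concentration_mmol_L")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("measurement table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!df$modality %in% c("SP", "MP"))
  if (length(bad))
    stop("row ", bad[1], ": modality must be SP or MP (got '",
         df$modality[bad[1]], "')", call. = FALSE)
  bad <- which(!df$series %in% c("blood", "dialysate"))
  if (length(bad))
    stop("row ", bad[1], ": series must be blood or dialysate", call. = FALSE)
  bad <- which(df$modality == "SP" & df$series == "dialysate")
  if (length(bad))
    stop("row ", bad[1], ": SP has no dialysate series", call. = FALSE)
  df$time_h <- as.numeric(df$time_h)
  df$concentration_mmol_L <- as.numeric(df$concentration_mmol_L)
  bad <- which(!is.finite(df$time_h) | df$time_h < 0)
  if (length(bad))
    stop("row ", bad[1], ", column time_h: must be a finite nonnegative number",
         call. = FALSE)
  bad <- which(!is.finite(df$concentration_mmol_L) | df$concentration_mmol_L < 0)
  if (length(bad))
    stop("row ", bad[1], ", column concentration_mmol_L: must be a finite ",
         "nonnegative number", call. = FALSE)
  key <- paste(df$patient_id, df$modality, df$series, df$time_h)
  if (anyDuplicated(key))
    stop("row ", which(duplicated(key))[1],
         ": duplicate (patient, modality, series, time)", call. = FALSE)

  consts <- if (!is.null(constants_path)) read_patient_constants(constants_path)

  out <- lapply(split(df, df$patient_id), function(d) {
    pid <- d$patient_id[1]
    sp <- NULL; mp <- NULL
    dsp <- d[d$modality == "SP", ]
    if (nrow(dsp))
      sp <- data.frame(time = dsp$time_h, conc = dsp$concentration_mmol_L)
    dmp <- d[d$modality == "MP", ]
    if (nrow(dmp)) {
      b <- dmp[dmp$series == "blood", ]
      y <- dmp[dmp$series == "dialysate", ]
      b <- b[order(b$time_h), ]; y <- y[order(y$time_h), ]
      if (nrow(b) != nrow(y) || !isTRUE(all.equal(b$time_h, y$time_h)))
        stop("patient ", pid, ": MP blood and dialysate series must share ",
             "the same time grid", call. = FALSE)
      mp <- data.frame(time = b$time_h, x = b$concentration_mmol_L,
                       y = y$concentration_mmol_L)
    }
    cc <- if (!is.null(consts)) consts[consts$patient_id == pid, ]
    if (!is.null(cc) && nrow(cc) == 0)
      stop("patient ", pid, " missing from constants table", call. = FALSE)
    measurement_set(pid, sp = sp, mp = mp,
                    Cd0 = if (!is.null(cc)) cc$Cd0_mmol_L else NA_real_,
                    Vd0 = if (!is.null(cc)) cc$Vd0_L else NA_real_,
                    Vb0_clinical = if (!is.null(cc)) cc$Vb0_L else NA_real_)
  })
  out
}

#' Read the per-patient constants table
#'
#' @param path CSV with columns `patient_id`, `Cd0_mmol_L`, `Vd0_L`, `Vb0_L`.
#' @return A data frame, one row per patient.
#' @export
read_patient_constants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "Cd0_mmol_L", "Vd0_L", "Vb0_L")
  miss <- setdiff(need, names(cc))
  if (length(miss))
    stop("constants table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cc$patient_id))
    stop("constants table: duplicated patient_id", call. = FALSE)
  if (any(!is.finite(cc$Vd0_L) | cc$Vd0_L <= 0) ||
      any(!is.finite(cc$Vb0_L) | cc$Vb0_L <= 0))
    stop("constants table: volumes must be positive", call. = FALSE)
  cc$patient_id <- as.character(cc$patient_id)
  cc
}

#' Write measurement sets to the measurement-table schema
#'
#' @param sets a [measurement_set()] or list of them.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(sets, path) {
  if (inherits(sets, "measurement_set")) sets <- list(sets)
  rows <- do.call(rbind, lapply(sets, function(ms) {
    r <- NULL
    if (!is.null(ms$sp))
      r <- rbind(r, data.frame(patient_id = ms$patient_id, modality = "SP",
                               series = "blood", time_h = ms$sp$time,
                               concentration_mmol_L = ms$sp$conc))
    if (!is.null(ms$mp))
      r <- rbind(r,
                 data.frame(patient_id = ms$patient_id, modality = "MP",
                            series = "blood", time_h = ms$mp$time,
                            concentration_mmol_L = ms$mp$x),
                 data.frame(patient_id = ms$patient_id, modality = "MP",
                            series = "dialysate", time_h = ms$mp$time,
                            concentration_mmol_L = ms$mp$y))
    r
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the per-patient constants table
#'
#' @param sets a [measurement_set()] or list of them.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_patient_constants <- function(sets, path) {
  if (inherits(sets, "measurement_set")) sets <- list(sets)
  cc <- do.call(rbind, lapply(sets, function(ms)
    data.frame(patient_id = ms$patient_id, Cd0_mmol_L = ms$Cd0,
               Vd0_L = ms$Vd0, Vb0_L = ms$Vb0_clinical)))
  utils::write.csv(cc, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tabulate fit results in the published-table layout
#'
#' One row per patient with estimate and 95% half-width columns for each
#' free parameter, the implied `Cs`, and the RMSE — the layout of the
#' study's per-modality results tables.
#'
#' @param results a `"fit_result"` or list of them (same mode).
#' @return A data frame.
#' @export
fit_table <- function(results) {
  if (inherits(results, "fit_result")) results <- list(results)
  do.call(rbind, lapply(results, function(f) {
    row <- data.frame(patient_id = f$patient_id, mode = f$mode,
                      Cs = unname(f$estimates[["Cs"]]))
    for (nm in f$free) {
      row[[nm]] <- unname(f$estimates[[nm]])
      row[[paste0(nm, "_ci95")]] <- unname(f$ci_halfwidth[[nm]])
    }
    row$rmse <- f$rmse
    row$converged <- f$converged
    row
  }))
}
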