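#' Simulate the aggregate model
#'
#' Integrates the five-state delay system with a fixed-step 4th-order
#' Runge-Kutta scheme. Delays are fixed time lags served from a history
#' buffer recorded at every integration step, with linear interpolation for
#' off-grid lookups: glucose appearance in plasma replays the gastric
#' outflow flux from `T_lag_SP` minutes earlier (zero before the lag has
#' elapsed), and the insulin signal is the plasma insulin concentration
#' from `T_lag_IS` minutes earlier (`iIs` before the lag). The Z-schedule
#' is looked up at every Runge-Kutta stage time on half-open intervals.
#'
#' By default the *whole outflow flux* `k_SP(t') * Gl_S(t')` at the past
#' time `t' = t - T_lag_SP` is replayed, which makes glucose appearance an
#' exact time-shift of gastric outflow and conserves hexose mass even when
#' the outflow code switches inside the lag window. Setting
#' `lag_outflux = FALSE` selects the alternative convention
#' `k_SP(t) * Gl_S(t - T_lag_SP)` for robustness checks.
#'
#' @param params a [model_parameters()] object.
#' @param z a [z_schedule()].
#' @param horizon simulation length, min (default 420).
#' @param dt integration step, min (default 0.002).
#' @param report_every reporting grid spacing, min (default 1); must be a
#'   multiple of `dt`.
#' @param lag_outflux logical; see Details.
#' @return A `gi_trajectory`: a data frame with one row per reported time
#'   and columns `time_min`, the five state masses (`AcS_mg`, `AcP_mg`,
#'   `GlS_mmol`, `GlP_mmol`, `InP_ug`), the concentrations
#'   (`cAcP_mg_per_L`, `cGlP_mM`, `cInP_ug_per_L`), the fluxes
#'   (`PGlex_mmol_per_min`, `UGl_mmol_per_min`, `PIn_ug_per_min`,
#'   `UIn_ug_per_min`), the insulin signal `Is_ug_per_L`, and the
#'   cumulative exogenous glucose appearance `cumPGlex_mmol`.
#' @examples
#' ref <- reference_animal()
#' traj <- simulate_gi(ref$params, ref$z, dt = 0.01)
#' auc(traj, "glucose")
#' @export
simulate_gi <- function(params, z, horizon = 420, dt = 0.002,
                        report_every = 1, lag_outflux = TRUE) {
  stopifnot(inherits(z, "z_schedule"))
  validate_parameters(params)
  if (dt <= 0) stop("dt must be > 0")
  if (horizon < 0) stop("horizon must be >= 0")
  if (abs(report_every / dt - round(report_every / dt)) > 1e-8)
    stop("report_every must be a multiple of dt")
  res <- .sim_core_cpp(.sim_param_vector(params), z$breakpoints,
                       z$values, horizon, dt, report_every, lag_outflux)
  if (res$status != 0)
    stop("simulation failed at t = ", format(res$fail_time),
         " min: state became negative or non-finite ",
         "(pathological parameter set; no clamping is applied)")
  m <- res$mat
  colnames(m) <- c("time_min", "AcS_mg", "AcP_mg", "GlS_mmol", "GlP_mmol",
                   "InP_ug", "cAcP_mg_per_L", "cGlP_mM", "cInP_ug_per_L",
                   "PGlex_mmol_per_min", "UGl_mmol_per_min",
                   "PIn_ug_per_min", "UIn_ug_per_min", "Is_ug_per_L",
                   "cumPGlex_mmol")
  traj <- as.data.frame(m)
  attr(traj, "params") <- params
  attr(traj, "z") <- z
  attr(traj, "dt") <- dt
  attr(traj, "lag_outflux") <- lag_outflux
  class(traj) <- c("gi_trajectory", "data.frame")
  traj
}

.analyte_column <- function(analyte) {
  switch(match.arg(analyte, c("glucose", "insulin", "acetaminophen")),
         glucose = "cGlP_mM",
         insulin = "cInP_ug_per_L",
         acetaminophen = "cAcP_mg_per_L")
}

#' Area under a trajectory concentration curve
#'
#' Trapezoidal integral of the reported concentration grid between `t0` and
#' `t1`. In `"incremental"` mode the t = 0 concentration is subtracted
#' before integrating (so excursions below baseline contribute negatively).
#'
#' @param traj a [simulate_gi()] trajectory.
#' @param analyte one of `"glucose"`, `"insulin"`, `"acetaminophen"`.
#' @param t0,t1 integration window, min; must lie within the trajectory.
#' @param mode `"total"` or `"incremental"`.
#' @return AUC in concentration x min units (mM min, ug/L min, mg/L min).
#' @export
auc <- function(traj, analyte = c("glucose", "insulin", "acetaminophen"),
                t0 = 0, t1 = max(traj$time_min),
                mode = c("total", "incremental")) {
  mode <- match.arg(mode)
  col <- .analyte_column(analyte)
  if (t0 >= t1) stop("need t0 < t1")
  if (t0 < min(traj$time_min) - 1e-9 || t1 > max(traj$time_min) + 1e-9)
    stop("[t0, t1] outside the trajectory span")
  sel <- traj$time_min >= t0 - 1e-9 & traj$time_min <= t1 + 1e-9
  tt <- traj$time_min[sel]
  y <- traj[[col]][sel]
  if (mode == "incremental") y <- y - traj[[col]][1]
  sum(diff(tt) * (y[-1] + y[-length(y)]) / 2)
}

#' Count local maxima of a trajectory concentration curve
#'
#' Strict interior local maxima of the reported series, ignoring wiggles
#' smaller than `tol` (a point counts as a peak if it exceeds the running
#' minimum since the previous peak, and the subsequent running maximum,
#' by more than `tol`). Used to check the multi-peak postprandial pattern.
#'
#' @param traj a [simulate_gi()] trajectory.
#' @param analyte one of `"glucose"`, `"insulin"`, `"acetaminophen"`.
#' @param tol minimum rise/fall to count a peak (default 1e-6 in the
#'   analyte's concentration unit).
#' @return Integer number of peaks.
#' @export
count_peaks <- function(traj, analyte, tol = 1e-6) {
  y <- traj[[.analyte_column(analyte)]]
  n <- length(y)
  peaks <- 0L
  i <- 1L
  # walk the series alternating between rising and falling phases of
  # amplitude > tol
  last_ext <- y[1]
  rising <- NA
  for (j in 2:n) {
    if (is.na(rising)) {
      if (y[j] > last_ext + tol) { rising <- TRUE; last_ext <- y[j] }
      else if (y[j] < last_ext - tol) { rising <- FALSE; last_ext <- y[j] }
    } else if (rising) {
      if (y[j] > last_ext) last_ext <- y[j]
      else if (y[j] < last_ext - tol) {
        peaks <- peaks + 1L
        rising <- FALSE
        last_ext <- y[j]
      }
    } else {
      if (y[j] < last_ext) last_ext <- y[j]
      else if (y[j] > last_ext + tol) { rising <- TRUE; last_ext <- y[j] }
    }
  }
  peaks
}

#' @export
print.gi_trajectory <- function(x, ...) {
  cat("<gi_trajectory> ", nrow(x), " reported points over [",
      x$time_min[1], ", ", x$time_min[nrow(x)], "] min (dt = ",
      attr(x, "dt"), ")\n", sep = "")
  utils::str(utils::head(as.data.frame(x), 3))
  invisible(x)
}

#' Export a trajectory as tidy CSV
#'
#' Writes the reported grid with all state, concentration and flux columns.
#'
#' @param traj a [simulate_gi()] trajectory.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
export_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
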