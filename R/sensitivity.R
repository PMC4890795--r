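#' AUC sensitivity coefficient of one parameter
#'
#' Perturbs a parameter to `factors[1]` x and `factors[2]` x its reference
#' value (default 0.5x and 1.5x), re-derives the basal steady-state
#' constraints as required, simulates the 420-min response for each
#' setting and returns the sensitivity coefficient of the glucose and
#' insulin areas under the curve:
#'
#' `SC = | (AUC(1.5x) - AUC(0.5x)) / AUC(1.5x) | / ((1.5 - 0.5) / 1.5)`
#'
#' i.e. the fractional change in AUC relative to the fractional change in
#' parameter value. The axis `"k_SP"` scales `k_SP2` and `k_SP3` jointly
#' (constant ratio).
#'
#' Two conventions are under-specified upstream and therefore exposed:
#' `auc_mode` (`"total"` integrates the concentration itself,
#' `"incremental"` subtracts the basal concentration first) and
#' `k_in_uin_mode` (`"derived"` re-derives `k_In_UIn` and `iPGl_end` from
#' the basal steady state for every run including the reference;
#' `"table"` keeps the stored values except where the perturbed parameter
#' forces a re-derivation: `k_In_UIn` when `V_PIn`, `K_Gl_PIn` or
#' `exp_PIn` is perturbed, `iPGl_end` when `k_Gl_UGl` or `k_Is_UGl` is).
#'
#' @param param_name one of `"k_SP"`, `"k_Gl_UGl"`, `"k_Is_UGl"`,
#'   `"T_lag_SP"`, `"T_lag_IS"`, `"V_PIn"`, `"K_Gl_PIn"`, `"exp_PIn"`.
#' @param params reference [model_parameters()].
#' @param z a [z_schedule()].
#' @param auc_mode `"total"` or `"incremental"`.
#' @param k_in_uin_mode `"derived"` or `"table"`.
#' @param factors length-2 perturbation multipliers (low, high).
#' @param horizon,dt,report_every passed to [simulate_gi()].
#' @return A `sensitivity_result`: list with `parameter`, `SC_Gl`,
#'   `SC_In`, `AUC_Gl_lo/hi`, `AUC_In_lo/hi`, and the convention record.
#' @export
sensitivity_coefficient <- function(param_name, params, z,
                                    auc_mode = c("total", "incremental"),
                                    k_in_uin_mode = c("derived", "table"),
                                    factors = c(0.5, 1.5),
                                    horizon = 420, dt = 0.002,
                                    report_every = 1) {
  valid <- c("k_SP", "k_Gl_UGl", "k_Is_UGl", "T_lag_SP", "T_lag_IS",
             "V_PIn", "K_Gl_PIn", "exp_PIn")
  if (!param_name %in% valid)
    stop("unknown parameter '", param_name, "'; valid names: ",
         paste(valid, collapse = ", "))
  auc_mode <- match.arg(auc_mode)
  k_in_uin_mode <- match.arg(k_in_uin_mode)
  if (length(factors) != 2 || any(factors <= 0))
    stop("factors must be two positive multipliers")

  run_auc <- function(f) {
    p <- params
    if (param_name == "k_SP") {
      p <- update_parameters(p, k_SP2 = f * p$k_SP2, k_SP3 = f * p$k_SP3)
    } else {
      p <- do.call(update_parameters,
                   c(list(p), stats::setNames(list(f * p[[param_name]]),
                                              param_name)))
    }
    if (k_in_uin_mode == "derived") {
      p <- apply_steady_state(p, k_in_uin = TRUE, ipgl_end = TRUE)
    } else {
      if (param_name %in% c("V_PIn", "K_Gl_PIn", "exp_PIn"))
        p <- update_parameters(p, k_In_UIn = steady_state_k_in_uin(p))
      if (param_name %in% c("k_Gl_UGl", "k_Is_UGl"))
        p <- update_parameters(p, iPGl_end = steady_state_ipgl_end(p))
    }
    traj <- simulate_gi(p, z, horizon = horizon, dt = dt,
                        report_every = report_every)
    c(gl = auc(traj, "glucose", mode = auc_mode),
      ins = auc(traj, "insulin", mode = auc_mode))
  }

  lo <- run_auc(factors[1])
  hi <- run_auc(factors[2])
  denom <- (factors[2] - factors[1]) / factors[2]
  sc <- function(a_lo, a_hi) {
    if (a_hi == a_lo) return(0)
    unname(abs((a_hi - a_lo) / a_hi) / denom)
  }
  structure(list(parameter = param_name,
                 SC_Gl = sc(lo["gl"], hi["gl"]),
                 SC_In = sc(lo["ins"], hi["ins"]),
                 AUC_Gl_lo = unname(lo["gl"]), AUC_Gl_hi = unname(hi["gl"]),
                 AUC_In_lo = unname(lo["ins"]), AUC_In_hi = unname(hi["ins"]),
                 auc_mode = auc_mode, k_in_uin_mode = k_in_uin_mode,
                 factors = factors),
            class = "sensitivity_result")
}

#' Full parameter sensitivity table
#'
#' Computes the AUC sensitivity coefficient of all eight parameter axes on
#' the reference settings and returns them sorted from highest to lowest
#' influence on the glucose AUC.
#'
#' @inheritParams sensitivity_coefficient
#' @return A `sensitivity_table`: a data frame with columns `parameter`,
#'   `SC_Gl`, `SC_In` (one row per axis, SC_Gl descending) and the AUC
#'   columns; conventions recorded as attributes.
#' @export
sensitivity_table <- function(params, z,
                              auc_mode = c("total", "incremental"),
                              k_in_uin_mode = c("derived", "table"),
                              factors = c(0.5, 1.5),
                              horizon = 420, dt = 0.002,
                              report_every = 1) {
  auc_mode <- match.arg(auc_mode)
  k_in_uin_mode <- match.arg(k_in_uin_mode)
  axes <- c("k_SP", "k_Gl_UGl", "k_Is_UGl", "T_lag_SP", "T_lag_IS",
            "V_PIn", "K_Gl_PIn", "exp_PIn")
  rows <- lapply(axes, function(a)
    sensitivity_coefficient(a, params, z, auc_mode = auc_mode,
                            k_in_uin_mode = k_in_uin_mode,
                            factors = factors, horizon = horizon,
                            dt = dt, report_every = report_every))
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(parameter = r$parameter, SC_Gl = r$SC_Gl, SC_In = r$SC_In,
               AUC_Gl_lo = r$AUC_Gl_lo, AUC_Gl_hi = r$AUC_Gl_hi,
               AUC_In_lo = r$AUC_In_lo, AUC_In_hi = r$AUC_In_hi)))
  df <- df[order(-df$SC_Gl), ]
  rownames(df) <- NULL
  attr(df, "auc_mode") <- auc_mode
  attr(df, "k_in_uin_mode") <- k_in_uin_mode
  attr(df, "factors") <- factors
  class(df) <- c("sensitivity_table", "data.frame")
  df
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat("<sensitivity_table> AUC mode:", attr(x, "auc_mode"),
      "| k_In_UIn:", attr(x, "k_in_uin_mode"), "\n")
  print(data.frame(parameter = x$parameter,
                   SC_glucose = sprintf("%.3f", x$SC_Gl),
                   SC_insulin = sprintf("%.3f", x$SC_In)))
  invisible(x)
}
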