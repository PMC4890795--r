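#' Model state
#'
#' The five state masses of the aggregate model at one time point: stomach
#' and plasma acetaminophen (mg), stomach and plasma glucose (mmol), and
#' plasma insulin (ug).
#'
#' @param t time since the meal, min.
#' @param Ac_S,Ac_P stomach / plasma acetaminophen mass, mg.
#' @param Gl_S,Gl_P stomach / plasma glucose mass, mmol.
#' @param In_P plasma insulin mass, ug.
#' @return An object of class `gi_state`.
#' @export
model_state <- function(t = 0, Ac_S = 0, Ac_P = 0, Gl_S = 0, Gl_P = 0,
                        In_P = 0) {
  s <- list(t = t, Ac_S = Ac_S, Ac_P = Ac_P, Gl_S = Gl_S, Gl_P = Gl_P,
            In_P = In_P)
  if (any(unlist(s[-1]) < 0)) stop("state masses must be >= 0")
  structure(s, class = "gi_state")
}

#' Initial state implied by a parameter set
#'
#' Dose delivery is instantaneous at t = 0: the stomach starts with the full
#' acetaminophen dose and meal hexose load, plasma with the basal masses.
#'
#' @param params a [model_parameters()] object.
#' @return A `gi_state`.
#' @export
initial_state <- function(params) {
  model_state(t = 0, Ac_S = params$iAc_S, Ac_P = params$iAc_P,
              Gl_S = params$iGl_S, Gl_P = params$iGl_P,
              In_P = params$iIn_P)
}

#' Plasma concentrations from state masses
#'
#' Concentrations are masses divided by fixed volumes of distribution:
#' `vd_Ac * BW` litres for acetaminophen (0.9 L/kg) and `vd_GlIn * BW`
#' litres for glucose and insulin (0.251 L/kg).
#'
#' @param state a [model_state()].
#' @param params a [model_parameters()] object.
#' @return Named list with `cAc_P` (mg/L), `cGl_P` (mM), `cIn_P` (ug/L).
#' @export
concentrations <- function(state, params) {
  list(cAc_P = state$Ac_P / (params$vd_Ac * params$BW),
       cGl_P = state$Gl_P / (params$vd_GlIn * params$BW),
       cIn_P = state$In_P / (params$vd_GlIn * params$BW))
}

#' Hill-equation pancreatic insulin secretion
#'
#' `PIn = V_PIn / (1 + (K_Gl_PIn / cGl_P)^exp_PIn)`, returning 0 at
#' `cGl_P <= 0` (the continuous limit), monotone increasing in `cGl_P` and
#' bounded above by `V_PIn`.
#'
#' @param cGl_P plasma glucose concentration, mM.
#' @param params a [model_parameters()] object.
#' @return Secretion rate, ug/min.
#' @export
insulin_secretion <- function(cGl_P, params) {
  ifelse(cGl_P <= 0, 0,
         params$V_PIn / (1 + (params$K_Gl_PIn / cGl_P)^params$exp_PIn))
}

#' Instantaneous model fluxes
#'
#' Evaluates all mass fluxes of the model at a state, given the current
#' gastric-outflow code and the two delayed quantities, which the caller
#' (normally the simulator, which owns the history) must supply: the gastric
#' glucose outflow flux from `T_lag_SP` minutes ago (0 before the lag has
#' elapsed) and the plasma insulin concentration from `T_lag_IS` minutes ago
#' (`iIs` before the lag). This function is pure: it contains no integration
#' or history logic.
#'
#' @param state a [model_state()].
#' @param z_code gastric-outflow code in `{0, 1, 2}`.
#' @param lagged_PGl_ex gastric glucose outflow flux at `t - T_lag_SP`,
#'   mmol/min.
#' @param lagged_cIn_P plasma insulin concentration at `t - T_lag_IS`, ug/L.
#' @param params a [model_parameters()] object.
#' @return Named list of fluxes: `dAcS`, `dAcP` (mg/min); `PGl_ex`,
#'   `PGl_end`, `UGl`, `dGlS`, `dGlP` (mmol/min); `PIn`, `UIn`, `dInP`
#'   (ug/min); `Is` (ug/L); and the concentrations `cAc_P`, `cGl_P`,
#'   `cIn_P`.
#' @export
model_fluxes <- function(state, z_code, lagged_PGl_ex, lagged_cIn_P,
                         params) {
  k <- emptying_rate(z_code, params)
  cc <- concentrations(state, params)
  Is <- lagged_cIn_P
  UGl <- params$k_Gl_UGl * cc$cGl_P + params$k_Is_UGl * Is * cc$cGl_P
  PIn <- insulin_secretion(cc$cGl_P, params)
  UIn <- params$k_In_UIn * cc$cIn_P
  list(dAcS = -k * state$Ac_S,
       dAcP = k * state$Ac_S - params$k_Ac_UAc * state$Ac_P,
       dGlS = -k * state$Gl_S,
       PGl_ex = lagged_PGl_ex,
       PGl_end = params$iPGl_end,
       UGl = UGl,
       dGlP = lagged_PGl_ex + params$iPGl_end - UGl,
       PIn = PIn,
       UIn = UIn,
       dInP = PIn - UIn,
       Is = Is,
       cAc_P = cc$cAc_P, cGl_P = cc$cGl_P, cIn_P = cc$cIn_P)
}

#' Steady-state insulin utilization constant
#'
#' The first-order insulin utilization constant that makes the plasma
#' insulin balance vanish at the basal state: basal secretion (Hill
#' equation at basal glucose) divided by basal insulin concentration,
#'
#' `k_In_UIn = V_PIn / (iIn_P / (vd_GlIn*BW)) /
#'             (1 + (K_Gl_PIn / (iGl_P / (vd_GlIn*BW)))^exp_PIn)`.
#'
#' @param params a [model_parameters()] object with `iIn_P > 0`.
#' @return k_In_UIn, L/min.
#' @export
steady_state_k_in_uin <- function(params) {
  if (params$iIn_P <= 0)
    stop("steady-state k_In_UIn undefined: iIn_P must be > 0")
  vol <- params$vd_GlIn * params$BW
  cIn0 <- params$iIn_P / vol
  cGl0 <- params$iGl_P / vol
  insulin_secretion(cGl0, params) / cIn0
}

#' Steady-state endogenous glucose production
#'
#' The zero-order endogenous production that makes the plasma glucose
#' balance vanish at the basal state (pre-meal, no exogenous appearance):
#'
#' `iPGl_end = k_Gl_UGl * cGl0 + k_Is_UGl * cIn0 * cGl0`
#'
#' with `cGl0 = iGl_P / (vd_GlIn*BW)` and `cIn0 = iIn_P / (vd_GlIn*BW)`.
#'
#' @param params a [model_parameters()] object.
#' @return iPGl_end, mmol/min.
#' @export
steady_state_ipgl_end <- function(params) {
  vol <- params$vd_GlIn * params$BW
  cGl0 <- params$iGl_P / vol
  cIn0 <- params$iIn_P / vol
  params$k_Gl_UGl * cGl0 + params$k_Is_UGl * cIn0 * cGl0
}

#' Apply the basal steady-state constraints to a parameter set
#'
#' Replaces `k_In_UIn` and/or `iPGl_end` with the values derived from the
#' basal state, so that the glucose and insulin balances are exactly zero at
#' t = 0 and the post-prandial response starts from a steady pre-prandial
#' state. `iIs` is also reset to the basal insulin concentration
#' `iIn_P / (vd_GlIn*BW)`.
#'
#' @param params a [model_parameters()] object.
#' @param k_in_uin,ipgl_end logical: derive that constant?
#' @return A `gi_params` object.
#' @export
apply_steady_state <- function(params, k_in_uin = TRUE, ipgl_end = TRUE) {
  if (k_in_uin)
    params <- update_parameters(params,
                                k_In_UIn = steady_state_k_in_uin(params))
  if (ipgl_end)
    params <- update_parameters(params,
                                iPGl_end = steady_state_ipgl_end(params))
  update_parameters(params,
                    iIs = params$iIn_P / (params$vd_GlIn * params$BW))
}
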