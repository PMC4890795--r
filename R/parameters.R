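#' Model parameter set
#'
#' Constructs and validates the full parameter set of the aggregate
#' gastric-emptying / glucose-insulin model: the animal description (body
#' weight, basal masses, meal and marker doses), the acetaminophen marker
#' subsystem, the minimal-model glucose disposal constants, the
#' Hill-equation insulin secretion constants, the two fixed time lags, and
#' the volume-of-distribution coefficients.
#'
#' Units are fixed package-wide: time in min, acetaminophen in mg, glucose
#' in mmol, insulin in ug, volumes in L, body weight in kg, concentrations
#' in mg/L, mmol/L (mM) and ug/L respectively.
#'
#' @param BW body weight, kg.
#' @param iAc_S oral acetaminophen dose placed in the stomach at t = 0, mg.
#' @param iAc_P basal plasma acetaminophen mass, mg.
#' @param iGl_S meal hexose-equivalent load entering the stomach, mmol.
#' @param iGl_P basal plasma glucose mass, mmol.
#' @param iIn_P basal plasma insulin mass, ug.
#' @param iIs basal insulin signal, ug/L (the pre-lag value of the delayed
#'   insulin signal; at basal steady state it equals `iIn_P / (vd_GlIn*BW)`).
#' @param k_SP2 slow gastric-emptying rate constant, 1/min.
#' @param k_SP3 fast gastric-emptying rate constant, 1/min; must be at
#'   least `k_SP2`.
#' @param k_Ac_UAc first-order acetaminophen elimination constant, 1/min.
#' @param k_Gl_UGl glucose-effectiveness constant, L/min.
#' @param k_Is_UGl insulin-sensitivity constant, L^2/(ug min).
#' @param iPGl_end zero-order endogenous glucose production, mmol/min.
#' @param T_lag_SP stomach-to-plasma glucose absorption lag, min.
#' @param T_lag_IS insulin-to-signal lag, min.
#' @param V_PIn maximal pancreatic insulin secretion rate, ug/min.
#' @param K_Gl_PIn half-saturation glucose concentration of secretion, mM.
#' @param exp_PIn Hill coefficient of secretion (>= 1), unitless.
#' @param k_In_UIn first-order insulin utilization constant, L/min.
#' @param vd_Ac acetaminophen volume-of-distribution coefficient, L/kg.
#' @param vd_GlIn glucose/insulin volume-of-distribution coefficient, L/kg.
#'
#' @return An object of class `gi_params` (a named list).
#' @seealso [reference_animal()], [steady_state_k_in_uin()],
#'   [steady_state_ipgl_end()]
#' @export
model_parameters <- function(BW, iAc_S = 0, iAc_P = 0, iGl_S = 0, iGl_P = 0,
                             iIn_P = 0, iIs = 0,
                             k_SP2 = 0, k_SP3 = 0, k_Ac_UAc = 0,
                             k_Gl_UGl = 0, k_Is_UGl = 0, iPGl_end = 0,
                             T_lag_SP = 0, T_lag_IS = 0,
                             V_PIn = 0, K_Gl_PIn = 1, exp_PIn = 1,
                             k_In_UIn = 0, vd_Ac = 0.9, vd_GlIn = 0.251) {
  p <- list(BW = BW, iAc_S = iAc_S, iAc_P = iAc_P, iGl_S = iGl_S,
            iGl_P = iGl_P, iIn_P = iIn_P, iIs = iIs,
            k_SP2 = k_SP2, k_SP3 = k_SP3, k_Ac_UAc = k_Ac_UAc,
            k_Gl_UGl = k_Gl_UGl, k_Is_UGl = k_Is_UGl, iPGl_end = iPGl_end,
            T_lag_SP = T_lag_SP, T_lag_IS = T_lag_IS,
            V_PIn = V_PIn, K_Gl_PIn = K_Gl_PIn, exp_PIn = exp_PIn,
            k_In_UIn = k_In_UIn, vd_Ac = vd_Ac, vd_GlIn = vd_GlIn)
  validate_parameters(p)
  structure(p, class = "gi_params")
}

#' @rdname model_parameters
#' @param p a named list of parameter values.
#' @export
validate_parameters <- function(p) {
  nm <- param_names()
  missing <- setdiff(nm, names(p))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  for (k in nm) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", k, "' must be a single finite number")
  }
  nonneg <- setdiff(nm, c("BW", "K_Gl_PIn", "exp_PIn"))
  bad <- nonneg[vapply(nonneg, function(k) p[[k]] < 0, logical(1))]
  if (length(bad))
    stop("parameters must be >= 0: ", paste(bad, collapse = ", "))
  if (p$BW <= 0) stop("BW must be > 0")
  if (p$K_Gl_PIn <= 0) stop("K_Gl_PIn must be > 0")
  if (p$exp_PIn < 1) stop("exp_PIn must be >= 1")
  if (p$k_SP3 < p$k_SP2)
    stop("k_SP3 (fast) must be >= k_SP2 (slow): got ",
         p$k_SP3, " < ", p$k_SP2)
  invisible(p)
}

# canonical ordering of the parameter symbols
param_names <- function() {
  c("BW", "iAc_S", "iAc_P", "iGl_S", "iGl_P", "iIn_P", "iIs",
    "k_SP2", "k_SP3", "k_Ac_UAc", "k_Gl_UGl", "k_Is_UGl", "iPGl_end",
    "T_lag_SP", "T_lag_IS", "V_PIn", "K_Gl_PIn", "exp_PIn", "k_In_UIn",
    "vd_Ac", "vd_GlIn")
}

# flat numeric vector in the layout the C++ core expects
.sim_param_vector <- function(p) {
  unlist(p[param_names()], use.names = FALSE)
}

#' Update a parameter set
#'
#' Returns a copy of `params` with the named values replaced, re-validated.
#' Unknown keys are rejected with the list of valid symbols.
#'
#' @param params a [model_parameters()] object.
#' @param ... `name = value` replacements.
#' @return A `gi_params` object.
#' @export
update_parameters <- function(params, ...) {
  repl <- list(...)
  unknown <- setdiff(names(repl), param_names())
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         "; valid symbols are: ", paste(param_names(), collapse = ", "))
  params[names(repl)] <- repl
  validate_parameters(params)
  structure(params, class = "gi_params")
}

#' @export
print.gi_params <- function(x, ...) {
  cat("<gi_params>\n")
  v <- unlist(x[param_names()])
  for (k in names(v)) cat(sprintf("  %-10s %g\n", k, v[[k]]))
  invisible(x)
}

#' Read / write a parameter set as a flat key-value config file
#'
#' The on-disk format is one `key = value` pair per line, one key per model
#' symbol, in the package's fixed units. Lines starting with `#` and blank
#' lines are ignored. Unknown keys are rejected with the list of valid
#' symbols.
#'
#' @param path file path.
#' @return `read_parameters()` returns a `gi_params` object;
#'   `write_parameters()` invisibly returns `path`.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty parameter file: ", path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop("malformed line(s) in ", path, " (expected 'key = value')")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  unknown <- setdiff(keys, param_names())
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         "; valid symbols are: ", paste(param_names(), collapse = ", "))
  if (anyNA(vals)) stop("non-numeric value(s) in ", path)
  p <- as.list(vals)
  names(p) <- keys
  do.call(model_parameters, p)
}

#' @rdname read_parameters
#' @param params a `gi_params` object.
#' @export
write_parameters <- function(params, path) {
  v <- unlist(params[param_names()])
  writeLines(sprintf("%s = %.17g", names(v), v), path)
  invisible(path)
}
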