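#' Default bounds for the eight fitted glucose-insulin parameters
#'
#' An order of magnitude around typical calf values. Lower bounds that the
#' model requires to be strictly positive are represented by a small
#' epsilon; candidates that make the simulation unstable are culled with an
#' infinite objective.
#'
#' @return A 2 x 8 matrix with rows `lower`, `upper` and the parameter
#'   names as columns.
#' @export
gi_fit_bounds <- function() {
  b <- rbind(
    lower = c(k_Gl_UGl = 0,     k_Is_UGl = 0, T_lag_SP = 0, T_lag_IS = 0,
              V_PIn = 1e-6, K_Gl_PIn = 1e-6, exp_PIn = 1, iIn_P = 1e-6),
    upper = c(k_Gl_UGl = 1e-3,  k_Is_UGl = 1, T_lag_SP = 120,
              T_lag_IS = 120, V_PIn = 100, K_Gl_PIn = 30, exp_PIn = 20,
              iIn_P = 50))
  b
}

.gi_free_names <- function() colnames(gi_fit_bounds())

# build the full parameter set for one candidate vector: free parameters
# replaced, then the basal steady-state constraints applied so the
# postprandial response starts from a steady pre-prandial state
.candidate_params <- function(theta, ac_params) {
  nm <- .gi_free_names()
  p <- ac_params
  for (i in seq_along(nm)) p[[nm[i]]] <- theta[i]
  p <- validate_parameters(p)
  class(p) <- "gi_params"
  apply_steady_state(p, k_in_uin = TRUE, ipgl_end = TRUE)
}

#' Sum-of-squares objective for the glucose-insulin fit
#'
#' Derives `k_In_UIn` and `iPGl_end` from the candidate via the basal
#' steady-state constraints, simulates the 420-min response, samples the
#' trajectory at the observation times and returns the unweighted sum of
#' the glucose and insulin residual sums of squares. A candidate whose
#' simulation fails returns `Inf` (culled by the optimizer).
#'
#' @param theta candidate vector in the order of [gi_fit_bounds()]
#'   columns: `k_Gl_UGl`, `k_Is_UGl`, `T_lag_SP`, `T_lag_IS`, `V_PIn`,
#'   `K_Gl_PIn`, `exp_PIn`, `iIn_P`.
#' @param glucose,insulin observed [timecourse()] objects sharing sample
#'   times on the 1-min grid.
#' @param ac_params [model_parameters()] carrying the animal description
#'   and the marker-derived `k_SP2`, `k_SP3` (fitted first, then fixed).
#' @param z the marker-derived [z_schedule()].
#' @param dt integration step for candidate simulations, min.
#' @param details logical; if `TRUE` return a list with residuals and the
#'   full parameter set instead of the bare RSS.
#' @return The RSS (glucose + insulin), or a detail list.
#' @export
gi_objective <- function(theta, glucose, insulin, ac_params, z,
                         dt = 0.01, details = FALSE) {
  p <- tryCatch(.candidate_params(theta, ac_params), error = function(e) NULL)
  if (is.null(p)) return(if (details) NULL else Inf)
  horizon <- max(glucose$time_min, insulin$time_min)
  traj <- tryCatch(
    simulate_gi(p, z, horizon = horizon, dt = dt, report_every = 1),
    error = function(e) NULL)
  if (is.null(traj)) return(if (details) NULL else Inf)
  ig <- match(round(glucose$time_min), traj$time_min)
  ii <- match(round(insulin$time_min), traj$time_min)
  if (anyNA(ig) || anyNA(ii)) stop("observation times must lie on the ",
                                   "1-min reporting grid")
  rg <- traj$cGlP_mM[ig] - glucose$value
  ri <- traj$cInP_ug_per_L[ii] - insulin$value
  rss <- sum(rg^2) + sum(ri^2)
  if (!details) return(rss)
  list(rss = rss, residuals_glucose = rg, residuals_insulin = ri,
       params = p,
       rmspe_glucose = rmspe(traj$cGlP_mM[ig], glucose$value),
       rmspe_insulin = rmspe(traj$cInP_ug_per_L[ii], insulin$value))
}

#' Fit the glucose-insulin parameters by differential evolution
#'
#' Estimates the eight free parameters (`k_Gl_UGl`, `k_Is_UGl`,
#' `T_lag_SP`, `T_lag_IS`, `V_PIn`, `K_Gl_PIn`, `exp_PIn`, `iIn_P`) by
#' differential evolution (best/1/bin, per-trial dithered mutation factor
#' in U(0.5, 1), crossover rate 0.9) over a bounded box, minimizing the summed glucose and insulin
#' residual sums of squares under the basal steady-state constraints
#' (`k_In_UIn` and `iPGl_end` derived for every candidate). After the final
#' generation the `elite` lowest-objective distinct members yield a mean
#' and standard error (sd/sqrt(elite)) per parameter.
#'
#' The marker subsystem (`k_SP2`, `k_SP3`, Z-schedule) is fitted first from
#' acetaminophen data and enters here as fixed inputs; the basal glucose
#' state (`iGl_P`, `iGl_S`) is measured, not fitted.
#'
#' @inheritParams gi_objective
#' @param popsize population size per generation (default 80).
#' @param generations number of generations (default 200).
#' @param elite number of best final members summarized (default 30; may
#'   equal `popsize`).
#' @param seed integer RNG seed (all randomness is drawn from it).
#' @param bounds a 2 x 8 bounds matrix as [gi_fit_bounds()].
#' @return A `gi_fit` object: `estimate` and `se` (named length-8
#'   vectors), derived `k_In_UIn` and `iPGl_end` at the estimate, `rss`,
#'   `rmspe_glucose`, `rmspe_insulin` (percent), `best_par`, `best_rss`,
#'   `trace` (best RSS per generation), `elite_pop`, `generations`,
#'   `popsize`, `seed`, `params` (full parameter set at the estimate).
#' @export
fit_gi <- function(glucose, insulin, ac_params, z,
                   popsize = 80, generations = 200, elite = 30,
                   seed = 1L, bounds = gi_fit_bounds(), dt = 0.01) {
  stopifnot(inherits(glucose, "timecourse"), inherits(insulin, "timecourse"))
  if (elite > popsize) stop("elite must be <= popsize")
  lo <- bounds["lower", ]
  hi <- bounds["upper", ]
  d <- length(lo)
  set.seed(seed)

  obj <- function(th) gi_objective(th, glucose, insulin, ac_params, z,
                                   dt = dt)

  pop <- matrix(stats::runif(popsize * d, rep(lo, each = popsize),
                             rep(hi, each = popsize)),
                nrow = popsize, ncol = d)
  colnames(pop) <- names(lo)
  fx <- apply(pop, 1, obj)
  trace <- numeric(generations)
  CR <- 0.9

  for (g in seq_len(generations)) {
    ibest <- which.min(fx)
    best <- pop[ibest, ]
    for (i in seq_len(popsize)) {
      # per-trial dithered mutation factor: plain F = 0.8 lets the
      # population collapse prematurely into a deceptive shallow-Hill
      # basin on some seeds; U(0.5, 1) dithering escapes it reliably
      Fw <- stats::runif(1, 0.5, 1)
      idx <- sample(seq_len(popsize)[-i], 2L)
      v <- best + Fw * (pop[idx[1], ] - pop[idx[2], ])
      v <- pmin(pmax(v, lo), hi)
      jrand <- sample.int(d, 1L)
      cross <- stats::runif(d) < CR
      cross[jrand] <- TRUE
      u <- ifelse(cross, v, pop[i, ])
      fu <- obj(u)
      if (fu <= fx[i]) {
        pop[i, ] <- u
        fx[i] <- fu
      }
    }
    trace[g] <- min(fx)
  }

  ord <- order(fx)
  keep <- ord[!duplicated(lapply(ord, function(i) pop[i, ]))]
  elite_idx <- utils::head(keep, elite)
  elite_pop <- pop[elite_idx, , drop = FALSE]
  if (nrow(elite_pop) < elite)
    warning("population collapsed: only ", nrow(elite_pop),
            " distinct members; standard errors may be 0")
  est <- colMeans(elite_pop)
  se <- apply(elite_pop, 2, stats::sd) / sqrt(nrow(elite_pop))

  det <- gi_objective(est, glucose, insulin, ac_params, z, dt = dt,
                      details = TRUE)
  best_i <- ord[1]
  structure(list(
    estimate = est, se = se,
    k_In_UIn = det$params$k_In_UIn, iPGl_end = det$params$iPGl_end,
    rss = det$rss,
    rmspe_glucose = det$rmspe_glucose, rmspe_insulin = det$rmspe_insulin,
    best_par = pop[best_i, ], best_rss = fx[best_i],
    trace = trace, elite_pop = elite_pop,
    generations = generations, popsize = popsize, seed = seed,
    params = det$params), class = "gi_fit")
}

#' @export
print.gi_fit <- function(x, ...) {
  cat("<gi_fit> DE", x$generations, "generations x popsize", x$popsize,
      "(seed", paste0(x$seed, ")\n"))
  tab <- data.frame(estimate = x$estimate, se = x$se)
  print(format(tab, digits = 4))
  cat(sprintf("  derived k_In_UIn = %.4g, iPGl_end = %.4g\n",
              x$k_In_UIn, x$iPGl_end))
  cat(sprintf("  RSS = %.6g; rMSPE glucose %.1f%%, insulin %.1f%%\n",
              x$rss, x$rmspe_glucose, x$rmspe_insulin))
  invisible(x)
}
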