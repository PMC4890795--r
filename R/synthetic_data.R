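#' Meal descriptor
#'
#' Describes a liquid milk-replacer meal from which the model's initial
#' stomach hexose load is computed: volume, dry-matter content, lactose
#' fraction of dry matter, and the fixed absorption fractions (complete
#' lactose digestion; 10% of the galactose moiety entering circulation as
#' free glucose; 90% of the glucose moiety surviving splanchnic
#' extraction).
#'
#' @param volume meal volume, L.
#' @param dry_matter dry matter content, g/L.
#' @param lactose_fraction lactose fraction of dry matter, unitless.
#' @param galactose_to_glucose_fraction fraction of the galactose moiety
#'   appearing as free glucose (default 0.10).
#' @param glucose_splanchnic_survival fraction of the glucose moiety
#'   surviving splanchnic extraction (default 0.90).
#' @param lactose_digestibility fraction of lactose digested (default 1).
#' @return A `meal_spec` object.
#' @export
meal_spec <- function(volume, dry_matter = 150, lactose_fraction = 0.452,
                      galactose_to_glucose_fraction = 0.10,
                      glucose_splanchnic_survival = 0.90,
                      lactose_digestibility = 1.0) {
  fr <- c(lactose_fraction, galactose_to_glucose_fraction,
          glucose_splanchnic_survival, lactose_digestibility)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (volume < 0 || dry_matter < 0)
    stop("volume and dry_matter must be >= 0")
  structure(list(volume = volume, dry_matter = dry_matter,
                 lactose_fraction = lactose_fraction,
                 galactose_to_glucose_fraction =
                   galactose_to_glucose_fraction,
                 glucose_splanchnic_survival = glucose_splanchnic_survival,
                 lactose_digestibility = lactose_digestibility),
            class = "meal_spec")
}

# anhydrous lactose molar mass, g/mol
LACTOSE_G_PER_MOL <- 342.3

#' Hexose-equivalent load of a meal
#'
#' Millimoles of monosaccharide expected to reach circulation as free
#' glucose: meal lactose (g) over its molar mass, times the sum of the
#' glucose-moiety splanchnic survival and the galactose-to-glucose
#' conversion fractions. The 2-L reference meal (150 g/L dry matter, 45.2%
#' lactose) gives 396 mmol.
#'
#' @param meal a [meal_spec()].
#' @return iGl_S, mmol.
#' @examples
#' hexose_load(meal_spec(2))   # ~396
#' @export
hexose_load <- function(meal) {
  stopifnot(inherits(meal, "meal_spec"))
  lactose_g <- meal$volume * meal$dry_matter * meal$lactose_fraction *
    meal$lactose_digestibility
  mol <- lactose_g / LACTOSE_G_PER_MOL
  1000 * mol * (meal$glucose_splanchnic_survival +
                  meal$galactose_to_glucose_fraction)
}

#' Acetaminophen marker dose
#'
#' Metabolic-weight dosing: `rate * BW^0.75` mg.
#'
#' @param bw body weight, kg (> 0).
#' @param rate dose rate, mg per kg^0.75 (default 150).
#' @return iAc_S, mg.
#' @examples
#' ac_dose(60)   # ~3234
#' @export
ac_dose <- function(bw, rate = 150) {
  if (bw <= 0) stop("bw must be > 0")
  rate * bw^0.75
}

#' The built-in reference animal
#'
#' The 60-kg calf consuming a 2-L milk-replacer meal: all model constants
#' and the typical gastric-outflow pattern (fast initial emptying followed
#' by intermittent slow gushes) on a uniform 30-min grid over 0-420 min.
#'
#' @return A list with `params` (a [model_parameters()] object) and `z`
#'   (a [z_schedule()] with 14 interval codes).
#' @export
reference_animal <- function() {
  params <- model_parameters(
    BW = 60,
    iAc_S = 3234, iAc_P = 0,
    iGl_S = 396, iGl_P = 90,
    iIn_P = 5.92, iIs = 0.393,
    k_SP2 = 0.0015, k_SP3 = 0.003, k_Ac_UAc = 0.0022,
    k_Gl_UGl = 8.7e-7, k_Is_UGl = 0.0757, iPGl_end = 0.178,
    T_lag_SP = 15, T_lag_IS = 16,
    V_PIn = 10, K_Gl_PIn = 8.8, exp_PIn = 9, k_In_UIn = 0.7,
    vd_Ac = 0.9, vd_GlIn = 0.251)
  z <- z_schedule(seq(0, 420, by = 30),
                  c(2, 1, 2, 2, 1, 0, 0, 1, 1, 1, 0, 0, 0, 0))
  list(params = params, z = z)
}

#' The 4-L meal fixture
#'
#' A larger-meal variant of the reference animal for range testing: same
#' 60-kg calf, 4 L of the same milk replacer (iGl_S ~ 792 mmol by the
#' hexose-load formula).
#'
#' @return A list with `params` and `z`, as [reference_animal()].
#' @export
reference_animal_4L <- function() {
  ref <- reference_animal()
  ref$params <- update_parameters(ref$params,
                                  iGl_S = hexose_load(meal_spec(4)))
  ref
}

# multiplicative lognormal noise with a given coefficient of variation and
# unit mean
.apply_lognormal_noise <- function(values, noise_cv) {
  if (noise_cv == 0) return(values)
  sdlog <- sqrt(log(1 + noise_cv^2))
  values * stats::rlnorm(length(values), meanlog = -sdlog^2 / 2,
                         sdlog = sdlog)
}

#' Generate synthetic observed timecourses
#'
#' Simulates the model, samples the three plasma concentrations at the
#' requested times, and applies multiplicative lognormal observation noise
#' with coefficient of variation `noise_cv` (unit mean, so the expected
#' value equals the model output; `noise_cv = 0` returns exact model
#' samples). Emulates the 12-sample, 420-min postprandial sampling design
#' with multiple rises and falls driven by an intermittent Z-schedule.
#'
#' @param params a [model_parameters()] object.
#' @param z a [z_schedule()].
#' @param sample_times sampling times, min (default the 12-point design
#'   `c(0, 30, 60, ..., 240, 300, 360, 420)`).
#' @param noise_cv observation coefficient of variation (>= 0).
#' @param seed RNG seed.
#' @param dt integration step passed to [simulate_gi()].
#' @return A list of three [timecourse()] objects: `acetaminophen`,
#'   `glucose`, `insulin`.
#' @export
generate_observations <- function(params, z,
                                  sample_times = c(seq(0, 240, by = 30),
                                                   300, 360, 420),
                                  noise_cv = 0.05, seed = 1L, dt = 0.002) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  horizon <- max(sample_times)
  # report on a grid containing the sample times
  traj <- simulate_gi(params, z, horizon = horizon, dt = dt,
                      report_every = 1)
  idx <- match(round(sample_times), traj$time_min)
  if (anyNA(idx)) stop("sample_times must lie on the 1-min reporting grid ",
                       "within the horizon")
  set.seed(seed)
  list(
    acetaminophen = timecourse(sample_times,
                               .apply_lognormal_noise(
                                 traj$cAcP_mg_per_L[idx], noise_cv),
                               "acetaminophen"),
    glucose = timecourse(sample_times,
                         .apply_lognormal_noise(traj$cGlP_mM[idx],
                                                noise_cv),
                         "glucose"),
    insulin = timecourse(sample_times,
                         .apply_lognormal_noise(traj$cInP_ug_per_L[idx],
                                                noise_cv),
                         "insulin"))
}
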