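#' Synthetic fermentation and assay data with known ground truth
#'
#' Deliberately simple generative laws whose only job is to exercise the
#' metric calculators with inputs of known truth: a two-phase batch
#' fermentation (slow exponential consumption during growth, then linear
#' drawdown during lipogenesis, lipid strictly proportional to glucose
#' consumed) and linear absorbance traces mapped through the inverse of the
#' specific-activity estimator. Concentration noise is multiplicative
#' log-normal (concentrations stay positive); absorbance noise is additive
#' Gaussian. All randomness is seeded and reproducible.
#'
#' @name synthetic_data
NULL

# run code under a temporary RNG state
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fermentation simulation parameters
#'
#' Defaults emulate a 5-day glucose batch: 150 g/L initial glucose, daily
#' sampling, lipogenesis onset at day 2 (after which growth has slowed),
#' 0.20 g/g lipid yield, 0.25 g/g biomass yield on the growth-phase
#' glucose (half of total consumption), 10 g/L residual glucose, 5 % CV
#' measurement noise - implying a final lipid content around 60 % of DCW.
#'
#' @param initial_glucose g/L at inoculation.
#' @param true_lipid_yield g lipid per g glucose consumed (ground truth).
#' @param true_biomass_yield g lipid-free biomass per g glucose routed to
#'   growth.
#' @param lag_days lag before measurable consumption.
#' @param lipogenesis_onset_day day growth stops and linear drawdown begins.
#' @param sampling_days sampling grid (days); must contain the onset day.
#' @param residual_glucose g/L left at the final sample.
#' @param dcw0 inoculum dry cell weight (g/L).
#' @param growth_fraction fraction of total consumption spent before onset.
#' @param noise_cv multiplicative noise coefficient of variation (< 0.5).
#' @param seed integer seed (required for reproducibility).
#' @return object of class `fermentation_sim_params`.
#' @export
fermentation_sim_params <- function(initial_glucose = 150,
                                    true_lipid_yield = 0.20,
                                    true_biomass_yield = 0.25,
                                    lag_days = 0.5,
                                    lipogenesis_onset_day = 2,
                                    sampling_days = 0:5,
                                    residual_glucose = 10,
                                    dcw0 = 0.2,
                                    growth_fraction = 0.5,
                                    noise_cv = 0.05,
                                    seed = 1L) {
  if (true_lipid_yield <= 0 || true_biomass_yield <= 0)
    stop("yields must be positive")
  if (true_lipid_yield + true_biomass_yield > 1)
    stop("lipid + biomass yield exceed 1 g/g: carbon closure violated")
  if (noise_cv < 0 || noise_cv >= 0.5) stop("noise_cv must be in [0, 0.5)")
  if (residual_glucose >= initial_glucose) stop("residual exceeds initial glucose")
  tend <- max(sampling_days)
  if (!(lag_days < lipogenesis_onset_day && lipogenesis_onset_day < tend))
    stop("need lag < lipogenesis onset < final sampling day")
  if (!lipogenesis_onset_day %in% sampling_days)
    stop("sampling_days must contain the lipogenesis onset day")
  structure(as.list(environment()), class = "fermentation_sim_params")
}

# cumulative glucose consumed (g/L) at time t under the two-phase law
consumption_curve <- function(p, t) {
  ctot <- p$initial_glucose - p$residual_glucose
  con <- p$growth_fraction * ctot
  tend <- max(p$sampling_days)
  r <- 4 / (p$lipogenesis_onset_day - p$lag_days)
  ramp <- function(u) (exp(r * u) - 1) / (exp(r * (p$lipogenesis_onset_day - p$lag_days)) - 1)
  ifelse(t <= p$lag_days, 0,
    ifelse(t <= p$lipogenesis_onset_day, con * ramp(t - p$lag_days),
      con + (ctot - con) * (t - p$lipogenesis_onset_day) /
        (tend - p$lipogenesis_onset_day)))
}

#' Simulate a batch fermentation time course
#'
#' Lipid titer is strictly proportional to cumulative glucose consumed
#' (slope = `true_lipid_yield`), so at zero noise [fermentation_metrics()]
#' recovers the true yield exactly; lipid-free biomass grows at
#' `true_biomass_yield` on the pre-onset consumption and is constant
#' afterwards. Multiplicative log-normal noise (mean 1, CV `noise_cv`) is
#' applied per sample and per series; if noise pushes DCW below the lipid
#' titer, DCW is clipped up and the result flagged.
#'
#' @param p a [fermentation_sim_params()].
#' @return list of class `fermentation_sim`: `course`
#'   (a [fermentation_time_course()]), `truth` (true yield, content, CSP
#'   over the onset-to-end window, final LFDCW), `clipped`.
#' @export
simulate_fermentation <- function(p) {
  stopifnot(inherits(p, "fermentation_sim_params"))
  t <- p$sampling_days
  C <- consumption_curve(p, t)
  lipid <- p$true_lipid_yield * C
  con <- p$growth_fraction * (p$initial_glucose - p$residual_glucose)
  lfdcw <- p$dcw0 + p$true_biomass_yield * pmin(C, con)
  glucose <- p$initial_glucose - C
  dcw <- lfdcw + lipid
  clipped <- FALSE
  if (p$noise_cv > 0) {
    s <- sqrt(log(1 + p$noise_cv^2))
    fac <- local_seed(p$seed, matrix(stats::rlnorm(3 * length(t), -s^2 / 2, s), ncol = 3))
    glucose <- glucose * fac[, 1]
    dcw <- dcw * fac[, 2]
    lipid <- lipid * fac[, 3]
    if (any(dcw < lipid)) { clipped <- TRUE; dcw <- pmax(dcw, lipid) }
  }
  tol <- max(0.05, 6 * p$noise_cv)
  course <- fermentation_time_course(t, glucose, dcw, lipid, glucose_tol = tol)
  tend <- max(t)
  span <- tend - p$lipogenesis_onset_day
  csp_true <- p$true_lipid_yield *
    (consumption_curve(p, tend) - consumption_curve(p, p$lipogenesis_onset_day)) /
    (utils::tail(lfdcw, 1) * span)
  truth <- list(
    lipid_yield = p$true_lipid_yield,
    biomass_yield = p$true_biomass_yield,
    lipid_content_final = utils::tail(p$true_lipid_yield * C, 1) /
      (utils::tail(lfdcw, 1) + utils::tail(p$true_lipid_yield * C, 1)),
    csp = csp_true,
    csp_window = c(p$lipogenesis_onset_day, tend),
    lfdcw_final = utils::tail(lfdcw, 1)
  )
  structure(list(course = course, truth = truth, clipped = clipped,
                 params = p), class = "fermentation_sim")
}

#' Assay plate simulation parameters
#'
#' @param true_specific_activity umol min^-1 mg^-1 ground truth.
#' @param protein_mg_per_ml,extract_volume_ul,reaction_volume_ml,path_length_cm
#'   assay context (as in [absorbance_kinetics()]).
#' @param epsilon extinction coefficient (mM^-1 cm^-1).
#' @param background_slope instrument/background drift (A/min).
#' @param a0 initial absorbance offset (AU).
#' @param noise_sd additive Gaussian read noise (AU).
#' @param n_replicates traces to generate.
#' @param times_min reading times.
#' @param seed integer seed (required).
#' @return object of class `assay_sim_params`.
#' @export
assay_sim_params <- function(true_specific_activity = 1,
                             protein_mg_per_ml = 1, extract_volume_ul = 10,
                             reaction_volume_ml = 1, path_length_cm = 1,
                             epsilon = 13.5, background_slope = 0,
                             a0 = 0.05, noise_sd = 0.005, n_replicates = 4,
                             times_min = 0:10, seed = 1L) {
  if (true_specific_activity < 0) stop("activity must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(times_min) < 2L) stop("need at least two reading times")
  structure(as.list(environment()), class = "assay_sim_params")
}

#' Simulate absorbance kinetics traces
#'
#' The signal slope is the true activity mapped through the inverse of
#' [pta_specific_activity()]'s Beer-Lambert arithmetic, plus
#' `background_slope`, plus additive Gaussian read noise.
#'
#' @param p an [assay_sim_params()].
#' @return list of class `assay_sim`: `traces` (list of
#'   [absorbance_kinetics()]), `truth`.
#' @export
simulate_assay_plate <- function(p) {
  stopifnot(inherits(p, "assay_sim_params"))
  protein_mg <- p$extract_volume_ul * p$protein_mg_per_ml / 1000
  signal_slope <- p$true_specific_activity * protein_mg *
    p$epsilon * p$path_length_cm / p$reaction_volume_ml
  slope <- signal_slope + p$background_slope
  traces <- local_seed(p$seed, lapply(seq_len(p$n_replicates), function(i) {
    a <- p$a0 + slope * p$times_min +
      if (p$noise_sd > 0) stats::rnorm(length(p$times_min), 0, p$noise_sd) else 0
    absorbance_kinetics(p$times_min, a,
                        path_length_cm = p$path_length_cm,
                        reaction_volume_ml = p$reaction_volume_ml,
                        extract_volume_ul = p$extract_volume_ul,
                        protein_mg_per_ml = p$protein_mg_per_ml)
  }))
  structure(list(traces = traces,
                 truth = list(specific_activity = p$true_specific_activity,
                              signal_slope = signal_slope),
                 params = p), class = "assay_sim")
}
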