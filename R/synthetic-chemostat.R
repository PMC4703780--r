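# Steady-state chemostat observations and linear batch series with
# controlled noise, constructed to satisfy carbon and nitrogen conservation
# exactly before noise is added.

#' Describe a chemostat scenario
#'
#' Defaults reflect the enrichment conditions the package emulates: 20 mM
#' nitrite and 1 mM nitrate as electron acceptors, 28 mM-C organic carbon
#' (37.5 mM-C is the value used for cold cultures), 5.3 mM-N organic
#' nitrogen, a dilution rate of 0.36 culture volumes per day and a true
#' growth yield of 0.4 C-mol assimilated per C-mol converted.
#'
#' @param influent_nitrite,influent_nitrate mM in the influent medium.
#' @param influent_organic_carbon mM-C in the influent medium.
#' @param influent_organic_n mM-N in the influent medium.
#' @param dilution_rate Culture-volume changes per day (> 0).
#' @param temperature Degrees Celsius.
#' @param true_yield C-mol assimilated per C-mol converted, in `[0, 1]`.
#' @param noise_sd Relative (multiplicative) measurement noise on effluent
#'   observables; the default 0.05 is a plain choice in the absence of a
#'   stated instrument error model and is configuration-exposed.
#' @param seed Integer seed.
#' @return A `chemostat_scenario` list.
#' @export
chemostat_scenario <- function(influent_nitrite = 20, influent_nitrate = 1,
                               influent_organic_carbon = 28,
                               influent_organic_n = 5.3,
                               dilution_rate = 0.36, temperature = 25,
                               true_yield = 0.4, noise_sd = 0.05, seed = 1L) {
  stopifnot(
    influent_nitrite >= 0, influent_nitrate >= 0,
    influent_organic_carbon >= 0, influent_organic_n >= 0,
    dilution_rate > 0, true_yield >= 0, true_yield <= 1, noise_sd >= 0
  )
  structure(
    list(
      influent_nitrite = influent_nitrite,
      influent_nitrate = influent_nitrate,
      influent_organic_carbon = influent_organic_carbon,
      influent_organic_n = influent_organic_n,
      dilution_rate = dilution_rate, temperature = temperature,
      true_yield = true_yield, noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "chemostat_scenario"
  )
}

#' Simulate steady-state chemostat observations
#'
#' Constructs an effluent state that conserves carbon and nitrogen exactly
#' given the scenario's true yield, then applies relative measurement noise
#' to the effluent observables.  Before noise: converted carbon equals the
#' influent organic carbon (complete consumption), assimilated carbon is
#' `true_yield x converted`, assimilated nitrogen is `n_to_c x` assimilated
#' carbon, effluent ammonium is influent organic N minus assimilated N, and
#' protein follows the biomass model.  Negative concentrations after noise
#' are clipped to zero and flagged.
#'
#' @param scenario A [chemostat_scenario()].
#' @param model A [biomass_model()].
#' @return A `chemostat_state` list with influent/effluent concentrations
#'   (mM), `protein_g_per_l`, `dilution_rate`, `temperature`, plus
#'   bookkeeping fields `converted_carbon`, `clipped` and the noise-free
#'   `truth` sub-list.
#' @export
simulate_chemostat <- function(scenario, model = biomass_model()) {
  stopifnot(inherits(scenario, "chemostat_scenario"))
  converted_c <- scenario$influent_organic_carbon
  assim_c <- scenario$true_yield * converted_c
  assim_n <- model$n_to_c * assim_c
  if (assim_n > scenario$influent_organic_n) {
    stop(
      "scenario infeasible: biomass nitrogen demand (", round(assim_n, 3),
      " mM-N) exceeds influent organic nitrogen"
    )
  }
  ammonium <- scenario$influent_organic_n - assim_n
  protein <- assim_c / 1000 * model$formula_mass * model$protein_fraction
  truth <- list(
    effluent_ammonium = ammonium, effluent_nitrite = 0,
    protein_g_per_l = protein, assimilated_n = assim_n,
    assimilated_c = assim_c, converted_carbon = converted_c
  )
  obs <- c(ammonium, 0, protein)
  clipped <- FALSE
  if (scenario$noise_sd > 0) {
    obs <- with_seed(
      scenario$seed,
      obs * (1 + rnorm(length(obs), 0, scenario$noise_sd))
    )
    if (any(obs < 0)) {
      obs[obs < 0] <- 0
      clipped <- TRUE
    }
  }
  structure(
    list(
      influent_nitrite = scenario$influent_nitrite,
      influent_nitrate = scenario$influent_nitrate,
      influent_organic_carbon = scenario$influent_organic_carbon,
      influent_organic_n = scenario$influent_organic_n,
      effluent_ammonium = obs[1], effluent_nitrite = obs[2],
      protein_g_per_l = obs[3],
      dilution_rate = scenario$dilution_rate,
      temperature = scenario$temperature,
      converted_carbon = converted_c, clipped = clipped, truth = truth
    ),
    class = "chemostat_state"
  )
}

#' Simulate a linear batch-incubation concentration series
#'
#' Concentration follows `c0 + true_rate * t` at `n_samples` time points
#' spaced `interval_h` hours apart (the package emulates nitrite depletion
#' series sampled 7 times at 20-minute intervals).  Gaussian noise with
#' standard deviation `noise_sd * c0` is added; negative concentrations are
#' clipped to zero and flagged.
#'
#' @param true_rate Slope in mM/h (negative for consumption).
#' @param n_samples Number of samples (>= 3).
#' @param interval_h Sampling interval in hours (default 1/3 h = 20 min).
#' @param c0 Initial concentration in mM.
#' @param noise_sd Relative noise (fraction of `c0`).
#' @param seed Integer seed.
#' @param analyte Label for the measured analyte.
#' @return A `batch_series` data.frame with columns `time_h`,
#'   `concentration_mM` and `clipped`, and attribute `analyte`.
#' @export
simulate_batch <- function(true_rate, n_samples = 7L, interval_h = 1 / 3,
                           c0 = 0.7, noise_sd = 0, seed = 1L,
                           analyte = "nitrite") {
  stopifnot(n_samples >= 3, interval_h > 0, c0 >= 0, noise_sd >= 0)
  t <- (seq_len(n_samples) - 1L) * interval_h
  conc <- c0 + true_rate * t
  if (noise_sd > 0) {
    conc <- with_seed(seed, conc + rnorm(n_samples, 0, noise_sd * c0))
  }
  clipped <- conc < 0
  conc[clipped] <- 0
  out <- data.frame(time_h = t, concentration_mM = conc, clipped = clipped)
  attr(out, "analyte") <- analyte
  class(out) <- c("batch_series", "data.frame")
  out
}
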