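# Chemostat stoichiometry: C:N ratio of the feed, nitrogen balance and
# predicted protein, growth yield, medium recipe and batch rate estimation.
#
# Unit conventions: concentrations in mM; mM-C and mM-N count carbon and
# nitrogen atoms; protein in g/L; rates in mM/h (with a derived
# umol L^-1 day^-1 value); yields in C-mol assimilated per C-mol converted.

#' Biomass composition model
#'
#' Converts between assimilated nitrogen, biomass carbon and measured
#' protein.  The composition is the standard biomass formula CH1.8O0.5N0.2:
#' `n_to_c = 0.2` mol N per mol C and `formula_mass = 24.6` g per C-mol.
#' The protein share of biomass is not pinned down by that formula; the
#' package default of 0.47 g protein per g biomass sits in the middle of the
#' usual bacterial range (0.40-0.55) and is the single calibrated constant
#' that lets the standard composition reproduce both protein-from-nitrogen
#' predictions and growth yields of the enrichment cultures the package
#' emulates.  All three constants are configuration-exposed.
#'
#' @param n_to_c mol N per mol C in biomass (> 0, <= 1).
#' @param formula_mass g per C-mol of biomass.
#' @param protein_fraction g protein per g biomass.
#' @return A `biomass_model` list.
#' @export
biomass_model <- function(n_to_c = 0.2, formula_mass = 24.6,
                          protein_fraction = 0.47) {
  stopifnot(
    n_to_c > 0, n_to_c <= 1, formula_mass > 0,
    protein_fraction > 0, protein_fraction <= 1
  )
  structure(
    list(
      n_to_c = n_to_c, formula_mass = formula_mass,
      protein_fraction = protein_fraction
    ),
    class = "biomass_model"
  )
}

#' Influent C:N ratio
#'
#' Organic carbon supplied per mole of nitrogen in the electron acceptors:
#' `organic carbon (mM-C) / (nitrite + nitrate) (mM-N)`.  Dimensionless
#' (C-mol/N-mol); invariant under scaling all concentrations.
#'
#' @param state A `chemostat_state` (from [simulate_chemostat()]) or any
#'   list with fields `influent_organic_carbon`, `influent_nitrite`,
#'   `influent_nitrate`.
#' @return C:N ratio in C-mol/N-mol.
#' @export
cn_ratio <- function(state) {
  n <- state$influent_nitrite + state$influent_nitrate
  if (n <= 0) stop("no nitrogen in the electron acceptors: C:N undefined")
  state$influent_organic_carbon / n
}

#' Nitrogen balance of the culture
#'
#' Organic nitrogen unaccounted for in the effluent must have been
#' assimilated into biomass (or, if negative, produced - which points at
#' dissimilatory nitrate reduction to ammonium and triggers a warning).
#'
#' @param state As in [cn_ratio()]; needs `influent_organic_n` and
#'   `effluent_ammonium`.
#' @return Assimilated nitrogen in mM-N.
#' @export
nitrogen_balance <- function(state) {
  assim <- state$influent_organic_n - state$effluent_ammonium
  if (assim < 0) {
    warning("effluent ammonium exceeds influent organic N: possible DNRA")
  }
  assim
}

#' Predict protein concentration from assimilated nitrogen
#'
#' `protein = assimilated_n / 1000 / n_to_c * formula_mass *
#' protein_fraction`: assimilated nitrogen fixes the biomass carbon via the
#' N:C ratio, which converts to dry mass and then to protein.  Linear in
#' `assimilated_n`.
#'
#' @param assimilated_n mM-N, e.g. from [nitrogen_balance()].
#' @param model A [biomass_model()].
#' @return Predicted protein in g/L.
#' @export
protein_from_nitrogen <- function(assimilated_n, model = biomass_model()) {
  stopifnot(inherits(model, "biomass_model"))
  assimilated_n / 1000 / model$n_to_c * model$formula_mass *
    model$protein_fraction
}

#' Growth yield from measured protein
#'
#' Biomass carbon (mM-C) is `protein / protein_fraction / formula_mass *
#' 1000`; the yield is that carbon over the converted substrate carbon.
#'
#' @param protein_g_per_l Measured protein in g/L.
#' @param converted_carbon Converted substrate carbon in mM-C (> 0);
#'   defaults to complete consumption of the influent organic carbon when a
#'   `chemostat_state` is used upstream.
#' @param model A [biomass_model()].
#' @return Growth yield in C-mol assimilated per C-mol converted.
#' @export
growth_yield <- function(protein_g_per_l, converted_carbon,
                         model = biomass_model()) {
  stopifnot(inherits(model, "biomass_model"), converted_carbon > 0)
  biomass_c <- protein_g_per_l / model$protein_fraction /
    model$formula_mass * 1000
  y <- biomass_c / converted_carbon
  if (y > 1) {
    stop(
      "infeasible yield ", round(y, 3),
      ": more carbon assimilated than converted"
    )
  }
  y
}

#' Full mass balance for a chemostat state
#'
#' Convenience wrapper combining [cn_ratio()], [nitrogen_balance()],
#' [protein_from_nitrogen()] and [growth_yield()].
#'
#' @param state A `chemostat_state`.
#' @param model A [biomass_model()].
#' @param converted_carbon Converted carbon in mM-C; defaults to the
#'   influent organic carbon (complete consumption).
#' @return A `mass_balance_result` list with `cn_ratio`, `assimilated_n`,
#'   `predicted_protein`, `measured_protein` and `yield`.
#' @export
mass_balance <- function(state, model = biomass_model(),
                         converted_carbon = state$influent_organic_carbon) {
  assim_n <- nitrogen_balance(state)
  structure(
    list(
      cn_ratio = cn_ratio(state),
      assimilated_n = assim_n,
      predicted_protein = protein_from_nitrogen(assim_n, model),
      measured_protein = state$protein_g_per_l,
      yield = growth_yield(state$protein_g_per_l, converted_carbon, model)
    ),
    class = "mass_balance_result"
  )
}

#' @export
print.mass_balance_result <- function(x, ...) {
  cat("Chemostat mass balance\n")
  cat(sprintf("  C:N ratio:          %.2f C-mol/N-mol\n", x$cn_ratio))
  cat(sprintf("  assimilated N:      %.2f mM-N\n", x$assimilated_n))
  cat(sprintf("  predicted protein:  %.3f g/L\n", x$predicted_protein))
  if (!is.null(x$measured_protein)) {
    cat(sprintf("  measured protein:   %.3f g/L\n", x$measured_protein))
  }
  cat(sprintf("  growth yield:       %.2f C-mol/C-mol\n", x$yield))
  invisible(x)
}

#' Split total medium carbon into substrate classes
#'
#' The emulated medium supplies 44% of carbon as glucose, 8% as acetate and
#' 48% as a mixture of seven amino acids.
#'
#' @param total_carbon Total carbon in mM-C.
#' @param fractions Named numeric vector of class fractions summing to 1
#'   (within 0.01).
#' @return Named numeric vector of mM-C allocations summing to
#'   `total_carbon` (within 1e-9; any rounding slack goes to the largest
#'   class).
#' @export
medium_recipe <- function(total_carbon,
                          fractions = c(
                            glucose = 0.44, acetate = 0.08,
                            aminoacids = 0.48
                          )) {
  stopifnot(total_carbon >= 0, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 0.01) {
    stop("substrate fractions must sum to 1 (within 0.01)")
  }
  alloc <- total_carbon * fractions / sum(fractions)
  alloc
}

#' Estimate a conversion rate from a batch series
#'
#' Ordinary least-squares slope of concentration versus time, with its
#' standard error and 95% confidence interval, reported in mM/h and
#' converted to umol L^-1 day^-1 (factor 24,000).
#'
#' @param series A [simulate_batch()] data.frame, or any data.frame with
#'   columns `time_h` and `concentration_mM` (>= 3 points, strictly
#'   increasing times).
#' @return A `batch_rate` list with `slope_mM_per_h`, `se`, `ci95` (length
#'   2), `slope_umol_per_l_per_day` and the underlying `fit`.
#' @export
batch_rate <- function(series) {
  stopifnot(
    is.data.frame(series),
    all(c("time_h", "concentration_mM") %in% names(series))
  )
  if (nrow(series) < 3) stop("need at least 3 time points")
  if (any(diff(series$time_h) <= 0)) {
    stop("time points must be strictly increasing")
  }
  fit <- lm(concentration_mM ~ time_h, data = series)
  slope <- unname(coef(fit)["time_h"])
  # noise-free series fit exactly; the "perfect fit" caveat is expected
  se <- suppressWarnings(sqrt(vcov(fit)["time_h", "time_h"]))
  tcrit <- qt(0.975, df = fit$df.residual)
  structure(
    list(
      slope_mM_per_h = slope, se = se,
      ci95 = c(slope - tcrit * se, slope + tcrit * se),
      slope_umol_per_l_per_day = slope * 24000,
      fit = fit
    ),
    class = "batch_rate"
  )
}

#' @export
print.batch_rate <- function(x, ...) {
  cat(sprintf(
    "Batch rate: %.4f mM/h (SE %.4f, 95%% CI [%.4f, %.4f])\n",
    x$slope_mM_per_h, x$se, x$ci95[1], x$ci95[2]
  ))
  cat(sprintf("  = %.1f umol L^-1 day^-1\n", x$slope_umol_per_l_per_day))
  invisible(x)
}
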