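# Measurement-class observation model: deterministic, differentiable link
# functions from a latent binding free energy (kcal/mol) to each assay
# readout, plus a squared-error loss adapter so heterogeneous measurement
# types can train a single latent quantity.

# gas constant in kcal mol^-1 K^-1
GAS_CONSTANT_KCAL <- 1.987204259e-3

#' Thermodynamic context for the link functions
#'
#' @param temperature Kelvin; default 298.15 (standard laboratory
#'   conditions; the supported assay databases do not report temperature).
#' @param probe_concentration Molar probe concentration; required by the
#'   percent-displacement link only, and never defaulted.
#' @param reference_concentration Standard-state concentration in molar;
#'   default 1.
#' @return An object of class `ThermoContext` carrying the gas constant
#'   `R` (kcal/mol/K), `T`, and the concentrations.
#' @export
thermo_context <- function(temperature = 298.15,
                           probe_concentration = NULL,
                           reference_concentration = 1) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            temperature > 0)
  if (!is.null(probe_concentration)) {
    stopifnot(is.numeric(probe_concentration),
              length(probe_concentration) == 1L, probe_concentration > 0)
  }
  stopifnot(reference_concentration > 0)
  structure(
    list(R = GAS_CONSTANT_KCAL, T = temperature,
         probe_concentration = probe_concentration,
         reference_concentration = reference_concentration),
    class = "ThermoContext"
  )
}

# build a ThermoContext from a measurement's assay conditions
context_from_conditions <- function(conditions) {
  thermo_context(temperature = conditions$temperature,
                 probe_concentration = conditions$probe_concentration)
}

#' Dissociation constant scale: pKd from binding free energy
#'
#' `Kd = c0 * exp(dG / (R T))` with `c0` the standard-state concentration,
#' so `pKd = -log10(Kd) = -dG / (R T ln 10) - log10(c0)`. Strictly
#' decreasing in `dG`: more negative free energy, tighter binding, higher
#' pKd.
#'
#' @param dG Binding free energy, kcal/mol (vectorized).
#' @param ctx A [thermo_context()].
#' @return pKd values (unitless).
#' @export
#' @examples
#' pkd_from_dg(0, thermo_context())  # 0: Kd = 1 M at standard state
pkd_from_dg <- function(dG, ctx = thermo_context()) {
  -dG / (ctx$R * ctx$T * log(10)) - log10(ctx$reference_concentration)
}

#' Binding free energy from pKd
#'
#' Exact inverse of [pkd_from_dg()].
#'
#' @param pKd pKd values (unitless, vectorized).
#' @param ctx A [thermo_context()].
#' @return Free energies in kcal/mol.
#' @export
dg_from_pkd <- function(pKd, ctx = thermo_context()) {
  -(pKd + log10(ctx$reference_concentration)) * ctx$R * ctx$T * log(10)
}

#' Percent displacement from binding free energy
#'
#' Single-site competitive occupancy at one probe concentration `L`:
#' `100 * L / (L + Kd)`, with `Kd` from the free energy. Strictly
#' decreasing in `dG`. This is the standard single-concentration
#' competition-binding approximation.
#'
#' @param dG Binding free energy, kcal/mol (vectorized).
#' @param ctx A [thermo_context()] with `probe_concentration` set.
#' @return Percent displacement in `(0, 100)`.
#' @export
displacement_from_dg <- function(dG, ctx) {
  if (is.null(ctx$probe_concentration)) {
    stop("the percent-displacement link requires a probe_concentration ",
         "in the thermodynamic context; it is never defaulted")
  }
  kd <- ctx$reference_concentration * exp(dG / (ctx$R * ctx$T))
  100 * ctx$probe_concentration / (ctx$probe_concentration + kd)
}

#' Predict an observable on a measurement type's native scale
#'
#' Dispatches `dG` through the link function of the measurement type and
#' returns both the value and its analytic derivative with respect to `dG`,
#' so any gradient-based trainer can consume the link without symbolic
#' differentiation. `pKi` and `pIC50` share the `pKd` link, optionally
#' shifted by a per-assay additive `offset` (e.g., a Cheng-Prusoff
#' correction computed upstream when substrate concentration and Km are
#' known).
#'
#' @param dG Binding free energy, kcal/mol (scalar).
#' @param mtype One of `"pKd"`, `"pKi"`, `"pIC50"`,
#'   `"percent_displacement"`.
#' @param ctx A [thermo_context()].
#' @param offset Additive offset on the p-scale for `pKi`/`pIC50`.
#' @return A list with `value` and `grad` (= d value / d dG).
#' @export
predict_observable <- function(dG, mtype, ctx = thermo_context(),
                               offset = 0) {
  rt <- ctx$R * ctx$T
  if (mtype %in% c("pKd", "pKi", "pIC50")) {
    value <- pkd_from_dg(dG, ctx) + if (mtype == "pKd") 0 else offset
    list(value = value, grad = -1 / (rt * log(10)))
  } else if (mtype == "percent_displacement") {
    if (is.null(ctx$probe_concentration)) {
      stop("the percent-displacement link requires a probe_concentration ",
           "in the thermodynamic context; it is never defaulted")
    }
    kd <- ctx$reference_concentration * exp(dG / rt)
    l <- ctx$probe_concentration
    value <- 100 * l / (l + kd)
    # d value / d Kd = -100 L / (L+Kd)^2 ; d Kd / d dG = Kd / (R T)
    grad <- -100 * l * kd / ((l + kd)^2 * rt)
    list(value = value, grad = grad)
  } else {
    stop("unknown measurement type: '", mtype, "'")
  }
}

#' Squared-error observation loss and its gradient
#'
#' Mean squared error between the link-function prediction for `dG` and the
#' observed values of a measurement (replicates averaged), with the
#' chain-rule gradient with respect to `dG`. The thermodynamic context is
#' derived from the measurement's own assay conditions unless supplied.
#'
#' @param dG Latent binding free energy, kcal/mol (scalar).
#' @param measurement A [Measurement].
#' @param ctx Optional [thermo_context()]; default derives temperature and
#'   probe concentration from `measurement$conditions`.
#' @param offset Additive p-scale offset passed to [predict_observable()].
#' @return A list with `loss` (non-negative) and `grad`.
#' @export
observation_loss <- function(dG, measurement, ctx = NULL, offset = 0) {
  stopifnot(inherits(measurement, "Measurement"))
  if (is.null(ctx)) ctx <- context_from_conditions(measurement$conditions)
  pred <- predict_observable(dG, measurement$mtype, ctx, offset = offset)
  resid <- pred$value - measurement$values
  list(loss = mean(resid^2), grad = 2 * mean(resid) * pred$grad)
}

#' Recover a latent free energy from a system's measurements
#'
#' Minimizes the summed [observation_loss()] over all measurements of one
#' system by bounded scalar optimization.
#'
#' @param measurements List of [Measurement]s for one system.
#' @param interval Search interval for `dG` in kcal/mol.
#' @param ctx Optional shared [thermo_context()]; default per-measurement
#'   contexts from each measurement's conditions.
#' @return The minimizing `dG` in kcal/mol.
#' @export
fit_dg <- function(measurements, interval = c(-25, 5), ctx = NULL) {
  stopifnot(is.list(measurements), length(measurements) > 0L)
  objective <- function(dg) {
    sum(vapply(measurements,
               function(m) observation_loss(dg, m, ctx = ctx)$loss,
               numeric(1)))
  }
  stats::optimize(objective, interval = interval, tol = 1e-7)$minimum
}

#' Evaluate free-energy recovery on a simulated study
#'
#' For each simulated system, recovers the latent free energy by scalar
#' minimization of the observation loss and compares it with the truth at a
#' statistical tolerance of three standard errors: the observation noise is
#' propagated to the free-energy scale through the local link slope,
#' `tol = 3 * sigma / (|d obs / d dG| * sqrt(replicates))`.
#'
#' @param study Output of
#'   [generate_observation_study()].
#' @param interval Search interval for the free energy, kcal/mol.
#' @return A data.frame with columns `dg_true`, `dg_hat`, `mtype`, `tol`
#'   and `recovered`.
#' @export
evaluate_dg_recovery <- function(study, interval = c(-25, 5)) {
  rows <- lapply(study, function(sys) {
    m <- sys$measurement
    ctx <- context_from_conditions(m$conditions)
    dg_hat <- fit_dg(list(m), interval = interval)
    slope <- abs(predict_observable(sys$dg_true, sys$mtype, ctx)$grad)
    tol <- 3 * sys$sigma / (slope * sqrt(length(m$values)))
    data.frame(dg_true = sys$dg_true, dg_hat = dg_hat, mtype = sys$mtype,
               tol = tol,
               recovered = abs(dg_hat - sys$dg_true) <= tol,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
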