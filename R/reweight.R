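#' Temperature scaling factor
#'
#' Running a simulation at an elevated temperature `T_sim` is equivalent to
#' scaling the potential energy surface by `lambda = T_sim / T_ref`: the
#' Boltzmann weight at `T_sim` on the original potential equals the weight at
#' `T_ref` on the potential divided by `lambda`. This ratio is the scaling
#' factor used by [reweight_population()] and [reweight_log_rate()].
#'
#' @param T_sim simulation temperature (K), strictly positive.
#' @param T_ref reference (room) temperature (K), default 300.
#' @return dimensionless scaling factor `T_sim / T_ref`.
#' @examples
#' scaling_factor(900, 300)  # 3
#' @export
scaling_factor <- function(T_sim, T_ref = 300) {
  if (!is.numeric(T_sim) || !is.numeric(T_ref) ||
      any(!is.finite(T_sim)) || any(!is.finite(T_ref)) ||
      any(T_sim <= 0) || any(T_ref <= 0)) {
    stop_invalid("temperatures must be finite and strictly positive")
  }
  T_sim / T_ref
}

#' Reweight state populations observed on a scaled landscape
#'
#' State probabilities sampled at a scaled temperature are related to the
#' unscaled Boltzmann populations by an element-wise power: each observed
#' probability is raised to `lambda` and the vector is renormalized. With
#' `lambda = T_sim / T_ref` this recovers the populations that equilibrium
#' sampling at `T_ref` would have produced.
#'
#' @param p_scaled probability vector observed at the scaled temperature;
#'   nonnegative, summing to 1 (renormalized internally within tolerance).
#' @param lambda positive scaling factor, see [scaling_factor()].
#' @return probability vector on the unscaled landscape, same length.
#' @examples
#' reweight_population(c(0.75, 0.25), lambda = 2)  # c(0.9, 0.1)
#' @export
reweight_population <- function(p_scaled, lambda) {
  if (!is.numeric(p_scaled) || length(p_scaled) == 0 ||
      any(!is.finite(p_scaled)) || any(p_scaled < 0)) {
    stop_invalid("p_scaled must be a nonnegative, finite probability vector")
  }
  s <- sum(p_scaled)
  if (s <= 0) stop_invalid("p_scaled must have positive total probability")
  if (abs(s - 1) > 1e-6) {
    stop_invalid("p_scaled must sum to 1 (got ", format(s), ")")
  }
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda <= 0) {
    stop_invalid("lambda must be a single positive number")
  }
  # Work in log space: p_i^lambda under/overflows for sharp distributions.
  lp <- lambda * log(p_scaled)
  lp <- lp - max(lp[is.finite(lp)])
  w <- exp(lp)
  w / sum(w)
}

#' Reweight a log10 rate from the scaled to the reference temperature
#'
#' Under an Arrhenius rate law with a barrier-independent prefactor, scaling
#' the temperature by `lambda` divides the exponent by `lambda`, so the
#' log-rate observed at `T_sim` maps back to `T_ref` linearly:
#' `log10 k(T_ref) = lambda * log10 k(T_sim) + c`. The additive constant `c`
#' collects the prefactor and unit choices; it cancels in rate differences
#' and is absorbed when predictions are normalized onto an experimental
#' range ([normalize_to_reference()]). The map is strictly increasing, so
#' the rank order of ligands is preserved for any `lambda > 0`.
#'
#' @param log10_k_scaled log10 of the rate measured at the scaled
#'   temperature (any consistent rate unit).
#' @param lambda positive scaling factor `T_sim / T_ref`.
#' @param offset additive constant `c` on the log10 scale, default 0.
#' @return log10 rate at the reference temperature (relative scale).
#' @export
reweight_log_rate <- function(log10_k_scaled, lambda, offset = 0) {
  if (!is.numeric(log10_k_scaled) || any(!is.finite(log10_k_scaled))) {
    stop_invalid("log10_k_scaled must be finite")
  }
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda <= 0) {
    stop_invalid("lambda must be a single positive number")
  }
  if (!is.numeric(offset) || length(offset) != 1 || !is.finite(offset)) {
    stop_invalid("offset must be a single finite number")
  }
  lambda * log10_k_scaled + offset
}

#' Convert a median first-unbinding time to a rate
#'
#' For an exponential first-passage time distribution with rate `k`, the
#' median is `ln(2) / k`, so the rate recovered from a median unbinding time
#' is `ln(2) / tau_median`. Any other constant convention only shifts the
#' log-rate by a constant, which cancels in relative comparisons; the
#' constant is configurable for that reason.
#'
#' @param tau_median median unbinding time, finite and positive (censoring
#'   must be resolved upstream, see [median_unbinding_time()]).
#' @param convention_constant numerator constant, default `log(2)`.
#' @return rate in inverse units of `tau_median`.
#' @export
rate_from_median_time <- function(tau_median, convention_constant = log(2)) {
  if (!is.numeric(tau_median) || any(!is.finite(tau_median)) ||
      any(tau_median <= 0)) {
    stop_invalid("tau_median must be finite and strictly positive ",
                 "(censored medians cannot be converted to a rate)")
  }
  convention_constant / tau_median
}

#' Binding free energy from a dissociation constant
#'
#' `dG = R T ln(Kd)` with `R = 1.987e-3` kcal mol^-1 K^-1 and a 1 M
#' standard-state reference. A 10 nM binder at 298 K corresponds to
#' -10.9 kcal/mol.
#'
#' @param kd dissociation constant (M), strictly positive.
#' @param temperature temperature (K), default 298.
#' @return free energy of binding (kcal/mol); negative for sub-molar Kd.
#' @examples
#' dg_from_kd(1e-8, 298)  # approximately -10.9
#' @export
dg_from_kd <- function(kd, temperature = 298) {
  if (!is.numeric(kd) || any(!is.finite(kd)) || any(kd <= 0)) {
    stop_invalid("kd must be finite and strictly positive")
  }
  if (any(temperature <= 0)) stop_invalid("temperature must be positive")
  R_KCAL_PER_MOL_K * temperature * log(kd)
}

#' Dissociation constant from a binding free energy
#'
#' Inverse of [dg_from_kd()]: `Kd = exp(dG / (R T))`.
#'
#' @inheritParams dg_from_kd
#' @param dg free energy of binding (kcal/mol).
#' @return dissociation constant (M).
#' @export
kd_from_dg <- function(dg, temperature = 298) {
  if (!is.numeric(dg) || any(!is.finite(dg))) stop_invalid("dg must be finite")
  if (any(temperature <= 0)) stop_invalid("temperature must be positive")
  exp(dg / (R_KCAL_PER_MOL_K * temperature))
}

#' Dissociation constant from kinetic rates
#'
#' `Kd = k_off / k_on`: affinity improves (Kd drops) as the off-rate slows
#' or the on-rate speeds up.
#'
#' @param koff dissociation rate (s^-1), positive.
#' @param kon association rate (M^-1 s^-1), positive.
#' @return equilibrium dissociation constant (M).
#' @export
kd_from_rates <- function(koff, kon) {
  if (!is.numeric(koff) || !is.numeric(kon) ||
      any(!is.finite(koff)) || any(!is.finite(kon)) ||
      any(koff <= 0) || any(kon <= 0)) {
    stop_invalid("koff and kon must be finite and strictly positive")
  }
  koff / kon
}

#' Min-max normalization of predicted scores onto a reference range
#'
#' Relative log-rate predictions carry an undetermined additive constant and
#' scale; to compare them to experiment they are mapped affinely so that the
#' prediction minimum and maximum land on the experimental minimum and
#' maximum for the target. Rank order is unchanged.
#'
#' @param pred numeric vector of predicted scores with at least two distinct
#'   values.
#' @param ref_min,ref_max reference range endpoints, `ref_max > ref_min`.
#' @return vector of the same length spanning exactly
#'   `[ref_min, ref_max]`.
#' @examples
#' normalize_to_reference(c(1, 2, 4), 0, 6)  # c(0, 2, 6)
#' @export
normalize_to_reference <- function(pred, ref_min, ref_max) {
  if (!is.numeric(pred) || length(pred) < 2 || any(!is.finite(pred))) {
    stop_invalid("pred must be a finite numeric vector of length >= 2")
  }
  rng <- range(pred)
  if (rng[1] == rng[2]) {
    stop_invalid("pred is constant: range normalization is degenerate")
  }
  if (!is.numeric(ref_min) || !is.numeric(ref_max) || ref_max <= ref_min) {
    stop_invalid("require ref_max > ref_min")
  }
  ref_min + (pred - rng[1]) / (rng[2] - rng[1]) * (ref_max - ref_min)
}
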