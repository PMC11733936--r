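#' Piecewise-parabolic metastable well with a tunable barrier
#'
#' A one-dimensional model of a bound ligand: a harmonic well at the origin
#' (the bound pose) joined C1-continuously to an inverted parabola whose top
#' sits at the barrier height `barrier_height` above the well bottom.
#' Escape over the barrier mimics ligand unbinding; the closed-form Kramers
#' rate ([kramers_rate()]) makes the model an analytic oracle for the
#' statistics of the full pipeline.
#'
#' Reduced units are used throughout: `k_B = 1`, so energies are in units of
#' `k_B * T_ref` and temperature is dimensionless (1 = reference
#' temperature). The barrier position is not free: continuity of value and
#' slope fixes the join point `x* = sqrt(2 dV / (wa2 (1 + wa2/wb2)))` and
#' the barrier top `b = x* (1 + wa2/wb2)`. Keeping the curvatures fixed
#' while varying the height therefore leaves the Kramers prefactor
#' unchanged — the property that makes rate ratios purely Arrhenius.
#'
#' @param barrier_height barrier height above the well bottom, in k_B T_ref
#'   units; strictly positive.
#' @param well_curvature second derivative of the potential at the well
#'   bottom (omega_a^2), positive; default 1.
#' @param barrier_curvature magnitude of the second derivative at the
#'   barrier top (omega_b^2), positive; default 1.
#' @param symmetric if `TRUE`, the potential is mirrored about the well so
#'   that `V(x) = V(-x)` (a genuine double well); escape simulations use the
#'   one-sided form.
#' @return object of class `toy_potential` with fields `barrier_height`,
#'   `well_curvature`, `barrier_curvature`, `well_position` (0),
#'   `barrier_position`, `join_position`, `symmetric`.
#' @export
toy_potential <- function(barrier_height, well_curvature = 1,
                          barrier_curvature = 1, symmetric = FALSE) {
  if (!is.numeric(barrier_height) || length(barrier_height) != 1 ||
      !is.finite(barrier_height) || barrier_height <= 0) {
    stop_invalid("barrier_height must be a single positive number")
  }
  if (well_curvature <= 0 || barrier_curvature <= 0) {
    stop_invalid("curvatures must be positive")
  }
  ratio <- well_curvature / barrier_curvature
  xjoin <- sqrt(2 * barrier_height / (well_curvature * (1 + ratio)))
  structure(
    list(barrier_height = barrier_height,
         well_curvature = well_curvature,
         barrier_curvature = barrier_curvature,
         well_position = 0,
         join_position = xjoin,
         barrier_position = xjoin * (1 + ratio),
         symmetric = isTRUE(symmetric)),
    class = "toy_potential"
  )
}

#' @export
print.toy_potential <- function(x, ...) {
  cat(sprintf(
    "toy_potential: barrier %.3g kT_ref at x = %.3g (well curvature %.3g, barrier curvature %.3g%s)\n",
    x$barrier_height, x$barrier_position, x$well_curvature,
    x$barrier_curvature, if (x$symmetric) ", symmetric" else ""))
  invisible(x)
}

#' Potential energy of the toy well
#'
#' Vectorized over `x`; zero at the well bottom, `barrier_height` at the
#' barrier top.
#'
#' @param x positions (reduced length units).
#' @param pot a [toy_potential()].
#' @return energies in k_B T_ref units.
#' @export
double_well_energy <- function(x, pot) {
  stopifnot(inherits(pot, "toy_potential"))
  if (!is.numeric(x) || any(!is.finite(x))) stop_invalid("x must be finite")
  xx <- if (pot$symmetric) abs(x) else x
  ifelse(xx <= pot$join_position,
         0.5 * pot$well_curvature * xx^2,
         pot$barrier_height -
           0.5 * pot$barrier_curvature * (xx - pot$barrier_position)^2)
}

#' Closed-form Kramers escape rate for the toy well
#'
#' High-barrier escape rate of overdamped dynamics over a parabolic barrier:
#' `k = sqrt(wa2 * wb2) / (2 pi gamma) * exp(-dV / T)`. Exact in the limit
#' `dV / T -> Inf`; a warning is issued below `dV / T = 3` where the
#' saddle-point approximation degrades.
#'
#' @param pot a [toy_potential()].
#' @param temperature reduced temperature (k_B T in well-energy units).
#' @param friction friction coefficient gamma (inverse reduced time).
#' @return escape rate in inverse reduced time units.
#' @examples
#' kramers_rate(toy_potential(5), temperature = 1)  # (1/2pi) exp(-5)
#' @export
kramers_rate <- function(pot, temperature, friction = 1) {
  stopifnot(inherits(pot, "toy_potential"))
  if (!is.numeric(temperature) || any(temperature <= 0) || any(friction <= 0)) {
    stop_invalid("temperature and friction must be positive")
  }
  if (any(pot$barrier_height / temperature < 3)) {
    warning("barrier height below 3 kT: Kramers approximation is inaccurate",
            call. = FALSE)
  }
  sqrt(pot$well_curvature * pot$barrier_curvature) / (2 * pi * friction) *
    exp(-pot$barrier_height / temperature)
}

#' Replica plan for toy Langevin escape simulations
#'
#' @param temperature reduced simulation temperature (> 0).
#' @param friction friction gamma, default 1.
#' @param dt integration time step; must satisfy the overdamped stability
#'   bound `dt < 0.1 / friction`.
#' @param t_max maximum simulated time per replica; replicas that have not
#'   escaped by then are censored.
#' @param seed base integer seed; replica `i` uses `seed + i - 1`.
#' @param n_replicas number of independent replicas (>= 1).
#' @return object of class `langevin_spec`.
#' @export
langevin_spec <- function(temperature, friction = 1, dt = 0.005, t_max,
                          seed = 1L, n_replicas = 1L) {
  if (temperature <= 0) stop_invalid("temperature must be positive")
  if (friction <= 0) stop_invalid("friction must be positive")
  if (dt <= 0 || dt >= 0.1 / friction) {
    stop_invalid("dt violates the stability bound dt < 0.1 / friction")
  }
  if (t_max <= 0) stop_invalid("t_max must be positive")
  if (n_replicas < 1) stop_invalid("n_replicas must be >= 1")
  structure(
    list(temperature = temperature, friction = friction, dt = dt,
         t_max = t_max, seed = as.integer(seed),
         n_replicas = as.integer(n_replicas)),
    class = "langevin_spec"
  )
}

#' Simulate first-passage escape times from the toy well
#'
#' Runs `n_replicas` independent overdamped Langevin (Euler-Maruyama)
#' trajectories starting at the well bottom and records, per replica, the
#' first time the particle crosses the absorbing boundary one reduced length
#' unit beyond the barrier top (irreversible escape, the analogue of the
#' ligand-RMSD unbinding cutoff). Replicas that never escape within
#' `t_max` are censored. Replica `i` is seeded with `spec$seed + i - 1`, so
#' results are reproducible and independent of execution order.
#'
#' @param pot a [toy_potential()].
#' @param spec a [langevin_spec()].
#' @param margin absorbing-boundary offset beyond the barrier top (reduced
#'   length), default 1.
#' @return data.frame of class `escape_sample` with columns `replica_id`,
#'   `escape_time` (NA when censored), `censored`, `t_max`.
#' @export
simulate_escape <- function(pot, spec, margin = 1) {
  stopifnot(inherits(pot, "toy_potential"), inherits(spec, "langevin_spec"))
  absorb <- pot$barrier_position + margin
  times <- vapply(seq_len(spec$n_replicas), function(i) {
    set.seed(spec$seed + i - 1L)
    langevin_escape_time(pot$well_curvature, pot$barrier_curvature,
                         pot$barrier_height, pot$barrier_position,
                         pot$join_position, absorb, spec$temperature,
                         spec$friction, spec$dt, spec$t_max)
  }, numeric(1))
  out <- data.frame(replica_id = seq_len(spec$n_replicas),
                    escape_time = times,
                    censored = is.na(times),
                    t_max = spec$t_max)
  class(out) <- c("escape_sample", class(out))
  out
}

#' Empirical escape rate from an escape sample
#'
#' Median-based rate estimate used by the main pipeline: censored replicas
#' enter the order statistics at `t_max` and the rate is
#' `ln(2) / median`. Provided as a convenience wrapper around
#' [median_unbinding_time()] + [rate_from_median_time()].
#'
#' @param sample an `escape_sample` from [simulate_escape()].
#' @return list with `rate`, `tau_median`, `quality`.
#' @export
escape_rate <- function(sample) {
  events <- unbinding_events(
    replica_id = sample$replica_id,
    unbind_time = sample$escape_time,
    t_max = sample$t_max
  )
  med <- median_unbinding_time(events)
  list(rate = rate_from_median_time(med$tau_median),
       tau_median = med$tau_median, quality = med$quality)
}
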