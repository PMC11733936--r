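#' Superpose every frame onto the first frame (protein-to-protein)
#'
#' Removes rigid-body drift by least-squares (Kabsch) superposition of the
#' protein selection of each frame onto frame 1; the fitted transform is
#' applied to all atoms, so subsequent ligand RMSD reflects motion relative
#' to the protein, not global tumbling.
#'
#' @param traj a [trajectory()].
#' @param selection atom indices used for the fit; default all protein
#'   atoms. Must contain at least 3 non-collinear atoms.
#' @return a superposed [trajectory()].
#' @export
superpose_to_first_frame <- function(traj,
                                     selection = traj$topology$protein) {
  stopifnot(inherits(traj, "trajectory"))
  selection <- as.integer(selection)
  if (length(selection) < 3) {
    stop_invalid("superposition selection needs at least 3 atoms")
  }
  ref <- frame_coords(traj, 1, selection)
  centered <- sweep(ref, 2, colMeans(ref))
  if (sum(svd(centered)$d > 1e-8) < 2) {
    stop_invalid("superposition selection is degenerate (collinear atoms)")
  }
  inds <- xyz_indices(selection)
  fitted <- bio3d::fit.xyz(fixed = traj$xyz[1, ], mobile = traj$xyz,
                           fixed.inds = inds, mobile.inds = inds)
  fitted <- matrix(fitted, nrow = nrow(traj$xyz))
  trajectory(fitted, traj$times, traj$topology)
}

#' Ligand RMSD time series against the first frame
#'
#' Per-frame root-mean-square deviation of the ligand heavy atoms from
#' their frame-1 positions. No additional fitting is applied to the ligand:
#' the trajectory must already be protein-superposed
#' ([superpose_to_first_frame()]), so the series measures displacement of
#' the ligand out of the binding pose.
#'
#' @param traj a superposed [trajectory()].
#' @return object of class `rmsd_series`: a data.frame with columns `time`
#'   (ps) and `rmsd` (A); the first value is 0 by construction.
#' @export
ligand_rmsd_series <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- traj$topology$ligand_heavy
  if (length(idx) == 0) stop_invalid("ligand heavy-atom selection is empty")
  ref <- frame_coords(traj, 1, idx)
  vals <- vapply(seq_len(nrow(traj$xyz)), function(f) {
    d <- frame_coords(traj, f, idx) - ref
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  structure(data.frame(time = traj$times, rmsd = vals),
            class = c("rmsd_series", "data.frame"))
}

#' Construct a table of per-replica unbinding events
#'
#' @param replica_id replica identifiers.
#' @param unbind_time first-unbinding times; `NA` marks a censored replica
#'   (still bound at `t_max`).
#' @param t_max maximum simulated time per replica (same units as
#'   `unbind_time`).
#' @return data.frame of class `unbinding_events` with columns
#'   `replica_id`, `unbind_time`, `censored`, `t_max`.
#' @export
unbinding_events <- function(replica_id, unbind_time, t_max) {
  censored <- is.na(unbind_time)
  df <- data.frame(replica_id = replica_id, unbind_time = unbind_time,
                   censored = censored, t_max = t_max)
  bad <- !censored & (df$unbind_time <= 0 | df$unbind_time > df$t_max + 1e-9)
  if (any(bad)) {
    stop_invalid("uncensored unbinding times must lie in (0, t_max]")
  }
  class(df) <- c("unbinding_events", class(df))
  df
}

#' Detect the first sustained unbinding event in an RMSD series
#'
#' The ligand is classified unbound when its RMSD exceeds `cutoff`
#' (default 5 A). To suppress transient recrossing excursions, unbinding is
#' only called at the first frame that begins a run of at least
#' `persistence` consecutive unbound frames (the single-cutoff rule is
#' recovered with `persistence = 1`); shorter excursions, including one
#' truncated by the end of the trajectory, are ignored. The reported time
#' is the time stamp of that first frame (earliest-evidence convention). If
#' no qualifying run exists, the event is censored at the last frame time.
#'
#' @param series an [ligand_rmsd_series()] result.
#' @param cutoff bound/unbound RMSD cutoff in A, default 5.
#' @param persistence minimum run length in frames, default 5 (50 ps at a
#'   10 ps interval).
#' @param replica_id identifier stored in the event, default `NA`.
#' @return one-row [unbinding_events()] table.
#' @export
detect_unbinding <- function(series, cutoff = 5, persistence = 5,
                             replica_id = NA_integer_) {
  if (!inherits(series, "rmsd_series") || nrow(series) == 0) {
    stop_invalid("series must be a nonempty rmsd_series")
  }
  if (persistence < 1) stop_invalid("persistence must be >= 1")
  above <- series$rmsd > cutoff
  t_max <- series$time[nrow(series)]
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  hit <- which(runs$values & runs$lengths >= persistence)
  if (length(hit) == 0) {
    return(unbinding_events(replica_id, NA_real_, t_max))
  }
  unbinding_events(replica_id, series$time[starts[hit[1]]], t_max)
}

#' Bundle per-replica events for one ligand at one temperature
#'
#' @param ligand_id ligand identifier.
#' @param T_sim simulation temperature (K, or reduced units for the toy
#'   backend).
#' @param events an [unbinding_events()] table.
#' @return object of class `replica_set_result` with `fraction_unbound`.
#' @export
replica_set_result <- function(ligand_id, T_sim, events) {
  stopifnot(inherits(events, "unbinding_events"))
  if (nrow(events) == 0) stop_invalid("event list is empty")
  structure(
    list(ligand_id = ligand_id, T_sim = T_sim, events = events,
         fraction_unbound = mean(!events$censored)),
    class = "replica_set_result"
  )
}

#' Median unbinding time across replicas, with censoring
#'
#' Replicas whose ligand never unbinds carry information (their time is at
#' least `t_max`); dropping them would bias the median low. Under the
#' default policy censored replicas therefore enter the order statistics at
#' `t_max`. The estimate is flagged `RELIABLE` only when strictly more than
#' half the replicas are uncensored — then the sample median cannot sit on
#' a censored value — and `LOWER_BOUND` otherwise. Even counts use the mean
#' of the two middle order statistics.
#'
#' @param events an [unbinding_events()] table with at least one row.
#' @param policy `"tmax"` (default: censored events enter at `t_max`) or
#'   `"drop"` (censored events are discarded; biased, for comparison only).
#' @return list with `tau_median`, `quality` (`"RELIABLE"` or
#'   `"LOWER_BOUND"`), `n`, `n_unbound`.
#' @export
median_unbinding_time <- function(events, policy = c("tmax", "drop")) {
  stopifnot(inherits(events, "unbinding_events"))
  policy <- match.arg(policy)
  if (nrow(events) == 0) stop_invalid("event list is empty")
  n <- nrow(events)
  n_unbound <- sum(!events$censored)
  values <- switch(policy,
    tmax = ifelse(events$censored, events$t_max, events$unbind_time),
    drop = {
      if (n_unbound == 0) stop_invalid("all replicas censored: no median")
      events$unbind_time[!events$censored]
    })
  list(tau_median = stats::median(values),
       quality = if (n_unbound > n / 2) "RELIABLE" else "LOWER_BOUND",
       n = n, n_unbound = n_unbound)
}

to_ns <- function(t, time_in) {
  switch(time_in, ps = t / 1000, ns = t, reduced = t,
         stop_invalid("time_in must be 'ps', 'ns' or 'reduced'"))
}

#' Reweighted off-rate estimate for one ligand
#'
#' Composes the full estimator: median first-unbinding time across replicas
#' ([median_unbinding_time()]) -> scaled-temperature rate
#' ([rate_from_median_time()]) -> log10 rate reweighted to the reference
#' temperature ([reweight_log_rate()] with `lambda = T_sim / T_ref`). All
#' intermediates are kept on the returned object for audit.
#'
#' An estimate whose median is only a lower bound (half or more replicas
#' censored) is refused unless `accept_lower_bound = TRUE`; raise the
#' simulation temperature or extend `t_max` so that most replicas unbind.
#'
#' @param result a [replica_set_result()].
#' @param T_ref reference temperature, default 300 (K); use 1 for
#'   reduced-unit toy systems.
#' @param offset additive constant on the reweighted log10 scale, default 0
#'   (absorbed by [normalize_to_reference()]).
#' @param time_in unit of the event times: `"ps"` (default, converted to ns
#'   for the rate), `"ns"`, or `"reduced"`.
#' @param censoring_policy passed to [median_unbinding_time()].
#' @param accept_lower_bound allow a `LOWER_BOUND` median, default `FALSE`.
#' @return object of class `rate_estimate`: `ligand_id`, `T_sim`, `T_ref`,
#'   `lambda`, `tau_median` (input units), `tau_ns`, `quality`,
#'   `n_replicas`, `n_unbound`, `k_scaled` (ns^-1, or inverse reduced
#'   time), `log10_koff_ref`, `offset`, `normalized` (FALSE).
#' @export
estimate_koff <- function(result, T_ref = 300, offset = 0, time_in = "ps",
                          censoring_policy = "tmax",
                          accept_lower_bound = FALSE) {
  stopifnot(inherits(result, "replica_set_result"))
  med <- median_unbinding_time(result$events, policy = censoring_policy)
  if (med$quality == "LOWER_BOUND" && !accept_lower_bound) {
    stop_invalid("median unbinding time for '", result$ligand_id,
                 "' is only a lower bound (", med$n_unbound, "/", med$n,
                 " replicas unbound): raise the simulation temperature or ",
                 "extend t_max, or pass accept_lower_bound = TRUE")
  }
  lambda <- scaling_factor(result$T_sim, T_ref)
  tau_ns <- to_ns(med$tau_median, time_in)
  k_scaled <- rate_from_median_time(tau_ns)
  structure(
    list(ligand_id = result$ligand_id, T_sim = result$T_sim, T_ref = T_ref,
         lambda = lambda, tau_median = med$tau_median, tau_ns = tau_ns,
         quality = med$quality, n_replicas = med$n,
         n_unbound = med$n_unbound, k_scaled = k_scaled,
         log10_koff_ref = reweight_log_rate(log10(k_scaled), lambda, offset),
         offset = offset, normalized = FALSE),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "rate_estimate [%s]: tau_median = %.4g (%s), k_scaled = %.4g, lambda = %.3g -> log10 k_off(T_ref) = %.4g\n",
    x$ligand_id, x$tau_median, x$quality, x$k_scaled, x$lambda,
    x$log10_koff_ref))
  invisible(x)
}

#' Pick the lowest workable simulation temperature from a scan
#'
#' Given replica sets for one or more reference ligands across several
#' candidate temperatures, recommends the lowest temperature at which every
#' ligand has a `RELIABLE` median unbinding time inside the target window
#' (e.g. a dynamic range achievable within <= 4 ns per replica). Lower
#' temperatures distort the landscape less, so among qualifying
#' temperatures the lowest wins.
#'
#' @param results list of [replica_set_result()] objects covering >= 2
#'   temperatures.
#' @param target_window length-2 numeric `c(t_lo, t_hi)` in ns.
#' @param time_in unit of the event times, as in [estimate_koff()].
#' @return list with `recommended` (temperature, or `NA` with
#'   `no_solution = TRUE`) and `table` (one row per temperature x ligand:
#'   `temperature`, `ligand_id`, `tau_ns`, `quality`, `in_window`).
#' @export
temperature_scan <- function(results, target_window, time_in = "ps") {
  if (!length(results) ||
      !all(vapply(results, inherits, logical(1), "replica_set_result"))) {
    stop_invalid("results must be a list of replica_set_result objects")
  }
  if (length(target_window) != 2 || target_window[1] >= target_window[2]) {
    stop_invalid("target_window must be c(t_lo, t_hi) with t_lo < t_hi")
  }
  rows <- do.call(rbind, lapply(results, function(r) {
    med <- median_unbinding_time(r$events)
    tau_ns <- to_ns(med$tau_median, time_in)
    data.frame(temperature = r$T_sim, ligand_id = r$ligand_id,
               tau_ns = tau_ns, quality = med$quality,
               in_window = med$quality == "RELIABLE" &
                 tau_ns >= target_window[1] & tau_ns <= target_window[2])
  }))
  temps <- sort(unique(rows$temperature))
  if (length(temps) < 2) {
    stop_invalid("temperature scan needs results at >= 2 temperatures")
  }
  ok <- temps[vapply(temps, function(tt) {
    all(rows$in_window[rows$temperature == tt])
  }, logical(1))]
  list(recommended = if (length(ok)) min(ok) else NA_real_,
       no_solution = length(ok) == 0,
       table = rows[order(rows$temperature, rows$ligand_id), ])
}
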