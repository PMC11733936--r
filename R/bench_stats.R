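#' Regression metrics for log-scale benchmark predictions
#'
#' Correlation and error summaries in the convention of prediction-vs-
#' experiment scatter plots: `r_squared` is the squared Pearson correlation
#' (invariant under affine transforms of the predictions, matching how
#' normalized relative predictions are judged), `rmse` and `mue` are the
#' root-mean-square and mean unsigned error of `predicted - observed` on
#' the shared (log) scale.
#'
#' @param records data.frame with numeric columns `observed` and
#'   `predicted` on the same scale; at least 3 rows, non-constant
#'   `observed`.
#' @return list with `r_squared`, `rmse`, `mue`, `n`.
#' @export
regression_metrics <- function(records) {
  if (!all(c("observed", "predicted") %in% names(records))) {
    stop_invalid("records need columns 'observed' and 'predicted'")
  }
  obs <- records$observed
  pred <- records$predicted
  if (length(obs) < 3) stop_invalid("need at least 3 records")
  if (any(!is.finite(obs)) || any(!is.finite(pred))) {
    stop_invalid("observed/predicted must be finite")
  }
  if (stats::sd(obs) == 0) {
    stop_invalid("observed values are constant: R^2 undefined")
  }
  err <- pred - obs
  list(r_squared = stats::cor(obs, pred)^2,
       rmse = sqrt(mean(err^2)),
       mue = mean(abs(err)),
       n = length(obs))
}

#' Filtering rules for benchmark records
#'
#' @param excluded_mode_classes character vector of `binding_mode_class`
#'   labels to drop (e.g. kinase inhibitors classified type-1/type-2 for
#'   the same target, or transition-state-targeting inhibitors, whose
#'   k_off/K_d relationship is dominated by binding-mode and protein
#'   conformational effects).
#' @param drop_singleton_targets drop targets contributing a single record
#'   (range normalization is impossible for them), default `FALSE`.
#' @return object of class `filter_rules`.
#' @export
filter_rules <- function(excluded_mode_classes = character(0),
                         drop_singleton_targets = FALSE) {
  structure(list(excluded_mode_classes = as.character(excluded_mode_classes),
                 drop_singleton_targets = isTRUE(drop_singleton_targets)),
            class = "filter_rules")
}

#' Apply filtering rules to benchmark records
#'
#' @param records data.frame with at least `target_id`; a
#'   `binding_mode_class` column is required when mode classes are
#'   excluded.
#' @param rules a [filter_rules()].
#' @return list with `records` (survivors) and `removal_log` (data.frame
#'   of `rule`, `value`, `n_removed`).
#' @export
filter_records <- function(records, rules) {
  stopifnot(inherits(rules, "filter_rules"))
  log_rows <- list()
  if (length(rules$excluded_mode_classes)) {
    if (!("binding_mode_class" %in% names(records))) {
      stop_invalid("rules exclude mode classes but records have no ",
                   "'binding_mode_class' column")
    }
    for (cls in rules$excluded_mode_classes) {
      drop <- records$binding_mode_class == cls
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(rule = "excluded_mode_class", value = cls,
                   n_removed = sum(drop))
      records <- records[!drop, , drop = FALSE]
    }
  }
  if (rules$drop_singleton_targets) {
    counts <- table(records$target_id)
    singletons <- names(counts)[counts == 1]
    drop <- records$target_id %in% singletons
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(rule = "drop_singleton_targets",
                 value = sprintf("%d targets", length(singletons)),
                 n_removed = sum(drop))
    records <- records[!drop, , drop = FALSE]
  }
  list(records = records,
       removal_log = if (length(log_rows)) do.call(rbind, log_rows)
                     else data.frame(rule = character(0),
                                     value = character(0),
                                     n_removed = integer(0)))
}

#' Per-target range normalization of predictions
#'
#' Relative predictions carry a per-target offset and scale; to pool
#' targets, each target's predictions are mapped affinely onto that
#' target's observed min-max range ([normalize_to_reference()] per group).
#' Within-target rank order is unchanged. Targets with a single record (or
#' a degenerate range) cannot be normalized: they raise an error unless
#' `drop_singletons = TRUE`, in which case they are removed and counted.
#'
#' @param records data.frame with `target_id`, `observed`, `predicted`.
#' @param drop_singletons drop non-normalizable targets instead of
#'   erroring, default `FALSE`.
#' @return list with `records` (predicted replaced by its normalized
#'   value), `n_targets_dropped`, `dropped_targets`.
#' @export
per_target_range_normalize <- function(records, drop_singletons = FALSE) {
  req <- c("target_id", "observed", "predicted")
  if (!all(req %in% names(records))) {
    stop_invalid("records need columns: ", paste(req, collapse = ", "))
  }
  groups <- split(seq_len(nrow(records)), records$target_id)
  normalizable <- vapply(groups, function(idx) {
    length(idx) >= 2 &&
      length(unique(records$observed[idx])) >= 2 &&
      length(unique(records$predicted[idx])) >= 2
  }, logical(1))
  if (any(!normalizable) && !drop_singletons) {
    stop_invalid("target(s) not normalizable (need >= 2 distinct observed ",
                 "and predicted values): ",
                 paste(names(groups)[!normalizable], collapse = ", "),
                 "; set drop_singletons = TRUE to remove them")
  }
  for (g in names(groups)[normalizable]) {
    idx <- groups[[g]]
    rng <- range(records$observed[idx])
    records$predicted[idx] <-
      normalize_to_reference(records$predicted[idx], rng[1], rng[2])
  }
  keep <- unlist(groups[normalizable], use.names = FALSE)
  list(records = records[sort(keep), , drop = FALSE],
       n_targets_dropped = sum(!normalizable),
       dropped_targets = names(groups)[!normalizable])
}

#' Fraction of predictions within absolute error bands
#'
#' The headline accuracy summary for log-scale predictions: the fraction
#' of records with `|predicted - observed| <= band`, for each band width
#' (boundary inclusive). Nondecreasing in the band width.
#'
#' @param records data.frame with `observed` and `predicted`.
#' @param bands nonnegative band widths in the shared (log) unit, e.g.
#'   `c(1, 2)`.
#' @return named numeric vector of fractions, one per band.
#' @export
error_band_fractions <- function(records, bands = c(1, 2)) {
  if (!all(c("observed", "predicted") %in% names(records)) ||
      nrow(records) == 0) {
    stop_invalid("records need >= 1 row with 'observed' and 'predicted'")
  }
  if (any(bands < 0)) stop_invalid("bands must be nonnegative")
  err <- abs(records$predicted - records$observed)
  setNames(vapply(bands, function(b) mean(err <= b), numeric(1)),
           paste0("within_", bands))
}
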