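#' Enrichment factor
#'
#' `EF = (a/n) / (A/N)`: the concentration of actives among the top `n`
#' selected compounds relative to the whole library. 1 is random
#' expectation; the maximum is `N/A` (or `n` when `n < A`... capped by
#' `min(n, A)/n / (A/N)`).
#'
#' @param a actives found in the sample.
#' @param n sample size.
#' @param A total actives in the library.
#' @param N total library size (actives + decoys).
#' @return dimensionless enrichment factor.
#' @examples
#' enrichment_factor(5, 5, 20, 100)  # 5
#' @export
enrichment_factor <- function(a, n, A, N) {
  ok <- is.numeric(c(a, n, A, N)) && a >= 0 && n > 0 && A > 0 && N > 0 &&
    a <= min(n, A) && n <= N && A <= N
  if (!ok) {
    stop_invalid("require 0 <= a <= min(n, A), 0 < n <= N, 0 < A <= N")
  }
  (a / n) / (A / N)
}

check_screen_records <- function(records, score_field) {
  req <- c("compound_id", "label", score_field)
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop_invalid("records are missing columns: ",
                 paste(missing_cols, collapse = ", "))
  }
  if (!all(records$label %in% c("ACTIVE", "DECOY"))) {
    stop_invalid("labels must be 'ACTIVE' or 'DECOY'")
  }
  for (cls in c(ACTIVE = "ACTIVE", DECOY = "DECOY")) {
    if (!any(records$label == cls)) {
      stop_invalid("records contain no ", cls, " compounds")
    }
  }
  if (any(!is.finite(records[[score_field]]))) {
    stop_invalid("scores in '", score_field, "' must be finite")
  }
  invisible(records)
}

# Scores oriented so that larger = better, per the declared direction.
oriented_scores <- function(records, score_field,
                            direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  s <- records[[score_field]]
  if (direction == "lower") -s else s
}

#' Cumulative enrichment curve from ranked screening records
#'
#' Sorts compounds by the chosen score — the direction of "better" must be
#' stated explicitly, since docking scores are better-lower while
#' predicted log10 k_off is better-lower for slow dissociaters — and
#' accumulates the fraction of actives recovered versus the fraction of the
#' library screened. Ties are broken by the stable input order of
#' `compound_id` and counted on the result.
#'
#' @param records data.frame with columns `compound_id`, `label`
#'   (`"ACTIVE"`/`"DECOY"`) and the score column.
#' @param score_field name of the score column.
#' @param direction `"lower"` if smaller scores are better (default) or
#'   `"higher"`.
#' @return object of class `enrichment_curve`: data.frame with
#'   `fraction_screened` and `fraction_actives_found` (including the (0,0)
#'   origin), with attributes `auc` (area under this curve), `n_ties`,
#'   `n_actives`, `n_total`.
#' @export
rank_and_curve <- function(records, score_field = "docking_score",
                           direction = c("lower", "higher")) {
  check_screen_records(records, score_field)
  s <- oriented_scores(records, score_field, direction)
  ord <- order(-s)  # stable radix/shell order: ties keep input order
  hits <- records$label[ord] == "ACTIVE"
  A <- sum(hits)
  N <- length(hits)
  curve <- data.frame(
    fraction_screened = c(0, seq_len(N) / N),
    fraction_actives_found = c(0, cumsum(hits) / A)
  )
  auc <- sum(diff(curve$fraction_screened) *
               (utils::head(curve$fraction_actives_found, -1) +
                utils::tail(curve$fraction_actives_found, -1)) / 2)
  structure(curve, class = c("enrichment_curve", "data.frame"),
            auc = auc, n_ties = N - length(unique(s)),
            n_actives = A, n_total = N)
}

#' Enrichment factor at a top fraction of the ranked library
#'
#' @inheritParams rank_and_curve
#' @param fraction fraction of the library to select (e.g. 0.05); the
#'   sample size is `max(1, floor(fraction * N))`.
#' @return enrichment factor, see [enrichment_factor()].
#' @export
enrichment_at_fraction <- function(records, fraction,
                                   score_field = "docking_score",
                                   direction = c("lower", "higher")) {
  if (fraction <= 0 || fraction > 1) stop_invalid("fraction must be in (0,1]")
  check_screen_records(records, score_field)
  s <- oriented_scores(records, score_field, direction)
  ord <- order(-s)
  N <- nrow(records)
  n <- max(1L, floor(fraction * N))
  a <- sum(records$label[ord][seq_len(n)] == "ACTIVE")
  enrichment_factor(a, n, sum(records$label == "ACTIVE"), N)
}

#' ROC AUC of a virtual screen
#'
#' Mann-Whitney formulation: the probability that a randomly chosen active
#' outscores a randomly chosen decoy, with ties counted half. Equivalent to
#' the trapezoidal area under the ROC curve.
#'
#' @inheritParams rank_and_curve
#' @return AUC in `[0, 1]`; 1 is perfect separation, 0.5 is random.
#' @export
roc_auc <- function(records, score_field = "docking_score",
                    direction = c("lower", "higher")) {
  check_screen_records(records, score_field)
  s <- oriented_scores(records, score_field, direction)
  active <- records$label == "ACTIVE"
  r <- rank(s)  # midranks handle ties with half credit
  A <- sum(active)
  D <- sum(!active)
  (sum(r[active]) - A * (A + 1) / 2) / (A * D)
}

#' Hit rate binned by score
#'
#' Bins records by a score and reports the experimental hit fraction per
#' bin — the diagnostic showing whether better predicted scores actually
#' extract more true hits. Empty bins are reported with `n = 0` and an
#' undefined (`NA`) rate, not a zero rate.
#'
#' @param records data.frame with the score column and a logical/0-1 `hit`
#'   column.
#' @param score_field name of the score column.
#' @param bin_edges strictly increasing numeric vector covering the score
#'   range (`length >= 2`); bins are left-closed, last bin closed.
#' @return data.frame with `bin` (label), `lower`, `upper`, `n`,
#'   `hit_rate`.
#' @export
hit_rate_by_bin <- function(records, score_field, bin_edges) {
  if (!all(c(score_field, "hit") %in% names(records))) {
    stop_invalid("records need columns '", score_field, "' and 'hit'")
  }
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0)) {
    stop_invalid("bin_edges must be strictly increasing, length >= 2")
  }
  s <- records[[score_field]]
  if (any(s < bin_edges[1] | s > bin_edges[length(bin_edges)])) {
    stop_invalid("bin_edges must cover the full score range")
  }
  idx <- findInterval(s, bin_edges, rightmost.closed = TRUE)
  k <- length(bin_edges) - 1
  hit <- as.logical(records$hit)
  out <- data.frame(
    bin = sprintf("[%g, %g%s", utils::head(bin_edges, -1),
                  utils::tail(bin_edges, -1),
                  c(rep(")", k - 1), "]")),
    lower = utils::head(bin_edges, -1),
    upper = utils::tail(bin_edges, -1),
    n = vapply(seq_len(k), function(b) sum(idx == b), integer(1))
  )
  out$hit_rate <- vapply(seq_len(k), function(b) {
    if (out$n[b] == 0) NA_real_ else mean(hit[idx == b])
  }, numeric(1))
  out
}
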