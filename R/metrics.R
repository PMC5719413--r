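# Scoring of recalled networks against their targets.

#' Score the structure of a recalled network
#'
#' Precision is the number of correctly recalled ties divided by the
#' number of recalled ties; coverage is the number of correctly recalled
#' ties divided by the number of ties present in the target network.  A
#' tie is correct when the same unordered node pair is connected in the
#' target.
#'
#' @param target a [signed_network].
#' @param recalled a `recalled_network` (or any object with an `edges`
#'   data frame holding `from`/`to`).
#' @return A list of class `metric_summary`: `precision` (NA when nothing
#'   was recalled), `coverage`, `n_recalled`, `n_correct`.
#' @export
score_structure <- function(target, recalled) {
  stopifnot(inherits(target, "signed_network"))
  keys <- pair_key(recalled$edges$from, recalled$edges$to)
  correct <- keys %in% edge_keys(target)
  n_rec <- length(keys)
  n_cor <- sum(correct)
  structure(list(
    precision = if (n_rec > 0L) n_cor / n_rec else NA_real_,
    coverage = n_cor / n_edges(target),
    n_recalled = n_rec,
    n_correct = n_cor
  ), class = "metric_summary")
}

#' @export
print.metric_summary <- function(x, ...) {
  cat(sprintf("Recall score: precision %s, coverage %.3f (%d recalled, %d correct)\n",
              if (is.na(x$precision)) "NA" else sprintf("%.3f", x$precision),
              x$coverage, x$n_recalled, x$n_correct))
  invisible(x)
}

#' Score the affective quality of a recalled network
#'
#' Quality is the number of correctly recalled valences divided by the
#' number of correctly recalled ties.  Spurious ties (recalled but absent
#' from the target) never enter the numerator or denominator.
#'
#' @param target a [signed_network].
#' @param recalled a `recalled_network` whose edges carry a `valence`
#'   column (see [simulate_affective_recall()]).
#' @return A fraction in `[0, 1]`, or `NA` when no tie was correctly
#'   recalled.
#' @export
score_quality <- function(target, recalled) {
  stopifnot(inherits(target, "signed_network"))
  if (is.null(recalled$edges$valence)) {
    stop("recalled network has no valences; run simulate_affective_recall() first")
  }
  keys <- pair_key(recalled$edges$from, recalled$edges$to)
  truth <- valence_map(target)
  correct <- keys %in% names(truth)
  if (!any(correct)) return(NA_real_)
  mean(recalled$edges$valence[correct] == unname(truth[keys[correct]]))
}

#' Standardised deviation of a model mean from an experimental mean
#'
#' `|model_mean - exp_mean| / exp_sd`.  Values below 1 mean the model
#' mean lies within one experimental standard deviation.
#'
#' @param model_mean,exp_mean means to compare.
#' @param exp_sd experimental standard deviation; must be positive.
#' @return A non-negative number.
#' @export
delta <- function(model_mean, exp_mean, exp_sd) {
  if (!is.numeric(exp_sd) || any(exp_sd <= 0)) {
    stop("exp_sd must be positive")
  }
  abs(model_mean - exp_mean) / exp_sd
}
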