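# broom-style accessors for fitted ensembles.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-snoRNA prediction records of an ensemble fit
#'
#' @param x a `sno_ensemble_fit`.
#' @param ... unused.
#' @return tibble, one row per snoRNA: iteration, truth, per-family and
#'   ensemble statuses/scores, confusion category.
#' @export
tidy.sno_ensemble_fit <- function(x, ...) {
  x$predictions
}

#' One-row performance summary of an ensemble fit
#'
#' @param x a `sno_ensemble_fit`.
#' @param ... unused.
#' @return tibble: n, accuracy, sensitivity, specificity, auc,
#'   proportion_expressed (ensemble calls).
#' @export
glance.sno_ensemble_fit <- function(x, ...) {
  m <- confusion_and_metrics(x$predictions)
  tibble(n = nrow(x$predictions), accuracy = m$accuracy,
         sensitivity = m$sensitivity, specificity = m$specificity,
         auc = m$auc,
         proportion_expressed = mean(x$predictions$ensemble_status))
}
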