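# Unified prognostic framework: evaluation metrics, the OR-combination of
# visual nodal detection with radiomic prediction, and the per-mode
# pipeline evaluation.

# Half-up rounding to integer percent, applied only at reporting time.
percent <- function(rate) floor(rate * 100 + 0.5)

#' Confusion counts and derived rates
#'
#' @param predictions,truth aligned binary vectors (1 = LN-positive call /
#'   LN metastases at histology).
#' @param patient_ids optional ids stored alongside the per-patient
#'   predictions.
#' @return an `evaluation_report`: list with `TP`, `TN`, `FP`, `FN`,
#'   `sensitivity`, `specificity`, `gmean` and `predictions`.
#' @export
confusion <- function(predictions, truth, patient_ids = NULL) {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth differ in length (", length(predictions),
         " vs ", length(truth), ")")
  }
  stopifnot(all(predictions %in% c(0, 1)), all(truth %in% c(0, 1)))
  tp <- sum(predictions == 1 & truth == 1)
  tn <- sum(predictions == 0 & truth == 0)
  fp <- sum(predictions == 1 & truth == 0)
  fn <- sum(predictions == 0 & truth == 1)
  evaluation_report(tp, tn, fp, fn,
                    predictions = setNames(as.integer(predictions),
                                           patient_ids))
}

#' @param TP,TN,FP,FN confusion counts.
#' @param predictions optional per-patient binary predictions.
#' @rdname confusion
#' @export
evaluation_report <- function(TP, TN, FP, FN, predictions = NULL) {
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 sensitivity = sens, specificity = spec,
                 gmean = gmean(sens, spec), predictions = predictions),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Confusion: TP", x$TP, " TN", x$TN, " FP", x$FP, " FN", x$FN, "\n")
  cat(sprintf("sensitivity %d%%, specificity %d%%, gmean %.4f\n",
              percent(x$sensitivity), percent(x$specificity), x$gmean))
  invisible(x)
}

#' Unified prognostic rule: visual OR radiomic
#'
#' A patient is called LN-positive when either the visual nodal reading or
#' the radiomic prediction calls positive. Consequently, on any dataset the
#' unified sensitivity is at least each component's sensitivity and the
#' unified specificity is at most each component's specificity. (Applying
#' the radiomic rule only to visually negative patients is algebraically
#' identical for binary outputs.)
#'
#' @param visual,radiomic binary vectors.
#' @return binary vector of unified calls.
#' @export
unified_predict <- function(visual, radiomic) {
  stopifnot(length(visual) == length(radiomic))
  as.integer(visual == 1 | radiomic == 1)
}

#' Univariate cut-off classifier
#'
#' For `direction = "positive-low"` a patient is called positive when the
#' feature value is strictly below the cut-off (a value exactly at the
#' cut-off is negative); symmetric for `"positive-high"`.
#'
#' @param feature_value numeric vector of feature values.
#' @param cutoff decision threshold.
#' @param direction `"positive-low"` or `"positive-high"`.
#' @return binary vector.
#' @export
univariate_classifier <- function(feature_value, cutoff,
                                  direction = c("positive-low",
                                                "positive-high")) {
  direction <- match.arg(direction)
  classify_cutoff(feature_value, cutoff, direction)
}

#' Scanner robustness check
#'
#' Kruskal-Wallis test of a feature across scanner groups: a small p-value
#' indicates the feature's distribution depends on the scanner.
#'
#' @param cohort a cohort with extracted features.
#' @param feature_name feature to test.
#' @return the Kruskal-Wallis p-value.
#' @export
scanner_robustness <- function(cohort, feature_name) {
  x <- as.data.frame(cohort)[[feature_name]]
  if (is.null(x)) stop("feature not found: ", feature_name)
  g <- factor(cohort$scanner_id)
  tab <- table(g)
  if (length(tab) < 2) stop("at least 2 scanner groups required")
  if (any(tab < 2)) stop("every scanner group needs >= 2 members")
  kruskal.test(x, g)$p.value
}

#' Evaluate a prediction mode on a cohort
#'
#' Modes: `"visual"` (the visual nodal reading), `"univariate"` (cut-off
#' rule on one feature), `"multivariate"` (a trained ensemble),
#' `"unified-univariate"` and `"unified-multivariate"` (OR of visual with
#' the respective radiomic mode). For the univariate modes the cut-off and
#' direction default to a fit on the cohort itself via [screen_all()]
#' statistics when not supplied; pass a published cut-off explicitly to
#' test a frozen rule.
#'
#' @param cohort a cohort with extracted features.
#' @param mode one of the five modes.
#' @param feature_name feature for the univariate modes (default
#'   `"GLSZM_ZP"`).
#' @param cutoff,direction univariate decision rule; fitted on the cohort
#'   when `NULL`.
#' @param ensemble a trained [train_final_ensemble()] for the multivariate
#'   modes.
#' @return an `evaluation_report`.
#' @export
evaluate_pipeline <- function(cohort,
                              mode = c("visual", "univariate",
                                       "multivariate", "unified-univariate",
                                       "unified-multivariate"),
                              feature_name = "GLSZM_ZP", cutoff = NULL,
                              direction = NULL, ensemble = NULL) {
  mode <- match.arg(mode)
  truth <- cohort$ln_histology
  radiomic <- NULL
  if (mode %in% c("univariate", "unified-univariate")) {
    x <- as.data.frame(cohort)[[feature_name]]
    if (is.null(x)) stop("feature not found: ", feature_name)
    if (is.null(cutoff) || is.null(direction)) {
      pos <- x[truth == 1]
      neg <- x[truth == 0]
      a <- auc(pos, neg)
      if (is.null(direction)) direction <- a$direction
      if (is.null(cutoff)) cutoff <- youden_cutoff(pos, neg, direction)
    }
    radiomic <- univariate_classifier(x, cutoff, direction)
  }
  if (mode %in% c("multivariate", "unified-multivariate")) {
    if (is.null(ensemble)) stop("mode ", mode, " requires a trained ensemble")
    radiomic <- predict(ensemble, cohort, type = "class")
  }
  pred <- switch(mode,
                 visual = cohort$visual_detection,
                 univariate = radiomic,
                 multivariate = radiomic,
                 `unified-univariate` = ,
                 `unified-multivariate` =
                   unified_predict(cohort$visual_detection, radiomic))
  confusion(pred, truth, patient_ids = cohort$patient_id)
}
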