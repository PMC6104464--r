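# Univariate association of each radiomic feature with LN status: two-sided
# Wilcoxon rank-sum test, orientation-corrected AUC, Youden-optimal cut-off
# and its leave-one-out assessment.

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample is small (<= 20) and tie-free,
#' otherwise the normal approximation with tie and continuity correction
#' (the default at cohort scale).
#'
#' @param values_pos,values_neg feature values of the LN-positive and
#'   LN-negative groups.
#' @param exact `NULL` for the size-based rule, or `TRUE`/`FALSE` to force.
#' @return the two-sided p-value.
#' @export
rank_test <- function(values_pos, values_neg, exact = NULL) {
  if (!length(values_pos) || !length(values_neg)) {
    stop("both groups must be non-empty")
  }
  n <- length(values_pos) + length(values_neg)
  has_ties <- anyDuplicated(c(values_pos, values_neg)) > 0
  if (is.null(exact)) exact <- n <= 20 && !has_ties
  suppressWarnings(
    wilcox.test(values_pos, values_neg, alternative = "two.sided",
                exact = exact, correct = TRUE)$p.value)
}

#' Orientation-corrected AUC
#'
#' The Mann-Whitney AUC `U / (n1 * n2)` with ties counted 1/2. If the raw
#' AUC is below 0.5 the direction is flipped so the reported AUC is always
#' >= 0.5; `direction` records whether high (`"positive-high"`) or low
#' (`"positive-low"`) feature values indicate the positive class.
#'
#' @inheritParams rank_test
#' @return `list(auc=, direction=, raw_auc=)`.
#' @export
auc <- function(values_pos, values_neg) {
  if (!length(values_pos) || !length(values_neg)) {
    stop("both groups must be non-empty")
  }
  n1 <- length(values_pos)
  n2 <- length(values_neg)
  r <- rank(c(values_pos, values_neg))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  raw <- u / (n1 * n2)
  if (raw >= 0.5) {
    list(auc = raw, direction = "positive-high", raw_auc = raw)
  } else {
    list(auc = 1 - raw, direction = "positive-low", raw_auc = raw)
  }
}

# Classify with a cut-off: positive-low features call "value < cutoff"
# positive; positive-high features call "value > cutoff" positive.
classify_cutoff <- function(values, cutoff, direction) {
  if (direction == "positive-low") as.integer(values < cutoff)
  else as.integer(values > cutoff)
}

#' Youden-optimal cut-off
#'
#' Maximizes Youden's index (sensitivity + specificity - 1) over candidate
#' thresholds placed at midpoints between adjacent sorted unique pooled
#' values. Ties are broken toward the cut-off with higher sensitivity, then
#' toward the smaller threshold.
#'
#' @inheritParams rank_test
#' @param direction `"positive-high"` or `"positive-low"` (from [auc()]).
#' @return the optimal cut-off (within the observed feature range).
#' @export
youden_cutoff <- function(values_pos, values_neg, direction) {
  u <- sort(unique(c(values_pos, values_neg)))
  if (length(u) == 1) return(u)  # constant feature: only possible threshold
  cand <- (u[-1] + u[-length(u)]) / 2
  sens <- vapply(cand, function(c_) {
    mean(classify_cutoff(values_pos, c_, direction))
  }, numeric(1))
  spec <- vapply(cand, function(c_) {
    1 - mean(classify_cutoff(values_neg, c_, direction))
  }, numeric(1))
  j <- sens + spec - 1
  best <- which(j > max(j) - 1e-12)
  best <- best[order(-sens[best], cand[best])][1]
  cand[best]
}

#' Leave-one-out assessment of a univariate cut-off classifier
#'
#' For each patient, the direction and Youden cut-off of `feature_name` are
#' fitted on the remaining patients and the held-out patient is classified;
#' the aggregated confusion against LN histology is returned.
#'
#' @param cohort a cohort with extracted features.
#' @param feature_name the feature to assess.
#' @return an [evaluation_report()] with per-patient predictions.
#' @export
loo_cutoff_assessment <- function(cohort, feature_name) {
  x <- as.data.frame(cohort)[[feature_name]]
  if (is.null(x)) stop("feature not found: ", feature_name)
  y <- cohort$ln_histology
  n <- length(y)
  pred <- integer(n)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2) {
      stop("leave-one-out fold ", i, " loses all members of one class")
    }
    pos <- x[-i][yi == 1]
    neg <- x[-i][yi == 0]
    a <- auc(pos, neg)
    cut <- youden_cutoff(pos, neg, a$direction)
    pred[i] <- classify_cutoff(x[i], cut, a$direction)
  }
  confusion(pred, y, patient_ids = cohort$patient_id)
}

#' Univariate screening of all features
#'
#' One [rank_test()] p-value, oriented [auc()] and [youden_cutoff()] per
#' feature column, sorted by p-value (feature-name tie-break). Constant
#' features are flagged and assigned p = 1, AUC = 0.5. A
#' Benjamini-Hochberg-adjusted column is added for information only; the
#' screening rule used downstream is the raw p <= 0.01 gate.
#'
#' @param cohort a cohort with extracted features.
#' @param exact passed to [rank_test()].
#' @return a `data.frame` (class `rad_screen`) with columns `feature`,
#'   `p_value`, `p_bh`, `auc`, `direction`, `cutoff`, `constant`.
#' @export
screen_all <- function(cohort, exact = NULL) {
  fm <- cohort_features(cohort)
  y <- cohort$ln_histology
  if (length(unique(y)) < 2) stop("cohort must contain both LN classes")
  rows <- lapply(colnames(fm), function(f) {
    x <- fm[, f]
    pos <- x[y == 1]
    neg <- x[y == 0]
    if (max(x) - min(x) < 1e-15) {
      return(data.frame(feature = f, p_value = 1, auc = 0.5,
                        direction = "positive-high", cutoff = x[1],
                        constant = TRUE))
    }
    a <- auc(pos, neg)
    data.frame(feature = f,
               p_value = rank_test(pos, neg, exact = exact),
               auc = a$auc, direction = a$direction,
               cutoff = youden_cutoff(pos, neg, a$direction),
               constant = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bh <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$feature), ]
  rownames(res) <- NULL
  res <- res[, c("feature", "p_value", "p_bh", "auc", "direction",
                 "cutoff", "constant")]
  class(res) <- c("rad_screen", "data.frame")
  res
}

#' @export
print.rad_screen <- function(x, n = 10, ...) {
  cat("Univariate screening:", nrow(x), "features,",
      sum(x$p_value <= 0.01), "with p <= 0.01\n")
  print.data.frame(head(as.data.frame(x), n), digits = 4)
  invisible(x)
}
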