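#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a uniformly
#' random pathogenic score exceeds a uniformly random benign score, ties
#' counted one half. Identical to the trapezoidal area under the
#' vertex-based ROC curve.
#'
#' @param scores Numeric scores, oriented so higher means more pathogenic.
#' @param outcomes Binary vector (1 = pathogenic), same length.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  outcomes <- as.integer(outcomes)
  n1 <- sum(outcomes == 1L)
  n0 <- sum(outcomes == 0L)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present", call. = FALSE)
  r <- rank(scores)   # midranks handle ties as 1/2
  (sum(r[outcomes == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve vertices
#'
#' Curve built from the observed score values used as thresholds
#' (call pathogenic iff score >= threshold); starts at (0,0), ends at
#' (1,1), both coordinates non-decreasing.
#'
#' @inheritParams auroc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  outcomes <- as.integer(outcomes)
  n1 <- sum(outcomes == 1L)
  n0 <- sum(outcomes == 0L)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sp <- sort(scores[outcomes == 1L])
  sb <- sort(scores[outcomes == 0L])
  tpr <- (n1 - findInterval(thr, sp, left.open = TRUE)) / n1
  fpr <- (n0 - findInterval(thr, sb, left.open = TRUE)) / n0
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

threshold_metrics <- function(scores, outcomes) {
  outcomes <- as.integer(outcomes)
  n1 <- sum(outcomes == 1L)
  n0 <- sum(outcomes == 0L)
  cand <- c(sort(unique(scores)), Inf)
  sp <- sort(scores[outcomes == 1L])
  sb <- sort(scores[outcomes == 0L])
  sens <- (n1 - findInterval(cand, sp, left.open = TRUE)) / n1   # score >= t
  spec <- findInterval(cand, sb, left.open = TRUE) / n0          # score <  t
  data.frame(threshold = cand, sensitivity = sens, specificity = spec,
             J = sens + spec - 1)
}

#' Youden-optimal decision threshold
#'
#' Scans every observed score value plus +Inf as candidate threshold under
#' the rule "call pathogenic iff score >= threshold" and returns the one
#' maximising the Youden J statistic (sensitivity + specificity - 1).
#' Ties on J are broken in favour of higher sensitivity, then lower
#' threshold: in this setting a missed pathogenic variant is the costlier
#' error.
#'
#' @inheritParams auroc
#' @param scope Label stored with the result (`"global"` or a region).
#' @param vep Optional predictor name stored with the result.
#' @return One-row data frame of class `threshold_result`: `vep`, `scope`,
#'   `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
youden_threshold <- function(scores, outcomes, scope = "global", vep = NA_character_) {
  outcomes <- as.integer(outcomes)
  if (length(unique(outcomes)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  m <- threshold_metrics(scores, outcomes)
  ord <- order(-m$J, -m$sensitivity, m$threshold)
  best <- m[ord[1L], , drop = FALSE]
  out <- data.frame(vep = vep, scope = scope,
                    threshold = best$threshold, J = best$J,
                    sensitivity = best$sensitivity, specificity = best$specificity,
                    stringsAsFactors = FALSE)
  class(out) <- c("threshold_result", class(out))
  out
}

#' Sensitivity and specificity at a fixed threshold
#'
#' Call rule: pathogenic iff score >= threshold. Sensitivity is TP/(TP+FN)
#' over pathogenic variants, specificity TN/(TN+FP) over benign variants;
#' an empty class yields `NA` for its rate (flagged, not an error).
#'
#' @inheritParams auroc
#' @param threshold Decision threshold in (oriented) score units.
#' @return List: `sensitivity`, `specificity`, `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_threshold <- function(scores, outcomes, threshold) {
  stopifnot(length(scores) == length(outcomes))
  outcomes <- as.integer(outcomes)
  call_path <- scores >= threshold
  tp <- sum(call_path & outcomes == 1L)
  fn <- sum(!call_path & outcomes == 1L)
  fp <- sum(call_path & outcomes == 0L)
  tn <- sum(!call_path & outcomes == 0L)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Binary pathogenicity calls at a threshold
#'
#' @inheritParams confusion_at_threshold
#' @return Integer vector, 1 = predicted pathogenic (score >= threshold).
#' @export
binarize <- function(scores, threshold) {
  as.integer(scores >= threshold)
}

#' Global and region-specific Youden thresholds for one VEP
#'
#' The global threshold uses all variants; each region-specific threshold
#' uses only that region's variants, mirroring the derivation of
#' region-aware operating points. A region whose subset lacks one outcome
#' class is skipped with a warning.
#'
#' @param dataset An `evaluation_dataset` (see [intersect_complete()]).
#' @param vep Predictor name (must be a column of the score matrix).
#' @return Data frame of [youden_threshold()] rows, scopes `global` plus
#'   the available regions.
#' @export
region_thresholds <- function(dataset, vep) {
  stopifnot(inherits(dataset, "evaluation_dataset"), vep %in% colnames(dataset$scores))
  s <- dataset$scores[, vep]
  y <- dataset$variants$outcome
  out <- list(youden_threshold(s, y, scope = "global", vep = vep))
  for (r in REGION_LEVELS) {
    idx <- dataset$variants$region == r
    if (!any(idx)) next
    if (length(unique(y[idx])) < 2L) {
      warning(sprintf("VEP '%s': region '%s' lacks one outcome class; scope skipped", vep, r),
              call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- youden_threshold(s[idx], y[idx], scope = r, vep = vep)
  }
  do.call(rbind, out)
}

#' Region-stratified performance metrics for every VEP
#'
#' For each predictor and each scope (global plus regions with both
#' classes): AUROC, the scope-specific Youden threshold with its
#' sensitivity/specificity, and -- for region scopes -- sensitivity and
#' specificity at the *global* threshold, which is what a user applying
#' one cutoff everywhere would experience.
#'
#' @param dataset An `evaluation_dataset`.
#' @return Data frame, one row per VEP x scope: `vep`, `group`, `scope`,
#'   `n_pathogenic`, `n_benign`, `auroc`, `threshold`, `J`, `sensitivity`,
#'   `specificity`, `sensitivity_global_thr`, `specificity_global_thr`.
#' @export
vep_performance <- function(dataset) {
  stopifnot(inherits(dataset, "evaluation_dataset"))
  y <- dataset$variants$outcome
  region <- dataset$variants$region
  rows <- list()
  for (v in colnames(dataset$scores)) {
    s <- dataset$scores[, v]
    grp <- dataset$veps$group[match(v, dataset$veps$name)]
    thr <- region_thresholds(dataset, v)
    g <- thr[thr$scope == "global", , drop = FALSE]
    for (sc in thr$scope) {
      idx <- if (sc == "global") rep(TRUE, length(y)) else region == sc
      row <- thr[thr$scope == sc, , drop = FALSE]
      at_g <- confusion_at_threshold(s[idx], y[idx], g$threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        vep = v, group = grp, scope = sc,
        n_pathogenic = sum(y[idx] == 1L), n_benign = sum(y[idx] == 0L),
        auroc = auroc(s[idx], y[idx]),
        threshold = row$threshold, J = row$J,
        sensitivity = row$sensitivity, specificity = row$specificity,
        sensitivity_global_thr = at_g$sensitivity,
        specificity_global_thr = at_g$specificity,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
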