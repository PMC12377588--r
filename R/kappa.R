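#' Cohen's kappa between two binary call vectors
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e) with p_o
#' the observed agreement fraction and p_e the agreement expected from
#' the two marginal call rates. Degenerate case p_e = 1 (both vectors
#' constant): kappa = 1 when the constants agree, 0 when they differ.
#'
#' @param calls_a,calls_b Equal-length binary vectors (1 = pathogenic
#'   call).
#' @return Kappa in [-1, 1].
#' @export
cohens_kappa <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) {
    stop("call vectors must have equal length", call. = FALSE)
  }
  n <- length(calls_a)
  if (n < 1L) stop("call vectors must be non-empty", call. = FALSE)
  a <- as.integer(calls_a)
  b <- as.integer(calls_b)
  p_o <- mean(a == b)
  p_e <- mean(a == 1L) * mean(b == 1L) + mean(a == 0L) * mean(b == 0L)
  if (p_e >= 1) {
    return(if (p_o == 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Pairwise kappa matrix over a call matrix
#'
#' @param calls Matrix, variants in rows, one column of binary calls per
#'   VEP.
#' @return Symmetric matrix of pairwise kappas (diagonal 1).
#' @export
kappa_matrix <- function(calls) {
  stopifnot(is.matrix(calls), ncol(calls) >= 1L)
  k <- ncol(calls)
  out <- diag(1, k)
  dimnames(out) <- list(colnames(calls), colnames(calls))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        out[i, j] <- out[j, i] <- cohens_kappa(calls[, i], calls[, j])
      }
    }
  }
  out
}

#' Mean pairwise agreement within and between VEP groups
#'
#' For every unordered pair of VEP groups (including each group with
#' itself) the mean Cohen's kappa over the constituent predictor pairs is
#' reported with the standard error of the mean taken over pairs (sample
#' standard deviation / sqrt(number of pairs); `NA` when only one pair).
#' Within-group entries require at least two members, otherwise they are
#' skipped with a warning.
#'
#' @param calls Binary call matrix (variants x VEPs), e.g. each VEP
#'   binarized at its global Youden threshold.
#' @param groups Character vector of group labels, one per column of
#'   `calls`.
#' @param scope Label stored with the results (default `"global"`).
#' @return Data frame: `scope`, `group_a`, `group_b`, `mean_kappa`,
#'   `sem`, `n_pairs`.
#' @export
group_agreement <- function(calls, groups, scope = "global") {
  stopifnot(is.matrix(calls), length(groups) == ncol(calls))
  if (ncol(calls) < 2L) stop("at least two VEPs required", call. = FALSE)
  km <- kappa_matrix(calls)
  glv <- unique(groups)
  rows <- list()
  for (i in seq_along(glv)) {
    for (j in i:length(glv)) {
      ga <- glv[i]; gb <- glv[j]
      ia <- which(groups == ga); ib <- which(groups == gb)
      if (ga == gb) {
        if (length(ia) < 2L) {
          warning(sprintf("group '%s' has fewer than two VEPs; within-group entry skipped", ga),
                  call. = FALSE)
          next
        }
        pr <- utils::combn(ia, 2L)
        ks <- km[cbind(pr[1L, ], pr[2L, ])]
      } else {
        ks <- as.vector(km[ia, ib, drop = FALSE])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scope = scope, group_a = ga, group_b = gb,
        mean_kappa = mean(ks),
        sem = if (length(ks) > 1L) stats::sd(ks) / sqrt(length(ks)) else NA_real_,
        n_pairs = length(ks), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Region-stratified group agreement at global thresholds
#'
#' Binarizes every VEP at its own *global* Youden threshold, then
#' computes [group_agreement()] globally and within each region's
#' variants.
#'
#' @param dataset An `evaluation_dataset`.
#' @return List with `calls` (binary matrix), `kappa` (named list of
#'   per-scope kappa matrices) and `agreement` (row-bound
#'   [group_agreement()] tables over scopes).
#' @export
agreement_by_region <- function(dataset) {
  stopifnot(inherits(dataset, "evaluation_dataset"))
  y <- dataset$variants$outcome
  calls <- vapply(colnames(dataset$scores), function(v) {
    thr <- youden_threshold(dataset$scores[, v], y, vep = v)
    binarize(dataset$scores[, v], thr$threshold)
  }, integer(nrow(dataset$variants)))
  groups <- dataset$veps$group[match(colnames(calls), dataset$veps$name)]
  scopes <- c("global", intersect(REGION_LEVELS, unique(dataset$variants$region)))
  kap <- list(); agr <- list()
  for (sc in scopes) {
    idx <- if (sc == "global") rep(TRUE, nrow(calls)) else dataset$variants$region == sc
    kap[[sc]] <- kappa_matrix(calls[idx, , drop = FALSE])
    agr[[sc]] <- group_agreement(calls[idx, , drop = FALSE], groups, scope = sc)
  }
  list(calls = calls, kappa = kap, agreement = do.call(rbind, agr))
}
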