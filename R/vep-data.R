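#' Construct a VEP score set
#'
#' One predictor's scores over a set of variants, with the metadata the
#' evaluation needs: the group defined by training strategy
#' (clinical-trained, population-tuned, population-free) and the score
#' orientation. Variants the predictor does not cover are simply absent
#' from the map.
#'
#' @param name Predictor name.
#' @param group One of `"clinical_trained"`, `"population_tuned"`,
#'   `"population_free"`.
#' @param higher_is_pathogenic `TRUE` when larger scores mean more likely
#'   pathogenic.
#' @param scores Named numeric vector; names are variant keys
#'   ([variant_key()]).
#' @return Object of class `vep_scoreset`.
#' @export
vep_scoreset <- function(name, group, higher_is_pathogenic, scores) {
  stopifnot(is.character(name), length(name) == 1L)
  group <- match.arg(group, VEP_GROUPS)
  stopifnot(is.logical(higher_is_pathogenic), length(higher_is_pathogenic) == 1L)
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop(sprintf("VEP '%s': scores must be finite (omit uncovered variants instead)", name),
         call. = FALSE)
  }
  if (anyDuplicated(names(scores))) {
    stop(sprintf("VEP '%s': duplicated variant keys in score map", name), call. = FALSE)
  }
  structure(list(name = name, group = group,
                 higher_is_pathogenic = higher_is_pathogenic,
                 oriented = FALSE, scores = scores),
            class = "vep_scoreset")
}

#' @export
print.vep_scoreset <- function(x, ...) {
  cat(sprintf("<vep_scoreset> %s (%s): %d scored variants, higher_is_pathogenic = %s%s\n",
              x$name, x$group, length(x$scores), x$higher_is_pathogenic,
              if (x$oriented) " [oriented]" else ""))
  invisible(x)
}

#' Read VEP metadata
#'
#' TSV with columns `name`, `group`, `higher_is_pathogenic`
#' (TRUE/FALSE).
#'
#' @param path Path to the metadata TSV.
#' @return Data frame with one row per VEP.
#' @export
read_vep_metadata <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("name", "group", "higher_is_pathogenic")
  if (!all(need %in% names(meta))) {
    stop(sprintf("VEP metadata must have columns %s", paste(need, collapse = ", ")), call. = FALSE)
  }
  bad <- !(meta$group %in% VEP_GROUPS)
  if (any(bad)) {
    stop(sprintf("unknown VEP group '%s'; allowed: %s", meta$group[bad][1L],
                 paste(VEP_GROUPS, collapse = ", ")), call. = FALSE)
  }
  meta$higher_is_pathogenic <- as.logical(meta$higher_is_pathogenic)
  if (anyNA(meta$higher_is_pathogenic)) {
    stop("higher_is_pathogenic must be TRUE or FALSE", call. = FALSE)
  }
  meta
}

#' Read VEP scores (long or wide table)
#'
#' Long form: columns `vep`, `protein_id`, `position`, `ref_aa`, `alt_aa`,
#' `score`. Wide form: the four variant-identity columns plus one numeric
#' column per VEP, empty cells meaning "not covered". Metadata supplies
#' group and orientation per VEP; every VEP in the table must appear in
#' the metadata.
#'
#' @param path Path to the score TSV.
#' @param metadata Data frame from [read_vep_metadata()].
#' @param format `"long"` (default) or `"wide"`.
#' @return Named list of [vep_scoreset()] objects.
#' @export
read_vep_scores <- function(path, metadata, format = c("long", "wide")) {
  format <- match.arg(format)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  idcols <- c("protein_id", "position", "ref_aa", "alt_aa")
  if (format == "long") {
    need <- c("vep", idcols, "score")
    if (!all(need %in% names(tab))) {
      stop(sprintf("long score table must have columns %s", paste(need, collapse = ", ")),
           call. = FALSE)
    }
    veps <- unique(tab$vep)
    sets <- lapply(veps, function(v) {
      sub <- tab[tab$vep == v, , drop = FALSE]
      make_scoreset(v, metadata, stats::setNames(sub$score, variant_key(sub)))
    })
  } else {
    if (!all(idcols %in% names(tab))) {
      stop(sprintf("wide score table must have columns %s", paste(idcols, collapse = ", ")),
           call. = FALSE)
    }
    veps <- setdiff(names(tab), idcols)
    keys <- variant_key(tab)
    sets <- lapply(veps, function(v) {
      s <- suppressWarnings(as.numeric(tab[[v]]))
      keep <- !is.na(s)
      make_scoreset(v, metadata, stats::setNames(s[keep], keys[keep]))
    })
  }
  stats::setNames(sets, veps)
}

make_scoreset <- function(name, metadata, scores) {
  i <- match(name, metadata$name)
  if (is.na(i)) stop(sprintf("VEP '%s' has no metadata entry", name), call. = FALSE)
  vep_scoreset(name, metadata$group[i], metadata$higher_is_pathogenic[i], scores)
}

#' Orient a score set so that higher means more pathogenic
#'
#' When `higher_is_pathogenic` is `FALSE` all scores are negated, making
#' the "score >= threshold implies pathogenic" rule valid for every
#' predictor downstream. Orientation is explicit, never inferred from the
#' data; an optional audit computes the AUROC against supplied outcomes
#' and warns -- without flipping -- when it falls below 0.5, which usually
#' indicates a misdeclared orientation.
#'
#' @param scoreset A [vep_scoreset()].
#' @param outcomes Optional named binary vector (1 = pathogenic) keyed
#'   like the score map, used only by the audit.
#' @param audit Run the AUROC audit (default `FALSE`).
#' @return The oriented score set (`oriented` flag set).
#' @export
orient_scores <- function(scoreset, outcomes = NULL, audit = FALSE) {
  stopifnot(inherits(scoreset, "vep_scoreset"))
  if (scoreset$oriented) return(scoreset)
  if (!scoreset$higher_is_pathogenic) {
    scoreset$scores <- -scoreset$scores
  }
  scoreset$oriented <- TRUE
  if (audit && !is.null(outcomes)) {
    common <- intersect(names(scoreset$scores), names(outcomes))
    if (length(unique(outcomes[common])) == 2L) {
      a <- auroc(scoreset$scores[common], outcomes[common])
      if (a < 0.5) {
        warning(sprintf("VEP '%s': oriented AUROC %.3f < 0.5; orientation metadata may be wrong (scores left unchanged)",
                        scoreset$name, a), call. = FALSE)
      }
    }
  }
  scoreset
}

#' Coverage-filter VEPs
#'
#' Keeps every VEP whose score map covers at least `min_frac` (inclusive)
#' of the supplied variants -- the full pathogenic plus putatively benign
#' set, after any gene exclusions. This filter runs *before* the variant
#' intersection ([intersect_complete()]); the order is normative.
#'
#' @param scoresets Named list of [vep_scoreset()] objects.
#' @param variants Variant data frame defining the coverage denominator.
#' @param min_frac Minimum covered fraction, inclusive (default 0.75).
#' @return List with `scoresets` (retained) and `report` (data frame:
#'   `vep`, `n_scored`, `coverage`, `retained`).
#' @export
filter_by_coverage <- function(scoresets, variants, min_frac = 0.75) {
  check_scalar_number(min_frac, "min_frac", 0, 1)
  keys <- variant_key(variants)
  cov <- vapply(scoresets, function(s) mean(keys %in% names(s$scores)), numeric(1))
  n_sc <- vapply(scoresets, function(s) sum(keys %in% names(s$scores)), numeric(1))
  retained <- cov >= min_frac
  report <- data.frame(vep = vapply(scoresets, `[[`, "", "name"),
                       n_scored = as.integer(n_sc),
                       coverage = cov, retained = retained,
                       row.names = NULL, stringsAsFactors = FALSE)
  if (!any(retained)) {
    stop(sprintf("no VEP reaches the %.0f%% coverage threshold", 100 * min_frac), call. = FALSE)
  }
  list(scoresets = scoresets[retained], report = report)
}

#' Build the complete evaluation dataset
#'
#' Retains exactly the variants scored by every retained VEP ("scores
#' shared across all VEPs"), restricted to the two evaluation classes:
#' ClinVar pathogenic (outcome 1) versus gnomAD putatively benign
#' (outcome 0). The resulting score matrix has no missing cell. Per-region
#' class counts are logged; losing one class within a region triggers a
#' warning, losing a class globally is an error.
#'
#' @param variants Assigned variant data frame.
#' @param scoresets Named list of *oriented* retained [vep_scoreset()]s.
#' @return Object of class `evaluation_dataset`: list with `variants`
#'   (with `outcome` column), `scores` (matrix variants x VEPs, oriented),
#'   `veps` (metadata data frame), `report`.
#' @export
intersect_complete <- function(variants, scoresets) {
  if (length(scoresets) == 0L) stop("at least one retained VEP required", call. = FALSE)
  if (!all(vapply(scoresets, `[[`, TRUE, "oriented"))) {
    stop("score sets must be oriented first (see `orient_scores()`)", call. = FALSE)
  }
  eval_classes <- c("clinvar_pathogenic", "gnomad_benign")
  n_other <- sum(!variants$class_label %in% eval_classes)
  if (n_other > 0L) {
    message(sprintf("excluding %d variant(s) outside the evaluation classes (%s)",
                    n_other, paste(eval_classes, collapse = " vs ")))
  }
  v <- variants[variants$class_label %in% eval_classes, , drop = FALSE]
  keys <- variant_key(v)
  covered <- Reduce(`&`, lapply(scoresets, function(s) keys %in% names(s$scores)))
  n_dropped <- sum(!covered)
  v <- v[covered, , drop = FALSE]
  keys <- keys[covered]
  if (nrow(v) == 0L) stop("no variant is scored by every retained VEP", call. = FALSE)
  v$outcome <- as.integer(v$class_label == "clinvar_pathogenic")
  if (length(unique(v$outcome)) < 2L) {
    stop("one outcome class vanished entirely after intersection", call. = FALSE)
  }
  for (r in intersect(REGION_LEVELS, unique(v$region))) {
    cls <- unique(v$outcome[v$region == r])
    if (length(cls) < 2L) {
      warning(sprintf("region '%s' lost one outcome class after intersection", r), call. = FALSE)
    }
  }
  scores <- vapply(scoresets, function(s) unname(s$scores[keys]), numeric(nrow(v)))
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = nrow(v),
                                           dimnames = list(NULL, names(scoresets)))
  rownames(scores) <- keys
  meta <- data.frame(name = vapply(scoresets, `[[`, "", "name"),
                     group = vapply(scoresets, `[[`, "", "group"),
                     row.names = NULL, stringsAsFactors = FALSE)
  counts <- table(region = v$region, outcome = v$outcome)
  message(sprintf("evaluation dataset: %d variants (%d pathogenic, %d benign) x %d VEPs; %d dropped by intersection",
                  nrow(v), sum(v$outcome == 1L), sum(v$outcome == 0L), ncol(scores), n_dropped))
  structure(list(variants = v, scores = scores, veps = meta,
                 report = list(n_dropped_intersection = n_dropped,
                               n_excluded_classes = n_other,
                               region_class_counts = counts)),
            class = "evaluation_dataset")
}

#' @export
print.evaluation_dataset <- function(x, ...) {
  cat(sprintf("<evaluation_dataset> %d variants (%d pathogenic) x %d VEPs\n",
              nrow(x$variants), sum(x$variants$outcome), ncol(x$scores)))
  invisible(x)
}
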