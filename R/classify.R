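#' Residue disorder classification parameters
#'
#' Thresholds of the pLDDT-based three-state residue classifier. A residue
#' is *disordered* when its pLDDT is below `disorder_plddt_max` and it lies
#' inside a qualifying low-confidence stretch; *ordered* when its pLDDT is
#' at least `ordered_plddt_min`; *intermediate* otherwise. A qualifying
#' stretch is a contiguous run of at least `stretch_min_len` residues with
#' average pLDDT below `stretch_mean_max`.
#'
#' Two readings of "contiguous stretch" are supported. The default,
#' `maximal_run`, takes the maximal runs of consecutive residues with
#' pLDDT < `stretch_mean_max` and keeps those of length >=
#' `stretch_min_len`; short low-confidence dips flanked by confident
#' structure therefore stay intermediate. The alternative, `any_window`,
#' marks a residue as inside a stretch when it lies in at least one window
#' of exactly `stretch_min_len` residues whose mean pLDDT is below
#' `stretch_mean_max`; it is retained for sensitivity analysis and is
#' strictly more permissive.
#'
#' @param disorder_plddt_max Exclusive pLDDT upper bound for a disordered
#'   residue (default 50).
#' @param stretch_min_len Minimum stretch length in residues (default 30).
#' @param stretch_mean_max Exclusive upper bound on the stretch mean pLDDT
#'   (default 70).
#' @param ordered_plddt_min Inclusive pLDDT lower bound for an ordered
#'   residue (default 70).
#' @param stretch_mode `"maximal_run"` (default) or `"any_window"`.
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(disorder_plddt_max = 50,
                              stretch_min_len = 30L,
                              stretch_mean_max = 70,
                              ordered_plddt_min = 70,
                              stretch_mode = c("maximal_run", "any_window")) {
  stretch_mode <- match.arg(stretch_mode)
  check_scalar_number(disorder_plddt_max, "disorder_plddt_max", 0, 100)
  check_scalar_number(stretch_mean_max, "stretch_mean_max", 0, 100)
  check_scalar_number(ordered_plddt_min, "ordered_plddt_min", 0, 100)
  check_scalar_number(stretch_min_len, "stretch_min_len", 1, Inf)
  if (ordered_plddt_min <= 0) stop("`ordered_plddt_min` must be in (0, 100]", call. = FALSE)
  if (disorder_plddt_max > stretch_mean_max) {
    stop("`disorder_plddt_max` must not exceed `stretch_mean_max`", call. = FALSE)
  }
  structure(list(disorder_plddt_max = disorder_plddt_max,
                 stretch_min_len = as.integer(stretch_min_len),
                 stretch_mean_max = stretch_mean_max,
                 ordered_plddt_min = ordered_plddt_min,
                 stretch_mode = stretch_mode),
            class = "classifier_params")
}

#' Find qualifying low-confidence stretches in a profile
#'
#' Returns the segments that license disordered calls: contiguous stretches
#' of at least `stretch_min_len` residues with mean pLDDT below
#' `stretch_mean_max`, under the stretch mode set in `params` (see
#' [classifier_params()]). Segments are non-overlapping, sorted by start,
#' with 1-based inclusive coordinates.
#'
#' @param profile A [plddt_profile()].
#' @param params A [classifier_params()].
#' @return Data frame with columns `protein_id`, `start`, `end`,
#'   `mean_plddt` (zero rows when no stretch qualifies).
#' @export
find_low_confidence_stretches <- function(profile, params = classifier_params()) {
  stopifnot(inherits(profile, "plddt_profile"), inherits(params, "classifier_params"))
  x <- profile$plddt
  n <- length(x)
  w <- params$stretch_min_len
  low <- x < params$stretch_mean_max

  empty <- data.frame(protein_id = character(), start = integer(), end = integer(),
                      mean_plddt = numeric(), stringsAsFactors = FALSE)

  if (params$stretch_mode == "maximal_run") {
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= w
    if (!any(keep)) return(empty)
    starts <- starts[keep]; ends <- ends[keep]
  } else {
    if (n < w) return(empty)
    cs <- c(0, cumsum(x))
    win_start <- seq_len(n - w + 1L)
    win_mean <- (cs[win_start + w] - cs[win_start]) / w
    qs <- win_start[win_mean < params$stretch_mean_max]
    if (length(qs) == 0L) return(empty)
    covered <- logical(n)
    for (s in qs) covered[s:(s + w - 1L)] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    starts <- starts[keep]; ends <- ends[keep]
  }

  means <- vapply(seq_along(starts), function(i) mean(x[starts[i]:ends[i]]), numeric(1))
  if (params$stretch_mode == "maximal_run") {
    # every residue in a run is < stretch_mean_max, so the mean must be too
    stopifnot(all(means < params$stretch_mean_max))
  }
  data.frame(protein_id = profile$protein_id, start = starts, end = ends,
             mean_plddt = means, stringsAsFactors = FALSE)
}

#' Classify each residue as disordered, intermediate or ordered
#'
#' Applies the three-state rule: disordered iff pLDDT <
#' `disorder_plddt_max` *and* the residue lies inside a qualifying
#' low-confidence stretch ([find_low_confidence_stretches()]); ordered iff
#' pLDDT >= `ordered_plddt_min`; intermediate otherwise. Exactly one label
#' per residue.
#'
#' @param profile A [plddt_profile()].
#' @param params A [classifier_params()].
#' @return Data frame with columns `protein_id`, `position`, `plddt`,
#'   `label` (factor with levels disordered, intermediate, ordered).
#' @export
classify_residues <- function(profile, params = classifier_params()) {
  stopifnot(inherits(profile, "plddt_profile"))
  segs <- find_low_confidence_stretches(profile, params)
  x <- profile$plddt
  in_segment <- logical(length(x))
  if (nrow(segs) > 0L) {
    for (i in seq_len(nrow(segs))) in_segment[segs$start[i]:segs$end[i]] <- TRUE
  }
  label <- rep("intermediate", length(x))
  label[x >= params$ordered_plddt_min] <- "ordered"
  label[x < params$disorder_plddt_max & in_segment] <- "disordered"
  data.frame(protein_id = profile$protein_id,
             position = seq_along(x),
             plddt = x,
             label = factor(label, levels = REGION_LEVELS),
             stringsAsFactors = FALSE)
}

#' Classify a set of profiles
#'
#' Convenience wrapper running [classify_residues()] over a list of
#' profiles and row-binding the annotations.
#'
#' @param profiles List of [plddt_profile()] objects.
#' @param params A [classifier_params()].
#' @return One residue-annotation data frame covering all proteins.
#' @export
classify_profiles <- function(profiles, params = classifier_params()) {
  do.call(rbind, lapply(profiles, classify_residues, params = params))
}

#' Summarize disorder content of one protein
#'
#' @param annotations Residue annotations for a single protein, as
#'   returned by [classify_residues()].
#' @param highly_disordered_min Inclusive lower bound on the disordered
#'   fraction for the `highly_disordered` flag (default 0.30).
#' @return One-row data frame: `protein_id`, `n_residues`, per-label
#'   counts and fractions, `has_disordered_region`, `highly_disordered`.
#' @export
summarize_protein <- function(annotations, highly_disordered_min = 0.30) {
  if (is.null(annotations) || nrow(annotations) == 0L) {
    stop("no residue annotations supplied", call. = FALSE)
  }
  if (length(unique(annotations$protein_id)) != 1L) {
    stop("annotations must cover exactly one protein", call. = FALSE)
  }
  n <- nrow(annotations)
  cnt <- table(factor(annotations$label, levels = REGION_LEVELS))
  fr <- as.numeric(cnt) / n
  data.frame(protein_id = annotations$protein_id[1L],
             n_residues = n,
             n_disordered = as.integer(cnt[["disordered"]]),
             n_intermediate = as.integer(cnt[["intermediate"]]),
             n_ordered = as.integer(cnt[["ordered"]]),
             fraction_disordered = fr[1L],
             fraction_intermediate = fr[2L],
             fraction_ordered = fr[3L],
             has_disordered_region = cnt[["disordered"]] > 0L,
             highly_disordered = fr[1L] >= highly_disordered_min,
             stringsAsFactors = FALSE)
}

#' Summarize disorder content across a set of proteins
#'
#' Label fractions are residue-weighted (total residues per label over
#' total residues), not averaged per protein; protein-level flags are
#' reported as fractions of proteins.
#'
#' @param summaries Data frame of per-protein summaries
#'   ([summarize_protein()] rows).
#' @return List with `n_proteins`, `n_residues`, residue-weighted
#'   `fraction_disordered` / `fraction_intermediate` / `fraction_ordered`,
#'   `prop_proteins_with_idr`, `prop_highly_disordered`.
#' @export
summarize_proteome <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) == 0L) {
    stop("at least one protein summary required", call. = FALSE)
  }
  n_res <- sum(summaries$n_residues)
  list(n_proteins = nrow(summaries),
       n_residues = n_res,
       fraction_disordered = sum(summaries$n_disordered) / n_res,
       fraction_intermediate = sum(summaries$n_intermediate) / n_res,
       fraction_ordered = sum(summaries$n_ordered) / n_res,
       prop_proteins_with_idr = mean(summaries$has_disordered_region),
       prop_highly_disordered = mean(summaries$highly_disordered))
}
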