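#' Parameters of the block-structured pLDDT generator
#'
#' Proteins are built from alternating ordered and disordered blocks;
#' per-residue pLDDT is emitted independently from the block state's
#' normal distribution, truncated to [0, 100]. Emission defaults (ordered
#' mean 90 sd 4, disordered mean 40 sd 6) keep the two states well
#' separated so the classifier's ground truth is recoverable. The
#' disordered length range deliberately dips below 30 residues so that
#' some blocks fall under the minimum-stretch rule and are truthed as
#' intermediate.
#'
#' @param n_proteins Number of proteins (default 100).
#' @param blocks_per_protein Integer range, blocks per protein (default
#'   c(3, 9)).
#' @param ordered_len,disordered_len Integer length ranges per block state
#'   (defaults c(100, 400) and c(25, 80)).
#' @param ordered_mean,ordered_sd,disordered_mean,disordered_sd Emission
#'   parameters (defaults 90/4 and 40/6).
#' @param min_disordered_len_truth Disordered blocks shorter than this are
#'   labelled intermediate in the ground truth (default 30, matching the
#'   classifier's minimum stretch).
#' @param seed Integer seed.
#' @return Object of class `segment_model_params`.
#' @export
segment_model_params <- function(n_proteins = 100L,
                                 blocks_per_protein = c(3L, 9L),
                                 ordered_len = c(100L, 400L),
                                 disordered_len = c(25L, 80L),
                                 ordered_mean = 90, ordered_sd = 4,
                                 disordered_mean = 40, disordered_sd = 6,
                                 min_disordered_len_truth = 30L,
                                 seed = 1L) {
  stopifnot(n_proteins >= 1L, ordered_sd >= 0, disordered_sd >= 0)
  if (!(disordered_mean < 50 && ordered_mean >= 70)) {
    stop("defaults require disordered emission mean < 50 and ordered mean >= 70 so ground truth is recoverable",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "segment_model_params")
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

emit_plddt <- function(n, mean, sd) {
  pmin(100, pmax(0, stats::rnorm(n, mean, sd)))
}

#' Simulate block-structured pLDDT profiles with ground truth
#'
#' @param params A [segment_model_params()].
#' @return List with `profiles` (named list of [plddt_profile()]),
#'   `truth` (data frame `protein_id`, `position`, `truth`) and `blocks`
#'   (data frame of generating blocks).
#' @export
simulate_plddt_profiles <- function(params = segment_model_params()) {
  stopifnot(inherits(params, "segment_model_params"))
  set.seed(params$seed)
  profiles <- vector("list", params$n_proteins)
  truth <- vector("list", params$n_proteins)
  blocks <- vector("list", params$n_proteins)
  ids <- sprintf("P%04d", seq_len(params$n_proteins))
  for (i in seq_len(params$n_proteins)) {
    n_blocks <- runif_int(1L, params$blocks_per_protein)
    state <- sample(c("ordered", "disordered"), 1L)
    vals <- numeric(0); lab <- character(0)
    binfo <- list()
    for (b in seq_len(n_blocks)) {
      if (state == "ordered") {
        len <- runif_int(1L, params$ordered_len)
        v <- emit_plddt(len, params$ordered_mean, params$ordered_sd)
        l <- rep("ordered", len)
      } else {
        len <- runif_int(1L, params$disordered_len)
        v <- emit_plddt(len, params$disordered_mean, params$disordered_sd)
        l <- rep(if (len >= params$min_disordered_len_truth) "disordered" else "intermediate", len)
      }
      binfo[[b]] <- data.frame(protein_id = ids[i], state = state,
                               start = length(vals) + 1L, end = length(vals) + len,
                               stringsAsFactors = FALSE)
      vals <- c(vals, v); lab <- c(lab, l)
      state <- if (state == "ordered") "disordered" else "ordered"
    }
    profiles[[i]] <- plddt_profile(ids[i], vals)
    truth[[i]] <- data.frame(protein_id = ids[i], position = seq_along(vals),
                             truth = lab, stringsAsFactors = FALSE)
    blocks[[i]] <- do.call(rbind, binfo)
  }
  names(profiles) <- ids
  list(profiles = profiles,
       truth = do.call(rbind, truth),
       blocks = do.call(rbind, blocks))
}

#' Parameters of the variant generator
#'
#' Expected variant counts per (region, class); defaults reproduce the
#' qualitative pattern of real data -- pathogenic variants strongly
#' depleted in disordered regions, ClinVar benign strongly enriched,
#' gnomAD variants mildly enriched -- using the published region splits
#' as proportions (pathogenic 3.6/15.1/81.3%; gnomAD 27.2% disordered;
#' ClinVar benign 39.8% disordered). Pathogenic variants receive AD/AR
#' inheritance with a region-dependent AD probability (AD enriched in
#' disorder) and, within AD, a molecular mechanism label.
#'
#' @param expected_counts 3x3 numeric matrix, rows = regions (disordered,
#'   intermediate, ordered), columns = classes (clinvar_pathogenic,
#'   clinvar_benign, gnomad_benign).
#' @param inheritance_ad_prob Named vector, probability a pathogenic
#'   variant in each region is AD (remainder AR).
#' @param mechanism_probs 3x3 matrix, rows = regions, columns =
#'   LOF/GOF/DN probabilities for AD pathogenic variants.
#' @param fixed_counts If `TRUE`, use the expected counts exactly
#'   (rounded) instead of Poisson draws.
#' @param seed Integer seed.
#' @return Object of class `variant_sim_params`.
#' @export
variant_sim_params <- function(expected_counts = NULL,
                               inheritance_ad_prob = c(disordered = 0.67,
                                                       intermediate = 0.61,
                                                       ordered = 0.48),
                               mechanism_probs = NULL,
                               fixed_counts = FALSE,
                               seed = 1L) {
  if (is.null(expected_counts)) {
    expected_counts <- cbind(clinvar_pathogenic = 2000 * c(0.036, 0.151, 0.813),
                             clinvar_benign = 600 * c(0.398, 0.202, 0.400),
                             gnomad_benign = 3000 * c(0.272, 0.180, 0.548))
    rownames(expected_counts) <- REGION_LEVELS
  }
  stopifnot(all(expected_counts >= 0), sum(expected_counts) > 0)
  if (is.null(mechanism_probs)) {
    mechanism_probs <- rbind(disordered = c(LOF = 0.45, GOF = 0.30, DN = 0.25),
                             intermediate = c(LOF = 0.35, GOF = 0.35, DN = 0.30),
                             ordered = c(LOF = 0.50, GOF = 0.20, DN = 0.30))
  }
  structure(list(expected_counts = expected_counts,
                 inheritance_ad_prob = inheritance_ad_prob,
                 mechanism_probs = mechanism_probs,
                 fixed_counts = fixed_counts,
                 seed = seed),
            class = "variant_sim_params")
}

#' Simulate a missense variant table over annotated residues
#'
#' Variants are placed uniformly at random on the residues of each
#' structural region; counts per (region, class) are Poisson around the
#' expected counts (or exact with `fixed_counts`). Reference and
#' alternate amino acids are distinct uniform draws; duplicate
#' (protein, position, alt, class) draws are collapsed. A region with a
#' positive expected count but no annotated residues is skipped with a
#' warning.
#'
#' @param params A [variant_sim_params()].
#' @param annotations Residue annotation data frame
#'   ([classify_profiles()]).
#' @return Variant data frame in the [load_variants()] layout, `region`
#'   column carrying the generating region.
#' @export
simulate_variants <- function(params = variant_sim_params(), annotations) {
  stopifnot(inherits(params, "variant_sim_params"))
  set.seed(params$seed)
  out <- list()
  for (r in REGION_LEVELS) {
    res <- annotations[annotations$label == r, , drop = FALSE]
    for (cl in VARIANT_CLASSES) {
      lambda <- params$expected_counts[r, cl]
      if (lambda <= 0) next
      if (nrow(res) == 0L) {
        warning(sprintf("no '%s' residues available; expected count for class '%s' ignored", r, cl),
                call. = FALSE)
        next
      }
      n <- if (params$fixed_counts) as.integer(round(lambda)) else stats::rpois(1L, lambda)
      if (n == 0L) next
      idx <- sample.int(nrow(res), n, replace = TRUE)
      inh <- rep("unknown", n)
      mech <- rep("unknown", n)
      if (cl == "clinvar_pathogenic") {
        is_ad <- stats::runif(n) < params$inheritance_ad_prob[[r]]
        inh <- ifelse(is_ad, "AD", "AR")
        mech[!is_ad] <- "LOF"
        if (any(is_ad)) {
          mech[is_ad] <- sample(colnames(params$mechanism_probs), sum(is_ad),
                                replace = TRUE, prob = params$mechanism_probs[r, ])
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        protein_id = res$protein_id[idx],
        gene = sub("^P", "GENE", res$protein_id[idx]),
        position = res$position[idx],
        class_label = cl, inheritance = inh, mechanism = mech,
        region = r, stringsAsFactors = FALSE)
    }
  }
  v <- do.call(rbind, out)
  # one reference amino acid per residue, shared by every variant at it
  res_key <- paste(v$protein_id, v$position, sep = ":")
  uk <- unique(res_key)
  ref_by_res <- stats::setNames(sample(AA_ALPHABET, length(uk), replace = TRUE), uk)
  v$ref_aa <- unname(ref_by_res[res_key])
  v$alt_aa <- vapply(v$ref_aa, function(a) sample(setdiff(AA_ALPHABET, a), 1L), "")
  # a substitution belongs to exactly one class: drop cross-class repeats
  dup <- duplicated(paste(v$protein_id, v$position, v$alt_aa, sep = ":"))
  if (any(dup)) message(sprintf("dropped %d duplicate substitution draw(s)", sum(dup)))
  v <- v[!dup, , drop = FALSE]
  rownames(v) <- NULL
  v[c("protein_id", "gene", "position", "ref_aa", "alt_aa",
      "class_label", "inheritance", "mechanism", "region")]
}

#' Parameters of the binormal VEP score generator
#'
#' Per VEP and region, pathogenic and benign scores are drawn from normal
#' distributions; the closed-form AUROC of this model is
#' `pnorm((mu_path - mu_ben) / sqrt(sigma_path^2 + sigma_ben^2))`
#' ([expected_auroc()]). Presets:
#' \describe{
#'   \item{paper-like}{seven VEPs across the three training-strategy
#'     groups. Scores in disordered regions are shifted down for both
#'     classes -- much further for benign -- with a tighter spread, so the
#'     region separates well (high AUROC) yet pathogenic variants sit
#'     below a globally derived threshold (low sensitivity). One VEP has
#'     an inverted score orientation and one has 30% missingness so the
#'     coverage filter and orientation machinery are exercised.}
#'   \item{null}{three VEPs with zero separation everywhere (AUROC 0.5).}
#'   \item{separable}{three VEPs with a large, region-independent
#'     separation.}
#' }
#'
#' @param preset `"paper-like"` (default), `"null"` or `"separable"`.
#' @param seed Integer seed.
#' @return Object of class `score_sim_params`: list with `veps` (data
#'   frame: name, group, higher_is_pathogenic, missingness) and `effects`
#'   (data frame: vep, region, mu_path, mu_ben, sigma_path, sigma_ben).
#' @export
score_sim_params <- function(preset = c("paper-like", "null", "separable"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "paper-like") {
    veps <- data.frame(
      name = c("clinA", "clinB", "clinC", "popA", "popB", "tunedA", "lowcov"),
      group = c("clinical_trained", "clinical_trained", "clinical_trained",
                "population_free", "population_free", "population_tuned",
                "clinical_trained"),
      higher_is_pathogenic = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
      missingness = c(0, 0, 0.05, 0, 0, 0, 0.30),
      stringsAsFactors = FALSE)
    base <- data.frame(region = REGION_LEVELS,
                       mu_path = c(0.0, 1.5, 2.0),
                       mu_ben = c(-1.8, -0.7, 0.0),
                       sigma = c(0.6, 0.9, 1.0))
    shift <- c(0, 0.15, -0.15, 0.20, -0.10, 0.10, 0)
    effects <- do.call(rbind, lapply(seq_len(nrow(veps)), function(i) {
      data.frame(vep = veps$name[i], region = base$region,
                 mu_path = base$mu_path + shift[i], mu_ben = base$mu_ben,
                 sigma_path = base$sigma, sigma_ben = base$sigma,
                 stringsAsFactors = FALSE)
    }))
  } else {
    veps <- data.frame(name = c("vepA", "vepB", "vepC"),
                       group = c("clinical_trained", "population_free", "population_tuned"),
                       higher_is_pathogenic = TRUE,
                       missingness = 0, stringsAsFactors = FALSE)
    mu_path <- if (preset == "null") 0 else 3
    effects <- do.call(rbind, lapply(veps$name, function(v) {
      data.frame(vep = v, region = REGION_LEVELS,
                 mu_path = mu_path, mu_ben = 0, sigma_path = 1, sigma_ben = 1,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(preset = preset, veps = veps, effects = effects, seed = seed),
            class = "score_sim_params")
}

#' Simulate VEP score sets over a variant table
#'
#' Each variant's score is drawn from the normal distribution of its
#' (VEP, region, class) cell; missingness is applied independently per
#' VEP at the configured rate; when a VEP's orientation flag is
#' `FALSE` its emitted scores are negated, so downstream orientation
#' restores them.
#'
#' @param params A [score_sim_params()].
#' @param variants Variant data frame with `region` and `class_label`.
#' @return List with `scoresets` (named list of [vep_scoreset()]) and
#'   `metadata` (data frame usable in place of [read_vep_metadata()]
#'   output).
#' @export
simulate_vep_scores <- function(params = score_sim_params(), variants) {
  stopifnot(inherits(params, "score_sim_params"))
  set.seed(params$seed)
  keys <- variant_key(variants)
  is_path <- variants$class_label == "clinvar_pathogenic"
  sets <- list()
  for (i in seq_len(nrow(params$veps))) {
    v <- params$veps$name[i]
    eff <- params$effects[params$effects$vep == v, , drop = FALSE]
    j <- match(variants$region, eff$region)
    if (anyNA(j)) stop(sprintf("VEP '%s': missing effect parameters for some region", v), call. = FALSE)
    mu <- ifelse(is_path, eff$mu_path[j], eff$mu_ben[j])
    sg <- ifelse(is_path, eff$sigma_path[j], eff$sigma_ben[j])
    s <- stats::rnorm(nrow(variants), mu, sg)
    if (!params$veps$higher_is_pathogenic[i]) s <- -s
    keep <- stats::runif(nrow(variants)) >= params$veps$missingness[i]
    sets[[v]] <- vep_scoreset(v, params$veps$group[i],
                              params$veps$higher_is_pathogenic[i],
                              stats::setNames(s[keep], keys[keep]))
  }
  list(scoresets = sets,
       metadata = params$veps[c("name", "group", "higher_is_pathogenic")])
}

#' Closed-form binormal AUROC
#'
#' For pathogenic ~ Normal(mu_path, sigma_path^2) and benign ~
#' Normal(mu_ben, sigma_ben^2), the AUROC is
#' `pnorm((mu_path - mu_ben) / sqrt(sigma_path^2 + sigma_ben^2))`.
#'
#' @param mu_path,mu_ben Class means.
#' @param sigma_path,sigma_ben Class standard deviations (> 0).
#' @return Expected AUROC.
#' @export
expected_auroc <- function(mu_path, mu_ben, sigma_path = 1, sigma_ben = 1) {
  stopifnot(all(sigma_path > 0), all(sigma_ben > 0))
  stats::pnorm((mu_path - mu_ben) / sqrt(sigma_path^2 + sigma_ben^2))
}

#' Simulate a full study dataset
#'
#' Generates pLDDT profiles, classifies them, places variants on the
#' annotated residues and draws VEP scores, all from one master seed
#' fanned out to per-component substreams ([substream_seeds()]).
#'
#' @param preset Score preset, see [score_sim_params()].
#' @param seed Master seed.
#' @param plddt_params,variant_params Optional parameter objects; their
#'   `seed` fields are overwritten by the fanned-out substream seeds.
#' @param classifier A [classifier_params()] used for the annotations the
#'   variant generator samples from.
#' @param out_dir If non-`NULL`, write the pipeline-consumable TSV files
#'   there (see [write_simulation()]).
#' @return List: `profiles`, `truth`, `annotations`, `variants`,
#'   `scoresets`, `vep_metadata`, `seed`, and `paths` when `out_dir` was
#'   given.
#' @export
simulate_dataset <- function(preset = "paper-like", seed = 1L,
                             plddt_params = NULL, variant_params = NULL,
                             classifier = classifier_params(),
                             out_dir = NULL) {
  seeds <- substream_seeds(seed, 3L)
  pp <- plddt_params %||% segment_model_params()
  pp$seed <- seeds[1L]
  vp <- variant_params %||% variant_sim_params()
  vp$seed <- seeds[2L]
  sp <- score_sim_params(preset, seed = seeds[3L])

  prof <- simulate_plddt_profiles(pp)
  ann <- classify_profiles(prof$profiles, classifier)
  variants <- simulate_variants(vp, ann)
  scores <- simulate_vep_scores(sp, variants)

  sim <- list(profiles = prof$profiles, truth = prof$truth, annotations = ann,
              variants = variants, scoresets = scores$scoresets,
              vep_metadata = scores$metadata, seed = seed)
  if (!is.null(out_dir)) {
    sim$paths <- write_simulation(sim, out_dir)
  }
  sim
}

#' Write a simulated dataset as pipeline input files
#'
#' Writes `plddt.tsv` (protein_id, position, plddt), `variants.tsv`,
#' `scores.tsv` (long form) and `vep_metadata.tsv` into `out_dir`.
#'
#' @param sim Result of [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(plddt = file.path(out_dir, "plddt.tsv"),
                variants = file.path(out_dir, "variants.tsv"),
                scores = file.path(out_dir, "scores.tsv"),
                vep_meta = file.path(out_dir, "vep_metadata.tsv"))
  plddt <- do.call(rbind, lapply(sim$profiles, function(p) {
    data.frame(protein_id = p$protein_id, position = seq_len(p$length),
               plddt = round(p$plddt, 3), stringsAsFactors = FALSE)
  }))
  write_tsv <- function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(plddt, paths$plddt)
  vcols <- c("protein_id", "gene", "position", "ref_aa", "alt_aa",
             "class_label", "inheritance", "mechanism")
  write_tsv(sim$variants[vcols], paths$variants)
  long <- do.call(rbind, lapply(sim$scoresets, function(s) {
    parts <- strsplit(names(s$scores), ":", fixed = TRUE)
    data.frame(vep = s$name,
               protein_id = vapply(parts, `[[`, "", 1L),
               position = as.integer(vapply(parts, `[[`, "", 2L)),
               ref_aa = vapply(parts, `[[`, "", 3L),
               alt_aa = vapply(parts, `[[`, "", 4L),
               score = unname(s$scores), stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  write_tsv(long, paths$scores)
  write_tsv(sim$vep_metadata, paths$vep_meta)
  invisible(paths)
}
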