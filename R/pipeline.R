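CONFIG_KEYS <- c("paths", "classifier", "min_coverage", "ci_level",
                 "highly_disordered_min", "strata", "score_format",
                 "strict_assign", "seed", "log_level")
PATH_KEYS <- c("plddt", "variants", "exclusion", "scores", "vep_meta", "out_dir")
CLASSIFIER_KEYS <- c("disorder_plddt_max", "stretch_min_len", "stretch_mean_max",
                     "ordered_plddt_min", "stretch_mode")

#' Validate and normalize a run configuration
#'
#' Accepts a config as a nested list or a YAML file path, injects the
#' default parameters (classifier thresholds 50/30/70/70, minimum VEP
#' coverage 0.75, CI level 0.95, highly-disordered cut-off 0.30), rejects
#' unknown keys and out-of-range values, and checks that the input files
#' exist.
#'
#' @param config Nested list or path to a YAML file. Required entries
#'   under `paths`: `plddt`, `variants`, `scores`, `vep_meta`, `out_dir`;
#'   optional: `exclusion`.
#' @return Normalized config list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  paths <- config$paths %||% list()
  unknown <- setdiff(names(paths), PATH_KEYS)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown path key(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (p in c("plddt", "variants", "scores", "vep_meta", "out_dir")) {
    if (is.null(paths[[p]])) stop(sprintf("config paths$%s is required", p), call. = FALSE)
  }
  for (p in c("plddt", "variants", "scores", "vep_meta", "exclusion")) {
    if (!is.null(paths[[p]]) && !file.exists(paths[[p]])) {
      stop(sprintf("input file not found: %s (paths$%s)", paths[[p]], p), call. = FALSE)
    }
  }
  cl <- config$classifier %||% list()
  unknown <- setdiff(names(cl), CLASSIFIER_KEYS)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown classifier key(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  classifier <- classifier_params(
    disorder_plddt_max = cl$disorder_plddt_max %||% 50,
    stretch_min_len = cl$stretch_min_len %||% 30L,
    stretch_mean_max = cl$stretch_mean_max %||% 70,
    ordered_plddt_min = cl$ordered_plddt_min %||% 70,
    stretch_mode = cl$stretch_mode %||% "maximal_run")
  out <- list(paths = paths,
              classifier = classifier,
              min_coverage = config$min_coverage %||% 0.75,
              ci_level = config$ci_level %||% 0.95,
              highly_disordered_min = config$highly_disordered_min %||% 0.30,
              strata = config$strata %||% "class_label",
              score_format = config$score_format %||% "long",
              strict_assign = isTRUE(config$strict_assign),
              seed = config$seed %||% 1L,
              log_level = config$log_level %||% "info")
  check_scalar_number(out$min_coverage, "min_coverage", 0, 1)
  check_scalar_number(out$ci_level, "ci_level", 0, 1)
  check_scalar_number(out$highly_disordered_min, "highly_disordered_min", 0, 1)
  out$score_format <- match.arg(out$score_format, c("long", "wide"))
  out
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

fingerprint <- function(path) {
  list(file = basename(path),
       md5 = unname(tools::md5sum(path)),
       n_lines = length(readLines(path, warn = FALSE)))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full region-stratified analysis
#'
#' Executes classify -> assign -> distributions/enrichment -> evaluate ->
#' agreement over the files named in the config, writing every stage's
#' table under `paths$out_dir` together with a machine-readable run
#' report (`run_report.json`) whose record counts satisfy
#' loaded = gene-excluded + unassigned + class-excluded +
#' dropped-by-intersection + retained. Reruns on identical inputs produce
#' byte-identical outputs.
#'
#' @param config Config list or YAML path (see [validate_config()]).
#' @param stages Character subset of
#'   `c("classify", "variants", "evaluate")`; later stages read the
#'   earlier stages' files from `out_dir`, so partial runs compose to the
#'   same outputs as a full run.
#' @return The run report, invisibly.
#' @export
run_all <- function(config, stages = c("classify", "variants", "evaluate")) {
  config <- validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(tool = "idrvep",
                 version = as.character(utils::packageVersion("idrvep")),
                 parameters = list(classifier = unclass(config$classifier),
                                   min_coverage = config$min_coverage,
                                   ci_level = config$ci_level,
                                   highly_disordered_min = config$highly_disordered_min),
                 inputs = Filter(Negate(is.null),
                                 lapply(config$paths[setdiff(PATH_KEYS, "out_dir")],
                                        function(p) if (is.null(p)) NULL else fingerprint(p))),
                 counts = list())

  ann_path <- file.path(out_dir, "residue_annotations.tsv")
  assigned_path <- file.path(out_dir, "variants_assigned.tsv")

  if ("classify" %in% stages) {
    run_stage("classify", {
      profiles <- read_plddt_table(config$paths$plddt)
      ann <- classify_profiles(profiles, config$classifier)
      segs <- do.call(rbind, lapply(profiles, find_low_confidence_stretches,
                                    params = config$classifier))
      summaries <- do.call(rbind, lapply(split(ann, ann$protein_id), summarize_protein,
                                         highly_disordered_min = config$highly_disordered_min))
      rownames(summaries) <- NULL
      proteome <- summarize_proteome(summaries)
      write_tsv(ann, ann_path)
      # segment TSV uses 1-based inclusive protein coordinates, unlike genomic BED
      write_tsv(segs, file.path(out_dir, "disorder_segments.tsv"))
      write_tsv(summaries, file.path(out_dir, "protein_summaries.tsv"))
      jsonlite::write_json(proteome, file.path(out_dir, "proteome_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      report$counts$n_proteins <- length(profiles)
      report$counts$n_residues <- proteome$n_residues
    })
  }

  if ("variants" %in% stages) {
    run_stage("variants", {
      variants <- load_variants(config$paths$variants)
      n_loaded <- nrow(variants)
      n_excluded <- 0L
      if (!is.null(config$paths$exclusion)) {
        excl <- exclude_genes(variants, read_gene_list(config$paths$exclusion))
        variants <- excl$variants
        n_excluded <- excl$report$n_removed
        report$counts$gene_excluded_per_class <- as.list(excl$report$removed_per_class)
      }
      ann <- utils::read.delim(ann_path, stringsAsFactors = FALSE)
      asg <- assign_regions(variants, ann, strict = config$strict_assign)
      variants <- asg$variants
      write_tsv(variants, assigned_path)

      dist <- region_distribution(variants, strata = config$strata)
      write_tsv(dist, file.path(out_dir, "region_distribution.tsv"))

      path_inh <- variants[variants$class_label == "clinvar_pathogenic" &
                             variants$inheritance %in% c("AD", "AR") &
                             variants$region != "unassigned", , drop = FALSE]
      enrich <- list()
      if (nrow(path_inh) > 0L) {
        inh_dist <- region_distribution(path_inh, strata = "inheritance")
        write_tsv(inh_dist, file.path(out_dir, "inheritance_distribution.tsv"))
        if (length(unique(path_inh$inheritance)) == 2L) {
          for (r in REGION_LEVELS) {
            tab <- rbind(AD = c(sum(path_inh$inheritance == "AD" & path_inh$region == r),
                                sum(path_inh$inheritance == "AD" & path_inh$region != r)),
                         AR = c(sum(path_inh$inheritance == "AR" & path_inh$region == r),
                                sum(path_inh$inheritance == "AR" & path_inh$region != r)))
            colnames(tab) <- c("in_region", "elsewhere")
            fe <- fisher_exact_2x2(tab)
            enrich[[paste0("ad_vs_ar_", r)]] <- list(
              region = r, table = as.data.frame(tab),
              prop_ad = tab[1, 1] / sum(tab[1, ]),
              prop_ar = tab[2, 1] / sum(tab[2, ]),
              odds_ratio = fe$odds_ratio, p_value = fe$p_value,
              degenerate = fe$degenerate)
          }
        }
      }
      jsonlite::write_json(enrich, file.path(out_dir, "enrichment.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)

      ad_path <- path_inh[path_inh$inheritance == "AD" &
                            path_inh$mechanism %in% c("LOF", "GOF", "DN"), , drop = FALSE]
      if (nrow(ad_path) > 0L) {
        ci_rows <- list()
        for (m in intersect(c("LOF", "GOF", "DN"), unique(ad_path$mechanism))) {
          sub <- ad_path[ad_path$mechanism == m, , drop = FALSE]
          for (r in REGION_LEVELS) {
            ci <- binomial_ci(sum(sub$region == r), nrow(sub), level = config$ci_level)
            ci <- cbind(mechanism = m, region = r, ci)
            ci_rows[[length(ci_rows) + 1L]] <- ci
          }
        }
        write_tsv(do.call(rbind, ci_rows), file.path(out_dir, "mechanism_binomial_ci.tsv"))
      }
      report$counts$n_loaded <- n_loaded
      report$counts$n_excluded_genes <- n_excluded
      report$counts$n_unassigned <- asg$report$n_unassigned
      report$counts$n_assigned <- asg$report$n_assigned
    })
  }

  if ("evaluate" %in% stages) {
    run_stage("evaluate", {
      variants <- utils::read.delim(assigned_path, stringsAsFactors = FALSE)
      meta <- read_vep_metadata(config$paths$vep_meta)
      sets <- read_vep_scores(config$paths$scores, meta, format = config$score_format)
      assigned <- variants[variants$region != "unassigned", , drop = FALSE]
      flt <- filter_by_coverage(sets, assigned, min_frac = config$min_coverage)
      oriented <- lapply(flt$scoresets, orient_scores)
      ds <- intersect_complete(assigned, oriented)
      perf <- vep_performance(ds)
      agr <- agreement_by_region(ds)
      write_tsv(flt$report, file.path(out_dir, "vep_coverage.tsv"))
      write_tsv(perf, file.path(out_dir, "vep_performance.tsv"))
      write_tsv(agr$agreement, file.path(out_dir, "group_agreement.tsv"))
      for (sc in names(agr$kappa)) {
        km <- as.data.frame(agr$kappa[[sc]])
        km <- cbind(vep = rownames(km), km)
        write_tsv(km, file.path(out_dir, sprintf("kappa_%s.tsv", sc)))
      }
      report$vep_coverage <- flt$report
      report$counts$n_excluded_classes <- ds$report$n_excluded_classes
      report$counts$n_dropped_intersection <- ds$report$n_dropped_intersection
      report$counts$n_retained_eval <- nrow(ds$variants)
    })
  }

  cn <- report$counts
  if (!is.null(cn$n_loaded) && !is.null(cn$n_retained_eval)) {
    stopifnot(cn$n_loaded == cn$n_excluded_genes + cn$n_unassigned +
                cn$n_excluded_classes + cn$n_dropped_intersection + cn$n_retained_eval)
  }
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
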