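REGION_LEVELS <- c("disordered", "intermediate", "ordered")
VARIANT_CLASSES <- c("clinvar_pathogenic", "clinvar_benign", "gnomad_benign")
INHERITANCE_LEVELS <- c("AD", "AR", "unknown")
MECHANISM_LEVELS <- c("LOF", "GOF", "DN", "unknown")
VEP_GROUPS <- c("clinical_trained", "population_tuned", "population_free")
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive independent sub-seeds from one master seed
#'
#' A single user-facing seed fans out to one sub-seed per generator
#' component, so adding a new generator does not perturb the random
#' streams of existing ones.
#'
#' @param seed Integer master seed.
#' @param n Number of sub-seeds required.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 1]`.
#' @export
substream_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Build the canonical variant key
#'
#' Variants are keyed by protein, position and amino-acid change; the key
#' joins variant tables to VEP score maps.
#'
#' @param df Data frame with columns `protein_id`, `position`, `ref_aa`, `alt_aa`.
#' @return Character vector of keys.
#' @export
variant_key <- function(df) {
  paste(df$protein_id, df$position, df$ref_aa, df$alt_aa, sep = ":")
}

check_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lo, hi), call. = FALSE)
  }
  invisible(x)
}
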