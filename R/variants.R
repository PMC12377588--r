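#' Load a missense variant table
#'
#' Reads a tab-separated variant file with required columns `protein_id`,
#' `gene`, `position`, `ref_aa`, `alt_aa`, `class_label` and optional
#' `inheritance` and `mechanism` columns (missing values become
#' `"unknown"`). Rows failing validation are reported with their line
#' number. Duplicates -- same protein, position, alternate amino acid and
#' class -- are collapsed to one record with a logged count; collisions of
#' the same substitution across classes are reported but kept.
#'
#' @param path Path to the TSV file.
#' @return Data frame of validated variant records with a `region` column
#'   initialised to `"unassigned"`.
#' @export
load_variants <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_id", "gene", "position", "ref_aa", "alt_aa", "class_label")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop(sprintf("variant table missing columns: %s", paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("variant table is empty", call. = FALSE)
  row_id <- seq_len(nrow(tab)) + 1L  # +1 for the header line

  fail <- function(rows, what) {
    stop(sprintf("variant table line %d: %s", rows[1L], what), call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(tab$position))
  if (anyNA(pos) || any(pos <= 0L)) fail(row_id[is.na(pos) | pos <= 0L], "position must be a positive integer")
  tab$position <- pos
  bad_aa <- !(tab$ref_aa %in% AA_ALPHABET) | !(tab$alt_aa %in% AA_ALPHABET)
  if (any(bad_aa)) fail(row_id[bad_aa], "ref_aa/alt_aa must be single-letter amino acids")
  same <- tab$ref_aa == tab$alt_aa
  if (any(same)) fail(row_id[same], "ref_aa equals alt_aa (not a missense variant)")
  bad_class <- !(tab$class_label %in% VARIANT_CLASSES)
  if (any(bad_class)) {
    fail(row_id[bad_class], sprintf("class_label '%s' not one of: %s",
                                    tab$class_label[bad_class][1L],
                                    paste(VARIANT_CLASSES, collapse = ", ")))
  }
  for (col in c("inheritance", "mechanism")) {
    allowed <- if (col == "inheritance") INHERITANCE_LEVELS else MECHANISM_LEVELS
    if (!col %in% names(tab)) {
      tab[[col]] <- "unknown"
    } else {
      tab[[col]][is.na(tab[[col]]) | tab[[col]] == ""] <- "unknown"
      bad <- !(tab[[col]] %in% allowed)
      if (any(bad)) {
        fail(row_id[bad], sprintf("%s '%s' not one of: %s", col, tab[[col]][bad][1L],
                                  paste(allowed, collapse = ", ")))
      }
    }
  }

  dup_key <- paste(tab$protein_id, tab$position, tab$alt_aa, tab$class_label, sep = ":")
  n_dup <- sum(duplicated(dup_key))
  if (n_dup > 0L) {
    message(sprintf("deduplicated %d variant record(s) (same protein, position, alt, class)", n_dup))
    tab <- tab[!duplicated(dup_key), , drop = FALSE]
  }
  cross_key <- paste(tab$protein_id, tab$position, tab$alt_aa, sep = ":")
  n_cross <- sum(duplicated(cross_key))
  if (n_cross > 0L) {
    message(sprintf("%d substitution(s) appear under more than one class label (kept)", n_cross))
  }

  tab$region <- "unassigned"
  rownames(tab) <- NULL
  tab[c(need, "inheritance", "mechanism", "region")]
}

#' Read a gene exclusion list
#'
#' One gene symbol per line; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path Path to the text file.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Remove variants in excluded genes
#'
#' Drops every variant whose gene symbol is in the exclusion list
#' (case-insensitive exact match; no alias resolution). Typical use is the
#' removal of collagen-helix genes, which are fibrous yet consistently
#' predicted disordered and otherwise dominate the disordered pathogenic
#' set.
#'
#' @param variants Variant data frame from [load_variants()].
#' @param exclusion Character vector of gene symbols (see
#'   [read_gene_list()]).
#' @return List with `variants` (filtered data frame) and `report`
#'   (list: `n_removed`, `removed_per_class` named vector).
#' @export
exclude_genes <- function(variants, exclusion) {
  if (length(exclusion) == 0L) {
    warning("empty exclusion list; no variants removed", call. = FALSE)
    return(list(variants = variants,
                report = list(n_removed = 0L,
                              removed_per_class = integer(0))))
  }
  hit <- toupper(variants$gene) %in% toupper(exclusion)
  removed <- variants[hit, , drop = FALSE]
  per_class <- table(factor(removed$class_label, levels = VARIANT_CLASSES))
  if (sum(hit) > 0L) {
    message(sprintf("excluded %d variant(s) in %d listed gene(s)",
                    sum(hit), length(unique(removed$gene))))
  }
  list(variants = variants[!hit, , drop = FALSE],
       report = list(n_removed = sum(hit),
                     removed_per_class = as.integer(per_class) |> stats::setNames(VARIANT_CLASSES)))
}

#' Assign each variant a structural region
#'
#' Looks up each variant's residue in a residue-annotation table (from
#' [classify_residues()] / [classify_profiles()]) and copies the label
#' into the `region` column. Variants on proteins or positions without an
#' annotation stay `"unassigned"` and are counted in the report; with
#' `strict = TRUE` any unassigned variant is an error.
#'
#' @param variants Variant data frame.
#' @param annotations Residue annotation data frame.
#' @param strict Error on unassignable variants (default `FALSE`).
#' @return List with `variants` (region column filled) and `report`
#'   (list: `n_assigned`, `n_unassigned`).
#' @export
assign_regions <- function(variants, annotations, strict = FALSE) {
  if (any(variants$position <= 0L)) stop("variant positions must be positive", call. = FALSE)
  key_v <- paste(variants$protein_id, variants$position, sep = ":")
  key_a <- paste(annotations$protein_id, annotations$position, sep = ":")
  idx <- match(key_v, key_a)
  region <- as.character(annotations$label)[idx]
  region[is.na(region)] <- "unassigned"
  n_un <- sum(region == "unassigned")
  if (n_un > 0L) {
    if (strict) {
      stop(sprintf("%d variant(s) have no residue annotation (strict mode)", n_un), call. = FALSE)
    }
    message(sprintf("%d variant(s) left unassigned (no residue annotation)", n_un))
  }
  variants$region <- region
  list(variants = variants, report = list(n_assigned = nrow(variants) - n_un, n_unassigned = n_un))
}

#' Region distribution of variants, by stratum
#'
#' Counts assigned variants per structural region within each stratum
#' (e.g. per class label, inheritance mode or molecular mechanism) and
#' converts counts to proportions. Unassigned variants are excluded with a
#' logged count; an empty stratum yields zero counts and `NA` proportions
#' (flagged via `proportion_defined`).
#'
#' @param variants Assigned variant data frame.
#' @param strata Character vector of grouping columns (default
#'   `"class_label"`).
#' @return Long data frame: stratum columns, `region`, `count`,
#'   `proportion`, `proportion_defined`.
#' @export
region_distribution <- function(variants, strata = "class_label") {
  stopifnot(all(strata %in% names(variants)))
  n_un <- sum(variants$region == "unassigned")
  if (n_un > 0L) {
    message(sprintf("excluding %d unassigned variant(s) from the distribution", n_un))
  }
  v <- variants[variants$region != "unassigned", , drop = FALSE]
  lvls <- lapply(strata, function(s) sort(unique(variants[[s]])))
  names(lvls) <- strata
  grid <- expand.grid(c(lvls, list(region = REGION_LEVELS)),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  key_grid <- do.call(paste, c(grid[c(strata, "region")], sep = "\r"))
  key_v <- do.call(paste, c(v[c(strata, "region")], sep = "\r"))
  cnt <- table(factor(key_v, levels = key_grid))
  grid$count <- as.integer(cnt)
  key_stratum <- do.call(paste, c(grid[strata], sep = "\r"))
  totals <- stats::ave(grid$count, key_stratum, FUN = sum)
  grid$proportion <- ifelse(totals > 0, grid$count / totals, NA_real_)
  grid$proportion_defined <- totals > 0
  grid[order(key_stratum, match(grid$region, REGION_LEVELS)), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}
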