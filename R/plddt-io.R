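#' Construct a per-residue pLDDT profile
#'
#' A pLDDT profile is one protein's ordered vector of per-residue AlphaFold
#' confidence values on the 0-100 scale. Positions are implicitly 1-based
#' and contiguous.
#'
#' @param protein_id Identifier string.
#' @param plddt Numeric vector, one value per residue, each in [0, 100].
#' @return An object of class `plddt_profile` with elements `protein_id`,
#'   `plddt` and `length`.
#' @export
plddt_profile <- function(protein_id, plddt) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L, nzchar(protein_id))
  plddt <- as.numeric(plddt)
  if (length(plddt) < 1L) {
    stop("a pLDDT profile needs at least one residue", call. = FALSE)
  }
  if (anyNA(plddt) || any(plddt < 0 | plddt > 100)) {
    bad <- which(is.na(plddt) | plddt < 0 | plddt > 100)[1L]
    stop(sprintf("pLDDT out of [0, 100] for %s at position %d", protein_id, bad), call. = FALSE)
  }
  structure(list(protein_id = protein_id, plddt = plddt, length = length(plddt)),
            class = "plddt_profile")
}

#' @export
print.plddt_profile <- function(x, ...) {
  cat(sprintf("<plddt_profile> %s: %d residues, mean pLDDT %.1f\n",
              x$protein_id, x$length, mean(x$plddt)))
  invisible(x)
}

#' Read pLDDT profiles from a per-residue table
#'
#' Expects a tab-separated file with header columns `protein_id`,
#' `position`, `plddt`. Rows for one protein may be unsorted; positions
#' must be contiguous starting at 1. Some tools emit pLDDT on the 0-1
#' scale; set `rescale = TRUE` to accept such input (all values must then
#' be <= 1) and multiply by 100, with a warning. Without the flag,
#' fractional-only input is rejected like any other out-of-convention data.
#'
#' @param path Path to the TSV file.
#' @param rescale If `TRUE` and every value in the file is <= 1, values are
#'   multiplied by 100 (warning emitted). Default `FALSE`.
#' @return A named list of [plddt_profile()] objects, in order of first
#'   appearance in the file.
#' @export
read_plddt_table <- function(path, rescale = FALSE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "plddt")
  if (!all(need %in% names(tab))) {
    stop(sprintf("pLDDT table must have columns %s", paste(need, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("pLDDT table is empty", call. = FALSE)
  if (rescale) {
    if (all(tab$plddt <= 1.0)) {
      tab$plddt <- tab$plddt * 100
      warning("all pLDDT values were <= 1; rescaled to the 0-100 scale", call. = FALSE)
    }
  }
  ids <- unique(tab$protein_id)
  profiles <- lapply(ids, function(id) {
    sub <- tab[tab$protein_id == id, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    expected <- seq_len(nrow(sub))
    if (!identical(as.integer(sub$position), as.integer(expected))) {
      gap <- expected[match(FALSE, sub$position == expected)]
      stop(sprintf("protein %s: positions not contiguous from 1 (gap at position %d)", id, gap),
           call. = FALSE)
    }
    plddt_profile(id, sub$plddt)
  })
  names(profiles) <- ids
  profiles
}

#' Extract a pLDDT profile from an AlphaFold-style structure file
#'
#' AlphaFold DB models store per-residue pLDDT in the B-factor field of
#' every atom. This reads a single-chain PDB or mmCIF file and returns one
#' value per residue, taken from the first atom of the residue. If a
#' residue carries heterogeneous per-atom B-factors the CA atom's value is
#' used and a warning is emitted (such files are not AlphaFold DB models).
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param chain Chain identifier to select when the file has several
#'   chains; by default the file must be single-chain.
#' @param protein_id Identifier for the profile; defaults to the file name
#'   without extension.
#' @return A [plddt_profile()].
#' @export
read_plddt_from_structure <- function(path, chain = NULL, protein_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path, multi = FALSE)
  }
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("structure contains no protein atoms", call. = FALSE)
  if (!is.null(pdb$xyz) && is.matrix(unclass(pdb$xyz)) && nrow(unclass(pdb$xyz)) > 1L) {
    stop("multi-model structure; supply a single-model file", call. = FALSE)
  }
  chains <- unique(atoms$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L) {
      stop(sprintf("structure has %d chains (%s); select one with the `chain` argument",
                   length(chains), paste(chains, collapse = ", ")), call. = FALSE)
    }
  } else {
    if (!chain %in% chains) stop(sprintf("chain '%s' not present in structure", chain), call. = FALSE)
    atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  }
  resno <- atoms$resno
  ord <- order(resno)
  atoms <- atoms[ord, , drop = FALSE]
  by_res <- split(atoms, factor(atoms$resno, levels = unique(atoms$resno)))
  vals <- vapply(by_res, function(a) {
    b <- a$b
    if (length(unique(b)) > 1L) {
      ca <- a[a$elety == "CA", , drop = FALSE]
      if (nrow(ca) == 0L) {
        stop(sprintf("residue %d: heterogeneous B-factors and no CA atom", a$resno[1L]), call. = FALSE)
      }
      warning(sprintf("residue %d: per-atom B-factors differ; using CA value", a$resno[1L]),
              call. = FALSE)
      ca$b[1L]
    } else {
      b[1L]
    }
  }, numeric(1))
  id <- protein_id %||% tools::file_path_sans_ext(basename(path))
  plddt_profile(id, unname(vals))
}
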