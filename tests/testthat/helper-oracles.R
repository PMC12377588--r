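# Independent brute-force oracles. Each is written from the definition,
# not from the implementation it checks.

# AUROC as the exhaustive Mann-Whitney pairwise count, ties counted 1/2.
oracle_auroc <- function(scores, outcomes) {
  p <- scores[outcomes == 1]
  b <- scores[outcomes == 0]
  total <- 0
  for (x in p) for (y in b) total <- total + (x > y) + 0.5 * (x == y)
  total / (length(p) * length(b))
}

# Two-sided Fisher p by literal enumeration of all tables with the
# observed margins, probabilities from choose() directly.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  kk <- max(0, c1 - r2):min(c1, r1)
  prob <- choose(r1, kk) * choose(r2, c1 - kk) / choose(n, c1)
  p_obs <- prob[match(a, kk)]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Youden scan over all candidate thresholds, naive loops, same tie-break
# (max J, then max sensitivity, then min threshold).
oracle_youden <- function(scores, outcomes) {
  cand <- c(sort(unique(scores)), Inf)
  best <- NULL
  for (t in cand) {
    sens <- mean(scores[outcomes == 1] >= t)
    spec <- mean(scores[outcomes == 0] < t)
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-15 ||
        (abs(J - best$J) <= 1e-15 && sens > best$sens + 1e-15)) {
      best <- list(threshold = t, J = J, sens = sens, spec = spec)
    }
  }
  best
}

# any_window stretches by brute force: union of all length-w windows with
# mean below the bound.
oracle_window_union <- function(x, w, mean_max) {
  n <- length(x)
  covered <- logical(n)
  if (n >= w) {
    for (s in 1:(n - w + 1)) {
      if (mean(x[s:(s + w - 1)]) < mean_max) covered[s:(s + w - 1)] <- TRUE
    }
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

write_tsv_tmp <- function(d, dir = tempdir(), name = "tab.tsv") {
  path <- file.path(dir, name)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# 20-variant toy with three VEPs covering 16, 15 and 12 variants;
# exercises the inclusive 75% coverage boundary and the filtering order.
coverage_toy <- function() {
  v <- make_variant_df(20)
  v$class_label <- rep(c("clinvar_pathogenic", "gnomad_benign"), 10)
  keys <- variant_key(v)
  mk <- function(name, idx) {
    vep_scoreset(name, "clinical_trained", TRUE,
                 stats::setNames(seq_along(idx) * 0.1, keys[idx]))
  }
  list(variants = v,
       sets = list(A = mk("A", 1:16), B = mk("B", 3:17), C = mk("C", 5:16)))
}

make_variant_df <- function(n, protein_id = "P1", class_label = "clinvar_pathogenic",
                            region = "ordered") {
  data.frame(protein_id = protein_id, gene = paste0("GENE_", protein_id),
             position = seq_len(n), ref_aa = "A", alt_aa = "V",
             class_label = class_label, inheritance = "unknown",
             mechanism = "unknown", region = region, stringsAsFactors = FALSE)
}
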