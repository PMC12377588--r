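test_that("profile simulation is deterministic and truth follows the block rule", {
  p <- segment_model_params(n_proteins = 10L, seed = 42L)
  a <- simulate_plddt_profiles(p)
  b <- simulate_plddt_profiles(p)
  expect_identical(a, b)

  # sub-30 disordered blocks are truthed intermediate
  p20 <- segment_model_params(n_proteins = 10L, disordered_len = c(20L, 20L), seed = 3L)
  s20 <- simulate_plddt_profiles(p20)
  expect_false(any(s20$truth$truth == "disordered"))
  expect_true(any(s20$truth$truth == "intermediate"))

  # bad emission defaults are rejected
  expect_error(segment_model_params(disordered_mean = 60), "recoverable")
})

test_that("noiseless block profiles are recovered exactly by the classifier", {
  p <- segment_model_params(n_proteins = 20L, ordered_sd = 0, disordered_sd = 0,
                            disordered_len = c(30L, 80L), seed = 11L)
  sim <- simulate_plddt_profiles(p)
  ann <- classify_profiles(sim$profiles)
  m <- merge(ann, sim$truth, by = c("protein_id", "position"))
  expect_equal(mean(as.character(m$label) == m$truth), 1)
})

test_that("noisy default emissions still recover ground truth at high accuracy", {
  sim <- simulate_plddt_profiles(segment_model_params(seed = 101L))
  ann <- classify_profiles(sim$profiles)
  m <- merge(ann, sim$truth, by = c("protein_id", "position"))
  expect_gte(mean(as.character(m$label) == m$truth), 0.99)
})

test_that("variant placement respects region rates, classes and determinism", {
  # the default-size proteome keeps the substitution space large enough
  # that dropping duplicate draws cannot bias the region proportions
  sim <- simulate_plddt_profiles(segment_model_params(seed = 5L))
  ann <- classify_profiles(sim$profiles)

  only <- matrix(0, 3, 3, dimnames = list(c("disordered", "intermediate", "ordered"),
                                          c("clinvar_pathogenic", "clinvar_benign", "gnomad_benign")))
  only["ordered", "clinvar_pathogenic"] <- 100
  v <- simulate_variants(variant_sim_params(expected_counts = only, seed = 1L), ann)
  expect_true(all(v$region == "ordered"))
  expect_true(all(v$class_label == "clinvar_pathogenic"))
  expect_true(all(v$ref_aa != v$alt_aa))

  # observed region proportions within 3 binomial SE of the specified rates
  probs <- c(disordered = 0.2, intermediate = 0.3, ordered = 0.5)
  big <- only; big[, "clinvar_pathogenic"] <- 5000 * probs
  vp <- variant_sim_params(expected_counts = big, fixed_counts = TRUE, seed = 2L)
  vv <- simulate_variants(vp, ann)
  for (r in names(probs)) {
    obs <- mean(vv$region == r)
    se <- sqrt(probs[[r]] * (1 - probs[[r]]) / nrow(vv))
    expect_lt(abs(obs - probs[[r]]), 3 * se + 1e-3)
  }

  expect_identical(simulate_variants(vp, ann), simulate_variants(vp, ann))

  # a positive rate for a region with no residues is ignored with a warning
  ann_ord <- ann[ann$label == "ordered", ]
  bad <- only; bad["disordered", "clinvar_benign"] <- 50
  expect_warning(v2 <- simulate_variants(variant_sim_params(expected_counts = bad, seed = 3L), ann_ord),
                 "no 'disordered' residues")
  expect_true(all(v2$region == "ordered"))
})

test_that("binormal score generation matches its closed-form AUROC", {
  v <- make_variant_df(2000)
  v$class_label <- rep(c("clinvar_pathogenic", "gnomad_benign"), 1000)
  v$position <- seq_len(nrow(v))

  null <- score_sim_params("null", seed = 6L)
  s0 <- simulate_vep_scores(null, v)$scoresets[[1]]
  y <- stats::setNames(as.integer(v$class_label == "clinvar_pathogenic"), variant_key(v))
  a0 <- auroc(s0$scores[names(y)], y)
  expect_lt(abs(a0 - 0.5), 3 * 0.013)  # SE of AUROC ~ 0.013 at 1000/class

  sep <- score_sim_params("separable", seed = 7L)
  s3 <- simulate_vep_scores(sep, v)$scoresets[[1]]
  expect_gt(auroc(s3$scores[names(y)], y), 0.95)

  expect_equal(expected_auroc(0, 0), 0.5)
  expect_equal(expected_auroc(2, 0, 1, 1), pnorm(sqrt(2)))
  expect_equal(expected_auroc(0, 2, 1, 1), 1 - expected_auroc(2, 0, 1, 1))
})

test_that("missingness drives the coverage filter on a fixed draw", {
  sim <- simulate_dataset("paper-like", seed = 31L)
  flt <- filter_by_coverage(sim$scoresets,
                            sim$variants[sim$variants$region != "unassigned", ],
                            min_frac = 0.75)
  expect_false("lowcov" %in% names(flt$scoresets))        # 30% missingness -> ~0.70
  expect_true(all(c("clinA", "popB") %in% names(flt$scoresets)))
  lc <- flt$report[flt$report$vep == "lowcov", ]
  expect_lt(lc$coverage, 0.75)
})

test_that("the full simulated dataset is reproducible from one master seed", {
  a <- simulate_dataset("paper-like", seed = 12L)
  b <- simulate_dataset("paper-like", seed = 12L)
  expect_identical(a$variants, b$variants)
  expect_identical(a$annotations, b$annotations)
  expect_identical(lapply(a$scoresets, `[[`, "scores"),
                   lapply(b$scoresets, `[[`, "scores"))
  c_ <- simulate_dataset("paper-like", seed = 13L)
  expect_false(identical(a$variants, c_$variants))
})
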