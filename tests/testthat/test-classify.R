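test_that("maximal-run stretch detection follows the length and mean rules", {
  p_all_low <- plddt_profile("P1", rep(40, 100))
  seg <- find_low_confidence_stretches(p_all_low)
  expect_equal(seg$start, 1L)
  expect_equal(seg$end, 100L)
  expect_equal(seg$mean_plddt, 40)

  p_all_high <- plddt_profile("P2", rep(90, 100))
  expect_equal(nrow(find_low_confidence_stretches(p_all_high)), 0L)

  # a 20-residue dip flanked by confident structure is too short for a run
  p_dip <- plddt_profile("P3", c(rep(90, 50), rep(40, 20), rep(90, 50)))
  expect_equal(nrow(find_low_confidence_stretches(p_dip)), 0L)
})

test_that("any-window stretch detection matches the brute-force window union", {
  x <- c(rep(90, 50), rep(40, 20), rep(90, 50))
  params <- classifier_params(stretch_mode = "any_window")
  seg <- find_low_confidence_stretches(plddt_profile("P1", x), params)
  oracle <- oracle_window_union(x, 30, 70)
  expect_equal(nrow(seg), nrow(oracle))
  expect_equal(seg$start, unname(oracle[, "start"]))
  expect_equal(seg$end, unname(oracle[, "end"]))
  # the dip plus flanking residues forms one covered segment
  expect_equal(nrow(seg), 1L)
  expect_true(seg$start <= 51 && seg$end >= 70)

  # random profiles, block structure: union must always agree with the oracle
  set.seed(421)
  for (i in 1:20) {
    y <- pmin(100, pmax(0, rnorm(150, sample(c(40, 60, 90), 150, replace = TRUE), 8)))
    s <- find_low_confidence_stretches(plddt_profile("Q", y), params)
    o <- oracle_window_union(y, 30, 70)
    expect_equal(s$start, unname(o[, "start"]))
    expect_equal(s$end, unname(o[, "end"]))
  }
})

test_that("residue labels apply the pLDDT thresholds inside qualifying stretches", {
  expect_true(all(classify_residues(plddt_profile("P1", rep(90, 40)))$label == "ordered"))
  expect_true(all(classify_residues(plddt_profile("P2", rep(40, 100)))$label == "disordered"))

  # 40-residue low block: pLDDT-45 residues disordered, pLDDT-60 intermediate
  block <- rep(c(45, 45, 45, 60), 10)  # 30 x 45 interleaved with 10 x 60
  x <- c(rep(90, 50), block, rep(90, 10))
  ann <- classify_residues(plddt_profile("P3", x))
  expect_true(all(ann$label[x == 90] == "ordered"))
  expect_true(all(ann$label[x == 45] == "disordered"))
  expect_true(all(ann$label[x == 60] == "intermediate"))

  # short low-confidence segments go to the intermediate category
  x2 <- c(rep(90, 50), rep(40, 20), rep(90, 50))
  ann2 <- classify_residues(plddt_profile("P4", x2))
  expect_true(all(ann2$label[x2 == 40] == "intermediate"))
  expect_true(all(ann2$label[x2 == 90] == "ordered"))
})

test_that("label partition and threshold consistency hold on random profiles", {
  set.seed(99)
  for (mode in c("maximal_run", "any_window")) {
    params <- classifier_params(stretch_mode = mode)
    for (i in 1:15) {
      n <- sample(5:400, 1)
      x <- pmin(100, pmax(0, rnorm(n, sample(c(35, 55, 85), n, replace = TRUE), 10)))
      ann <- classify_residues(plddt_profile("R", x), params)
      expect_equal(nrow(ann), n)
      expect_false(anyNA(ann$label))
      expect_true(all(ann$plddt[ann$label == "ordered"] >= 70))
      expect_true(all(ann$plddt[ann$label != "ordered"] < 70))
      expect_true(all(ann$plddt[ann$label == "disordered"] < 50))
    }
  }
})

test_that("every maximal-run disordered residue is also disordered under any-window", {
  set.seed(2024)
  for (i in 1:15) {
    n <- sample(40:300, 1)
    x <- pmin(100, pmax(0, rnorm(n, sample(c(40, 65, 90), n, replace = TRUE), 12)))
    run <- classify_residues(plddt_profile("S", x), classifier_params())
    win <- classify_residues(plddt_profile("S", x), classifier_params(stretch_mode = "any_window"))
    expect_true(all(win$label[run$label == "disordered"] == "disordered"))
  }
})

test_that("returned segments respect minimum length and mean bound after shuffling", {
  set.seed(7)
  x <- c(rep(40, 60), rep(90, 60), rep(55, 40))
  for (i in 1:10) {
    y <- sample(x)
    for (mode in c("maximal_run", "any_window")) {
      seg <- find_low_confidence_stretches(plddt_profile("T", y),
                                           classifier_params(stretch_mode = mode))
      if (nrow(seg) > 0) {
        expect_true(all(seg$end - seg$start + 1 >= 30))
        expect_true(all(seg$mean_plddt < 70))
        expect_true(all(seg$start >= 1 & seg$end <= length(y)))
      }
      ann <- classify_residues(plddt_profile("T", y), classifier_params(stretch_mode = mode))
      expect_equal(as.integer(table(factor(ann$label, levels = c("disordered", "intermediate", "ordered")))) |> sum(),
                   length(y))
    }
  }
})

test_that("proteins shorter than the minimum stretch never contain disordered residues", {
  for (mode in c("maximal_run", "any_window")) {
    ann <- classify_residues(plddt_profile("U", rep(30, 29)),
                             classifier_params(stretch_mode = mode))
    expect_true(all(ann$label == "intermediate"))
  }
})

test_that("protein summaries use inclusive boundaries and correct fractions", {
  ann <- classify_residues(plddt_profile("P1", rep(90, 100)))
  s <- summarize_protein(ann)
  expect_equal(s$fraction_ordered, 1)
  expect_false(s$has_disordered_region)
  expect_false(s$highly_disordered)

  mk <- function(n_dis, n_tot) {
    # n_dis disordered residues out of n_tot (disordered block first)
    x <- c(rep(40, n_dis), rep(90, n_tot - n_dis))
    summarize_protein(classify_residues(plddt_profile("PX", x)))
  }
  s30 <- mk(30, 100)
  expect_equal(s30$fraction_disordered, 0.30)
  expect_true(s30$highly_disordered)   # boundary is inclusive
  expect_true(s30$has_disordered_region)
  expect_false(mk(29, 100)$highly_disordered)  # 29 < 30: run too short anyway -> 0 disordered
  expect_equal(mk(29, 100)$fraction_disordered, 0)

  expect_error(summarize_protein(ann[0, ]), "no residue annotations")
  fr <- c(s30$fraction_disordered, s30$fraction_intermediate, s30$fraction_ordered)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
})

test_that("proteome summary is residue-weighted, not protein-averaged", {
  a1 <- classify_residues(plddt_profile("A", rep(40, 100)))
  a2 <- classify_residues(plddt_profile("B", rep(90, 300)))
  sums <- rbind(summarize_protein(a1), summarize_protein(a2))
  ps <- summarize_proteome(sums)
  expect_equal(ps$fraction_disordered, 0.25)
  expect_equal(ps$prop_proteins_with_idr, 0.5)
  expect_equal(ps$prop_highly_disordered, 0.5)

  a3 <- classify_residues(plddt_profile("C", rep(90, 100)))
  one <- summarize_proteome(summarize_protein(a3))
  expect_equal(one$fraction_ordered, 1)
  expect_error(summarize_proteome(sums[0, ]), "at least one")
})
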