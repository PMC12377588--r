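test_that("AUROC equals the pairwise probability with ties at one half", {
  expect_equal(auroc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(auroc(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)
  expect_error(auroc(1:4, rep(1, 4)), "both outcome classes")
})

test_that("AUROC matches the brute-force oracle and pROC on random instances", {
  set.seed(314)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(round(rnorm(n), 1))   # rounding forces ties
    a <- auroc(s, y)
    expect_equal(a, oracle_auroc(s, y), tolerance = 1e-12)
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("ROC curves run from (0,0) to (1,1) and are monotone", {
  set.seed(5)
  s <- round(rnorm(60), 1)
  y <- rbinom(60, 1, 0.4)
  rc <- roc_curve(s, y)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  # trapezoidal area under the vertex curve equals the rank AUROC
  area <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
  expect_equal(area, auroc(s, y), tolerance = 1e-12)
})

test_that("Youden thresholds maximise J with the documented tie-breaks", {
  r <- youden_threshold(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_equal(r$threshold, 3)
  expect_equal(r$J, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  # all scores identical: J = 0 everywhere; prefer sens 1 / spec 0
  r2 <- youden_threshold(rep(2, 4), c(1, 1, 0, 0))
  expect_equal(r2$J, 0)
  expect_equal(r2$threshold, 2)
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 0)

  # two maximisers: tie-break towards higher sensitivity
  r3 <- youden_threshold(c(1, 3, 0, 2), c(1, 1, 0, 0))
  expect_equal(r3$J, 0.5)
  expect_equal(r3$threshold, 1)
  expect_equal(r3$sensitivity, 1)

  expect_error(youden_threshold(1:3, c(1, 1, 1)), "both outcome classes")
})

test_that("Youden search agrees with the exhaustive oracle on random instances", {
  set.seed(2718)
  for (i in 1:40) {
    n <- sample(4:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), 1)
    got <- youden_threshold(s, y)
    want <- oracle_youden(s, y)
    expect_equal(got$J, want$J, tolerance = 1e-12)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$sensitivity, want$sens)
    expect_equal(got$specificity, want$spec)
  }
})

test_that("AUROC and Youden operating point are invariant under monotone transforms", {
  set.seed(42)
  s <- round(rnorm(80), 2)
  y <- c(0, 1, rbinom(78, 1, 0.4))
  base_a <- auroc(s, y)
  base_t <- youden_threshold(s, y)
  for (g in list(function(x) 2 * x + 1, function(x) exp(x), function(x) x^3)) {
    expect_equal(auroc(g(s), y), base_a, tolerance = 1e-12)
    tr <- youden_threshold(g(s), y)
    expect_equal(tr$J, base_t$J, tolerance = 1e-12)
    expect_equal(tr$sensitivity, base_t$sensitivity)
    expect_equal(tr$specificity, base_t$specificity)
    expect_equal(tr$threshold, g(base_t$threshold), tolerance = 1e-9)
  }
})

test_that("confusion counts implement the >= call rule", {
  s <- c(3, 1, 2, 0); y <- c(1, 1, 0, 0)
  below <- confusion_at_threshold(s, y, -10)
  expect_equal(below$sensitivity, 1)
  expect_equal(below$specificity, 0)
  above <- confusion_at_threshold(s, y, 10)
  expect_equal(above$sensitivity, 0)
  expect_equal(above$specificity, 1)
  mid <- confusion_at_threshold(s, y, 2)
  expect_equal(mid$sensitivity, 0.5)
  expect_equal(mid$specificity, 0.5)
  expect_equal(mid$tp + mid$fn, 2)

  nopos <- confusion_at_threshold(c(1, 2), c(0, 0), 1.5)
  expect_true(is.na(nopos$sensitivity))
  expect_equal(nopos$specificity, 0.5)

  expect_equal(binarize(c(1, 2, 3), 2), c(0L, 1L, 1L))
  expect_equal(binarize(c(1, 2, 3), Inf), c(0L, 0L, 0L))
})

test_that("orientation flag plus negation leaves calls and AUROC unchanged", {
  set.seed(8)
  keys <- sprintf("P1:%d:A:V", 1:50)
  s <- rnorm(50)
  y <- stats::setNames(c(rep(1, 25), rep(0, 25)), keys)
  up <- orient_scores(vep_scoreset("up", "clinical_trained", TRUE, stats::setNames(s, keys)))
  down <- orient_scores(vep_scoreset("down", "clinical_trained", FALSE, stats::setNames(-s, keys)))
  expect_equal(up$scores, down$scores)
  expect_equal(auroc(up$scores, y), auroc(down$scores, y))
  thr <- youden_threshold(up$scores, y)
  expect_equal(binarize(up$scores, thr$threshold), binarize(down$scores, thr$threshold))

  # audit warns on sub-0.5 AUROC but never flips
  inv <- vep_scoreset("inv", "clinical_trained", TRUE,
                      stats::setNames(-(y * 2 + rnorm(50, 0, 0.1)), keys))
  expect_warning(got <- orient_scores(inv, outcomes = y, audit = TRUE), "AUROC")
  expect_equal(got$scores, inv$scores)
})

test_that("region thresholds reuse the global machinery per stratum", {
  # identical composition in every region: all four thresholds coincide
  sub_scores <- c(3, 4, 1, 2)
  sub_y <- c(1, 1, 0, 0)
  v <- do.call(rbind, lapply(c("disordered", "intermediate", "ordered"), function(r) {
    d <- make_variant_df(4, protein_id = paste0("P_", r), region = r)
    d$class_label <- ifelse(sub_y == 1, "clinvar_pathogenic", "gnomad_benign")
    d
  }))
  keys <- variant_key(v)
  ss <- orient_scores(vep_scoreset("v1", "clinical_trained", TRUE,
                                   stats::setNames(rep(sub_scores, 3), keys)))
  ds <- suppressMessages(intersect_complete(v, list(v1 = ss)))
  thr <- region_thresholds(ds, "v1")
  expect_equal(nrow(thr), 4L)
  expect_true(all(thr$threshold == 3))
  expect_true(all(thr$J == 1))

  # a region with a single class is skipped with a warning
  v2 <- v
  v2$class_label[v2$region == "disordered"] <- "gnomad_benign"
  ds2 <- suppressWarnings(suppressMessages(intersect_complete(v2, list(v1 = ss))))
  expect_warning(thr2 <- region_thresholds(ds2, "v1"), "disordered")
  expect_false("disordered" %in% thr2$scope)
})
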