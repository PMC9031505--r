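test_that("confusion counts match a per-pixel loop on random masks", {
  p <- random_mask(c(3L, 10L, 10L), p = 0.4, seed = 1)
  y <- random_mask(c(3L, 10L, 10L), p = 0.3, seed = 2)
  cc <- confusion(p, y)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(p$voxels)) {
    if (p$voxels[i] == 1 && y$voxels[i] == 1) tp <- tp + 1L
    else if (p$voxels[i] == 1) fp <- fp + 1L
    else if (y$voxels[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  expect_equal(c(cc$tp, cc$fp, cc$fn, cc$tn), c(tp, fp, fn, tn))
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, length(p$voxels))

  perfect <- confusion(y, y)
  expect_equal(c(perfect$fp, perfect$fn), c(0, 0))
  comp <- lesion_mask(1L - y$voxels)
  anti <- confusion(comp, y)
  expect_equal(c(anti$tp, anti$tn), c(0, 0))
  expect_error(confusion(random_mask(c(2L, 10L, 10L)), y), "differ")
})

test_that("rate metrics follow their printed formulas on a worked example", {
  cc <- confusion_counts(tp = 3, fp = 1, fn = 1, tn = 10)
  expect_equal(sensitivity(cc), 0.75)
  expect_equal(specificity_as_printed(cc), 0.75)
  expect_equal(f1(cc), 0.75)
  expect_equal(jaccard(cc), 0.6)
  expect_equal(true_specificity(cc), 10 / 11)

  perfect <- confusion_counts(tp = 5, fp = 0, fn = 0, tn = 5)
  expect_equal(c(sensitivity(perfect), specificity_as_printed(perfect),
                 f1(perfect), jaccard(perfect)), rep(1, 4))
})

test_that("jaccard and F1 satisfy their algebraic identity on random counts", {
  set.seed(10)
  for (i in 1:200) {
    cc <- confusion_counts(tp = sample(0:50, 1), fp = sample(0:50, 1),
                           fn = sample(0:50, 1), tn = sample(0:50, 1))
    f <- f1(cc); j <- jaccard(cc)
    for (v in c(f, j, sensitivity(cc), specificity_as_printed(cc),
                volume_similarity(cc))) {
      expect_gte(v, 0); expect_lte(v, 1)
    }
    if (f > 0) expect_equal(j, f / (2 - f))
    if (cc$tp > 0) expect_gte(f, j)
  }
})

test_that("volume similarity equals its set-cardinality form", {
  set.seed(11)
  for (i in 1:200) {
    cc <- confusion_counts(tp = sample(0:40, 1), fp = sample(0:40, 1),
                           fn = sample(0:40, 1))
    meas <- cc$tp + cc$fp; gt <- cc$tp + cc$fn
    if (meas + gt > 0)
      expect_equal(volume_similarity(cc), 1 - abs(meas - gt) / (meas + gt))
  }
  expect_equal(volume_similarity(confusion_counts(3, 2, 2)), 1)
  expect_equal(volume_similarity(confusion_counts(0, 0, 5)), 0)
  expect_equal(volume_similarity(confusion_counts(5, 3, 1)), 1 - 2 / 14)
  expect_equal(volume_similarity(confusion_counts(0, 0, 0)), 1)
  # VS ignores localization: equal counts with zero overlap still give 1
  expect_equal(volume_similarity(confusion_counts(tp = 0, fp = 7, fn = 7)), 1)
})

test_that("MAE averages absolute volume errors", {
  expect_equal(mean_absolute_error(c(3.0, 1.0), c(2.5, 1.5)), 0.5)
  expect_equal(mean_absolute_error(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(12)
  a <- runif(20, 0, 50); b <- runif(20, 0, 50)
  expect_equal(mean_absolute_error(a, b), sum(abs(a - b)) / 20)
  expect_error(mean_absolute_error(numeric(0), numeric(0)), "empty")
})

test_that("cohort evaluation macro-averages per patient and handles controls", {
  st1 <- random_study(c(2L, 16L, 16L), pixel_spacing_mm = c(1, 1),
                      slice_thickness_mm = 1, id = "p1")
  st2 <- random_study(c(2L, 16L, 16L), pixel_spacing_mm = c(1, 1),
                      slice_thickness_mm = 1, id = "p2")
  y1 <- array(0L, c(2, 16, 16)); y1[1, 1:4, 1:4] <- 1L
  p1 <- y1                                   # perfect
  y2 <- array(0L, c(2, 16, 16)); y2[2, 1:4, 1:4] <- 1L
  p2 <- array(0L, c(2, 16, 16)); p2[2, 1:4, 1:2] <- 1L  # half found
  rep <- evaluate_cohort(list(lesion_mask(p1), lesion_mask(p2)),
                         list(lesion_mask(y1), lesion_mask(y2)),
                         list(st1, st2))
  # hand-computed macro averages: patient 1 all 1, patient 2 sens 0.5,
  # precision 1, f1 2/3, jaccard 0.5, vs 1 - 8/24
  expect_equal(rep$summary$sensitivity_pct, 100 * (1 + 0.5) / 2)
  expect_equal(rep$summary$specificity_pct, 100)
  expect_equal(rep$summary$f1_pct, 100 * (1 + 2 / 3) / 2)
  expect_equal(rep$summary$jaccard_pct, 100 * (1 + 0.5) / 2)
  expect_equal(rep$summary$vs_pct, 100 * (1 + (1 - 8 / 24)) / 2)
  expect_equal(rep$summary$mae_cc, (0 + 8 / 1000) / 2)

  # control-only cohort with empty predictions: rates degenerate, MAE 0
  ctrl <- evaluate_cohort(list(lesion_mask(array(0L, c(2, 16, 16)))),
                          list(lesion_mask(array(0L, c(2, 16, 16)))),
                          list(st1))
  expect_equal(ctrl$summary$mae_cc, 0)
  expect_true(ctrl$per_patient$degenerate[1])
  expect_error(evaluate_cohort(list(), list(), list()), "empty")
})
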