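test_that("confusion counts match hand-worked and brute-force cases", {
  pred <- array(0L, c(1, 2, 4)); pred[1, 1, 1:3] <- 1L
  expect_identical(confusion_counts(pred, pred),
                   c(TP = 3L, FP = 0L, FN = 0L, TN = 5L))
  allp <- array(1L, c(1, 2, 4)); allt <- array(0L, c(1, 2, 4))
  expect_identical(confusion_counts(allp, allt),
                   c(TP = 0L, FP = 8L, FN = 0L, TN = 0L))
  set.seed(42)
  for (i in 1:25) {
    mp <- random_mask_pair(c(2, 8, 8))
    expect_identical(confusion_counts(mp$pred, mp$truth),
                     oracle_confusion(mp$pred, mp$truth))
  }
  expect_error(confusion_counts(array(0, c(1, 2, 2)), array(0, c(1, 2, 3))),
               "different grids")
})

test_that("overlap metrics follow their closed forms and conventions", {
  m <- overlap_metrics(c(TP = 1, FP = 1, FN = 1, TN = 5))
  expect_equal(m$dice, 0.5)
  expect_equal(m$jaccard, 1 / 3)
  same <- array(1L, c(1, 3, 3))
  r <- overlap_metrics(confusion_counts(same, same))
  expect_equal(r$dice, 1); expect_equal(r$sensitivity, 1)
  expect_true(!is.finite(r$specificity) && !r$defined[["specificity"]])
  a <- array(0L, c(1, 2, 4)); a[1, 1, 1] <- 1L
  b <- array(0L, c(1, 2, 4)); b[1, 2, 4] <- 1L
  d <- overlap_metrics(confusion_counts(a, b))
  expect_equal(d$dice, 0); expect_equal(d$jaccard, 0)
  e <- overlap_metrics(c(TP = 0, FP = 0, FN = 0, TN = 8))
  expect_equal(e$dice, 1)            # both-empty convention
  expect_false(e$defined[["dice"]])
})

test_that("volume similarity is volume-only and matches both formulas", {
  # equal volumes, zero overlap
  expect_equal(as.numeric(volume_similarity(c(TP = 0, FP = 5, FN = 5, TN = 90))), 1)
  expect_equal(as.numeric(volume_similarity(c(TP = 1, FP = 1, FN = 1, TN = 5))), 1)
  expect_equal(as.numeric(volume_similarity(c(TP = 0, FP = 0, FN = 10, TN = 90))), 0)
  vs0 <- volume_similarity(c(TP = 0, FP = 0, FN = 0, TN = 8))
  expect_true(is.nan(as.numeric(vs0)) && !attr(vs0, "defined"))
  set.seed(11)
  for (i in 1:50) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    if (2 * tp + fp + fn == 0) next
    v1 <- tp + fp; v2 <- tp + fn
    expect_equal(as.numeric(volume_similarity(c(TP = tp, FP = fp, FN = fn, TN = 3))),
                 1 - abs(v1 - v2) / (v1 + v2), tolerance = 1e-12)
  }
})

test_that("Hausdorff distance matches hand geometry and is symmetric", {
  a <- array(0L, c(2, 5, 6)); a[1, 1, 1] <- 1L
  b <- array(0L, c(2, 5, 6)); b[1, 4, 5] <- 1L
  expect_equal(as.numeric(hausdorff_distance(a, b)), 5)   # 3-4-5 triangle
  expect_equal(as.numeric(hausdorff_distance(a, a)), 0)
  set.seed(9)
  for (i in 1:20) {
    mp <- random_mask_pair(c(3, 7, 7), p = 0.4)
    if (sum(mp$pred) == 0 || sum(mp$truth) == 0) next
    expect_equal(as.numeric(hausdorff_distance(mp$pred, mp$truth)),
                 as.numeric(hausdorff_distance(mp$truth, mp$pred)))
  }
  # mm mode scales by spacing: neighbours along z, 2 mm slices
  c1 <- array(0L, c(3, 4, 4)); c1[1, 2, 2] <- 1L
  c2 <- array(0L, c(3, 4, 4)); c2[2, 2, 2] <- 1L
  expect_equal(as.numeric(hausdorff_distance(c1, c2, units = "mm",
                                             spacing = c(0.8, 0.8, 2))), 2)
  h <- hausdorff_distance(array(0L, c(1, 2, 2)), array(1L, c(1, 2, 2)))
  expect_true(is.nan(as.numeric(h)) && !attr(h, "defined"))
})

test_that("jaccard = dice / (2 - dice) on random masks", {
  set.seed(5)
  for (i in 1:100) {
    mp <- random_mask_pair(c(2, 10, 10))
    om <- overlap_metrics(confusion_counts(mp$pred, mp$truth))
    expect_equal(om$jaccard, om$dice / (2 - om$dice), tolerance = 1e-12)
  }
})

test_that("metrics are invariant under a common slice permutation", {
  set.seed(31)
  mp <- random_mask_pair(c(6, 10, 10))
  perm <- sample(6)
  # voxelwise metrics do not care about slice order at all
  r1 <- metrics_report(mp$pred, mp$truth)
  r2 <- metrics_report(mp$pred[perm, , ], mp$truth[perm, , ])
  for (m in c("dice", "jaccard", "sensitivity", "specificity",
              "volume_similarity"))
    expect_equal(r1[[m]], r2[[m]], tolerance = 1e-12)
  # per-slice tables are equivariant: the same rows, re-indexed
  s1 <- slice_metrics(mp$pred, mp$truth, keep_empty = TRUE)
  s2 <- slice_metrics(mp$pred[perm, , ], mp$truth[perm, , ],
                      keep_empty = TRUE)
  reordered <- s2[order(perm), ]
  rownames(reordered) <- NULL
  expect_equal(reordered$dice, s1$dice, tolerance = 1e-12)
  expect_equal(reordered$hausdorff, s1$hausdorff, tolerance = 1e-12)
})

test_that("paired comparison reproduces the t-test arithmetic and flags degeneracy", {
  base <- data.frame(slice = 1:4, dice = c(0.5, 0.6, 0.7, 0.8),
                     jaccard = 0.5, sensitivity = 0.5, specificity = 0.5,
                     volume_similarity = 0.5, hausdorff = 1)
  other <- base
  other$dice <- base$dice + c(1, 2, 3, 4)    # d = 1,2,3,4
  cmp <- compare_methods(base, other, metrics = "dice")
  expect_equal(cmp$t, 2.5 / (stats::sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-6)
  expect_equal(cmp$t, 3.873, tolerance = 1e-3)
  expect_equal(cmp$p, 0.0305, tolerance = 2e-3)
  # identical methods: degenerate, p reported as 1
  same <- compare_methods(base, base, metrics = "dice")
  expect_true(same$degenerate); expect_equal(same$p, 1)
  # constant nonzero differences: degenerate, p undefined
  shifted <- base; shifted$dice <- base$dice + 0.1
  degen <- compare_methods(base, shifted, metrics = "dice")
  expect_true(degen$degenerate); expect_true(is.na(degen$p))
  expect_error(compare_methods(base[1, ], base[1, ]), "at least 2")
})
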