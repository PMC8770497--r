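test_that("the worked confusion table yields the hand-computed six metrics", {
  p <- matrix(c(90, 3, 5, 2), 2, 2)  # truth rows: [[90, 5], [3, 2]]
  r <- compute_metrics(p)
  expect_equal(r$PA, 0.92, tolerance = 1e-12)
  expect_equal(r$MPA, (90 / 95 + 2 / 5) / 2, tolerance = 1e-12)
  expect_equal(r$Pre, 2 / 7, tolerance = 1e-12)
  expect_equal(r$Re, 0.4, tolerance = 1e-12)
  expect_equal(r$F1, 1 / 3, tolerance = 1e-12)
  expect_equal(r$MIoU, (90 / 98 + 2 / 10) / 2, tolerance = 1e-12)
})

test_that("all six metrics agree with the brute-force loop implementation", {
  set.seed(23)
  for (rep in 1:300) {
    p <- matrix(sample(0:40, 4, replace = TRUE), 2, 2)
    if (sum(p) == 0) p[1, 1] <- 1
    got <- compute_metrics(p)
    want <- oracle_metrics(p)
    for (k in names(want)) {
      expect_lt(abs(got[[k]] - want[[k]]), 1e-12)
    }
  }
})

test_that("confusion counting equals a pixel-by-pixel tally", {
  set.seed(29)
  for (rep in 1:20) {
    h <- sample(1:6, 1); w <- sample(1:6, 1)
    pred <- matrix(stats::rbinom(h * w, 1, 0.5), h, w)
    truth <- matrix(stats::rbinom(h * w, 1, 0.5), h, w)
    tab <- confusion_table(mask_image(pred), mask_image(truth))
    brute <- matrix(0L, 2, 2)
    for (i in 1:h) for (j in 1:w) {
      brute[truth[i, j] + 1, pred[i, j] + 1] <-
        brute[truth[i, j] + 1, pred[i, j] + 1] + 1L
    }
    expect_equal(unclass(tab), brute, ignore_attr = TRUE)
  }
  # perfect agreement leaves the off-diagonal empty
  m <- mask_image(matrix(stats::rbinom(25, 1, 0.3), 5, 5))
  tab <- confusion_table(m, m)
  expect_equal(tab[1, 2] + tab[2, 1], 0)
  # all-background prediction against 5 positives in 100 pixels
  truth <- matrix(0, 10, 10); truth[1, 1:5] <- 1
  tab <- confusion_table(matrix(0, 10, 10), truth)
  expect_equal(as.vector(unclass(tab)), c(95, 5, 0, 0))
})

test_that("degenerate frames follow the stated conventions", {
  # perfect prediction with both classes present: everything is 1
  r <- compute_metrics(matrix(c(90, 0, 0, 10), 2, 2))
  expect_true(all(unlist(r) == 1))
  # all-background truth and prediction: PA 1, no-positives convention
  r0 <- compute_metrics(matrix(c(100, 0, 0, 0), 2, 2))
  expect_equal(r0$PA, 1)
  expect_equal(r0$Pre, 1)   # no positives anywhere
  expect_equal(r0$Re, 1)
  expect_equal(r0$MIoU, 1)  # absent class contributes IoU 1
  # false positives on an all-background frame: precision collapses to 0
  rfp <- compute_metrics(matrix(c(95, 0, 5, 0), 2, 2))
  expect_equal(rfp$Pre, 0)
  expect_equal(rfp$F1, 0)
})

test_that("metrics are permutation-invariant but not relabel-invariant", {
  set.seed(37)
  pred <- matrix(stats::rbinom(64, 1, 0.4), 8, 8)
  truth <- matrix(stats::rbinom(64, 1, 0.2), 8, 8)
  perm <- sample(64)
  r1 <- compute_metrics(confusion_table(pred, truth))
  r2 <- compute_metrics(confusion_table(matrix(pred[perm], 8, 8),
                                        matrix(truth[perm], 8, 8)))
  expect_equal(r1, r2)
  # swapping class labels preserves PA but changes precision
  r3 <- compute_metrics(confusion_table(1 - pred, 1 - truth))
  expect_equal(r3$PA, r1$PA)
  expect_false(isTRUE(all.equal(r3$Pre, r1$Pre)))
})

test_that("converting a false positive to a true negative never hurts", {
  set.seed(43)
  for (rep in 1:50) {
    p <- matrix(sample(0:30, 4, replace = TRUE), 2, 2)
    p[1, 2] <- p[1, 2] + 1   # ensure an FP exists
    q <- p; q[1, 2] <- q[1, 2] - 1; q[1, 1] <- q[1, 1] + 1
    a <- compute_metrics(p); b <- compute_metrics(q)
    expect_gte(b$PA, a$PA)
    expect_gte(b$Pre, a$Pre)
    expect_gte(b$MIoU, a$MIoU)
  }
})

test_that("aggregation reports mean and sample standard deviation", {
  r1 <- compute_metrics(matrix(c(90, 5, 5, 0), 2, 2))
  # single report: mean is the report, sd is 0
  s1 <- aggregate_metrics(list(r1))
  expect_equal(unname(s1$mean["PA"]), r1$PA)
  expect_true(all(s1$sd == 0))
  # two reports with PA 0.9 and 1.0: mean 0.95, sd = sqrt(0.005)
  ra <- compute_metrics(matrix(c(90, 10, 0, 0), 2, 2))
  rb <- compute_metrics(matrix(c(100, 0, 0, 0), 2, 2))
  s2 <- aggregate_metrics(list(ra, rb))
  expect_equal(unname(s2$mean["PA"]), 0.95, tolerance = 1e-12)
  expect_equal(unname(s2$sd["PA"]), sqrt(0.005), tolerance = 1e-9)
  # identical reports have sd exactly 0
  s3 <- aggregate_metrics(list(r1, r1, r1, r1))
  expect_true(all(s3$sd == 0))
  expect_error(aggregate_metrics(list()), "empty")
})
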