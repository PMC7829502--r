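blobs <- function(n_per = 10L, gap = 6, p = 8L, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p), n_per))
  x[seq_len(n_per), 1:3] <- x[seq_len(n_per), 1:3] + gap
  list(x = x, y = rep(c("MHE", "noHE"), each = n_per))
}

test_that("F-score matches the two-class definition exactly", {
  # positives {1,2}, negatives {3,4}: numerator 2, denominator 1
  expect_equal(unname(f_score(matrix(c(1, 2, 3, 4), 4), c(TRUE, TRUE, FALSE, FALSE))), 2)
  # equal class means give 0
  expect_equal(unname(f_score(matrix(c(1, 3, 2, 2), 4), c(TRUE, TRUE, FALSE, FALSE))), 0)
  # doubling the mean gap at fixed variances quadruples the F-score
  f1 <- f_score(matrix(c(0, 1, 2, 3), 4), c(TRUE, TRUE, FALSE, FALSE))
  f2 <- f_score(matrix(c(0, 1, 4, 5), 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(f2 / f1), 4)
  # zero within-class variance with unequal means: infinite, with warning
  expect_warning(fi <- f_score(matrix(c(1, 1, 2, 2), 4),
                               c(TRUE, TRUE, FALSE, FALSE)), "infinite")
  expect_true(is.infinite(fi))
})

test_that("LOOCV separates well-separated blobs and runs n folds", {
  b <- blobs()
  cv <- loocv_classify(b$x, b$y, k = 3)
  expect_equal(cv$accuracy, 100)
  expect_equal(cv$sensitivity, 100)
  expect_equal(cv$specificity, 100)
  expect_equal(cv$auc, 1)
  expect_length(cv$predictions, 20L)
  expect_equal(nrow(cv$selected), 20L)
  # the informative features are the consensus
  expect_setequal(cv$consensus_features, 1:3)
  expect_error(loocv_classify(b$x, b$y, k = 99), "k must be")
})

test_that("feature selection never sees the held-out subject", {
  b <- blobs(n_per = 8L, gap = 1.5, seed = 3)
  cv1 <- loocv_classify(b$x, b$y, k = 4)
  x2 <- b$x
  x2[5, ] <- x2[5, ] + 100   # corrupt only the held-out subject
  cv2 <- loocv_classify(x2, b$y, k = 4)
  expect_equal(cv2$selected[5, ], cv1$selected[5, ])
})

test_that("confusion-derived rates are internally consistent", {
  b <- blobs(n_per = 10L, gap = 1.2, seed = 7)
  cv <- loocv_classify(b$x, b$y, k = 4)
  cm <- cv$confusion
  expect_equal(cv$accuracy, 100 * (cm["tp"] + cm["tn"]) / 20,
               ignore_attr = TRUE)
  expect_equal(cv$sensitivity, 100 * cm["tp"] / (cm["tp"] + cm["fn"]),
               ignore_attr = TRUE)
  expect_equal(cv$specificity, 100 * cm["tn"] / (cm["tn"] + cm["fp"]),
               ignore_attr = TRUE)
})

test_that("trapezoid AUC equals pair counting, including ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3),
                       c(TRUE, FALSE, TRUE, FALSE))$auc, 0.75)
  expect_equal(roc_auc(4:1, c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  set.seed(14)
  for (rep in 1:100) {
    n <- sample(6:20, 1)
    pos <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    s <- sample(round(runif(n), 2))   # rounded: tied scores occur
    expect_equal(roc_auc(s, pos)$auc, oracle_auc(s, pos))
  }
  # spot check against an established ROC implementation
  set.seed(15)
  s <- rnorm(30); pos <- runif(30) > 0.4
  expect_equal(roc_auc(s, pos)$auc,
               as.numeric(pROC::auc(pROC::roc(pos, s, quiet = TRUE,
                                              direction = "<"))))
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("permutation p uses the add-one estimator and is reproducible", {
  b <- blobs(n_per = 6L, gap = 5, p = 4L, seed = 5)
  pt1 <- permutation_test(b$x, b$y, k = 2, n_perm = 19, seed = 11)
  pt2 <- permutation_test(b$x, b$y, k = 2, n_perm = 19, seed = 11)
  expect_identical(pt1$p, pt2$p)
  expect_identical(pt1$null, pt2$null)
  # perfectly separable observed accuracy beats nearly all shuffles
  expect_equal(pt1$observed, 100)
  expect_lte(pt1$p, 3 / 20)
  expect_gte(pt1$p, 1 / 20)
})

test_that("k selection scans the grid with per-fold selection intact", {
  b <- blobs(n_per = 8L, gap = 4, seed = 9)
  ks <- select_k(b$x, b$y, k_grid = c(2L, 3L, 6L))
  expect_length(ks$accuracy, 3L)
  expect_true(ks$k %in% c(2L, 3L, 6L))
  expect_equal(max(ks$accuracy), 100)
})
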