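mk_hc <- function(n = 20L, seed = 1L) {
  set.seed(seed)
  age <- runif(n, 40, 60)
  edu <- runif(n, 8, 16)
  data.frame(age = age, education = edu,
             nct_a = 20 + 0.4 * age - 0.3 * edu + rnorm(n, 0, 3),
             dst = 70 - 0.4 * age + 0.8 * edu + rnorm(n, 0, 4))
}

test_that("the 2-SD residual rule labels patients one-sidedly per test", {
  model <- fit_label_model(mk_hc())
  pt <- data.frame(age = 50, education = 12)
  pred_dst <- predict(model$dst, pt)
  pred_nct <- predict(model$nct_a, pt)
  # exactly at prediction: noHE
  pt1 <- cbind(pt, nct_a = pred_nct, dst = pred_dst)
  expect_equal(apply_labels(model, pt1)$label, "noHE")
  # DST 3 residual SDs below prediction: MHE
  pt2 <- cbind(pt, nct_a = pred_nct, dst = pred_dst - 3 * model$sd_dst)
  lab2 <- apply_labels(model, pt2)
  expect_equal(lab2$label, "MHE")
  expect_equal(lab2$dev_dst_sd, 3)
  # NCT-A alone beyond threshold suffices ("either" rule)
  pt3 <- cbind(pt, nct_a = pred_nct + 2.5 * model$sd_nct_a, dst = pred_dst)
  expect_equal(apply_labels(model, pt3)$label, "MHE")
  # deviations in the unimpaired direction never label MHE
  pt4 <- cbind(pt, nct_a = pred_nct - 4 * model$sd_nct_a,
               dst = pred_dst + 4 * model$sd_dst)
  expect_equal(apply_labels(model, pt4)$label, "noHE")
})

test_that("label model requires HC data and a full-rank design", {
  expect_error(fit_label_model(mk_hc(2)), "at least 3")
  hc <- mk_hc(10)
  hc$education <- hc$age * 2   # collinear
  expect_error(fit_label_model(hc), "rank-deficient")
})

test_that("Kruskal-Wallis H matches the hand rank-sum formula", {
  g <- rep(c("a", "b", "c"), each = 3)
  # identical multisets across groups: H = 0
  res0 <- compare_groups(matrix(rep(1:3, 3), ncol = 1), g)
  expect_equal(res0$H, 0)
  expect_equal(res0$p, 1)
  # separated groups {1,2,3},{4,5,6},{7,8,9}:
  # H = 12/(9*10) * (6^2 + 15^2 + 24^2)/3 - 3*10 = 7.2
  res <- compare_groups(matrix(1:9, ncol = 1), g)
  expect_equal(res$H, 7.2)
  # omnibus below alpha gates post hoc Mann-Whitney columns
  expect_true(res$p < 0.05)
  expect_false(is.na(res$p_a_vs_b))
  expect_true(is.na(res0$p_a_vs_b))
})

test_that("BH adjustment matches the step-up definition and is monotone", {
  set.seed(10)
  vals <- matrix(rnorm(12 * 6), 12)
  vals[, 1] <- vals[, 1] + rep(c(0, 0, 3), each = 4)   # one real effect
  g <- rep(c("a", "b", "c"), each = 4)
  res <- compare_groups(vals, g)
  expect_equal(res$p_fdr, oracle_bh(res$p))
  ord <- order(res$p)
  expect_true(all(diff(res$p_fdr[ord]) > -1e-12))
  expect_true(all(res$p_fdr >= res$p - 1e-12))
})

test_that("partial correlation equals the two-stage OLS oracle", {
  # no covariates: plain Pearson
  set.seed(12)
  x <- rnorm(15); y <- x + rnorm(15, 0, 0.5)
  pc <- partial_corr(x, y)
  expect_equal(pc$r, cor(x, y))
  ct <- cor.test(x, y)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-12)
  # score identical to metric, independent covariates: r = 1
  z <- rnorm(15)
  expect_equal(partial_corr(x, x, data.frame(z = z))$r, 1)
  # 6-subject fixture against an explicit normal-equations oracle
  xf <- c(3.1, 4.0, 2.2, 5.5, 4.8, 3.9)
  yf <- c(10.2, 12.5, 9.1, 15.0, 13.2, 12.0)
  cv <- data.frame(age = c(41, 52, 47, 60, 55, 49))
  mm <- cbind(1, cv$age)
  rx <- xf - mm %*% solve(crossprod(mm), crossprod(mm, xf))
  ry <- yf - mm %*% solve(crossprod(mm), crossprod(mm, yf))
  r_oracle <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  pc2 <- partial_corr(xf, yf, cv)
  expect_equal(pc2$r, r_oracle, tolerance = 1e-12)
  expect_equal(pc2$df, 6 - 1 - 2)
  t_oracle <- r_oracle * sqrt(pc2$df / (1 - r_oracle^2))
  expect_equal(pc2$p, 2 * pt(-abs(t_oracle), pc2$df), tolerance = 1e-12)
})

test_that("degenerate inputs take the documented paths", {
  g <- rep(c("a", "b", "c"), each = 3)
  res <- compare_groups(matrix(5, 9, 1), g)
  expect_equal(res$H, 0)
  expect_equal(res$p, 1)
  expect_true(is.na(partial_corr(rep(1, 10), rnorm(10))$r))
  expect_error(partial_corr(1:3, 1:3, data.frame(a = rnorm(3))), "need n")
})
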