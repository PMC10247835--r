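# Logistic screen/fit, ROC cutoff, and prediction-mode comparison.

test_that("univariable screen selects at the 0.15 threshold and reports Wald ORs", {
  set.seed(31)
  n <- 400
  df <- data.frame(x_strong = rnorm(n), x_noise = rnorm(n),
                   d_catheter_wire = abs(rnorm(n, 0, 0.2)))
  eta <- -1 + 0.8 * df$x_strong + log(1.5) * df$d_catheter_wire / 0.1
  df$y <- runif(n) < plogis(eta)
  sc <- univariable_screen(df, "y", c("x_strong", "x_noise", "d_catheter_wire"))
  expect_equal(sc$selected, sc$p_value < 0.15 & !sc$flagged)
  expect_true(sc$selected[sc$variable == "x_strong"])
  # cross-check one row against a direct glm fit
  fit <- glm(y ~ x_strong, binomial(), data = df)
  expect_equal(sc$odds_ratio[1], exp(unname(coef(fit)[2])), tolerance = 1e-9)
  se <- sqrt(diag(vcov(fit)))[2]
  expect_equal(sc$ci_low[1], exp(unname(coef(fit)[2] - qnorm(0.975) * se)),
               tolerance = 1e-9)
  # distance variables are reported per 0.1 mm
  expect_match(sc$scale_note[sc$variable == "d_catheter_wire"], "0.1 mm")
  expect_true(all(sc$ci_low <= sc$odds_ratio & sc$odds_ratio <= sc$ci_high))
})

test_that("complete separation is flagged and never selected", {
  df <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                   y = c(rep(FALSE, 20), rep(TRUE, 20)))
  expect_warning(sc <- univariable_screen(df, "y", "x"), "separation")
  expect_true(sc$flagged)
  expect_false(sc$selected)
  expect_error(univariable_screen(data.frame(x = 1:5, y = rep(TRUE, 5)),
                                  "y", "x"), "both classes")
})

test_that("multivariable fit recovers a known odds ratio and handles no-ops", {
  set.seed(32)
  n <- 600
  d <- ifelse(runif(n) < 0.75, 0, sample(seq(0.05, 0.6, by = 0.05), n, TRUE))
  z <- rnorm(n)
  eta <- qlogis(0.2) + log(1.7) * d / 0.1 + 0.3 * z
  df <- data.frame(d_catheter_wire = d, z = z, y = runif(n) < plogis(eta))
  out <- multivariable_logistic(df, "y", c("d_catheter_wire", "z"))
  expect_equal(out$status, "ok")
  row <- out$results[out$results$variable == "d_catheter_wire", ]
  expect_true(row$ci_low <= 1.7 && 1.7 <= row$ci_high)
  # empty selection is an explicit no-op
  expect_equal(multivariable_logistic(df, "y", character())$status,
               "empty_selection")
  # a duplicated predictor is singular
  df$d2 <- df$d_catheter_wire
  expect_error(multivariable_logistic(df, "y", c("d_catheter_wire", "d2")),
               "singular")
})

test_that("null predictors give OR near 1 with nominal CI coverage", {
  set.seed(33)
  cover <- 0
  reps <- 60
  for (i in seq_len(reps)) {
    df <- data.frame(x = rnorm(150), y = runif(150) < 0.4)
    r <- multivariable_logistic(df, "y", "x")$results
    if (r$ci_low <= 1 && 1 <= r$ci_high) cover <- cover + 1
  }
  expect_gt(cover / reps, 0.85)   # nominal 95%, binomial slack at 60 reps
})

test_that("cluster-robust variance widens CIs under within-lesion correlation", {
  set.seed(38)
  n_lesion <- 40; per <- 10
  lesion <- rep(seq_len(n_lesion), each = per)
  u <- rnorm(n_lesion)[lesion]          # shared lesion effect
  x <- rnorm(n_lesion)[lesion]          # lesion-constant predictor
  y <- runif(length(x)) < plogis(-0.5 + 0.5 * x + u)
  df <- data.frame(x = x, y = y)
  plain <- multivariable_logistic(df, "y", "x")$results
  robust <- multivariable_logistic(df, "y", "x", cluster = lesion)$results
  # with a lesion-constant predictor and lesion-level noise the model-based
  # CI is anti-conservative; the sandwich CI must be wider
  expect_gt(robust$ci_high / robust$ci_low, plain$ci_high / plain$ci_low)
})

test_that("ROC handles separable, null, and tied-score inputs", {
  # perfectly separating scores
  r1 <- roc_optimal_cutoff(c(1, 2, 3, 11, 12, 13), c(F, F, F, T, T, T))
  expect_equal(r1$auc, 1.0)
  expect_equal(r1$sensitivity, 100)
  expect_equal(r1$specificity, 100)
  expect_true(r1$cutoff >= 3 && r1$cutoff < 11)
  # label-independent scores hover at chance
  set.seed(34)
  r2 <- roc_optimal_cutoff(rnorm(2000), runif(2000) < 0.5)
  expect_lt(abs(r2$auc - 0.5), 0.05)
  expect_gt(r2$p_value, 0.05)
  # spec of point-mass scores: cutoff sits between the masses
  r3 <- roc_optimal_cutoff(c(0, 0, 0, 1, 1), c(F, F, F, T, T))
  expect_equal(r3$auc, 1.0)
  expect_true(r3$cutoff >= 0 && r3$cutoff < 1)
  expect_error(roc_optimal_cutoff(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC equals the exhaustive pair-counting statistic, and pROC agrees", {
  set.seed(35)
  for (i in 1:10) {
    sc <- round(rnorm(20), 1)           # ties likely
    lb <- runif(20) < 0.5
    if (length(unique(lb)) < 2) lb[1] <- !lb[1]
    r <- roc_optimal_cutoff(sc, lb)
    pos <- sc[lb]; neg <- sc[!lb]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(r$auc, mean(pairs), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(36)
  sc <- c(rnorm(50), rnorm(50, 0.8)); lb <- rep(c(FALSE, TRUE), each = 50)
  r <- roc_optimal_cutoff(sc, lb)
  pr <- pROC::roc(lb, sc, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-9)
  yj <- pROC::coords(pr, "best", best.method = "youden",
                     ret = c("sensitivity", "specificity"))
  expect_equal(r$sensitivity / 100, yj$sensitivity[1], tolerance = 1e-9)
  expect_equal(r$specificity / 100, yj$specificity[1], tolerance = 1e-9)
})

test_that("mode comparison reports medians and Mann-Whitney p per stratum", {
  set.seed(37)
  n <- 100
  base <- runif(n, 20, 80)
  mk <- function(vals, mode, contact) {
    data.frame(mode = mode, contact = contact, pct_correct_area = vals,
               pct_error_area = 100 - vals, pct_correct_angle = vals,
               pct_error_angle = 100 - vals)
  }
  # identical metric vectors: no difference, p = 1
  ft <- rbind(mk(base, "catheter", TRUE), mk(base, "wire", TRUE))
  cmp <- compare_prediction_modes(ft)
  con <- cmp[cmp$stratum == "contact", ]
  expect_true(all(con$p_value == 1))
  expect_true(all(cmp[cmp$stratum == "non_contact", "status"] == "skipped"))
  # constant positive shift in wire mode is detected
  ft2 <- rbind(mk(base, "catheter", TRUE), mk(base + 15, "wire", TRUE))
  cmp2 <- compare_prediction_modes(ft2)
  row <- cmp2[cmp2$stratum == "contact" & cmp2$metric == "pct_correct_area", ]
  expect_gt(row$median_wire, row$median_catheter)
  expect_lt(row$p_value, 0.05)
  # cross-check against wilcox.test directly
  expect_equal(row$p_value,
               wilcox.test(base, base + 15, exact = FALSE)$p.value,
               tolerance = 1e-12)
})
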