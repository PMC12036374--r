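test_that("min-max scaling maps fit rows to [0,1] and handles degenerates", {
  tb <- tibble::tibble(a = c(2, 4, 6), b = c(5, 5, 5))
  out <- minmax_normalize(tb)
  expect_equal(out$table$a, c(0, 0.5, 1))
  expect_equal(out$table$b, c(0, 0, 0))

  # fitted on train rows only; out-of-range transform values are not clipped
  tr <- tibble::tibble(a = c(0, 10))
  f <- minmax_normalize(tr)$fit
  te <- minmax_normalize(tibble::tibble(a = 12), fit = f)
  expect_equal(te$table$a, 1.2)
})

test_that("one-hot encoding partitions observed rows and freezes levels", {
  tb <- tibble::tibble(sex = c("F", "M", "F"))
  out <- one_hot(tb, kinds = c(sex = "categorical"))
  expect_named(out$table, c("sex=F", "sex=M"))
  expect_equal(out$table$`sex=F`, c(1, 0, 1))

  single <- one_hot(tibble::tibble(x = rep("only", 4)),
                    kinds = c(x = "categorical"))
  expect_equal(single$table$`x=only`, rep(1, 4))

  set.seed(1)
  tb3 <- tibble::tibble(c3 = sample(c("a", "b", "c", NA), 100, replace = TRUE))
  enc <- one_hot(tb3, kinds = c(c3 = "categorical"))
  sums <- rowSums(as.matrix(enc$table))
  expect_true(all(sums[!is.na(tb3$c3)] == 1))
  expect_true(all(is.na(sums[is.na(tb3$c3)])))

  # unseen level at transform time -> all-zero indicators with a warning
  expect_warning(
    un <- one_hot(tibble::tibble(sex = "X"), kinds = c(sex = "categorical"),
                  fit = out$fit),
    "unseen")
  expect_equal(unname(unlist(un$table[1, ])), c(0, 0))
})

test_that("missingness filter drops strictly over the threshold", {
  n <- 100
  tb <- tibble::tibble(
    over = replace(rnorm(n), 1:31, NA),    # 31%
    at = replace(rnorm(n), 1:30, NA),      # exactly 30%
    full = rnorm(n))
  out <- drop_high_missingness(tb)
  expect_equal(out$dropped$column, "over")
  expect_named(out$table, c("at", "full"))
})

test_that("selection applies the four rules and reports every column", {
  set.seed(4)
  n <- 400
  y <- rep(c(0, 1), n / 2)
  tb <- tibble::tibble(
    constant = rep(0.5, n),
    informative = y * 2 + rnorm(n),
    label_copy = as.numeric(y),
    noise = rnorm(n))
  kinds <- c(constant = "continuous", informative = "continuous",
             label_copy = "indicator", noise = "continuous")
  out <- select_features(tb, y, kinds = kinds)
  rep_ <- out$report
  expect_setequal(rep_$column, names(tb))
  expect_false(rep_$kept[rep_$column == "constant"])
  expect_match(rep_$reasons[rep_$column == "constant"], "low_variance")
  expect_true(rep_$kept[rep_$column == "informative"])
  expect_true(rep_$kept[rep_$column == "label_copy"])
  expect_error(select_features(tb, rep(1, n), kinds = kinds),
               class = "rapidprog_input_error")
})

test_that("pure-noise continuous columns are dropped under the null", {
  # a null column survives only when ANOVA p < 0.05 AND |r| >= 0.01, i.e.
  # with probability ~0.05; the observed drop rate over 200 replicates must
  # sit within 3 binomial standard errors of 0.95
  set.seed(11)
  n <- 400
  y <- rep(c(0, 1), n / 2)
  dropped <- replicate(200, {
    v <- rnorm(n)
    out <- select_features(tibble::tibble(x = v), y,
                           kinds = c(x = "continuous"),
                           raw_variance = c(x = var(v)))
    !out$report$kept
  })
  se <- sqrt(0.95 * 0.05 / 200)
  expect_lte(abs(mean(dropped) - 0.95), 3 * se)
})

test_that("KNN imputation matches the brute-force neighbor oracle", {
  tb <- tibble::tibble(a = c(0, 0, 0, 0), b = c(0, 1, 2, NA))
  out <- knn_impute(tb, k = 3)
  expect_equal(out$b[4], 1.0)

  # all observed -> identity
  full <- tibble::tibble(a = rnorm(5), b = rnorm(5))
  expect_equal(as.data.frame(knn_impute(full, k = 2)), as.data.frame(full))

  # zero-distance duplicate dominates at k = 1
  dup <- tibble::tibble(a = c(1, 1, 9), b = c(2, 2, 9), c = c(3, NA, 9))
  expect_equal(knn_impute(dup, k = 1)$c[2], 3)

  # random instances vs an independent brute-force search
  set.seed(21)
  for (rep_i in 1:10) {
    x <- matrix(runif(8 * 3), 8, 3)
    colnames(x) <- c("a", "b", "c")
    x[2, 3] <- NA
    got <- knn_impute(tibble::as_tibble(as.data.frame(x)), k = 3)$c[2]
    cand <- setdiff(which(!is.na(x[, 3])), 2)
    d <- sapply(cand, function(r) {
      sh <- !is.na(x[2, ]) & !is.na(x[r, ])
      sqrt(sum((x[2, sh] - x[r, sh])^2) / sum(sh))
    })
    nn <- cand[order(d, cand)][1:3]
    expect_equal(got, mean(x[nn, 3]))
  }

  expect_error(knn_impute(tibble::tibble(a = c(NA_real_, 1), b = c(NA_real_, 1))),
               class = "rapidprog_input_error")
})

test_that("column with too few observed values falls back to the mean", {
  tb <- tibble::tibble(a = 1:5 + 0, b = c(7, NA, NA, NA, NA))
  expect_warning(out <- knn_impute(tb, k = 3), "column mean")
  expect_equal(out$b, c(7, 7, 7, 7, 7))
})

test_that("fitted pipeline is idempotent and leak-free", {
  co <- small_cohort(n = 80, seed = 3)
  y <- as.numeric(co$truth$label == "RP")
  kinds <- setNames(co$feature_meta$kind, co$feature_meta$column)
  fit1 <- fit_feature_pipeline(co$features, y, kinds = kinds, fit_rows = 1:60)

  p1 <- predict(fit1, co$features[1:60, ])
  p2 <- predict(fit1, co$features[1:60, ])
  expect_identical(p1, p2)
  expect_true(all(!is.na(as_matrix <- as.matrix(p1[setdiff(names(p1), "patient_id")]))))

  # corrupting non-training rows must change nothing fitted
  corrupted <- co$features
  for (cn in setdiff(names(corrupted), "patient_id")) {
    if (is.numeric(corrupted[[cn]])) corrupted[[cn]][61:80] <- 999
  }
  fit2 <- suppressWarnings(
    fit_feature_pipeline(corrupted, y, kinds = kinds, fit_rows = 1:60))
  expect_identical(fit1$minmax, fit2$minmax)
  expect_identical(fit1$levels, fit2$levels)
  expect_identical(fit1$report, fit2$report)
  expect_identical(predict(fit1, co$features[1:60, ]),
                   predict(fit2, co$features[1:60, ]))
})

test_that("selection report covers each encoded column exactly once", {
  co <- small_cohort(n = 100, seed = 13)
  y <- as.numeric(co$truth$label == "RP")
  kinds <- setNames(co$feature_meta$kind, co$feature_meta$column)
  fp <- fit_feature_pipeline(co$features, y, kinds = kinds)
  expect_equal(anyDuplicated(tidy(fp)$column), 0)
  n_cont <- sum(kinds == "continuous")
  n_ind <- sum(lengths(fp$levels))
  expect_equal(nrow(tidy(fp)), n_cont + n_ind)
})
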