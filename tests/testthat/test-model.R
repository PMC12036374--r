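zero_params_model <- function(d = 4, d1 = 3, d2 = 2, ch = 2) {
  cfg <- model_config(d, encoder_dims = c(d1, d2), classifier_hidden = ch,
                      dropout = 0, seed = 1)
  p <- withr::with_seed(1, rapidprog:::init_params(cfg))
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4",
               "W5", "b5", "W6", "b6")) {
    p[[nm]][] <- 0
  }
  p$bn_mean <- rep(0, ch)
  p$bn_var <- rep(1, ch)
  structure(list(params = p, config = cfg), class = "rp_model")
}

test_that("encoder and decoder forward passes follow the stated maps", {
  m0 <- zero_params_model()
  x <- matrix(runif(8), 2, 4)
  expect_equal(encode(m0, x), matrix(0, 2, 2))
  expect_equal(decode(m0, matrix(1, 2, 2)), matrix(0, 2, 4))

  # identity weights on non-negative inputs pass through both ReLU layers
  mI <- zero_params_model(d = 3, d1 = 3, d2 = 3)
  mI$params$W1 <- diag(3)
  mI$params$W2 <- diag(3)
  xpos <- matrix(c(0.2, 0.5, 0.9), 1)
  expect_equal(encode(mI, xpos), xpos)

  # determinism
  set.seed(2)
  mr <- zero_params_model()
  mr$params$W1 <- matrix(rnorm(12), 4, 3)
  mr$params$W2 <- matrix(rnorm(6), 3, 2)
  expect_identical(encode(mr, x), encode(mr, x))
  expect_error(encode(m0, matrix(1, 1, 5)), class = "rapidprog_input_error")
})

test_that("classifier respects eval/train modes and batch-norm state", {
  m0 <- zero_params_model()
  h <- matrix(runif(6), 3, 2)
  # zeroed head -> logit 0 -> probability one half
  expect_equal(rapidprog:::sigmoid(classify(m0, h)), rep(0.5, 3))
  expect_identical(classify(m0, h), classify(m0, h))

  unfit <- zero_params_model()
  unfit$params$bn_mean <- rep(NA_real_, 2)
  expect_error(classify(unfit, h), class = "rapidprog_state_error")

  # seeded dropout in train mode is reproducible
  md <- zero_params_model()
  md$config$dropout <- 0.6
  md$params$W5 <- matrix(1, 2, 2)
  md$params$W6 <- matrix(1, 2, 1)
  l1 <- withr::with_seed(3, classify(md, h, mode = "train"))
  l2 <- withr::with_seed(3, classify(md, h, mode = "train"))
  expect_identical(l1, l2)
})

test_that("focal loss matches hand-computed closed forms", {
  # gamma 0, alpha 0.5, p_t = 0.5: 0.5 * (-ln 0.5)
  expect_equal(focal_loss(0, 1, alpha = 0.5, gamma = 0), 0.5 * log(2),
               tolerance = 1e-10)
  expect_equal(round(focal_loss(0, 1, alpha = 0.5, gamma = 0), 5), 0.34657)
  # alpha 0.3, gamma 2, logit 0, y = 1: 0.3 * 0.25 * ln 2
  expect_equal(focal_loss(0, 1, alpha = 0.3, gamma = 2),
               0.3 * 0.25 * log(2), tolerance = 1e-10)
  expect_equal(round(focal_loss(0, 1, alpha = 0.3, gamma = 2), 5), 0.05199)
  # well-classified limit
  expect_lt(focal_loss(20, 1, alpha = 0.3, gamma = 2), 1e-8)
})

test_that("focal loss reduces to half cross-entropy at gamma 0, alpha 0.5", {
  set.seed(7)
  logits <- rnorm(1000, sd = 3)
  y <- rbinom(1000, 1, 0.5)
  p <- rapidprog:::sigmoid(logits)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(focal_loss(logits, y, alpha = 0.5, gamma = 0), 0.5 * bce,
               tolerance = 1e-6)
})

test_that("reconstruction and total losses follow their formulas", {
  expect_equal(reconstruction_loss(matrix(1, 2, 3), matrix(1, 2, 3)), 0)
  expect_equal(reconstruction_loss(matrix(0, 1, 2), matrix(1, 1, 2)), 1)
  r1 <- reconstruction_loss(matrix(0, 2, 2), matrix(0.3, 2, 2))
  r2 <- reconstruction_loss(matrix(0, 2, 2), matrix(0.6, 2, 2))
  expect_equal(r2, 4 * r1)
  expect_error(reconstruction_loss(matrix(0, 2, 2), matrix(0, 2, 3)),
               class = "rapidprog_input_error")

  expect_equal(total_loss(0.7, 0.2, lambda = 1), 0.7)
  expect_equal(total_loss(0.7, 0.2, lambda = 0), 0.2)
  expect_equal(total_loss(0.2, 0.4, lambda = 0.5), 0.3)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- model_config(5, encoder_dims = c(4, 3), classifier_hidden = 3,
                      dropout = 0, alpha = 0.3, gamma = 2, lambda = 0.5,
                      seed = 2)
  p <- withr::with_seed(8, rapidprog:::init_params(cfg))
  X <- matrix(runif(7 * 5), 7, 5)
  y <- c(1, 0, 1, 1, 0, 0, 1)
  bg <- rapidprog:::batch_grads(p, cfg, X, y)
  eps <- 1e-6
  for (nm in c("W1", "W2", "W3", "W4", "W5", "W6", "b2", "b4", "b6",
               "bn_gamma", "bn_beta")) {
    for (i in seq_len(min(3, length(p[[nm]])))) {
      p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (rapidprog:::batch_grads(p1, cfg, X, y)$total -
                rapidprog:::batch_grads(p2, cfg, X, y)$total) / (2 * eps)
      expect_equal(bg$grads[[nm]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("training is bit-reproducible and losses trend downward", {
  set.seed(12)
  x <- matrix(runif(200 * 8), 200, 8)
  y <- as.numeric(x[, 1] + x[, 2] + 0.3 * rnorm(200) > 1)
  cfg <- model_config(8, max_epochs = 12, patience = 20, seed = 4)
  f1 <- fit_rp_model(x[1:160, ], y[1:160], x[161:200, ], y[161:200], cfg)
  f2 <- fit_rp_model(x[1:160, ], y[1:160], x[161:200, ], y[161:200], cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$params, f2$params)
  expect_identical(predict(f1, x), predict(f2, x))

  tt <- f1$trace$train_total
  expect_lt(median(tt[7:12]), median(tt[1:6]))
  expect_lt(tt[length(tt)], tt[1])
})

test_that("early stopping honours patience and returns best parameters", {
  set.seed(3)
  x <- matrix(runif(60 * 4), 60, 4)
  y <- rbinom(60, 1, 0.5)  # unlearnable: validation loss soon stops improving
  cfg <- model_config(4, max_epochs = 60, patience = 0, seed = 2)
  fit <- fit_rp_model(x[1:45, ], y[1:45], x[46:60, ], y[46:60], cfg)
  expect_equal(fit$stop_reason, "early_stopping")
  # patience 0: stops right after the first epoch that fails to improve
  expect_equal(fit$trace$val_total[fit$best_epoch],
               min(fit$trace$val_total))
  expect_equal(nrow(fit$trace), fit$best_epoch + 1)

  cfg2 <- model_config(4, max_epochs = 40, patience = 5, seed = 2)
  fit2 <- fit_rp_model(x[1:45, ], y[1:45], x[46:60, ], y[46:60], cfg2)
  if (fit2$stop_reason == "early_stopping") {
    after <- fit2$trace$val_total[(fit2$best_epoch + 1):nrow(fit2$trace)]
    expect_equal(length(after), 5)
    expect_true(all(after >= fit2$trace$val_total[fit2$best_epoch]))
  }
})

test_that("autoencoder drives reconstruction loss to near zero on rank-1 data", {
  set.seed(9)
  v <- runif(8)
  a <- runif(150, 0.2, 1)
  x <- outer(a, v)
  cfg <- model_config(8, encoder_dims = c(6, 2), lambda = 0, dropout = 0,
                      lr = 0.01, max_epochs = 200, patience = 200, seed = 6)
  fit <- fit_rp_model(x[1:120, ], rbinom(120, 1, 0.5),
                      x[121:150, ], rbinom(30, 1, 0.5), cfg)
  h <- encode(fit, x[121:150, ])
  expect_lt(reconstruction_loss(x[121:150, ], decode(fit, h)), 1e-3)
})

test_that("predictions are probabilities, row-order invariant, and thresholded", {
  g <- trained_group()
  x <- g$x[g$split$test, ]
  pr <- predict(g$model, x)
  expect_true(all(pr > 0 & pr < 1))
  perm <- sample(nrow(x))
  expect_equal(predict(g$model, x[perm, ]), pr[perm])
  cls <- predict(g$model, x, type = "class")
  expect_equal(cls, as.integer(pr >= 0.5))
  expect_equal(rapidprog:::sigmoid(predict(g$model, x, type = "logit")), pr)
})

test_that("separable synthetic data is learned with high sensitivity", {
  g <- trained_group()
  expect_gte(g$metrics$sensitivity, 0.9)
  expect_gte(g$metrics$auroc, 0.9)
})

test_that("training rejects empty splits and single-class labels warn", {
  x <- matrix(runif(40), 10, 4)
  cfg <- model_config(4, max_epochs = 1, seed = 1)
  expect_error(fit_rp_model(x[0, ], numeric(0), x, rbinom(10, 1, 0.5), cfg),
               class = "rapidprog_input_error")
  expect_warning(
    fit_rp_model(x[1:8, ], rep(1, 8), x[9:10, ], c(0, 1), cfg),
    "single class")
})
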