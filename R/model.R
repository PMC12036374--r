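# Autoencoder-based classifier for tabular EHR features.
#
# Architecture:
#   encoder     h    = ReLU(W2 ReLU(W1 x + b1) + b2)
#   decoder     xhat = ReLU(W4 ReLU(W3 h + b3) + b4)
#   classifier  z    = W6 Dropout(ReLU(BatchNorm(W5 h + b5))) + b6   (logit)
# trained with the joint objective
#   L = lambda * FocalLoss(z, y) + (1 - lambda) * MSE(x, xhat)
# by Adam with minibatches, seeded shuffling/dropout, and early stopping on
# the validation total loss. Everything (including batch-norm backward) is
# implemented directly on matrices; rows are samples.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1
PT_CLAMP <- 1e-7

#' Model configuration
#'
#' @param input_dim Number of input features.
#' @param encoder_dims Two hidden sizes for the encoder; defaults to
#'   `max(32, input_dim/2)` then `max(16, input_dim/4)`, with the latent size
#'   capped below `input_dim`.
#' @param classifier_hidden Hidden width of the classifier MLP (default 32).
#' @param alpha,gamma Focal-loss weighting and focusing parameters
#'   (defaults 0.3 and 2.0, the MMSE-group setting; the MoCA-group setting is
#'   0.5 and 3.0).
#' @param lambda Trade-off between classification and reconstruction loss in
#'   `[0, 1]` (default 0.5).
#' @param dropout Dropout fraction in the classifier MLP (default 0.6).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 16).
#' @param max_epochs Maximum training epochs (default 80).
#' @param patience Early-stopping patience in epochs (default 20);
#'   `patience = 0` stops after the first non-improving epoch.
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @param decision_threshold Probability threshold for class predictions.
#' @return A `model_config` list.
#' @export
model_config <- function(input_dim, encoder_dims = NULL,
                         classifier_hidden = 32,
                         alpha = 0.3, gamma = 2.0, lambda = 0.5,
                         dropout = 0.6, lr = 1e-3, batch_size = 16,
                         max_epochs = 80, patience = 20, seed = 1L,
                         decision_threshold = 0.5) {
  assert_count(input_dim, "input_dim", positive = TRUE)
  if (alpha < 0 || alpha > 1) abort_config("`alpha` must be in [0,1]")
  if (gamma < 0) abort_config("`gamma` must be >= 0")
  if (lambda < 0 || lambda > 1) abort_config("`lambda` must be in [0,1]")
  if (dropout < 0 || dropout >= 1) abort_config("`dropout` must be in [0,1)")
  if (is.null(encoder_dims)) {
    d1 <- max(32, ceiling(input_dim / 2))
    d2 <- max(16, ceiling(input_dim / 4))
    d2 <- max(2, min(d2, input_dim - 1))
    encoder_dims <- c(d1, d2)
  }
  if (length(encoder_dims) != 2 || any(encoder_dims < 1)) {
    abort_config("`encoder_dims` must be two positive sizes")
  }
  structure(list(
    input_dim = as.integer(input_dim),
    encoder_dims = as.integer(encoder_dims),
    classifier_hidden = as.integer(classifier_hidden),
    alpha = alpha, gamma = gamma, lambda = lambda, dropout = dropout,
    lr = lr, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    seed = as.integer(seed), decision_threshold = decision_threshold
  ), class = "model_config")
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# He-normal initialization; weights stored as d_in x d_out, rows = samples.
# Hidden biases start slightly positive so ReLU units are born alive (a dead
# encoder cannot recover once every latent unit rectifies to zero).
init_params <- function(cfg) {
  d <- cfg$input_dim
  d1 <- cfg$encoder_dims[1]
  d2 <- cfg$encoder_dims[2]
  ch <- cfg$classifier_hidden
  he <- function(din, dout) {
    matrix(rnorm(din * dout, 0, sqrt(2 / din)), din, dout)
  }
  list(
    W1 = he(d, d1), b1 = rep(0.01, d1),
    W2 = he(d1, d2), b2 = rep(0.01, d2),
    W3 = he(d2, d1), b3 = rep(0.01, d1),
    W4 = he(d1, d), b4 = rep(0.01, d),
    W5 = he(d2, ch), b5 = rep(0.01, ch),
    W6 = he(ch, 1), b6 = numeric(1),
    bn_gamma = rep(1, ch), bn_beta = numeric(ch),
    bn_mean = rep(NA_real_, ch), bn_var = rep(NA_real_, ch)
  )
}

add_bias <- function(a, b) sweep(a, 2, b, `+`)

#' Encode inputs to the latent representation
#'
#' `h = ReLU(W2 ReLU(W1 x + b1) + b2)`. Deterministic given parameters.
#'
#' @param model A fitted `rp_model` (or a bare parameter list with a config).
#' @param x Numeric matrix, rows = samples, `input_dim` columns.
#' @return Latent matrix, rows = samples.
#' @export
encode <- function(model, x) {
  p <- model$params
  x <- as_feature_matrix(x)
  if (ncol(x) != nrow(p$W1)) abort_input("`x` has the wrong number of features")
  relu(add_bias(relu(add_bias(x %*% p$W1, p$b1)) %*% p$W2, p$b2))
}

#' Decode a latent representation back to feature space
#'
#' `xhat = ReLU(W4 ReLU(W3 h + b3) + b4)` — symmetric to the encoder.
#'
#' @param model A fitted `rp_model`.
#' @param h Latent matrix, rows = samples.
#' @return Reconstruction matrix.
#' @export
decode <- function(model, h) {
  p <- model$params
  if (!is.matrix(h)) h <- matrix(h, nrow = 1)
  if (ncol(h) != nrow(p$W3)) abort_input("`h` has the wrong latent size")
  relu(add_bias(relu(add_bias(h %*% p$W3, p$b3)) %*% p$W4, p$b4))
}

#' Classify a latent representation
#'
#' `logit = W6 Dropout(ReLU(BatchNorm(W5 h + b5))) + b6`. Batch
#' normalization uses batch statistics in `"train"` mode and frozen running
#' statistics in `"eval"` mode; dropout is active only in `"train"` mode.
#'
#' @param model A fitted `rp_model`.
#' @param h Latent matrix.
#' @param mode `"eval"` (default) or `"train"`.
#' @return Numeric vector of logits.
#' @export
classify <- function(model, h, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  p <- model$params
  cfg <- model$config
  if (!is.matrix(h)) h <- matrix(h, nrow = 1)
  a5 <- add_bias(h %*% p$W5, p$b5)
  if (mode == "eval") {
    if (any(is.na(p$bn_mean))) {
      abort_state("batch-norm statistics not fitted yet; train the model first")
    }
    z <- sweep(sweep(a5, 2, p$bn_mean, `-`), 2, sqrt(p$bn_var + BN_EPS), `/`)
  } else {
    mu <- colMeans(a5)
    v <- colMeans(sweep(a5, 2, mu, `-`)^2)
    z <- sweep(sweep(a5, 2, mu, `-`), 2, sqrt(v + BN_EPS), `/`)
  }
  bn <- add_bias(sweep(z, 2, p$bn_gamma, `*`), p$bn_beta)
  r <- relu(bn)
  if (mode == "train" && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    mask <- matrix(runif(length(r)) < keep, nrow(r)) / keep
    r <- r * mask
  }
  drop(add_bias(r %*% p$W6, p$b6))
}

#' Focal loss
#'
#' `mean(-alpha_t * (1 - p_t)^gamma * log(p_t))` with
#' `p_t = sigmoid(logit)` for positives and `1 - sigmoid(logit)` for
#' negatives, `alpha_t = alpha` for positives and `1 - alpha` for negatives,
#' and `p_t` clamped to `[1e-7, 1 - 1e-7]` for log stability. At
#' `gamma = 0, alpha = 0.5` this is exactly half the binary cross-entropy.
#'
#' @param logit Numeric vector of logits.
#' @param y Binary labels (0/1).
#' @param alpha,gamma Focal parameters.
#' @return Mean loss (scalar >= 0).
#' @export
focal_loss <- function(logit, y, alpha = 0.3, gamma = 2.0) {
  p <- sigmoid(logit)
  pt <- ifelse(y == 1, p, 1 - p)
  pt <- pmin(pmax(pt, PT_CLAMP), 1 - PT_CLAMP)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  mean(-at * (1 - pt)^gamma * log(pt))
}

# d(mean focal)/d(logit), length n (already divided by n).
focal_loss_grad <- function(logit, y, alpha, gamma) {
  p <- sigmoid(logit)
  pt <- ifelse(y == 1, p, 1 - p)
  ptc <- pmin(pmax(pt, PT_CLAMP), 1 - PT_CLAMP)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  term1 <- if (gamma > 0) -gamma * (1 - ptc)^(gamma - 1) * log(ptc) else 0
  dL_dpt <- -at * (term1 + (1 - ptc)^gamma / ptc)
  dpt_dz <- (2 * y - 1) * p * (1 - p)
  dL_dpt * dpt_dz / length(logit)
}

#' Reconstruction loss
#'
#' Mean squared difference over all samples and features.
#'
#' @param x,xhat Matrices of identical shape.
#' @return Scalar >= 0.
#' @export
reconstruction_loss <- function(x, xhat) {
  if (!identical(dim(as.matrix(x)), dim(as.matrix(xhat)))) {
    abort_input("`x` and `xhat` must have the same shape")
  }
  mean((x - xhat)^2)
}

#' Joint training objective
#'
#' `lambda * l_cls + (1 - lambda) * l_rec`.
#'
#' @param l_cls,l_rec Classification and reconstruction loss values.
#' @param lambda Trade-off weight in `[0, 1]`.
#' @return Scalar.
#' @export
total_loss <- function(l_cls, l_rec, lambda = 0.5) {
  if (lambda < 0 || lambda > 1) abort_input("`lambda` must be in [0,1]")
  lambda * l_cls + (1 - lambda) * l_rec
}

# Full forward + backward for one minibatch; returns gradients, losses and
# updated batch-norm running statistics.
batch_grads <- function(p, cfg, X, y) {
  n <- nrow(X)
  A1 <- add_bias(X %*% p$W1, p$b1);  H1 <- relu(A1)
  A2 <- add_bias(H1 %*% p$W2, p$b2); H <- relu(A2)
  A3 <- add_bias(H %*% p$W3, p$b3);  H3 <- relu(A3)
  A4 <- add_bias(H3 %*% p$W4, p$b4); Xhat <- relu(A4)

  A5 <- add_bias(H %*% p$W5, p$b5)
  mu <- colMeans(A5)
  v <- colMeans(sweep(A5, 2, mu, `-`)^2)
  sdv <- sqrt(v + BN_EPS)
  Z <- sweep(sweep(A5, 2, mu, `-`), 2, sdv, `/`)
  BN <- add_bias(sweep(Z, 2, p$bn_gamma, `*`), p$bn_beta)
  R5 <- relu(BN)
  if (cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    mask <- matrix(runif(length(R5)) < keep, n) / keep
  } else {
    mask <- matrix(1, n, ncol(R5))
  }
  RD <- R5 * mask
  logit <- drop(add_bias(RD %*% p$W6, p$b6))

  l_cls <- focal_loss(logit, y, cfg$alpha, cfg$gamma)
  l_rec <- reconstruction_loss(X, Xhat)

  # --- backward ---
  g <- list()
  dlogit <- matrix(cfg$lambda * focal_loss_grad(logit, y, cfg$alpha, cfg$gamma),
                   ncol = 1)
  g$W6 <- t(RD) %*% dlogit
  g$b6 <- colSums(dlogit)
  dRD <- dlogit %*% t(p$W6)
  dR5 <- dRD * mask
  dBN <- dR5 * (BN > 0)
  g$bn_gamma <- colSums(dBN * Z)
  g$bn_beta <- colSums(dBN)
  dZ <- sweep(dBN, 2, p$bn_gamma, `*`)
  dA5 <- sweep(dZ - matrix(colMeans(dZ), n, ncol(dZ), byrow = TRUE) -
                 Z * matrix(colMeans(dZ * Z), n, ncol(dZ), byrow = TRUE),
               2, sdv, `/`)
  g$W5 <- t(H) %*% dA5
  g$b5 <- colSums(dA5)
  dH_cls <- dA5 %*% t(p$W5)

  dXhat <- (1 - cfg$lambda) * 2 * (Xhat - X) / (n * ncol(X))
  dA4 <- dXhat * (A4 > 0)
  g$W4 <- t(H3) %*% dA4
  g$b4 <- colSums(dA4)
  dH3 <- dA4 %*% t(p$W4)
  dA3 <- dH3 * (A3 > 0)
  g$W3 <- t(H) %*% dA3
  g$b3 <- colSums(dA3)
  dH_dec <- dA3 %*% t(p$W3)

  dH <- dH_cls + dH_dec
  dA2 <- dH * (A2 > 0)
  g$W2 <- t(H1) %*% dA2
  g$b2 <- colSums(dA2)
  dH1 <- dA2 %*% t(p$W2)
  dA1 <- dH1 * (A1 > 0)
  g$W1 <- t(X) %*% dA1
  g$b1 <- colSums(dA1)

  list(grads = g, l_cls = l_cls, l_rec = l_rec,
       total = total_loss(l_cls, l_rec, cfg$lambda),
       batch_mean = mu, batch_var = v)
}

eval_losses <- function(model, X, y) {
  h <- encode(model, X)
  xhat <- decode(model, h)
  logit <- classify(model, h, mode = "eval")
  l_cls <- focal_loss(logit, y, model$config$alpha, model$config$gamma)
  l_rec <- reconstruction_loss(X, xhat)
  c(cls = l_cls, rec = l_rec,
    total = total_loss(l_cls, l_rec, model$config$lambda))
}

#' Train the autoencoder-based classifier
#'
#' Optimizes the joint focal/reconstruction objective with Adam over seeded
#' minibatches, tracking per-epoch training and validation losses and
#' stopping early when the validation total loss fails to improve for
#' `patience` consecutive epochs. The parameters from the best validation
#' epoch are returned. Fully reproducible under a fixed seed.
#'
#' @param x_train,x_val Numeric feature matrices (rows = samples).
#' @param y_train,y_val Binary labels (1 = rapid progressor).
#' @param config A [model_config()]; built automatically from
#'   `ncol(x_train)` when omitted.
#' @return An object of class `rp_model` with elements `params`, `config`,
#'   `trace` (per-epoch loss tibble), `best_epoch`, `stop_reason`.
#' @examples
#' \donttest{
#' set.seed(1)
#' x <- matrix(runif(120 * 8), 120, 8)
#' y <- as.numeric(x[, 1] + x[, 2] > 1)
#' cfg <- model_config(8, max_epochs = 10, seed = 1)
#' fit <- fit_rp_model(x[1:100, ], y[1:100], x[101:120, ], y[101:120], cfg)
#' glance(fit)
#' }
#' @export
fit_rp_model <- function(x_train, y_train, x_val, y_val,
                         config = model_config(ncol(x_train))) {
  X <- as_feature_matrix(x_train)
  Xv <- as_feature_matrix(x_val)
  y <- as.numeric(y_train)
  yv <- as.numeric(y_val)
  if (nrow(X) == 0 || nrow(Xv) == 0) abort_input("empty training or validation split")
  if (ncol(X) != config$input_dim) {
    abort_input("`config$input_dim` does not match the data")
  }
  if (length(unique(y)) < 2) {
    warn("training labels contain a single class; proceeding anyway")
  }

  with_seed(config$seed, {
    p <- init_params(config)
    m <- lapply(p[1:14], function(w) w * 0)  # Adam first moments (trainables)
    v <- lapply(p[1:14], function(w) w * 0)
    trainable <- names(p)[1:14]
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0

    best <- list(loss = Inf, params = NULL, epoch = 0)
    bad_epochs <- 0
    stop_reason <- "max_epochs"
    trace <- vector("list", config$max_epochs)

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(nrow(X))
      starts <- seq(1, nrow(X), by = config$batch_size)
      ep_losses <- matrix(0, length(starts), 3)
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1, nrow(X))]
        bg <- batch_grads(p, config, X[idx, , drop = FALSE], y[idx])
        # running batch-norm statistics
        if (any(is.na(p$bn_mean))) {
          p$bn_mean <- bg$batch_mean
          p$bn_var <- bg$batch_var
        } else {
          p$bn_mean <- (1 - BN_MOMENTUM) * p$bn_mean + BN_MOMENTUM * bg$batch_mean
          p$bn_var <- (1 - BN_MOMENTUM) * p$bn_var + BN_MOMENTUM * bg$batch_var
        }
        step <- step + 1
        for (nm in trainable) {
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * bg$grads[[nm]]
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * bg$grads[[nm]]^2
          mh <- m[[nm]] / (1 - beta1^step)
          vh <- v[[nm]] / (1 - beta2^step)
          p[[nm]] <- p[[nm]] - config$lr * mh / (sqrt(vh) + eps)
        }
        ep_losses[bi, ] <- c(bg$total, bg$l_cls, bg$l_rec)
      }
      model_now <- structure(list(params = p, config = config),
                             class = "rp_model")
      vl <- eval_losses(model_now, Xv, yv)
      trace[[epoch]] <- tibble(
        epoch = epoch,
        train_total = mean(ep_losses[, 1]), train_cls = mean(ep_losses[, 2]),
        train_rec = mean(ep_losses[, 3]),
        val_total = unname(vl["total"]), val_cls = unname(vl["cls"]),
        val_rec = unname(vl["rec"])
      )
      if (vl["total"] < best$loss - 1e-10) {
        best <- list(loss = unname(vl["total"]), params = p, epoch = epoch)
        bad_epochs <- 0
      } else {
        bad_epochs <- bad_epochs + 1
        if (bad_epochs >= max(1L, config$patience)) {
          stop_reason <- "early_stopping"
          trace <- trace[seq_len(epoch)]
          break
        }
      }
    }

    structure(list(
      params = best$params %||% p,
      config = config,
      trace = dplyr::bind_rows(trace),
      best_epoch = best$epoch,
      stop_reason = stop_reason
    ), class = "rp_model")
  })
}

#' Predict with a fitted model
#'
#' Runs the encoder and classifier in eval mode (frozen batch-norm
#' statistics, no dropout); deterministic and row-order invariant.
#'
#' @param object A fitted `rp_model`.
#' @param newdata Feature matrix or tibble.
#' @param type `"prob"` (default), `"logit"` or `"class"`.
#' @param ... Unused.
#' @return Numeric vector (probabilities/logits) or integer 0/1 classes.
#' @export
predict.rp_model <- function(object, newdata, type = c("prob", "logit", "class"),
                             ...) {
  type <- match.arg(type)
  if (is.null(object$params)) abort_state("model has no fitted parameters")
  h <- encode(object, newdata)
  logit <- classify(object, h, mode = "eval")
  switch(type,
         logit = logit,
         prob = sigmoid(logit),
         class = as.integer(sigmoid(logit) >= object$config$decision_threshold))
}

#' @export
print.rp_model <- function(x, ...) {
  cat("<rp_model>", x$config$input_dim, "->",
      paste(x$config$encoder_dims, collapse = " -> "), "latent\n")
  cat("  best epoch:", x$best_epoch, " stop:", x$stop_reason, "\n")
  invisible(x)
}

#' Tidy the training trace of a fitted model
#'
#' @param x A fitted `rp_model`.
#' @param ... Unused.
#' @return The per-epoch loss tibble.
#' @method tidy rp_model
#' @export
tidy.rp_model <- function(x, ...) x$trace

#' One-row model summary
#'
#' @param x A fitted `rp_model`.
#' @param ... Unused.
#' @return Tibble with best epoch, stop reason and best validation loss.
#' @method glance rp_model
#' @export
glance.rp_model <- function(x, ...) {
  tibble(best_epoch = x$best_epoch,
         epochs_run = nrow(x$trace),
         stop_reason = x$stop_reason,
         best_val_total = min(x$trace$val_total))
}
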