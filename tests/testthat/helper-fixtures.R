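# Shared fixtures and independent oracles, built in code at test time.

small_cohort <- function(n = 120, seed = 7, ...) {
  simulate_cohort(synth_config(n_patients = n, seed = seed, ...))
}

# One small trained group, computed once per session and reused by the
# model / attribution / ensemble tests.
.fixture_env <- new.env(parent = emptyenv())
trained_group <- function() {
  if (is.null(.fixture_env$group)) {
    co <- simulate_cohort(synth_config(
      n_patients = 250, instruments = "MMSE", effect_size = 1.5,
      n_continuous = 10, n_categorical = 5, seed = 31))
    .fixture_env$group <- run_group(
      co, "MMSE", sampler_config("scus", seed = 3),
      model_cfg = list(max_epochs = 30), split_seed = 5, seed = 5)
  }
  .fixture_env$group
}

# Hand-constructed network that is linear over [0,1]^d inputs: every ReLU
# pre-activation is pushed positive by large biases, so the model output is
# an affine function of x with a computable coefficient vector.
make_linear_model <- function(d = 4, seed = 5) {
  cfg <- model_config(d, encoder_dims = c(3, 2), classifier_hidden = 2,
                      dropout = 0, seed = 1)
  withr::with_seed(seed, {
    p <- list(
      W1 = matrix(runif(d * 3, -0.2, 0.2), d, 3), b1 = rep(5, 3),
      W2 = matrix(runif(6, -0.2, 0.2), 3, 2), b2 = rep(5, 2),
      W3 = matrix(runif(6, -0.2, 0.2), 2, 3), b3 = rep(5, 3),
      W4 = matrix(runif(3 * d, -0.2, 0.2), 3, d), b4 = rep(5, d),
      W5 = matrix(runif(4, -0.2, 0.2), 2, 2), b5 = rep(5, 2),
      W6 = matrix(runif(2, -1, 1), 2, 1), b6 = 0,
      bn_gamma = c(1, 1), bn_beta = c(10, 10),
      bn_mean = c(0, 0), bn_var = c(1, 1)
    )
    structure(list(params = p, config = cfg, trace = NULL,
                   best_epoch = 1, stop_reason = "fixture"),
              class = "rp_model")
  })
}

# Effective input coefficients of the linear-regime model above.
linear_model_coefs <- function(model) {
  p <- model$params
  s <- p$bn_gamma / sqrt(p$bn_var + 1e-5)
  drop(p$W1 %*% p$W2 %*% p$W5 %*% diag(s) %*% p$W6)
}

# Brute-force oracles -------------------------------------------------------

bf_mean_cosine <- function(x_min, x_maj) {
  sapply(seq_len(nrow(x_min)), function(i) {
    mean(sapply(seq_len(nrow(x_maj)), function(j) {
      a <- x_min[i, ]; b <- x_maj[j, ]
      sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
    }))
  })
}

bf_auroc <- function(y, prob) {
  pos <- prob[y == 1]
  neg <- prob[y == 0]
  conc <- 0
  for (p in pos) for (q in neg) {
    conc <- conc + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  conc / (length(pos) * length(neg))
}
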