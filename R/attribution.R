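# Additive feature attribution for the autoencoder classifier, in the
# DeepLIFT/DeepSHAP family: multipliers are propagated backwards through the
# eval-mode encoder + classifier with the rescale rule at every ReLU (and,
# for the probability scale, through the final sigmoid). For each background
# row the contributions satisfy summation-to-delta exactly, so averaging
# over backgrounds preserves the local-accuracy contract:
# base_value + sum(attributions) == model output, up to floating-point error.

# Multipliers for all explain rows against a single reference row.
# Returns an n x d matrix of per-input multipliers.
deeplift_multipliers <- function(p, X, ref, scale) {
  n <- nrow(X)
  fwd <- function(M) {
    A1 <- add_bias(M %*% p$W1, p$b1); H1 <- relu(A1)
    A2 <- add_bias(H1 %*% p$W2, p$b2); H <- relu(A2)
    A5 <- add_bias(H %*% p$W5, p$b5)
    s <- p$bn_gamma / sqrt(p$bn_var + BN_EPS)
    BN <- add_bias(sweep(sweep(A5, 2, p$bn_mean, `-`), 2, s, `*`), p$bn_beta)
    R5 <- relu(BN)
    logit <- unname(drop(add_bias(R5 %*% p$W6, p$b6)))
    list(A1 = A1, H1 = H1, A2 = A2, H = H, A5 = A5, BN = BN, R5 = R5,
         logit = logit, bn_scale = s)
  }
  fx <- fwd(X)
  fr <- fwd(matrix(ref, nrow = 1))

  relu_ratio <- function(d_in, d_out, a) {
    r <- ifelse(abs(d_in) > 1e-9, d_out / d_in, as.numeric(a > 0))
    r
  }
  bcast <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

  m_logit <- if (scale == "logit") {
    rep(1, n)
  } else {
    dz <- fx$logit - fr$logit
    ifelse(abs(dz) > 1e-9,
           (sigmoid(fx$logit) - sigmoid(fr$logit)) / dz,
           sigmoid(fx$logit) * (1 - sigmoid(fx$logit)))
  }
  mR5 <- matrix(m_logit, n, 1) %*% t(p$W6)
  mBN <- mR5 * relu_ratio(fx$BN - bcast(fr$BN, n), fx$R5 - bcast(fr$R5, n),
                          fx$BN)
  mA5 <- sweep(mBN, 2, fx$bn_scale, `*`)
  mH_cls <- mA5 %*% t(p$W5)
  mA2 <- mH_cls * relu_ratio(fx$A2 - bcast(fr$A2, n), fx$H - bcast(fr$H, n),
                             fx$A2)
  mH1 <- mA2 %*% t(p$W2)
  mA1 <- mH1 * relu_ratio(fx$A1 - bcast(fr$A1, n), fx$H1 - bcast(fr$H1, n),
                          fx$A1)
  mX <- mA1 %*% t(p$W1)
  list(mult = mX, out_x = if (scale == "logit") fx$logit else sigmoid(fx$logit),
       out_ref = if (scale == "logit") fr$logit else sigmoid(fr$logit))
}

#' Per-feature attributions for model predictions
#'
#' Computes additive feature attributions for each explained row relative to
#' the expectation over a background set, by backward multiplier propagation
#' with the rescale rule at each nonlinearity. On both the `"logit"`
#' (default) and `"prob"` scales the attributions satisfy local accuracy
#' exactly: `base_value + rowSums(attributions)` equals the model output for
#' every explained row.
#'
#' @param model A fitted `rp_model`.
#' @param background Feature matrix of reference rows (e.g. up to 100
#'   training rows); the base value is the mean model output over them.
#' @param x_explain Feature matrix of rows to explain.
#' @param scale `"logit"` or `"prob"`.
#' @return Object of class `rp_attribution`: list with `attributions`
#'   (matrix rows x features), `base_value`, `output` (model outputs),
#'   `features`, `scale`.
#' @export
attribute_features <- function(model, background, x_explain,
                               scale = c("logit", "prob")) {
  scale <- match.arg(scale)
  if (is.null(model$params)) abort_state("model has no fitted parameters")
  if (any(is.na(model$params$bn_mean))) {
    abort_state("batch-norm statistics not fitted; train the model first")
  }
  B <- as_feature_matrix(background)
  X <- as_feature_matrix(x_explain)
  if (nrow(B) == 0) abort_input("`background` must be non-empty")
  p <- model$params

  total <- matrix(0, nrow(X), ncol(X))
  base <- 0
  for (b in seq_len(nrow(B))) {
    dl <- deeplift_multipliers(p, X, B[b, ], scale)
    total <- total + dl$mult * sweep(X, 2, B[b, ], `-`)
    base <- base + dl$out_ref
  }
  attributions <- total / nrow(B)
  colnames(attributions) <- colnames(X)
  structure(list(
    attributions = attributions,
    base_value = base / nrow(B),
    output = dl$out_x,
    features = colnames(X) %||% paste0("V", seq_len(ncol(X))),
    scale = scale
  ), class = "rp_attribution")
}

#' @export
print.rp_attribution <- function(x, ...) {
  cat("<rp_attribution>", nrow(x$attributions), "rows x",
      ncol(x$attributions), "features on the", x$scale, "scale\n")
  invisible(x)
}

#' Tidy attribution values into long form
#'
#' @param x An `rp_attribution`.
#' @param ... Unused.
#' @return Tibble with `row`, `feature`, `attribution`.
#' @method tidy rp_attribution
#' @export
tidy.rp_attribution <- function(x, ...) {
  as_tibble(x$attributions) |>
    dplyr::mutate(row = dplyr::row_number()) |>
    tidyr::pivot_longer(-"row", names_to = "feature",
                        values_to = "attribution")
}

#' Rank features by mean absolute attribution
#'
#' @param report An `rp_attribution`.
#' @param k Number of top features to return (default 10).
#' @return Tibble with `rank`, `feature`, `importance` (mean absolute
#'   attribution), descending with index tie-break.
#' @export
rank_features <- function(report, k = 10) {
  if (k <= 0) abort_input("`k` must be positive")
  imp <- colMeans(abs(report$attributions))
  ord <- order(-imp, seq_along(imp))
  n <- min(k, length(imp))
  tibble(rank = seq_len(n),
         feature = report$features[ord[seq_len(n)]],
         importance = unname(imp[ord[seq_len(n)]]))
}

#' Compare top-ranked features across two models
#'
#' @param report_a,report_b `rp_attribution` objects (e.g. the two
#'   instrument-specific models explained on the composite group).
#' @param k Top-k depth.
#' @return Tibble of features present in both top-k lists with both ranks
#'   and importances.
#' @export
compare_rankings <- function(report_a, report_b, k = 10) {
  ra <- rank_features(report_a, k)
  rb <- rank_features(report_b, k)
  dplyr::inner_join(ra, rb, by = "feature", suffix = c("_a", "_b")) |>
    dplyr::arrange(.data$rank_a)
}
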