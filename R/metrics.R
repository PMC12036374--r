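# Evaluation utilities: seeded train/validation/test splits and the four
# study metrics (sensitivity, F1, AUROC, AUPRC). AUROC uses the rank
# statistic with tie-midpoint correction; AUPRC integrates the
# precision-recall curve stepwise over descending score thresholds.

#' Seeded train/validation/test split
#'
#' Shuffles `1:n` with a fixed seed and cuts it into disjoint, exhaustive
#' index sets. Validation and test sizes are the rounded fractions; the
#' remainder goes to training.
#'
#' @param n Number of rows.
#' @param fractions Length-3 fractions `(train, val, test)` summing to 1.
#' @param seed Integer seed.
#' @return List with integer vectors `train`, `val`, `test`.
#' @export
split_indices <- function(n, fractions = c(0.70, 0.10, 0.20), seed = 1L) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    abort_config("`fractions` must be three values summing to 1")
  }
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 1) {
    abort_input("a split would be empty at this n")
  }
  with_seed(seed, {
    ord <- sample(n)
    list(train = sort(ord[seq_len(n_train)]),
         val = sort(ord[n_train + seq_len(n_val)]),
         test = sort(ord[n_train + n_val + seq_len(n_test)]))
  })
}

auroc_rank <- function(y, prob) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(prob)  # midpoint ranks on ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

auprc_step <- function(y, prob) {
  ord <- order(-prob)
  y <- y[ord]
  prob <- prob[ord]
  # group tied scores: confusion counts change only between distinct scores
  cum_tp <- cumsum(y == 1)
  cum_fp <- cumsum(y == 0)
  last_of_group <- c(diff(prob) != 0, TRUE)
  tp <- cum_tp[last_of_group]
  fp <- cum_fp[last_of_group]
  n_pos <- sum(y == 1)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Compute classification metrics
#'
#' Confusion counts at `threshold`, plus sensitivity, precision, F1, AUROC
#' and AUPRC. Requires both classes present (AUROC/AUPRC are undefined
#' otherwise).
#'
#' @param y_true Binary labels (0/1).
#' @param prob Predicted probabilities.
#' @param threshold Decision threshold, default 0.5.
#' @return One-row tibble with `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `precision`, `f1`, `auroc`, `auprc`.
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(0.9, 0.6, 0.4, 0.2))
#' @export
compute_metrics <- function(y_true, prob, threshold = 0.5) {
  y <- as.numeric(y_true)
  if (length(unique(y)) < 2) {
    abort_input("AUROC/AUPRC undefined with a single class in `y_true`")
  }
  pred <- as.numeric(prob >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  sens <- tp / (tp + fn)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  tibble(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sens, precision = prec, f1 = f1,
         auroc = auroc_rank(y, prob), auprc = auprc_step(y, prob))
}
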