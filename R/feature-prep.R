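# Structured-feature preprocessing: min-max scaling, one-hot encoding,
# missingness filtering, four-rule feature selection, and KNN imputation.
# All fit statistics come from training rows only; fitted transforms are
# frozen and reapplied to new rows without refitting (no leakage).

#' Min-max normalize continuous columns
#'
#' Scales each continuous column to `(x - min)/(max - min)` using statistics
#' from `fit_rows` only. Values outside the fitted range are not clipped
#' (a test value above the training max maps above 1). Constant columns map
#' to 0.
#'
#' @param table Data frame / tibble of features (a `patient_id` column, if
#'   present, is passed through untouched).
#' @param kinds Named character vector mapping column -> "continuous" /
#'   "categorical"; defaults to treating numeric columns as continuous.
#' @param fit_rows Integer row indices used to fit min/max (default: all).
#' @param fit Optional previously fitted statistics (tibble column/min/max);
#'   when supplied, `fit_rows` is ignored.
#' @return List with `table` (transformed tibble) and `fit` (tibble with
#'   columns `column`, `min`, `max`).
#' @export
minmax_normalize <- function(table, kinds = NULL, fit_rows = seq_len(nrow(table)),
                             fit = NULL) {
  table <- as_tibble(table)
  if (is.null(kinds)) {
    cand <- setdiff(names(table), "patient_id")
    kinds <- setNames(ifelse(purrr::map_lgl(table[cand], is.numeric),
                             "continuous", "categorical"), cand)
  }
  cont <- names(kinds)[kinds == "continuous"]
  if (is.null(fit)) {
    if (length(fit_rows) == 0) abort_input("`fit_rows` must be non-empty")
    fit <- purrr::map_dfr(cont, function(cn) {
      v <- table[[cn]][fit_rows]
      if (!is.numeric(v)) abort_input(sprintf("column `%s` is not numeric", cn))
      tibble(column = cn, min = suppressWarnings(min(v, na.rm = TRUE)),
             max = suppressWarnings(max(v, na.rm = TRUE)))
    })
  }
  for (i in seq_len(nrow(fit))) {
    cn <- fit$column[i]
    rng <- fit$max[i] - fit$min[i]
    if (!is.finite(rng) || rng == 0) {
      table[[cn]] <- ifelse(is.na(table[[cn]]), NA_real_, 0)
    } else {
      table[[cn]] <- (table[[cn]] - fit$min[i]) / rng
    }
  }
  list(table = table, fit = fit)
}

#' One-hot encode categorical columns
#'
#' Replaces each categorical column by one 0/1 indicator per level observed
#' in the fitting rows. A missing value yields missing indicators across the
#' whole block; a level unseen at fit time yields all-zero indicators with a
#' warning. The level -> column mapping is fitted once and frozen.
#'
#' @inheritParams minmax_normalize
#' @param fit Optional frozen level map (named list column -> levels).
#' @return List with `table` (tibble; categorical columns replaced by
#'   `col=level` indicator columns) and `fit` (the level map).
#' @export
one_hot <- function(table, kinds = NULL, fit_rows = seq_len(nrow(table)),
                    fit = NULL) {
  table <- as_tibble(table)
  if (is.null(kinds)) {
    cand <- setdiff(names(table), "patient_id")
    kinds <- setNames(ifelse(purrr::map_lgl(table[cand], is.numeric),
                             "continuous", "categorical"), cand)
  }
  cats <- names(kinds)[kinds == "categorical"]
  if (is.null(fit)) {
    fit <- purrr::map(setNames(cats, cats), function(cn) {
      lv <- sort(unique(stats::na.omit(as.character(table[[cn]][fit_rows]))))
      if (length(lv) == 0) {
        abort_input(sprintf("categorical column `%s` has no observed level", cn))
      }
      lv
    })
  }
  out <- table
  for (cn in names(fit)) {
    v <- as.character(out[[cn]])
    unseen <- !is.na(v) & !(v %in% fit[[cn]])
    if (any(unseen)) {
      warn(sprintf("column `%s`: %d value(s) at unseen level -> all-zero indicators",
                   cn, sum(unseen)))
    }
    block <- purrr::map(fit[[cn]], function(lv) {
      ind <- as.numeric(v == lv)
      ind[is.na(v)] <- NA_real_
      ind
    })
    names(block) <- paste0(cn, "=", fit[[cn]])
    pos <- match(cn, names(out))
    out <- dplyr::bind_cols(out[seq_len(pos - 1)], as_tibble(block),
                            out[seq_len(ncol(out)) > pos])
  }
  list(table = out, fit = fit)
}

#' Drop columns with high missingness
#'
#' Removes columns whose missing fraction is strictly over `max_missing`
#' (a column at exactly the threshold is kept).
#'
#' @param table Feature tibble (`patient_id` passed through).
#' @param max_missing Maximum tolerated missing fraction, default 0.30.
#' @param fit_rows Rows over which missingness is measured.
#' @return List with `table` (columns dropped) and `dropped` (tibble with
#'   `column`, `missing_fraction`).
#' @export
drop_high_missingness <- function(table, max_missing = 0.30,
                                  fit_rows = seq_len(nrow(table))) {
  table <- as_tibble(table)
  cols <- setdiff(names(table), "patient_id")
  frac <- purrr::map_dbl(table[cols], function(v) mean(is.na(v[fit_rows])))
  drop <- cols[frac > max_missing]
  list(
    table = table[setdiff(names(table), drop)],
    dropped = tibble(column = drop,
                     missing_fraction = unname(frac[drop]))
  )
}

# Selection-rule statistics. Chi-squared applies to binary (0/1 indicator)
# columns via a 2x2 contingency table against the label; ANOVA to continuous
# columns (one-way across the two label groups). All statistics use
# pairwise-complete observations (imputation happens after selection).
selection_stats <- function(v, y, kind, raw = NULL) {
  obs <- !is.na(v)
  vv <- v[obs]
  yy <- y[obs]
  variance <- if (!is.null(raw)) var(raw, na.rm = TRUE) else var(vv)
  pearson <- if (length(vv) > 2 && sd(vv) > 0 && sd(yy) > 0) {
    abs(cor(vv, yy))
  } else {
    0
  }
  is_binary <- kind != "continuous" || all(vv %in% c(0, 1))
  chi2_p <- NA_real_
  anova_p <- NA_real_
  if (is_binary && kind != "continuous") {
    tab <- table(factor(vv, levels = c(0, 1)), factor(yy, levels = c(0, 1)))
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      chi2_p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
  }
  if (kind == "continuous") {
    if (sd(vv) > 0 && length(unique(yy)) == 2) {
      fit <- lm(vv ~ factor(yy))
      an <- anova(fit)
      anova_p <- an$`Pr(>F)`[1]
      if (is.nan(anova_p)) anova_p <- 0  # zero residual variance: perfect separation
    }
  }
  c(variance = variance, pearson = pearson, chi2_p = chi2_p, anova_p = anova_p)
}

#' Four-rule feature selection
#'
#' Drops a column when it violates any applicable rule:
#' variance `< var_min` (continuous columns use pre-scaling variance, 0/1
#' indicators their own variance); absolute Pearson correlation with the
#' label `< cor_min`; chi-squared p-value `>= p_max` (indicator columns);
#' ANOVA p-value `>= p_max` (continuous columns). The report covers every
#' input column with all four statistics and the drop reasons.
#'
#' @param table Encoded/normalized feature tibble (`patient_id` optional).
#' @param labels Binary (0/1) label vector aligned to rows.
#' @param kinds Named vector, column -> "continuous"/"indicator"; indicator
#'   is assumed for columns not listed.
#' @param raw_variance Optional named vector of pre-scaling variances for
#'   continuous columns (used for the variance rule).
#' @param var_min,cor_min,p_max Rule thresholds (defaults 0.1, 0.01, 0.05).
#' @param fit_rows Rows used to compute every statistic.
#' @return List with `table` (kept columns) and `report` (tibble: `column`,
#'   `kind`, `variance`, `pearson`, `chi2_p`, `anova_p`, `kept`, `reasons`).
#' @export
select_features <- function(table, labels, kinds = NULL, raw_variance = NULL,
                            var_min = 0.1, cor_min = 0.01, p_max = 0.05,
                            fit_rows = seq_len(nrow(table))) {
  table <- as_tibble(table)
  cols <- setdiff(names(table), "patient_id")
  y <- as.numeric(labels)
  if (length(y) != nrow(table)) abort_input("`labels` must align to rows")
  if (var(y[fit_rows]) == 0) abort_input("labels have zero variance")
  if (is.null(kinds)) {
    kinds <- setNames(rep("indicator", length(cols)), cols)
    numc <- cols[purrr::map_lgl(table[cols], function(v)
      is.numeric(v) && !all(v %in% c(0, 1, NA)))]
    kinds[numc] <- "continuous"
  }
  report <- purrr::map_dfr(cols, function(cn) {
    kind <- unname(kinds[cn] %||% "indicator")
    if (is.na(kind)) kind <- "indicator"
    raw_for_var <- if (kind == "continuous" && !is.null(raw_variance) &&
                       cn %in% names(raw_variance)) raw_variance[[cn]] else NULL
    st <- selection_stats(table[[cn]][fit_rows], y[fit_rows], kind)
    if (!is.null(raw_for_var)) st["variance"] <- raw_for_var
    reasons <- character()
    if (is.na(st["variance"]) || st["variance"] < var_min) {
      reasons <- c(reasons, "low_variance")
    }
    if (st["pearson"] < cor_min) reasons <- c(reasons, "low_pearson")
    if (kind != "continuous" &&
        (is.na(st["chi2_p"]) || st["chi2_p"] >= p_max)) {
      reasons <- c(reasons, "chi2_ns")
    }
    if (kind == "continuous" &&
        (is.na(st["anova_p"]) || st["anova_p"] >= p_max)) {
      reasons <- c(reasons, "anova_ns")
    }
    tibble(column = cn, kind = kind,
           variance = unname(st["variance"]), pearson = unname(st["pearson"]),
           chi2_p = unname(st["chi2_p"]), anova_p = unname(st["anova_p"]),
           kept = length(reasons) == 0,
           reasons = paste(reasons, collapse = ";"))
  })
  keep <- report$column[report$kept]
  keep_cols <- intersect(names(table), c("patient_id", keep))
  list(table = table[keep_cols], report = report)
}

#' K-nearest-neighbor imputation
#'
#' Fills each missing cell with the mean of that column's values among the
#' `k` nearest rows, using Euclidean distance over mutually observed columns
#' normalized by the number of shared columns. Ties break on row index.
#' Neighbor candidates must have the target column observed; columns with
#' fewer than `k` observed values in the pool fall back to the column mean
#' with a warning. When `pool` is supplied (e.g. training rows), neighbors
#' are searched there instead of within `table` itself.
#'
#' @param table Numeric feature tibble/matrix (`patient_id` passed through).
#' @param k Number of neighbors, default 3.
#' @param pool Optional neighbor pool with identical columns.
#' @return Imputed tibble with the same shape as `table`.
#' @export
knn_impute <- function(table, k = 3, pool = NULL) {
  tbl <- as_tibble(table)
  id <- if ("patient_id" %in% names(tbl)) tbl["patient_id"] else NULL
  x <- as_feature_matrix(tbl)
  px <- if (is.null(pool)) x else as_feature_matrix(as_tibble(pool))
  if (!identical(colnames(px), colnames(x))) {
    abort_input("`pool` must have the same feature columns as `table`")
  }
  blank <- rowSums(!is.na(x)) == 0
  if (any(blank)) {
    # standalone contract: reject; with an external pool (applying a fitted
    # pipeline) fall back to pool column means for fully missing rows
    if (is.null(pool)) abort_input("a row has no observed value")
    warn(sprintf("%d row(s) with no observed value imputed to column means",
                 sum(blank)))
    x[blank, ] <- matrix(colMeans(px, na.rm = TRUE), sum(blank), ncol(x),
                         byrow = TRUE)
  }

  filled <- x
  col_warned <- character()
  pool_obs <- !is.na(px)
  for (i in seq_len(nrow(x))) {
    miss <- which(is.na(x[i, ]))
    if (length(miss) == 0) next
    obs_i <- !is.na(x[i, ])
    # distances from row i to every pool row over mutually observed columns,
    # normalized by the number of shared columns
    shared <- pool_obs & matrix(obs_i, nrow(px), ncol(px), byrow = TRUE)
    diff2 <- sweep(px, 2, x[i, ], `-`)^2
    diff2[!shared] <- 0
    ns <- rowSums(shared)
    d <- sqrt(rowSums(diff2) / pmax(ns, 1))
    d[ns == 0] <- Inf
    for (j in miss) {
      cand <- which(pool_obs[, j])
      if (is.null(pool)) cand <- setdiff(cand, i)
      if (length(cand) < k) {
        cm <- mean(px[, j], na.rm = TRUE)
        if (!(colnames(x)[j] %in% col_warned)) {
          warn(sprintf("column `%s` has fewer than %d observed values; using column mean",
                       colnames(x)[j], k))
          col_warned <- c(col_warned, colnames(x)[j])
        }
        filled[i, j] <- cm
        next
      }
      ord <- order(d[cand], cand)  # index tie-break
      nn <- cand[ord[seq_len(k)]]
      filled[i, j] <- mean(px[nn, j])
    }
  }
  out <- as_tibble(as.data.frame(filled))
  if (!is.null(id)) out <- dplyr::bind_cols(id, out)
  out
}

#' Fit the full feature-preparation pipeline
#'
#' Runs, in order: missingness filter, min-max normalization, one-hot
#' encoding, four-rule selection, and KNN imputation — fitting every
#' statistic on `fit_rows` only. The returned object reapplies the frozen
#' transforms to arbitrary rows via [predict()].
#'
#' @param features Feature tibble with a `patient_id` column.
#' @param labels Binary (0/1) labels aligned to `features` rows.
#' @param kinds Named vector column -> "continuous"/"categorical"; defaults
#'   from a `feature_meta` tibble via `setNames(meta$kind, meta$column)`.
#' @param fit_rows Training row indices.
#' @param max_missing,var_min,cor_min,p_max,k Stage parameters.
#' @return Object of class `feature_pipeline`.
#' @examples
#' cohort <- simulate_cohort(synth_config(n_patients = 80, seed = 3))
#' y <- as.numeric(cohort$truth$label == "RP")
#' fp <- fit_feature_pipeline(cohort$features, y,
#'   kinds = setNames(cohort$feature_meta$kind, cohort$feature_meta$column),
#'   fit_rows = 1:60)
#' head(predict(fp, cohort$features[61:80, ]))
#' @export
fit_feature_pipeline <- function(features, labels, kinds = NULL,
                                 fit_rows = seq_len(nrow(features)),
                                 max_missing = 0.30, var_min = 0.1,
                                 cor_min = 0.01, p_max = 0.05, k = 3) {
  features <- as_tibble(features)
  y <- as.numeric(labels)
  if (is.null(kinds)) {
    cand <- setdiff(names(features), "patient_id")
    kinds <- setNames(ifelse(purrr::map_lgl(features[cand], is.numeric),
                             "continuous", "categorical"), cand)
  }

  ms <- drop_high_missingness(features, max_missing, fit_rows)
  kinds <- kinds[intersect(names(kinds), names(ms$table))]

  raw_variance <- purrr::map_dbl(
    names(kinds)[kinds == "continuous"],
    function(cn) var(ms$table[[cn]][fit_rows], na.rm = TRUE))
  names(raw_variance) <- names(kinds)[kinds == "continuous"]

  mm <- minmax_normalize(ms$table, kinds, fit_rows)
  oh <- one_hot(mm$table, kinds, fit_rows)

  enc_kinds <- setNames(rep("indicator", 0), character())
  for (cn in names(kinds)) {
    if (kinds[cn] == "continuous") {
      enc_kinds[cn] <- "continuous"
    } else {
      for (lv in oh$fit[[cn]]) enc_kinds[paste0(cn, "=", lv)] <- "indicator"
    }
  }

  sel <- select_features(oh$table, y, kinds = enc_kinds,
                         raw_variance = raw_variance,
                         var_min = var_min, cor_min = cor_min, p_max = p_max,
                         fit_rows = fit_rows)

  train_pool <- sel$table[fit_rows, setdiff(names(sel$table), "patient_id"),
                          drop = FALSE]

  structure(
    list(
      kinds = kinds, missing_dropped = ms$dropped, minmax = mm$fit,
      levels = oh$fit, report = sel$report,
      kept = setdiff(names(sel$table), "patient_id"),
      train_pool = train_pool, k = k,
      params = list(max_missing = max_missing, var_min = var_min,
                    cor_min = cor_min, p_max = p_max)
    ),
    class = "feature_pipeline"
  )
}

#' Apply a fitted feature pipeline to new rows
#'
#' @param object A `feature_pipeline`.
#' @param newdata Feature tibble with the original raw columns.
#' @param ... Unused.
#' @return Fully transformed, imputed tibble (kept columns only, plus
#'   `patient_id` when present).
#' @export
predict.feature_pipeline <- function(object, newdata, ...) {
  tbl <- as_tibble(newdata)
  tbl <- tbl[setdiff(names(tbl), object$missing_dropped$column)]
  mm <- minmax_normalize(tbl, object$kinds, fit = object$minmax)
  oh <- one_hot(mm$table, object$kinds, fit = object$levels)
  keep <- intersect(names(oh$table), c("patient_id", object$kept))
  out <- oh$table[keep]
  knn_impute(out, k = object$k, pool = object$train_pool)
}

#' @export
print.feature_pipeline <- function(x, ...) {
  cat("<feature_pipeline>\n")
  cat("  dropped (missingness):", nrow(x$missing_dropped), "\n")
  cat("  encoded columns:", nrow(x$report), " kept:", length(x$kept), "\n")
  invisible(x)
}

#' @rdname fit_feature_pipeline
#' @param x A `feature_pipeline`.
#' @param ... Unused.
#' @method tidy feature_pipeline
#' @export
tidy.feature_pipeline <- function(x, ...) x$report
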