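# Class-imbalance upsampling by duplication of real minority rows: a hybrid
# of k-means-centroid candidates and cosine-similarity ranking, plus the
# standard comparators (random, similarity, dissimilarity, clustering).
# No synthetic interpolation is ever performed: every added row is an exact
# copy of an original minority row, carrying provenance.

#' Sampler configuration
#'
#' @param strategy One of `"default"` (no resampling), `"random"`,
#'   `"similarity"`, `"dissimilarity"`, `"clustering"`, `"scus"`.
#' @param p_nr Desired positive-to-negative ratio after sampling (default 1).
#' @param w_clu,w_sim Hybrid weights for the clustering- and similarity-based
#'   components; must sum to 1. Defaults 0.8/0.2.
#' @param seed Integer seed (k-means initialization, random duplication).
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(strategy = c("scus", "default", "random",
                                        "similarity", "dissimilarity",
                                        "clustering"),
                           p_nr = 1.0, w_clu = 0.8, w_sim = 1 - w_clu,
                           seed = 1L) {
  strategy <- match.arg(strategy)
  if (!isTRUE(all.equal(w_clu + w_sim, 1)) || w_clu < 0 || w_sim < 0) {
    abort_config("`w_clu` and `w_sim` must be non-negative and sum to 1")
  }
  if (p_nr <= 0) abort_config("`p_nr` must be positive")
  structure(list(strategy = strategy, p_nr = p_nr, w_clu = w_clu,
                 w_sim = w_sim, seed = as.integer(seed)),
            class = "sampler_config")
}

# Cosine similarity matrix between rows of a and rows of b.
cosine_matrix <- function(a, b) {
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  if (any(na == 0) || any(nb == 0)) {
    abort_input("cosine similarity undefined for zero-norm rows")
  }
  (a %*% t(b)) / outer(na, nb)
}

# Mean cosine similarity of each minority row to all majority rows, and the
# resulting ranking (descending for similarity, ascending for dissimilarity;
# ties broken by row index). Min-max-scaled data can contain exact-zero rows,
# for which cosine is undefined; `zero_norm = "rank_last"` drops zero-norm
# majority rows from the averaging and gives zero-norm minority rows the
# lowest possible mean similarity instead of failing.
similarity_ranking <- function(x_min, x_maj, descending = TRUE,
                               zero_norm = c("error", "rank_last")) {
  zero_norm <- match.arg(zero_norm)
  if (zero_norm == "error") {
    avg <- rowMeans(cosine_matrix(x_min, x_maj))
  } else {
    nmaj <- sqrt(rowSums(x_maj^2))
    x_maj <- x_maj[nmaj > 0, , drop = FALSE]
    if (nrow(x_maj) == 0) abort_input("all majority rows have zero norm")
    nmin <- sqrt(rowSums(x_min^2))
    avg <- rep(-Inf, nrow(x_min))
    if (any(nmin > 0)) {
      avg[nmin > 0] <- rowMeans(
        cosine_matrix(x_min[nmin > 0, , drop = FALSE], x_maj))
    }
  }
  ord <- if (descending) order(-avg, seq_along(avg)) else order(avg, seq_along(avg))
  list(avg = avg, order = ord)
}

#' Clustering-based upsampling candidates
#'
#' Fits `m = min(n_clu, nrow(x_min))` k-means clusters on the minority rows
#' (seeded, Lloyd iterations, 10 restarts) and takes, per cluster, the row
#' nearest its centroid (Euclidean, lowest-index tie-break) as a candidate.
#' Candidates are replicated cyclically up to `n_clu` rows.
#'
#' @param x_min Numeric matrix of minority rows.
#' @param n_clu Number of rows to produce.
#' @param seed Integer seed.
#' @return Integer vector of length `n_clu`: minority row indices to copy.
#' @export
cluster_upsample <- function(x_min, n_clu, seed = 1L) {
  if (!is.matrix(x_min)) x_min <- as.matrix(x_min)
  if (nrow(x_min) == 0) abort_input("`x_min` must be non-empty")
  if (n_clu < 0) abort_input("`n_clu` must be >= 0")
  if (n_clu == 0) return(integer(0))
  m <- min(n_clu, nrow(x_min))
  ux <- unique(x_min)
  m <- min(m, nrow(ux))
  with_seed(seed, {
    cl <- if (m == 1) {
      list(cluster = rep(1L, nrow(x_min)),
           centers = matrix(colMeans(x_min), nrow = 1))
    } else {
      fit <- NULL
      for (attempt in 1:25) {
        fit <- tryCatch(
          suppressWarnings(kmeans(x_min, centers = m, nstart = 10,
                                  iter.max = 100, algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit)) break
      }
      if (is.null(fit)) abort_input("k-means failed to initialize")
      fit
    }
    cand <- purrr::map_int(seq_len(m), function(j) {
      members <- which(cl$cluster == j)
      d <- sqrt(colSums((t(x_min[members, , drop = FALSE]) - cl$centers[j, ])^2))
      members[which.min(d)]  # which.min takes the first (lowest index) on ties
    })
    rep_len(cand, n_clu)
  })
}

#' Similarity-based upsampling selection
#'
#' Ranks minority rows by descending mean cosine similarity to the majority
#' class and duplicates the top-ranked rows, cycling through the ranked list
#' when more rows are needed than exist.
#'
#' @param x_min,x_maj Numeric matrices (no zero-norm rows).
#' @param n_sim Number of rows to produce.
#' @param descending Rank descending (similarity) or ascending
#'   (dissimilarity).
#' @param zero_norm `"error"` (default) rejects zero-norm rows, for which
#'   cosine similarity is undefined; `"rank_last"` treats zero-norm minority
#'   rows as least similar and ignores zero-norm majority rows (used by the
#'   pipeline, where min-max scaling can produce exact-zero rows).
#' @return Integer vector of length `n_sim`: minority row indices to copy.
#' @export
similarity_upsample <- function(x_min, x_maj, n_sim, descending = TRUE,
                                zero_norm = c("error", "rank_last")) {
  if (!is.matrix(x_min)) x_min <- as.matrix(x_min)
  if (!is.matrix(x_maj)) x_maj <- as.matrix(x_maj)
  if (n_sim < 0) abort_input("`n_sim` must be >= 0")
  if (n_sim == 0) return(integer(0))
  rk <- similarity_ranking(x_min, x_maj, descending, zero_norm)
  rep_len(rk$order, n_sim)
}

build_result <- function(x, y, add_idx, method, config) {
  min_idx <- which(y == 1)
  counts <- list(n_min = sum(y == 1), n_maj = sum(y == 0),
                 n_added = length(add_idx))
  if (length(add_idx) > 0) {
    x_new <- rbind(x, x[min_idx[add_idx], , drop = FALSE])
    y_new <- c(y, rep(1, length(add_idx)))
    prov <- tibble(row = nrow(x) + seq_along(add_idx),
                   source_row = min_idx[add_idx], method = method)
  } else {
    x_new <- x
    y_new <- y
    prov <- tibble(row = integer(), source_row = integer(),
                   method = character())
  }
  structure(list(x = x_new, y = y_new, provenance = prov,
                 counts = counts, config = config),
            class = "sampling_result")
}

#' Hybrid clustering/similarity upsampling (the SCUS strategy)
#'
#' Balances a binary training set to a positive-to-negative ratio `p_nr` by
#' duplicating real minority rows. The number of additional rows is
#' `N_desired = max(0, round(p_nr * n_maj) - n_min)`; `round(w_clu *
#' N_desired)` of them come from k-means-centroid candidates
#' ([cluster_upsample()]) and the remainder from cosine-similarity ranking
#' ([similarity_upsample()]), so the two components conserve the total
#' exactly.
#'
#' @param x Numeric feature matrix (or tibble) for all training rows.
#' @param y Binary labels (1 = minority/positive).
#' @param config A [sampler_config()]; `strategy` is ignored here.
#' @return A `sampling_result`: list with `x`, `y`, `provenance` (tibble:
#'   row, source_row, method), `counts`, `config`.
#' @examples
#' x <- matrix(runif(60), ncol = 2)
#' y <- rep(c(1, 0), c(5, 25))
#' res <- scus(x, y, sampler_config("scus", seed = 4))
#' res$counts
#' @export
scus <- function(x, y, config = sampler_config("scus")) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  n_min <- sum(y == 1)
  n_maj <- sum(y == 0)
  if (n_min < 1 || n_maj < 1) abort_input("both classes must be present")
  n_desired <- max(0, round(config$p_nr * n_maj) - n_min)
  n_clu <- round(config$w_clu * n_desired)
  n_sim <- n_desired - n_clu
  x_min <- x[y == 1, , drop = FALSE]
  x_maj <- x[y == 0, , drop = FALSE]
  idx_clu <- cluster_upsample(x_min, n_clu, seed = config$seed)
  idx_sim <- similarity_upsample(x_min, x_maj, n_sim, zero_norm = "rank_last")
  build_result(x, y, c(idx_clu, idx_sim),
               rep(c("clu", "sim"), c(n_clu, n_sim)), config)
}

#' Upsample a training set with a chosen strategy
#'
#' Dispatches to no-op (`default`), uniform random duplication (`random`),
#' single-method similarity / dissimilarity / clustering samplers, or the
#' hybrid [scus()] sampler. All strategies except `default` reach the target
#' ratio `p_nr` exactly (up to rounding) and only ever copy original
#' minority rows.
#'
#' @inheritParams scus
#' @param config A [sampler_config()] carrying the strategy.
#' @return A `sampling_result`.
#' @export
upsample <- function(x, y, config = sampler_config()) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  if (config$strategy == "default") {
    return(build_result(x, y, integer(0), character(0), config))
  }
  if (config$strategy == "scus") return(scus(x, y, config))
  n_min <- sum(y == 1)
  n_maj <- sum(y == 0)
  if (n_min < 1 || n_maj < 1) abort_input("both classes must be present")
  n_desired <- max(0, round(config$p_nr * n_maj) - n_min)
  x_min <- x[y == 1, , drop = FALSE]
  x_maj <- x[y == 0, , drop = FALSE]
  idx <- switch(
    config$strategy,
    random = with_seed(config$seed,
                       sample(seq_len(n_min), n_desired, replace = TRUE)),
    similarity = similarity_upsample(x_min, x_maj, n_desired,
                                     zero_norm = "rank_last"),
    dissimilarity = similarity_upsample(x_min, x_maj, n_desired,
                                        descending = FALSE,
                                        zero_norm = "rank_last"),
    clustering = cluster_upsample(x_min, n_desired, seed = config$seed),
    abort_config(sprintf("unknown strategy `%s`", config$strategy))
  )
  method <- switch(config$strategy, random = "random", similarity = "sim",
                   dissimilarity = "dissim", clustering = "clu")
  build_result(x, y, idx, rep(method, length(idx)), config)
}

#' @export
print.sampling_result <- function(x, ...) {
  cat("<sampling_result>", x$config$strategy, "\n")
  cat(sprintf("  %d minority + %d majority -> +%d duplicated rows\n",
              x$counts$n_min, x$counts$n_maj, x$counts$n_added))
  invisible(x)
}

#' @rdname upsample
#' @param ... Unused.
#' @method tidy sampling_result
#' @export
tidy.sampling_result <- function(x, ...) x$provenance
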