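test_that("cosine similarity matches hand values", {
  cm <- rapidprog:::cosine_matrix
  expect_equal(cm(matrix(c(1, 0), 1), matrix(c(1, 0), 1))[1, 1], 1)
  expect_equal(cm(matrix(c(1, 0), 1), matrix(c(0, 1), 1))[1, 1], 0)
  expect_equal(cm(matrix(c(1, 0), 1), matrix(c(1, 1), 1))[1, 1], 1 / sqrt(2))
  expect_equal(round(cm(matrix(c(1, 0), 1), matrix(c(1, 1), 1))[1, 1], 4),
               0.7071)
  expect_error(cm(matrix(c(0, 0), 1), matrix(c(1, 1), 1)),
               class = "rapidprog_input_error")
})

test_that("similarity selection prefers rows closest to the majority class", {
  x_maj <- matrix(c(1, 0,
                    1, 0.1), 2, byrow = TRUE)
  x_min <- matrix(c(1, 0,     # equals a majority row
                    0, 1),    # near-orthogonal to the majority
                  2, byrow = TRUE)
  expect_equal(similarity_upsample(x_min, x_maj, 1), 1L)
  expect_equal(similarity_upsample(x_min, x_maj, 1, descending = FALSE), 2L)
  expect_equal(similarity_upsample(x_min, x_maj, 0), integer(0))
  # cycling beyond the minority size
  expect_equal(similarity_upsample(x_min, x_maj, 5), c(1L, 2L, 1L, 2L, 1L))
})

test_that("cluster candidates sit nearest their centroids with index tie-break", {
  x_min <- matrix(c(0, 0,
                    0.1, 0,
                    5, 5), 3, byrow = TRUE)
  idx <- cluster_upsample(x_min, 2, seed = 1)
  expect_setequal(unique(idx), c(1L, 3L))  # (0,0) wins its cluster tie by index
  expect_equal(cluster_upsample(x_min, 0), integer(0))
  # cyclic replication when fewer distinct rows than needed
  two <- matrix(c(0, 0, 9, 9), 2, byrow = TRUE)
  expect_equal(length(cluster_upsample(two, 5, seed = 2)), 5)
  expect_setequal(unique(cluster_upsample(two, 5, seed = 2)), c(1L, 2L))
})

test_that("SCUS arithmetic reproduces the composite-group worked example", {
  set.seed(2)
  x <- matrix(runif(157 * 3) + 0.1, ncol = 3)
  y <- rep(c(1, 0), c(20, 137))
  res <- scus(x, y, sampler_config("scus", p_nr = 1, w_clu = 0.8, seed = 9))
  expect_equal(res$counts$n_added, 117)
  expect_equal(sum(res$provenance$method == "clu"), 94)
  expect_equal(sum(res$provenance$method == "sim"), 23)
  expect_equal(sum(res$y == 1), 137)
  expect_equal(sum(res$y == 0), 137)
})

test_that("SCUS no-ops when the ratio is already met and respects w boundaries", {
  x <- matrix(runif(40) + 0.1, ncol = 2)
  y <- rep(c(1, 0), each = 10)
  res <- scus(x, y, sampler_config("scus", seed = 1))
  expect_equal(res$counts$n_added, 0)
  expect_equal(res$x, x)

  y2 <- rep(c(1, 0), c(4, 16))
  r1 <- scus(x, y2, sampler_config("scus", w_clu = 1, seed = 1))
  expect_true(all(r1$provenance$method == "clu"))
  r0 <- scus(x, y2, sampler_config("scus", w_clu = 0, seed = 1))
  expect_true(all(r0$provenance$method == "sim"))
})

test_that("weight split conserves the total for any w_clu", {
  x <- matrix(runif(60) + 0.1, ncol = 2)
  y <- rep(c(1, 0), c(5, 25))
  for (w in c(0, 0.25, 0.5, 0.63, 0.8, 1)) {
    res <- scus(x, y, sampler_config("scus", w_clu = w, seed = 2))
    expect_equal(res$counts$n_added, 20)
    expect_equal(sum(res$provenance$method == "clu") +
                   sum(res$provenance$method == "sim"), 20)
    expect_equal(sum(res$provenance$method == "clu"), round(w * 20))
  }
})

test_that("baseline strategies behave per contract", {
  set.seed(5)
  x <- matrix(runif(60) + 0.1, ncol = 2)
  y <- rep(c(1, 0), c(6, 24))

  def <- upsample(x, y, sampler_config("default"))
  expect_equal(def$x, x)
  expect_equal(def$y, y)

  r1 <- upsample(x, y, sampler_config("random", seed = 8))
  r2 <- upsample(x, y, sampler_config("random", seed = 8))
  expect_identical(r1$provenance, r2$provenance)
  expect_equal(sum(r1$y == 1), 24)

  x_min <- x[y == 1, ]; x_maj <- x[y == 0, ]
  sim <- upsample(x, y, sampler_config("similarity"))
  dis <- upsample(x, y, sampler_config("dissimilarity"))
  avg <- rowMeans(rapidprog:::cosine_matrix(x_min, x_maj))
  expect_equal(sim$provenance$source_row[1], which.max(avg))
  expect_equal(dis$provenance$source_row[1], which.min(avg))
})

test_that("similarity/dissimilarity match brute force on 200 small instances", {
  set.seed(101)
  for (i in 1:200) {
    sizes <- sort(sample(2:8, 2, replace = TRUE))
    n_min <- sizes[1]
    n_maj <- sizes[2]
    d <- sample(2:4, 1)
    x_min <- matrix(runif(n_min * d) + 0.05, n_min)
    x_maj <- matrix(runif(n_maj * d) + 0.05, n_maj)
    avg <- bf_mean_cosine(x_min, x_maj)
    expect_equal(similarity_upsample(x_min, x_maj, n_min),
                 order(-avg, seq_len(n_min)))
    expect_equal(similarity_upsample(x_min, x_maj, n_min, descending = FALSE),
                 order(avg, seq_len(n_min)))
  }
})

test_that("every strategy only copies existing rows and hits the ratio", {
  set.seed(33)
  for (i in 1:20) {
    sizes <- sort(sample(2:8, 2, replace = TRUE))
    n_min <- sizes[1]
    n_maj <- sizes[2]
    x <- matrix(runif((n_min + n_maj) * 3) + 0.05, n_min + n_maj)
    y <- rep(c(1, 0), c(n_min, n_maj))
    for (s in c("random", "similarity", "dissimilarity", "clustering", "scus")) {
      res <- upsample(x, y, sampler_config(s, seed = i))
      # copy-only: no new distinct feature vectors
      before <- unique(apply(x, 1, paste, collapse = ","))
      after <- unique(apply(res$x, 1, paste, collapse = ","))
      expect_setequal(after, before)
      # ratio: positives == round(p_nr * majority)
      expect_equal(sum(res$y == 1), n_maj)
      # provenance points at true minority rows
      expect_true(all(res$y[res$provenance$source_row] == 1))
      expect_true(all(apply(
        res$x[res$provenance$row, , drop = FALSE] ==
          res$x[res$provenance$source_row, , drop = FALSE], 1, all)))
    }
  }
})

test_that("sampler config validates weights and ratio", {
  expect_error(sampler_config(w_clu = 0.8, w_sim = 0.5),
               class = "rapidprog_config_error")
  expect_error(sampler_config(p_nr = 0), class = "rapidprog_config_error")
  expect_error(upsample(matrix(1, 2), c(1, 1),
                        structure(list(strategy = "bogus"),
                                  class = "sampler_config")))
})
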