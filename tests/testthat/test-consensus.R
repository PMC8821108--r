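test_that("consensus matrix separates duplicated distant points perfectly", {
  # 20 samples: two exact copies of two far-apart points
  base <- cbind(matrix(-5, 5, 10), matrix(5, 5, 10))
  base <- base + matrix(rep(rnorm(5 * 2, sd = 0.01), each = 1), 5, 20)
  m <- toy_matrix(base)
  cm <- consensus_matrix(m, k = 2, reps = 100, subsample_frac = 0.8,
                         seed = 1)
  within <- cm$consensus[1:10, 1:10]
  between <- cm$consensus[1:10, 11:20]
  expect_true(all(within[cm$co_sample_counts[1:10, 1:10] > 0] == 1))
  expect_true(all(between[cm$co_sample_counts[1:10, 11:20] > 0] == 0))
})

test_that("consensus matrix obeys its structural invariants", {
  set.seed(7)
  m <- toy_matrix(matrix(rnorm(8 * 30), 8, 30))
  cm <- consensus_matrix(m, k = 3, reps = 50, seed = 2)$consensus
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 30))
  expect_true(all(cm >= 0 & cm <= 1))
})

test_that("no resampling means every pair co-sampled every rep", {
  set.seed(1)
  m <- toy_matrix(matrix(rnorm(5 * 12), 5, 12))
  cm <- consensus_matrix(m, k = 2, reps = 25, subsample_frac = 1, seed = 3)
  off <- cm$co_sample_counts[upper.tri(cm$co_sample_counts)]
  expect_true(all(off == 25))
})

test_that("consensus entries replay an independently coded loop on the same stream", {
  set.seed(5)
  m <- toy_matrix(matrix(c(rnorm(12, -2), rnorm(12, 2)), nrow = 4))
  # 4 genes x 6 samples (first 3 low, last 3 high)
  n <- ncol(m)
  reps <- 2000
  frac <- 0.8
  seed <- 17
  k <- 2
  nstart <- 3
  cm <- consensus_matrix(m, k = k, reps = reps, subsample_frac = frac,
                         seed = seed, nstart = nstart)
  # independent bookkeeping over the documented RNG stream: per rep,
  # sample.int then stats::kmeans on z-scored, transposed data
  z <- (m - rowMeans(m)) / apply(m, 1, sd)
  x <- t(z)
  mm <- ceiling(frac * n)
  co_clu <- matrix(0, n, n)
  co_smp <- matrix(0, n, n)
  set.seed(seed)
  for (r in seq_len(reps)) {
    idx <- sample.int(n, mm)
    km <- stats::kmeans(x[idx, , drop = FALSE], centers = k,
                        nstart = nstart, iter.max = 50L)
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        co_smp[idx[a], idx[b]] <- co_smp[idx[a], idx[b]] + 1
        if (km$cluster[a] == km$cluster[b]) {
          co_clu[idx[a], idx[b]] <- co_clu[idx[a], idx[b]] + 1
        }
      }
    }
  }
  expected <- ifelse(co_smp > 0, co_clu / co_smp, 0)
  diag(expected) <- 1
  dimnames(expected) <- dimnames(cm$consensus)
  expect_equal(cm$consensus, expected, tolerance = 1e-12)
})

test_that("final assignments recover exact block structure and ignore order", {
  blocks <- rep(1:3, times = c(4, 5, 6))
  cons <- outer(blocks, blocks, "==") * 1
  diag(cons) <- 1
  dimnames(cons) <- list(sprintf("s%02d", 1:15), sprintf("s%02d", 1:15))
  asg <- final_assignments(cons, 3)
  expect_equal(adjusted_rand_index(asg$cluster, blocks), 1)

  perm <- sample(15)
  asg2 <- final_assignments(cons[perm, perm], 3)
  merged <- merge(asg, asg2, by = "sample_id")
  expect_equal(adjusted_rand_index(merged$cluster.x, merged$cluster.y), 1)

  expect_error(final_assignments(cons, 16), "exceed")
})

test_that("model selection recovers three patterns and flags null structure", {
  co <- reference_cohort(seed = 2, pattern_shift = 3)
  cc <- consensus_cluster(co$expression, attr(co, "regulator_genes"),
                          k_range = 2:6, reps = 150, seed = 4)
  expect_equal(cc$chosen_k, 3L)
  ari <- adjusted_rand_index(cc$assignments$cluster, co$truth$pattern)
  expect_gte(ari, 0.9)

  # single Gaussian blob: no crisp structure, high PAC flagged
  set.seed(9)
  blob <- toy_matrix(matrix(rnorm(10 * 40), 10, 40))
  expect_message(
    cc0 <- consensus_cluster(blob, k_range = 2:5, reps = 100, seed = 6),
    "PAC"
  )
  expect_gt(min(cc0$metrics$pac), 0.2)

  # degenerate single-k range
  expect_warning(k1 <- select_k(tibble::tibble(k = 4L, area = 1, pac = 0)),
                 "single")
  expect_identical(k1, 4L)
})

test_that("adjusted Rand index matches the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(3)
  for (i in 1:10) {
    a <- sample(1:4, 30, TRUE)
    b <- sample(1:3, 30, TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(rep(1:3, 5), rep(1:3, 5)), 1)
})

test_that("panel handling warns on absent and zero-variance genes", {
  set.seed(1)
  m <- toy_matrix(rbind(matrix(rnorm(40), 2, 20), 0))
  expect_warning(
    expect_warning(
      consensus_matrix(m, panel = c(rownames(m), "missing"), k = 2,
                       reps = 10, seed = 1),
      "absent"),
    "zero-variance")
  expect_error(consensus_matrix(m[, 1:3], panel = rownames(m)[1:2], k = 2,
                                reps = 5, seed = 1))
})
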