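test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-14)
    # monotone in sorted-p order, bounded by 1, >= p
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-14))
    expect_true(all(adj <= 1 & adj >= p - 1e-14))
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("moderated t reduces to the ordinary pooled t when d0 = 0", {
  set.seed(22)
  m <- toy_matrix(matrix(rnorm(100 * 12), 100, 12))
  lab <- rep(c("A", "B"), each = 6)
  de <- moderated_de(m, lab, d0_override = 0)
  deA <- de[de$contrast == "A_vs_rest", ]
  plain <- apply(m, 1, function(r)
    t.test(r[1:6], r[7:12], var.equal = TRUE)$statistic)
  expect_equal(deA$t_mod, unname(plain), tolerance = 1e-10)
})

test_that("a gene identical across groups is a perfect null", {
  set.seed(23)
  m <- toy_matrix(matrix(rnorm(20 * 10), 20, 10))
  m[1, ] <- rep(c(1, 2, 3, 4, 5), 2)
  lab <- rep(c("A", "B"), times = 5)
  de <- suppressWarnings(moderated_de(m, lab))  # homoscedastic: d0 -> 0
  null_rows <- de[de$gene == "g01", ]
  expect_equal(null_rows$log2_fc, rep(0, 2))
  expect_equal(null_rows$p, rep(1, 2))
})

test_that("shifted genes dominate the ranking and match a shrinkage oracle", {
  set.seed(24)
  n_genes <- 200
  m <- toy_matrix(matrix(rnorm(n_genes * 40), n_genes, 40))
  m[1:20, 21:40] <- m[1:20, 21:40] + 2
  lab <- rep(c("A", "B"), each = 20)
  de <- moderated_de(m, lab)
  deB <- de[de$contrast == "B_vs_rest", ]
  top20 <- deB$gene[order(deB$adj_p, deB$p)][1:20]
  expect_setequal(top20, sprintf("g%02d", 1:20))

  # independently coded ordinary-t + shrinkage oracle: same ranking
  v1 <- apply(m[, 1:20], 1, var)
  v2 <- apply(m[, 21:40], 1, var)
  s2 <- (19 * v1 + 19 * v2) / 38
  fc <- rowMeans(m[, 21:40]) - rowMeans(m[, 1:20])
  # moment-match a scaled inverse chi-square prior on log s2
  e <- log(s2) - digamma(19) + log(19)
  excess <- var(e) - trigamma(19)
  d0 <- 2 * limma::trigammaInverse(excess)
  s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  t_or <- fc / sqrt(((d0 * s0 + 38 * s2) / (d0 + 38)) * (1 / 20 + 1 / 20))
  expect_equal(deB$t_mod, unname(t_or), tolerance = 1e-8)
})

test_that("moderated DE ignores sample and gene order", {
  set.seed(25)
  m <- toy_matrix(matrix(rnorm(50 * 18), 50, 18))
  lab <- rep(c("A", "B", "C"), each = 6)
  de <- suppressWarnings(moderated_de(m, lab))
  ps <- sample(ncol(m))
  pg <- sample(nrow(m))
  de2 <- suppressWarnings(moderated_de(m[pg, ps], lab[ps]))
  merged <- merge(de, de2, by = c("gene", "contrast"))
  expect_equal(merged$t_mod.x, merged$t_mod.y, tolerance = 1e-10)
  expect_equal(merged$adj_p.x, merged$adj_p.y, tolerance = 1e-10)
})

test_that("DEG selection applies strict dual thresholds over any contrast", {
  tbl <- tibble::tibble(
    gene = c("keep", "fc_fails", "p_fails", "neg_fc"),
    contrast = "A_vs_rest",
    log2_fc = c(log2(1.6), log2(1.4), log2(3), -log2(1.7)),
    t_mod = 1, p = c(1e-4, 1e-4, 1e-4, 1e-4),
    adj_p = c(5e-4, 5e-4, 0.01, 5e-4))
  expect_setequal(select_degs(tbl, 1.5, 0.001), c("keep", "neg_fc"))

  set.seed(26)
  rand <- tibble::tibble(gene = sprintf("g%03d", 1:300),
                         contrast = sample(c("A", "B"), 300, TRUE),
                         log2_fc = rnorm(300),
                         t_mod = 0,
                         p = runif(300),
                         adj_p = runif(300))
  got <- select_degs(rand, 1.5, 0.05)
  want <- unique(rand$gene[rand$adj_p < 0.05 &
                             abs(rand$log2_fc) > log2(1.5)])
  expect_identical(got, want)
})

test_that("group size preconditions are enforced", {
  m <- toy_matrix(matrix(rnorm(10 * 5), 10, 5))
  expect_error(moderated_de(m, c("A", "A", "A", "A", "B")), "fewer than 2")
  expect_error(moderated_de(m, rep("A", 5)), "2 groups")
})
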