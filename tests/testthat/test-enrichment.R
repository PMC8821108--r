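test_that("ssGSEA matches the brute-force running sum on toy cases", {
  # 3-gene set occupying the top 3 of 10 ranks, alpha = 0: maximal ES
  vals <- 10:1
  m <- toy_matrix(matrix(vals, ncol = 1), genes = sprintf("g%02d", 1:10))
  top_set <- list(top = c("g01", "g02", "g03"))
  es <- ssgsea_score(m, top_set, alpha = 0)$score
  expect_equal(es, oracle_ssgsea(m[, 1], rownames(m), top_set$top, 0))
  # no other placement of a 3-gene set scores higher
  other <- combn(rownames(m), 3)
  all_es <- apply(other, 2, function(g)
    oracle_ssgsea(m[, 1], rownames(m), g, 0))
  expect_equal(es, max(all_es))

  # uniformly interleaved set on an 8-gene toy
  m8 <- toy_matrix(matrix(8:1, ncol = 1), genes = sprintf("g%d", 1:8))
  inter <- c("g1", "g3", "g5", "g7")
  es8 <- ssgsea_score(m8, list(s = inter), alpha = 0)$score
  expect_equal(es8, oracle_ssgsea(m8[, 1], rownames(m8), inter, 0),
               tolerance = 1e-12)
})

test_that("ssGSEA equals the oracle on random instances across alpha", {
  set.seed(11)
  for (rep in 1:25) {
    G <- sample(10:50, 1)
    S <- sample(2:5, 1)
    m <- toy_matrix(matrix(rnorm(G * S), G, S))
    set_genes <- sample(rownames(m), sample(2:(G - 2), 1))
    for (alpha in c(0, 0.25, 1)) {
      got <- ssgsea_score(m, list(gs = set_genes), alpha = alpha)
      want <- vapply(seq_len(S), function(s)
        oracle_ssgsea(m[, s], rownames(m), set_genes, alpha), numeric(1))
      expect_equal(got$score, want, tolerance = 1e-10)
    }
  }
})

test_that("ssGSEA is rank-invariant and monotone in set-gene position", {
  set.seed(12)
  m <- toy_matrix(matrix(rnorm(30), 15, 2))
  gs <- list(s = rownames(m)[c(2, 5, 9)])
  base <- ssgsea_score(m, gs, alpha = 0.25)$score
  m2 <- m
  m2[, 1] <- m2[, 1] + 100   # constant shift: ranks unchanged
  shifted <- ssgsea_score(m2, gs, alpha = 0.25)$score
  expect_equal(shifted, base)

  # swapping a set gene one rank upward never decreases ES at alpha = 0
  vals <- sort(rnorm(12), decreasing = TRUE)
  genes <- sprintf("g%02d", 1:12)
  for (pos in c(4, 7, 10)) {
    set_genes <- genes[c(pos, 12)]
    m_lo <- toy_matrix(matrix(vals, ncol = 1), genes = genes)
    swapped <- genes
    swapped[c(pos - 1, pos)] <- swapped[c(pos, pos - 1)]
    m_hi <- toy_matrix(matrix(vals, ncol = 1), genes = swapped)
    es_lo <- ssgsea_score(m_lo, list(s = set_genes), alpha = 0)$score
    es_hi <- ssgsea_score(m_hi, list(s = set_genes), alpha = 0)$score
    expect_gte(es_hi, es_lo)
  }
})

test_that("ssGSEA rejects empty and exhaustive sets", {
  m <- toy_matrix(matrix(rnorm(20), 10, 2))
  expect_error(suppressWarnings(ssgsea_score(m, list(bad = c("nope1", "nope2")))),
               "bad")
  expect_error(ssgsea_score(m, list(all = rownames(m))), "every gene")
  expect_warning(ssgsea_score(m, list(s = c(rownames(m)[1:2], "nope"))),
                 "absent")
})

test_that("score normalization rescales per set and is idempotent", {
  tbl <- tibble::tibble(set = rep(c("a", "b"), each = 3),
                        sample_id = rep(c("s1", "s2", "s3"), 2),
                        score = c(2, 4, 6, 5, 5, 5))
  expect_warning(norm <- normalize_scores(tbl), "constant")
  expect_equal(norm$score[norm$set == "a"], c(0, 0.5, 1))
  expect_equal(norm$score[norm$set == "b"], c(0, 0, 0))
  norm2 <- suppressWarnings(normalize_scores(norm))
  expect_equal(norm2$score, norm$score)
})

test_that("hypergeometric ORA matches closed forms and exact sums", {
  universe <- sprintf("u%02d", 1:20)
  sets <- list(hit = universe[1:5])
  res <- ora_hypergeom(universe[1:5], sets, universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)

  # zero overlap is a certain event
  res0 <- ora_hypergeom(universe[6:10], list(s = universe[1:5]), universe)
  expect_equal(res0$p, 1)

  # query = universe: p = 1
  resF <- ora_hypergeom(universe, list(s = universe[1:7]), universe)
  expect_equal(resF$overlap, 7L)
  expect_equal(resF$p, 1)

  # random instances vs direct combinatorial summation (universe <= 25)
  set.seed(13)
  for (i in 1:20) {
    N <- sample(10:25, 1)
    uni <- sprintf("x%02d", seq_len(N))
    st <- sample(uni, sample(2:(N - 1), 1))
    qu <- sample(uni, sample(2:(N - 1), 1))
    got <- ora_hypergeom(qu, list(s = st), uni)
    ov <- length(intersect(qu, st))
    want <- if (ov == 0) 1 else
      oracle_hyper_upper(ov, length(st), N, length(qu))
    expect_equal(got$p, want, tolerance = 1e-12)
    expect_true(got$p > 0 && got$p <= 1)
  }

  expect_warning(ora_hypergeom(c(universe[1], "alien"), sets, universe),
                 "outside")
  expect_error(suppressWarnings(ora_hypergeom("alien", sets, universe)))
})
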