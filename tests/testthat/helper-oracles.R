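# Independent reference implementations used as oracles.  These are kept
# deliberately naive (explicit loops, direct formulas) and never share code
# with the package internals they check.

# ssGSEA running sum, walked position by position down the ranking.
oracle_ssgsea <- function(values, gene_ids, set_genes, alpha) {
  G <- length(values)
  ord <- order(-values, gene_ids)  # value desc, id asc: the documented rule
  ranked_ids <- gene_ids[ord]
  ranks <- G:1
  in_set <- ranked_ids %in% set_genes
  w <- abs(ranks)^alpha
  w_sum <- sum(w[in_set])
  n_out <- G - sum(in_set)
  p_in <- 0
  p_out <- 0
  es <- 0
  for (j in seq_len(G)) {
    if (in_set[j]) p_in <- p_in + w[j] / w_sum
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  es
}

# BH step-up from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- pmin(1, sorted * m / seq_len(m))
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-group log-rank O/E/V tabulation, straight from the formulas.
oracle_logrank2 <- function(time, event, in_group) {
  death_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (dt in death_times) {
    risk <- time >= dt
    n_tot <- sum(risk)
    n_1 <- sum(risk & in_group)
    d_tot <- sum(time == dt & event == 1)
    d_1 <- sum(time == dt & event == 1 & in_group)
    o_minus_e <- o_minus_e + (d_1 - d_tot * n_1 / n_tot)
    if (n_tot > 1) {
      v <- v + d_tot * (n_1 / n_tot) * (n_tot - n_1) / n_tot *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  list(oe = o_minus_e, v = v, chi2 = o_minus_e^2 / v)
}

# Efron partial log-likelihood for a single covariate, written from the
# textbook formula (no shared code with the fitter).
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (dt in sort(unique(time[event == 1]))) {
    dead <- which(time == dt & event == 1)
    risk <- which(time >= dt)
    d <- length(dead)
    s_risk <- sum(exp(beta * x[risk]))
    s_dead <- sum(exp(beta * x[dead]))
    ll <- ll + sum(beta * x[dead])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(s_risk - (l / d) * s_dead)
    }
  }
  ll
}

# All permutations of seq_len(n), rows of a matrix (n <= 7 in tests).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Exact two-sided Spearman permutation p by full enumeration.
oracle_spearman_exact <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rs_obs <- cor(rx, ry)
  perms <- all_permutations(n)
  rs_all <- apply(perms, 1, function(pm) cor(rx, ry[pm]))
  mean(abs(rs_all) >= abs(rs_obs) - 1e-9)
}

# Pearson chi-square from the closed form sum((O - E)^2 / E).
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Upper-tail hypergeometric by direct combinatorial summation.
oracle_hyper_upper <- function(overlap, set_size, universe, draws) {
  k_max <- min(set_size, draws)
  if (overlap > k_max) return(0)
  sum(vapply(overlap:k_max, function(k) {
    choose(set_size, k) * choose(universe - set_size, draws - k) /
      choose(universe, draws)
  }, numeric(1)))
}

# Small reference cohort shared across tests.
reference_cohort <- function(seed = 1L, ...) {
  simulate_cohort(cohort_config(seed = seed, ...))
}

# Toy expression matrix with named genes/samples.
toy_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# Write a cohort plus gene sets and drug tables to a temp dir, return paths.
pipeline_fixture <- function(dir, seed = 11L, with_drugs = TRUE,
                             n_batches = 1L) {
  co <- simulate_cohort(cohort_config(seed = seed, n_batches = n_batches))
  drugs <- if (with_drugs) {
    simulate_drug_response(co$truth, n_drugs = 30L, n_true = 6L,
                           rho_true = 0.5, seed = seed + 1L)
  } else NULL
  write_cohort(co, dir, drugs = drugs)
  phe <- attr(co, "phenotype_genes")
  noi <- attr(co, "noise_genes")
  sets <- list(PATTERN_UP = phe[1:25],
               BYSTANDER_A = noi[1:20],
               BYSTANDER_B = noi[21:40])
  write_gmt(sets, file.path(dir, "sets.gmt"))
  write_gmt(list(MESENCHYMAL = phe[26:45], EPITHELIAL = noi[41:60]),
            file.path(dir, "emt.gmt"))
  list(cohort = co, dir = dir)
}

pipeline_fixture_config <- function(dir, reps = 200L, seed = 5L,
                                    with_drugs = TRUE) {
  pipeline_config(
    expression = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    regulators = file.path(dir, "regulators.txt"),
    gene_sets_gmt = file.path(dir, "sets.gmt"),
    emt_gmt = file.path(dir, "emt.gmt"),
    drug_auc = if (with_drugs) file.path(dir, "drug_auc.tsv") else NULL,
    drug_annotation = if (with_drugs)
      file.path(dir, "drug_annotation.tsv") else NULL,
    reps = reps, seed = seed)
}
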