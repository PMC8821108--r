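#' Configuration for a synthetic cohort
#'
#' The generator emulates the latent structure the analysis assumes: a
#' regulator panel whose expression separates three activity patterns
#' (A, B, C), downstream phenotype genes co-regulated with the patterns,
#' survival hazard increasing with a per-sample latent score, and pure
#' noise genes.  Pattern means are ordered A < C < B on the expression
#' scale, mirroring the observation that the aggressive pattern carries
#' the highest regulator expression.
#'
#' @param n_per_pattern Integer vector of length 3: samples in patterns
#'   A, B, C.
#' @param n_regulators Regulator-panel size; 36 by default, the size of
#'   the curated histone-acetylation writer/eraser/reader panel.
#' @param n_phenotype_genes Downstream genes co-regulated with the
#'   patterns (candidate signature genes).
#' @param n_noise_genes Genes independent of everything.
#' @param pattern_shift Separation, in within-pattern SD units, between
#'   adjacent pattern means (A at -shift, C at 0, B at +shift).
#' @param hazard_coef Log-hazard increase per SD of the latent score.
#' @param baseline_hazard Exponential baseline hazard rate.
#' @param censor_rate Target fraction of censored samples, in [0, 1).
#' @param n_batches Number of batches samples are assigned to,
#'   independently of pattern.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_pattern = c(30L, 30L, 60L),
                          n_regulators = 36L,
                          n_phenotype_genes = 120L,
                          n_noise_genes = 200L,
                          pattern_shift = 2.5,
                          hazard_coef = 0.7,
                          baseline_hazard = 0.1,
                          censor_rate = 0.3,
                          n_batches = 1L,
                          seed = 1L) {
  stopifnot(length(n_per_pattern) == 3L, all(n_per_pattern >= 1L),
            n_regulators >= 1L, n_phenotype_genes >= 1L,
            n_noise_genes >= 0L, pattern_shift >= 0,
            baseline_hazard > 0, censor_rate >= 0, censor_rate < 1,
            n_batches >= 1L)
  structure(list(n_per_pattern = as.integer(n_per_pattern),
                 n_regulators = as.integer(n_regulators),
                 n_phenotype_genes = as.integer(n_phenotype_genes),
                 n_noise_genes = as.integer(n_noise_genes),
                 pattern_shift = pattern_shift,
                 hazard_coef = hazard_coef,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 n_batches = as.integer(n_batches),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a cohort with known pattern structure
#'
#' Regulator and phenotype genes are drawn Normal(mu_pattern, 1) with
#' pattern means -shift (A), 0 (C), +shift (B); noise genes Normal(0, 1).
#' The expression scale is directly log2-like: every downstream statistic
#' in the pipeline is rank- or z-based, so generating counts first would
#' add machinery without changing any tested behavior.
#'
#' The per-sample latent score is the standardized mean of the
#' phenotype-gene expression.  Survival times are Exponential with hazard
#' `baseline_hazard * exp(hazard_coef * latent)` — the simplest generator
#' consistent with proportional hazards, which is all the downstream
#' analysis assumes.  Censoring is independent Uniform(0, c) with c solved
#' numerically so the expected censored fraction equals `censor_rate`
#' (non-informative by construction).
#'
#' @param cfg A [cohort_config()].
#' @return A list with elements `expression` (genes x samples matrix,
#'   log2-like scale), `clinical` (tibble: sample_id, os_time, os_event,
#'   batch), and `truth` (tibble: sample_id, pattern, latent_score) plus
#'   attributes `regulator_genes`, `phenotype_genes`, `noise_genes`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- sum(cfg$n_per_pattern)
  g <- cfg$n_regulators + cfg$n_phenotype_genes + cfg$n_noise_genes
  if (g < 2L) stop("need at least 2 genes in total")
  if (n < 4L) stop("need at least 4 samples in total")
  withr_seed <- cfg$seed
  old <- .Random.seed_exists()
  set.seed(withr_seed)
  on.exit(.Random.seed_restore(old), add = TRUE)

  pattern <- rep(c("A", "B", "C"), times = cfg$n_per_pattern)
  mu <- c(A = -cfg$pattern_shift, B = cfg$pattern_shift, C = 0)[pattern]

  reg_genes <- sprintf("REG%02d", seq_len(cfg$n_regulators))
  phe_genes <- sprintf("PHE%03d", seq_len(cfg$n_phenotype_genes))
  noi_genes <- if (cfg$n_noise_genes > 0L) {
    sprintf("NOI%03d", seq_len(cfg$n_noise_genes))
  } else character(0)
  sample_ids <- sprintf("S%03d", seq_len(n))

  n_struct <- cfg$n_regulators + cfg$n_phenotype_genes
  structured <- matrix(stats::rnorm(n_struct * n, mean = rep(mu, each = n_struct)),
                       nrow = n_struct, ncol = n)
  noise <- if (cfg$n_noise_genes > 0L) {
    matrix(stats::rnorm(cfg$n_noise_genes * n), nrow = cfg$n_noise_genes)
  } else matrix(numeric(0), nrow = 0L, ncol = n)
  expr <- rbind(structured, noise)
  dimnames(expr) <- list(c(reg_genes, phe_genes, noi_genes), sample_ids)

  latent_raw <- colMeans(expr[phe_genes, , drop = FALSE])
  latent <- as.numeric(scale(latent_raw))

  rate <- cfg$baseline_hazard * exp(cfg$hazard_coef * latent)
  t_event <- stats::rexp(n, rate = rate)
  if (cfg$censor_rate > 0) {
    cmax <- .solve_censor_bound(rate, cfg$censor_rate)
    t_cens <- stats::runif(n, 0, cmax)
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)
  } else {
    os_time <- t_event
    os_event <- rep(1L, n)
  }
  os_time <- pmax(os_time, .Machine$double.eps)

  batch <- if (cfg$n_batches > 1L) {
    sprintf("batch%d", sample(rep_len(seq_len(cfg$n_batches), n)))
  } else rep("batch1", n)

  clinical <- tibble::tibble(sample_id = sample_ids,
                             os_time = os_time,
                             os_event = os_event,
                             batch = batch)
  truth <- tibble::tibble(sample_id = sample_ids,
                          pattern = pattern,
                          latent_score = latent)
  out <- list(expression = expr, clinical = clinical, truth = truth)
  attr(out, "regulator_genes") <- reg_genes
  attr(out, "phenotype_genes") <- phe_genes
  attr(out, "noise_genes") <- noi_genes
  attr(out, "config") <- cfg
  out
}

# Expected censored fraction for T ~ Exp(rate_i), C ~ Unif(0, cmax):
# P(C < T | rate) = (1 - exp(-rate * cmax)) / (rate * cmax).
.solve_censor_bound <- function(rate, target) {
  f <- function(cmax) mean((1 - exp(-rate * cmax)) / (rate * cmax)) - target
  # f is decreasing in cmax, -> 1 as cmax -> 0 and -> 0 as cmax -> Inf
  stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Simulate a sample-by-drug AUC table correlated with a latent score
#'
#' `n_true` drug columns are generated via a Gaussian copula so their
#' population Spearman correlation with the latent score is approximately
#' `rho_true`, with alternating sign across the true columns; the
#' remaining columns are independent Normal noise.  Higher AUC is read as
#' greater resistance throughout the package.
#'
#' @param truth Truth tibble from [simulate_cohort()] (needs
#'   `sample_id`, `latent_score`).
#' @param n_drugs Total number of drug columns.
#' @param n_true Number of columns truly correlated with the score.
#' @param rho_true Target population Spearman correlation, |rho| < 1.
#' @param seed Integer seed.
#' @return A list with `auc` (samples x drugs matrix), `annotation`
#'   (tibble: drug, pathway) and `true_drugs` (tibble: drug, true_rho).
#' @export
simulate_drug_response <- function(truth, n_drugs = 50L, n_true = 10L,
                                   rho_true = 0.5, seed = 1L) {
  stopifnot(n_true >= 0L, abs(rho_true) < 1)
  if (n_true > n_drugs) stop("n_true cannot exceed n_drugs")
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(.Random.seed_restore(old), add = TRUE)

  n <- nrow(truth)
  # normal scores of the latent ranking: the copula's shared gaussian
  z <- stats::qnorm(rank(truth$latent_score, ties.method = "average") / (n + 1))
  z <- as.numeric(scale(z))
  drugs <- sprintf("drug%03d", seq_len(n_drugs))
  auc <- matrix(NA_real_, nrow = n, ncol = n_drugs,
                dimnames = list(truth$sample_id, drugs))
  true_rho <- numeric(0)
  if (n_true > 0L) {
    signs <- rep_len(c(1, -1), n_true)
    # pearson correlation in gaussian space giving spearman rho_true
    r_pearson <- 2 * sin(pi * rho_true / 6)
    for (j in seq_len(n_true)) {
      eps <- stats::rnorm(n)
      auc[, j] <- signs[j] * (r_pearson * z + sqrt(1 - r_pearson^2) * eps)
    }
    true_rho <- signs * rho_true
  }
  if (n_true < n_drugs) {
    auc[, (n_true + 1L):n_drugs] <-
      stats::rnorm(n * (n_drugs - n_true))
  }
  pathways <- rep_len(c("PI3K/MTOR", "ERK MAPK", "RTK signaling",
                        "Cell cycle", "Chromatin histone acetylation",
                        "Apoptosis regulation", "WNT signaling",
                        "Genome integrity", "Metabolism", "Other"),
                      n_drugs)
  list(auc = auc,
       annotation = tibble::tibble(drug = drugs, pathway = pathways),
       true_drugs = tibble::tibble(drug = drugs[seq_len(n_true)],
                                   true_rho = true_rho))
}

# save/restore .Random.seed so simulators do not disturb the caller's stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Writes `expression.tsv`, `clinical.tsv`, `truth.tsv` and, when a drug
#' simulation is supplied, `drug_auc.tsv` and `drug_annotation.tsv`, plus
#' `regulators.txt` (the panel gene list, one id per line).
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param drugs Optional result of [simulate_drug_response()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, drugs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(attr(cohort, "regulator_genes"),
             file.path(dir, "regulators.txt"))
  if (!is.null(drugs)) {
    df <- data.frame(sample_id = rownames(drugs$auc), drugs$auc,
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, "drug_auc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(drugs$annotation,
                       file.path(dir, "drug_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
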