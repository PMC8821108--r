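#' Spearman rank correlation with exact small-sample p-value
#'
#' `rs` is the Pearson correlation of mid-ranks.  For n > 10 the
#' two-sided p-value uses the t approximation
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` on n - 2 degrees of freedom;
#' for n <= 10 it is computed exactly by enumerating all n!
#' permutations (compiled enumeration), counting those at least as
#' extreme as the observed |rs|.
#'
#' @param x,y Numeric vectors of equal length >= 3; neither constant.
#' @return Tibble: `rs`, `p`, `n`, `method` ("exact" or "t-approx").
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("constant vector: Spearman correlation undefined")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rs <- stats::cor(rx, ry)
  if (n <= 10L) {
    center <- n * mean(rx) * mean(ry)
    s_obs <- sum(rx * ry)
    count <- spearman_perm_count(rx, ry, center,
                                 abs(s_obs - center), 1e-9)
    p <- count / factorial(n)
    method <- "exact"
  } else {
    if (abs(rs) >= 1) {
      p <- 0
    } else {
      t_stat <- rs * sqrt((n - 2) / (1 - rs^2))
      p <- 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
    }
    method <- "t-approx"
  }
  tibble::tibble(rs = rs, p = p, n = n, method = method)
}

#' Screen drugs for correlation with a per-sample score
#'
#' For each drug, the Spearman correlation between the score and the
#' drug's AUC over shared samples; p-values BH-adjusted across all
#' drugs; hits filtered by `|rs| > rs_thresh` (strict) and
#' `fdr < fdr_thresh` (strict), sorted by |rs| descending.
#'
#' AUC is oriented "higher = more resistant", so `rs < 0` means the drug
#' is more effective (lower AUC) in high-score samples.
#'
#' @param score Named per-sample score vector (names = sample ids).
#' @param auc Samples x drugs AUC matrix with sample-id row names.
#' @param annotation Optional tibble (`drug`, `pathway`) joined onto
#'   hits.
#' @param rs_thresh Absolute Spearman threshold (default 0.3).
#' @param fdr_thresh FDR threshold (default 0.05).
#' @return List with `hits` (tibble: drug, rs, p, fdr, direction,
#'   pathway) and `all` (unfiltered per-drug tibble).
#' @export
drug_correlation <- function(score, auc, annotation = NULL,
                             rs_thresh = 0.3, fdr_thresh = 0.05) {
  stopifnot(!is.null(names(score)), !is.null(rownames(auc)))
  shared <- intersect(names(score), rownames(auc))
  if (length(shared) < 10L) {
    stop("fewer than 10 samples shared between score and drug table")
  }
  s <- score[shared]
  m <- auc[shared, , drop = FALSE]
  per_drug <- purrr::map_dfr(colnames(m), function(d) {
    sc <- spearman_cor(s, m[, d])
    tibble::tibble(drug = d, rs = sc$rs, p = sc$p)
  })
  per_drug$fdr <- bh_adjust(per_drug$p)
  hits <- per_drug |>
    dplyr::filter(abs(.data$rs) > rs_thresh, .data$fdr < fdr_thresh) |>
    dplyr::mutate(direction = ifelse(.data$rs > 0, "positive", "negative")) |>
    dplyr::arrange(dplyr::desc(abs(.data$rs)))
  if (!is.null(annotation)) {
    hits <- dplyr::left_join(hits, annotation, by = "drug")
  }
  stopifnot(all(abs(hits$rs) > rs_thresh), all(hits$fdr < fdr_thresh))
  list(hits = hits, all = per_drug)
}

#' Association between a dichotomized score and a categorical feature
#'
#' Builds the contingency table and dispatches: Fisher's exact test when
#' any expected cell count is below 5 and the table is 2x2; Pearson
#' chi-square without continuity correction otherwise (with a warning
#' when a larger table has small expected cells).
#'
#' @param groups Group label per sample (e.g. "high"/"low").
#' @param feature Categorical feature per sample.
#' @return Tibble: `test` ("chi-squared" or "fisher"), `statistic`
#'   (NA for Fisher), `p`.
#' @export
categorical_association <- function(groups, feature) {
  groups <- as.factor(as.character(groups))
  feature <- as.factor(as.character(feature))
  if (nlevels(groups) < 2L) stop("groups has fewer than 2 levels")
  if (nlevels(feature) < 2L) stop("feature has fewer than 2 levels")
  tab <- table(groups, feature)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  small <- any(expected < 5)
  if (small && all(dim(tab) == c(2L, 2L))) {
    ft <- stats::fisher.test(tab)
    return(tibble::tibble(test = "fisher", statistic = NA_real_,
                          p = ft$p.value))
  }
  if (small) {
    warning("expected cell(s) below 5 in a table larger than 2x2; ",
            "using chi-square anyway")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(test = "chi-squared",
                 statistic = unname(ct$statistic), p = ct$p.value)
}
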