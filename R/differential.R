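#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin validating wrapper around `stats::p.adjust(method = "BH")`:
#' `adjP_(i) = min_{j >= i} min(1, p_(j) * m / j)` for sorted p, restored
#' to input order.  Inputs outside (0, 1] are rejected rather than
#' clamped.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Moderated one-vs-rest differential expression
#'
#' For each group g the contrast is g versus all remaining samples:
#' `log2FC = mean_g - mean_rest` on the log2-scale input.  Per-gene
#' pooled two-group variances are shrunk by empirical Bayes toward a
#' prior `(d0, s0^2)` estimated by method of moments from the
#' distribution of log sample variances (digamma/trigamma inversion of
#' the scaled-F moments).  The moderated statistic is
#' `t = log2FC / (s_tilde * sqrt(1/n_g + 1/n_rest))` on `d0 + d_res`
#' degrees of freedom; p-values are BH-adjusted within each contrast.
#'
#' If the observed variance of the log variances is no larger than the
#' sampling component, the prior degrees of freedom are set to 0 and the
#' statistic reduces to the ordinary pooled-variance t (a warning is
#' emitted).  `d0 = 0` can also be forced to obtain the ordinary t.
#'
#' @param mat Expression matrix (genes x samples), log2 scale.
#' @param labels Group label per sample (column order).
#' @param d0_override Optional: force the prior degrees of freedom
#'   (0 disables shrinkage).
#' @return Tibble: `gene`, `contrast`, `log2_fc`, `t_mod`, `p`, `adj_p`.
#' @export
moderated_de <- function(mat, labels, d0_override = NULL) {
  stopifnot(is.matrix(mat), length(labels) == ncol(mat))
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  n <- ncol(mat)
  res <- purrr::map_dfr(groups, function(g) {
    in_g <- labels == g
    n1 <- sum(in_g)
    n2 <- n - n1
    m1 <- rowMeans(mat[, in_g, drop = FALSE])
    m2 <- rowMeans(mat[, !in_g, drop = FALSE])
    v1 <- .row_vars(mat[, in_g, drop = FALSE])
    v2 <- .row_vars(mat[, !in_g, drop = FALSE])
    d_res <- n - 2L
    s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d_res
    if (all(s2 == 0)) stop("zero residual variance for every gene")
    eb <- .squeeze_var(s2, d_res, d0_override)
    se <- sqrt(eb$s2_post * (1 / n1 + 1 / n2))
    fc <- m1 - m2
    t_mod <- ifelse(se > 0, fc / se, 0)
    df_total <- d_res + eb$d0
    p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    tibble::tibble(gene = rownames(mat), contrast = paste0(g, "_vs_rest"),
                   log2_fc = unname(fc), t_mod = unname(t_mod),
                   p = unname(p), adj_p = bh_adjust(unname(p)))
  })
  attr(res, "groups") <- groups
  res
}

.row_vars <- function(m) {
  nc <- ncol(m)
  if (nc < 2L) return(rep(0, nrow(m)))
  rowSums((m - rowMeans(m))^2) / (nc - 1L)
}

# Empirical-Bayes variance shrinkage: method-of-moments fit of a scaled
# inverse-chi-square prior to the observed s^2, via the moments of
# log s^2 ~ log s0^2 + log F(d, d0).
.squeeze_var <- function(s2, d, d0_override = NULL) {
  pos <- s2 > 0
  if (!is.null(d0_override)) {
    d0 <- d0_override
    if (d0 == 0) {
      return(list(d0 = 0, s0_2 = NA_real_, s2_post = s2))
    }
  } else {
    d0 <- NA_real_
  }
  z <- log(s2[pos])
  e <- z - digamma(d / 2) + log(d / 2)
  e_var <- stats::var(e)
  excess <- e_var - trigamma(d / 2)
  if (is.na(d0)) {
    if (!is.finite(excess) || excess <= 0) {
      warning("log-variance spread no larger than sampling noise; ",
              "falling back to the ordinary t (d0 = 0)")
      return(list(d0 = 0, s0_2 = NA_real_, s2_post = s2))
    }
    d0 <- 2 * .trigamma_inverse(excess)
  }
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

# Newton inversion of trigamma on (0, Inf); trigamma is decreasing
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Select differentially expressed genes by fold-change and FDR
#'
#' A gene is selected if, in any contrast, `adj_p < adjp_thresh` and
#' `|log2_fc| > log2(fc_thresh)` — the usual reading of a linear
#' fold-change threshold applied to log2 data.  The union across
#' contrasts is returned, deduplicated, in first-appearance order.
#'
#' @param de_table Tibble from [moderated_de()].
#' @param fc_thresh Linear fold-change threshold, > 1 (default 1.5).
#' @param adjp_thresh Adjusted p threshold in (0, 1) (default 0.001).
#' @return Character vector of gene ids.
#' @export
select_degs <- function(de_table, fc_thresh = 1.5, adjp_thresh = 0.001) {
  stopifnot(fc_thresh > 1, adjp_thresh > 0, adjp_thresh < 1)
  hit <- de_table$adj_p < adjp_thresh &
    abs(de_table$log2_fc) > log2(fc_thresh)
  unique(de_table$gene[hit])
}
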