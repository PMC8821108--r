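#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' Per sample, genes are ranked by expression in descending order (ties
#' broken by gene id ascending, a stable and documented rule).  Walking
#' down the ranking, the enrichment score is the sum over rank positions
#' of the difference between the weighted in-set empirical CDF and the
#' uniform out-of-set empirical CDF.  In-set steps are rank-normalized
#' values raised to `alpha` and normalized to sum to one over set
#' members; out-of-set steps are `1 / (G - |set|)`.
#'
#' Weights use per-sample ranks (G down to 1) in place of raw expression,
#' which makes scores invariant to any monotone transform of a sample's
#' values — a deliberate choice for mixed microarray/RNA-seq inputs.
#'
#' @param mat Expression matrix (genes x samples).
#' @param gene_sets Named list of character vectors, or a single
#'   character vector (treated as one set called `"set"`).
#' @param alpha Rank weighting exponent; 0.25 is the ssGSEA convention.
#' @return Tibble with columns `set`, `sample_id`, `score`
#'   (`normalized = FALSE` attribute).
#' @export
ssgsea_score <- function(mat, gene_sets, alpha = 0.25) {
  stopifnot(is.matrix(mat))
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  if (is.null(names(gene_sets))) stop("gene_sets must be named")
  genes <- rownames(mat)
  G <- nrow(mat)
  # rank matrix: per sample, rank G for the highest value, ties broken
  # by gene id ascending (stable given the documented order)
  ord_gene <- order(genes)
  res <- vector("list", length(gene_sets))
  # per sample descending order index and rank weights, computed once
  rank_w <- matrix(0, G, ncol(mat))
  ord_idx <- matrix(0L, G, ncol(mat))
  for (s in seq_len(ncol(mat))) {
    o <- order(-mat[, s], genes, method = "radix")
    ord_idx[, s] <- o
    rank_w[o, s] <- G:1  # rank-normalized value: G for top gene
  }
  for (gi in seq_along(gene_sets)) {
    gs <- unique(gene_sets[[gi]])
    present <- intersect(gs, genes)
    if (length(present) < length(gs)) {
      warning("set '", names(gene_sets)[gi], "': ",
              length(gs) - length(present),
              " gene(s) absent from the matrix, dropped")
    }
    if (length(present) == 0L) {
      stop("no gene of set '", names(gene_sets)[gi],
           "' is present in the matrix")
    }
    if (length(present) == G) {
      stop("set '", names(gene_sets)[gi],
           "' covers every gene; out-of-set CDF undefined")
    }
    in_set <- genes %in% present
    scores <- vapply(seq_len(ncol(mat)), function(s) {
      o <- ord_idx[, s]
      hit <- in_set[o]
      w <- rank_w[o[hit], s]^alpha
      p_in <- cumsum(replace(numeric(G), which(hit), w / sum(w)))
      p_out <- cumsum(!hit) / (G - length(present))
      sum(p_in - p_out)
    }, numeric(1L))
    res[[gi]] <- tibble::tibble(set = names(gene_sets)[gi],
                                sample_id = colnames(mat),
                                score = scores)
  }
  out <- dplyr::bind_rows(res)
  attr(out, "normalized") <- FALSE
  out
}

#' Min-max normalize enrichment scores per set
#'
#' Each set's scores are rescaled to [0, 1] across samples.  Scores are
#' used only comparatively (relative abundance), so an affine per-set
#' rescale changes nothing downstream while giving a common scale for
#' display.  Constant sets are mapped to all-zeros with a warning.
#'
#' @param scores Tibble from [ssgsea_score()] (columns `set`,
#'   `sample_id`, `score`).
#' @return Tibble of the same shape with `normalized = TRUE` attribute.
#' @export
normalize_scores <- function(scores) {
  stopifnot(all(c("set", "sample_id", "score") %in% colnames(scores)))
  out <- scores |>
    dplyr::group_by(.data$set) |>
    dplyr::mutate(score = {
      rng <- range(.data$score)
      if (diff(rng) == 0) rep(0, length(.data$score))
      else (.data$score - rng[1L]) / diff(rng)
    }) |>
    dplyr::ungroup()
  n_const <- scores |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(const = diff(range(.data$score)) == 0) |>
    dplyr::pull(.data$const) |>
    sum()
  if (n_const > 0L) {
    warning(n_const, " constant set(s) mapped to all-zero scores")
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Pivot a long enrichment table to a set-by-sample matrix
#'
#' @param scores Tibble with `set`, `sample_id`, `score`.
#' @return Numeric matrix, sets in rows, samples in columns.
#' @export
enrichment_matrix <- function(scores) {
  wide <- tidyr::pivot_wider(scores, names_from = "sample_id",
                             values_from = "score")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$set
  m
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability
#' `P(X >= overlap)` of drawing at least the observed overlap when
#' `|query|` genes are drawn without replacement from the universe, of
#' which `|set ∩ universe|` are successes.  P-values are BH-adjusted
#' across sets.  Query genes outside the universe are dropped with a
#' warning.
#'
#' @param query Character vector of genes of interest.
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector: the gene background.
#' @return Tibble: `set`, `set_size`, `overlap`, `p`, `adj_p`, sorted by
#'   `p`.
#' @export
ora_hypergeom <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("universe is empty")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (length(query) == 0L) stop("no query gene left after universe filtering")
  N <- length(universe)
  q <- length(query)
  rows <- purrr::imap_dfr(gene_sets, function(gs, nm) {
    K <- length(intersect(unique(gs), universe))
    ov <- length(intersect(query, gs))
    p <- if (ov == 0L) 1 else
      stats::phyper(ov - 1L, K, N - K, q, lower.tail = FALSE)
    tibble::tibble(set = nm, set_size = K, overlap = ov, p = p)
  })
  rows$adj_p <- bh_adjust(rows$p)
  dplyr::arrange(rows, .data$p)
}
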