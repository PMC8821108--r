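#' Prognostic gene screen by univariate Cox regression
#'
#' Fits a univariate Cox model per gene and retains the genes whose Wald
#' p-value falls below `p_thresh` (default 0.05).  This is the filter
#' that turns pattern-characteristic genes into a prognostic signature.
#'
#' @param mat Expression matrix (genes x samples).
#' @param clinical Clinical tibble (`sample_id`, `os_time`, `os_event`).
#' @param genes Candidate genes (e.g. pattern DEGs).
#' @param p_thresh Wald p-value threshold.
#' @return Character vector of retained genes, in input order.
#' @export
prognostic_screen <- function(mat, clinical, genes, p_thresh = 0.05) {
  if (length(genes) == 0L) stop("empty candidate gene list")
  screen <- cox_screen(mat, clinical, genes)
  keep <- screen$gene[!is.na(screen$p) & screen$p < p_thresh]
  if (length(keep) == 0L) {
    stop("no gene passed the prognostic screen at p < ", p_thresh,
         "; consider relaxing the threshold")
  }
  keep
}

#' PCA-based signature score (HAscore)
#'
#' Signature-gene expression is z-scored per gene across samples and the
#' samples-by-genes z-matrix is decomposed by SVD (the z-scoring already
#' centers each gene, so no further centering is applied).  Each
#' sample's score is its coordinate on the first principal component
#' plus its coordinate on the second; raw coordinates are summed without
#' variance normalization, following the score-model construction this
#' signature family uses.  The construction concentrates weight on the
#' largest block of well-correlated genes and down-weights genes that do
#' not track the rest of the set.
#'
#' SVD signs are arbitrary, so each component is oriented to correlate
#' non-negatively with the per-sample mean signature z-expression; "high
#' score = high signature expression" then holds on any backend.
#'
#' @param mat Expression matrix (genes x samples).
#' @param signature Character vector of signature genes; absent or
#'   zero-variance genes are dropped with a warning.
#' @return Named numeric vector of per-sample scores.
#' @export
hascore <- function(mat, signature) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 3L) stop("need at least 3 samples")
  present <- intersect(signature, rownames(mat))
  if (length(present) < length(signature)) {
    warning(length(signature) - length(present),
            " signature gene(s) absent from the matrix, dropped")
  }
  sub <- mat[present, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance signature gene(s) dropped")
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(sub) < 2L) stop("fewer than 2 usable signature genes")
  z <- (sub - rowMeans(sub)) / sds       # genes x samples
  zs <- t(z)                              # samples x genes
  sv <- svd(zs, nu = 2L, nv = 0L)
  coord <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], nrow = 2L)
  mean_z <- rowMeans(zs)
  for (j in 1:2) {
    if (sum(coord[, j] * mean_z) < 0) coord[, j] <- -coord[, j]
  }
  stats::setNames(coord[, 1L] + coord[, 2L], colnames(mat))
}

#' Epithelial-mesenchymal transition score
#'
#' Per sample, the mean expression of the mesenchymal marker genes found
#' in the matrix minus the mean expression of the epithelial markers
#' found.  Positive values indicate a mesenchymal shift.
#'
#' @param mat Expression matrix (genes x samples).
#' @param mesenchymal,epithelial Character vectors of marker genes.
#' @return Named numeric vector of per-sample scores.
#' @export
emt_score <- function(mat, mesenchymal, epithelial) {
  stopifnot(is.matrix(mat))
  m_in <- intersect(mesenchymal, rownames(mat))
  e_in <- intersect(epithelial, rownames(mat))
  if (length(m_in) == 0L) stop("no mesenchymal marker present in the matrix")
  if (length(e_in) == 0L) stop("no epithelial marker present in the matrix")
  m_mean <- colMeans(mat[m_in, , drop = FALSE])
  e_mean <- colMeans(mat[e_in, , drop = FALSE])
  m_mean - e_mean
}
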