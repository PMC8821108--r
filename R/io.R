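#' Read a gene-by-sample expression matrix from TSV
#'
#' The expected layout is the field's usual one: first column gene
#' identifiers, one column per sample, a header row of sample ids.  Values
#' are conventionally on the log2(TPM + 1) scale, but the reader does not
#' enforce a scale.
#'
#' Rows containing any empty or non-numeric cell are dropped with a warning
#' rather than imputed: every downstream statistic (SVD, enrichment,
#' moderated tests) requires complete rows.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix (genes x samples) with unique, ordered row and
#'   column names.
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           blank.lines.skip = TRUE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("expression file '", path, "' is empty or has no sample columns")
  }
  genes <- raw[[1L]]
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g) > 0L) {
    stop("duplicate gene identifier(s) in '", path, "': ",
         paste(dup_g, collapse = ", "))
  }
  samples <- colnames(raw)[-1L]
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s) > 0L) {
    stop("duplicate sample identifier(s) in '", path, "': ",
         paste(dup_s, collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(raw[-1L], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(genes, samples))
  bad <- !stats::complete.cases(vals) | rowSums(!is.finite(vals)) > 0L
  if (any(bad)) {
    warning("dropping ", sum(bad), " gene row(s) with missing or ",
            "non-numeric cells: ",
            paste(utils::head(genes[bad], 5L), collapse = ", "),
            if (sum(bad) > 5L) ", ..." else "")
    vals <- vals[!bad, , drop = FALSE]
  }
  if (nrow(vals) == 0L) stop("no complete gene rows left in '", path, "'")
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: gene ids in the first column, one column
#' per sample.  Values are written with full double precision so a
#' write/read round trip preserves them.
#'
#' @param mat Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample clinical table from TSV
#'
#' Reserved column names: `sample_id`, `os_time` (overall-survival time,
#' any consistent unit), `os_event` (1 = death, 0 = censored) and,
#' optionally, `batch`.  Any further columns are carried along as
#' covariates.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L) {
    stop("clinical table '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in clinical table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if (any(!is.finite(df$os_time)) || any(df$os_time <= 0)) {
    stop("os_time must be positive and finite for every sample")
  }
  if (!all(df$os_event %in% c(0, 1))) {
    stop("os_event must be 0 (censored) or 1 (death)")
  }
  tibble::as_tibble(df)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.  The description field is
#' ignored and within-set duplicate genes are removed (first occurrence
#' kept).
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors, in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file '", path, "' is empty")
  sets <- vector("list", length(lines))
  names_out <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 non-empty fields")
    }
    names_out[[i]] <- fields[[1L]]
    sets[[i]] <- unique(fields[-c(1L, 2L)])
  }
  if (anyDuplicated(names_out)) {
    stop("duplicate gene-set name(s) in '", path, "': ",
         paste(unique(names_out[duplicated(names_out)]), collapse = ", "))
  }
  stats::setNames(sets, names_out)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], description, sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Convert linear-scale FPKM to linear-scale TPM
#'
#' Per sample j, `TPM_ij = FPKM_ij / sum_i FPKM_ij * 1e6`, so each sample
#' column sums to one million.  The transform is scale-free within a
#' sample, which is what makes TPM comparable across libraries.  A
#' subsequent `log2(TPM + 1)` step is the caller's responsibility (see
#' [run_pipeline()]).
#'
#' @param mat Numeric matrix of non-negative linear FPKM values.
#' @return Matrix of the same shape on the linear TPM scale.
#' @export
fpkm_to_tpm <- function(mat) {
  stopifnot(is.matrix(mat))
  if (any(mat < 0)) stop("FPKM values must be non-negative")
  cs <- colSums(mat)
  zero <- cs == 0
  if (any(zero)) {
    stop("sample(s) with all-zero FPKM column: ",
         paste(colnames(mat)[zero], collapse = ", "))
  }
  sweep(mat, 2L, cs, "/") * 1e6
}

#' Location-scale batch adjustment
#'
#' Per gene, each batch's values are standardized by the batch mean and
#' standard deviation and re-expressed on the pooled (all-sample) mean and
#' standard deviation of that gene.  After adjustment the per-gene batch
#' means (and sds) agree across batches, while the gene's pooled mean is
#' preserved.  This is a deliberate location-scale simplification: no
#' empirical-Bayes shrinkage of batch parameters is performed.
#'
#' Genes with zero variance inside some batch cannot be rescaled there;
#' such genes are passed through centered only (batch mean replaced by the
#' pooled mean) with a warning.
#'
#' @param mat Numeric matrix (genes x samples).
#' @param batch Character or factor vector of batch labels, one per sample
#'   (in column order).
#' @return Adjusted matrix of the same shape.
#' @export
batch_adjust <- function(mat, batch) {
  stopifnot(is.matrix(mat))
  if (length(batch) != ncol(mat)) {
    stop("need one batch label per sample column")
  }
  if (anyNA(batch)) stop("every sample needs a batch label")
  batch <- as.factor(batch)
  sizes <- table(batch)
  if (any(sizes < 2L)) {
    stop("batch(es) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  if (nlevels(batch) == 1L) return(mat)
  pooled_mean <- rowMeans(mat)
  pooled_sd <- apply(mat, 1L, stats::sd)
  out <- mat
  n_degenerate <- 0L
  for (b in levels(batch)) {
    idx <- which(batch == b)
    sub <- mat[, idx, drop = FALSE]
    bm <- rowMeans(sub)
    bs <- apply(sub, 1L, stats::sd)
    ok <- bs > 0 & pooled_sd > 0
    n_degenerate <- n_degenerate + sum(!ok)
    z <- sub
    z[ok, ] <- (sub[ok, , drop = FALSE] - bm[ok]) / bs[ok] *
      pooled_sd[ok] + pooled_mean[ok]
    # degenerate genes: shift the batch onto the pooled mean, no rescale
    z[!ok, ] <- sub[!ok, , drop = FALSE] - bm[!ok] + pooled_mean[!ok]
    out[, idx] <- z
  }
  if (n_degenerate > 0L) {
    warning(n_degenerate,
            " gene-within-batch case(s) had zero variance; centered only")
  }
  out
}
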