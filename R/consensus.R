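#' Resampling consensus matrix for one value of k
#'
#' For each repetition a random `ceiling(subsample_frac * n)` subset of
#' samples is clustered into `k` groups by k-means (multiple seeded
#' restarts) on per-gene z-scored expression with Euclidean distance.
#' `consensus[i, j]` is the fraction of repetitions in which samples i and
#' j were placed in the same cluster, among the repetitions in which both
#' were sampled.  Pairs never co-sampled (possible at very low `reps`)
#' get consensus 0 with a warning.
#'
#' The RNG contract, which the test suite replays: `set.seed(seed)` once,
#' then per repetition first draw the subsample with
#' `sample.int(n, m)` and then run `stats::kmeans(..., nstart = nstart)`
#' on the same stream.
#'
#' @param mat Expression matrix (genes x samples).
#' @param panel Character vector of panel gene ids; genes absent from
#'   `mat` are dropped with a warning.
#' @param k Number of clusters, >= 2.
#' @param reps Number of resampling repetitions.
#' @param subsample_frac Fraction of samples drawn each repetition.
#' @param seed Integer seed.
#' @param nstart k-means restarts per repetition.
#' @return List with `consensus` (n x n symmetric matrix, unit diagonal)
#'   and `co_sample_counts` (n x n integer matrix of co-sampling counts).
#' @export
consensus_matrix <- function(mat, panel = rownames(mat), k, reps = 1000L,
                             subsample_frac = 0.8, seed = 1L,
                             nstart = 3L) {
  stopifnot(is.matrix(mat), k >= 2L, reps >= 1L,
            subsample_frac > 0, subsample_frac <= 1)
  z <- .panel_zscore(mat, panel)
  n <- ncol(z)
  m <- ceiling(subsample_frac * n)
  if (k > m) stop("k = ", k, " exceeds the subsample size ", m)
  if (n < 2L * k) stop("need at least 2k samples")

  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(.Random.seed_restore(old), add = TRUE)

  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  x <- t(z)  # samples x genes for kmeans
  for (r in seq_len(reps)) {
    idx <- sample.int(n, m)
    km <- stats::kmeans(x[idx, , drop = FALSE], centers = k,
                        nstart = nstart, iter.max = 50L)
    lab <- km$cluster
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    for (g in seq_len(k)) {
      members <- idx[lab == g]
      co_cluster[members, members] <- co_cluster[members, members] + 1
    }
  }
  never <- co_sample == 0
  diag(never) <- FALSE
  consensus <- ifelse(co_sample > 0, co_cluster / co_sample, 0)
  if (any(never)) {
    warning(sum(never) / 2, " sample pair(s) were never co-sampled; ",
            "their consensus is set to 0 (increase reps)")
  }
  diag(consensus) <- 1
  dimnames(consensus) <- list(colnames(mat), colnames(mat))
  dimnames(co_sample) <- dimnames(consensus)
  list(consensus = consensus, co_sample_counts = co_sample)
}

# restrict to panel, drop absent / zero-variance genes, z-score per gene
.panel_zscore <- function(mat, panel) {
  present <- intersect(panel, rownames(mat))
  absent <- setdiff(panel, rownames(mat))
  if (length(absent) > 0L) {
    warning(length(absent), " panel gene(s) absent from the matrix: ",
            paste(utils::head(absent, 5L), collapse = ", "))
  }
  if (length(present) == 0L) stop("no panel gene present in the matrix")
  sub <- mat[present, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance panel gene(s) dropped")
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(sub) == 0L) stop("no informative panel gene left")
  (sub - rowMeans(sub)) / sds
}

#' Consensus clustering over a range of k with model selection
#'
#' Runs [consensus_matrix()] for each k, computes the empirical CDF of
#' off-diagonal consensus values, the relative delta-area under the CDF,
#' and the proportion of ambiguous clustering (PAC, the CDF mass between
#' `pac_lower` and `pac_upper`).  `k` is chosen by the delta-area elbow
#' (largest relative increase in CDF area; ties broken toward smaller k),
#' with PAC reported alongside.  Final assignments cut an average-linkage
#' hierarchical tree on distance `1 - consensus`.
#'
#' @param mat Expression matrix (genes x samples).
#' @param panel Panel gene ids.
#' @param k_range Contiguous integer range starting at 2 (a single k is
#'   accepted with a warning).
#' @param reps,subsample_frac,seed,nstart Passed to [consensus_matrix()].
#' @param pac_lower,pac_upper PAC interval bounds.
#' @return An object of class `ha_consensus`: list with `consensus`
#'   (per-k list), `metrics` (tibble: k, area, delta_area, pac),
#'   `chosen_k`, `assignments` (tibble: sample_id, cluster).
#' @export
consensus_cluster <- function(mat, panel = rownames(mat), k_range = 2:6,
                              reps = 1000L, subsample_frac = 0.8,
                              seed = 1L, nstart = 3L,
                              pac_lower = 0.1, pac_upper = 0.9) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) > 1L &&
      (k_range[1L] != 2L || any(diff(k_range) != 1L))) {
    stop("k_range must be contiguous and start at 2")
  }
  if (length(k_range) == 1L) {
    warning("k_range has a single value; model selection is degenerate")
  }
  cons <- vector("list", length(k_range))
  names(cons) <- paste0("k", k_range)
  area <- pac <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    # distinct seed per k so repetitions are independent across k
    cm <- consensus_matrix(mat, panel, k = k_range[i], reps = reps,
                           subsample_frac = subsample_frac,
                           seed = seed + (k_range[i] - 2L) * 1000L,
                           nstart = nstart)
    cons[[i]] <- cm$consensus
    off <- cm$consensus[upper.tri(cm$consensus)]
    area[i] <- .cdf_area(off)
    pac[i] <- mean(off > pac_lower & off < pac_upper)
  }
  delta <- if (length(k_range) == 1L) NA_real_
  else c(area[1L], diff(area) / area[-length(area)])
  metrics <- tibble::tibble(k = k_range, area = area,
                            delta_area = delta, pac = pac)
  chosen_k <- suppressWarnings(select_k(metrics))
  chosen <- cons[[paste0("k", chosen_k)]]
  assignments <- final_assignments(chosen, chosen_k)
  structure(list(consensus = cons,
                 metrics = metrics,
                 chosen_k = chosen_k,
                 assignments = assignments),
            class = "ha_consensus")
}

# area under the empirical CDF of consensus values over [0, 1]
.cdf_area <- function(vals) {
  if (length(vals) == 0L) return(0)
  s <- sort(vals)
  n <- length(s)
  knots <- c(s, 1)
  heights <- seq_len(n) / n
  sum(diff(knots) * heights) + 0  # CDF is 0 left of the first knot
}

#' Cut a consensus matrix into final cluster assignments
#'
#' Average-linkage hierarchical clustering on distance `1 - consensus`,
#' cut into `k` groups.  Labels are arbitrary integers but deterministic
#' for a given matrix.
#'
#' @param consensus Symmetric consensus matrix with unit diagonal.
#' @param k Number of groups.
#' @return Tibble with `sample_id` and integer `cluster`.
#' @export
final_assignments <- function(consensus, k) {
  n <- nrow(consensus)
  if (k > n) stop("k cannot exceed the number of samples")
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = k)
  ids <- colnames(consensus)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  tibble::tibble(sample_id = ids, cluster = unname(cl))
}

#' Select k from per-k consensus metrics
#'
#' The delta-area elbow rule: the chosen k maximizes the relative
#' increase in area under the consensus CDF; ties break toward smaller k.
#' A high PAC at the chosen k (no crisp structure anywhere) is flagged
#' with a message.
#'
#' @param metrics Tibble with columns `k`, `area`, `pac` (as produced by
#'   [consensus_cluster()]).
#' @param pac_flag PAC above which a lack of structure is flagged.
#' @return The chosen k (integer).
#' @export
select_k <- function(metrics, pac_flag = 0.3) {
  k <- metrics$k
  if (length(k) == 1L) {
    warning("single k supplied; returning it")
    return(k)
  }
  area <- metrics$area
  delta <- c(area[1L], diff(area) / area[-length(area)])
  chosen <- k[which.max(delta)]
  if (metrics$pac[k == chosen] > pac_flag) {
    message("PAC at chosen k (", round(metrics$pac[k == chosen], 3),
            ") is high; the data may lack cluster structure")
  }
  chosen
}

#' Adjusted Rand index between two partitions
#'
#' Hubert–Arabie adjusted Rand index; 1 for identical partitions (up to
#' relabeling), ~0 for independent ones.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A number <= 1.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

#' @export
glance.ha_consensus <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k,
                 pac = x$metrics$pac[x$metrics$k == x$chosen_k],
                 n_samples = nrow(x$assignments),
                 k_min = min(x$metrics$k),
                 k_max = max(x$metrics$k))
}

#' @export
tidy.ha_consensus <- function(x, ...) {
  x$assignments
}

#' @export
print.ha_consensus <- function(x, ...) {
  cat("Consensus clustering over k =", min(x$metrics$k), "..",
      max(x$metrics$k), "\n")
  cat("Chosen k:", x$chosen_k, "(delta-area elbow; PAC",
      round(x$metrics$pac[x$metrics$k == x$chosen_k], 3), ")\n")
  print(table(x$assignments$cluster))
  invisible(x)
}

#' Consensus CDF and delta-area diagnostic plot
#'
#' Left panel: empirical CDFs of off-diagonal consensus values, one curve
#' per k.  Right panel: relative delta-area against k; the elbow is the
#' chosen k.
#'
#' @param object An `ha_consensus` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ha_consensus <- function(object, ...) {
  cdf_df <- purrr::imap_dfr(object$consensus, function(cm, nm) {
    off <- sort(cm[upper.tri(cm)])
    tibble::tibble(k = as.integer(sub("^k", "", nm)),
                   consensus = off,
                   cdf = seq_along(off) / length(off))
  })
  ggplot2::ggplot(cdf_df,
                  ggplot2::aes(x = .data$consensus, y = .data$cdf,
                               colour = factor(.data$k))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "consensus index", y = "empirical CDF",
                  colour = "k",
                  title = "Consensus CDF by number of clusters") +
    ggplot2::theme_minimal()
}
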