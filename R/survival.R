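#' Kaplan-Meier product-limit curve
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times.
#' Censoring times appear in the risk-set bookkeeping only.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = death, 0 = censored).
#' @return An `ha_km` tibble: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, ordered by time, covering every distinct observed time.
#' @export
km_curve <- function(time, event) {
  .check_surv(time, event)
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  ut <- unique(time)
  n <- length(time)
  n_event <- vapply(ut, function(t) sum(event[time == t]), numeric(1))
  n_censor <- vapply(ut, function(t) sum(1 - event[time == t]), numeric(1))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- tibble::tibble(time = ut, n_risk = n_risk, n_event = n_event,
                        n_censor = n_censor, survival = surv)
  class(out) <- c("ha_km", class(out))
  out
}

.check_surv <- function(time, event) {
  if (length(time) == 0L) stop("no samples")
  stopifnot(length(time) == length(event))
  if (any(!is.finite(time)) || any(time <= 0)) stop("time must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  invisible(TRUE)
}

# Per-group observed - expected and hypergeometric variance terms at each
# distinct event time; `ingroup` is a logical membership vector.
# Returns c(oe = O - E, v = Var) for the flagged group.
.logrank_oe <- function(time, event, ingroup) {
  et <- sort(unique(time[event == 1]))
  oe <- 0
  v <- 0
  for (t in et) {
    at_risk <- time >= t
    n_k <- sum(at_risk)
    n1 <- sum(at_risk & ingroup)
    d_k <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & ingroup)
    oe <- oe + d1 - d_k * n1 / n_k
    if (n_k > 1) {
      v <- v + d_k * (n1 / n_k) * (1 - n1 / n_k) * (n_k - d_k) / (n_k - 1)
    }
  }
  c(oe = oe, v = v)
}

#' Log-rank test for two or more groups
#'
#' The usual observed-minus-expected statistic with hypergeometric
#' variance summed over distinct event times; for g groups the statistic
#' is `(O - E)' V^{-1} (O - E)` over the first g - 1 groups, compared to
#' chi-square with g - 1 degrees of freedom.
#'
#' @param time,event Survival outcome as in [km_curve()].
#' @param group Group label per subject, at least two levels.
#' @return Tibble: `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  .check_surv(time, event)
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) == 0L)) stop("empty group level")
  g <- nlevels(group)
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0L) {
    return(tibble::tibble(statistic = 0, df = g - 1L, p = 1))
  }
  oe <- numeric(g - 1L)
  V <- matrix(0, g - 1L, g - 1L)
  lev <- levels(group)
  for (t in et) {
    at_risk <- time >= t
    n_k <- sum(at_risk)
    d_k <- sum(event == 1 & time == t)
    n_i <- vapply(lev, function(l) sum(at_risk & group == l), numeric(1))
    d_i <- vapply(lev, function(l) sum(event == 1 & time == t & group == l),
                  numeric(1))
    e_i <- d_k * n_i / n_k
    oe <- oe + (d_i - e_i)[seq_len(g - 1L)]
    if (n_k > 1) {
      p_i <- n_i / n_k
      mult <- d_k * (n_k - d_k) / (n_k - 1)
      vk <- mult * (diag(p_i, nrow = g) - outer(p_i, p_i))
      V <- V + vk[seq_len(g - 1L), seq_len(g - 1L), drop = FALSE]
    }
  }
  stat <- tryCatch(as.numeric(t(oe) %*% solve(V, oe)),
                   error = function(e) 0)
  if (!is.finite(stat) || stat < 0) stat <- 0
  tibble::tibble(statistic = stat, df = g - 1L,
                 p = stats::pchisq(stat, df = g - 1L, lower.tail = FALSE))
}

#' Cox proportional-hazards fit by Newton-Raphson (Efron ties)
#'
#' Maximizes the Efron-tie-corrected partial likelihood by Newton's
#' method with step-halving, declaring convergence when the largest
#' score component falls below `tol` (default 1e-8) or after `max_iter`
#' iterations.  Standard errors come from the inverse observed
#' information.  Categorical covariates should be expanded to dummy
#' columns beforehand (see [cox_screen()] / [run_pipeline()] for how the
#' pipeline does this).
#'
#' A monotone partial likelihood (complete separation) is detected when
#' a coefficient runs away; the coefficient is capped with a warning and
#' the fit flagged.
#'
#' @param time,event Survival outcome.
#' @param covariates Numeric matrix or data frame, one column per
#'   covariate, one row per subject.
#' @param tol Convergence tolerance on the score.
#' @param max_iter Iteration cap.
#' @return An `ha_cox` object; see [tidy.ha_cox()] and
#'   [glance.ha_cox()].
#' @export
cox_fit <- function(time, event, covariates, tol = 1e-8, max_iter = 50L) {
  .check_surv(time, event)
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  if (n != length(time)) stop("covariate rows must match subjects")
  if (n <= ncol(x)) stop("need more subjects than covariates")
  const <- apply(x, 2L, function(col) diff(range(col)) == 0)
  if (any(const)) {
    stop("constant covariate(s): ",
         paste(colnames(x)[const], collapse = ", "))
  }
  # center for numerical stability; beta unchanged by column shifts
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  p <- ncol(x)
  beta <- rep(0, p)
  ll_old <- .cox_ll(beta, time, event, xc)$ll
  converged <- FALSE
  separated <- FALSE
  cap <- 20
  for (it in seq_len(max_iter)) {
    d <- .cox_ll(beta, time, event, xc, derivs = TRUE)
    if (max(abs(d$score)) < tol) {
      converged <- TRUE
      ll_old <- d$ll
      break
    }
    step <- tryCatch(solve(d$info, d$score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving: never let the partial likelihood decrease
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- .cox_ll(cand, time, event, xc)$ll
      if (is.finite(ll_new) && ll_new >= d$ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { cand <- beta; ll_new <- d$ll; break }
    }
    beta <- cand
    ll_old <- ll_new
    if (any(abs(beta) > cap)) {
      separated <- TRUE
      beta <- pmin(pmax(beta, -cap), cap)
      warning("monotone partial likelihood (separation?); ",
              "coefficient capped at |beta| = ", cap)
      break
    }
  }
  d <- .cox_ll(beta, time, event, xc, derivs = TRUE)
  if (!converged && !separated && max(abs(d$score)) < tol) converged <- TRUE
  se <- sqrt(diag(tryCatch(solve(d$info), error = function(e)
    matrix(NA_real_, p, p))))
  z <- beta / se
  structure(list(beta = stats::setNames(beta, colnames(x)),
                 se = stats::setNames(se, colnames(x)),
                 loglik = d$ll,
                 score = d$score,
                 n = n,
                 n_events = sum(event),
                 iter = it,
                 converged = converged,
                 separated = separated,
                 wald_p = 2 * stats::pnorm(abs(z), lower.tail = FALSE)),
            class = "ha_cox")
}

# Efron partial log-likelihood, score and information.
.cox_ll <- function(beta, time, event, x, derivs = FALSE) {
  eta <- drop(x %*% beta)
  eta <- eta - max(eta)  # guard exp overflow; cancels in all ratios
  w <- exp(eta)
  ord <- order(-time)    # descending: risk sets are cumulative prefixes
  t_s <- time[ord]; e_s <- event[ord]; w_s <- w[ord]
  x_s <- x[ord, , drop = FALSE]
  p <- ncol(x)
  cw <- cumsum(w_s)
  cwx <- apply(x_s * w_s, 2L, cumsum)
  if (p == 1L) cwx <- matrix(cwx, ncol = 1L)
  if (derivs) {
    # cumulative weighted cross-products, packed lower-triangular
    cp_idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    cwxx <- apply(cp_idx, 1L, function(ij) {
      cumsum(w_s * x_s[, ij[1L]] * x_s[, ij[2L]])
    })
    if (nrow(cp_idx) == 1L) cwxx <- matrix(cwxx, ncol = 1L)
  }
  et <- unique(t_s[e_s == 1])
  ll <- 0
  score <- rep(0, p)
  info <- matrix(0, p, p)
  for (t in et) {
    risk_last <- max(which(t_s >= t))       # prefix covering the risk set
    dead <- which(t_s == t & e_s == 1)
    dk <- length(dead)
    sR <- cw[risk_last]
    aR <- cwx[risk_last, ]
    sD <- sum(w_s[dead])
    aD <- colSums(x_s[dead, , drop = FALSE] * w_s[dead])
    ll <- ll + sum(eta[ord][dead])
    if (derivs) {
      bR <- matrix(0, p, p)
      bD <- matrix(0, p, p)
      bR[lower.tri(bR, diag = TRUE)] <- cwxx[risk_last, ]
      bR <- bR + t(bR) - diag(diag(bR), nrow = p)
      xd <- x_s[dead, , drop = FALSE]
      bD <- crossprod(xd * sqrt(w_s[dead]))
      score <- score + colSums(xd)
    }
    for (l in seq_len(dk) - 1L) {
      frac <- l / dk
      denom <- sR - frac * sD
      ll <- ll - log(denom)
      if (derivs) {
        a_l <- (aR - frac * aD) / denom
        score <- score - a_l
        b_l <- (bR - frac * bD) / denom
        info <- info + b_l - outer(a_l, a_l)
      }
    }
  }
  list(ll = ll, score = score, info = info)
}

#' Maximally selected log-rank cutpoint
#'
#' Scans every distinct score value whose induced low/high split leaves
#' at least `ceiling(minprop * n)` subjects on each side, computes the
#' standardized two-group log-rank statistic, and returns the cutpoint
#' with the largest absolute statistic (ties resolved toward the
#' smallest cutpoint).  The returned `cutpoint` is the midpoint between
#' the last low and first high score value, so `score > cutpoint`
#' defines the high group.
#'
#' No multiplicity-adjusted p-value is attached: the cutpoint is used
#' for stratification, and group differences are then judged by an
#' ordinary log-rank test.
#'
#' @param score Continuous per-subject score.
#' @param time,event Survival outcome.
#' @param minprop Minimum fraction of subjects on each side (default
#'   0.1, the conventional choice).
#' @return Tibble: `cutpoint`, `statistic` (standardized, signed),
#'   `n_low`, `n_high`.
#' @export
best_cutpoint <- function(score, time, event, minprop = 0.1) {
  .check_surv(time, event)
  stopifnot(length(score) == length(time), minprop > 0, minprop < 0.5)
  n <- length(score)
  min_n <- ceiling(minprop * n)
  vals <- sort(unique(score))
  best <- NULL
  for (c_idx in seq_along(vals)) {
    low <- score <= vals[c_idx]
    n_low <- sum(low)
    if (n_low < min_n || n - n_low < min_n) next
    oev <- .logrank_oe(time, event, !low)  # O - E for the high group
    if (oev[["v"]] <= 0) next
    z <- oev[["oe"]] / sqrt(oev[["v"]])
    if (is.null(best) || abs(z) > best$abs_z + 1e-12) {
      best <- list(idx = c_idx, z = z, abs_z = abs(z), n_low = n_low)
    }
  }
  if (is.null(best)) stop("no admissible cutpoint under minprop = ", minprop)
  cut_val <- if (best$idx < length(vals)) {
    (vals[best$idx] + vals[best$idx + 1L]) / 2
  } else vals[best$idx]
  tibble::tibble(cutpoint = cut_val, statistic = best$z,
                 n_low = best$n_low, n_high = n - best$n_low)
}

#' Dichotomize a score at its maximally selected cutpoint
#'
#' Convenience wrapper around [best_cutpoint()]: returns "high"/"low"
#' labels.  When `batch` is supplied the cutpoint is found within each
#' batch separately and the groups pooled afterwards, so a location
#' shift between batches does not leak into the grouping.
#'
#' @inheritParams best_cutpoint
#' @param batch Optional batch label per subject.
#' @return Character vector of "high"/"low".
#' @export
dichotomize_score <- function(score, time, event, minprop = 0.1,
                              batch = NULL) {
  if (is.null(batch) || length(unique(batch)) == 1L) {
    cp <- best_cutpoint(score, time, event, minprop)
    return(ifelse(score > cp$cutpoint, "high", "low"))
  }
  out <- character(length(score))
  for (b in unique(batch)) {
    idx <- batch == b
    cp <- best_cutpoint(score[idx], time[idx], event[idx], minprop)
    out[idx] <- ifelse(score[idx] > cp$cutpoint, "high", "low")
  }
  out
}

#' Univariate Cox screen over many genes
#'
#' Fits [cox_fit()] per gene on its expression row and collects the
#' hazard ratio, confidence interval and Wald p-value.
#'
#' @param mat Expression matrix (genes x samples).
#' @param clinical Clinical tibble with `sample_id`, `os_time`,
#'   `os_event`; sample ids must match the matrix columns.
#' @param genes Genes to screen (default: all rows).
#' @return Tibble: `gene`, `beta`, `se`, `hr`, `ci_low`, `ci_high`, `p`.
#' @export
cox_screen <- function(mat, clinical, genes = rownames(mat)) {
  genes <- intersect(genes, rownames(mat))
  if (length(genes) == 0L) stop("no requested gene present in the matrix")
  idx <- match(clinical$sample_id, colnames(mat))
  if (anyNA(idx)) stop("clinical samples missing from the matrix")
  time <- clinical$os_time
  event <- clinical$os_event
  purrr::map_dfr(genes, function(g) {
    expr <- mat[g, idx]
    if (diff(range(expr)) == 0) {
      return(tibble::tibble(gene = g, beta = NA_real_, se = NA_real_,
                            hr = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p = NA_real_))
    }
    fit <- suppressWarnings(
      cox_fit(time, event, matrix(expr, ncol = 1L,
                                  dimnames = list(NULL, g)))
    )
    tibble::tibble(gene = g, beta = fit$beta[[1L]], se = fit$se[[1L]],
                   hr = exp(fit$beta[[1L]]),
                   ci_low = exp(fit$beta[[1L]] - 1.96 * fit$se[[1L]]),
                   ci_high = exp(fit$beta[[1L]] + 1.96 * fit$se[[1L]]),
                   p = fit$wald_p[[1L]])
  })
}

#' @export
tidy.ha_cox <- function(x, ...) {
  tibble::tibble(term = names(x$beta),
                 estimate = unname(x$beta),
                 std_error = unname(x$se),
                 hr = exp(unname(x$beta)),
                 ci_low = exp(unname(x$beta) - 1.96 * unname(x$se)),
                 ci_high = exp(unname(x$beta) + 1.96 * unname(x$se)),
                 p_value = unname(x$wald_p))
}

#' @export
glance.ha_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 log_partial_lik = x$loglik, iterations = x$iter,
                 converged = x$converged, separated = x$separated)
}

#' @export
print.ha_cox <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties), n =", x$n,
      ", events =", x$n_events, "\n")
  print(as.data.frame(tidy(x)), row.names = FALSE, digits = 4)
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' Kaplan-Meier step plot
#'
#' @param object An `ha_km` tibble (optionally with a `group` column
#'   added by the caller).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ha_km <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1,
                   group = if ("group" %in% colnames(object))
                     unique(object$group) else "all"),
    object |>
      dplyr::mutate(group = if ("group" %in% colnames(object))
        .data$group else "all")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  title = "Kaplan-Meier estimate") +
    ggplot2::theme_minimal()
}
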