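#' Assemble a pipeline configuration
#'
#' Paths point at the TSV/GMT inputs; parameters carry the analysis
#' defaults used throughout the package.  `expression_scale` declares
#' what the expression file contains: `"log2"` (already log2-like,
#' used as is) or `"fpkm"` (linear FPKM, converted to TPM and then
#' log2(TPM + 1) on load).
#'
#' @param expression,clinical,regulators Required input paths
#'   (expression TSV, clinical TSV, one-regulator-per-line panel file).
#' @param gene_sets_gmt,emt_gmt,drug_auc,drug_annotation Optional input
#'   paths; stages needing a missing input are skipped.
#' @param expression_scale `"log2"` or `"fpkm"`.
#' @param k_min,k_max,reps,subsample_frac Consensus-clustering settings.
#' @param fc_thresh,adjp_thresh DEG thresholds (linear fold change and
#'   BH-adjusted p).
#' @param prognostic_p Univariate-Cox screen threshold.
#' @param alpha ssGSEA rank-weight exponent.
#' @param minprop Minimum group fraction for the score cutpoint.
#' @param rs_thresh,fdr_thresh Drug-correlation hit thresholds.
#' @param covariates Clinical columns for the multivariate Cox model.
#' @param features Clinical columns tested against the score group by
#'   chi-square/Fisher.
#' @param seed Master seed; per-stage seeds are derived as
#'   `seed + 101 * stage_number`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, clinical, regulators,
                            gene_sets_gmt = NULL, emt_gmt = NULL,
                            drug_auc = NULL, drug_annotation = NULL,
                            expression_scale = c("log2", "fpkm"),
                            k_min = 2L, k_max = 6L, reps = 1000L,
                            subsample_frac = 0.8,
                            fc_thresh = 1.5, adjp_thresh = 0.001,
                            prognostic_p = 0.05, alpha = 0.25,
                            minprop = 0.1, rs_thresh = 0.3,
                            fdr_thresh = 0.05,
                            covariates = character(0),
                            features = character(0),
                            seed = 1L) {
  expression_scale <- match.arg(expression_scale)
  cfg <- list(paths = list(expression = expression, clinical = clinical,
                           regulators = regulators,
                           gene_sets_gmt = gene_sets_gmt,
                           emt_gmt = emt_gmt, drug_auc = drug_auc,
                           drug_annotation = drug_annotation),
              expression_scale = expression_scale,
              k_min = as.integer(k_min), k_max = as.integer(k_max),
              reps = as.integer(reps), subsample_frac = subsample_frac,
              fc_thresh = fc_thresh, adjp_thresh = adjp_thresh,
              prognostic_p = prognostic_p, alpha = alpha,
              minprop = minprop, rs_thresh = rs_thresh,
              fdr_thresh = fdr_thresh,
              covariates = covariates, features = features,
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()], with paths
#' under a `paths:` mapping and everything else at top level.  Relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  paths <- lapply(y$paths, resolve)
  args <- y[setdiff(names(y), "paths")]
  do.call(pipeline_config, c(paths, args))
}

.stage_seed <- function(cfg, stage) cfg$seed + 101L * stage

.write_stage <- function(df, path, stage, cfg) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# hapattern stage=%02d seed=%d", stage,
                     .stage_seed(cfg, stage)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full pattern-to-score analysis
#'
#' Executes, in order: expression preprocessing; resampling consensus
#' clustering of samples on the regulator panel (the sample patterns);
#' moderated one-vs-rest differential expression between patterns and
#' DEG selection; univariate-Cox prognostic screening of the DEGs;
#' consensus clustering of samples on the screened DEGs (the gene-level
#' clusters); the PCA-based HAscore; maximally selected cutpoint
#' dichotomization (within batch when a batch column with several
#' levels is present); Kaplan-Meier/log-rank/Cox survival analysis;
#' ssGSEA enrichment with Kruskal-Wallis comparison across patterns;
#' the EMT score; and drug/clinical association screens.  Each stage
#' writes a TSV named after it, every file starting with a single
#' `#`-prefixed provenance line, and a `manifest.tsv` records the stage
#' list.  Outputs are byte-identical for identical config and seed.
#'
#' @param cfg A `pipeline_config` (or path to a YAML accepted by
#'   [read_pipeline_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list of in-memory stage results (see names).
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  res <- list()
  note <- function(stage, name, files) {
    manifest[[length(manifest) + 1L]] <<-
      tibble::tibble(stage = stage, name = name,
                     files = paste(files, collapse = ";"))
  }
  fail <- function(stage, name, e) {
    stop("pipeline stage ", stage, " (", name, ") failed: ",
         conditionMessage(e), call. = FALSE)
  }
  run_stage <- function(stage, name, fun) {
    tryCatch(fun(), error = function(e) fail(stage, name, e))
  }

  # 1 -- load & preprocess ------------------------------------------------
  expr <- run_stage(1L, "preprocess", function() {
    m <- read_expression(cfg$paths$expression)
    if (cfg$expression_scale == "fpkm") {
      m <- log2(fpkm_to_tpm(m) + 1)
    }
    m
  })
  clinical <- run_stage(1L, "preprocess",
                        function() read_clinical(cfg$paths$clinical))
  idx <- match(clinical$sample_id, colnames(expr))
  if (anyNA(idx)) stop("pipeline stage 1 (preprocess): clinical sample(s) ",
                       "missing from the expression matrix", call. = FALSE)
  expr <- expr[, idx, drop = FALSE]
  has_batch <- "batch" %in% colnames(clinical) &&
    length(unique(clinical$batch)) > 1L
  if (has_batch) expr <- batch_adjust(expr, clinical$batch)
  f1 <- file.path(out_dir, "expression_processed.tsv")
  write_expression(expr, f1)
  note(1L, "preprocess", basename(f1))
  res$expression <- expr
  res$clinical <- clinical

  # 2 -- pattern consensus on the regulator panel -------------------------
  panel <- run_stage(2L, "pattern_consensus", function() {
    p <- readLines(cfg$paths$regulators, warn = FALSE)
    p[nzchar(trimws(p))]
  })
  cc <- run_stage(2L, "pattern_consensus", function() {
    consensus_cluster(expr, panel, k_range = cfg$k_min:cfg$k_max,
                      reps = cfg$reps,
                      subsample_frac = cfg$subsample_frac,
                      seed = .stage_seed(cfg, 2L))
  })
  pattern <- stats::setNames(LETTERS[cc$assignments$cluster],
                             cc$assignments$sample_id)
  f2a <- .write_stage(dplyr::mutate(cc$assignments,
                                    pattern = LETTERS[.data$cluster]),
                      file.path(out_dir, "pattern_assignments.tsv"), 2L, cfg)
  f2b <- .write_stage(cc$metrics,
                      file.path(out_dir, "pattern_consensus_metrics.tsv"),
                      2L, cfg)
  note(2L, "pattern_consensus", basename(c(f2a, f2b)))
  res$pattern_consensus <- cc

  # 3 -- differential expression between patterns -------------------------
  de <- run_stage(3L, "differential_expression", function() {
    tab <- moderated_de(expr, pattern[colnames(expr)])
    degs <- select_degs(tab, cfg$fc_thresh, cfg$adjp_thresh)
    list(table = tab, degs = degs)
  })
  f3a <- .write_stage(de$table, file.path(out_dir, "de_table.tsv"), 3L, cfg)
  f3b <- .write_stage(tibble::tibble(gene = de$degs),
                      file.path(out_dir, "degs.tsv"), 3L, cfg)
  note(3L, "differential_expression", basename(c(f3a, f3b)))
  res$de <- de

  # 4 -- prognostic screen of the DEGs -------------------------------------
  prog <- run_stage(4L, "prognostic_screen", function() {
    screen <- cox_screen(expr, clinical, de$degs)
    keep <- screen$gene[!is.na(screen$p) & screen$p < cfg$prognostic_p]
    if (length(keep) < 2L) {
      stop("fewer than 2 genes passed the prognostic screen at p < ",
           cfg$prognostic_p)
    }
    list(screen = screen, genes = keep)
  })
  f4 <- .write_stage(prog$screen,
                     file.path(out_dir, "prognostic_screen.tsv"), 4L, cfg)
  note(4L, "prognostic_screen", basename(f4))
  res$prognostic <- prog

  # 5 -- gene-level consensus on the screened DEGs ------------------------
  gc <- run_stage(5L, "gene_consensus", function() {
    consensus_cluster(expr, prog$genes, k_range = cfg$k_min:cfg$k_max,
                      reps = cfg$reps,
                      subsample_frac = cfg$subsample_frac,
                      seed = .stage_seed(cfg, 5L))
  })
  f5 <- .write_stage(gc$assignments,
                     file.path(out_dir, "gene_cluster_assignments.tsv"),
                     5L, cfg)
  note(5L, "gene_consensus", basename(f5))
  res$gene_consensus <- gc

  # 6 -- HAscore ------------------------------------------------------------
  score <- run_stage(6L, "hascore", function() hascore(expr, prog$genes))
  f6 <- .write_stage(tibble::tibble(sample_id = names(score),
                                    hascore = unname(score)),
                     file.path(out_dir, "hascore.tsv"), 6L, cfg)
  note(6L, "hascore", basename(f6))
  res$hascore <- score

  # 7 -- cutpoint dichotomization -----------------------------------------
  group <- run_stage(7L, "cutpoint", function() {
    dichotomize_score(score[clinical$sample_id], clinical$os_time,
                      clinical$os_event, minprop = cfg$minprop,
                      batch = if (has_batch) clinical$batch else NULL)
  })
  names(group) <- clinical$sample_id
  f7 <- .write_stage(tibble::tibble(sample_id = clinical$sample_id,
                                    ha_group = unname(group)),
                     file.path(out_dir, "score_groups.tsv"), 7L, cfg)
  note(7L, "cutpoint", basename(f7))
  res$ha_group <- group

  # 8 -- survival analysis --------------------------------------------------
  surv <- run_stage(8L, "survival", function() {
    lr <- logrank_test(clinical$os_time, clinical$os_event, group)
    km <- purrr::map_dfr(c("low", "high"), function(gr) {
      idx <- group == gr
      dplyr::mutate(km_curve(clinical$os_time[idx],
                             clinical$os_event[idx]), group = gr)
    })
    uni <- cox_fit(clinical$os_time, clinical$os_event,
                   matrix(unname(score[clinical$sample_id]), ncol = 1L,
                          dimnames = list(NULL, "hascore")))
    multi <- NULL
    if (length(cfg$covariates) > 0L) {
      mm <- .covariate_matrix(clinical, cfg$covariates)
      multi <- cox_fit(clinical$os_time, clinical$os_event,
                       cbind(hascore = unname(score[clinical$sample_id]),
                             mm))
    }
    list(logrank = lr, km = km, cox_uni = uni, cox_multi = multi)
  })
  cox_tab <- dplyr::mutate(tidy(surv$cox_uni), model = "univariate")
  if (!is.null(surv$cox_multi)) {
    cox_tab <- dplyr::bind_rows(
      cox_tab, dplyr::mutate(tidy(surv$cox_multi), model = "multivariate"))
  }
  f8a <- .write_stage(surv$km, file.path(out_dir, "km_curves.tsv"), 8L, cfg)
  f8b <- .write_stage(dplyr::bind_cols(surv$logrank,
                                       tibble::tibble(comparison =
                                                        "high_vs_low")),
                      file.path(out_dir, "logrank.tsv"), 8L, cfg)
  f8c <- .write_stage(cox_tab, file.path(out_dir, "cox_models.tsv"), 8L, cfg)
  note(8L, "survival", basename(c(f8a, f8b, f8c)))
  res$survival <- surv

  # 9 -- ssGSEA enrichment --------------------------------------------------
  if (!is.null(cfg$paths$gene_sets_gmt)) {
    enr <- run_stage(9L, "enrichment", function() {
      sets <- read_gmt(cfg$paths$gene_sets_gmt)
      raw <- ssgsea_score(expr, sets, alpha = cfg$alpha)
      norm <- suppressWarnings(normalize_scores(raw))
      comp <- raw |>
        dplyr::group_by(.data$set) |>
        dplyr::summarise(kruskal_p = stats::kruskal.test(
          .data$score, factor(pattern[.data$sample_id]))$p.value)
      list(scores = norm, comparison = comp)
    })
    f9a <- .write_stage(enr$scores,
                        file.path(out_dir, "enrichment_scores.tsv"), 9L, cfg)
    f9b <- .write_stage(enr$comparison,
                        file.path(out_dir, "enrichment_comparison.tsv"),
                        9L, cfg)
    note(9L, "enrichment", basename(c(f9a, f9b)))
    res$enrichment <- enr
  } else {
    note(9L, "enrichment", "skipped(no gene_sets_gmt)")
  }

  # 10 -- EMT score ----------------------------------------------------------
  if (!is.null(cfg$paths$emt_gmt)) {
    emt <- run_stage(10L, "emt", function() {
      sets <- read_gmt(cfg$paths$emt_gmt)
      nm <- tolower(names(sets))
      mi <- grep("mesenchymal", nm)
      ei <- grep("epithelial", nm)
      if (length(mi) != 1L || length(ei) != 1L) {
        stop("EMT GMT must contain one mesenchymal and one epithelial set")
      }
      emt_score(expr, sets[[mi]], sets[[ei]])
    })
    f10 <- .write_stage(tibble::tibble(sample_id = names(emt),
                                       emt_score = unname(emt)),
                        file.path(out_dir, "emt_scores.tsv"), 10L, cfg)
    note(10L, "emt", basename(f10))
    res$emt <- emt
  } else {
    note(10L, "emt", "skipped(no emt_gmt)")
  }

  # 11 -- drug & clinical associations --------------------------------------
  assoc_files <- character(0)
  if (!is.null(cfg$paths$drug_auc)) {
    drug <- run_stage(11L, "associations", function() {
      raw <- utils::read.delim(cfg$paths$drug_auc, check.names = FALSE)
      auc <- as.matrix(raw[, -1L, drop = FALSE])
      rownames(auc) <- raw[[1L]]
      annot <- if (!is.null(cfg$paths$drug_annotation)) {
        tibble::as_tibble(utils::read.delim(cfg$paths$drug_annotation,
                                            check.names = FALSE))
      } else NULL
      drug_correlation(score, auc, annot, cfg$rs_thresh, cfg$fdr_thresh)
    })
    f11a <- .write_stage(drug$hits, file.path(out_dir, "drug_hits.tsv"),
                         11L, cfg)
    f11b <- .write_stage(drug$all,
                         file.path(out_dir, "drug_correlations.tsv"),
                         11L, cfg)
    assoc_files <- c(assoc_files, basename(c(f11a, f11b)))
    res$drug <- drug
  }
  if (length(cfg$features) > 0L) {
    clin_assoc <- run_stage(11L, "associations", function() {
      purrr::map_dfr(cfg$features, function(fe) {
        if (!fe %in% colnames(clinical)) {
          stop("clinical feature '", fe, "' not found")
        }
        dplyr::mutate(categorical_association(group, clinical[[fe]]),
                      feature = fe)
      })
    })
    f11c <- .write_stage(clin_assoc,
                         file.path(out_dir, "clinical_associations.tsv"),
                         11L, cfg)
    assoc_files <- c(assoc_files, basename(f11c))
    res$clinical_assoc <- clin_assoc
  }
  if (length(assoc_files) == 0L) assoc_files <- "skipped(no drug/features)"
  note(11L, "associations", assoc_files)

  # manifest ----------------------------------------------------------------
  man <- dplyr::bind_rows(manifest) |>
    dplyr::group_by(.data$stage, .data$name) |>
    dplyr::summarise(files = paste(unique(unlist(strsplit(.data$files, ";"))),
                                   collapse = ";"), .groups = "drop") |>
    dplyr::arrange(.data$stage)
  man_path <- file.path(out_dir, "manifest.tsv")
  con <- file(man_path, "wt")
  writeLines(sprintf("# hapattern run seed=%d k=%d..%d reps=%d",
                     cfg$seed, cfg$k_min, cfg$k_max, cfg$reps), con)
  utils::write.table(man, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  res$manifest <- man
  invisible(res)
}

# reference-level dummy coding; reference = lexicographically first level
.covariate_matrix <- function(clinical, covariates) {
  cols <- lapply(covariates, function(cv) {
    if (!cv %in% colnames(clinical)) {
      stop("covariate '", cv, "' not found in the clinical table")
    }
    v <- clinical[[cv]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1L, dimnames = list(NULL, cv))
    } else {
      f <- factor(v, levels = sort(unique(as.character(v))))
      if (nlevels(f) < 2L) stop("covariate '", cv, "' is constant")
      m <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(m) <- paste0(cv, "_", levels(f)[-1L])
    }
    m
  })
  do.call(cbind, cols)
}
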