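#' Run the full quality-aware batch correction workflow
#'
#' Reproduces, for one dataset, the complete per-dataset analysis: size-factor
#' normalization, the batch detection report (Kruskal-Wallis of `p_low`
#' across batches + design bias), quality-outlier detection, adjusted PCA
#' under each correction variant — uncorrected, batch-corrected,
#' `p_low`-corrected and both-corrected, each with and without the detected
#' outliers — cluster metrics per variant, metric deltas against the
#' uncorrected baseline, and (optionally, for two-group designs) a DEG count
#' per variant. Fully deterministic given inputs and configuration.
#'
#' For corrected variants the penalty weight lambda is selected per variant
#' by [select_lambda()]; outlier-removed variants rebuild the confounder and
#' re-center the expression submatrix on the retained samples. DEG counts on
#' corrected variants are computed on the normalized values with the
#' confounder design regressed out gene-wise (regression residuals), keeping
#' the per-gene test full-rank and comparable to the uncorrected count.
#'
#' @param counts a [count_matrix()] or path to a counts file
#'   (TSV/MatrixMarket, see [read_counts()]).
#' @param samples a [sample_table()] or path to a metadata TSV.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, writes
#'   `summary.json`, per-variant `scores_<variant>.tsv` and `metrics.tsv`.
#' @return an object of class `dataset_summary`: `batch_report`, `outliers`,
#'   `runs` (named list of correction runs, `uncorrected` exactly once),
#'   `deltas` (per corrected variant vs uncorrected), `n_samples`,
#'   `n_genes`, `config`.
#' @export
run_pipeline <- function(counts, samples, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "]: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.character(counts)) counts <- stage("read_counts", read_counts(counts))
  if (is.character(samples))
    samples <- stage("read_sample_table", read_sample_table(samples))
  table <- stage("align_samples", align_samples(counts, samples))

  report <- stage("batch_report", batch_report(table))
  norm <- stage("normalize", log_normalize(counts, config$pseudocount))
  outliers <- stage("detect_outliers",
                    detect_quality_outliers(table, config$outlier_min_gap,
                                            config$outlier_threshold))

  groups <- unique(table$group)
  do_de <- config$compute_de && length(groups) == 2

  values_all <- norm$values  # genes x samples
  k <- config$n_components

  run_variant <- function(use, sample_ids, variant) {
    tab <- table[table$sample_id %in% sample_ids, , drop = FALSE]
    tab <- sample_table(as.data.frame(tab))
    X <- t(values_all[, tab$sample_id, drop = FALSE])
    X <- scale(X, center = TRUE, scale = FALSE)
    attr(X, "scaled:center") <- NULL
    if (is.null(use)) {
      conf <- NULL
      fit <- acpca(X, NULL, lambda = 0, k = k)
      sel <- NULL
    } else {
      conf <- build_confounder(tab, use = use)
      sel <- select_lambda(X, conf, grid = config$lambda_grid,
                           tol = config$penalty_tol, k = k)
      fit <- acpca(X, conf, lambda = sel$lambda, k = k)
    }
    metrics <- evaluate_clustering(fit, tab, n_components = k)
    deg <- NULL
    if (do_de) {
      vals <- if (is.null(use)) values_all[, tab$sample_id, drop = FALSE]
              else t(X - qr.fitted(qr(conf$design), X))
      if (min(table(tab$group)) >= 2)
        deg <- differential_expression(vals, tab, groups[1], groups[2],
                                       alpha = config$de_alpha)$deg_count
    }
    list(variant = variant,
         confounder = if (is.null(use)) "none"
                      else paste(use, collapse = "+"),
         outliers_removed = !setequal(sample_ids, table$sample_id),
         n_samples = nrow(tab),
         lambda = fit$lambda,
         lambda_converged = if (is.null(sel)) NA else sel$converged,
         penalty_ratio = as.numeric(fit$penalty_ratio),
         scores = fit$scores,
         metrics = metrics,
         deg_count = deg)
  }

  all_ids <- table$sample_id
  kept_ids <- setdiff(all_ids, outliers$outlier_sample_ids)
  conf_sets <- list(batch = "batch", plow = "p_low",
                    both = c("batch", "p_low"))

  runs <- list()
  runs$uncorrected <- stage("correct:uncorrected",
                            run_variant(NULL, all_ids, "uncorrected"))
  for (v in names(conf_sets)) {
    runs[[v]] <- stage(paste0("correct:", v),
                       run_variant(conf_sets[[v]], all_ids, v))
    vn <- paste0(v, "_no_outlier")
    runs[[vn]] <- stage(paste0("correct:", vn),
                        run_variant(conf_sets[[v]], kept_ids, vn))
  }

  deltas <- list()
  for (v in setdiff(names(runs), "uncorrected"))
    deltas[[v]] <- metrics_delta(runs$uncorrected$metrics,
                                 runs[[v]]$metrics, label = v)

  summary <- structure(list(batch_report = report, outliers = outliers,
                            runs = runs, deltas = deltas,
                            n_samples = length(all_ids),
                            n_genes = length(counts$gene_ids),
                            config = unclass(config)),
                       class = "dataset_summary")
  if (!is.null(out_dir)) write_summary(summary, out_dir)
  summary
}

#' Rank correction variants by their metric improvement
#'
#' Tabulates the per-variant metric deltas of a [run_pipeline()] summary,
#' sorted by Pearson-gamma delta descending, and flags variants whose sample
#' count differs from the uncorrected baseline (outlier-removed runs), since
#' the indices are sensitive to sample removal.
#'
#' @param summary a `dataset_summary`.
#' @return data.frame with one row per corrected variant.
#' @export
compare_corrections <- function(summary) {
  stopifnot(inherits(summary, "dataset_summary"))
  if (is.null(summary$runs$uncorrected))
    stop("compare_corrections: summary lacks the uncorrected baseline")
  if (length(summary$deltas) < 1)
    stop("compare_corrections: summary contains no corrected runs")
  rows <- lapply(summary$deltas, function(d)
    data.frame(variant = d$label,
               delta_pearson_gamma = d$pearson_gamma,
               delta_dunn1 = d$dunn1,
               delta_wb_ratio = d$wb_ratio,
               n_samples = d$n_after,
               n_changed = d$n_after != d$n_before,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$delta_pearson_gamma), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("dataset_summary:", x$n_genes, "genes x", x$n_samples, "samples\n")
  print(x$batch_report)
  print(x$outliers)
  cat("metric deltas vs uncorrected (gamma-ranked):\n")
  print(compare_corrections(x))
  invisible(x)
}

# plain-list view of a summary, suitable for deterministic JSON
summary_as_list <- function(x) {
  num <- function(v) unname(as.numeric(v))
  br <- x$batch_report
  list(
    n_samples = x$n_samples,
    n_genes = x$n_genes,
    batch_report = list(
      kw_statistic = num(br$kw_statistic), df = br$df,
      p_value = num(br$p_value), design_bias = num(br$design_bias),
      per_batch_mean_plow = as.list(stats::setNames(
        num(br$per_batch_mean_plow), names(br$per_batch_mean_plow))),
      n_per_batch = as.list(stats::setNames(
        as.integer(br$n_per_batch), names(br$n_per_batch)))),
    outliers = list(
      outlier_sample_ids = as.list(x$outliers$outlier_sample_ids),
      threshold_used = num(x$outliers$threshold_used),
      gap = num(x$outliers$gap), method = x$outliers$method),
    runs = lapply(x$runs, function(r) list(
      variant = r$variant, confounder = r$confounder,
      outliers_removed = r$outliers_removed, n_samples = r$n_samples,
      lambda = num(r$lambda), lambda_converged = r$lambda_converged,
      penalty_ratio = num(r$penalty_ratio),
      metrics = list(pearson_gamma = num(r$metrics$pearson_gamma),
                     dunn1 = num(r$metrics$dunn1),
                     wb_ratio = num(r$metrics$wb_ratio),
                     degenerate = r$metrics$degenerate),
      deg_count = r$deg_count)),
    deltas = lapply(x$deltas, function(d) list(
      pearson_gamma = num(d$pearson_gamma), dunn1 = num(d$dunn1),
      wb_ratio = num(d$wb_ratio), n_before = d$n_before,
      n_after = d$n_after)),
    config = x$config[c("pseudocount", "de_alpha", "n_components",
                        "penalty_tol", "outlier_min_gap")])
}

write_summary <- function(summary, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(summary_as_list(summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  for (v in names(summary$runs)) {
    sc <- summary$runs[[v]]$scores
    df <- data.frame(sample_id = rownames(sc), sc, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(out_dir, paste0("scores_", v, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(compare_corrections(summary),
                     file.path(out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
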