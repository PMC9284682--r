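#' Pipeline configuration
#'
#' Bundles the tunable parameters of the end-to-end workflow.
#'
#' @param pseudocount positive real added before the log2 transform.
#' @param de_alpha adjusted p-value cutoff for differential expression
#'   (default 0.05).
#' @param n_components number of adjusted principal components to extract and
#'   to feed to the clustering metrics (default 2, i.e. the first two
#'   dimensions of the PCA).
#' @param lambda_grid strictly increasing penalty-weight grid starting at 0.
#' @param penalty_tol per-component confounder-variance ratio below which a
#'   penalty weight counts as sufficient (default 0.05).
#' @param outlier_min_gap minimum jump in sorted p_low values for the
#'   largest-gap outlier rule, in (0, 1] (default 0.3).
#' @param outlier_threshold optional fixed p_low cutoff; when set it replaces
#'   the largest-gap rule.
#' @param compute_de if `TRUE` and exactly two biological groups are present,
#'   count differentially expressed genes per correction variant.
#' @param seed integer seed for any randomized stage.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(pseudocount = 1,
                            de_alpha = 0.05,
                            n_components = 2L,
                            lambda_grid = seq(0, 20, length.out = 41),
                            penalty_tol = 0.05,
                            outlier_min_gap = 0.3,
                            outlier_threshold = NULL,
                            compute_de = TRUE,
                            seed = 1L) {
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1, pseudocount > 0)
  stopifnot(is.numeric(de_alpha), length(de_alpha) == 1,
            de_alpha > 0, de_alpha < 1)
  n_components <- as.integer(n_components)
  stopifnot(n_components >= 1)
  check_lambda_grid(lambda_grid)
  stopifnot(is.numeric(penalty_tol), penalty_tol > 0, penalty_tol <= 1)
  stopifnot(is.numeric(outlier_min_gap), outlier_min_gap > 0,
            outlier_min_gap <= 1)
  if (!is.null(outlier_threshold))
    stopifnot(is.numeric(outlier_threshold), outlier_threshold >= 0,
              outlier_threshold <= 1)
  structure(list(pseudocount = pseudocount, de_alpha = de_alpha,
                 n_components = n_components, lambda_grid = lambda_grid,
                 penalty_tol = penalty_tol,
                 outlier_min_gap = outlier_min_gap,
                 outlier_threshold = outlier_threshold,
                 compute_de = isTRUE(compute_de),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

check_lambda_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 1 || any(!is.finite(grid)))
    stop("lambda_grid must be a nonempty finite numeric vector")
  if (grid[1] != 0)
    stop("lambda_grid must start at 0")
  if (length(grid) > 1 && any(diff(grid) <= 0))
    stop("lambda_grid must be strictly increasing")
  if (any(grid < 0)) stop("lambda_grid must be nonnegative")
  invisible(grid)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file holds any subset of the [pipeline_config()] field names;
#' unspecified fields keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("read_pipeline_config: file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("read_pipeline_config: unknown field(s): ",
         paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}
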