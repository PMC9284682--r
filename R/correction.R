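#' Build a confounder design for adjusted PCA
#'
#' Assembles the samples x q confounder matrix Y from any mix of a one-hot
#' encoded batch block, the standardized `p_low` column, and optional extra
#' columns (for example surrogate variables computed elsewhere). One-hot
#' blocks stay 0/1 and are then centered; continuous columns are centered and
#' scaled to unit variance. Column provenance is recorded.
#'
#' @param table a [sample_table()].
#' @param use character subset of `c("batch", "p_low")`.
#' @param extra_columns optional numeric matrix, rows aligned to
#'   `table$sample_id`, treated as continuous confounders.
#' @return list of class `confounder_spec` with `design` (centered matrix),
#'   `provenance` (per column) and `sample_ids`.
#' @export
build_confounder <- function(table, use = c("batch", "p_low"),
                             extra_columns = NULL) {
  stopifnot(inherits(table, "sample_table"))
  use <- match.arg(use, c("batch", "p_low"), several.ok = TRUE)
  n <- nrow(table)
  blocks <- list()
  prov <- character(0)
  if ("batch" %in% use) {
    if (length(unique(table$batch)) < 2)
      stop("build_confounder: column 'batch' is constant")
    f <- factor(table$batch)
    onehot <- stats::model.matrix(~ 0 + f)
    colnames(onehot) <- paste0("batch:", levels(f))
    blocks <- c(blocks, list(onehot))
    prov <- c(prov, rep("batch", ncol(onehot)))
  }
  if ("p_low" %in% use) {
    require_plow(table, "build_confounder")
    if (stats::sd(table$p_low) == 0)
      stop("build_confounder: column 'p_low' is constant")
    z <- (table$p_low - mean(table$p_low)) / stats::sd(table$p_low)
    blocks <- c(blocks, list(matrix(z, ncol = 1,
                                    dimnames = list(NULL, "p_low"))))
    prov <- c(prov, "p_low")
  }
  if (!is.null(extra_columns)) {
    ec <- as.matrix(extra_columns)
    if (nrow(ec) != n)
      stop("build_confounder: extra_columns must have one row per sample")
    sds <- apply(ec, 2, stats::sd)
    if (any(sds == 0)) {
      bad <- colnames(ec)[sds == 0]
      if (is.null(bad)) bad <- which(sds == 0)
      stop("build_confounder: constant extra column: ",
           paste(bad, collapse = ", "))
    }
    ec <- scale(ec)
    if (is.null(colnames(ec)))
      colnames(ec) <- paste0("extra", seq_len(ncol(ec)))
    blocks <- c(blocks, list(ec))
    prov <- c(prov, rep("extra", ncol(ec)))
  }
  if (!length(blocks))
    stop("build_confounder: no confounder columns requested")
  Y <- do.call(cbind, blocks)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  attr(Y, "scaled:center") <- NULL
  if (any(colSums(Y^2) == 0))
    stop("build_confounder: all-zero confounder column after centering")
  structure(list(design = Y, provenance = prov,
                 sample_ids = table$sample_id),
            class = "confounder_spec")
}

#' Confounder-adjusted principal component analysis
#'
#' Standard PCA extracts the top eigenvectors of \eqn{X^\top X}. Adjusted PCA
#' penalizes variance lying along a confounder kernel \eqn{K = YY^\top}
#' (trace-normalized to n) and extracts the top eigenvectors of
#' \eqn{X^\top (I - \lambda K) X} instead, so components are steered away
#' from directions predictable from the confounder. With `lambda = 0` this
#' reduces exactly to PCA.
#'
#' When there are more genes than samples the eigenproblem is solved in the
#' n-dimensional sample (row) space via the eigendecomposition of
#' \eqn{G = XX^\top}; this matches the dense gene-space solution on the
#' nonzero spectrum.
#'
#' Component signs are fixed so the largest-magnitude loading entry is
#' positive, making outputs reproducible.
#'
#' @param X column-centered samples x genes matrix (each gene mean 0).
#' @param conf a [build_confounder()] result, or `NULL` (allowed only with
#'   `lambda = 0`).
#' @param lambda penalty weight, >= 0.
#' @param k number of components, `k <= min(n - 1, p)`.
#' @param solver `"auto"` (row space when p > n), `"dense"` or `"rowspace"`.
#' @return object of class `acpca_result`: `loadings` (genes x k,
#'   orthonormal), `scores` (samples x k), `lambda`, `penalty_ratio` (per
#'   component: confounder-kernel variance over total variance of the
#'   component scores), `eigenvalues`, `k`.
#' @export
acpca <- function(X, conf, lambda = 0, k = 2,
                  solver = c("auto", "dense", "rowspace")) {
  solver <- match.arg(solver)
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  k <- as.integer(k)
  if (lambda < 0) stop("acpca: lambda must be >= 0")
  if (k < 1 || k > min(n - 1, p))
    stop("acpca: k must satisfy 1 <= k <= min(n - 1, p) = ", min(n - 1, p))
  scale_x <- max(abs(X), 1e-8)
  if (max(abs(colMeans(X))) > 1e-6 * scale_x)
    stop("acpca: X must be column-centered (gene means 0)")
  if (is.null(conf)) {
    if (lambda != 0)
      stop("acpca: a confounder is required when lambda > 0")
    K <- matrix(0, n, n)
  } else {
    stopifnot(inherits(conf, "confounder_spec"))
    Y <- conf$design
    if (nrow(Y) != n)
      stop("acpca: confounder rows (", nrow(Y), ") do not match samples (",
           n, ")")
    K <- tcrossprod(Y)
    K <- K * (n / sum(diag(K)))
  }
  B <- diag(n) - lambda * K
  if (solver == "auto") solver <- if (p > n) "rowspace" else "dense"
  if (solver == "dense") {
    A <- crossprod(X, B %*% X)
    A <- (A + t(A)) / 2
    ee <- eigen(A, symmetric = TRUE)
    V <- ee$vectors[, seq_len(k), drop = FALSE]
    evals <- ee$values[seq_len(k)]
  } else {
    G <- tcrossprod(X)
    G <- (G + t(G)) / 2
    eg <- eigen(G, symmetric = TRUE)
    keep <- eg$values > max(eg$values, 0) * 1e-12
    r <- sum(keep)
    if (k > r) stop("acpca: k exceeds the rank of X (", r, ")")
    Q <- eg$vectors[, keep, drop = FALSE]
    lam <- eg$values[keep]
    S <- crossprod(Q, B %*% Q) * outer(sqrt(lam), sqrt(lam))
    S <- (S + t(S)) / 2
    es <- eigen(S, symmetric = TRUE)
    W <- es$vectors[, seq_len(k), drop = FALSE]
    U <- Q %*% (W / lam^0.5)
    V <- crossprod(X, U)
    V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
    evals <- es$values[seq_len(k)]
  }
  # reproducible sign: largest-|loading| entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(X)
  colnames(V) <- paste0("PC", seq_len(k))
  scores <- X %*% V
  rownames(scores) <- rownames(X)
  tot <- colSums(scores^2)
  pen <- colSums((K %*% scores) * scores)
  ratio <- ifelse(tot > 0, pen / tot, NA_real_)
  structure(list(loadings = V, scores = scores, lambda = lambda,
                 penalty_ratio = ratio, eigenvalues = evals, k = k),
            class = "acpca_result")
}

#' @export
print.acpca_result <- function(x, ...) {
  cat(sprintf("acpca_result: %d components, lambda = %.4g\n", x$k, x$lambda))
  cat("  penalty ratios:", paste(sprintf("%.4f", x$penalty_ratio),
                                 collapse = " "), "\n")
  invisible(x)
}

#' Select the adjusted-PCA penalty weight
#'
#' Walks an increasing lambda grid (starting at 0) and returns the smallest
#' value at which every extracted component keeps at most `tol` of its
#' variance along the confounder kernel (penalty ratio
#' \eqn{v^\top X^\top K X v / v^\top X^\top X v}). If no grid value
#' qualifies, the value minimizing the worst ratio is returned and
#' convergence is flagged `FALSE`.
#'
#' @param X column-centered samples x genes matrix.
#' @param conf a [build_confounder()] result.
#' @param grid strictly increasing nonnegative reals, `grid[1] == 0`.
#' @param tol maximum acceptable per-component penalty ratio (default 0.05).
#' @param k number of components (default 2).
#' @return list of class `lambda_selection`: `lambda`, `converged`,
#'   `max_ratio` (at the selected lambda), `grid`, `max_ratio_by_lambda`.
#' @export
select_lambda <- function(X, conf, grid = seq(0, 20, length.out = 41),
                          tol = 0.05, k = 2) {
  check_lambda_grid(grid)
  ratios <- numeric(length(grid))
  for (i in seq_along(grid)) {
    fit <- acpca(X, conf, lambda = grid[i], k = k)
    ratios[i] <- max(fit$penalty_ratio)
    if (ratios[i] <= tol) {
      return(structure(list(lambda = grid[i], converged = TRUE,
                            max_ratio = ratios[i], grid = grid[seq_len(i)],
                            max_ratio_by_lambda = ratios[seq_len(i)]),
                       class = "lambda_selection"))
    }
  }
  best <- which.min(ratios)
  structure(list(lambda = grid[best], converged = FALSE,
                 max_ratio = ratios[best], grid = grid,
                 max_ratio_by_lambda = ratios),
            class = "lambda_selection")
}

#' Detect quality outliers from p_low values
#'
#' Mirrors the visual rule of scanning a per-sample quality bar plot for a
#' sudden jump to high values: sort `p_low` ascending and look for the
#' largest consecutive gap within the upper half of the sorted values; if it
#' reaches `min_gap`, every sample above the gap is an outlier. Restricting
#' the scan to the upper half means a gap among good-quality samples never
#' flags low-`p_low` samples. Alternatively a fixed threshold may be given,
#' in which case outliers are simply the samples with `p_low` above it.
#'
#' @param table a [sample_table()].
#' @param min_gap minimum jump in sorted p_low (largest-gap mode), in
#'   (0, 1].
#' @param fixed_threshold optional p_low cutoff; when given, overrides the
#'   gap rule.
#' @return list of class `outlier_result`: `outlier_sample_ids`,
#'   `threshold_used`, `gap`, `method`.
#' @export
detect_quality_outliers <- function(table, min_gap = 0.3,
                                    fixed_threshold = NULL) {
  stopifnot(inherits(table, "sample_table"))
  require_plow(table, "detect_quality_outliers")
  p <- table$p_low
  if (!is.null(fixed_threshold)) {
    ids <- table$sample_id[p > fixed_threshold]
    return(structure(list(outlier_sample_ids = ids,
                          threshold_used = fixed_threshold,
                          gap = NA_real_, method = "fixed_threshold"),
                     class = "outlier_result"))
  }
  stopifnot(min_gap > 0, min_gap <= 1)
  n <- length(p)
  if (n < 3)
    stop("detect_quality_outliers: largest_gap mode needs at least 3 samples")
  s <- sort(p)
  gaps <- diff(s)
  upper <- seq(ceiling(n / 2), n - 1)  # gap i sits between s[i] and s[i+1]
  gu <- gaps[upper]
  best <- upper[max(which(gu == max(gu)))]  # ties: highest cut, fewest flagged
  gap <- gaps[best]
  if (gap >= min_gap) {
    cut <- s[best]
    ids <- table$sample_id[p > cut]
    threshold <- cut
  } else {
    ids <- character(0)
    threshold <- NA_real_
  }
  structure(list(outlier_sample_ids = ids, threshold_used = threshold,
                 gap = gap, method = "largest_gap"),
            class = "outlier_result")
}

#' @export
print.outlier_result <- function(x, ...) {
  cat("outlier_result (", x$method, "): ",
      length(x$outlier_sample_ids), " outlier(s)", sep = "")
  if (length(x$outlier_sample_ids))
    cat(":", paste(x$outlier_sample_ids, collapse = ", "))
  cat("\n")
  invisible(x)
}
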