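#' Kruskal-Wallis rank test with tie correction
#'
#' Computes the tie-corrected Kruskal-Wallis statistic
#' \deqn{H = \left[\frac{12}{N(N+1)} \sum_j R_j^2 / n_j - 3(N+1)\right]
#'       \Big/ \left(1 - \sum T / (N^3 - N)\right)}
#' with midranks for ties and \eqn{T = t^3 - t} per tie group, and a p-value
#' from the chi-square upper tail with `k - 1` degrees of freedom. An exact
#' permutation p-value (enumeration of all distinct label assignments) is
#' available for small samples.
#'
#' Degenerate contract: when all observations are identical the test carries
#' no information and returns `H = 0`, `p = 1` instead of failing, so a
#' constant quality score reports "no detection" rather than crashing a
#' pipeline.
#'
#' @param values numeric observations.
#' @param labels group labels (coerced to factor), at least 2 levels.
#' @param p_method `"chisq"` (default) or `"permutation"` (exact enumeration;
#'   only for 10 or fewer observations).
#' @return list of class `kw_test` with `statistic`, `df`, `p_value`,
#'   `p_method`.
#' @examples
#' kruskal_wallis(1:6, rep(c("A", "B"), each = 3))  # H = 3.857
#' @export
kruskal_wallis <- function(values, labels,
                           p_method = c("chisq", "permutation")) {
  p_method <- match.arg(p_method)
  values <- as.numeric(values)
  labels <- droplevels(as.factor(labels))
  if (length(values) != length(labels))
    stop("kruskal_wallis: values and labels differ in length")
  if (anyNA(values) || anyNA(labels))
    stop("kruskal_wallis: missing values are not supported")
  k <- nlevels(labels)
  n <- length(values)
  if (k < 2) stop("kruskal_wallis: need at least 2 distinct labels")
  if (n < 3) stop("kruskal_wallis: need at least 3 observations")
  df <- k - 1L
  if (length(unique(values)) == 1L)
    return(structure(list(statistic = 0, df = df, p_value = 1,
                          p_method = "degenerate"), class = "kw_test"))
  H <- kw_statistic(values, labels)
  p <- if (p_method == "chisq") {
    stats::pchisq(H, df = df, lower.tail = FALSE)
  } else {
    if (n > 10)
      stop("kruskal_wallis: exact permutation limited to n <= 10")
    kw_exact_p(values, labels, H)
  }
  structure(list(statistic = H, df = df, p_value = p, p_method = p_method),
            class = "kw_test")
}

# tie-corrected H for a value/label pairing
kw_statistic <- function(values, labels) {
  n <- length(values)
  r <- rank(values)  # midranks
  Rj <- tapply(r, labels, sum)
  nj <- tabulate(labels)
  H <- 12 / (n * (n + 1)) * sum(Rj^2 / nj) - 3 * (n + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H / C
}

# exact permutation p: enumerate all distinct assignments of labels to
# positions (multinomial enumeration over index subsets)
kw_exact_p <- function(values, labels, H_obs) {
  nj <- tabulate(labels)
  assigns <- multiset_assignments(length(values), nj)
  lev <- levels(labels)
  hs <- vapply(assigns, function(a)
    kw_statistic(values, factor(lev[a], levels = lev)), numeric(1))
  mean(hs >= H_obs - 1e-12)
}

# all ways to partition positions 1..n into labeled groups of sizes nj;
# returns a list of integer label-index vectors of length n
multiset_assignments <- function(n, nj) {
  rec <- function(free, sizes, lab) {
    if (length(sizes) == 0) return(list(integer(0)))
    if (length(sizes) == 1) {
      a <- integer(0)
      a[free] <- lab
      return(list(a))
    }
    out <- list()
    picks <- utils::combn(free, sizes[1], simplify = FALSE)
    for (p in picks) {
      rest <- rec(setdiff(free, p), sizes[-1], lab + 1L)
      for (r in rest) {
        r[p] <- lab
        out[[length(out) + 1L]] <- r
      }
    }
    out
  }
  lapply(rec(seq_len(n), nj, 1L), function(a) a[seq_len(n)])
}

#' Pearson gamma of a clustering
#'
#' The correlation between pairwise distances and a 0/1 vector in which 0
#' marks a same-cluster pair and 1 a different-cluster pair: tight, well
#' separated clusters give values near 1.
#'
#' @param distances condensed pairwise distances over all unordered pairs
#'   (e.g. `as.numeric(dist(points))`).
#' @param same_cluster logical/0-1 vector over the same pairs, `TRUE` when
#'   the two points share a cluster.
#' @return the correlation in `[-1, 1]`, or `NA_real_` when either vector is
#'   constant (undefined-value signal; callers decide the fallback).
#' @export
pearson_gamma <- function(distances, same_cluster) {
  distances <- as.numeric(distances)
  same_cluster <- as.numeric(as.logical(same_cluster))
  if (length(distances) != length(same_cluster))
    stop("pearson_gamma: input lengths differ")
  if (length(distances) < 2)
    stop("pearson_gamma: need at least 2 pairs")
  different <- 1 - same_cluster
  if (stats::sd(distances) == 0 || stats::sd(different) == 0)
    return(NA_real_)
  stats::cor(distances, different)
}

# condensed same-cluster indicator matching dist() pair order
pair_same_cluster <- function(labels) {
  n <- length(labels)
  out <- logical(n * (n - 1) / 2)
  idx <- 1L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out[idx] <- labels[i] == labels[j]
    idx <- idx + 1L
  }
  out
}

#' Design bias: how strongly quality aligns with the biological groups
#'
#' Pearson gamma computed on the 1-D distances `|p_low_i - p_low_j|` against
#' the different-group indicator, rescaled from `[-1, 1]` to `[0, 1]` as
#' `(gamma + 1) / 2`. High values warn that samples cluster by quality along
#' group lines, so a quality-based correction risks removing biological
#' signal. A constant `p_low` carries no information and returns 0.5.
#'
#' @param table a [sample_table()] with at least 2 groups and 3 samples.
#' @return design bias in `[0, 1]`.
#' @export
design_bias <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  require_plow(table, "design_bias")
  if (length(unique(table$group)) < 2)
    stop("design_bias: need at least 2 groups")
  if (nrow(table) < 3)
    stop("design_bias: need at least 3 samples")
  d <- as.numeric(stats::dist(table$p_low))
  g <- pearson_gamma(d, pair_same_cluster(table$group))
  if (is.na(g)) return(0.5)
  (g + 1) / 2
}

#' Batch detection report
#'
#' The machine-readable summary of quality-based batch detection for one
#' dataset: the tie-corrected Kruskal-Wallis test of `p_low` across batches,
#' the design bias of `p_low` against the biological groups, and per-batch
#' `p_low` means and sizes.
#'
#' @param table a [sample_table()] with at least 2 distinct batches.
#' @return list of class `batch_report` with `kw_statistic`, `df`, `p_value`,
#'   `design_bias`, `per_batch_mean_plow`, `n_per_batch`.
#' @export
batch_report <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  require_plow(table, "batch_report")
  if (length(unique(table$batch)) < 2)
    stop("batch_report: need at least 2 distinct batches")
  kw <- kruskal_wallis(table$p_low, table$batch)
  structure(list(kw_statistic = kw$statistic, df = kw$df,
                 p_value = kw$p_value,
                 design_bias = design_bias(table),
                 per_batch_mean_plow =
                   tapply(table$p_low, table$batch, mean),
                 n_per_batch = table(table$batch)),
            class = "batch_report")
}

#' @export
print.batch_report <- function(x, ...) {
  cat("Quality-based batch detection\n")
  cat(sprintf("  Kruskal-Wallis H = %.4g (df = %d), p = %.3g\n",
              x$kw_statistic, x$df, x$p_value))
  cat(sprintf("  design bias (p_low vs group) = %.3f\n", x$design_bias))
  cat("  mean p_low per batch:\n")
  for (b in names(x$per_batch_mean_plow))
    cat(sprintf("    %s: %.3f (n = %d)\n", b, x$per_batch_mean_plow[[b]],
                as.integer(x$n_per_batch[[b]])))
  invisible(x)
}
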