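# shared fixtures and independent oracles

tiny_table <- function(p_low = c(0, 0.1, 0.8, 0.9),
                       group = c("A", "A", "B", "B"),
                       batch = c("b1", "b1", "b2", "b2")) {
  sample_table(data.frame(
    sample_id = sprintf("s%d", seq_along(p_low)),
    group = group, batch = batch, p_low = p_low,
    stringsAsFactors = FALSE))
}

tiny_counts <- function(m, genes = sprintf("g%d", seq_len(nrow(m))),
                        samples = sprintf("s%d", seq_len(ncol(m)))) {
  dimnames(m) <- list(genes, samples)
  count_matrix(m)
}

# brute-force pairwise-loop oracles for the cluster metrics: plain double
# loops, no shared code with the implementation
oracle_metrics <- function(points, labels) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  d <- c(); same <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- c(d, sqrt(sum((points[i, ] - points[j, ])^2)))
    same <- c(same, labels[i] == labels[j])
  }
  gamma <- if (sd(d) == 0 || all(same) || all(!same)) NA_real_
           else cor(d, as.numeric(!same))
  diam <- if (any(same)) max(d[same]) else 0
  sep <- min(d[!same])
  dunn <- if (diam == 0) { if (sep == 0) 0 else Inf } else sep / diam
  wb <- if (any(same)) mean(d[same]) / mean(d[!same]) else NA_real_
  list(gamma = gamma, dunn = dunn, wb = wb)
}

# tie-free Kruskal-Wallis H from first principles (no tie correction needed)
oracle_kw_h <- function(values, labels) {
  n <- length(values)
  r <- rank(values)
  s <- 0
  for (l in unique(labels)) {
    rl <- r[labels == l]
    s <- s + sum(rl)^2 / length(rl)
  }
  12 / (n * (n + 1)) * s - 3 * (n + 1)
}

# exact permutation p-value by enumerating all distinct assignments of the
# label multiset to positions (recursive over subsets)
oracle_kw_exact_p <- function(values, labels) {
  labels <- as.character(labels)
  h_obs <- oracle_kw_h(values, labels)
  sizes <- table(labels)
  levs <- names(sizes)
  hits <- 0; total <- 0
  rec <- function(free, li, assign) {
    if (li > length(levs)) {
      h <- oracle_kw_h(values, assign)
      total <<- total + 1
      if (h >= h_obs - 1e-12) hits <<- hits + 1
      return(invisible())
    }
    if (li == length(levs)) {
      assign[free] <- levs[li]
      rec(integer(0), li + 1L, assign)
      return(invisible())
    }
    for (p in utils::combn(free, sizes[[li]], simplify = FALSE)) {
      a2 <- assign; a2[p] <- levs[li]
      rec(setdiff(free, p), li + 1L, a2)
    }
  }
  rec(seq_along(values), 1L, character(length(values)))
  hits / total
}

# center the samples x genes view of a normalized matrix
centered_expr <- function(norm) {
  X <- scale(t(norm$values), center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  X
}
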