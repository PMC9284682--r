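#' Simulation configuration
#'
#' Describes a synthetic RNA-seq dataset with multiplicative group and batch
#' effects on negative-binomial counts and a per-sample low-quality
#' probability `p_low` that can be coupled to batch membership. The defaults
#' describe the quality-coupled regime the correction workflow is designed
#' for: 2 groups x 2 batches with 10 samples per cell (40 samples x 2000
#' genes), a batch effect carried
#' by 10% of genes at log2FC 2 whose per-sample magnitude scales with that
#' sample's `p_low` (`quality_coupling = 1`), a biological group effect on a
#' disjoint 10% of genes at log2FC 1.5, and `p_low` shifted upwards by 0.4 in
#' the second batch.
#'
#' Group effects apply to samples outside the first (reference) group; batch
#' effects and the `p_low` shift apply to samples outside the first
#' (reference) batch.
#'
#' @param n_genes number of genes.
#' @param groups,batches labels of the biological groups and batches.
#' @param samples_per_cell samples per (group, batch) cell: a single integer
#'   for a balanced design or a groups x batches matrix.
#' @param baseline_mean per-gene baseline means are drawn lognormal around
#'   this value (see `baseline_sdlog`).
#' @param baseline_sdlog spread (log scale sd) of the per-gene baseline means,
#'   giving size-factor estimation a realistic dynamic range.
#' @param dispersion negative-binomial dispersion; variance = mu + dispersion
#'   * mu^2.
#' @param frac_group_genes,group_log2fc fraction of genes carrying the group
#'   effect and its log2 fold change.
#' @param frac_batch_genes,batch_log2fc fraction of genes carrying the batch
#'   effect and its (maximal) log2 fold change.
#' @param plow_base baseline p_low.
#' @param plow_batch_shift added to p_low for samples in non-reference
#'   batches.
#' @param plow_noise_sd sd of Gaussian noise added to p_low before clipping
#'   to `[0, 1]`.
#' @param quality_coupling in `[0, 1]`: 0 = the batch perturbation is the same
#'   for every affected sample; 1 = it scales with the sample's
#'   `p_low / max(p_low)`.
#' @param seed integer seed; the full dataset is reproducible from it.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              groups = c("g1", "g2"),
                              batches = c("b1", "b2"),
                              samples_per_cell = 10L,
                              baseline_mean = 100,
                              baseline_sdlog = 1,
                              dispersion = 0.1,
                              frac_group_genes = 0.1,
                              group_log2fc = 1.5,
                              frac_batch_genes = 0.1,
                              batch_log2fc = 2,
                              plow_base = 0.2,
                              plow_batch_shift = 0.4,
                              plow_noise_sd = 0.05,
                              quality_coupling = 1,
                              seed = 1L) {
  groups <- as.character(groups)
  batches <- as.character(batches)
  if (length(groups) < 2)
    stop("simulation_config: need at least 2 groups")
  if (length(batches) < 1)
    stop("simulation_config: need at least 1 batch")
  if (is.matrix(samples_per_cell)) {
    if (!identical(dim(samples_per_cell),
                   c(length(groups), length(batches))))
      stop("simulation_config: samples_per_cell matrix must be groups x ",
           "batches")
    cells <- samples_per_cell
  } else {
    cells <- matrix(as.integer(samples_per_cell), length(groups),
                    length(batches))
  }
  dimnames(cells) <- list(groups, batches)
  if (any(cells < 0)) stop("simulation_config: negative cell counts")
  if (sum(cells) < 4)
    stop("simulation_config: total samples must be at least 4")
  stopifnot(n_genes >= 1, baseline_mean > 0, dispersion > 0,
            baseline_sdlog >= 0)
  for (f in c(frac_group_genes, frac_batch_genes, quality_coupling,
              plow_base))
    if (f < 0 || f > 1)
      stop("simulation_config: fractions, quality_coupling and plow_base ",
           "must lie in [0, 1]")
  if (frac_group_genes + frac_batch_genes > 1)
    stop("simulation_config: group and batch gene sets are disjoint; ",
         "their fractions must sum to at most 1")
  stopifnot(group_log2fc >= 0, batch_log2fc >= 0, plow_noise_sd >= 0)
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 batches = batches, samples_per_cell = cells,
                 baseline_mean = baseline_mean,
                 baseline_sdlog = baseline_sdlog, dispersion = dispersion,
                 frac_group_genes = frac_group_genes,
                 group_log2fc = group_log2fc,
                 frac_batch_genes = frac_batch_genes,
                 batch_log2fc = batch_log2fc, plow_base = plow_base,
                 plow_batch_shift = plow_batch_shift,
                 plow_noise_sd = plow_noise_sd,
                 quality_coupling = quality_coupling,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a counts + metadata dataset with known ground truth
#'
#' Counts are drawn per gene g and sample s from a negative binomial with
#' mean
#' \deqn{\mu_{gs} = b_g \cdot 2^{\mathrm{lfc}_{grp} I_{gs}} \cdot
#'       2^{\mathrm{lfc}_{bat} w_s J_{gs}}}
#' where \eqn{b_g} is the lognormal baseline, \eqn{I_{gs}} indicates a group
#' gene in an affected (non-reference) group, \eqn{J_{gs}} a batch gene in an
#' affected batch, and \eqn{w_s = (1 - c) + c\, p_{low}(s)/\max_s p_{low}}
#' couples the batch perturbation to sample quality with strength c.
#' `p_low(s)` is the clipped value
#' `clip(plow_base + shift * I[s in shifted batch] + N(0, sd), 0, 1)`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `counts` ([count_matrix()]), `table`
#'   ([sample_table()]) and `truth` (class `simulation_truth`: group and
#'   batch gene ids, per-sample batch-effect multiplier, unclipped p_low).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    cells <- config$samples_per_cell
    group <- batch <- character(0)
    for (g in rownames(cells)) for (b in colnames(cells)) {
      n <- cells[g, b]
      group <- c(group, rep(g, n))
      batch <- c(batch, rep(b, n))
    }
    n <- length(group)
    sample_ids <- sprintf("s%02d", seq_len(n))
    gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))

    in_shifted_batch <- batch != config$batches[1]
    p_raw <- config$plow_base +
      config$plow_batch_shift * in_shifted_batch +
      stats::rnorm(n, 0, config$plow_noise_sd)
    p_low <- pmin(pmax(p_raw, 0), 1)

    mx <- max(p_low)
    w <- if (mx > 0)
      (1 - config$quality_coupling) + config$quality_coupling * p_low / mx
    else rep(1 - config$quality_coupling, n)

    n_grp <- round(config$frac_group_genes * config$n_genes)
    n_bat <- round(config$frac_batch_genes * config$n_genes)
    pick <- sample.int(config$n_genes, n_grp + n_bat)
    group_genes <- sort(pick[seq_len(n_grp)])
    batch_genes <- sort(pick[n_grp + seq_len(n_bat)])

    baseline <- stats::rlnorm(config$n_genes,
                              meanlog = log(config$baseline_mean) -
                                config$baseline_sdlog^2 / 2,
                              sdlog = config$baseline_sdlog)

    in_affected_group <- group != config$groups[1]
    log2mu <- matrix(log2(baseline), config$n_genes, n)
    if (n_grp > 0)
      log2mu[group_genes, in_affected_group] <-
        log2mu[group_genes, in_affected_group] + config$group_log2fc
    bmult <- 2^(config$batch_log2fc * w * in_shifted_batch)
    if (n_bat > 0)
      log2mu[batch_genes, ] <- log2mu[batch_genes, ] +
        matrix(log2(bmult), n_bat, n, byrow = TRUE)

    mu <- 2^log2mu
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config$dispersion),
                     config$n_genes, n)
    dimnames(counts) <- list(gene_ids, sample_ids)

    table <- sample_table(data.frame(sample_id = sample_ids, group = group,
                                     batch = batch, p_low = p_low,
                                     stringsAsFactors = FALSE))
    truth <- structure(list(group_gene_ids = gene_ids[group_genes],
                            batch_gene_ids = gene_ids[batch_genes],
                            batch_multiplier = stats::setNames(bmult,
                                                               sample_ids),
                            p_low_unclipped = stats::setNames(p_raw,
                                                              sample_ids)),
                       class = "simulation_truth")
    list(counts = count_matrix(counts), table = table, truth = truth)
  })
}

#' Inject quality outliers into a simulated dataset
#'
#' Picks `k` samples at random, raises their `p_low` by 0.5 (clipped at 1)
#' and multiplies their counts gene-wise by iid lognormal(0, `severity`)
#' noise (rounded back to whole counts), emulating the grossly skewed samples
#' that are removed manually in practice.
#'
#' @param counts a [count_matrix()].
#' @param table the matching [sample_table()].
#' @param k number of samples to corrupt, `0 <= k < n`.
#' @param severity sd (log scale) of the multiplicative noise; must be > 0.
#' @param seed integer seed.
#' @return list with modified `counts`, `table` and the chosen `outlier_ids`.
#' @export
inject_outliers <- function(counts, table, k, severity = 1, seed = 1L) {
  stopifnot(inherits(counts, "count_matrix"), inherits(table, "sample_table"))
  n <- length(counts$sample_ids)
  k <- as.integer(k)
  if (k < 0 || k >= n)
    stop("inject_outliers: k must satisfy 0 <= k < n_samples (n = ", n, ")")
  if (severity <= 0) stop("inject_outliers: severity must be > 0")
  if (k == 0)
    return(list(counts = counts, table = table, outlier_ids = character(0)))
  withr::with_seed(as.integer(seed), {
    ids <- sample(counts$sample_ids, k)
    m <- counts$counts
    for (s in ids) {
      noise <- stats::rlnorm(nrow(m), 0, severity)
      m[, s] <- round(m[, s] * noise)
    }
    tab <- table
    hit <- tab$sample_id %in% ids
    tab$p_low[hit] <- pmin(1, tab$p_low[hit] + 0.5)
    list(counts = count_matrix(m), table = sample_table(as.data.frame(tab)),
         outlier_ids = ids)
  })
}
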