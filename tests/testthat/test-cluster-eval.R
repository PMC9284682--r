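test_that("dunn index follows the separation/diameter definition", {
  expect_equal(dunn_index(c(0, 1, 10, 11), c("A", "A", "B", "B")), 9)
  expect_equal(dunn_index(c(0, 10, 1, 11), c("A", "A", "B", "B")), 0.1)
  # singleton clusters: zero diameter, +Inf sentinel
  expect_identical(dunn_index(c(0, 5), c("A", "B")), Inf)
  # coincident points: 0 by contract
  expect_equal(dunn_index(rep(1, 4), c("A", "A", "B", "B")), 0)
  expect_error(dunn_index(1:4, rep("A", 4)), "2 clusters")
})

test_that("wb ratio follows the within/between mean definition", {
  expect_equal(wb_ratio(c(0, 1, 10, 11), c("A", "A", "B", "B")), 0.1)
  # label symmetry
  expect_equal(wb_ratio(c(0, 1, 10, 11), c("B", "B", "A", "A")), 0.1)
  # all-singleton error is distinct from the single-cluster error
  expect_error(wb_ratio(1:3, c("A", "B", "C")), "singleton")
  expect_error(wb_ratio(1:3, c("A", "A", "A")), "2 clusters")
})

test_that("wb ratio is near 1 when both clusters share a distribution", {
  withr::with_seed(9, {
    pts <- matrix(rnorm(80), 40, 2)
    wb <- wb_ratio(pts, rep(c("A", "B"), 20))
    expect_gte(wb, 0.8); expect_lte(wb, 1.2)
  })
})

test_that("all three metrics match brute-force oracles on random instances", {
  withr::with_seed(71, {
    for (i in 1:40) {
      n <- sample(4:30, 1); d <- sample(1:5, 1)
      pts <- matrix(rnorm(n * d), n, d)
      labs <- sample(letters[1:sample(2:4, 1)], n, replace = TRUE)
      if (length(unique(labs)) < 2 || !any(duplicated(labs))) next
      orc <- oracle_metrics(pts, labs)
      expect_equal(dunn_index(pts, labs), orc$dunn, tolerance = 1e-12)
      expect_equal(wb_ratio(pts, labs), orc$wb, tolerance = 1e-12)
    }
  })
})

test_that("metrics are rigid-motion invariant; ratios are scale invariant", {
  withr::with_seed(72, {
    pts <- matrix(rnorm(24), 12, 2)
    labs <- rep(c("A", "B", "C"), 4)
    th <- 0.7
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    moved <- pts %*% R + matrix(c(3, -5), 12, 2, byrow = TRUE)
    expect_equal(dunn_index(moved, labs), dunn_index(pts, labs),
                 tolerance = 1e-12)
    expect_equal(wb_ratio(moved, labs), wb_ratio(pts, labs),
                 tolerance = 1e-12)
    d0 <- as.numeric(dist(pts))
    same <- as.numeric(dist(as.integer(factor(labs)))) == 0
    expect_equal(pearson_gamma(as.numeric(dist(moved)), same),
                 pearson_gamma(d0, same), tolerance = 1e-12)
    expect_equal(dunn_index(pts * 7.3, labs), dunn_index(pts, labs),
                 tolerance = 1e-12)
    expect_equal(wb_ratio(pts * 7.3, labs), wb_ratio(pts, labs),
                 tolerance = 1e-12)
  })
})

test_that("pulling clusters apart moves gamma up and wb ratio down", {
  withr::with_seed(73, {
    base <- matrix(rnorm(60), 30, 2)
    labs <- rep(c("A", "B"), 15)
    seps <- seq(0, 4, by = 1)
    gammas <- wbs <- numeric(length(seps))
    for (i in seq_along(seps)) {
      pts <- base
      pts[labs == "B", 1] <- pts[labs == "B", 1] + seps[i]
      same <- as.numeric(dist(as.integer(factor(labs)))) == 0
      gammas[i] <- pearson_gamma(as.numeric(dist(pts)), same)
      wbs[i] <- wb_ratio(pts, labs)
    }
    expect_true(all(diff(gammas) > 0))
    expect_true(all(diff(wbs) < 0))
  })
})

test_that("evaluate_clustering scores embeddings against group labels", {
  # strong group separation, no batch structure
  sim <- simulate_dataset(simulation_config(
    n_genes = 400, group_log2fc = 3, batch_log2fc = 0, plow_batch_shift = 0,
    samples_per_cell = 5, seed = 14))
  X <- centered_expr(log_normalize(sim$counts))
  fit <- acpca(X, NULL, 0, 2)
  m <- evaluate_clustering(fit, sim$table)
  expect_gt(m$pearson_gamma, 0.5)
  expect_lt(m$wb_ratio, 0.5)
  expect_equal(m$n_samples, 20L)
  expect_equal(m$n_clusters, 2L)
  # random labels give near-zero gamma
  withr::with_seed(15, {
    tb <- sim$table
    tb$group <- sample(tb$group)
    m2 <- evaluate_clustering(fit, sample_table(as.data.frame(tb)))
    expect_lt(abs(m2$pearson_gamma), 0.25)
  })
  # identical points: degenerate flag, gamma 0, dunn 0
  sc <- matrix(0, 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  tb6 <- tiny_table(p_low = rep(0.2, 6), group = rep(c("A", "B"), 3),
                    batch = rep(c("b1", "b2"), each = 3))
  m3 <- evaluate_clustering(sc, tb6)
  expect_true(m3$degenerate)
  expect_equal(m3$pearson_gamma, 0)
  expect_equal(m3$dunn1, 0)
})

test_that("metric deltas subtract corrected minus uncorrected", {
  before <- cluster_metrics(0.09, 0.01, 0.91, n_samples = 10L,
                            n_clusters = 2L, n_components = 2L)
  after <- cluster_metrics(0.32, 0.17, 0.68, n_samples = 10L,
                           n_clusters = 2L, n_components = 2L)
  d <- metrics_delta(before, after, "batch")
  expect_equal(d$pearson_gamma, 0.23)
  expect_equal(d$wb_ratio, -0.23)
  # no-op correction: all deltas zero
  d0 <- metrics_delta(before, before)
  expect_equal(unlist(d0[c("pearson_gamma", "dunn1", "wb_ratio")]),
               c(pearson_gamma = 0, dunn1 = 0, wb_ratio = 0))
  bad <- cluster_metrics(0.5, 1, 0.5, n_clusters = 3L, n_components = 2L)
  expect_error(metrics_delta(before, bad), "different labelings")
})
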