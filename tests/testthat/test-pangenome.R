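test_that("partition counts families by occupancy class", {
  tab <- toy_ortholog_table(list(
    c(A = "a1", B = "b1", C = "c1"),
    c(A = "a2", B = "b2", C = "c2"),
    c(A = "a3", B = "b3"),
    c(A = "a4"),
    c(C = "c4")), c("A", "B", "C"))
  p <- partition_counts(tab)
  expect_equal(as.numeric(p[, 1:4]), c(5, 2, 1, 2))
  # conservation
  expect_equal(p$pan, p$core + p$accessory + p$singleton)

  # all families at occupancy G: core == pan
  tab2 <- toy_ortholog_table(list(c(A = "a1", B = "b1"),
                                  c(A = "a2", B = "b2")), c("A", "B"))
  p2 <- partition_counts(tab2)
  expect_equal(p2$core, p2$pan)
  expect_equal(p2$accessory + p2$singleton, 0)
})

test_that("development endpoints equal the exact values", {
  sim <- small_sim(seed = 41)
  tab <- suppressMessages(build_ortholog_table(sim$genomes, "g01"))
  curve <- pan_development(tab, seed = 1)
  med <- development_medians(curve)
  part <- partition_counts(tab)
  G <- part$n_genomes
  # N = G: single subset; pan/core equal the partition values
  expect_equal(med$pan_median[med$n == G], part$pan)
  expect_equal(med$core_median[med$n == G], part$core)
  # N = 1: per-genome gene counts
  sizes <- sim$genomes |> dplyr::filter(type == "protein") |>
    dplyr::count(genome) |> dplyr::pull(n)
  expect_equal(med$pan_median[med$n == 1], median(sizes))
  expect_equal(med$core_median[med$n == 1], median(sizes))
})

test_that("exhaustive medians equal an independent enumeration", {
  tab <- toy_ortholog_table(list(
    c(A = "a1", B = "b1", C = "c1", D = "d1"),
    c(A = "a2", B = "b2", C = "c2", D = "d2"),
    c(A = "a3", B = "b3", C = "c3"),
    c(B = "b4", C = "c4"),
    c(A = "a5"), c(D = "d5"), c(D = "d6")), c("A", "B", "C", "D"))
  curve <- pan_development(tab, seed = 4)
  med <- development_medians(curve)
  oracle <- enumerate_medians(tab)
  expect_equal(med$pan_median, oracle$pan_median)
  expect_equal(med$core_median, oracle$core_median)
})

test_that("per-subset invariants hold and sampling is reproducible", {
  sim <- small_sim(seed = 43)
  tab <- suppressMessages(build_ortholog_table(sim$genomes, "g01"))
  sizes <- sim$genomes |> dplyr::filter(type == "protein") |>
    dplyr::count(genome)
  sz <- stats::setNames(sizes$n, sizes$genome)
  curve <- pan_development(tab, max_samples_per_n = 3, seed = 10)
  expect_true(all(curve$pan >= curve$core))
  subset_sizes <- purrr::map(strsplit(curve$genomes, ","), ~ sz[.x])
  expect_true(all(curve$core <= purrr::map_dbl(subset_sizes, min)))
  expect_true(all(curve$pan <= purrr::map_dbl(subset_sizes, sum)))
  # monotone medians on the exhaustive curve
  med <- development_medians(pan_development(tab, seed = 10))
  expect_true(all(diff(med$pan_median) >= 0))
  expect_true(all(diff(med$core_median) <= 0))
  # capped sampling draws at most the cap, and the same seed reproduces it
  expect_true(all(table(curve$n) <= 3))
  curve2 <- pan_development(tab, max_samples_per_n = 3, seed = 10)
  expect_identical(as.data.frame(curve), as.data.frame(curve2))
})

test_that("Heaps' law refit recovers parameters from noiseless power laws", {
  for (gamma in c(0.1, 0.5, 0.9)) {
    d <- data.frame(n = 1:8, pan = 1500 * (1:8)^gamma)
    fit <- fit_heaps(d)
    expect_equal(fit$gamma, gamma, tolerance = 1e-6)
    expect_equal(fit$k, 1500, tolerance = 1e-6)
    expect_equal(fit$alpha + fit$gamma, 1)
  }
})

test_that("flat and linear pan curves give the boundary Heaps fits", {
  flat <- fit_heaps(data.frame(n = 1:6, pan = rep(2000, 6)))
  expect_equal(flat$gamma, 0)
  expect_equal(flat$alpha, 1)
  expect_equal(flat$k, 2000)
  linear <- fit_heaps(data.frame(n = 1:6, pan = 1:6))
  expect_equal(linear$gamma, 1, tolerance = 1e-6)
  expect_equal(linear$k, 1, tolerance = 1e-6)
  expect_equal(linear$alpha, 0, tolerance = 1e-6)
  expect_error(fit_heaps(data.frame(n = 1:2, pan = c(1, 2))), ">= 3")
})

test_that("exponential decay refit recovers known constants exactly", {
  d <- data.frame(n = 1:8, core = 100 * exp(-(1:8) / 2) + 1000)
  fit <- fit_decay(d)
  expect_equal(fit$k, 100, tolerance = 1e-6)
  expect_equal(fit$tau, 2, tolerance = 1e-6)
  expect_equal(fit$tg_theta, 1000, tolerance = 1e-6)

  flat <- fit_decay(data.frame(n = 1:6, core = rep(750, 6)))
  expect_equal(predict(flat, 1:6), rep(750, 6), tolerance = 1e-6)
  expect_error(fit_decay(data.frame(n = 1:3, core = 3:1)), ">= 4")
})

test_that("openness classification uses alpha < 1 with boundary closed", {
  mk <- function(alpha) structure(list(alpha = alpha), class = "heaps_fit")
  expect_equal(classify_openness(mk(0.815)), "open")
  expect_equal(classify_openness(mk(1.0)), "closed")
  expect_equal(classify_openness(mk(1.3)), "closed")
})

test_that("tidy and glance expose the fitted constants", {
  fit <- fit_heaps(data.frame(n = 1:8, pan = 2000 * (1:8)^0.3))
  td <- tidy(fit)
  expect_equal(td$term, c("k", "gamma", "alpha"))
  expect_equal(td$estimate[2], 0.3, tolerance = 1e-6)
  expect_equal(glance(fit)$openness, "open")
  dfit <- fit_decay(data.frame(n = 1:8, core = 50 * exp(-(1:8) / 3) + 900))
  expect_equal(tidy(dfit)$estimate, c(50, 3, 900), tolerance = 1e-5)
})

test_that("excluding a divergent genome narrows the core-size spread", {
  # a five-genome set where one genome lost 40% of its core genes: whenever
  # it is sampled the core drops, widening the spread at fixed N
  sim <- small_sim(seed = 59, n_genomes = 5, n_core = 30,
                   accessory_spectrum = NULL, n_singletons = 1)
  gs <- sim$genomes
  out_genes <- sim$truth |>
    dplyr::filter(genome == "g05", class == "core") |>
    dplyr::slice_head(n = 12) |>
    dplyr::pull(gene_id)
  gs_out <- gs[!(gs$genome == "g05" & gs$seq_id %in% out_genes), ]
  tab_with <- suppressMessages(build_ortholog_table(gs_out, "g01"))
  gs_without <- gs_out[gs_out$genome != "g05", ]
  tab_without <- suppressMessages(build_ortholog_table(gs_without, "g01"))
  iqr_core_at <- function(tab, N) {
    curve <- pan_development(tab, seed = 2)
    with(development_medians(curve), core_q3[n == N] - core_q1[n == N])
  }
  expect_gt(iqr_core_at(tab_with, 3), iqr_core_at(tab_without, 3))
})

test_that("development curve plot builds", {
  sim <- small_sim(seed = 61)
  tab <- suppressMessages(build_ortholog_table(sim$genomes, "g01"))
  curve <- pan_development(tab, seed = 1)
  p <- autoplot(curve, heaps = fit_heaps(curve), decay = fit_decay(curve))
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(length(built$data), 2)
})
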