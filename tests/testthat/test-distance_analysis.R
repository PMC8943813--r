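test_that("marker distances map anchors to the chain and are isometric", {
  ns <- small_fiber(4)
  topo <- build_chain(ns)
  cfg <- initial_configuration(topo, "straight")
  # straight chain: distance equals the contour distance between the joints
  pr <- marker_pair(topo$joint_anchor[2], topo$joint_anchor[8])
  expect_equal(marker_distance(cfg, topo, pr),
               sum(topo$segments$rest_length[2:7]))
  # same anchor bp on both sides -> 0 (via two pairs collapsing to a joint)
  j <- topo$joint_anchor[4]
  expect_equal(marker_distance(cfg, topo, marker_pair(j - 1e-9, j)), 0,
               tolerance = 1e-9)
  # isometry invariance
  cfg2 <- transform_config(initial_configuration(topo, "random_walk",
                                                 seed = 3))
  cfg1 <- initial_configuration(topo, "random_walk", seed = 3)
  expect_equal(marker_distance(cfg1, topo, pr),
               marker_distance(cfg2, topo, pr), tolerance = 1e-9)
  expect_error(marker_distance(cfg, topo, marker_pair(0, 1e7)), "outside")
})

test_that("beads-on-a-string maximum extension follows the stated formula", {
  expect_equal(max_extension(5000), 5000 * 0.34 / 7)
  expect_equal(round(max_extension(5000)), 243)
  expect_equal(max_extension(7), 0.34)
  expect_error(max_extension(0), "> 0")
})

test_that("cutoff filtering removes and counts, and is idempotent", {
  ds <- distance_dataset(c(240, 260), "3D", "measured", span_bp = 5000)
  cf <- apply_cutoff(ds, 250)
  expect_equal(cf$dataset$distances, 240)
  expect_equal(cf$excluded, 1L)
  cf2 <- apply_cutoff(cf$dataset, 250)
  expect_equal(cf2$dataset$distances, 240)
  expect_equal(cf2$excluded, 0L)
  all_in <- distance_dataset(c(10, 20), span_bp = 5000)
  expect_equal(apply_cutoff(all_in, 250)$dataset$distances, c(10, 20))
  expect_error(distance_dataset(c(-1, 3)), ">= 0")
})

test_that("omitting z projects distances downward", {
  a <- rbind(c(0, 0, 0), c(5, 1, 1), c(10, 2, 2))
  b <- rbind(c(7, 0, 0), c(0, 4, 5), c(10, 2, 2))
  d2 <- project_omit_z(a, b)
  expect_equal(d2[1], 0)            # differs only in z
  expect_equal(d2[3], 0)
  d3 <- sqrt(rowSums((a - b)^2))
  expect_true(all(d2 <= d3 + 1e-12))
  expect_equal(d2[3], d3[3])  # no z difference: 2D equals 3D
  # random pairs: strict mean reduction
  set.seed(2)
  A <- matrix(rnorm(300), ncol = 3); B <- matrix(rnorm(300), ncol = 3)
  expect_lt(mean(project_omit_z(A, B)), mean(sqrt(rowSums((A - B)^2))))
})

test_that("histograms are density-normalized on shared binning", {
  h1 <- dist_histogram(rep(25, 10), bin_width = 10, range = c(0, 100))
  expect_equal(h1$density[3], 1 / 10)
  expect_equal(sum(h1$density * 10), 1, tolerance = 1e-9)
  set.seed(1)
  x <- runif(5000, 0, 100)
  coarse <- dist_histogram(x, 20, range = c(0, 100))
  fine <- dist_histogram(x, 5, range = c(0, 100))
  expect_equal(sum(coarse$density * 20), 1, tolerance = 1e-9)
  expect_equal(sum(fine$density * 5), 1, tolerance = 1e-9)
  expect_error(rmse_hist(coarse, fine), "different binning")
})

test_that("histogram RMSE is symmetric, zero iff identical, hand-checked", {
  a <- manual_hist(c(0.2, 0.5, 0.3))
  b <- manual_hist(c(0.3, 0.4, 0.3))
  expect_equal(rmse_hist(a, a), 0)
  expect_equal(rmse_hist(a, b), sqrt((0.01 + 0.01 + 0) / 3))
  expect_equal(rmse_hist(a, b), rmse_hist(b, a))
})

test_that("mixture fit solves the constrained least-squares problem", {
  # identity: single component equal to target
  set.seed(3)
  x <- rlnorm(2000, 4, 0.4)
  h <- dist_histogram(x, 10, range = c(0, 300))
  fit <- fit_mixture(h, list(h))
  expect_equal(unname(fit$weights), 1, tolerance = 1e-9)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)

  # exact convex combination of two distinct components
  ha <- manual_hist(c(0.6, 0.3, 0.1, 0))
  hb <- manual_hist(c(0, 0.1, 0.4, 0.5))
  target <- manual_hist(0.5 * ha$density + 0.5 * hb$density)
  fit2 <- fit_mixture(target, list(A = ha, B = hb))
  expect_equal(unname(fit2$weights), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sum(fit2$weights), 1, tolerance = 1e-9)
  expect_true(all(fit2$weights >= 0))

  expect_error(fit_mixture(target, list()), "at least one")
  expect_error(fit_mixture(target, list(manual_hist(c(0, 0, 0, 0)))),
               "degenerate")
  expect_error(fit_mixture(target, list(dist_histogram(1:5, 1))), "binning")
})

test_that("mixture fit equals an exhaustive grid-search minimizer", {
  set.seed(9)
  comps <- list(manual_hist(c(0.5, 0.3, 0.15, 0.05)),
                manual_hist(c(0.05, 0.15, 0.3, 0.5)),
                manual_hist(c(0.25, 0.25, 0.25, 0.25)))
  target <- manual_hist(0.2 * comps[[1]]$density +
                          0.5 * comps[[2]]$density +
                          0.3 * comps[[3]]$density + c(0.01, -0.01, 0, 0))
  fit <- fit_mixture(target, comps)
  # grid search at 0.01 resolution over the simplex
  C <- sapply(comps, `[[`, "density")
  best <- Inf; best_w <- NULL
  for (w1 in seq(0, 1, by = 0.01)) for (w2 in seq(0, 1 - w1, by = 0.01)) {
    w <- c(w1, w2, 1 - w1 - w2)
    sse <- sum((target$density - C %*% w)^2)
    if (sse < best) { best <- sse; best_w <- w }
  }
  expect_lt(max(abs(fit$weights - best_w)), 0.011)
  expect_lte(sum((target$density - C %*% fit$weights)^2), best + 1e-12)
})

test_that("weights of a sampled convex mixture are recovered", {
  set.seed(11)
  n <- 1e4
  w_true <- c(0.6, 0.4)
  comp_draw <- list(function(m) rlnorm(m, 4.0, 0.3),
                    function(m) rlnorm(m, 5.0, 0.2))
  rng <- c(0, 300)
  comps <- lapply(comp_draw, function(f) dist_histogram(f(n), 10, rng))
  lab <- sample(1:2, n, TRUE, w_true)
  target <- dist_histogram(
    c(comp_draw[[1]](sum(lab == 1)), comp_draw[[2]](sum(lab == 2))), 10, rng)
  fit <- fit_mixture(target, comps)
  expect_lt(max(abs(fit$weights - w_true)), 0.05)
})

test_that("summary statistics and rank-sum comparison behave classically", {
  expect_equal(dist_summary(distance_dataset(c(1, 2, 3))),
               data.frame(median = 2, mean = 2, sd = 1, n = 3L))
  expect_equal(dist_summary(distance_dataset(rep(7, 5)))$sd, 0)
  set.seed(8)
  x <- rlnorm(4000, 4, 0.5)
  s <- dist_summary(distance_dataset(x))
  mu <- exp(4 + 0.125)
  sem <- s$sd / sqrt(s$n)
  expect_lt(abs(s$mean - mu), 3 * sem)
  expect_error(dist_summary(distance_dataset(numeric(0))), "empty")

  same <- rank_sum_compare(x, x)
  expect_gt(same$p_value, 0.9)
  a <- runif(100, 0, 1); b <- runif(100, 10, 11)
  expect_lt(rank_sum_compare(a, b)$p_value, 1e-10)
  # invariance under a common monotone transform
  r1 <- rank_sum_compare(a, b)
  r2 <- rank_sum_compare(log(a + 1), log(b + 1))
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("distance tables round-trip through TSV", {
  ds <- distance_dataset(c(10.5, 80.2, 199), "3D", "synthetic",
                         span_bp = 5000, label = "AB")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_table(ds, path)
  ds2 <- read_distance_table(path, span_bp = 5000, source = "measured")
  expect_equal(ds2$distances, ds$distances)
  expect_equal(ds2$dimensionality, "3D")
})

test_that("isotropic random projection shortens distances in distribution", {
  ds <- gen_distance_dataset(4000, seed = 2)
  p2 <- random_projection_2d(ds, seed = 3)
  expect_true(all(p2$distances <= ds$distances + 1e-12))
  # E[sin theta] = pi/4 for a uniform sphere
  expect_equal(mean(p2$distances) / mean(ds$distances), pi / 4,
               tolerance = 0.03)
})
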