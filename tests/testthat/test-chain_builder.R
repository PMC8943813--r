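test_that("bp to nm conversion uses the B-DNA rise", {
  expect_equal(bp_to_nm(100), 34)
  expect_equal(bp_to_nm(0), 0)
  expect_equal(bp_to_nm(53), 18.02)
  expect_error(bp_to_nm(-1), ">= 0")
})

test_that("linker discretization has at least 2 segments, 10-nm pieces above 20 nm", {
  cases <- list(list(len = 10, n = 2), list(len = 20, n = 2),
                list(len = 25, n = 3), list(len = 0.34, n = 2),
                list(len = 95, n = 10))
  for (cs in cases) {
    d <- discretize_linker(cs$len)
    expect_equal(d$n, cs$n)
    expect_equal(sum(d$lengths), cs$len)
    expect_equal(length(unique(round(d$lengths, 12))), 1L)
    if (cs$len > 20) expect_true(all(d$lengths > 0 & d$lengths <= 10))
  }
  expect_error(discretize_linker(0), "> 0")
})

test_that("H1 assignment is Bernoulli with the requested fraction", {
  expect_equal(assign_h1(5, 1), rep(TRUE, 5))
  expect_equal(assign_h1(5, 0), rep(FALSE, 5))
  x <- assign_h1(1e4, 0.5, seed = 3)
  expect_lt(abs(mean(x) - 0.5), 3 * sqrt(0.25 / 1e4))
  expect_identical(assign_h1(100, 0.3, seed = 9), assign_h1(100, 0.3, seed = 9))
})

test_that("build_chain composes linkers and stems with preserved anchors", {
  iv <- genomic_interval("chrT", 0, 347)
  ns <- nucleosome_set(iv, c(0, 200))   # 53-bp linker between footprints
  topo <- build_chain(ns)
  linkers <- topo$segments[topo$segments$kind == "linker", ]
  expect_equal(nrow(linkers), 2L)                 # one linker as 2 segments
  expect_equal(sum(linkers$rest_length), 18.02)
  expect_equal(length(topo$stem_seg), 2L)

  # genomic anchor round trip at segment boundaries
  for (j in seq_along(topo$joint_anchor)) {
    bp <- topo$joint_anchor[j]
    expect_equal(anchor_to_joint(topo, bp), j)
  }
  expect_error(anchor_to_joint(topo, 1e6), "outside interval")

  # empty set over 1 kb: pure DNA, ceil(340/10) = 34 segments
  topo2 <- build_chain(nucleosome_set(genomic_interval("chrT", 0, 1000),
                                      numeric(0)))
  expect_equal(topo2$n_seg, 34L)
  expect_equal(contour_length(topo2), 340)

  # touching footprints get a 0.34-nm stub (chain stays well defined)
  ns3 <- nucleosome_set(genomic_interval("chrT", 0, 500), c(0, 147))
  topo3 <- build_chain(ns3)
  stub <- topo3$segments$rest_length[topo3$segments$kind == "linker"]
  expect_true(any(abs(stub - 0.17) < 1e-12))  # 0.34 nm as 2 segments
})

test_that("contour length is conserved across H1 states", {
  ns <- small_fiber(5)
  t_no <- build_chain(ns, h1 = FALSE)
  t_h1 <- build_chain(ns, h1 = TRUE)
  expect_equal(contour_length(t_no), contour_length(t_h1))
  # wrapped bp do not contribute linker length
  expect_equal(contour_length(t_no),
               0.34 * (interval_width(ns$interval) - 5 * 147) +
                 5 * t_no$geometry$stem_length)
})

test_that("nucleosome placement is a rigid-body transform of the stem frame", {
  ns <- small_fiber(2)
  geom0 <- nucleosome_geometry(
    d = 0,
    angles_no_h1 = c(kink = 0, theta_d = 0, phi_d = 0, alpha = 0, beta = 0,
                     gamma = 0),
    angles_h1 = c(kink = 0, theta_d = 0, phi_d = 0, alpha = 0, beta = 0,
                  gamma = 0))
  topo0 <- build_chain(ns, geom0)
  cfg <- initial_configuration(topo0, "straight")
  nc <- nucleosome_center(cfg, topo0, 1)
  s <- topo0$stem_seg[1]
  expect_equal(nc$center, (cfg$pos[s, ] + cfg$pos[s + 1, ]) / 2)
  fr <- config_frames(cfg)
  expect_equal(nc$frame, cbind(fr$u[s, ], fr$v[s, ], fr$f[s, ]))

  # rotating the configuration rotates the center rigidly
  topo <- build_chain(ns)
  cfg <- initial_configuration(topo, "random_walk", seed = 4)
  nc1 <- nucleosome_center(cfg, topo, 1)
  cfg2 <- transform_config(cfg)
  nc2 <- nucleosome_center(cfg2, topo, 1)
  s <- topo$stem_seg[1]
  d1 <- sqrt(sum((nc1$center - (cfg$pos[s, ] + cfg$pos[s + 1, ]) / 2)^2))
  d2 <- sqrt(sum((nc2$center - (cfg2$pos[s, ] + cfg2$pos[s + 1, ]) / 2)^2))
  expect_equal(d1, d2, tolerance = 1e-9)
  expect_equal(d1, topo$geometry$d, tolerance = 1e-9)

  # H1 and no-H1 angle sets place the nucleosome differently
  th1 <- build_chain(ns, nucleosome_geometry(
    angles_h1 = c(kink = 1.27, theta_d = pi / 3, phi_d = 0.4, alpha = 0.2,
                  beta = 1, gamma = 0.1)), h1 = TRUE)
  nch1 <- nucleosome_center(cfg, th1, 1)
  expect_gt(sum(abs(nch1$center - nc1$center)), 1e-6)

  # R and compiled placements agree
  sim <- prep_sim(topo, force_field())
  cg <- chromdist:::cg_stem_geom(cfg$pos, cfg$v, sim)
  ncs <- nucleosome_centers(cfg, topo)
  expect_equal(cg$centers, ncs$centers, tolerance = 1e-12)
  expect_equal(cg$axes, ncs$axes, tolerance = 1e-12)
})

test_that("initial configurations satisfy the frame invariants", {
  topo <- naked_chain(20)
  cfg <- initial_configuration(topo, "straight")
  expect_equal(end_to_end(cfg), contour_length(topo))
  expect_true(validate_configuration(cfg, topo))

  r1 <- initial_configuration(topo, "random_walk", seed = 11)
  r2 <- initial_configuration(topo, "random_walk", seed = 11)
  expect_identical(r1, r2)
  expect_true(validate_configuration(r1, topo))
  expect_error(
    initial_configuration(topo, "random_walk", seed = 1,
                          avoid_radius = 500, max_retries = 3L),
    "failed after")
})

test_that("random-walk chains reproduce freely-jointed statistics", {
  topo <- naked_chain(20)
  l2 <- sum(topo$segments$rest_length^2)
  r2 <- vapply(1:1000, function(s)
    end_to_end(initial_configuration(topo, "random_walk", seed = s))^2,
    numeric(1))
  # FJC: <R^2> = sum l_i^2; SE of the mean ~ 4%
  expect_lt(abs(mean(r2) / l2 - 1), 0.15)
})
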