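test_that("straight relaxed chain has zero elastic energy", {
  topo <- naked_chain(10)
  cfg <- initial_configuration(topo, "straight")
  e <- elastic_energy(cfg, topo, ff_ideal())
  expect_equal(unname(e["total"]), 0, tolerance = 1e-12)
  # with pair terms off the total is zero too
  expect_equal(unname(total_energy(cfg, topo, ff_ideal())["total"]), 0,
               tolerance = 1e-12)
})

test_that("bending is harmonic with the discretization-corrected constant", {
  topo <- naked_chain(2, l_nm = 10)
  ff <- ff_ideal(torsion_persistence = 0.0001)  # isolate bending
  l_seg <- topo$segments$rest_length[1]
  kb <- bend_stiffness(ff$bend_persistence, l_seg)
  for (theta in c(0.1, 0.2, 0.4)) {
    cfg <- initial_configuration(topo, "straight")
    cfg$pos[3, ] <- cfg$pos[2, ] + l_seg * c(cos(theta), sin(theta), 0)
    e <- elastic_energy(cfg, topo, ff)
    expect_equal(unname(e["bend"]), kb / 2 * theta^2, tolerance = 1e-9)
  }
  # doubling the angle quadruples the bend energy
  mk <- function(theta) {
    cfg <- initial_configuration(topo, "straight")
    cfg$pos[3, ] <- cfg$pos[2, ] + l_seg * c(cos(theta), sin(theta), 0)
    unname(elastic_energy(cfg, topo, ff)["bend"])
  }
  expect_equal(mk(0.4) / mk(0.2), 4, tolerance = 1e-9)
  # the corrected constant reproduces <cos theta> = exp(-l/Lp) by design
  expect_lt(bend_stiffness(50, 10), 50 / 10)
})

test_that("screened electrostatics matches a quadrature oracle for two rods", {
  # two parallel 10-nm rods at distance h: kernel vs numeric double integral
  topo <- naked_chain(3, l_nm = 10)
  ff <- force_field(excluded_volume = FALSE, e_max = 0, charge_spacing = 0.25,
                    es_cutoff = 40)
  sim <- prep_sim(topo, ff)
  # charge only segments 1 and 3 (adjacent pairs are excluded anyway)
  sim$chg_q[sim$chg_seg == 2] <- 0
  lam <- ff$linear_charge; lB <- ff$bjerrum_length; ld <- ff$debye_length
  x2 <- sum(topo$segments$rest_length[1])  # rod 1 runs 0..x2 on the x axis
  for (h in c(5, 8)) {
    cfg <- initial_configuration(topo, "straight")
    # fold segment 3 to run parallel to segment 1 at distance h
    cfg$pos[3, ] <- c(10, h, 0)
    cfg$pos[4, ] <- c(0, h, 0)
    e <- chromdist:::cg_energy(cfg$pos, cfg$v, sim, unclass(ff))
    oracle <- stats::integrate(function(x) sapply(x, function(xi)
      stats::integrate(function(y) {
        r <- sqrt((xi - y)^2 + h^2)
        lB * lam^2 * exp(-r / ld) / r
      }, 0, 10, rel.tol = 1e-10)$value), 0, x2, rel.tol = 1e-10)$value
    expect_equal(unname(e["electrostatic"]), oracle, tolerance = 0.02)
  }

  # screening limit: far apart -> < 1e-6 kT; halving separation increases it
  e_at <- function(h) {
    cfg <- initial_configuration(topo, "straight")
    cfg$pos[3, ] <- c(10, h, 0); cfg$pos[4, ] <- c(0, h, 0)
    unname(chromdist:::cg_energy(cfg$pos, cfg$v, sim,
                                 unclass(ff))["electrostatic"])
  }
  expect_lt(e_at(20 * ff$debye_length), 1e-6)
  expect_gt(e_at(2.5), e_at(5))
  expect_gt(e_at(5), e_at(10))
  expect_gte(e_at(5), 0)
})

test_that("internucleosomal potential has depth -E_max at stacking, 0 beyond cutoff", {
  for (emax in c(4, 6)) {
    ff <- force_field(e_max = emax)
    ax <- c(0, 0, 1)
    # coaxial face-to-face at the contact distance (= height)
    e_min <- nucleosome_pair_energy(c(0, 0, 0), ax,
                                    c(0, 0, ff$nucleosome_height), ax, ff)
    expect_equal(e_min, -emax, tolerance = 1e-9)
    # scan: nothing anywhere is deeper than -E_max
    set.seed(1)
    for (i in 1:200) {
      a1 <- rnorm(3); a2 <- rnorm(3)
      p <- runif(1, 3, 25) * { u <- rnorm(3); u / sqrt(sum(u^2)) }
      expect_gte(nucleosome_pair_energy(c(0, 0, 0), a1, p, a2, ff),
                 -emax - 1e-9)
    }
    expect_identical(
      nucleosome_pair_energy(c(0, 0, 0), ax, c(0, 0, ff$cutoff + 1e-9), ax,
                             ff), 0)
  }
  # E_max = 0 switches the attraction off entirely
  ff0 <- force_field(e_max = 0)
  expect_identical(nucleosome_pair_energy(c(0, 0, 0), c(0, 0, 1),
                                          c(0, 0, 5.5), c(0, 0, 1), ff0), 0)
})

test_that("excluded volume penalizes overlap, is continuous, vanishes apart", {
  ns <- small_fiber(2, nrl = 400)
  topo <- build_chain(ns)
  ff <- force_field(e_max = 0)
  cfg <- initial_configuration(topo, "straight")
  expect_equal(excluded_volume_energy(cfg, topo, ff), 0, tolerance = 1e-12)

  # force the two stems (and their nucleosomes) to coincide
  s1 <- topo$stem_seg[1]; s2 <- topo$stem_seg[2]
  cfg2 <- cfg
  shiftv <- cfg$pos[s1, ] - cfg$pos[s2, ]
  idx <- (s2):(nrow(cfg$pos))
  cfg2$pos[idx, ] <- sweep(cfg$pos[idx, , drop = FALSE], 2, -shiftv)
  expect_gt(excluded_volume_energy(cfg2, topo, ff), 100)

  # continuity across the contact distance: the maximal grid-step change
  # shrinks proportionally with the step (a jump would not)
  ax <- c(0, 0, 1)
  ff4 <- force_field(e_max = 4)
  scan <- function(h) {
    dd <- seq(4.2, 7, by = h)
    ee <- vapply(dd, function(d)
      nucleosome_pair_energy(c(0, 0, 0), ax, c(0, 0, d), ax, ff4),
      numeric(1))
    max(abs(diff(ee)))
  }
  expect_lt(scan(0.001), 0.6 * scan(0.002) + 1e-9)
  expect_lt(scan(0.0005), 0.6 * scan(0.001) + 1e-9)
})

test_that("total energy is invariant under global isometries", {
  ns <- small_fiber(4)
  topo <- build_chain(ns)
  ff <- force_field()
  cfg <- initial_configuration(topo, "random_walk", seed = 8)
  e1 <- total_energy(cfg, topo, ff)
  e2 <- total_energy(transform_config(cfg), topo, ff)
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("naked straight chain total energy is electrostatics only", {
  topo <- naked_chain(12)
  ff <- force_field()
  cfg <- initial_configuration(topo, "straight")
  e <- total_energy(cfg, topo, ff)
  expect_equal(unname(e["total"]), unname(e["electrostatic"]),
               tolerance = 1e-9)
})

test_that("incremental energy equals full recomputation within 1e-6 kT", {
  ns <- small_fiber(6)
  topo <- build_chain(ns)
  ff <- force_field()
  cfg <- initial_configuration(topo, "straight")
  res <- metropolis_run(cfg, topo, ff, temperature = 1.5, n_steps = 5000,
                        sample_every = 500, seed = 2, paranoid = TRUE)
  expect_lt(res$max_drift, 1e-6)
})

test_that("mean pair energy is non-increasing in E_max at fixed geometry", {
  ax1 <- c(0.2, 0.3, 1); ax2 <- c(0, 1, 0.5); p <- c(3, 4, 5)
  vals <- vapply(c(0, 2, 4, 6), function(em)
    nucleosome_pair_energy(c(0, 0, 0), ax1, p, ax2, force_field(e_max = em)),
    numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})
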