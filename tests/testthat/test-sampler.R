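test_that("swap probability implements the replica-exchange rule", {
  expect_equal(swap_probability(10, 10, 1, 0.8), 1)
  expect_equal(swap_probability(10, 15, 1, 1), 1)
  expect_equal(swap_probability(10, 15, 1, 0.8), exp(-1))
  expect_equal(swap_probability(15, 10, 1, 0.8), 1)  # favorable swap
  expect_error(swap_probability(1, 2, -1, 1), "beta")
})

test_that("temperature ladders validate and space geometrically", {
  expect_error(temperature_ladder(c(1, 1, 2)), "strictly increasing")
  l <- geometric_ladder(8)
  expect_equal(l$temperatures[1], 1.0)
  expect_equal(l$temperatures[8], 2.5)
  expect_equal(diff(log(l$temperatures)), rep(log(2.5) / 7, 7),
               tolerance = 1e-12)
})

test_that("acceptance approaches 1 at very high temperature", {
  ns <- small_fiber(3)
  topo <- build_chain(ns)
  cfg <- initial_configuration(topo, "straight")
  res <- metropolis_run(cfg, topo, force_field(), temperature = 1e7,
                        n_steps = 3000, sample_every = 3000, seed = 1)
  expect_true(all(res$acceptance > 0.95))
})

test_that("runs are deterministic under the seed", {
  topo <- naked_chain(10)
  cfg <- initial_configuration(topo, "straight")
  a <- metropolis_run(cfg, topo, ff_ideal(), 1, 2000, seed = 5,
                      sample_every = 200)
  b <- metropolis_run(cfg, topo, ff_ideal(), 1, 2000, seed = 5,
                      sample_every = 200)
  expect_identical(a$samples, b$samples)
  expect_identical(a$config, b$config)

  ctl <- run_control(n_steps = 2e4, swap_interval = 5000, sample_every = 1000,
                     seed = 3)
  r1 <- replica_exchange_run(topo, ff_ideal(), geometric_ladder(3), ctl)
  r2 <- replica_exchange_run(topo, ff_ideal(), geometric_ladder(3), ctl)
  expect_identical(r1$trajectories[[1]]$samples, r2$trajectories[[1]]$samples)
  expect_identical(r1$trajectories[[3]]$configs, r2$trajectories[[3]]$configs)
})

test_that("a single-temperature ladder degenerates to plain Metropolis", {
  topo <- naked_chain(10)
  ctl <- run_control(n_steps = 1e4, sample_every = 500, seed = 21)
  re <- replica_exchange_run(topo, ff_ideal(), temperature_ladder(1.0), ctl)
  mp <- metropolis_run(initial_configuration(topo, "straight"), topo,
                       ff_ideal(), 1.0, 1e4, seed = 21, sample_every = 500,
                       collect_configs = TRUE)
  expect_identical(re$trajectories[[1]]$samples, mp$samples)
})

test_that("every ladder slot receives the full sample stream", {
  topo <- naked_chain(8)
  ctl <- run_control(n_steps = 2e4, swap_interval = 2000, sample_every = 500,
                     seed = 2)
  run <- replica_exchange_run(topo, ff_ideal(), geometric_ladder(4), ctl)
  for (tr in run$trajectories) {
    expect_equal(nrow(tr$samples), 40)
    expect_true(all(diff(tr$samples$step) > 0))
    expect_equal(length(tr$configs), 40)
  }
})

test_that("replica exchange leaves the target marginal invariant", {
  # bend-only toy chain: energy samples at T = 1 from a 2-replica run match
  # a single-temperature run (Kolmogorov-Smirnov)
  topo <- naked_chain(8)
  ff <- ff_ideal()
  ctl <- run_control(n_steps = 1.5e5, swap_interval = 2500,
                     sample_every = 250, seed = 31)
  re <- replica_exchange_run(topo, ff, temperature_ladder(c(1, 1.6)), ctl)
  single <- metropolis_run(initial_configuration(topo, "straight"), topo,
                           ff, 1, 1.5e5, seed = 77, sample_every = 250)
  a <- re$trajectories[[1]]$samples$total[-(1:100)]
  b <- single$samples$total[-(1:100)]
  # thin both streams to approximate independence
  a <- a[seq(1, length(a), by = 5)]
  b <- b[seq(1, length(b), by = 5)]
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.01)
})

test_that("ladder optimization keeps endpoints, monotonicity", {
  ns <- small_fiber(3)
  topo <- build_chain(ns)
  ctl <- run_control(n_steps = 4e4, swap_interval = 2000, sample_every = 2000,
                     seed = 5)
  opt <- suppressWarnings(
    optimize_ladder(topo, force_field(), geometric_ladder(5), ctl,
                    max_iter = 2))
  tt <- opt$ladder$temperatures
  expect_equal(tt[1], 1.0)
  expect_equal(tt[5], 2.5)
  expect_true(all(diff(tt) > 0))
  expect_equal(length(tt), 5L)
})

test_that("ladder optimization falls back to geometric spacing without flow", {
  topo <- naked_chain(6)
  ctl <- run_control(n_steps = 4000, swap_interval = 2000,
                     sample_every = 2000, seed = 5)
  expect_warning(
    optimize_ladder(topo, ff_ideal(), geometric_ladder(4), ctl,
                    max_iter = 1),
    "no measured replica flow")
})

test_that("simulated annealing relaxes and validates its schedule", {
  ns <- small_fiber(4)
  topo <- build_chain(ns)
  ff <- force_field()
  expect_error(simulated_annealing(initial_configuration(topo, "straight"),
                                   topo, ff, schedule = c(2, 1.5)),
               "end at 1.0")
  # median energy drop over seeds, starting from strained random walks
  drops <- vapply(1:5, function(s) {
    cfg <- initial_configuration(topo, "random_walk", seed = s)
    e0 <- unname(total_energy(cfg, topo, ff)["total"])
    ann <- simulated_annealing(cfg, topo, ff, sweeps_per_stage = 500,
                               seed = s)
    e0 - ann$energy
  }, numeric(1))
  expect_gt(stats::median(drops), 0)
  # deterministic under seed
  cfg <- initial_configuration(topo, "straight")
  a1 <- simulated_annealing(cfg, topo, ff, sweeps_per_stage = 200, seed = 4)
  a2 <- simulated_annealing(cfg, topo, ff, sweeps_per_stage = 200, seed = 4)
  expect_identical(a1$config, a2$config)
})

test_that("autocorrelation time matches known processes", {
  set.seed(10)
  x <- rnorm(20000)
  expect_lt(abs(autocorrelation_time(x) - 1), 0.2)
  # AR(1), phi = 0.9: tau = (1 + phi) / (1 - phi) = 19
  phi <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = phi), 60000))
  expect_lt(abs(autocorrelation_time(ar) - 19) / 19, 0.25)
  expect_error(autocorrelation_time(rep(1, 1000)), "constant")
  expect_error(autocorrelation_time(rnorm(10)), "too short")
})

test_that("equilibration cut finds the stationary window", {
  set.seed(4)
  n <- 400
  e_stat <- rnorm(n); r_stat <- rnorm(n)
  expect_equal(equilibration_cut(e_stat, r_stat), 0L)
  # step-function mean shift at k: cut at or after k
  k <- 120
  e_shift <- c(rnorm(k, 25), rnorm(n - k, 0))
  r_shift <- c(rnorm(k, 25), rnorm(n - k, 0))
  expect_gte(equilibration_cut(e_shift, r_shift), k)
  expect_equal(equilibration_cut(e_shift, r_shift, override = 7), 7L)
  # a never-stationary ramp errors
  ramp <- seq(0, 100, length.out = n) + rnorm(n, 0, 0.1)
  expect_error(equilibration_cut(ramp, ramp), "no stationary window")
})

test_that("thinning yields near-independent samples", {
  topo <- naked_chain(12)
  cfg <- initial_configuration(topo, "straight")
  res <- metropolis_run(cfg, topo, ff_ideal(), 1, 1.8e5, seed = 6,
                        sample_every = 60, collect_configs = TRUE)
  traj <- structure(list(temperature = 1, samples = res$samples,
                         configs = res$configs), class = "cg_trajectory")
  n <- nrow(traj$samples)
  expect_equal(nrow(thin(traj, 1)$samples), n)
  cut <- equilibration_cut(traj$samples$total, traj$samples$end_to_end)
  tau <- autocorrelation_time(traj$samples$total[(cut + 1):n])
  th <- thin(traj, tau, cut)
  expect_equal(nrow(th$samples),
               length(seq(cut + 1, n, by = ceiling(tau))))
  expect_equal(length(th$configs), nrow(th$samples))
  # spacing at twice the integrated time suppresses the autocorrelation
  th2 <- thin(traj, 2 * tau, cut)
  rho1 <- stats::acf(th2$samples$total, plot = FALSE)$acf[2]
  expect_lt(abs(rho1), 0.15)
})

test_that("toy-chain visit frequencies match exact Boltzmann weights", {
  # 4-segment bend-only chain: joint angles are i.i.d. with density
  # proportional to sin(theta) exp(-k/2 theta^2); compare binned MC visit
  # frequencies with exact quadrature probabilities (chi-squared)
  topo <- naked_chain(4, l_nm = 10)
  ff <- ff_ideal()
  kb <- bend_stiffness(ff$bend_persistence, 10)
  cfg <- initial_configuration(topo, "straight")
  res <- metropolis_run(cfg, topo, ff, 1, n_steps = 4e5, seed = 12,
                        sample_every = 100, collect_configs = TRUE)
  ang <- unlist(lapply(res$configs[-(1:200)], function(cf) {
    u <- diff(cf$pos); u <- u / sqrt(rowSums(u^2))
    acos(pmin(1, pmax(-1, rowSums(u[-nrow(u), ] * u[-1, ]))))
  }))
  ang <- ang[seq(1, length(ang), by = 3)]  # decorrelate
  breaks <- c(seq(0, 1.2, by = 0.15), pi)
  dens <- function(th) sin(th) * exp(-kb / 2 * th^2)
  Z <- stats::integrate(dens, 0, pi)$value
  p_exact <- vapply(seq_len(length(breaks) - 1), function(i)
    stats::integrate(dens, breaks[i], breaks[i + 1])$value / Z, numeric(1))
  obs <- table(cut(ang, breaks, include.lowest = TRUE))
  chi <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = p_exact))
  expect_gt(chi$p.value, 0.01)
})
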