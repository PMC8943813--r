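#' Replica-exchange swap probability
#'
#' Probability of exchanging the temperatures of two adjacent replicas with
#' energies `E_i`, `E_i1` (kT) at inverse temperatures `beta_i`, `beta_i1`:
#' `min(1, exp(-(beta_i - beta_i1) * (E_i1 - E_i)))`.
#'
#' @param E_i,E_i1 Replica energies, kT.
#' @param beta_i,beta_i1 Inverse temperatures (> 0).
#' @return Swap probability in `[0, 1]` (vectorized).
#' @export
swap_probability <- function(E_i, E_i1, beta_i, beta_i1) {
  stopifnot(all(beta_i > 0), all(beta_i1 > 0))
  pmin(1, exp(-(beta_i - beta_i1) * (E_i1 - E_i)))
}

#' Temperature ladder for replica exchange
#'
#' @param temperatures Strictly increasing dimensionless temperature
#'   multipliers; the first entry is the target (analysis) temperature.
#' @return Object of class `temperature_ladder`.
#' @export
temperature_ladder <- function(temperatures) {
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) > 1 && any(diff(temperatures) <= 0))
    stop("ladder temperatures must be strictly increasing")
  structure(list(temperatures = temperatures), class = "temperature_ladder")
}

#' Geometric temperature ladder
#' @param n Number of replicas.
#' @param t_min,t_max Ladder endpoints (dimensionless), defaults 1.0 and 2.5.
#' @return A `temperature_ladder`.
#' @export
geometric_ladder <- function(n, t_min = 1.0, t_max = 2.5) {
  stopifnot(n >= 1, t_min > 0, t_max > t_min || n == 1)
  if (n == 1) return(temperature_ladder(t_min))
  temperature_ladder(t_min * (t_max / t_min)^((seq_len(n) - 1) / (n - 1)))
}

#' Run-control parameters for a sampling run
#'
#' @param n_steps MC steps (attempted elementary moves) per replica.
#' @param swap_interval Steps between replica-exchange swap attempts.
#' @param sample_every Steps between recorded samples.
#' @param seed Integer master seed; every stream derives from it.
#' @param moveset Amplitudes and mixture of the elementary moves.
#' @return Object of class `run_control`.
#' @export
run_control <- function(n_steps = 2e5, swap_interval = 5000,
                        sample_every = 1000, seed = 1L,
                        moveset = default_moveset()) {
  stopifnot(n_steps >= 1, swap_interval >= 1, sample_every >= 1)
  structure(list(n_steps = as.integer(n_steps),
                 swap_interval = as.integer(swap_interval),
                 sample_every = as.integer(sample_every),
                 seed = as.integer(seed), moveset = moveset),
            class = "run_control")
}

#' Default elementary move set
#'
#' Local/crankshaft rotations of short interior stretches about their chord,
#' pivot rotations of a chain end about a random axis, and frame twists about
#' the segment axis. Amplitudes are radians; they are auto-tuned toward ~40%
#' acceptance during annealing and then frozen for production (fixed
#' amplitudes are required for detailed balance).
#'
#' @param amp_crank,amp_pivot,amp_twist Maximal rotation angles, radians.
#' @param p_crank,p_pivot Move-type probabilities (twist gets the rest).
#' @param max_span Maximal crankshaft span in joints.
#' @return List of move-set parameters.
#' @export
default_moveset <- function(amp_crank = 1.0, amp_pivot = 0.6, amp_twist = 1.0,
                            p_crank = 0.7, p_pivot = 0.1, max_span = 8L) {
  list(amplitudes = c(amp_crank, amp_pivot, amp_twist),
       probs = c(p_crank, p_pivot), max_span = as.integer(max_span))
}

# derive a 2^31-safe substream seed from (seed, replica, chunk)
substream_seed <- function(seed, replica, chunk = 0L) {
  (as.double(seed) * 2654435761 + as.double(replica) * 40503 +
     as.double(chunk) * 69069) %% 2^48
}

#' Metropolis Monte Carlo run at a single temperature
#'
#' One MC step is one attempted elementary move; moves are accepted with
#' probability `min(1, exp(-dE / T))`. Frames are re-orthonormalized within
#' numerical tolerance at every sample point.
#'
#' @param config Starting `cg_configuration`.
#' @param topology A `chain_topology`.
#' @param ff A `force_field`.
#' @param temperature Dimensionless temperature multiplier.
#' @param n_steps Number of attempted moves.
#' @param moveset See [default_moveset()].
#' @param seed Integer seed (deterministic runs).
#' @param sample_every Record a sample every this many steps.
#' @param collect_configs Keep full configurations at sample points.
#' @param paranoid Track the maximal deviation between the incrementally
#'   updated energy and a full recomputation (`max_drift` in the result).
#' @param sim Optional precomputed [prep_sim()] table.
#' @return List with final `config`, `samples` (data.frame), `configs`,
#'   `acceptance` (per move type), `energy` (final breakdown), `max_drift`.
#' @export
metropolis_run <- function(config, topology, ff, temperature = 1,
                           n_steps = 1e4, moveset = default_moveset(),
                           seed = 1L, sample_every = 1000,
                           collect_configs = FALSE, paranoid = FALSE,
                           sim = NULL) {
  if (is.null(sim)) sim <- prep_sim(topology, ff)
  res <- cg_mc_run(config$pos, config$v, sim, unclass(ff),
                   temperature, as.integer(n_steps),
                   moveset$amplitudes, moveset$probs, moveset$max_span,
                   substream_seed(seed, 1L, 1L), as.integer(sample_every),
                   collect_configs, paranoid)
  samples <- as.data.frame(res$samples)
  configs <- lapply(res$configs, function(cf)
    structure(list(pos = cf$pos, v = cf$v), class = "cg_configuration"))
  list(config = structure(list(pos = res$pos, v = res$v),
                          class = "cg_configuration"),
       samples = samples, configs = configs,
       acceptance = ifelse(res$attempts > 0, res$accepts / res$attempts, NA),
       energy = res$energy, max_drift = res$max_drift)
}

#' Replica-exchange Metropolis Monte Carlo
#'
#' Simulates one replica per ladder temperature with independent per-replica
#' RNG substreams; every `swap_interval` steps adjacent temperature pairs
#' attempt an exchange with [swap_probability()]. The replica-temperature
#' mapping stays a bijection throughout. A single-temperature ladder
#' degenerates to a plain Metropolis run.
#'
#' @param topology A `chain_topology`.
#' @param ff A `force_field`.
#' @param ladder A `temperature_ladder`.
#' @param control A `run_control`.
#' @param init Starting `cg_configuration` (default: straight chain); used
#'   for every replica.
#' @return Object of class `cg_trajectory_set`: per-temperature trajectories
#'   (`$trajectories`, target temperature first), swap statistics and replica
#'   flow counts.
#' @export
replica_exchange_run <- function(topology, ff, ladder, control, init = NULL) {
  temps <- ladder$temperatures
  m <- length(temps)
  sim <- prep_sim(topology, ff)
  if (is.null(init)) init <- initial_configuration(topology, "straight")
  if (m == 1L) {  # degenerate ladder: exactly a plain Metropolis run
    res <- metropolis_run(init, topology, ff, temps, control$n_steps,
                          control$moveset, control$seed,
                          control$sample_every, collect_configs = TRUE,
                          sim = sim)
    traj <- structure(list(temperature = temps, samples = res$samples,
                           configs = res$configs, ladder = ladder,
                           control = control, ff = ff),
                      class = "cg_trajectory")
    return(structure(list(trajectories = list(traj), ladder = ladder,
                          control = control, swap_rates = NA_real_,
                          flow_up = 0, flow_down = 0),
                     class = "cg_trajectory_set"))
  }
  states <- rep(list(init), m)

  n_chunks <- max(1L, control$n_steps %/% control$swap_interval)
  # temp_of[r]: ladder slot currently held by replica r
  temp_of <- seq_len(m)
  energies <- numeric(m)
  # per-slot accumulators
  samp <- vector("list", m)
  cfgs <- vector("list", m)
  for (k in seq_len(m)) { samp[[k]] <- list(); cfgs[[k]] <- list() }
  swap_att <- numeric(max(m - 1, 1)); swap_acc <- numeric(max(m - 1, 1))
  # replica flow bookkeeping (feedback-optimized ladder): label replicas
  # "up"/"down" by the last endpoint visited
  label <- rep(NA_character_, m)
  n_up <- numeric(m); n_dn <- numeric(m)
  rng_swap <- substream_seed(control$seed, 10007L)

  withr_seed(rng_swap %% 2^31, {
    for (chunk in seq_len(n_chunks)) {
      for (r in seq_len(m)) {
        slot <- temp_of[r]
        res <- cg_mc_run(states[[r]]$pos, states[[r]]$v, sim, unclass(ff),
                         temps[slot], control$swap_interval,
                         control$moveset$amplitudes, control$moveset$probs,
                         control$moveset$max_span,
                         substream_seed(control$seed, r, chunk),
                         as.integer(control$sample_every), TRUE, FALSE)
        states[[r]] <- structure(list(pos = res$pos, v = res$v),
                                 class = "cg_configuration")
        energies[r] <- res$energy[["total"]]
        keep <- as.data.frame(res$samples)
        keep$step <- keep$step + (chunk - 1L) * control$swap_interval
        samp[[slot]] <- c(samp[[slot]], list(keep))
        cfgs[[slot]] <- c(cfgs[[slot]], lapply(res$configs, function(cf)
          structure(list(pos = cf$pos, v = cf$v),
                    class = "cg_configuration")))
      }
      # replica flow labels at the endpoints
      for (r in seq_len(m)) {
        if (temp_of[r] == m) label[r] <- "down"
        if (temp_of[r] == 1) {
          if (identical(label[r], "down")) label[r] <- "up"
          if (is.na(label[r])) label[r] <- "up"
        }
      }
      for (r in seq_len(m)) {
        slot <- temp_of[r]
        if (identical(label[r], "up")) n_up[slot] <- n_up[slot] + 1
        if (identical(label[r], "down")) n_dn[slot] <- n_dn[slot] + 1
      }
      if (m > 1) {
        first <- if (chunk %% 2L) 1L else 2L
        if (first > m - 1L) first <- 1L  # 2-replica ladder: only one pair
        slot_of <- order(temp_of)  # replica holding each slot
        for (k in seq(first, m - 1L, by = 2L)) {
          ra <- slot_of[k]; rb <- slot_of[k + 1L]
          p <- swap_probability(energies[ra], energies[rb],
                                1 / temps[k], 1 / temps[k + 1L])
          swap_att[k] <- swap_att[k] + 1
          if (stats::runif(1) < p) {
            swap_acc[k] <- swap_acc[k] + 1
            temp_of[ra] <- k + 1L
            temp_of[rb] <- k
            slot_of[k] <- rb; slot_of[k + 1L] <- ra
          }
        }
      }
    }
  })

  trajectories <- vector("list", m)
  for (k in seq_len(m)) {
    sdf <- do.call(rbind, samp[[k]])
    trajectories[[k]] <- structure(
      list(temperature = temps[k], samples = sdf, configs = cfgs[[k]],
           ladder = ladder, control = control, ff = ff),
      class = "cg_trajectory")
  }
  structure(list(trajectories = trajectories, ladder = ladder,
                 control = control,
                 swap_rates = ifelse(swap_att > 0, swap_acc / swap_att, NA),
                 flow_up = n_up, flow_down = n_dn),
            class = "cg_trajectory_set")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> T = %.3f, %d samples\n",
              x$temperature, nrow(x$samples)))
  invisible(x)
}

#' Feedback-optimized temperature ladder
#'
#' Iteratively re-places the ladder temperatures from the measured fraction
#' of "up-flowing" replicas f(T) (replicas whose last endpoint visit was the
#' lowest temperature), following the feedback-optimization idea: the new
#' temperatures are placed at equally spaced quantiles of the monotonized
#' flow fraction, which concentrates replicas where the flow changes fastest
#' and improves the round-trip rate from the highest to the lowest
#' temperature and back. Endpoints are fixed; monotonicity is preserved.
#' With zero measured flow the ladder falls back to geometric spacing with a
#' warning.
#'
#' @param topology A `chain_topology`.
#' @param ff A `force_field`.
#' @param ladder Initial `temperature_ladder`.
#' @param pilot_control `run_control` for each pilot run.
#' @param max_iter Maximal number of feedback iterations.
#' @param init Optional starting configuration for the pilots.
#' @return List with the optimized `ladder`, per-iteration round-trip
#'   diagnostics (`history`), and the final pilot `run`.
#' @export
optimize_ladder <- function(topology, ff, ladder, pilot_control,
                            max_iter = 3L, init = NULL) {
  temps <- ladder$temperatures
  m <- length(temps)
  if (m < 3) stop("ladder optimization needs at least 3 temperatures")
  best <- ladder; best_rate <- -Inf; history <- list(); run <- NULL
  for (it in seq_len(max_iter)) {
    ctl <- pilot_control
    ctl$seed <- as.integer((pilot_control$seed + 101L * it) %% .Machine$integer.max)
    run <- replica_exchange_run(topology, ff, temperature_ladder(temps),
                                ctl, init = init)
    nu <- run$flow_up; nd <- run$flow_down
    tot <- nu + nd
    rate <- mean(run$swap_rates, na.rm = TRUE)
    round_trips <- sum(nu[m], na.rm = TRUE)
    history[[it]] <- data.frame(iter = it, mean_swap_rate = rate,
                                up_frac_top = if (tot[m] > 0) nu[m] / tot[m] else NA)
    if (tot[m] == 0 || nu[m] == 0) {  # no completed round trips
      warning("no measured replica flow; falling back to geometric spacing")
      temps <- geometric_ladder(m, temps[1], temps[m])$temperatures
      next
    }
    f <- ifelse(tot > 0, nu / tot, NA)
    f[1] <- 1; f[m] <- 0
    f <- stats::approx(seq_len(m)[!is.na(f)], f[!is.na(f)],
                       xout = seq_len(m))$y
    # monotonize (f should fall from 1 at T_min to 0 at T_max)
    f <- rev(cummax(rev(f)))
    # invert: place new temperatures at equal flow quantiles
    target_f <- seq(1, 0, length.out = m)
    new_t <- numeric(m)
    for (k in seq_len(m)) {
      idx <- which(f <= target_f[k])[1]
      if (is.na(idx) || idx == 1) new_t[k] <- temps[1]
      else {
        f0 <- f[idx - 1]; f1 <- f[idx]
        w <- if (f0 == f1) 0.5 else (f0 - target_f[k]) / (f0 - f1)
        new_t[k] <- temps[idx - 1] + w * (temps[idx] - temps[idx - 1])
      }
    }
    new_t[1] <- temps[1]; new_t[m] <- temps[m]
    new_t <- cummax(new_t)
    dup <- which(diff(new_t) <= 1e-9)
    if (length(dup)) new_t <- temps  # degenerate placement: keep previous
    if (rate >= best_rate) { best_rate <- rate; best <- temperature_ladder(temps) }
    if (max(abs(new_t - temps)) < 1e-3 * (temps[m] - temps[1])) {
      temps <- new_t
      break
    }
    temps <- new_t
  }
  list(ladder = temperature_ladder(temps), history = do.call(rbind, history),
       run = run)
}

#' Simulated-annealing pre-relaxation
#'
#' Runs the Metropolis kernel through a decreasing temperature schedule
#' ending at 1.0, optionally auto-tuning move amplitudes toward ~40%
#' acceptance; the tuned amplitudes are returned so production can freeze
#' them.
#'
#' @param config Starting `cg_configuration`.
#' @param topology A `chain_topology`.
#' @param ff A `force_field`.
#' @param schedule Monotone non-increasing temperatures ending at 1.0.
#' @param sweeps_per_stage MC steps per schedule stage.
#' @param moveset Initial move set.
#' @param tune Auto-tune amplitudes between stages.
#' @param seed Integer seed.
#' @return List with relaxed `config`, final `energy`, tuned `moveset`, and
#'   the per-stage energy trace.
#' @export
simulated_annealing <- function(config, topology, ff,
                                schedule = c(8, 4, 2, 1.5, 1.2, 1.0),
                                sweeps_per_stage = 2000,
                                moveset = default_moveset(), tune = TRUE,
                                seed = 1L) {
  if (any(diff(schedule) > 0) || utils::tail(schedule, 1) != 1.0)
    stop("schedule must be non-increasing and end at 1.0")
  sim <- prep_sim(topology, ff)
  trace <- numeric(length(schedule))
  for (k in seq_along(schedule)) {
    res <- metropolis_run(config, topology, ff, schedule[k],
                          n_steps = sweeps_per_stage, moveset = moveset,
                          seed = substream_seed(seed, k) %% 2^31,
                          sample_every = sweeps_per_stage, sim = sim)
    config <- res$config
    trace[k] <- res$energy[["total"]]
    if (tune) {
      for (i in 1:3) {
        a <- res$acceptance[i]
        if (!is.na(a)) {
          fac <- if (a > 0.5) 1.3 else if (a < 0.3) 0.7 else 1.0
          moveset$amplitudes[i] <-
            min(pi, max(0.01, moveset$amplitudes[i] * fac))
        }
      }
    }
  }
  list(config = config, energy = trace[length(trace)], moveset = moveset,
       trace = trace)
}

#' Integrated autocorrelation time
#'
#' Sokal-windowed estimate `tau = 1 + 2 * sum_k rho_k`, summing up to the
#' first window `W >= c * tau`.
#'
#' @param series Numeric series (stationary part of an observable).
#' @param c Window factor (default 5).
#' @param min_len Minimal series length (default 50).
#' @return Estimated `tau` in sampling intervals (>= 1).
#' @export
autocorrelation_time <- function(series, c = 5, min_len = 50L) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < min_len) stop("series too short for autocorrelation analysis")
  if (stats::sd(x) == 0)
    stop("constant series: autocorrelation time undefined")
  rho <- stats::acf(x, lag.max = min(n - 1, 10000L), plot = FALSE,
                    demean = TRUE)$acf[-1]
  tau <- 1
  for (k in seq_along(rho)) {
    tau <- tau + 2 * rho[k]
    if (k >= c * tau) break
  }
  max(tau, 1)
}

#' Automated equilibration point of a run
#'
#' Splits the energy and end-to-end series into windows and returns the start
#' of the first window from which on the running means of both observables
#' stay within `tol` standard errors of their late-run (second half) means.
#' An explicit `override` index is respected verbatim.
#'
#' @param energy,end_to_end Equal-length numeric series.
#' @param n_windows Number of windows (default 20).
#' @param tol Tolerance in late-run standard deviations (default 1).
#' @param override Optional explicit cut index (0-based samples dropped).
#' @return Cut index: samples `(cut+1):n` are considered equilibrated.
#' @export
equilibration_cut <- function(energy, end_to_end, n_windows = 20L,
                              tol = 1.5, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  stopifnot(length(energy) == length(end_to_end))
  n <- length(energy)
  if (n < 8L) return(0L)
  half <- floor(n / 2)
  ref_e <- mean(energy[(half + 1):n]); sd_e <- stats::sd(energy[(half + 1):n])
  ref_r <- mean(end_to_end[(half + 1):n]); sd_r <- stats::sd(end_to_end[(half + 1):n])
  sd_e <- max(sd_e, 1e-12); sd_r <- max(sd_r, 1e-12)
  L <- max(5L, n %/% n_windows)
  win_ok <- function(b) {
    lo <- b + 1L; hi <- min(n, b + L)
    abs(mean(energy[lo:hi]) - ref_e) <= tol * sd_e &&
      abs(mean(end_to_end[lo:hi]) - ref_r) <= tol * sd_r
  }
  for (b in 0:half) {
    # the running means of both observables must have stabilized: the window
    # starting at the cut and the following one both sit near the late mean
    if (win_ok(b) && win_ok(min(b + L, half))) {
      # trim leading stragglers a window mean can absorb
      while (b < half &&
             (abs(energy[b + 1] - ref_e) > 4 * sd_e ||
              abs(end_to_end[b + 1] - ref_r) > 4 * sd_r))
        b <- b + 1L
      return(as.integer(b))
    }
  }
  stop("no stationary window found; run longer or set an explicit override")
}

#' Thin a trajectory at the autocorrelation time
#'
#' Keeps every `ceiling(tau)`-th post-equilibration sample so retained
#' configurations are statistically independent.
#'
#' @param trajectory A `cg_trajectory`.
#' @param tau Autocorrelation time in sampling intervals (>= 1).
#' @param cut Equilibration cut: samples `1..cut` are dropped first.
#' @return The thinned `cg_trajectory`.
#' @export
thin <- function(trajectory, tau, cut = 0L) {
  stopifnot(tau >= 1)
  n <- nrow(trajectory$samples)
  idx <- seq(cut + 1L, n, by = as.integer(ceiling(tau)))
  trajectory$samples <- trajectory$samples[idx, , drop = FALSE]
  if (length(trajectory$configs))
    trajectory$configs <- trajectory$configs[idx]
  trajectory
}
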