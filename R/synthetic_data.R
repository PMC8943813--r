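# Seed-deterministic generators for every input the pipeline needs:
# nucleosome position sets with controlled NRL statistics, MNase-like
# occupancy tracks, right-tailed single-cell distance datasets, and
# two-color 3D image stacks. Every generator returns its ground truth
# alongside the data.

#' Generate a non-overlapping nucleosome position set
#'
#' Sequential placement with spacing (NRL) drawn from a normal distribution
#' truncated at `footprint + 1` bp, emulating the regime of population-scale
#' nucleosome maps (mean repeat length ~183 bp on the studied chromosome).
#' Occupancy scores are drawn i.i.d. log-normal (right-tailed, positive).
#'
#' @param region_length Region length in bp.
#' @param nrl_mean Mean nucleosome repeat length, bp (> 147).
#' @param nrl_sd NRL standard deviation, bp (0 gives perfectly periodic
#'   positions).
#' @param footprint Footprint, bp (default 147).
#' @param occ_meanlog,occ_sdlog Log-normal occupancy-score parameters.
#' @param chrom,start Coordinates of the generated interval.
#' @param seed Integer seed.
#' @return A `nucleosome_set`; attribute `true_nrl` holds the realized
#'   spacings.
#' @export
gen_positions <- function(region_length = 30000, nrl_mean = 183,
                          nrl_sd = 30, footprint = 147,
                          occ_meanlog = log(10), occ_sdlog = 0.5,
                          chrom = "chrS", start = 0, seed = 1L) {
  if (nrl_mean <= footprint)
    stop("nrl_mean must exceed the footprint (", footprint, " bp)")
  if (region_length < footprint)
    stop("region too short for a single nucleosome")
  withr_seed(seed, {
    min_sp <- footprint + 1
    # solve for the pre-truncation location so the truncated-normal spacing
    # has mean exactly nrl_mean (left truncation pulls the mean up)
    mu_adj <- nrl_mean
    if (nrl_sd > 0) {
      trunc_mean <- function(mu) {
        a <- (min_sp - mu) / nrl_sd
        mu + nrl_sd * stats::dnorm(a) /
          stats::pnorm(a, lower.tail = FALSE)
      }
      mu_adj <- stats::uniroot(function(mu) trunc_mean(mu) - nrl_mean,
                               lower = min_sp - 10 * nrl_sd,
                               upper = nrl_mean, tol = 1e-8,
                               extendInt = "upX")$root
    }
    rspace <- function(m) {
      if (nrl_sd == 0) return(rep(nrl_mean, m))
      x <- stats::rnorm(m, mu_adj, nrl_sd)
      while (any(bad <- x < min_sp))
        x[bad] <- stats::rnorm(sum(bad), mu_adj, nrl_sd)
      x
    }
    n_max <- ceiling(region_length / min_sp) + 10L
    sp <- round(rspace(n_max))
    dyads <- start + cumsum(c(0, sp))
    dyads <- dyads[dyads + footprint <= start + region_length]
    score <- stats::rlnorm(length(dyads), occ_meanlog, occ_sdlog)
    ns <- nucleosome_set(genomic_interval(chrom, start, start + region_length),
                         dyads, footprint, score)
    attr(ns, "true_nrl") <- diff(ns$nucleosomes$dyad_start)
    ns
  })
}

#' Generate an MNase-like occupancy track for a nucleosome set
#'
#' Expected coverage is a sum of Gaussian-smoothed footprints centered at
#' each nucleosome (with positional jitter of sd `fuzziness` bp emulating
#' cell-to-cell positioning variability), weighted by the set's occupancy
#' scores and scaled by sequencing `depth`; per-bp counts are Poisson.
#'
#' @param ns A `nucleosome_set` with occupancy scores.
#' @param fuzziness Positional jitter sd, bp.
#' @param depth Mean coverage scale at a footprint center.
#' @param smooth_sd Footprint smoothing sd, bp.
#' @param seed Integer seed.
#' @return An `occupancy_track`; attribute `true_weights` holds the
#'   normalized generating weights.
#' @export
gen_occupancy_track <- function(ns, fuzziness = 20, depth = 50,
                                smooth_sd = 50, seed = 1L) {
  nuc <- ns$nucleosomes
  iv <- ns$interval
  withr_seed(seed, {
    w <- nuc$occupancy_score / mean(nuc$occupancy_score)
    jit <- if (fuzziness > 0) stats::rnorm(nrow(nuc), 0, fuzziness) else
      numeric(nrow(nuc))
    x <- seq(iv$start, iv$end - 1)
    lam <- numeric(length(x))
    centers <- nuc$dyad_start + nuc$footprint / 2 + jit
    for (i in seq_len(nrow(nuc)))
      lam <- lam + depth * w[i] * exp(-(x - centers[i])^2 / (2 * smooth_sd^2))
    track <- occupancy_track(iv, stats::rpois(length(lam), lam))
    attr(track, "true_weights") <- w
    attr(track, "expected") <- lam
    track
  })
}

#' Generate a right-tailed single-cell distance dataset
#'
#' Draws true pair distances from a log-normal mixture (right-tailed,
#' positive support) and adds isotropic 3D localization error to both spot
#' positions such that the pairwise RMS distance error matches `noise_nm`
#' (~7.5 nm for STED-class localization). Ground-truth component labels are
#' kept for recovery tests.
#'
#' @param n Number of cells.
#' @param components data.frame with columns `meanlog`, `sdlog`, `weight`
#'   (weights >= 0, summing to 1). `sdlog = 0` gives a point mass.
#' @param noise_nm Pairwise RMS localization error, nm (0 disables noise).
#' @param span_bp Genomic span the dataset emulates, bp.
#' @param seed Integer seed.
#' @return A `distance_dataset` (synthetic, 3D) with attributes `labels`
#'   (component per cell) and `true_distances`.
#' @export
gen_distance_dataset <- function(n,
                                 components = data.frame(
                                   meanlog = 4.649, sdlog = 0.438,
                                   weight = 1),
                                 noise_nm = 7.5, span_bp = 5000, seed = 1L) {
  stopifnot(n >= 1, all(components$weight >= 0))
  w <- components$weight / sum(components$weight)
  withr_seed(seed, {
    lab <- sample.int(nrow(components), n, replace = TRUE, prob = w)
    d_true <- ifelse(components$sdlog[lab] == 0,
                     exp(components$meanlog[lab]),
                     stats::rlnorm(n, components$meanlog[lab],
                                   components$sdlog[lab]))
    if (noise_nm > 0) {
      s_ax <- noise_nm / sqrt(6)  # per endpoint, per axis
      e <- matrix(stats::rnorm(6 * n, 0, s_ax), n, 6)
      d <- sqrt((d_true + e[, 1] - e[, 4])^2 + (e[, 2] - e[, 5])^2 +
                  (e[, 3] - e[, 6])^2)
    } else d <- d_true
    ds <- distance_dataset(d, "3D", "synthetic", span_bp)
    attr(ds, "labels") <- lab
    attr(ds, "true_distances") <- d_true
    ds
  })
}

#' Generate a two-color pair of 3D image stacks
#'
#' One Gaussian-PSF spot per channel with Poisson photon noise and constant
#' background, at STED-like widths.
#'
#' @param center_ch1_nm,center_ch2_nm Spot centers (z, y, x), nm; must lie
#'   inside the stack.
#' @param dims Stack dimensions (z, y, x), voxels.
#' @param psf_sigma_nm PSF standard deviations (z, y, x), nm.
#' @param photons Total expected photons per spot.
#' @param background Expected background counts per voxel.
#' @param voxel_nm Voxel size (z, y, x), nm.
#' @param seed Integer seed.
#' @return List with `ch1`, `ch2` (`image_stack`s) and `truth` (the centers
#'   in nm).
#' @export
gen_image_stack <- function(center_ch1_nm, center_ch2_nm,
                            dims = c(21, 21, 21),
                            psf_sigma_nm = c(75, 40, 40),
                            photons = 500, background = 2,
                            voxel_nm = c(30, 30, 30), seed = 1L) {
  stopifnot(photons >= 0, background >= 0)
  extent <- (dims - 1) * voxel_nm
  for (cc in list(center_ch1_nm, center_ch2_nm))
    if (any(cc < 0) || any(cc > extent))
      stop("spot center outside the stack")
  one <- function(center, sd_seed) {
    ax <- lapply(1:3, function(k) (seq_len(dims[k]) - 1) * voxel_nm[k])
    # separable expected profile; amplitude normalized to `photons` total
    gz <- exp(-(ax[[1]] - center[1])^2 / (2 * psf_sigma_nm[1]^2))
    gy <- exp(-(ax[[2]] - center[2])^2 / (2 * psf_sigma_nm[2]^2))
    gx <- exp(-(ax[[3]] - center[3])^2 / (2 * psf_sigma_nm[3]^2))
    lam <- outer(outer(gz, gy), gx)
    tot <- sum(lam)
    lam <- if (tot > 0 && photons > 0) lam * (photons / tot) else lam * 0
    lam <- lam + background
    array(stats::rpois(length(lam), lam), dims)
  }
  withr_seed(seed, {
    s1 <- image_stack(one(center_ch1_nm), voxel_nm, "ch1")
    s2 <- image_stack(one(center_ch2_nm), voxel_nm, "ch2")
    list(ch1 = s1, ch2 = s2,
         truth = list(ch1 = center_ch1_nm, ch2 = center_ch2_nm))
  })
}
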