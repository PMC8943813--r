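#' Discretization-corrected harmonic bend stiffness
#'
#' For a discrete chain with harmonic joint bending `E = k/2 * theta^2` the
#' equilibrium measure carries the `sin(theta)` Jacobian, so the naive choice
#' `k = Lp / l` yields an effective persistence length a few percent above
#' `Lp`. This returns the stiffness `k` (kT/rad^2) solving
#' `<cos theta>_k = exp(-l / Lp)`, which makes the discrete chain reproduce
#' the continuous worm-like-chain statistics at segment length `l`.
#'
#' @param bend_persistence Target persistence length, nm.
#' @param l Segment length at the joint, nm.
#' @return Stiffness in kT/rad^2 (vectorized over `l`).
#' @export
bend_stiffness <- function(bend_persistence, l) {
  g_of_k <- function(k) {
    th <- seq(1e-7, pi, length.out = 2001)
    w <- sin(th) * exp(-k / 2 * th^2)
    sum(cos(th) * w) / sum(w)
  }
  one <- function(li) {
    target <- exp(-li / bend_persistence)
    k0 <- bend_persistence / li
    stats::uniroot(function(k) g_of_k(k) - target,
                   lower = max(0.05, 0.3 * k0), upper = 2 * k0 + 10,
                   tol = 1e-8)$root
  }
  vapply(l, one, numeric(1))
}

#' Prepare the simulation tables for a topology / force field pair
#'
#' Precomputes per-segment spring constants, per-joint bend/torsion constants
#' (stiffness `persistence / l` with `l` the mean of the adjacent rest
#' lengths), and the discrete charge points on linker segments (one point per
#' `charge_spacing` nm, Manning-reduced linear charge). The result is the
#' internal table handed to the compiled core; it is cached on the topology
#' via an attribute-free design: callers keep it alongside the topology.
#'
#' @param topology A `chain_topology`.
#' @param ff A `force_field`.
#' @return A list consumed by the compiled energy/sampler kernels.
#' @export
prep_sim <- function(topology, ff) {
  n <- topology$n_seg
  l0 <- topology$segments$rest_length
  is_stem <- as.integer(topology$segments$kind == "nucleosome_stem")
  ks <- ff$stretch_modulus / l0
  lj <- c(l0[1], (l0[-n] + l0[-1]) / 2, l0[n])  # per joint, length n+1
  # cache the corrected stiffness over unique joint lengths
  ulj <- unique(round(lj, 9))
  kb_u <- bend_stiffness(ff$bend_persistence, ulj)
  kb <- kb_u[match(round(lj, 9), ulj)]
  kt <- ff$torsion_persistence / lj
  # joint indexing in the kernel: joint j between segments j-1 and j (1-based
  # interior joints 2..n); theta0 built at chain construction
  chg_seg <- integer(0); chg_frac <- numeric(0); chg_q <- numeric(0)
  if (ff$electrostatics) {
    for (s in which(is_stem == 0L)) {
      m <- max(1L, round(l0[s] / ff$charge_spacing))
      chg_seg <- c(chg_seg, rep(s, m))
      chg_frac <- c(chg_frac, (seq_len(m) - 0.5) / m)
      chg_q <- c(chg_q, rep(ff$linear_charge * l0[s] / m, m))
    }
  }
  list(n_seg = n, l0 = l0, ks = ks, is_stem = is_stem,
       stem_seg = as.integer(topology$stem_seg),
       stem_d = as.numeric(topology$stem_d),
       stem_dvec = topology$stem_dvec,
       stem_rrel = topology$stem_rrel,
       theta0 = topology$joint_theta0,
       kb = kb, kt = kt,
       chg_seg = as.integer(chg_seg), chg_frac = chg_frac, chg_q = chg_q)
}

#' Total configuration energy with per-term breakdown
#'
#' Sum of the elastic (stretch, bend, torsion), screened electrostatic,
#' internucleosomal, and excluded-volume terms, in kT.
#'
#' @param config A `cg_configuration`.
#' @param topology A `chain_topology`.
#' @param ff A `force_field`.
#' @param sim Optional precomputed [prep_sim()] table.
#' @return Named numeric vector with the six terms and `total`.
#' @export
total_energy <- function(config, topology, ff, sim = NULL) {
  if (is.null(sim)) sim <- prep_sim(topology, ff)
  cg_energy(config$pos, config$v, sim, unclass(ff))
}

#' Elastic energy (stretch + bend + torsion)
#' @inheritParams total_energy
#' @return Named vector `stretch`, `bend`, `torsion`, `total` in kT.
#' @export
elastic_energy <- function(config, topology, ff, sim = NULL) {
  e <- total_energy(config, topology, ff, sim)
  c(e[c("stretch", "bend", "torsion")],
    total = unname(e["stretch"] + e["bend"] + e["torsion"]))
}

#' Screened electrostatic energy of the linker DNA
#'
#' Debye-Hueckel repulsion between discrete charge points on non-adjacent
#' linker segments; non-negative and vanishing at large separation.
#'
#' @inheritParams total_energy
#' @return Energy in kT.
#' @export
electrostatic_energy <- function(config, topology, ff, sim = NULL) {
  unname(total_energy(config, topology, ff, sim)["electrostatic"])
}

#' Excluded-volume energy
#'
#' Capped quartic overlap penalty for DNA-DNA, DNA-nucleosome and
#' nucleosome-nucleosome contacts; 0 when nothing overlaps.
#'
#' @inheritParams total_energy
#' @return Energy in kT.
#' @export
excluded_volume_energy <- function(config, topology, ff, sim = NULL) {
  unname(total_energy(config, topology, ff, sim)["excluded_volume"])
}

#' Anisotropic internucleosomal pair energy
#'
#' Orientation-dependent potential between two nucleosome bodies given their
#' centers and symmetry axes. The global minimum is exactly `-e_max` at
#' coaxial face-to-face stacking at contact distance; the energy is exactly 0
#' beyond the cutoff, and identically 0 when `e_max = 0`.
#'
#' @param center_i,center_j Nucleosome centers (3-vectors, nm).
#' @param axis_i,axis_j Symmetry axes (3-vectors, normalized internally).
#' @param ff A `force_field`.
#' @return Energy in kT.
#' @export
nucleosome_pair_energy <- function(center_i, axis_i, center_j, axis_j, ff) {
  cg_nuc_pair(as.numeric(center_i), as.numeric(axis_i),
              as.numeric(center_j), as.numeric(axis_j), unclass(ff))
}
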