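#' Convert base pairs to nanometers
#'
#' B-DNA rise of 0.34 nm per base pair.
#'
#' @param length_bp Non-negative length in bp.
#' @return Length in nm.
#' @export
bp_to_nm <- function(length_bp) {
  if (any(length_bp < 0)) stop("length in bp must be >= 0")
  length_bp * 0.34
}

#' Discretize a linker DNA length into chain segments
#'
#' Every linker is modeled by at least 2 segments; linkers longer than 20 nm
#' get `ceiling(length / 10)` equal segments.
#'
#' @param length_nm Linker length in nm, > 0.
#' @return List with `n` (segment count) and `lengths` (equal per-segment
#'   lengths summing to `length_nm`).
#' @export
discretize_linker <- function(length_nm) {
  if (length_nm <= 0) stop("linker length must be > 0 nm")
  n <- if (length_nm > 20) ceiling(length_nm / 10) else 2L
  list(n = as.integer(n), lengths = rep(length_nm / n, n))
}

#' Nucleosome placement geometry
#'
#' The nucleosome body (a spherocylinder of diameter `diameter` and height
#' `height`) is placed relative to the local frame of its stem segment by the
#' distance `d` and six angles. The six angles are, in order:
#' `kink` (rest bend angle at the two joints flanking the stem, radians;
#' encodes the linker entry/exit geometry), `theta_d`/`phi_d` (polar/azimuth
#' of the center displacement direction in the stem frame), and
#' `alpha`/`beta`/`gamma` (ZYZ Euler angles rotating the stem frame into the
#' nucleosome frame, whose third axis is the superhelical symmetry axis).
#' Chains with and without linker histone H1 differ only by the angle set:
#' the H1 set folds the entering/exiting linkers back more strongly (stem
#' formation), compacting the fiber.
#'
#' @param d Stem-center to nucleosome-center distance, nm.
#' @param stem_length Rest length of the stem segment, nm.
#' @param diameter,height Spherocylinder dimensions, nm.
#' @param angles_no_h1,angles_h1 Named numeric vectors with entries
#'   `kink`, `theta_d`, `phi_d`, `alpha`, `beta`, `gamma` (radians).
#' @return An object of class `nucleosome_geometry`.
#' @export
nucleosome_geometry <- function(
    d = 8, stem_length = 8, diameter = 11, height = 5.5,
    angles_no_h1 = c(kink = 0.83, theta_d = pi / 2, phi_d = pi / 2,
                     alpha = 0, beta = pi / 2, gamma = 0),
    angles_h1 = c(kink = 1.27, theta_d = pi / 2, phi_d = pi / 2,
                  alpha = 0, beta = pi / 2, gamma = 0)) {
  need <- c("kink", "theta_d", "phi_d", "alpha", "beta", "gamma")
  for (a in list(angles_no_h1, angles_h1))
    if (!all(need %in% names(a)))
      stop("angle sets must contain: ", paste(need, collapse = ", "))
  stopifnot(d >= 0, stem_length > 0, diameter > 0, height > 0)
  structure(list(d = d, stem_length = stem_length, diameter = diameter,
                 height = height,
                 angles_no_h1 = angles_no_h1[need],
                 angles_h1 = angles_h1[need]),
            class = "nucleosome_geometry")
}

#' Read a nucleosome geometry from a YAML/JSON-style config list
#' @param x A list with the fields of [nucleosome_geometry()].
#' @return A `nucleosome_geometry`.
#' @export
as_nucleosome_geometry <- function(x) {
  do.call(nucleosome_geometry,
          x[intersect(names(x), names(formals(nucleosome_geometry)))])
}

#' Assign linker histone H1 to nucleosomes at random
#'
#' Each nucleosome is H1-bound independently with probability `fraction`.
#'
#' @param n_nucleosomes Number of nucleosomes.
#' @param fraction Binding probability in `[0, 1]`.
#' @param seed Integer seed; the draw is reproducible.
#' @return Logical vector of length `n_nucleosomes`.
#' @export
assign_h1 <- function(n_nucleosomes, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(rep(FALSE, n_nucleosomes))
  if (fraction == 1) return(rep(TRUE, n_nucleosomes))
  withr_seed(seed, stats::runif(n_nucleosomes) < fraction)
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

rot_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle); C <- 1 - c
  matrix(c(
    c + a[1]^2 * C, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
    a[2] * a[1] * C + a[3] * s, c + a[2]^2 * C, a[2] * a[3] * C - a[1] * s,
    a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, c + a[3]^2 * C),
    3, 3, byrow = TRUE)
}

euler_zyz <- function(alpha, beta, gamma) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

resolve_stem_params <- function(geometry, h1_flags) {
  n <- length(h1_flags)
  d <- numeric(n); dvec <- matrix(0, n, 3); rrel <- matrix(0, n, 9)
  theta0 <- numeric(n)
  for (i in seq_len(n)) {
    a <- if (h1_flags[i]) geometry$angles_h1 else geometry$angles_no_h1
    d[i] <- geometry$d
    dvec[i, ] <- c(sin(a["theta_d"]) * cos(a["phi_d"]),
                   sin(a["theta_d"]) * sin(a["phi_d"]),
                   cos(a["theta_d"]))
    rrel[i, ] <- as.numeric(euler_zyz(a["alpha"], a["beta"], a["gamma"]))
    theta0[i] <- a["kink"]
  }
  list(d = d, dvec = dvec, rrel = rrel, theta0 = theta0)
}

#' Build a segment-chain topology from a nucleosome set
#'
#' Linker DNA between footprints is converted bp -> nm (0.34 nm/bp) and
#' discretized ([discretize_linker()]); each nucleosome contributes one stem
#' segment whose local frame carries the nucleosome body via the placement
#' geometry. Touching footprints (0-bp linker) get a 0.34-nm stub so the
#' chain stays well defined. Genomic anchors (bp at every joint) are
#' preserved so any bp coordinate maps to a chain position.
#'
#' @param ns A `nucleosome_set` (may be empty: pure DNA chain).
#' @param geometry A `nucleosome_geometry`.
#' @param h1 Logical vector of H1 occupancy per nucleosome (recycled).
#' @return An object of class `chain_topology`.
#' @export
build_chain <- function(ns, geometry = nucleosome_geometry(), h1 = FALSE) {
  nuc <- ns$nucleosomes
  nn <- nrow(nuc)
  h1 <- rep_len(as.logical(h1), nn)
  stems <- resolve_stem_params(geometry, h1)

  kind <- character(0); rest <- numeric(0)
  joint_bp <- ns$interval$start     # anchors at joints, bp
  stem_seg <- integer(0)

  add_linker <- function(bp_len, bp_from) {
    nm <- if (bp_len == 0) 0.34 else bp_to_nm(bp_len)
    dz <- discretize_linker(nm)
    kind <<- c(kind, rep("linker", dz$n))
    rest <<- c(rest, dz$lengths)
    joint_bp <<- c(joint_bp,
                   bp_from + bp_len * seq_len(dz$n) / dz$n)
  }

  cursor <- ns$interval$start
  for (i in seq_len(nn)) {
    gap <- nuc$dyad_start[i] - cursor
    if (gap > 0 || i > 1) add_linker(max(gap, 0), cursor)
    stem_seg <- c(stem_seg, length(kind) + 1L)
    kind <- c(kind, "nucleosome_stem")
    rest <- c(rest, geometry$stem_length)
    cursor <- nuc$dyad_start[i] + nuc$footprint[i]
    joint_bp <- c(joint_bp, cursor)
  }
  tail_gap <- ns$interval$end - cursor
  if (tail_gap > 0 || nn == 0) add_linker(max(tail_gap, 0), cursor)

  n_seg <- length(kind)
  theta0 <- numeric(n_seg + 1L)   # rest bend angle per joint (interior used)
  for (k in seq_along(stem_seg)) {
    s <- stem_seg[k]
    if (s > 1) theta0[s] <- stems$theta0[k]           # entry joint
    if (s < n_seg) theta0[s + 1L] <- stems$theta0[k]  # exit joint
  }

  structure(list(
    interval = ns$interval,
    segments = data.frame(kind = kind, rest_length = rest,
                          genomic_anchor = joint_bp[seq_len(n_seg)]),
    joint_anchor = joint_bp,
    n_seg = n_seg,
    stem_seg = stem_seg,
    h1 = h1,
    wrapped_bp = if (nn) nuc$footprint else numeric(0),
    stem_d = stems$d, stem_dvec = stems$dvec, stem_rrel = stems$rrel,
    joint_theta0 = theta0,
    geometry = geometry), class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  cat(sprintf(
    "<chain_topology> %d segments (%d nucleosome stems), contour %.1f nm, %s:%d-%d\n",
    x$n_seg, length(x$stem_seg), contour_length(x),
    x$interval$chrom, x$interval$start, x$interval$end))
  invisible(x)
}

#' Total chain contour length in nm
#' @param topology A `chain_topology`.
#' @return Sum of segment rest lengths, nm.
#' @export
contour_length <- function(topology) sum(topology$segments$rest_length)

#' Map a genomic coordinate to the nearest chain joint
#'
#' @param topology A `chain_topology`.
#' @param bp Genomic coordinate inside the topology interval.
#' @return Joint index (1-based; joints run 1..n_seg+1). Ties take the lower
#'   index.
#' @export
anchor_to_joint <- function(topology, bp) {
  iv <- topology$interval
  if (bp < iv$start || bp > iv$end)
    stop("anchor ", bp, " outside interval [", iv$start, ", ", iv$end, "]")
  which.min(abs(topology$joint_anchor - bp))
}

#' Initial chain configuration
#'
#' A configuration stores joint positions (`pos`, (n_seg+1) x 3, nm) and the
#' second frame vector per segment (`v`, n_seg x 3); `u` is the unit segment
#' direction and `f = u x v`, so frames are orthonormal by construction.
#'
#' @param topology A `chain_topology`.
#' @param mode `"straight"` (collinear, identity frames) or `"random_walk"`
#'   (independent uniform segment directions; optionally self-avoiding).
#' @param seed Integer seed for `"random_walk"`.
#' @param avoid_radius Minimal allowed distance between non-adjacent joints
#'   (nm) in `"random_walk"` mode; 0 disables the self-avoidance check.
#' @param max_retries Retries before giving up on a self-avoiding walk.
#' @return An object of class `cg_configuration`.
#' @export
initial_configuration <- function(topology, mode = c("straight", "random_walk"),
                                  seed = 1L, avoid_radius = 0,
                                  max_retries = 200L) {
  mode <- match.arg(mode)
  l <- topology$segments$rest_length
  n <- topology$n_seg
  if (mode == "straight") {
    pos <- cbind(c(0, cumsum(l)), 0, 0)
    v <- matrix(rep(c(0, 1, 0), each = n), n, 3)
    return(structure(list(pos = pos, v = v), class = "cg_configuration"))
  }
  withr_seed(seed, {
    for (try in seq_len(max_retries)) {
      z <- stats::runif(n, -1, 1)
      phi <- stats::runif(n, 0, 2 * pi)
      r <- sqrt(1 - z^2)
      u <- cbind(r * cos(phi), r * sin(phi), z)
      pos <- rbind(0, apply(u * l, 2, cumsum))
      if (avoid_radius > 0) {
        d <- as.matrix(stats::dist(pos))
        d[abs(row(d) - col(d)) <= 1] <- Inf
        if (min(d) < avoid_radius) next
      }
      v <- t(vapply(seq_len(n), function(i) perp_unit(u[i, ]), numeric(3)))
      return(structure(list(pos = pos, v = v), class = "cg_configuration"))
    }
    stop("self-avoiding random walk failed after ", max_retries, " retries")
  })
}

perp_unit <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * u) * u
  v / sqrt(sum(v^2))
}

#' Orthonormal local frames of a configuration
#' @param config A `cg_configuration`.
#' @return List of matrices `u`, `v`, `f` (n_seg x 3).
#' @export
config_frames <- function(config) {
  s <- diff(config$pos)
  u <- s / sqrt(rowSums(s^2))
  v <- config$v
  f <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  list(u = u, v = v, f = f)
}

#' Validate configuration frame invariants
#'
#' Checks unit norms, pairwise orthogonality within `tol`, and that `u` is
#' parallel to the vector to the next joint.
#'
#' @param config A `cg_configuration`.
#' @param topology The matching `chain_topology`.
#' @param tol Numerical tolerance (default 1e-9).
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_configuration <- function(config, topology, tol = 1e-9) {
  if (nrow(config$pos) != topology$n_seg + 1L)
    stop("configuration has ", nrow(config$pos), " joints, expected ",
         topology$n_seg + 1L)
  fr <- config_frames(config)
  if (max(abs(rowSums(fr$v^2) - 1)) > tol) stop("|v| != 1")
  if (max(abs(rowSums(fr$u * fr$v))) > tol) stop("u.v != 0")
  invisible(TRUE)
}

#' End-to-end distance of a configuration
#' @param config A `cg_configuration`.
#' @return Distance between first and last joint, nm.
#' @export
end_to_end <- function(config) {
  d <- config$pos[nrow(config$pos), ] - config$pos[1, ]
  sqrt(sum(d^2))
}

#' Nucleosome center and orientation from the stem frame
#'
#' Deterministic rigid-body transform of the stem segment frame by the
#' distance `d` and the placement angles resolved at build time.
#'
#' @param config A `cg_configuration`.
#' @param topology A `chain_topology`.
#' @param index Nucleosome index (1..number of stems).
#' @return List with `center` (3-vector, nm) and `frame` (3x3 matrix whose
#'   columns are the nucleosome axes; column 3 is the symmetry axis).
#' @export
nucleosome_center <- function(config, topology, index) {
  if (index < 1 || index > length(topology$stem_seg))
    stop("no nucleosome with index ", index)
  s <- topology$stem_seg[index]
  fr <- config_frames(config)
  Fm <- cbind(fr$u[s, ], fr$v[s, ], fr$f[s, ])
  mid <- (config$pos[s, ] + config$pos[s + 1, ]) / 2
  dv <- topology$stem_dvec[index, ]
  center <- mid + topology$stem_d[index] * as.numeric(Fm %*% dv)
  frame <- Fm %*% matrix(topology$stem_rrel[index, ], 3, 3)
  list(center = center, frame = frame)
}

#' All nucleosome centers and symmetry axes
#' @param config A `cg_configuration`.
#' @param topology A `chain_topology`.
#' @return List with `centers` (n x 3) and `axes` (n x 3, unit vectors).
#' @export
nucleosome_centers <- function(config, topology) {
  n <- length(topology$stem_seg)
  centers <- matrix(0, n, 3); axes <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nc <- nucleosome_center(config, topology, i)
    centers[i, ] <- nc$center
    axes[i, ] <- nc$frame[, 3]
  }
  list(centers = centers, axes = axes)
}
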