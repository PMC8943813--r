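#' Marker pair: two genomic anchors for distance measurement
#'
#' Anchors are probe-set midpoints in bp (midpoint-to-midpoint spacing).
#'
#' @param anchor_a,anchor_b Genomic positions in bp, `anchor_a < anchor_b`.
#' @param label Optional label.
#' @return Object of class `marker_pair`.
#' @export
marker_pair <- function(anchor_a, anchor_b, label = NULL) {
  if (anchor_a >= anchor_b) stop("need anchor_a < anchor_b")
  structure(list(anchor_a = anchor_a, anchor_b = anchor_b,
                 label = label %||% sprintf("%g-%g", anchor_a, anchor_b),
                 span = anchor_b - anchor_a),
            class = "marker_pair")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Euclidean distance between two genomic anchors in a configuration
#'
#' Each anchor maps to its nearest chain joint; the distance is the 3D
#' Euclidean distance between the two joint positions, invariant under
#' global isometries of the configuration.
#'
#' @param config A `cg_configuration`.
#' @param topology A `chain_topology`.
#' @param pair A `marker_pair`.
#' @return Distance in nm.
#' @export
marker_distance <- function(config, topology, pair) {
  ja <- anchor_to_joint(topology, pair$anchor_a)
  jb <- anchor_to_joint(topology, pair$anchor_b)
  d <- config$pos[jb, ] - config$pos[ja, ]
  sqrt(sum(d^2))
}

#' Maximum extension of a beads-on-a-string fiber
#'
#' Physical upper bound for the separation of two loci spaced by `span_bp`:
#' `span_bp * 0.34 / 7` nm (a fully stretched nucleosomal fiber is ~7-fold
#' shorter than naked B-DNA). For 5 kb this gives ~243 nm.
#'
#' @param span_bp Genomic span in bp, > 0.
#' @return Length in nm.
#' @export
max_extension <- function(span_bp) {
  if (any(span_bp <= 0)) stop("genomic span must be > 0 bp")
  span_bp * 0.34 / 7
}

#' Single-observation marker distance dataset
#'
#' @param distances Non-negative distances, nm (one per cell/configuration).
#' @param dimensionality `"3D"` or `"2D"`.
#' @param source `"simulated"`, `"measured"` or `"synthetic"`.
#' @param span_bp Genomic span of the marker pair, bp.
#' @param label Optional label.
#' @return Object of class `distance_dataset`.
#' @export
distance_dataset <- function(distances, dimensionality = c("3D", "2D"),
                             source = c("simulated", "measured", "synthetic"),
                             span_bp = NA_real_, label = NULL) {
  dimensionality <- match.arg(dimensionality)
  source <- match.arg(source)
  distances <- as.numeric(distances)
  if (any(distances < 0)) stop("distances must be >= 0")
  structure(list(distances = distances, dimensionality = dimensionality,
                 source = source, span_bp = span_bp, label = label),
            class = "distance_dataset")
}

#' @export
print.distance_dataset <- function(x, ...) {
  cat(sprintf("<distance_dataset> %d %s %s distances (span %s bp)\n",
              length(x$distances), x$dimensionality, x$source,
              format(x$span_bp)))
  invisible(x)
}

#' Read a measured/synthetic distance table (TSV)
#'
#' Expects a header with at least a `distance_nm` column; optional columns
#' `cell_id`, `dimensionality`, `pair`.
#'
#' @param path Path to the TSV file.
#' @param span_bp Genomic span of the pair, bp.
#' @param source Dataset provenance tag.
#' @return A `distance_dataset`.
#' @export
read_distance_table <- function(path, span_bp = NA_real_,
                                source = "measured") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!"distance_nm" %in% names(df)) stop("no distance_nm column in ", path)
  dim3 <- if ("dimensionality" %in% names(df)) df$dimensionality[1] else "3D"
  distance_dataset(df$distance_nm, dim3, source, span_bp,
                   label = if ("pair" %in% names(df)) df$pair[1] else NULL)
}

#' Write a distance dataset as TSV
#' @param ds A `distance_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_table <- function(ds, path) {
  df <- data.frame(cell_id = seq_along(ds$distances),
                   distance_nm = ds$distances,
                   dimensionality = ds$dimensionality,
                   pair = ds$label %||% NA)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cut off distances above a physical threshold
#'
#' Removes distances larger than `threshold` (by default the beads-on-a-
#' string maximum extension of the dataset's genomic span) and reports how
#' many observations were excluded. Idempotent.
#'
#' @param ds A `distance_dataset`.
#' @param threshold Cutoff in nm (> 0).
#' @return List with `dataset` (filtered) and `excluded` (count).
#' @export
apply_cutoff <- function(ds, threshold = max_extension(ds$span_bp)) {
  stopifnot(threshold > 0)
  keep <- ds$distances <= threshold
  out <- ds
  out$distances <- ds$distances[keep]
  list(dataset = out, excluded = sum(!keep))
}

#' Project 3D coordinate pairs to 2D distances by omitting z
#'
#' Mirrors the treatment of 2D-depletion microscopy data: 3D coordinates are
#' projected by dropping the optical (z) axis, so every projected distance is
#' less than or equal to its 3D counterpart.
#'
#' @param coords_a,coords_b Matrices (n x 3) of paired 3D coordinates, nm,
#'   ordered (z, y, x).
#' @return Numeric vector of 2D distances, nm.
#' @export
project_omit_z <- function(coords_a, coords_b) {
  coords_a <- rbind(coords_a); coords_b <- rbind(coords_b)
  stopifnot(ncol(coords_a) == 3, ncol(coords_b) == 3,
            nrow(coords_a) == nrow(coords_b))
  d <- coords_a[, 2:3, drop = FALSE] - coords_b[, 2:3, drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Density-normalized distance histogram
#'
#' Fixed binning shared across compared datasets: two histograms are
#' comparable only if their `breaks` are identical (enforced structurally by
#' [rmse_hist()] and [fit_mixture()]).
#'
#' @param ds A `distance_dataset` or numeric vector, nm.
#' @param bin_width Bin width in nm (default 10).
#' @param range Histogram range, nm; distances outside are dropped.
#' @return Object of class `dist_histogram` with `breaks`, `density`,
#'   `counts`, `n`.
#' @export
dist_histogram <- function(ds, bin_width = 10, range = NULL) {
  stopifnot(bin_width > 0)
  x <- if (inherits(ds, "distance_dataset")) ds$distances else as.numeric(ds)
  if (is.null(range)) {
    hi <- if (inherits(ds, "distance_dataset") && !is.na(ds$span_bp))
      max_extension(ds$span_bp) else max(x)
    range <- c(0, ceiling(hi / bin_width) * bin_width)
  }
  breaks <- seq(range[1], range[2], by = bin_width)
  if (utils::tail(breaks, 1) < range[2]) breaks <- c(breaks, range[2])
  x <- x[x >= range[1] & x <= range[2]]
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(list(breaks = breaks, density = h$density, counts = h$counts,
                 n = length(x)),
            class = "dist_histogram")
}

same_binning <- function(a, b) {
  length(a$breaks) == length(b$breaks) &&
    max(abs(a$breaks - b$breaks)) < 1e-9
}

#' Root mean square error between two histograms
#'
#' `sqrt(mean((density_a - density_b)^2))` over shared bins; symmetric, and 0
#' iff the histograms are identical.
#'
#' @param hist_a,hist_b `dist_histogram` objects with identical breaks.
#' @return RMSE over bins.
#' @export
rmse_hist <- function(hist_a, hist_b) {
  if (!same_binning(hist_a, hist_b))
    stop("histograms have different binning; rebuild with shared breaks")
  sqrt(mean((hist_a$density - hist_b$density)^2))
}

#' Constrained mixture deconvolution of a distance histogram
#'
#' Finds non-negative component weights summing to one that minimize the
#' squared bin-wise difference between the target histogram and the weighted
#' combination of component histograms; solved exactly as a quadratic
#' program (Goldfarb-Idnani dual method). Reports the RMSE of the fitted
#' mixture against the target.
#'
#' @param target_hist `dist_histogram` (e.g., measured distances).
#' @param component_hists List of `dist_histogram`s with identical binning
#'   (e.g., simulations with 0..5 nucleosomes removed).
#' @return Object of class `mixture_fit`: `weights`, `rmse`, `fitted`
#'   (mixture density), `target`.
#' @export
fit_mixture <- function(target_hist, component_hists) {
  if (!length(component_hists)) stop("need at least one component")
  for (h in component_hists)
    if (!same_binning(target_hist, h))
      stop("component binning differs from target; rebuild with shared breaks")
  C <- vapply(component_hists, `[[`, numeric(length(target_hist$density)),
              "density")
  C <- matrix(C, ncol = length(component_hists))
  if (any(colSums(abs(C)) == 0))
    stop("degenerate all-zero component histogram")
  y <- target_hist$density
  k <- ncol(C)
  Dmat <- crossprod(C)
  # tiny ridge keeps the QP strictly convex when components are collinear
  Dmat <- Dmat + diag(1e-10 * max(diag(Dmat)), k)
  dvec <- crossprod(C, y)
  Amat <- cbind(rep(1, k), diag(k))
  bvec <- c(1, rep(0, k))
  sol <- quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = 1)
  w <- pmax(sol$solution, 0)
  w <- w / sum(w)
  fitted <- as.numeric(C %*% w)
  names(w) <- names(component_hists) %||% paste0("component_", seq_len(k))
  structure(list(weights = w,
                 rmse = sqrt(mean((y - fitted)^2)),
                 fitted = fitted, target = y,
                 breaks = target_hist$breaks),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> weights:",
      paste(sprintf("%s=%.3f", names(x$weights), x$weights), collapse = ", "),
      sprintf("| RMSE %.5g\n", x$rmse))
  invisible(x)
}

#' Summary statistics of a distance dataset
#' @param ds A `distance_dataset` (non-empty).
#' @return data.frame with `median`, `mean`, `sd`, `n` (nm).
#' @export
dist_summary <- function(ds) {
  x <- ds$distances
  if (!length(x)) stop("empty distance dataset")
  data.frame(median = stats::median(x), mean = mean(x),
             sd = stats::sd(x), n = length(x))
}

#' Two-sided Wilcoxon rank-sum comparison of two distance datasets
#'
#' Mann-Whitney test with normal approximation and midrank tie correction,
#' as used to compare the pooled active- and inactive-region distributions.
#'
#' @param ds_a,ds_b `distance_dataset`s or numeric vectors.
#' @return List with `statistic` (W) and `p_value`.
#' @export
rank_sum_compare <- function(ds_a, ds_b) {
  xa <- if (inherits(ds_a, "distance_dataset")) ds_a$distances else ds_a
  xb <- if (inherits(ds_b, "distance_dataset")) ds_b$distances else ds_b
  if (!length(xa) || !length(xb)) stop("both datasets must be non-empty")
  wt <- stats::wilcox.test(xa, xb, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Distances of one marker pair across a thinned trajectory
#'
#' @param trajectory A `cg_trajectory` with stored configurations.
#' @param topology The matching `chain_topology`.
#' @param pair A `marker_pair`.
#' @param cutoff Apply the beads-on-a-string cutoff (default TRUE).
#' @return A `distance_dataset` (3D, simulated); the number of observations
#'   excluded by the cutoff is in attribute `excluded`.
#' @export
trajectory_distances <- function(trajectory, topology, pair, cutoff = TRUE) {
  if (!length(trajectory$configs))
    stop("trajectory has no stored configurations")
  d <- vapply(trajectory$configs, marker_distance, numeric(1),
              topology = topology, pair = pair)
  ds <- distance_dataset(d, "3D", "simulated", span_bp = pair$span,
                         label = pair$label)
  if (!cutoff) return(ds)
  cf <- apply_cutoff(ds)
  out <- cf$dataset
  attr(out, "excluded") <- cf$excluded
  out
}

#' Isotropic random projection of 3D distances to 2D
#'
#' For comparing 3D simulated distances with 2D microscopy data: each 3D
#' distance is multiplied by `sin(theta)` with `theta` drawn from the
#' uniform-sphere polar density, emulating random cell orientation relative
#' to the optical axis.
#'
#' @param ds A 3D `distance_dataset`.
#' @param seed Integer seed.
#' @return A 2D `distance_dataset` (labeled as projected).
#' @export
random_projection_2d <- function(ds, seed = 1L) {
  stopifnot(ds$dimensionality == "3D")
  d2 <- withr_seed(seed, {
    ct <- stats::runif(length(ds$distances), -1, 1)  # cos(theta) uniform
    ds$distances * sqrt(1 - ct^2)
  })
  distance_dataset(d2, "2D", ds$source, ds$span_bp,
                   label = paste0(ds$label %||% "", " (projected)"))
}
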