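# Shared fixtures, all generated in code.

# naked-DNA chain: n segments of length l_nm each (no nucleosomes)
naked_chain <- function(n = 30, l_nm = 10) {
  bp <- floor(n * l_nm / 0.34)
  ns <- nucleosome_set(genomic_interval("chrT", 0, bp), numeric(0))
  build_chain(ns)
}

# small nucleosome fiber with deterministic scores
small_fiber <- function(n_nuc = 6, nrl = 183, scores = NULL) {
  dyads <- seq(0, by = nrl, length.out = n_nuc)
  iv <- genomic_interval("chrT", 0, max(dyads) + 147 + 36)
  nucleosome_set(iv, dyads, 147,
                 scores %||% seq(2, by = 1, length.out = n_nuc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ideal-chain force field (no pair interactions)
ff_ideal <- function(...) {
  force_field(electrostatics = FALSE, excluded_volume = FALSE, e_max = 0, ...)
}

# histogram object with prescribed densities (for arithmetic checks)
manual_hist <- function(density, bin_width = 1) {
  structure(list(breaks = seq(0, by = bin_width,
                              length.out = length(density) + 1L),
                 density = density,
                 counts = rep(NA_integer_, length(density)),
                 n = NA_integer_),
            class = "dist_histogram")
}

# rigid rotation + translation of a configuration
transform_config <- function(config, angle = 0.7,
                             axis = c(1, 2, 3), shift = c(5, -3, 2)) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  config$pos <- sweep(config$pos %*% t(R), 2, -shift)
  config$v <- config$v %*% t(R)
  config
}
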