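#' Genomic interval (0-based, half-open)
#'
#' Minimal container for a contiguous genomic region. Coordinates follow the
#' BED convention: `start` is 0-based inclusive, `end` exclusive.
#'
#' @param chrom Chromosome name.
#' @param start,end Interval bounds in base pairs, `0 <= start < end`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start >= 0 && start < end))
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%d-%d (%d bp)\n",
              x$chrom, x$start, x$end, x$end - x$start))
  invisible(x)
}

#' Width of a genomic interval in bp
#' @param x A `genomic_interval`.
#' @return Numeric width in bp.
#' @export
interval_width <- function(x) x$end - x$start

#' Non-overlapping nucleosome position set
#'
#' An ordered set of nucleosome footprints on one genomic interval, each with
#' an occupancy score. `dyad_start` is the 0-based start of the footprint
#' (the canonical core particle occupies `[dyad_start, dyad_start + footprint)`).
#' Footprints must be sorted, non-overlapping and fully inside the interval.
#'
#' @param interval A `genomic_interval`.
#' @param dyad_start Numeric vector of footprint starts (bp).
#' @param footprint Footprint width(s) in bp, recycled; default 147.
#' @param occupancy_score Non-negative score per nucleosome (arbitrary units),
#'   `NA` if unknown.
#' @return An object of class `nucleosome_set` with elements `interval` and
#'   `nucleosomes` (a data.frame).
#' @export
nucleosome_set <- function(interval, dyad_start, footprint = 147,
                           occupancy_score = NA_real_) {
  stopifnot(inherits(interval, "genomic_interval"))
  n <- length(dyad_start)
  nuc <- data.frame(dyad_start = as.numeric(dyad_start),
                    footprint = rep_len(as.numeric(footprint), n),
                    occupancy_score = rep_len(as.numeric(occupancy_score), n))
  nuc <- nuc[order(nuc$dyad_start), , drop = FALSE]
  rownames(nuc) <- NULL
  ns <- structure(list(interval = interval, nucleosomes = nuc),
                  class = "nucleosome_set")
  validate_nucleosome_set(ns)
  ns
}

validate_nucleosome_set <- function(ns) {
  nuc <- ns$nucleosomes
  if (nrow(nuc) == 0L) return(invisible(ns))
  if (any(nuc$footprint < 1))
    stop("all footprints must be >= 1 bp")
  if (any(!is.na(nuc$occupancy_score) & nuc$occupancy_score < 0))
    stop("occupancy scores must be >= 0")
  if (nuc$dyad_start[1] < ns$interval$start ||
      max(nuc$dyad_start + nuc$footprint) > ns$interval$end)
    stop("nucleosome footprints must lie fully inside the interval")
  if (nrow(nuc) >= 2L) {
    ends <- nuc$dyad_start + nuc$footprint
    bad <- which(nuc$dyad_start[-1] < ends[-nrow(nuc)])
    if (length(bad)) {
      i <- bad[1]
      stop(sprintf(
        "overlapping nucleosomes: records %d [%d, %d) and %d [%d, %d)",
        i, nuc$dyad_start[i], ends[i],
        i + 1L, nuc$dyad_start[i + 1], ends[i + 1]))
    }
  }
  invisible(ns)
}

#' @export
print.nucleosome_set <- function(x, ...) {
  cat(sprintf("<nucleosome_set> %d nucleosomes on %s:%d-%d\n",
              nrow(x$nucleosomes), x$interval$chrom,
              x$interval$start, x$interval$end))
  invisible(x)
}

#' Number of nucleosomes in a set
#' @param ns A `nucleosome_set`.
#' @return Integer count.
#' @export
n_nucleosomes <- function(ns) nrow(ns$nucleosomes)

#' Read nucleosome positions from a BED-like file
#'
#' Expects at least `chrom`, `start`, `end` columns (whitespace separated, no
#' header; `track`/`#` lines are skipped); column 5, when present, is taken as
#' the occupancy score (BED convention: name in column 4, score in column 5).
#' All records must share one chromosome; the set interval is taken from
#' `interval` or, when `NULL`, from the span of the records.
#'
#' @param path Path to the file.
#' @param interval Optional `genomic_interval` enclosing all records.
#' @return A validated `nucleosome_set`.
#' @export
read_positions <- function(path, interval = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no records in ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed line ", lineno[which(nf < 3L)[1]],
         ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed line ", lineno[which(is.na(start) | is.na(end))[1]],
         ": non-numeric coordinates")
  score <- rep(NA_real_, length(lines))
  has5 <- nf >= 5L
  score[has5] <- suppressWarnings(
    as.numeric(vapply(fields[has5], `[[`, "", 5L)))
  if (length(unique(chrom)) != 1L)
    stop("all records must be on one chromosome, found: ",
         paste(unique(chrom), collapse = ", "))
  if (is.null(interval))
    interval <- genomic_interval(chrom[1], min(start), max(end))
  nucleosome_set(interval, dyad_start = start, footprint = end - start,
                 occupancy_score = score)
}

#' Write nucleosome positions as BED5
#' @param ns A `nucleosome_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_positions <- function(ns, path) {
  nuc <- ns$nucleosomes
  df <- data.frame(chrom = ns$interval$chrom,
                   start = format(nuc$dyad_start, scientific = FALSE, trim = TRUE),
                   end = format(nuc$dyad_start + nuc$footprint,
                                scientific = FALSE, trim = TRUE),
                   name = sprintf("nuc_%d", seq_len(nrow(nuc))),
                   score = ifelse(is.na(nuc$occupancy_score), 0,
                                  nuc$occupancy_score))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-bp occupancy track
#'
#' @param interval A `genomic_interval`.
#' @param values Non-negative signal, one value per bp of the interval.
#' @return An object of class `occupancy_track`.
#' @export
occupancy_track <- function(interval, values) {
  stopifnot(inherits(interval, "genomic_interval"))
  values <- as.numeric(values)
  if (length(values) != interval_width(interval))
    stop("track length (", length(values), ") must equal interval width (",
         interval_width(interval), ")")
  if (any(values < 0)) stop("occupancy values must be >= 0")
  structure(list(interval = interval, values = values),
            class = "occupancy_track")
}

#' Read a 4-column bedGraph-like occupancy track
#'
#' Columns: chrom, start, end, value; expanded to per-bp resolution over the
#' covered span (uncovered bp get 0).
#'
#' @param path Path to the file.
#' @param interval Optional enclosing `genomic_interval`.
#' @return An `occupancy_track`.
#' @export
read_occupancy <- function(path, interval = NULL) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  if (is.null(interval))
    interval <- genomic_interval(df$chrom[1], min(df$start), max(df$end))
  values <- numeric(interval_width(interval))
  for (i in seq_len(nrow(df))) {
    a <- df$start[i] - interval$start
    b <- df$end[i] - interval$start
    values[(a + 1):b] <- df$value[i]
  }
  occupancy_track(interval, values)
}

#' Write an occupancy track as bedGraph (run-length compressed)
#' @param track An `occupancy_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(track, path) {
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  df <- data.frame(chrom = track$interval$chrom,
                   start = format(track$interval$start + starts,
                                  scientific = FALSE, trim = TRUE),
                   end = format(track$interval$start + ends,
                                scientific = FALSE, trim = TRUE),
                   value = r$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Linker DNA lengths between successive nucleosomes
#'
#' The linker between nucleosome i and i+1 is
#' `dyad_start[i+1] - dyad_start[i] - footprint[i]` bp; touching footprints
#' give a 0-bp linker.
#'
#' @param ns A `nucleosome_set`.
#' @return Numeric vector of length N-1 (empty for N < 2).
#' @export
linker_lengths <- function(ns) {
  nuc <- ns$nucleosomes
  if (nrow(nuc) < 2L) return(numeric(0))
  diff(nuc$dyad_start) - nuc$footprint[-nrow(nuc)]
}

#' Sliding-window nucleosome repeat length
#'
#' NRL values are successive dyad_start differences. Within each window,
#' individual NRL values larger than `max_nrl` bp are discarded, and windows
#' containing fewer than `min_nucleosomes` nucleosomes emit no value.
#'
#' @param ns A `nucleosome_set`.
#' @param window Window width in bp (default 30000).
#' @param step Window step in bp (default `window / 2`).
#' @param max_nrl Individual NRL values above this are excluded (default 300).
#' @param min_nucleosomes Minimum nucleosomes per emitted window (default 3).
#' @return data.frame with columns `midpoint`, `mean_nrl`, `n_nrl`.
#' @export
nrl_sliding_window <- function(ns, window = 30000, step = window / 2,
                               max_nrl = 300, min_nucleosomes = 3) {
  stopifnot(window > 0, step > 0)
  out <- data.frame(midpoint = numeric(0), mean_nrl = numeric(0),
                    n_nrl = integer(0))
  nuc <- ns$nucleosomes
  if (nrow(nuc) == 0L) return(out)
  iv <- ns$interval
  starts <- seq(iv$start, max(iv$start, iv$end - window), by = step)
  for (s in starts) {
    e <- s + window
    idx <- which(nuc$dyad_start >= s & nuc$dyad_start < e)
    if (length(idx) < min_nucleosomes) next
    nrl <- diff(nuc$dyad_start[idx])
    nrl <- nrl[nrl <= max_nrl]
    if (!length(nrl)) next
    out <- rbind(out, data.frame(midpoint = s + window / 2,
                                 mean_nrl = mean(nrl),
                                 n_nrl = length(nrl)))
  }
  out
}

#' Occupancy signal per nucleosome
#'
#' Mean per-bp track value over each footprint when a track is supplied,
#' otherwise the stored `occupancy_score` column.
#'
#' @param ns A `nucleosome_set`.
#' @param track Optional `occupancy_track` covering all footprints.
#' @return Numeric vector, one signal per nucleosome.
#' @export
occupancy_signal <- function(ns, track = NULL) {
  nuc <- ns$nucleosomes
  if (is.null(track)) {
    if (anyNA(nuc$occupancy_score))
      stop("no occupancy track given and scores contain NA")
    return(nuc$occupancy_score)
  }
  iv <- track$interval
  if (nrow(nuc) &&
      (nuc$dyad_start[1] < iv$start ||
       max(nuc$dyad_start + nuc$footprint) > iv$end))
    stop("occupancy track does not cover all footprints")
  vapply(seq_len(nrow(nuc)), function(i) {
    a <- nuc$dyad_start[i] - iv$start
    mean(track$values[(a + 1):(a + nuc$footprint[i])])
  }, numeric(1))
}

#' Rank nucleosomes by ascending occupancy signal
#'
#' Stable ascending order; ties are broken by ascending genomic position.
#'
#' @inheritParams occupancy_signal
#' @return Integer permutation: `ranking[1]` is the index of the
#'   lowest-occupancy nucleosome.
#' @export
rank_by_occupancy <- function(ns, track = NULL) {
  sig <- occupancy_signal(ns, track)
  order(sig, ns$nucleosomes$dyad_start)
}

#' Replace the k lowest-occupancy nucleosomes by naked DNA
#'
#' Deletes the k nucleosomes with the lowest occupancy signal; their wrapped
#' DNA becomes linker DNA (adjacent linkers merge). The genomic interval is
#' unchanged, so total DNA length is conserved.
#'
#' @inheritParams occupancy_signal
#' @param k Number of nucleosomes to remove, `0 <= k < N`.
#' @return A new `nucleosome_set`.
#' @export
remove_lowest <- function(ns, k, track = NULL) {
  n <- n_nucleosomes(ns)
  if (k < 0 || k >= n)
    stop("k must satisfy 0 <= k < ", n, ", got ", k)
  if (k == 0) return(ns)
  drop <- rank_by_occupancy(ns, track)[seq_len(k)]
  nuc <- ns$nucleosomes[-drop, , drop = FALSE]
  nucleosome_set(ns$interval, nuc$dyad_start, nuc$footprint,
                 nuc$occupancy_score)
}
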