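test_that("nucleosome sets validate ordering, bounds and overlap", {
  iv <- genomic_interval("chr1", 0, 1000)
  ns <- nucleosome_set(iv, c(300, 0, 600))
  expect_equal(ns$nucleosomes$dyad_start, c(0, 300, 600))
  expect_equal(n_nucleosomes(ns), 3L)
  expect_error(nucleosome_set(iv, c(0, 100)), "overlap")
  expect_error(nucleosome_set(iv, 900), "inside the interval")
  expect_error(genomic_interval("chr1", 10, 10), "invalid interval")
  expect_error(nucleosome_set(iv, 0, footprint = 0), "footprint")
})

test_that("BED round trip preserves the set and errors are located", {
  ns <- small_fiber(5)
  path <- withr::local_tempfile(fileext = ".bed")
  write_positions(ns, path)
  ns2 <- read_positions(path, interval = ns$interval)
  expect_equal(ns2$nucleosomes$dyad_start, ns$nucleosomes$dyad_start)
  expect_equal(ns2$nucleosomes$occupancy_score, ns$nucleosomes$occupancy_score)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t147\tn1\t5", "chr1\t100\t247\tn2\t4"), bad)
  expect_error(read_positions(bad), "overlap")
  writeLines(c("chr1\t0\t147", "chr1\tx"), bad)
  expect_error(read_positions(bad), "line 2")
})

test_that("occupancy track round-trips through bedGraph", {
  iv <- genomic_interval("chr1", 100, 160)
  tr <- occupancy_track(iv, rep(c(0, 3, 1), each = 20))
  path <- withr::local_tempfile(fileext = ".bg")
  write_occupancy(tr, path)
  tr2 <- read_occupancy(path, iv)
  expect_equal(tr2$values, tr$values)
  expect_error(occupancy_track(iv, 1:10), "must equal interval width")
})

test_that("linker lengths follow dyad spacing minus footprint", {
  iv <- genomic_interval("chr1", 0, 2000)
  expect_equal(linker_lengths(nucleosome_set(iv, c(0, 200))), 53)
  expect_equal(linker_lengths(nucleosome_set(iv, c(0, 147))), 0)
  ns <- nucleosome_set(iv, seq(0, by = 183, length.out = 10))
  expect_equal(linker_lengths(ns), rep(36, 9))
  expect_equal(linker_lengths(nucleosome_set(iv, 0)), numeric(0))
})

test_that("sliding-window NRL applies the published filters", {
  # perfectly periodic positions: every window mean is the spacing
  ns <- small_fiber(500, nrl = 183)
  res <- nrl_sliding_window(ns, window = 30000)
  expect_true(nrow(res) > 1)
  expect_true(all(abs(res$mean_nrl - 183) < 1e-9))

  # windows with fewer than 3 nucleosomes are omitted
  iv <- genomic_interval("chr1", 0, 30000)
  ns2 <- nucleosome_set(iv, c(0, 183))
  expect_equal(nrow(nrl_sliding_window(ns2, window = 30000)), 0L)

  # a single 400-bp spacing among 183s is excluded from the mean
  dy <- c(seq(0, by = 183, length.out = 10),
          max(seq(0, by = 183, length.out = 10)) + 400)
  ns3 <- nucleosome_set(genomic_interval("chr1", 0, 40000), dy)
  res3 <- nrl_sliding_window(ns3, window = 40000)
  expect_equal(res3$mean_nrl, 183)
  expect_equal(res3$n_nrl, 9L)

  # empty set
  ns4 <- nucleosome_set(iv, numeric(0))
  expect_equal(nrow(nrl_sliding_window(ns4)), 0L)
})

test_that("occupancy ranking sorts ascending with positional tie-break", {
  ns <- small_fiber(3, scores = c(5, 2, 9))
  expect_equal(rank_by_occupancy(ns), c(2L, 1L, 3L))

  # uniform track: all tie, ranking falls back to genomic order
  iv <- ns$interval
  tr <- occupancy_track(iv, rep(1, interval_width(iv)))
  expect_equal(rank_by_occupancy(ns, tr), 1:3)

  # a zeroed stretch makes that nucleosome rank first
  vals <- rep(1, interval_width(iv))
  mid <- ns$nucleosomes$dyad_start[2]
  vals[(mid + 1):(mid + 147)] <- 0
  expect_equal(rank_by_occupancy(ns, occupancy_track(iv, vals))[1], 2L)

  # track not covering footprints errors
  short_iv <- genomic_interval("chrT", 0, 200)
  expect_error(occupancy_signal(ns, occupancy_track(short_iv, rep(1, 200))),
               "cover")
  expect_true(all(sort(rank_by_occupancy(ns)) == 1:3))  # permutation
})

test_that("remove_lowest deletes by rank, merges linkers, conserves DNA", {
  ns <- small_fiber(3, nrl = 200, scores = c(5, 2, 9))
  expect_identical(remove_lowest(ns, 0), ns)
  r1 <- remove_lowest(ns, 1)   # middle nucleosome has the lowest score
  expect_equal(n_nucleosomes(r1), 2L)
  expect_equal(linker_lengths(r1), 53 + 147 + 53)
  # total DNA (linkers + wrapped) is conserved: the wrap becomes linker
  total_dna <- function(x) sum(linker_lengths(x)) +
    sum(x$nucleosomes$footprint)
  expect_equal(total_dna(r1), total_dna(ns))
  expect_equal(r1$interval$end, ns$interval$end)
  expect_error(remove_lowest(ns, 3), "k must satisfy")
  expect_error(remove_lowest(ns, -1), "k must satisfy")
})

test_that("sliding-window NRL recovers the generating mean within 2 SEM", {
  ns <- gen_positions(region_length = 60000, nrl_mean = 190, nrl_sd = 20,
                      seed = 5)
  res <- nrl_sliding_window(ns, window = 60000)
  spac <- attr(ns, "true_nrl")
  sem <- stats::sd(spac) / sqrt(length(spac))
  expect_lt(abs(res$mean_nrl[1] - 190), 2 * sem + abs(mean(spac) - 190))
})
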