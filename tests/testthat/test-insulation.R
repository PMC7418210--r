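test_that("insulation is zero on a uniform matrix and invariant to scaling", {
  m <- constant_diag_map(40)
  ins <- insulation_score(m, window = 2.5e5)
  expect_true(all(abs(ins$value) < 1e-12, na.rm = TRUE))
  expect_true(all(is.na(ins$value[c(1:5, 36:40)])))  # edges undefined

  sim <- sim_tads(beta = 2, depth = 5e5, seed = 12)
  m2 <- sim$maps[[1]]
  ins1 <- insulation_score(m2)
  m3 <- m2; m3$count <- m3$count * 2
  ins2 <- insulation_score(m3)
  expect_equal(ins1$value, ins2$value, tolerance = 1e-12)
})

test_that("planted boundaries are insulation minima and recovered within one bin", {
  sim <- sim_tads(beta = 2, depth = 2e6, seed = 13, sparse = FALSE)
  ins <- insulation_score(sim$maps[[1]])
  called <- call_tad_boundaries(ins)
  res <- 5e4
  cb <- floor(called$boundaries$start / res)
  pb <- floor((sim$truth$boundaries$start + sim$truth$boundaries$end) / 2 / res)
  recovery <- mean(vapply(pb, function(p) any(abs(cb - p) <= 1), TRUE))
  expect_gte(recovery, 0.9)
  # derived TADs are non-overlapping, sorted, >= 2 bins
  td <- called$tads
  expect_true(all(td$end - td$start >= 2 * res))
  expect_true(all(td$start[-1] >= td$end[-nrow(td)]))
})

test_that("boundary calling follows the tie and monotony rules", {
  mk_track <- function(v) tibble::tibble(chrom = "c", start = (seq_along(v) - 1) * 5e4,
                                         end = seq_along(v) * 5e4, value = v)
  # monotone score: no boundaries
  expect_equal(nrow(call_tad_boundaries(mk_track(seq(-1, 1, length.out = 20)))$boundaries), 0)
  # two minima 1 bin apart: deeper kept
  v <- c(0.5, 0.4, -0.6, -0.9, 0.4, 0.5)
  b <- call_tad_boundaries(mk_track(v), min_strength = 0.1)$boundaries
  expect_equal(nrow(b), 1)
  expect_equal(b$start, 3 * 5e4)
  # equal depths: leftmost kept
  v2 <- c(0.5, 0.4, -0.9, -0.9, 0.4, 0.5)
  b2 <- call_tad_boundaries(mk_track(v2), min_strength = 0.1)$boundaries
  expect_equal(b2$start, 2 * 5e4)
})

test_that("aggregate boundary profiles dip at true boundaries and are flat at random ones", {
  sim <- sim_tads(beta = 2, depth = 2e6, seed = 14, sparse = FALSE)
  ins <- insulation_score(sim$maps[[1]])
  prof <- aggregate_boundary_is(ins, sim$truth$boundaries)
  dip <- attr(prof, "dip")
  flank_mean <- mean(prof$mean_is[abs(prof$offset) > 3e5], na.rm = TRUE)
  expect_lt(dip, flank_mean)

  set.seed(3)
  rnd <- tibble::tibble(chrom = "chrT",
                        start = sort(sample(seq(1e6, 1.4e7, 5e4), 20)))
  rnd$end <- rnd$start + 5e4
  prof_r <- aggregate_boundary_is(ins, rnd)
  se <- stats::sd(ins$value, na.rm = TRUE) / sqrt(20)
  expect_lt(abs(attr(prof_r, "dip") - mean(prof_r$mean_is, na.rm = TRUE)), 3 * se)
})

test_that("boundary dips deepen monotonically with planted insulation strength", {
  dips <- vapply(c(0.5, 1, 2), function(b) {
    sim <- sim_tads(beta = b, depth = 2e6, seed = 15, sparse = FALSE)
    ins <- insulation_score(sim$maps[[1]])
    attr(aggregate_boundary_is(ins, sim$truth$boundaries), "dip")
  }, 0)
  expect_true(all(diff(dips) < 0))
})

test_that("aggregate TAD signal is 0.5 on flat maps, rises with beta, and shuffles to 0.5", {
  m <- constant_diag_map(120)
  td <- tibble::tibble(chrom = "chr1", start = c(1e6, 3e6), end = c(1.5e6, 3.6e6))
  expect_equal(aggregate_tad_signal(m, td)$signal, 0.5, tolerance = 1e-9)

  sigs <- vapply(c(0.5, 2), function(b) {
    s <- sim_tads(beta = b, depth = 2e6, seed = 16)
    aggregate_tad_signal(s$maps[[1]], s$truth$tads)$signal
  }, 0)
  expect_gt(sigs[2], sigs[1])
  expect_gt(sigs[2], 0.5)

  sim <- sim_tads(beta = 2, depth = 2e6, seed = 16)
  set.seed(4)
  sh <- replicate(30, aggregate_tad_signal(
    sim$maps[[1]], shuffle_tads(sim$truth$tads, chrom_sizes("chrT", 1.5e7)))$signal)
  expect_lt(abs(mean(sh) - 0.5), 0.02)
})

test_that("differential boundaries are null on identical tracks and recover planted shifts", {
  set.seed(9)
  n <- 1000; res <- 5e4
  base <- stats::rnorm(n, 0, 0.1)
  mk <- function(v) tibble::tibble(chrom = "c", start = (0:(n - 1)) * res,
                                   end = (1:n) * res, value = v)
  bnd_bins <- seq(10, 990, by = 5)[1:200]
  bounds <- tibble::tibble(chrom = "c", start = bnd_bins * res, end = (bnd_bins + 1) * res)

  expect_warning(
    same <- differential_boundaries(bounds, mk(base), mk(base)),
    "single-replicate")
  expect_equal(sum(same$significant), 0)

  shifted <- base
  hit <- bnd_bins[1:20]
  shifted[hit + 1] <- shifted[hit + 1] - 0.3
  suppressWarnings(
    res2 <- differential_boundaries(bounds,
                                    list(mk(base + stats::rnorm(n, 0, 0.02))),
                                    list(mk(shifted + stats::rnorm(n, 0, 0.02)))))
  found <- res2$significant[match(hit * res, res2$start)]
  expect_gte(sum(found), 16)
  false_flags <- sum(res2$significant) - sum(found)
  expect_lte(false_flags / max(1, sum(res2$significant)), 0.25)
})

test_that("differential-boundary FDR holds on pure-null replicate pairs", {
  set.seed(10)
  n <- 600; res <- 5e4
  bnd_bins <- seq(5, 595, by = 3)[1:150]
  bounds <- tibble::tibble(chrom = "c", start = bnd_bins * res, end = (bnd_bins + 1) * res)
  mk <- function() tibble::tibble(chrom = "c", start = (0:(n - 1)) * res,
                                  end = (1:n) * res, value = stats::rnorm(n, 0, 0.1))
  fdr <- vapply(1:20, function(s) {
    r <- differential_boundaries(bounds, list(mk(), mk()), list(mk(), mk()), alpha = 0.05)
    mean(r$significant)
  }, 0)
  expect_lte(mean(fdr), 1.5 * 0.05)
})

test_that("boundary context profiles localize features and split motif orientations", {
  bounds <- tibble::tibble(chrom = "c", start = c(1e6, 2e6), end = c(1e6, 2e6) + 5e4)
  central <- tibble::tibble(chrom = "c", start = c(1.02e6, 2.02e6),
                            end = c(1.03e6, 2.03e6))
  prof <- boundary_context_profile(bounds, central, flank = 1e5, bin = 1e4)
  expect_equal(sum(prof$mean_count[abs(prof$offset) < 1e4]), 1)
  expect_equal(sum(prof$mean_count), 1)

  motifs <- tibble::tibble(chrom = "c",
                           start = c(9.5e5, 1.95e6, 1.08e6, 2.08e6),
                           end = c(9.6e5, 1.96e6, 1.09e6, 2.09e6),
                           strand = c("+", "+", "-", "-"))
  mp <- boundary_context_profile(bounds, motifs, flank = 1e5, bin = 1e4)
  fwd <- mp[mp$strand == "+", ]; rev <- mp[mp$strand == "-", ]
  expect_gt(sum(fwd$mean_count[fwd$offset < 0]), sum(fwd$mean_count[fwd$offset > 0]))
  expect_gt(sum(rev$mean_count[rev$offset > 0]), sum(rev$mean_count[rev$offset < 0]))

  empty <- boundary_context_profile(bounds, central[0, ], flank = 1e5, bin = 1e4)
  expect_true(all(empty$mean_count == 0))
})
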