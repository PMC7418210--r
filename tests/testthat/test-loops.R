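loop_sim <- function(lambda = 5, seed = 41, depth = 2e6, with_loops = TRUE) {
  sizes <- chrom_sizes("chrL", 6e6)
  loops <- NULL
  if (with_loops) {
    a1 <- seq(5e5, 5e6, by = 9e5)
    loops <- tibble::tibble(chrom = "chrL", start1 = a1, start2 = a1 + 5e5,
                            lambda = lambda, orientation = "+-")
  }
  simulate_hic(architecture_spec(sizes = sizes, resolution = 1e4, gamma = 0,
                                 compartments = NULL, tads = NULL, loops = loops,
                                 depth = depth), seed = seed)
}

test_that("planted focal loops are recovered and short-range loops are excluded", {
  sim <- loop_sim(lambda = 5, seed = 41)
  calls <- call_loops(sim$maps[[1]])
  tr <- sim$truth$loops
  hit <- vapply(seq_len(nrow(tr)), function(k)
    any(calls$start1 == tr$start1[k] & calls$start2 == tr$start2[k]), TRUE)
  expect_gte(mean(hit), 0.8)
  expect_true(all(calls$distance >= 3e5))
  expect_true(all(calls$q_value < 0.01))

  # a loop planted below the distance cutoff is never reported
  near <- tibble::tibble(chrom = "chrL", start1 = 2e6, start2 = 2.2e6,
                         lambda = 8, orientation = "+-")
  sim2 <- simulate_hic(architecture_spec(sizes = chrom_sizes("chrL", 6e6),
                                         resolution = 1e4, gamma = 0,
                                         compartments = NULL, tads = NULL,
                                         loops = near, depth = 2e6), seed = 42)
  calls2 <- call_loops(sim2$maps[[1]])
  expect_false(any(calls2$start1 == 2e6 & calls2$start2 == 2.2e6))
})

test_that("pure-decay maps rarely produce loop calls", {
  n_called <- vapply(1:5, function(s)
    nrow(call_loops(loop_sim(with_loops = FALSE, seed = 100 + s)$maps[[1]])), 0)
  expect_lte(sum(n_called > 0), 1)
})

test_that("a chromosome shorter than the distance cutoff yields an empty loop set", {
  m <- constant_diag_map(10, res = 1e4)
  expect_equal(nrow(call_loops(m, min_distance = 3e5)), 0)
})

test_that("convergent filtering keeps only peak-supported convergent motif pairs", {
  loops <- tibble::tibble(chrom = "c", start1 = 1e6, end1 = 1e6 + 1e4,
                          start2 = 1.6e6, end2 = 1.6e6 + 1e4)
  peaks <- tibble::tibble(chrom = "c", start = c(1e6, 1.6e6) - 2e3,
                          end = c(1e6, 1.6e6) + 1.2e4)
  conv <- tibble::tibble(chrom = "c", start = c(1.002e6, 1.602e6),
                         end = c(1.0021e6, 1.6021e6), strand = c("+", "-"))
  expect_equal(nrow(filter_convergent(loops, peaks, conv)), 1)

  tandem <- conv; tandem$strand <- c("+", "+")
  expect_equal(nrow(filter_convergent(loops, peaks, tandem)), 0)

  expect_equal(nrow(filter_convergent(loops, peaks[1, ], conv)), 0)  # anchor 2 peakless
  expect_equal(nrow(filter_convergent(loops[0, ], peaks, conv)), 0)
})

test_that("APA equals 1 exactly on constant O/E and scores planted loops highly", {
  m <- constant_diag_map(120, res = 1e4)
  loops <- tibble::tibble(chrom = "chr1", start1 = 3e5, start2 = 8e5)
  expect_identical(apa(m, loops)$score, 1)
  m2 <- m; m2$count <- m2$count * 5
  expect_identical(apa(m2, loops)$score, 1)   # scale invariance

  sim <- loop_sim(lambda = 5, seed = 43)
  ap <- apa(sim$maps[[1]], sim$truth$loops)
  expect_gt(ap$score, 1.5)

  set.seed(7)
  rnd <- tibble::tibble(chrom = "chrL",
                        start1 = sample(seq(5e5, 2e6, 1e4), 40),
                        start2 = 0)
  rnd$start2 <- rnd$start1 + sample(seq(4e5, 3e6, 1e4), 40, replace = TRUE)
  ap0 <- apa(loop_sim(with_loops = FALSE, seed = 44)$maps[[1]], rnd)
  expect_lt(abs(ap0$score - 1), 0.15)
})

test_that("inter-homolog ratios track the planted rate and profiles are uniform", {
  mk <- function(rho, seed) {
    simulate_hic(architecture_spec(sizes = chrom_sizes("c", 1e7), resolution = 1e5,
                                   gamma = 0, compartments = NULL, tads = NULL,
                                   allele_rho = rho, depth = 5e5), seed = seed)
  }
  g <- bin_grid(chrom_sizes("c", 1e7), 1e5)
  s0 <- mk(0, 51)
  r0 <- interhomolog_stats(s0$alleles, g)
  expect_equal(r0$ratios$ratio, 0)

  s1 <- mk(0.1, 52)
  bounds <- tibble::tibble(chrom = "c", start = seq(2e6, 8e6, 2e6))
  bounds$end <- bounds$start + 1e5
  r1 <- interhomolog_stats(s1$alleles, g, bounds)
  expect_equal(r1$ratios$ratio, 0.1 / 0.9,
               tolerance = 3 * sqrt(0.1 * 0.9 / 5e5) / (0.1 / 0.9))
  expect_gt(r1$uniformity_p, 0.001)
  expect_equal(nrow(r1$profile), 20)
})

test_that("the inter-homolog ratio estimator is unbiased across planted rates", {
  g <- bin_grid(chrom_sizes("c", 1e7), 1e5)
  for (rho in c(0.05, 0.2)) {
    est <- vapply(1:5, function(s) {
      sim <- simulate_hic(architecture_spec(sizes = chrom_sizes("c", 1e7),
                                            resolution = 1e5, gamma = 0,
                                            compartments = NULL, tads = NULL,
                                            allele_rho = rho, depth = 2e5),
                          seed = 60 + s)
      interhomolog_stats(sim$alleles, g)$ratios$ratio
    }, 0)
    truth <- rho / (1 - rho)
    expect_lt(abs(mean(est) - truth), 4 * stats::sd(est) / sqrt(5) + 1e-3)
  }
})
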