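test_that("COO loading parses, canonicalizes symmetry, and sums duplicates", {
  g <- toy_grid(4, 5e4)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t0\t50000\t4", "chr1\t50000\t50000\t7"), f)
  maps <- load_contacts(f, g)
  m <- maps$chr1
  expect_equal(nrow(m), 2)
  expect_equal(m$count[m$bin1 == 0 & m$bin2 == 1], 4)
  expect_equal(m$count[m$bin1 == 1 & m$bin2 == 1], 7)
  expect_equal(total_contacts(m), 11)

  writeLines("chr1\t50000\t0\t4", f)  # reversed coordinates
  m <- load_contacts(f, g)$chr1
  expect_equal(unname(unlist(m[1, c("bin1", "bin2", "count")])), c(0, 1, 4))

  writeLines(c("chr1\t0\t50000\t4", "chr1\t0\t50000\t4"), f)  # duplicate pixel
  m <- load_contacts(f, g)$chr1
  expect_equal(nrow(m), 1)
  expect_equal(m$count, 8)
})

test_that("COO loading rejects off-grid coordinates and unknown chromosomes", {
  g <- toy_grid(4, 5e4)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t0\t12345\t4", f)
  expect_error(load_contacts(f, g), "resolution")
  writeLines("chr9\t0\t50000\t4", f)
  expect_error(load_contacts(f, g), "unknown chromosome")
})

test_that("counts are conserved through write/load/pool round trips", {
  sim <- sim_tads(depth = 5e4, seed = 3)
  m <- sim$maps[[1]]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contacts(m, f)
  m2 <- load_contacts(f, map_grid(m))[[map_chrom(m)]]
  expect_equal(total_contacts(m2), total_contacts(m))
  pooled <- pool_contacts(m, m)
  expect_equal(total_contacts(pooled), 2 * total_contacts(m))
})

test_that("balancing leaves a doubly-stochastic matrix untouched and equalizes row sums", {
  # constant 3x3: already balanced; weights equal up to scale
  m <- toy_map(tibble::tibble(bin1 = c(0, 0, 0, 1, 1, 2),
                              bin2 = c(0, 1, 2, 1, 2, 2),
                              count = c(1, 1, 1, 1, 1, 1)), n_bins = 3)
  mb <- balance_kr(m)
  w <- attr(mb, "weights")
  expect_equal(w / w[1], rep(1, 3))

  # diagonally dominant 2x2: row sums equalized within tolerance
  m2 <- toy_map(tibble::tibble(bin1 = c(0, 0, 1), bin2 = c(0, 1, 1),
                               count = c(2, 1, 8)), n_bins = 2)
  m2b <- balance_kr(m2, tol = 1e-8, mask_frac = 0)
  bm <- as_matrix(m2b, "balanced")
  rs <- rowSums(bm)
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-7)
})

test_that("all-zero bins are masked and excluded from balancing", {
  m <- toy_map(tibble::tibble(bin1 = c(0, 0, 1), bin2 = c(0, 1, 1),
                              count = c(3, 2, 4)), n_bins = 3)  # bin 2 empty
  mb <- balance_kr(m)
  expect_true(masked_bins(mb)[3])
  expect_false(any(masked_bins(mb)[1:2]))
  expect_true(all(is.na(as_matrix(mb, "balanced")[3, ])))
})

test_that("balancing equalizes row sums on random positive matrices", {
  set.seed(42)
  for (n in c(50, 400)) {
    g <- bin_grid(chrom_sizes("c", n * 1e5), 1e5)
    px <- tidyr::expand_grid(bin1 = 0:(n - 1), bin2 = 0:(n - 1))
    px <- px[px$bin1 <= px$bin2, ]
    px$count <- stats::rexp(nrow(px)) + 0.1
    m <- balance_kr(contact_map(px, g, "c"), tol = 1e-8)
    rs <- rowSums(as_matrix(m, "balanced"))
    expect_lt(max(abs(rs / mean(rs) - 1)), 1e-7)
  }
})

test_that("O/E is 1 on diagonally-constant matrices and matches the toy oracle", {
  m <- constant_diag_map(10)
  oe <- oe_transform(m)
  expect_true(all(abs(oe$count - 1) < 1e-12))

  # 4-bin toy, first off-diagonal values (2, 4, 6): expected 4, O/E (0.5, 1, 1.5)
  m2 <- toy_map(tibble::tibble(bin1 = 0:2, bin2 = 1:3, count = c(2, 4, 6)))
  ed <- expected_by_distance(m2)
  expect_equal(ed$expected[ed$dist == 1], 4)
  oe2 <- oe_transform(m2)
  expect_equal(sort(oe2$count), c(0.5, 1, 1.5))
})

test_that("per-diagonal O/E mean is 1 on random Poisson maps", {
  set.seed(7)
  n <- 60
  g <- bin_grid(chrom_sizes("c", n * 1e5), 1e5)
  px <- tidyr::expand_grid(bin1 = 0:(n - 1), bin2 = 0:(n - 1))
  px <- px[px$bin1 <= px$bin2, ]
  px$count <- stats::rpois(nrow(px), 6) + 1
  m <- balance_kr(contact_map(px, g, "c"))
  oe <- oe_transform(m)
  d <- oe$bin2 - oe$bin1
  means <- tapply(oe$count, d, mean)
  expect_lt(max(abs(means - 1)), 1e-9)
})

test_that("downsampling is exact, reproducible, and hypergeometric", {
  m <- toy_map(tibble::tibble(bin1 = 0, bin2 = 1, count = 10), n_bins = 2)
  expect_equal(total_contacts(downsample_contacts(m, 10, seed = 1)), 10)  # identity
  d4 <- downsample_contacts(m, 4, seed = 1)
  expect_equal(d4$count, 4)
  expect_identical(downsample_contacts(m, 4, seed = 9)$count,
                   downsample_contacts(m, 4, seed = 9)$count)

  # two pixels of 50 each, target 50: pixel-1 count ~ Hypergeom(100, 50, 50)
  m2 <- toy_map(tibble::tibble(bin1 = c(0, 0), bin2 = c(1, 2), count = c(50, 50)),
                n_bins = 3)
  draws <- vapply(1:200, function(s) {
    d <- downsample_contacts(m2, 50, seed = s)
    sum(d$count[d$bin2 == 1])
  }, 0)
  expect_equal(mean(draws), 25, tolerance = 0.05)
  expect_true(all(vapply(1:20, function(s)
    total_contacts(downsample_contacts(m2, 37, seed = s)), 0) == 37))
})

test_that("downsampling beyond depth errors naming the sample", {
  m <- toy_map(tibble::tibble(bin1 = 0, bin2 = 1, count = 10), n_bins = 2)
  attr(m, "sample") <- "shallow_one"
  expect_error(downsample_contacts(m, 11), "shallow_one")
})

test_that("matrix PCC is 1 on identical and scaled maps, matches the direct formula, and is symmetric", {
  sim <- sim_tads(depth = 2e5, seed = 5)
  m <- sim$maps[[1]]
  expect_equal(matrix_pcc(m, m), 1)
  m2 <- m; m2$count <- 2 * m2$count
  expect_equal(matrix_pcc(m, m2), 1)

  a <- toy_map(tibble::tibble(bin1 = c(0, 0, 1, 1, 2), bin2 = c(1, 2, 2, 3, 3),
                              count = c(5, 3, 8, 2, 7)), n_bins = 4)
  b <- toy_map(tibble::tibble(bin1 = c(0, 0, 1, 1, 2), bin2 = c(1, 2, 2, 3, 3),
                              count = c(4, 4, 9, 1, 6)), n_bins = 4)
  expect_equal(matrix_pcc(a, b), stats::cor(c(5, 3, 8, 2, 7), c(4, 4, 9, 1, 6)))
  expect_equal(matrix_pcc(a, b), matrix_pcc(b, a))
})

test_that("PCC is undefined with fewer than 3 shared pixels", {
  a <- toy_map(tibble::tibble(bin1 = 0, bin2 = 1, count = 5), n_bins = 2)
  expect_warning(r <- matrix_pcc(a, a), "fewer than 3")
  expect_true(is.na(r))
})
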