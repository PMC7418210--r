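test_that("PC1 recovers planted checkerboard blocks and is null without them", {
  sim <- sim_comp(gamma = 1, depth = 1e6, seed = 21)
  m <- sim$maps[[1]]
  ov <- orientation_of(sim)
  prof <- pc1_profile(m, ov)
  truth_sign <- sim$truth$bins$sign
  agree <- mean((prof$pc1 > 0) == (truth_sign == "A"), na.rm = TRUE)
  expect_gte(agree, 0.95)

  sim0 <- sim_comp(gamma = 0, depth = 1e6, seed = 22)
  prof0 <- pc1_profile(sim0$maps[[1]], orientation_of(sim0))
  planted <- as.numeric(sim0$truth$bins$sign == "A")
  expect_lt(abs(stats::cor(prof0$pc1, planted, use = "complete.obs")), 0.3)
})

test_that("reversing the orientation track negates PC1 exactly", {
  sim <- sim_comp(gamma = 1, depth = 5e5, seed = 23)
  m <- sim$maps[[1]]
  ov <- orientation_of(sim)
  p1 <- pc1_profile(m, ov)
  p2 <- pc1_profile(m, max(ov) - ov)
  expect_equal(p2$pc1, -p1$pc1)
})

test_that("too few bins give an all-NA degenerate profile", {
  m <- constant_diag_map(8)
  prof <- pc1_profile(m, rep(1, 8), min_bins = 20)
  expect_true(all(is.na(prof$pc1)))
  expect_match(attr(prof, "degenerate"), "few")
})

test_that("compartment strength is 1 on a flat map and matches brute force on planted maps", {
  m <- constant_diag_map(60, res = 1e5)
  ref <- pc1_profile(m, seq_len(60))
  set.seed(2)
  ref$pc1 <- sample(60)      # scattered reference ranks so every class has >= 2 Mb pairs
  st <- compartment_strength(m, ref)
  expect_equal(st$strength, 1, tolerance = 1e-9, ignore_attr = TRUE)

  # dual route: brute-force AA/BB/AB means from the dense O/E matrix
  sim <- sim_comp(gamma = 1, depth = 1e6, seed = 24)
  mm <- sim$maps[[1]]
  prof <- pc1_profile(mm, orientation_of(sim))
  st2 <- compartment_strength(mm, prof)
  om <- oe_matrix(mm)
  pc1 <- prof$pc1
  ok <- which(!is.na(pc1))
  nt <- floor(length(ok) * 0.2)
  A <- ok[order(pc1[ok], decreasing = TRUE)][1:nt]
  B <- ok[order(pc1[ok])][1:nt]
  pair_mean <- function(s1, s2) {
    d <- abs(outer(s1, s2, "-")); v <- om[s1, s2]
    mean(v[d >= 20], na.rm = TRUE)
  }
  brute <- pair_mean(A, A) * pair_mean(B, B) / pair_mean(A, B)^2
  expect_equal(st2$strength, brute, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("permuted-reference strength is near 1", {
  sim <- sim_comp(gamma = 1, depth = 1e6, seed = 25)
  m <- sim$maps[[1]]
  prof <- pc1_profile(m, orientation_of(sim))
  set.seed(1)
  perm <- replicate(100, {
    pp <- prof
    pp$pc1 <- sample(pp$pc1)
    attr(compartment_strength(m, pp), "mean_strength")
  })
  expect_lt(abs(mean(perm) - 1), 0.05)
})

test_that("saddle is flat on a flat map and polarized on planted compartments", {
  m <- constant_diag_map(120, res = 1e5)
  ref <- pc1_profile(m, seq_len(120))
  ref$pc1 <- seq_len(120) - 60.5
  sd0 <- saddle(m, ref, n_groups = 10, corner = 2)
  expect_true(all(abs(sd0$matrix - 1) < 1e-9, na.rm = TRUE))
  expect_equal(sd0$corners$AA_over_AB, 1, tolerance = 1e-9)

  sim <- sim_comp(gamma = 1, depth = 1e6, seed = 26)
  prof <- pc1_profile(sim$maps[[1]], orientation_of(sim))
  sd1 <- saddle(sim$maps[[1]], prof)
  expect_gt(sd1$corners$AA_over_AB, 1.3)
  expect_gt(sd1$corners$BB_over_BA, 1.3)

  sim0 <- sim_comp(gamma = 0, depth = 1e6, seed = 27)
  prof0 <- pc1_profile(sim0$maps[[1]], orientation_of(sim0))
  # rank by the planted signs to probe the null map
  prof0$pc1 <- as.numeric(sim0$truth$bins$sign == "A") + stats::runif(nrow(prof0), 0, 1e-3)
  sd2 <- saddle(sim0$maps[[1]], prof0)
  expect_lt(abs(sd2$corners$AA_over_AB - 1), 0.1)
  expect_lt(abs(sd2$corners$BB_over_BA - 1), 0.1)
})

test_that("profile comparison identities hold, with and without homology", {
  sim <- sim_comp(gamma = 1, depth = 5e5, seed = 28)
  prof <- pc1_profile(sim$maps[[1]], orientation_of(sim))
  self <- compare_compartments(prof, prof)
  expect_equal(self$pcc, 1)
  expect_equal(self$concordance, 1)

  neg <- prof; neg$pc1 <- -neg$pc1
  neg$label <- ifelse(neg$label == "A", "B", "A")
  anti <- compare_compartments(prof, neg)
  expect_equal(anti$pcc, -1)
  expect_equal(anti$concordance, 0)

  g <- sim$truth$grid
  idh <- identity_homology(g)
  with_h <- compare_compartments(prof, prof, homology = idh)
  expect_equal(with_h$pcc, self$pcc)
  expect_equal(with_h$concordance, self$concordance)
  expect_equal(with_h$n_bins, self$n_bins)

  # 30% of bins dropped from the homology: comparison on the remainder only
  set.seed(5)
  keep <- sort(sample(nrow(idh), round(0.7 * nrow(idh))))
  part <- compare_compartments(prof, prof, homology = idh[keep, ])
  n_def <- sum(!is.na(prof$pc1[prof$bin %in% (idh$start[keep] / 1e5)]))
  expect_equal(part$n_bins, n_def)
  expect_equal(part$concordance, 1)
})

test_that("A-versus-B track test detects a planted shift and is null otherwise", {
  lab <- rep(c("A", "B"), each = 200)
  prof <- tibble::tibble(chrom = "c", bin = 0:399, start = (0:399) * 1e5,
                         end = (1:400) * 1e5,
                         pc1 = ifelse(lab == "A", 1, -1), label = lab)
  set.seed(6)
  null_track <- stats::rnorm(400)
  r0 <- track_ab_test(prof, null_track)
  expect_gt(r0$p_value, 0.05)
  shifted <- null_track + ifelse(lab == "A", 1, 0)
  expect_lt(track_ab_test(prof, shifted)$p_value, 0.01)

  prof_b <- prof; prof_b$label[prof_b$label == "B"] <- NA
  expect_true(is.na(track_ab_test(prof_b, null_track)$p_value))
})
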