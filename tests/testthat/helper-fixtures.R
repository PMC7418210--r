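# Shared in-code fixtures: tiny deterministic maps and small simulations.

toy_grid <- function(n_bins = 4, res = 5e4, chrom = "chr1") {
  bin_grid(chrom_sizes(chrom, n_bins * res), res)
}

# dense symmetric toy map from an upper-triangular pixel table
toy_map <- function(px, n_bins = 4, res = 5e4, chrom = "chr1") {
  contact_map(px, toy_grid(n_bins, res, chrom), chrom)
}

# map whose counts are constant on every diagonal (O/E identically 1)
constant_diag_map <- function(n_bins = 20, res = 5e4, value_by_d = NULL, chrom = "chr1") {
  g <- bin_grid(chrom_sizes(chrom, n_bins * res), res)
  px <- tidyr::expand_grid(bin1 = 0:(n_bins - 1), bin2 = 0:(n_bins - 1))
  px <- px[px$bin1 <= px$bin2, ]
  d <- px$bin2 - px$bin1
  px$count <- if (is.null(value_by_d)) 10 else value_by_d[d + 1]
  contact_map(px, g, chrom)
}

# small TAD simulation: one 15-Mb chromosome at 50-kb bins, sparse 1.5-Mb TADs
sim_tads <- function(beta = 2, depth = 1e6, seed = 11, sparse = TRUE) {
  sizes <- chrom_sizes("chrT", 1.5e7)
  tads <- if (sparse) {
    starts <- seq(0, 1.5e7 - 3e6, by = 3e6)
    tibble::tibble(chrom = "chrT", start = starts, end = starts + 1.5e6, beta = beta)
  } else 1.5e6
  simulate_hic(architecture_spec(sizes = sizes, resolution = 5e4, gamma = 0,
                                 compartments = NULL, tads = tads,
                                 tad_beta = beta, depth = depth), seed = seed)
}

# small compartment simulation: one 30-Mb chromosome at 100-kb bins
sim_comp <- function(gamma = 1, depth = 1e6, seed = 21, block = 5e6) {
  sizes <- chrom_sizes("chrC", 3e7)
  simulate_hic(architecture_spec(sizes = sizes, resolution = 1e5, gamma = gamma,
                                 compartments = block, tads = NULL, depth = depth),
               seed = seed)
}

orientation_of <- function(sim, chrom = NULL) {
  b <- sim$truth$bins
  if (!is.null(chrom)) b <- b[b$chrom == chrom, ]
  as.numeric(b$sign == "A")
}
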