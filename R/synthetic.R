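#' Architecture specification for the synthetic Hi-C generator
#'
#' Describes a planted chromatin architecture: power-law distance decay with
#' an optional short-range local-contact peak, checkerboard A/B compartments
#' of tunable strength (including >10 Mb superdomain blocks), TAD blocks with
#' tunable intra-TAD enrichment, focal loop peaks, finite sequencing depth,
#' and optional two-allele structure with a tunable inter-homolog contact
#' rate. Defaults describe the desk-scale genome used throughout the package:
#' two 60-Mb chromosomes at 100-kb bins, decay exponent 1, 6-Mb alternating
#' compartment blocks at strength 1, 1.2-Mb TADs, two million contacts.
#'
#' @param sizes Chromosome-sizes tibble (default two 60-Mb chromosomes).
#' @param resolution Bin size in bp (default 100 kb).
#' @param alpha Distance-decay exponent (P(s) ~ s^-alpha), > 0.
#' @param gamma Compartment strength: like-sign pixels enriched `1 + gamma`,
#'   unlike-sign depleted `1 / (1 + gamma)`.
#' @param compartments Named list (per chromosome) of tibbles with columns
#'   `length` (bp) and `sign` (`"A"`/`"B"`), tiling the chromosome; or a
#'   single block length in bp to tile alternating A/B blocks (default 6 Mb);
#'   or NULL for no compartments.
#' @param tads Tibble `chrom`, `start`, `end`, `beta` of non-overlapping TADs
#'   (intra-TAD pixels enriched `1 + beta`); a single TAD length in bp to
#'   tile TADs with `tad_beta`; or NULL.
#' @param tad_beta Intra-TAD enrichment used when `tads` is a length.
#' @param loops Tibble `chrom`, `start1`, `start2`, `lambda`, `orientation`
#'   (e.g. `"+-"`) of focal loop anchors (positions, one bin each), or NULL.
#' @param local_peak NULL or `list(center = <bp, < 20 kb>, weight >= 0,
#'   sd_log = <sd in log-distance>)` adding a short-range contact bump.
#' @param allele_rho NULL (single-allele) or inter-homolog contact rate in
#'   `[0, 1)`: each contact event is tagged maternal/paternal and re-routed
#'   between homologs with this probability.
#' @param depth Total number of contacts to draw.
#' @return An `architecture_spec` object.
#' @export
architecture_spec <- function(sizes = chrom_sizes(c("chrS1", "chrS2"), c(60e6, 60e6)),
                              resolution = 1e5,
                              alpha = 1,
                              gamma = 1,
                              compartments = 6e6,
                              tads = 1.2e6,
                              tad_beta = 1,
                              loops = NULL,
                              local_peak = NULL,
                              allele_rho = NULL,
                              depth = 2e6) {
  stopifnot(alpha > 0, gamma >= 0, depth > 0)
  if (!is.null(allele_rho)) stopifnot(allele_rho >= 0, allele_rho < 1)
  if (!is.null(local_peak)) {
    stopifnot(is.list(local_peak), local_peak$center < 2e4, local_peak$weight >= 0)
    if (is.null(local_peak$sd_log)) local_peak$sd_log <- 0.5
  }
  if (is.numeric(compartments) && length(compartments) == 1)
    compartments <- lapply(stats::setNames(sizes$length, sizes$chrom),
                           alternating_blocks, block = compartments)
  if (!is.null(compartments)) {
    for (ch in names(compartments)) {
      blk <- compartments[[ch]]
      if (abs(sum(blk$length) - sizes$length[match(ch, sizes$chrom)]) > 0)
        stop("compartment blocks must tile chromosome ", ch)
    }
  }
  if (is.numeric(tads) && length(tads) == 1)
    tads <- tile_tads(sizes, tads, tad_beta)
  if (!is.null(tads) && nrow(tads)) {
    for (d in split(tads, tads$chrom)) {
      d <- d[order(d$start), ]
      if (any(d$start[-1] < d$end[-nrow(d)])) stop("overlapping TADs in spec")
    }
  }
  structure(list(sizes = sizes, resolution = resolution, alpha = alpha,
                 gamma = gamma, compartments = compartments, tads = tads,
                 loops = loops, local_peak = local_peak,
                 allele_rho = allele_rho, depth = depth),
            class = "architecture_spec")
}

#' Alternating A/B compartment blocks tiling a chromosome
#' @param chrom_len Chromosome length (bp).
#' @param block Block length (bp); the final block absorbs the remainder.
#' @param first Sign of the first block.
#' @return Tibble with `length`, `sign`.
#' @export
alternating_blocks <- function(chrom_len, block, first = "A") {
  n <- max(1L, floor(chrom_len / block))
  len <- rep(block, n)
  len[n] <- chrom_len - block * (n - 1)
  signs <- rep(c(first, setdiff(c("A", "B"), first)), length.out = n)
  tibble::tibble(length = len, sign = signs)
}

#' Tile non-overlapping TADs along each chromosome
#' @param sizes Chromosome-sizes tibble.
#' @param tad_len TAD length (bp).
#' @param beta Intra-TAD enrichment.
#' @return Tibble `chrom`, `start`, `end`, `beta`.
#' @export
tile_tads <- function(sizes, tad_len, beta = 1) {
  purrr::pmap_dfr(sizes, function(chrom, length) {
    starts <- seq(0, length - tad_len, by = tad_len)
    tibble::tibble(chrom = chrom, start = starts,
                   end = pmin(starts + tad_len, length), beta = beta)
  })
}

spec_bin_signs <- function(spec, chrom) {
  g <- bin_grid(spec$sizes, spec$resolution)
  n <- grid_nbins(g, chrom)
  if (is.null(spec$compartments) || is.null(spec$compartments[[chrom]]))
    return(rep(NA_character_, n))
  blk <- spec$compartments[[chrom]]
  bounds <- cumsum(c(0, blk$length))
  mid <- ((seq_len(n) - 1) + 0.5) * spec$resolution
  blk$sign[findInterval(pmin(mid, sum(blk$length) - 1), bounds,
                        rightmost.closed = TRUE)]
}

#' Analytic contact probability matrices of a planted architecture
#'
#' Builds, per chromosome, the dense probability matrix
#' `p_ij ~ s^-alpha * C_ij * T_ij * L_ij * K_ij` where `C` is the
#' compartment checkerboard factor, `T` the intra-TAD factor, `L` the loop
#' factor and `K` the local-peak kernel (Gaussian in log distance), jointly
#' normalized so all upper-triangular probabilities sum to 1 across
#' chromosomes.
#'
#' @param spec An [architecture_spec()].
#' @return Named list of dense symmetric probability matrices; total
#'   upper-triangle mass 1.
#' @export
build_truth_probability <- function(spec) {
  g <- bin_grid(spec$sizes, spec$resolution)
  mats <- lapply(spec$sizes$chrom, function(ch) {
    n <- grid_nbins(g, ch)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    s <- pmax(d, 0.5) * spec$resolution
    p <- s^(-spec$alpha)
    if (!is.null(spec$local_peak)) {
      lp <- spec$local_peak
      p <- p * (1 + lp$weight * exp(-(log(s) - log(lp$center))^2 / (2 * lp$sd_log^2)))
    }
    fac <- matrix(1, n, n)
    sg <- spec_bin_signs(spec, ch)
    if (!all(is.na(sg))) {
      same <- outer(sg, sg, "==")
      fac[same & !is.na(same)] <- 1 + spec$gamma
      fac[!same & !is.na(same)] <- 1 / (1 + spec$gamma)
    }
    if (!is.null(spec$tads) && nrow(spec$tads)) {
      td <- spec$tads[spec$tads$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(td))) {
        i0 <- floor(td$start[k] / spec$resolution) + 1
        i1 <- ceiling(td$end[k] / spec$resolution)
        fac[i0:i1, i0:i1] <- fac[i0:i1, i0:i1] * (1 + td$beta[k])
      }
    }
    if (!is.null(spec$loops) && nrow(spec$loops)) {
      lp <- spec$loops[spec$loops$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(lp))) {
        i <- floor(lp$start1[k] / spec$resolution) + 1
        j <- floor(lp$start2[k] / spec$resolution) + 1
        fac[i, j] <- fac[i, j] * (1 + lp$lambda[k])
        fac[j, i] <- fac[i, j]
      }
    }
    # equalize the structure factor's marginals (Sinkhorn): planted
    # enrichments live on the O/E scale, not in per-bin coverage, matching
    # balanced real Hi-C maps; a pure-decay truth stays distance-stationary
    if (any(fac != 1)) {
      x <- rep(1, n)
      for (it in 1:200) {
        r <- as.vector(fac %*% x) * x
        if (max(abs(r / mean(r) - 1)) < 1e-10) break
        x <- x / sqrt(r)
      }
      fac <- fac * outer(x, x)
    }
    p * fac
  })
  names(mats) <- spec$sizes$chrom
  mass <- sum(vapply(mats, function(m) sum(m[upper.tri(m, diag = TRUE)]), 0))
  lapply(mats, function(m) m / mass)
}

#' Sample finite-depth contacts from a truth probability matrix
#'
#' Multinomial draw of `n` contact events over the upper triangles of the
#' probability matrices. In two-allele mode each event is tagged
#' maternal/paternal uniformly and re-routed to an inter-homolog pair at the
#' same bin coordinates with probability `rho`; the bin-level map is
#' unchanged by re-routing, so totals are conserved.
#'
#' @param truth Named list of probability matrices from
#'   [build_truth_probability()] (or a single matrix).
#' @param grid The matching [bin_grid()].
#' @param n Number of events to draw (> 0).
#' @param seed Integer seed.
#' @param rho NULL, or inter-homolog re-routing probability.
#' @param sample Sample label.
#' @return List with `maps` (named list of `contact_map`) and `alleles`
#'   (tibble `chrom`, `bin1`, `bin2`, `allele1`, `allele2`, `count`, or NULL).
#' @export
sample_contacts <- function(truth, grid, n, seed = 1L, rho = NULL,
                            sample = "synthetic") {
  if (is.matrix(truth)) truth <- stats::setNames(list(truth), grid$sizes$chrom[1])
  stopifnot(n >= 0)
  with_seed(seed, {
    probs <- lapply(truth, function(m) {
      ut <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
      list(idx = ut, p = m[ut])
    })
    pvec <- unlist(lapply(probs, `[[`, "p"))
    counts <- if (n > 0) as.vector(stats::rmultinom(1, n, pvec)) else rep(0L, length(pvec))
    off <- cumsum(c(0, vapply(probs, function(x) length(x$p), 0)))
    maps <- list(); alleles <- NULL
    for (k in seq_along(probs)) {
      ch <- names(truth)[k]
      cnt <- counts[(off[k] + 1):off[k + 1]]
      keep <- cnt > 0
      px <- tibble::tibble(bin1 = probs[[k]]$idx[keep, 2] - 1L,  # row<col upper tri: row=bin1
                           bin2 = probs[[k]]$idx[keep, 1] - 1L,
                           count = as.numeric(cnt[keep]))
      # upper.tri gives row < col; enforce bin1 <= bin2
      b1 <- pmin(px$bin1, px$bin2); b2 <- pmax(px$bin1, px$bin2)
      px$bin1 <- b1; px$bin2 <- b2
      maps[[ch]] <- contact_map(px, grid, ch, sample = sample)
      if (!is.null(rho)) {
        inter <- stats::rbinom(nrow(px), px$count, rho)
        intra <- px$count - inter
        intra_m <- stats::rbinom(nrow(px), intra, 0.5)
        al <- dplyr::bind_rows(
          tibble::tibble(chrom = ch, bin1 = px$bin1, bin2 = px$bin2,
                         allele1 = "maternal", allele2 = "maternal", count = intra_m),
          tibble::tibble(chrom = ch, bin1 = px$bin1, bin2 = px$bin2,
                         allele1 = "paternal", allele2 = "paternal", count = intra - intra_m),
          tibble::tibble(chrom = ch, bin1 = px$bin1, bin2 = px$bin2,
                         allele1 = "maternal", allele2 = "paternal", count = inter))
        alleles <- dplyr::bind_rows(alleles, al[al$count > 0, ])
      }
    }
    list(maps = maps, alleles = alleles)
  })
}

#' Simulate a synthetic Hi-C experiment with known ground truth
#'
#' One call builds the analytic truth for an [architecture_spec()], samples
#' finite-depth contacts, and returns the maps together with the realized
#' ground truth (per-bin compartment signs, TAD intervals, boundary
#' positions, loop pixels) for parameter-recovery testing.
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed.
#' @param sample Sample label.
#' @return List with `maps`, `alleles`, `truth` (list: `bins`, `tads`,
#'   `boundaries`, `loops`, `prob`, `spec`, `grid`).
#' @export
simulate_hic <- function(spec, seed = 1L, sample = "synthetic") {
  g <- bin_grid(spec$sizes, spec$resolution)
  prob <- build_truth_probability(spec)
  drawn <- sample_contacts(prob, g, spec$depth, seed = seed,
                           rho = spec$allele_rho, sample = sample)
  bins <- grid_bins(g)
  bins$sign <- unlist(lapply(spec$sizes$chrom, function(ch) spec_bin_signs(spec, ch)))
  boundaries <- NULL
  if (!is.null(spec$tads) && nrow(spec$tads)) {
    td <- spec$tads
    # interior TAD borders: shared edges of adjacent TADs plus isolated edges
    pos <- unique(dplyr::bind_rows(
      tibble::tibble(chrom = td$chrom, pos = td$start),
      tibble::tibble(chrom = td$chrom, pos = td$end)))
    pos <- pos[pos$pos > 0 & pos$pos < spec$sizes$length[match(pos$chrom, spec$sizes$chrom)], ]
    boundaries <- tibble::tibble(chrom = pos$chrom,
                                 start = pos$pos - spec$resolution / 2,
                                 end = pos$pos + spec$resolution / 2)
    boundaries <- dplyr::arrange(boundaries, .data$chrom, .data$start)
  }
  list(maps = drawn$maps, alleles = drawn$alleles,
       truth = list(bins = bins, tads = spec$tads, boundaries = boundaries,
                    loops = spec$loops, prob = prob, spec = spec, grid = g))
}

#' Synthetic cross-assembly homology map
#'
#' Stands in for a liftover chain between two assemblies: a mostly-identity
#' bin-to-bin correspondence with randomly dropped (unmappable) segments,
#' Gaussian coordinate jitter, and strand-flipped segments. The overlap
#' fraction of each mapped bin with its best-aligned destination bin is
#' recorded.
#'
#' @param grid Source [bin_grid()] (destination coordinates use the same
#'   sizes unless `dst_sizes` given).
#' @param unmappable_fraction Probability a source bin has no destination.
#' @param shift_sd SD (bp) of the coordinate jitter.
#' @param inversion_rate Probability a mapped bin is strand-flipped.
#' @param seed Integer seed.
#' @param dst_sizes Optional destination chromosome sizes.
#' @return A homology-map tibble: `chrom`, `start`, `end`, `dst_chrom`,
#'   `dst_start`, `dst_end`, `strand`, `overlap`.
#' @export
generate_homology_map <- function(grid, unmappable_fraction = 0, shift_sd = 0,
                                  inversion_rate = 0, seed = 1L,
                                  dst_sizes = NULL) {
  stopifnot(unmappable_fraction >= 0, unmappable_fraction <= 1,
            inversion_rate >= 0, inversion_rate <= 1, shift_sd >= 0)
  if (is.null(dst_sizes)) dst_sizes <- grid$sizes
  with_seed(seed, {
    bins <- grid_bins(grid)
    n <- nrow(bins)
    mapped <- stats::runif(n) >= unmappable_fraction
    shift <- if (shift_sd > 0) round(stats::rnorm(n, 0, shift_sd)) else rep(0, n)
    inv <- stats::runif(n) < inversion_rate
    res <- grid$resolution
    out <- tibble::tibble(
      chrom = bins$chrom, start = bins$start, end = bins$end,
      dst_chrom = bins$chrom,
      dst_start = bins$start + shift,
      dst_end = bins$end + shift,
      strand = ifelse(inv, "-", "+"),
      overlap = pmax(0, res - abs(shift)) / res)[mapped, ]
    lim <- dst_sizes$length[match(out$dst_chrom, dst_sizes$chrom)]
    out <- out[out$dst_start >= 0 & out$dst_end <= lim, ]
    out
  })
}

#' Identity homology map of a grid
#' @param grid A [bin_grid()].
#' @return Homology-map tibble mapping every bin to itself (overlap 1).
#' @export
identity_homology <- function(grid) {
  bins <- grid_bins(grid)
  tibble::tibble(chrom = bins$chrom, start = bins$start, end = bins$end,
                 dst_chrom = bins$chrom, dst_start = bins$start,
                 dst_end = bins$end, strand = "+", overlap = 1)
}

#' Map intervals through a homology map
#'
#' Each query interval is mapped via the source bins it overlaps; intervals
#' touching any unmapped bin are dropped. The destination interval is the
#' coordinate range of the mapped bins (a liftover-style conversion, so
#' jitter can widen it).
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (extra columns kept).
#' @param homology Homology-map tibble.
#' @return Mapped intervals with `dst_chrom`, `dst_start`, `dst_end` added;
#'   unmappable intervals dropped.
#' @export
apply_homology <- function(intervals, homology) {
  out <- purrr::pmap_dfr(intervals, function(chrom, start, end, ...) {
    h <- homology[homology$chrom == chrom & homology$start < end &
                    homology$end > start, , drop = FALSE]
    cov <- if (nrow(h)) sum(pmin(h$end, end) - pmax(h$start, start)) else 0
    if (cov < (end - start) || !nrow(h)) return(NULL)
    if (length(unique(h$dst_chrom)) > 1) return(NULL)
    tibble::tibble(chrom = chrom, start = start, end = end, ...,
                   dst_chrom = h$dst_chrom[1],
                   dst_start = min(h$dst_start) + max(0, start - min(h$start)),
                   dst_end = max(h$dst_end) - max(0, max(h$end) - end))
  })
  tibble::as_tibble(out)
}

#' Write a simulation to plain-text files
#'
#' Emits COO contacts, chrom.sizes, ground-truth BED files (compartment
#' signs, TADs, boundaries), BEDPE loops, allele contacts (TSV) and a JSON
#' manifest recording the spec parameters and seed.
#'
#' @param sim Result of [simulate_hic()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_contacts(sim$maps, file.path(dir, "contacts.coo.tsv"))
  utils::write.table(sim$truth$spec$sizes, file.path(dir, "chrom.sizes"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  b <- sim$truth$bins
  utils::write.table(b[!is.na(b$sign), c("chrom", "start", "end", "sign")],
                     file.path(dir, "compartments.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(sim$truth$tads))
    utils::write.table(sim$truth$tads[, c("chrom", "start", "end")],
                       file.path(dir, "tads.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(sim$truth$boundaries))
    utils::write.table(sim$truth$boundaries, file.path(dir, "boundaries.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(sim$truth$loops) && nrow(sim$truth$loops)) {
    lp <- sim$truth$loops; res <- sim$truth$spec$resolution
    utils::write.table(
      tibble::tibble(c1 = lp$chrom, s1 = lp$start1, e1 = lp$start1 + res,
                     c2 = lp$chrom, s2 = lp$start2, e2 = lp$start2 + res),
      file.path(dir, "loops.bedpe"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(sim$alleles))
    readr::write_tsv(sim$alleles, file.path(dir, "alleles.tsv"))
  sp <- sim$truth$spec
  manifest <- list(resolution = sp$resolution, alpha = sp$alpha,
                   gamma = sp$gamma, depth = sp$depth,
                   allele_rho = sp$allele_rho, seed = seed,
                   chromosomes = as.list(stats::setNames(sp$sizes$length, sp$sizes$chrom)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
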