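#' Distance-stratified significance calling of chromatin loops
#'
#' The expected contact probability at each bin separation is estimated
#' from the per-distance empirical mean count, smoothed by monotone
#' (decreasing in distance) isotonic regression; each tested pixel gets a
#' binomial p value for its observed count against that expectation, and
#' Benjamini-Hochberg q values are computed over all tested pixels
#' (unrecorded pixels enter with p = 1). Pixels with `q < q_max` at anchor
#' separations of at least `min_distance` are reported as loops.
#'
#' @param map A raw-count `contact_map`, typically at 10-kb bins.
#' @param q_max BH q-value cutoff (default 0.01).
#' @param min_distance Minimum anchor separation in bp (default 300 kb,
#'   avoiding distance-decay artifacts).
#' @return Loop tibble `chrom`, `start1`, `end1`, `start2`, `end2`,
#'   `distance`, `count`, `expected`, `p_value`, `q_value` (empty when the
#'   chromosome is shorter than `min_distance`).
#' @export
call_loops <- function(map, q_max = 0.01, min_distance = 3e5) {
  g <- map_grid(map); ch <- map_chrom(map)
  res <- g$resolution
  n <- grid_nbins(g, ch)
  dmin <- ceiling(min_distance / res)
  empty <- tibble::tibble(chrom = character(), start1 = numeric(), end1 = numeric(),
                          start2 = numeric(), end2 = numeric(), distance = numeric(),
                          count = numeric(), expected = numeric(),
                          p_value = numeric(), q_value = numeric())
  if (dmin >= n) return(empty)
  d <- map$bin2 - map$bin1
  dists <- 1:(n - 1)
  n_d <- n - dists
  sum_d <- rep(0, length(dists))
  t <- tapply(map$count[d > 0], d[d > 0], sum)
  sum_d[as.integer(names(t))] <- as.numeric(t)
  mu <- sum_d / n_d
  # monotone non-increasing fit of the decay (isotonic on the negated values)
  dec <- -stats::isoreg(dists, -mu)$yf
  dec[dec < 0] <- 0
  total <- sum(map$count[d > 0])
  tested <- d >= dmin
  m_tested <- sum(n_d[dists >= dmin])
  if (total == 0 || m_tested == 0) return(empty)
  p_pix <- dec[d[tested]] / total
  p_pix[p_pix <= 0] <- .Machine$double.xmin
  obs <- map$count[tested]
  pv <- stats::pbinom(obs - 1, size = total, prob = pmin(p_pix, 1), lower.tail = FALSE)
  # BH over all m_tested pixels; unrecorded pixels carry p = 1 and cannot
  # undercut recorded ones, so ranks of recorded pixels are their ranks here
  o <- order(pv)
  q <- rep(NA_real_, length(pv))
  q[o] <- rev(cummin(rev(pv[o] * m_tested / seq_along(pv))))
  q <- pmin(q, 1)
  keep <- q < q_max
  b1 <- map$bin1[tested][keep]; b2 <- map$bin2[tested][keep]
  tibble::tibble(chrom = ch, start1 = b1 * res, end1 = (b1 + 1) * res,
                 start2 = b2 * res, end2 = (b2 + 1) * res,
                 distance = (b2 - b1) * res,
                 count = obs[keep], expected = dec[d[tested]][keep] ,
                 p_value = pv[keep], q_value = q[keep])
}

anchor_motif_ok <- function(chrom, a_start, a_end, peaks, motifs, strand) {
  pk <- peaks[peaks$chrom == chrom &
                overlap_len(a_start, a_end, peaks$start, peaks$end) > 0, , drop = FALSE]
  if (!nrow(pk)) return(FALSE)
  mt <- motifs[motifs$chrom == chrom & motifs$strand == strand, , drop = FALSE]
  if (!nrow(mt)) return(FALSE)
  mid <- (mt$start + mt$end) / 2
  any(vapply(seq_len(nrow(pk)), function(k)
    any(mid >= pk$start[k] & mid < pk$end[k]), TRUE))
}

#' Filter loops to convergent-CTCF pairs
#'
#' Keeps loops whose upstream (smaller-coordinate) anchor overlaps a CTCF
#' peak containing a forward-strand motif and whose downstream anchor
#' overlaps a peak containing a reverse-strand motif — the convergent
#' orientation expected under loop extrusion.
#'
#' @param loops Loop tibble from [call_loops()].
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @param motifs Motif tibble (`chrom`, `start`, `end`, `strand`).
#' @return The convergent subset of `loops`.
#' @export
filter_convergent <- function(loops, peaks, motifs) {
  if (!nrow(loops)) return(loops)
  keep <- vapply(seq_len(nrow(loops)), function(r) {
    anchor_motif_ok(loops$chrom[r], loops$start1[r], loops$end1[r], peaks, motifs, "+") &&
      anchor_motif_ok(loops$chrom[r], loops$start2[r], loops$end2[r], peaks, motifs, "-")
  }, TRUE)
  loops[keep, , drop = FALSE]
}

#' Aggregate peak analysis (APA)
#'
#' O/E submatrices centered on loop pixels are averaged; the APA score is
#' the center value over the mean of the lower-left 3x3 corner block (the
#' short-distance background corner). Loops whose window leaves the matrix
#' are skipped.
#'
#' @param map A `contact_map` at the loop resolution (O/E computed if
#'   needed).
#' @param loops Loop tibble (anchors at single bins).
#' @param window Half-width of the window in bins (default 5).
#' @return List with `panel` (matrix, (2*window+1)^2) and `score`.
#' @export
apa <- function(map, loops, window = 5) {
  om <- oe_matrix(map)
  res <- map_grid(map)$resolution
  ch <- map_chrom(map)
  lp <- loops[loops$chrom == ch, , drop = FALSE]
  k <- 2 * window + 1
  sums <- matrix(0, k, k); cnts <- matrix(0, k, k)
  n <- nrow(om)
  for (r in seq_len(nrow(lp))) {
    i <- floor(lp$start1[r] / res) + 1
    j <- floor(lp$start2[r] / res) + 1
    if (i - window < 1 || j + window > n || i + window > n || j - window < 1) next
    sub <- om[(i - window):(i + window), (j - window):(j + window)]
    has <- !is.na(sub)
    sums[has] <- sums[has] + sub[has]
    cnts <- cnts + has
  }
  panel <- ifelse(cnts > 0, sums / cnts, NA)
  corner <- panel[(k - 2):k, 1:3]
  list(panel = panel,
       score = panel[window + 1, window + 1] / mean(corner, na.rm = TRUE))
}

#' Map loops across assemblies and count conserved loops
#'
#' Both anchors are converted through the homology map; loops whose mapped
#' anchors exceed `max_anchor` (default 15 kb) are discarded; a loop is
#' conserved when some target loop's anchors overlap both mapped anchors by
#' at least 1 bp (anchor 1 with anchor 1, anchor 2 with anchor 2).
#'
#' @param loops Source loop tibble.
#' @param homology Homology-map tibble.
#' @param target_loops Destination loop tibble.
#' @param max_anchor Mapped-anchor width cutoff in bp (default 15 kb).
#' @return List: `matched` (conserved mapped loops), `n_source`,
#'   `n_mapped`, `n_discarded`, `n_conserved`, `conserved_fraction`.
#' @export
map_homologous_loops <- function(loops, homology, target_loops, max_anchor = 1.5e4) {
  n_src <- nrow(loops)
  if (!n_src) return(list(matched = loops, n_source = 0, n_mapped = 0,
                          n_discarded = 0, n_conserved = 0,
                          conserved_fraction = NA_real_))
  a1 <- apply_homology(tibble::tibble(chrom = loops$chrom, start = loops$start1,
                                      end = loops$end1, id = seq_len(n_src)), homology)
  a2 <- apply_homology(tibble::tibble(chrom = loops$chrom, start = loops$start2,
                                      end = loops$end2, id = seq_len(n_src)), homology)
  j <- dplyr::inner_join(a1, a2, by = "id", suffix = c("_1", "_2"))
  wide <- (j$dst_end_1 - j$dst_start_1) > max_anchor |
    (j$dst_end_2 - j$dst_start_2) > max_anchor
  n_disc <- sum(wide)
  j <- j[!wide, , drop = FALSE]
  conserved <- vapply(seq_len(nrow(j)), function(r) {
    t <- target_loops[target_loops$chrom == j$dst_chrom_1[r], , drop = FALSE]
    if (!nrow(t)) return(FALSE)
    any(overlap_len(j$dst_start_1[r], j$dst_end_1[r], t$start1, t$end1) > 0 &
          overlap_len(j$dst_start_2[r], j$dst_end_2[r], t$start2, t$end2) > 0)
  }, TRUE)
  list(matched = j[conserved, , drop = FALSE], n_source = n_src,
       n_mapped = nrow(j) + n_disc, n_discarded = n_disc,
       n_conserved = sum(conserved),
       conserved_fraction = if (nrow(j)) mean(conserved) else NA_real_)
}

#' Inter-homolog contact statistics
#'
#' From allele-tagged contacts: the per-chromosome ratio of inter-homolog
#' to intra-allele contacts, the aggregate inter-homolog contact density
#' around TAD boundaries, and a chi-square test of uniformity of that
#' density across offset bins (inter-homolog contacts are expected to be
#' evenly distributed rather than concentrated at boundaries).
#'
#' @param alleles Allele-contact tibble (`chrom`, `bin1`, `bin2`, `allele1`,
#'   `allele2`, `count`).
#' @param grid The [bin_grid()] the bins refer to.
#' @param boundaries Boundary tibble on the same assembly (may be empty).
#' @param flank Profile flank in bp (default 1 Mb).
#' @param bin Profile bin width in bp (default 100 kb).
#' @return List: `ratios` tibble (`chrom`, `inter`, `intra`, `ratio`),
#'   `profile` tibble (`offset`, `count`), `uniformity_p`.
#' @export
interhomolog_stats <- function(alleles, grid, boundaries = NULL,
                               flank = 1e6, bin = 1e5) {
  inter <- alleles$allele1 != alleles$allele2
  ratios <- purrr::map_dfr(split(alleles, alleles$chrom), function(al) {
    it <- sum(al$count[al$allele1 != al$allele2])
    ia <- sum(al$count[al$allele1 == al$allele2])
    tibble::tibble(chrom = al$chrom[1], inter = it, intra = ia,
                   ratio = if (ia > 0) it / ia else NA_real_)
  })
  profile <- NULL; unif_p <- NA_real_
  if (!is.null(boundaries) && nrow(boundaries)) {
    res <- grid$resolution
    ev <- alleles[inter & alleles$count > 0, , drop = FALSE]
    # one locus per interaction (the midpoint of its two, mostly adjacent,
    # bins) so profile counts are independent and the test holds its level
    loci <- tibble::tibble(chrom = ev$chrom,
                           pos = (ev$bin1 + ev$bin2 + 1) / 2 * res,
                           count = ev$count)
    nb <- round(flank / bin)
    centers <- seq(-nb * bin + bin / 2, nb * bin - bin / 2, by = bin)
    tot <- rep(0, length(centers))
    for (r in seq_len(nrow(boundaries))) {
      c0 <- (boundaries$start[r] + boundaries$end[r]) / 2
      l <- loci[loci$chrom == boundaries$chrom[r], , drop = FALSE]
      gi <- floor((l$pos - c0 + nb * bin) / bin) + 1   # half-open offset bins
      ok <- gi >= 1 & gi <= length(centers)
      if (any(ok)) tot <- tot + vapply(seq_along(centers), function(g)
        sum(l$count[ok][gi[ok] == g]), 0)
    }
    profile <- tibble::tibble(offset = centers, count = tot)
    if (sum(tot) > 0)
      unif_p <- suppressWarnings(stats::chisq.test(tot)$p.value)
  }
  list(ratios = ratios, profile = profile, uniformity_p = unif_p)
}
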