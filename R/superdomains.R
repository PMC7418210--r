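#' Segment a compartment profile into compartment domains
#'
#' Maximal runs of consecutive same-sign PC1 bins are merged into domains.
#' Runs interrupted by NA bins are bridged when the NA gap does not exceed
#' `gap_tolerance` bins (unmappable gaps inside a sign run); longer NA gaps
#' break the run.
#'
#' @param profile A `compartment_profile` (may span several chromosomes).
#' @param gap_tolerance Maximum NA-gap length (bins) bridged inside a run.
#' @return Domain tibble `chrom`, `start`, `end`, `sign` (sorted,
#'   non-overlapping), empty for all-NA chromosomes.
#' @export
call_compartment_domains <- function(profile, gap_tolerance = 2) {
  purrr::map_dfr(split(profile, profile$chrom), function(p) {
    p <- p[order(p$bin), ]
    lab <- p$label
    if (all(is.na(lab))) return(NULL)
    # bridge NA gaps <= tolerance flanked by the same sign
    r <- rle(is.na(lab))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (r$values[k] && r$lengths[k] <= gap_tolerance &&
          k > 1 && k < length(r$values)) {
        left <- lab[starts[k] - 1]; right <- lab[ends[k] + 1]
        if (!is.na(left) && identical(left, right))
          lab[starts[k]:ends[k]] <- left
      }
    }
    rr <- rle(lab)
    e <- cumsum(rr$lengths); s <- e - rr$lengths + 1
    keep <- !is.na(rr$values)
    tibble::tibble(chrom = p$chrom[1],
                   start = p$start[s[keep]],
                   end = p$end[e[keep]],
                   sign = rr$values[keep])
  })
}

#' Superdomain genome coverage
#'
#' Fraction of the analyzed genome (total compartment-domain length) covered
#' by domains strictly longer than `threshold` (default 10 Mb), genome-wide
#' and per chromosome.
#'
#' @param domains Domain tibble from [call_compartment_domains()].
#' @param threshold Superdomain length threshold in bp (strict, default 10 Mb).
#' @return List with `coverage` (genome-wide fraction) and `per_chrom`
#'   tibble (`chrom`, `analyzed_bp`, `superdomain_bp`, `coverage`).
#' @export
superdomain_coverage <- function(domains, threshold = 1e7) {
  len <- domains$end - domains$start
  per <- dplyr::summarise(
    dplyr::group_by(domains, .data$chrom),
    analyzed_bp = sum(.data$end - .data$start),
    superdomain_bp = sum((.data$end - .data$start)[(.data$end - .data$start) > threshold]),
    .groups = "drop")
  per$coverage <- ifelse(per$analyzed_bp > 0, per$superdomain_bp / per$analyzed_bp, NA)
  list(coverage = sum(len[len > threshold]) / sum(len), per_chrom = per)
}

#' Cumulative genome-coverage curve of relative domain sizes
#'
#' For each sample, domains at least `min_size` long are expressed as a
#' relative size (domain length / chromosome length) and the cumulative
#' fraction of the analyzed genome they cover is accumulated in ascending
#' size order; mean domain sizes are compared pairwise with a Welch t test.
#'
#' @param domains_by_sample Named list of domain tibbles.
#' @param sizes Chromosome-sizes tibble (for relative sizes).
#' @param min_size Minimum domain length included (default 1 Mb).
#' @return List with `curves` (tibble `sample`, `relative_size`,
#'   `cumulative_coverage`) and `tests` (tibble `sample_a`, `sample_b`,
#'   `mean_a`, `mean_b`, `p_value`; p NA when a sample has < 2 domains).
#' @export
domain_size_curve <- function(domains_by_sample, sizes, min_size = 1e6) {
  curves <- purrr::imap_dfr(domains_by_sample, function(d, nm) {
    d <- d[(d$end - d$start) >= min_size, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    len <- d$end - d$start
    rel <- len / sizes$length[match(d$chrom, sizes$chrom)]
    o <- order(rel)
    tibble::tibble(sample = nm, relative_size = rel[o],
                   cumulative_coverage = cumsum(len[o]) / sum(sizes$length))
  })
  nms <- names(domains_by_sample)
  tests <- NULL
  if (length(nms) >= 2) {
    pairs <- utils::combn(nms, 2)
    tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      la <- with(domains_by_sample[[pairs[1, k]]], end - start)
      lb <- with(domains_by_sample[[pairs[2, k]]], end - start)
      la <- la[la >= min_size]; lb <- lb[lb >= min_size]
      p <- if (length(la) == length(lb) && isTRUE(all.equal(sort(la), sort(lb)))) {
        if (length(la) >= 2) 1 else NA_real_          # identical sets
      } else if (length(la) >= 2 && length(lb) >= 2 &&
                 (stats::sd(la) > 0 || stats::sd(lb) > 0)) {
        stats::t.test(la, lb)$p.value
      } else NA_real_
      tibble::tibble(sample_a = pairs[1, k], sample_b = pairs[2, k],
                     mean_a = mean(la), mean_b = mean(lb), p_value = p)
    })
  }
  list(curves = curves, tests = tests)
}
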