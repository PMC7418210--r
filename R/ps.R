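#' Contact-frequency decay curve p(s)
#'
#' Fraction of raw contacts as a function of genomic separation, aggregated
#' into log-spaced distance bins. The diagonal (distance 0) is excluded.
#'
#' @param maps A raw-count `contact_map` or list of maps (one sample).
#' @param n_log_bins Number of log-spaced bins (default 50) between one bin
#'   width and the longest chromosome.
#' @param breaks Optional explicit distance breaks in bp (overrides
#'   `n_log_bins`); use `"distance"` for one bin per bin-distance.
#' @return Tibble with `lower`, `upper` (bp), `fraction`, `sample`;
#'   fractions sum to 1 over populated bins.
#' @export
ps_curve <- function(maps, n_log_bins = 50, breaks = NULL) {
  if (inherits(maps, "contact_map")) maps <- list(maps)
  res <- map_grid(maps[[1]])$resolution
  smax <- max(vapply(maps, function(m) grid_chrom_length(map_grid(m), map_chrom(m)), 0))
  d <- unlist(lapply(maps, function(m) (m$bin2 - m$bin1) * res))
  cnt <- unlist(lapply(maps, function(m) m$count))
  keep <- d > 0
  d <- d[keep]; cnt <- cnt[keep]
  if (identical(breaks, "distance")) {
    breaks <- seq(res / 2, smax + res, by = res)
  } else if (is.null(breaks)) {
    breaks <- exp(seq(log(res * 0.999), log(smax + res), length.out = n_log_bins + 1))
  }
  grp <- findInterval(d, breaks, rightmost.closed = TRUE)
  ok <- grp >= 1 & grp <= length(breaks) - 1
  tot <- tapply(cnt[ok], grp[ok], sum)
  out <- tibble::tibble(lower = breaks[-length(breaks)], upper = breaks[-1],
                        fraction = 0)
  out$fraction[as.integer(names(tot))] <- as.numeric(tot) / sum(tot)
  out$sample <- map_sample(maps[[1]])
  out
}

#' Jensen-Shannon divergence between two p(s) curves
#'
#' `JSD(P, Q) = KL(P || M)/2 + KL(Q || M)/2` with `M = (P + Q)/2`, natural
#' logarithm, so the value lies in `[0, ln 2]` and is symmetric. Curves must
#' share identical distance binning; they are renormalized over the bins
#' where either has mass.
#'
#' @param a,b p(s) tibbles from [ps_curve()].
#' @return The divergence (nats).
#' @export
ps_jsd <- function(a, b) {
  if (nrow(a) != nrow(b) || !isTRUE(all.equal(a$lower, b$lower)) ||
      !isTRUE(all.equal(a$upper, b$upper)))
    stop("p(s) curves have mismatched distance bins")
  keep <- a$fraction > 0 | b$fraction > 0
  p <- a$fraction[keep] / sum(a$fraction[keep])
  q <- b$fraction[keep] / sum(b$fraction[keep])
  m <- (p + q) / 2
  kl <- function(x, y) sum(ifelse(x > 0, x * log(x / y), 0))
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Contact-class fractions per chromosome
#'
#' Fractions of local (< 20 kb), intermediate (> 50 kb and < 1 Mb) and
#' distal (> 10 Mb) contacts among all off-diagonal contacts, the
#' distance-class summary used to contrast decay curves between samples.
#'
#' @param maps Named list of raw `contact_map`s (one sample, per chromosome).
#' @param classes Named list of `c(lower, upper)` bp windows.
#' @return Tibble `chrom`, `class`, `fraction`, `sample`.
#' @export
contact_classes <- function(maps,
                            classes = list(local = c(0, 2e4),
                                           intermediate = c(5e4, 1e6),
                                           distal = c(1e7, Inf))) {
  if (inherits(maps, "contact_map")) maps <- list(maps)
  purrr::map_dfr(maps, function(m) {
    res <- map_grid(m)$resolution
    d <- (m$bin2 - m$bin1) * res
    keep <- d > 0
    tot <- sum(m$count[keep])
    purrr::imap_dfr(classes, function(w, nm) {
      tibble::tibble(chrom = map_chrom(m), class = nm,
                     fraction = if (tot > 0)
                       sum(m$count[keep & d > w[1] & d < w[2]]) / tot else NA_real_,
                     sample = map_sample(m))
    })
  })
}

#' Compare contact-class fractions between two samples
#'
#' Per-chromosome class fractions for both samples plus a two-sided
#' Wilcoxon rank-sum test across chromosomes for each class. Samples should
#' be depth-matched first (see [downsample_contacts()]).
#'
#' @param a,b Named lists of per-chromosome raw `contact_map`s.
#' @param classes Distance classes as in [contact_classes()].
#' @return List with `fractions` (long tibble) and `tests` (tibble `class`,
#'   `p_value`, `n_chrom`; p is NA with fewer than 2 chromosomes).
#' @export
contact_class_compare <- function(a, b, classes = list(local = c(0, 2e4),
                                                       intermediate = c(5e4, 1e6),
                                                       distal = c(1e7, Inf))) {
  fra <- contact_classes(a, classes); fra$which <- "a"
  frb <- contact_classes(b, classes); frb$which <- "b"
  fr <- dplyr::bind_rows(fra, frb)
  tests <- purrr::map_dfr(names(classes), function(cl) {
    xa <- fr$fraction[fr$class == cl & fr$which == "a"]
    xb <- fr$fraction[fr$class == cl & fr$which == "b"]
    p <- if (length(xa) >= 2 && length(xb) >= 2 &&
             (length(unique(c(xa, xb))) > 1))
      suppressWarnings(stats::wilcox.test(xa, xb)$p.value) else NA_real_
    if (!is.na(p) && isTRUE(all.equal(xa, xb))) p <- 1
    tibble::tibble(class = cl, p_value = p, n_chrom = length(xa))
  })
  list(fractions = fr, tests = tests)
}
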