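#' Matrix balancing of a contact map
#'
#' Computes per-bin weights `w` so that the balanced matrix
#' `W[i,j] = w_i * w_j * count[i,j]` has equal row sums over unmasked bins
#' (the Knight-Ruiz fixed point), by symmetric Sinkhorn-Knopp iteration.
#' Bins whose raw marginal falls below `mask_frac` of the chromosome median
#' marginal are masked first and excluded from balancing and from every
#' downstream statistic. If the iteration has not converged after `max_iter`
#' sweeps the map falls back to vanilla square-root-of-coverage weights and
#' carries a `balance_fallback` attribute.
#'
#' Raw counts are retained; use [pixel_values()] with `value = "balanced"`.
#'
#' @param map A raw-count `contact_map`.
#' @param tol Maximum relative deviation of unmasked row sums at convergence.
#' @param max_iter Maximum number of sweeps.
#' @param mask_frac Low-coverage mask threshold as a fraction of the median
#'   marginal (default 0.05).
#' @return The map with balancing weights attached.
#' @export
balance_kr <- function(map, tol = 1e-6, max_iter = 200, mask_frac = 0.05) {
  n <- grid_nbins(map_grid(map), map_chrom(map))
  m <- as_matrix(map, value = "count", mask_na = FALSE)
  marg <- rowSums(m)
  med <- stats::median(marg[marg > 0])
  mask <- marg <= 0
  if (!is.na(med)) mask <- mask | marg < mask_frac * med
  keep <- which(!mask)
  w <- rep(NA_real_, n)
  if (length(keep) == 0) {
    attr(map, "weights") <- w
    return(map)
  }
  k <- m[keep, keep, drop = FALSE]
  x <- rep(1, length(keep))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- as.vector(k %*% x) * x
    dev <- max(abs(r / mean(r) - 1))
    if (dev <= tol) { converged <- TRUE; break }
    x <- x / sqrt(r)
  }
  if (!converged) {
    x <- 1 / sqrt(rowSums(k))            # vanilla sqrt-coverage fallback
    attr(map, "balance_fallback") <- TRUE
  }
  # scale so the mean balanced row sum is 1 (scale choice is arbitrary)
  r <- as.vector(k %*% x) * x
  x <- x / sqrt(mean(r))
  w[keep] <- x
  attr(map, "weights") <- w
  map
}

#' Expected contacts by genomic distance
#'
#' Mean balanced contact value over all unmasked pixels at each bin
#' separation, counting unrecorded (zero) pixels.
#'
#' @param map A balanced `contact_map`.
#' @param value Scale passed to [pixel_values()].
#' @return Tibble with `dist` (bins), `n_pixels`, `expected`.
#' @export
expected_by_distance <- function(map, value = "auto") {
  n <- grid_nbins(map_grid(map), map_chrom(map))
  msk <- masked_bins(map)
  v <- pixel_values(map, value)
  d <- map$bin2 - map$bin1
  ok <- !msk[map$bin1 + 1] & !msk[map$bin2 + 1] & !is.na(v)
  sums <- tapply(v[ok], d[ok], sum)
  # number of unmasked pixels per diagonal, zeros included
  keep <- which(!msk) - 1L
  npix <- vapply(0:(n - 1), function(dd) {
    i <- keep[keep + dd <= n - 1]
    sum((i + dd) %in% keep)
  }, 0)
  out <- tibble::tibble(dist = 0:(n - 1), n_pixels = npix, expected = NA_real_)
  got <- as.integer(names(sums))
  out$expected[out$dist %in% got] <- as.numeric(sums)[match(out$dist[out$dist %in% got], got)] /
    npix[out$dist %in% got]
  out$expected[out$n_pixels > 0 & is.na(out$expected)] <- 0
  out
}

#' Observed/expected transform
#'
#' Divides each balanced pixel value by the mean balanced value at the same
#' genomic separation, so the mean O/E along every populated diagonal is 1.
#' Diagonals whose pixels are all masked stay undefined (no division by
#' zero occurs).
#'
#' @param map A balanced `contact_map`.
#' @return A `contact_map` whose `count` column holds O/E values
#'   (`oe` attribute set).
#' @export
oe_transform <- function(map) {
  if (is_oe(map)) return(map)
  v <- pixel_values(map, "auto")
  exp_d <- expected_by_distance(map)
  d <- map$bin2 - map$bin1
  e <- exp_d$expected[match(d, exp_d$dist)]
  oe <- ifelse(!is.na(e) & e > 0, v / e, NA_real_)
  keep <- !is.na(oe)
  new_contact_map(tibble::tibble(bin1 = map$bin1[keep], bin2 = map$bin2[keep],
                                 count = oe[keep]),
                  map_grid(map), map_chrom(map), sample = map_sample(map),
                  weights = map_weights(map), oe = TRUE)
}

#' Dense O/E matrix of a map
#'
#' Convenience wrapper: balances if needed, applies [oe_transform()], and
#' returns the dense symmetric O/E matrix with unrecorded pixels at their
#' true O/E of 0 and masked bins NA.
#'
#' @param map A `contact_map` (raw or balanced).
#' @return Dense symmetric matrix.
#' @export
oe_matrix <- function(map) {
  if (!is_balanced(map)) map <- balance_kr(map)
  om <- if (is_oe(map)) map else oe_transform(map)
  as_matrix(om, value = "oe")
}
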