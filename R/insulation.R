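#' Insulation score along the matrix diagonal
#'
#' Crane-style sliding square: for each bin i the mean balanced signal in
#' the `window` x `window` square spanning bins (i-w ... i-1) x (i+1 ... i+w)
#' is computed; the score is `log2(square mean / chromosome mean of square
#' means)`, so it is centered on the chromosome mean and invariant to global
#' count scaling. Bins where the square does not fit inside the chromosome,
#' or where over half of the square is masked, are NA.
#'
#' @param map A `contact_map` (balanced if available; raw maps are balanced
#'   first). Typically at 50-kb bins.
#' @param window Square side length in bp (default 500 kb).
#' @return An insulation track tibble (`chrom`, `start`, `end`, `value`)
#'   with `window` and `sample` attributes.
#' @export
insulation_score <- function(map, window = 5e5) {
  if (!is_balanced(map)) map <- balance_kr(map)
  g <- map_grid(map); ch <- map_chrom(map)
  res <- g$resolution
  w <- max(1L, round(window / res))
  m <- as_matrix(map, value = "balanced")
  n <- nrow(m)
  sq <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    block <- m[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
    if (mean(is.na(block)) > 0.5) next
    sq[i] <- mean(block, na.rm = TRUE)
  }
  mu <- mean(sq[sq > 0], na.rm = TRUE)
  is <- ifelse(!is.na(sq) & sq > 0 & !is.na(mu) & mu > 0, log2(sq / mu), NA_real_)
  out <- bin_track(g, stats::setNames(list(is), ch))
  out <- out[out$chrom == ch, ]
  attr(out, "window") <- window
  attr(out, "sample") <- map_sample(map)
  out
}

track_by_chrom <- function(track) split(track, track$chrom)

#' Call TAD boundaries from an insulation track
#'
#' Boundaries are local insulation minima whose strength — the mean rise of
#' the score towards its flanking maxima within `delta_span` — reaches
#' `min_strength`. Minima closer than 2 bins are resolved by keeping the
#' deeper one (ties keep the leftmost). The TAD set is the intervals between
#' consecutive boundaries (chromosome ends included), at least 2 bins long.
#'
#' @param track Insulation track from [insulation_score()] (may span
#'   several chromosomes when row-bound).
#' @param delta_span Flank span in bp over which the rise is measured
#'   (default 100 kb).
#' @param min_strength Minimum boundary strength in log2 units (default 0.1).
#' @return List with `boundaries` (tibble `chrom`, `start`, `end`,
#'   `strength`; 1-bin intervals) and `tads` (tibble `chrom`, `start`,
#'   `end`).
#' @export
call_tad_boundaries <- function(track, delta_span = 1e5, min_strength = 0.1) {
  res <- track$end[1] - track$start[1]
  d <- max(2L, round(delta_span / res))
  per <- purrr::map(track_by_chrom(track), function(t) {
    t <- t[order(t$start), ]
    v <- t$value
    n <- length(v)
    cand <- integer(0); str <- numeric(0)
    for (i in seq_len(n)) {
      if (i == 1 || i == n || is.na(v[i]) || is.na(v[i - 1]) || is.na(v[i + 1])) next
      if (v[i] > v[i - 1] || v[i] > v[i + 1]) next            # not a local minimum
      if (v[i - 1] == v[i] && v[i + 1] == v[i]) next          # flat plateau interior
      li <- max(1, i - d); ri <- min(n, i + d)
      lmax <- suppressWarnings(max(v[li:max(li, i - 1)], na.rm = TRUE))
      rmax <- suppressWarnings(max(v[min(ri, i + 1):ri], na.rm = TRUE))
      if (!is.finite(lmax) || !is.finite(rmax)) next
      s <- mean(c(lmax, rmax)) - v[i]
      if (s >= min_strength) { cand <- c(cand, i); str <- c(str, s) }
    }
    # resolve minima within 2 bins: deeper wins, ties leftmost
    if (length(cand) > 1) {
      keep <- rep(TRUE, length(cand))
      for (k in seq_len(length(cand) - 1)) {
        if (!keep[k]) next
        k2 <- k + 1
        while (k2 <= length(cand) && keep[k2] && cand[k2] - cand[k] <= 1) {
          if (v[cand[k2]] < v[cand[k]]) { keep[k] <- FALSE; break } else keep[k2] <- FALSE
          k2 <- k2 + 1
        }
      }
      cand <- cand[keep]; str <- str[keep]
    }
    list(boundaries = tibble::tibble(chrom = t$chrom[1],
                                     start = t$start[cand],
                                     end = t$end[cand], strength = str),
         chrom_len = max(t$end))
  })
  boundaries <- purrr::map_dfr(per, "boundaries")
  tads <- purrr::map_dfr(per, function(x) {
    b <- x$boundaries
    if (!nrow(b)) return(NULL)
    mids <- (b$start + b$end) / 2
    edges <- c(0, mids, x$chrom_len)
    tibble::tibble(chrom = b$chrom[1],
                   start = edges[-length(edges)], end = edges[-1])
  })
  if (nrow(tads)) tads <- tads[(tads$end - tads$start) >= 2 * res, ]
  list(boundaries = boundaries, tads = tads)
}

#' Aggregate insulation profile around reference boundaries
#'
#' Mean insulation score at each offset within `flank` of reference
#' boundary centers. The dip statistic is the mean score at the boundary
#' bin itself; to compare dips across samples, depth-match maps first.
#'
#' @param track Insulation track.
#' @param boundaries Reference boundary tibble (`chrom`, `start`, `end`).
#' @param flank Flank in bp on each side (default 625 kb).
#' @return Tibble `offset` (bp), `mean_is`, `n`; the dip is in attribute
#'   `dip` (and equals `mean_is` at offset 0).
#' @export
aggregate_boundary_is <- function(track, boundaries, flank = 6.25e5) {
  res <- track$end[1] - track$start[1]
  f <- round(flank / res)
  offs <- -f:f
  acc <- matrix(NA_real_, nrow(boundaries), length(offs))
  byc <- track_by_chrom(track)
  for (r in seq_len(nrow(boundaries))) {
    t <- byc[[boundaries$chrom[r]]]
    if (is.null(t)) next
    t <- t[order(t$start), ]
    c0 <- floor((boundaries$start[r] + boundaries$end[r]) / 2 / res) + 1
    idx <- c0 + offs
    ok <- idx >= 1 & idx <= nrow(t)
    acc[r, ok] <- t$value[idx[ok]]
  }
  out <- tibble::tibble(offset = offs * res,
                        mean_is = colMeans(acc, na.rm = TRUE),
                        n = colSums(!is.na(acc)))
  attr(out, "dip") <- out$mean_is[offs == 0]
  out
}

#' Aggregate TAD O/E panel and scalar TAD strength
#'
#' Each reference TAD, extended by half its length on both sides, is
#' rescaled onto a fixed grid (default 90 x 90: flank / TAD / flank thirds by
#' nearest-bin sampling) of O/E values and averaged over TADs. The scalar
#' signal is `W / (W + C)` where W is the mean O/E of the central TAD block
#' and C the mean of the two diagonal flank-corner blocks (left flank x left
#' flank and right flank x right flank, the distance-matched background):
#' 0.5 means no enrichment, values above 0.5 mark intra-TAD enrichment.
#'
#' @param map A `contact_map` (O/E is computed if needed).
#' @param tads Reference TAD tibble (`chrom`, `start`, `end`); TADs shorter
#'   than 4 bins or whose extended window leaves the chromosome are skipped.
#' @param panel_size Grid size, a multiple of 3 (default 90).
#' @return List with `panel` (matrix) and `signal` (scalar in (0, 1)).
#' @export
aggregate_tad_signal <- function(map, tads, panel_size = 90) {
  stopifnot(panel_size %% 3 == 0)
  om <- oe_matrix(map)
  res <- map_grid(map)$resolution
  ch <- map_chrom(map)
  td <- tads[tads$chrom == ch, , drop = FALSE]
  n <- nrow(om)
  sums <- matrix(0, panel_size, panel_size)
  cnts <- matrix(0, panel_size, panel_size)
  for (k in seq_len(nrow(td))) {
    i0 <- floor(td$start[k] / res) + 1
    i1 <- ceiling(td$end[k] / res)
    L <- i1 - i0 + 1
    if (L < 4) next
    fl <- floor(L / 2)
    a <- i0 - fl; b <- i1 + fl
    if (a < 1 || b > n) next
    span <- b - a + 1
    src <- a + floor((seq_len(panel_size) - 0.5) / panel_size * span)
    sub <- om[src, src]
    has <- !is.na(sub)
    sums[has] <- sums[has] + sub[has]
    cnts <- cnts + has
  }
  panel <- ifelse(cnts > 0, sums / cnts, NA)
  third <- panel_size / 3
  mid <- (third + 1):(2 * third)
  W <- mean(panel[mid, mid], na.rm = TRUE)
  hi <- (2 * third + 1):panel_size
  C <- mean(c(panel[1:third, 1:third], panel[hi, hi]), na.rm = TRUE)
  list(panel = panel, signal = W / (W + C))
}

overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

# TAD id of each interval: the TAD covering >= theta of the interval length
interval_tad_id <- function(intervals, tads, theta) {
  ids <- rep(NA_integer_, nrow(intervals))
  tads$.id <- seq_len(nrow(tads))
  for (ch in unique(intervals$chrom)) {
    ti <- tads[tads$chrom == ch, , drop = FALSE]
    qi <- which(intervals$chrom == ch)
    if (!nrow(ti) || !length(qi)) next
    ti <- ti[order(ti$start), ]
    mid <- (intervals$start[qi] + intervals$end[qi]) / 2
    k <- findInterval(mid, ti$start)
    for (off in c(0, 1)) {          # TAD containing the midpoint, then its right neighbor
      kk <- k + off
      ok <- kk >= 1 & kk <= nrow(ti)
      if (!any(ok)) next
      ov <- rep(0, length(qi))
      ov[ok] <- overlap_len(intervals$start[qi][ok], intervals$end[qi][ok],
                            ti$start[kk[ok]], ti$end[kk[ok]])
      hit <- ok & ov >= theta * (intervals$end[qi] - intervals$start[qi]) & is.na(ids[qi])
      ids[qi][hit] <- ti$.id[kk[hit]]
    }
  }
  ids
}

#' Randomly reposition TADs preserving sizes and count
#'
#' Per chromosome, the TAD length multiset is kept and TADs are placed
#' uniformly at random without overlap (stick-breaking over the free gap),
#' the shuffled-control construction used by the conservation statistics.
#'
#' @param tads TAD tibble.
#' @param sizes Chromosome-sizes tibble.
#' @return Shuffled TAD tibble.
#' @export
shuffle_tads <- function(tads, sizes) {
  purrr::map_dfr(split(tads, tads$chrom), function(td) {
    len <- sample(td$end - td$start)
    clen <- sizes$length[match(td$chrom[1], sizes$chrom)]
    free <- clen - sum(len)
    if (free < 0) stop("TADs exceed chromosome length")
    gaps <- diff(c(0, sort(stats::runif(nrow(td))), 1)) * free
    starts <- cumsum(gaps[-length(gaps)] + c(0, len[-length(len)]))
    tibble::tibble(chrom = td$chrom[1], start = round(starts),
                   end = round(starts) + len)
  })
}

#' Intra-TAD bin-pair conservation between two TAD sets
#'
#' Chromosomes are tiled at `resolution`; a bin belongs to a TAD when at
#' least `theta` of its length overlaps that TAD. For every intra-TAD bin
#' pair of `a` whose two bins map through the homology (identity when NULL),
#' the pair is conserved when both mapped bins fall inside one TAD of `b`.
#' The null repositions `b`'s TADs per chromosome preserving sizes and
#' count (`n_shuffles` times); the p value is a two-sided rank-sum test of
#' per-TAD conservation against the pooled shuffled per-TAD values.
#'
#' @param a,b TAD tibbles (`chrom`, `start`, `end`).
#' @param sizes Chromosome-sizes tibble of the source assembly.
#' @param homology Homology-map tibble at `resolution` bins, or NULL for
#'   identity.
#' @param resolution Bin size in bp (default 100 kb).
#' @param theta Bin-membership overlap threshold (default 0.6).
#' @param n_shuffles Number of shuffled controls (default 20).
#' @param seed Integer seed for the shuffles.
#' @return List: `conservation` (overall fraction), `per_tad` tibble,
#'   `shuffled` (per-shuffle overall fractions), `p_value`.
#' @export
tad_conservation <- function(a, b, sizes, homology = NULL, resolution = 1e5,
                             theta = 0.6, n_shuffles = 20, seed = 1L) {
  g <- bin_grid(sizes, resolution)
  bins <- grid_bins(g)
  if (is.null(homology)) homology <- identity_homology(g)
  a_id <- interval_tad_id(bins, a, theta)
  # destination interval of each source bin (NA when unmapped)
  h <- dplyr::left_join(bins, homology, by = c("chrom", "start", "end"))
  mapped <- !is.na(h$dst_start)
  by_tad <- split(which(mapped & !is.na(a_id)), a_id[mapped & !is.na(a_id)])
  pairs <- purrr::imap_dfr(by_tad, function(ix, tad) {
    if (length(ix) < 2) return(NULL)
    cmb <- utils::combn(ix, 2)
    tibble::tibble(tad = as.integer(tad), i = cmb[1, ], j = cmb[2, ])
  })
  if (!nrow(pairs)) stop("no mappable intra-TAD bin pairs")
  dst <- tibble::tibble(chrom = h$dst_chrom, start = h$dst_start, end = h$dst_end)
  score <- function(btads) {
    ok <- !is.na(dst$start)
    b_id <- rep(NA_integer_, nrow(dst))
    b_id[ok] <- interval_tad_id(dst[ok, ], btads, theta)
    conserved <- !is.na(b_id[pairs$i]) & b_id[pairs$i] == b_id[pairs$j]
    conserved[is.na(conserved)] <- FALSE
    per <- tapply(conserved, pairs$tad, mean)
    list(overall = mean(conserved),
         per_tad = tibble::tibble(tad = as.integer(names(per)),
                                  conservation = as.numeric(per)))
  }
  real <- score(b)
  shuffled <- NULL; sh_overall <- numeric(0); sh_per <- numeric(0)
  if (n_shuffles > 0) {
    with_seed(seed, {
      for (s in seq_len(n_shuffles)) {
        sc <- score(shuffle_tads(b, sizes))
        sh_overall[s] <- sc$overall
        sh_per <- c(sh_per, sc$per_tad$conservation)
      }
    })
  }
  p <- if (length(sh_per) && length(unique(c(real$per_tad$conservation, sh_per))) > 1)
    suppressWarnings(stats::wilcox.test(real$per_tad$conservation, sh_per)$p.value)
  else NA_real_
  list(conservation = real$overall, per_tad = real$per_tad,
       shuffled = sh_overall, p_value = p)
}

#' Cross-assembly TAD-boundary conservation
#'
#' Boundaries of `a` are mapped through the homology; mapped intervals
#' longer than `max_width` (default 50 kb) are discarded; a mapped boundary
#' is shared when it overlaps any boundary of `b` by at least 1 bp. The
#' control is an equal number of random destination loci with matched
#' widths; a Fisher exact test compares shared counts.
#'
#' @param a Source boundary tibble.
#' @param b Destination boundary tibble.
#' @param homology Homology-map tibble.
#' @param dst_sizes Destination chromosome-sizes tibble (for random loci).
#' @param max_width Mapped-boundary width cutoff in bp (default 50 kb).
#' @param n_random Random control loci per boundary (default 1).
#' @param seed Integer seed.
#' @return Tibble `shared_fraction`, `random_fraction`, `p_value`,
#'   `n_mapped`, `n_discarded`.
#' @export
boundary_conservation <- function(a, b, homology, dst_sizes,
                                  max_width = 5e4, n_random = 1, seed = 1L) {
  mp <- apply_homology(a[, c("chrom", "start", "end")], homology)
  wid <- mp$dst_end - mp$dst_start
  disc <- sum(wid > max_width)
  mp <- mp[wid <= max_width, , drop = FALSE]
  if (!nrow(mp)) return(tibble::tibble(shared_fraction = NA, random_fraction = NA,
                                       p_value = NA, n_mapped = 0, n_discarded = disc))
  hits_any <- function(q) {
    vapply(seq_len(nrow(q)), function(r) {
      bb <- b[b$chrom == q$chrom[r], , drop = FALSE]
      any(overlap_len(q$start[r], q$end[r], bb$start, bb$end) > 0)
    }, TRUE)
  }
  shared <- hits_any(tibble::tibble(chrom = mp$dst_chrom, start = mp$dst_start,
                                    end = mp$dst_end))
  rnd <- with_seed(seed, {
    w <- rep(mp$dst_end - mp$dst_start, n_random)
    ch <- sample(dst_sizes$chrom, length(w), replace = TRUE,
                 prob = dst_sizes$length / sum(dst_sizes$length))
    len <- dst_sizes$length[match(ch, dst_sizes$chrom)]
    s <- floor(stats::runif(length(w)) * (len - w))
    tibble::tibble(chrom = ch, start = s, end = s + w)
  })
  rshared <- hits_any(rnd)
  tab <- matrix(c(sum(shared), sum(!shared), sum(rshared), sum(!rshared)), 2)
  p <- stats::fisher.test(tab)$p.value
  tibble::tibble(shared_fraction = mean(shared), random_fraction = mean(rshared),
                 p_value = p, n_mapped = nrow(mp), n_discarded = disc)
}

#' Feature profile around TAD boundaries
#'
#' Average number of features (CTCF peaks, motifs, gene TSS) per boundary
#' in offset bins around boundary centers; stranded features (motifs) are
#' profiled separately by orientation, the convergence diagnostic at
#' boundaries.
#'
#' @param boundaries Boundary tibble.
#' @param features Tibble `chrom`, `start`, `end` and optional `strand`
#'   (`"+"`/`"-"`); features are counted by midpoint position.
#' @param flank Flank in bp (default 200 kb; use 100 kb with 10-kb bins for
#'   the ten-bin motif profile).
#' @param bin Offset bin width in bp (default 10 kb).
#' @return Tibble `offset` (bin center, bp), `strand`, `mean_count`.
#' @export
boundary_context_profile <- function(boundaries, features, flank = 2e5, bin = 1e4) {
  nb <- max(1L, round(flank / bin))
  centers <- seq(-nb * bin + bin / 2, nb * bin - bin / 2, by = bin)
  strands <- if ("strand" %in% names(features)) sort(unique(features$strand)) else "all"
  if (!nrow(boundaries))
    return(tibble::tibble(offset = rep(centers, length(strands)),
                          strand = rep(strands, each = length(centers)),
                          mean_count = 0))
  purrr::map_dfr(strands, function(st) {
    f <- if (identical(st, "all")) features else features[features$strand == st, ]
    fmid <- (f$start + f$end) / 2
    counts <- matrix(0, nrow(boundaries), length(centers))
    for (r in seq_len(nrow(boundaries))) {
      c0 <- (boundaries$start[r] + boundaries$end[r]) / 2
      rel <- fmid[f$chrom == boundaries$chrom[r]] - c0
      gi <- floor((rel + nb * bin) / bin) + 1          # half-open offset bins
      gi <- gi[gi >= 1 & gi <= length(centers)]
      if (length(gi)) counts[r, ] <- tabulate(gi, nbins = length(centers))
    }
    tibble::tibble(offset = centers, strand = st, mean_count = colMeans(counts))
  })
}

#' Boundaries with significantly different insulation between conditions
#'
#' Replicate insulation tracks are averaged per condition; the per-bin
#' between-condition difference at each boundary is z-scored against the
#' genome-wide distribution of differences at non-boundary bins, tested
#' two-sided, and Benjamini-Hochberg adjusted. With a single replicate per
#' condition the same pooled-null z test applies (a warning notes the
#' degenerate design).
#'
#' @param boundaries Reference boundary tibble.
#' @param tracks_a,tracks_b Lists of insulation tracks (replicates), on
#'   equal-depth maps.
#' @param alpha Two-sided BH-adjusted significance level (default 0.05).
#' @return The boundaries with `delta_is`, `z`, `p_value`, `q_value`,
#'   `significant` columns.
#' @export
differential_boundaries <- function(boundaries, tracks_a, tracks_b, alpha = 0.05) {
  if (is.data.frame(tracks_a)) tracks_a <- list(tracks_a)
  if (is.data.frame(tracks_b)) tracks_b <- list(tracks_b)
  if (length(tracks_a) < 2 || length(tracks_b) < 2)
    warning("single-replicate condition: pooled-null z test on one track pair")
  avg <- function(tr) {
    m <- dplyr::bind_rows(tr)
    dplyr::summarise(dplyr::group_by(m, .data$chrom, .data$start, .data$end),
                     value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  }
  ta <- avg(tracks_a); tb <- avg(tracks_b)
  j <- dplyr::inner_join(ta, tb, by = c("chrom", "start", "end"),
                         suffix = c("_a", "_b"))
  j$delta <- j$value_b - j$value_a
  res <- j$end[1] - j$start[1]
  bnd_key <- paste(boundaries$chrom,
                   floor((boundaries$start + boundaries$end) / 2 / res))
  j_key <- paste(j$chrom, floor(j$start / res))
  at_bnd <- j_key %in% bnd_key
  null_d <- j$delta[!at_bnd & !is.na(j$delta)]
  mu <- mean(null_d); sdv <- stats::sd(null_d)
  d_b <- j$delta[match(bnd_key, j_key)]
  z <- (d_b - mu) / sdv
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::p.adjust(p, method = "BH")
  out <- boundaries
  out$delta_is <- d_b; out$z <- z; out$p_value <- p; out$q_value <- q
  out$significant <- !is.na(q) & q < alpha
  out
}
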