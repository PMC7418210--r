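#' Contact map construction
#'
#' A contact map is a tibble of upper-triangular pixels (`bin1 <= bin2`,
#' 0-based bin indices within one chromosome) with a raw `count` column,
#' carrying its [bin_grid()], chromosome, balancing weights and sample label
#' as attributes. Symmetry is by construction: only `bin1 <= bin2` is stored.
#'
#' @param pixels Data frame with columns `bin1`, `bin2`, `count`.
#' @param grid A [bin_grid()].
#' @param chrom Chromosome name (must exist in `grid`).
#' @param sample Sample label.
#' @return A `contact_map` tibble.
#' @export
contact_map <- function(pixels, grid, chrom, sample = "sample") {
  stopifnot(inherits(grid, "bin_grid"),
            all(c("bin1", "bin2", "count") %in% names(pixels)))
  n <- grid_nbins(grid, chrom)
  b1 <- pmin(pixels$bin1, pixels$bin2)
  b2 <- pmax(pixels$bin1, pixels$bin2)
  if (length(b1) && (min(b1) < 0 || max(b2) >= n))
    stop("bin index outside chromosome ", chrom)
  if (any(pixels$count < 0)) stop("negative counts")
  px <- tibble::tibble(bin1 = as.integer(b1), bin2 = as.integer(b2),
                       count = as.numeric(pixels$count))
  px <- dplyr::summarise(dplyr::group_by(px, .data$bin1, .data$bin2),
                         count = sum(.data$count), .groups = "drop")
  px <- dplyr::arrange(px[px$count > 0, ], .data$bin1, .data$bin2)
  new_contact_map(px, grid = grid, chrom = chrom, sample = sample)
}

new_contact_map <- function(px, grid, chrom, sample = "sample",
                            weights = NULL, oe = FALSE) {
  out <- tibble::new_tibble(px, nrow = nrow(px), class = "contact_map")
  attr(out, "grid") <- grid
  attr(out, "chrom") <- chrom
  attr(out, "sample") <- sample
  attr(out, "weights") <- weights
  attr(out, "oe") <- oe
  out
}

map_grid   <- function(map) attr(map, "grid")
map_chrom  <- function(map) attr(map, "chrom")
map_sample <- function(map) attr(map, "sample")
map_weights <- function(map) attr(map, "weights")
is_balanced <- function(map) !is.null(attr(map, "weights"))
is_oe <- function(map) isTRUE(attr(map, "oe"))

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s | %s | %d pixels, total raw count %s%s%s\n",
              map_sample(x), map_chrom(x), nrow(x),
              format(sum(x$count), big.mark = ","),
              if (is_balanced(x)) " | balanced" else "",
              if (is_oe(x)) " | O/E" else ""))
  NextMethod()
}

#' Total raw contact count of a map
#' @param map A `contact_map`.
#' @return Numeric scalar.
#' @export
total_contacts <- function(map) sum(map$count)

#' Masked-bin indicator of a balanced map
#' @param map A `contact_map`.
#' @return Logical vector over bins (TRUE = masked), all-FALSE if unbalanced.
#' @export
masked_bins <- function(map) {
  n <- grid_nbins(map_grid(map), map_chrom(map))
  w <- map_weights(map)
  if (is.null(w)) rep(FALSE, n) else is.na(w)
}

#' Pixel values on a chosen scale
#'
#' Raw counts, balanced values (`count * w_i * w_j`) or the stored O/E
#' values. `"auto"` picks the most processed scale available.
#'
#' @param map A `contact_map`.
#' @param value One of `"auto"`, `"count"`, `"balanced"`, `"oe"`.
#' @return Numeric vector aligned with the pixel rows (NA on masked bins).
#' @export
pixel_values <- function(map, value = c("auto", "count", "balanced", "oe")) {
  value <- match.arg(value)
  if (value == "auto") value <- if (is_oe(map)) "oe" else if (is_balanced(map)) "balanced" else "count"
  if (value == "count" && is_oe(map)) stop("O/E map no longer carries raw counts on this scale")
  if (value == "oe") {
    if (!is_oe(map)) stop("map has no O/E values; run oe_transform() first")
    return(map$count)
  }
  if (value == "count") return(map$count)
  if (!is_balanced(map)) stop("map is not balanced; run balance_kr() first")
  w <- map_weights(map)
  map$count * w[map$bin1 + 1L] * w[map$bin2 + 1L]
}

#' Dense symmetric matrix of a contact map
#'
#' @param map A `contact_map`.
#' @param value Scale passed to [pixel_values()].
#' @param mask_na Set masked rows/columns to NA.
#' @return An n x n symmetric matrix (unrecorded pixels are 0).
#' @export
as_matrix <- function(map, value = "auto", mask_na = TRUE) {
  n <- grid_nbins(map_grid(map), map_chrom(map))
  v <- pixel_values(map, value)
  m <- matrix(0, n, n)
  i <- map$bin1 + 1L; j <- map$bin2 + 1L
  m[cbind(i, j)] <- v
  m[cbind(j, i)] <- v
  if (mask_na) {
    msk <- masked_bins(map)
    m[msk, ] <- NA_real_
    m[, msk] <- NA_real_
  }
  m
}

#' Load contact maps from COO text
#'
#' Reads tab-delimited sparse contacts. Two layouts are accepted:
#' 4 columns `chrom  bin1_start  bin2_start  count` (intra-chromosomal), or
#' 5 columns `chrom1  start1  chrom2  start2  count`, in which case
#' inter-chromosomal rows are routed to a `trans` attribute on the returned
#' list rather than into any per-chromosome map. Coordinates must be
#' multiples of the grid resolution and chromosomes known to the grid;
#' duplicate pixels are summed and counts are conserved.
#'
#' @param path Path to the COO text file.
#' @param grid A [bin_grid()].
#' @param sample Sample label attached to each map.
#' @return Named list of `contact_map` (one per chromosome present), with a
#'   `trans` attribute (tibble) when inter-chromosomal rows occur.
#' @export
load_contacts <- function(path, grid, sample = basename(path)) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) == 4) {
    names(raw) <- c("chrom1", "start1", "start2", "count")
    raw$chrom2 <- raw$chrom1
  } else if (ncol(raw) == 5) {
    names(raw) <- c("chrom1", "start1", "chrom2", "start2", "count")
  } else stop("COO file must have 4 or 5 columns")
  known <- grid$sizes$chrom
  bad <- setdiff(unique(c(raw$chrom1, raw$chrom2)), known)
  if (length(bad)) stop("unknown chromosome(s) in COO file: ", paste(bad, collapse = ", "))
  res <- grid$resolution
  if (any(raw$start1 %% res != 0) || any(raw$start2 %% res != 0))
    stop("coordinates are not multiples of the grid resolution (", res, " bp)")
  cis <- raw[raw$chrom1 == raw$chrom2, , drop = FALSE]
  trans <- raw[raw$chrom1 != raw$chrom2, , drop = FALSE]
  maps <- lapply(split(cis, cis$chrom1), function(d) {
    contact_map(tibble::tibble(bin1 = d$start1 %/% res, bin2 = d$start2 %/% res,
                               count = d$count),
                grid, d$chrom1[1], sample = sample)
  })
  maps <- maps[intersect(known, names(maps))]
  if (nrow(trans)) attr(maps, "trans") <- tibble::as_tibble(trans)
  maps
}

#' Write a contact map (or list of maps) as COO text
#' @param maps A `contact_map` or named list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(maps, path) {
  if (inherits(maps, "contact_map")) maps <- list(maps)
  rows <- purrr::map_dfr(maps, function(m) {
    res <- map_grid(m)$resolution
    tibble::tibble(chrom = map_chrom(m), start1 = m$bin1 * res,
                   start2 = m$bin2 * res, count = m$count)
  })
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pool replicate maps by pixel-wise summation of raw counts
#' @param ... `contact_map`s on the same grid and chromosome.
#' @param sample Label of the pooled map.
#' @return A pooled `contact_map` with raw counts.
#' @export
pool_contacts <- function(..., sample = "pooled") {
  maps <- list(...)
  if (length(maps) == 1 && is.list(maps[[1]]) && !inherits(maps[[1]], "contact_map"))
    maps <- maps[[1]]
  stopifnot(length(maps) >= 1)
  g <- map_grid(maps[[1]]); ch <- map_chrom(maps[[1]])
  for (m in maps) stopifnot(same_grid(map_grid(m), g), identical(map_chrom(m), ch))
  px <- dplyr::bind_rows(lapply(maps, function(m) m[, c("bin1", "bin2", "count")]))
  contact_map(px, g, ch, sample = sample)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

downsample_one <- function(map, target_pairs) {
  total <- sum(map$count)
  if (target_pairs > total)
    stop(sprintf("downsample target %s exceeds available pairs (%s) in sample '%s'",
                 format(target_pairs, big.mark = ","), format(total, big.mark = ","),
                 map_sample(map)))
  if (target_pairs == total) return(map)
  cum <- cumsum(map$count)
  idx <- sample.int(total, target_pairs)            # events without replacement
  pick <- findInterval(idx - 0.5, c(0, cum))        # pixel owning each event
  cnt <- tabulate(pick, nbins = nrow(map))
  keep <- cnt > 0
  new_contact_map(tibble::tibble(bin1 = map$bin1[keep], bin2 = map$bin2[keep],
                                 count = as.numeric(cnt[keep])),
                  map_grid(map), map_chrom(map), sample = map_sample(map))
}

#' Depth-match samples by random downsampling of contact events
#'
#' Draws exactly `target_pairs` contact events without replacement from the
#' multiset of recorded events (multivariate hypergeometric across pixels),
#' reproducibly for a given seed. Pass a single map, a per-chromosome list,
#' or a list of such lists (one per sample).
#'
#' @param maps A `contact_map`, a list of maps, or a list of lists of maps.
#'   For a per-chromosome list, `target_pairs` applies to the summed depth and
#'   events are drawn jointly across chromosomes.
#' @param target_pairs Number of events to keep.
#' @param seed Integer seed.
#' @return Object of the same shape with downsampled counts.
#' @export
downsample_contacts <- function(maps, target_pairs, seed = 1L) {
  with_seed(seed, {
    if (inherits(maps, "contact_map")) return(downsample_one(maps, target_pairs))
    if (all(vapply(maps, inherits, TRUE, "contact_map"))) {
      totals <- vapply(maps, total_contacts, 0)
      total <- sum(totals)
      if (target_pairs > total)
        stop(sprintf("downsample target exceeds available pairs (%s) in sample '%s'",
                     format(total, big.mark = ","), map_sample(maps[[1]])))
      # joint hypergeometric split of the target across chromosomes
      alloc <- numeric(length(maps)); remaining <- total; left <- target_pairs
      for (k in seq_along(maps)) {
        alloc[k] <- if (k == length(maps)) left else
          stats::rhyper(1, totals[k], remaining - totals[k], left)
        remaining <- remaining - totals[k]; left <- left - alloc[k]
      }
      out <- purrr::map2(maps, alloc, downsample_one)
      names(out) <- names(maps)
      return(out)
    }
    lapply(maps, function(s) downsample_contacts(s, target_pairs, seed = stats::runif(1, 1, 2^30)))
  })
}

#' Pearson correlation between two contact maps
#'
#' Correlation over the union of nonzero, unmasked pixels within a maximum
#' genomic separation, the replicate-reproducibility statistic for stratified
#' contact matrices.
#'
#' @param a,b `contact_map`s on the same grid and chromosome.
#' @param max_distance Maximum separation in bp (default 5 Mb).
#' @param value Scale passed to [pixel_values()] (default `"auto"`, resolved
#'   per map).
#' @return Pearson correlation (NA with a warning if fewer than 3 pixels).
#' @export
matrix_pcc <- function(a, b, max_distance = 5e6, value = "auto") {
  stopifnot(same_grid(map_grid(a), map_grid(b)),
            identical(map_chrom(a), map_chrom(b)))
  res <- map_grid(a)$resolution
  dmax <- floor(max_distance / res)
  da <- tibble::tibble(bin1 = a$bin1, bin2 = a$bin2, va = pixel_values(a, value))
  db <- tibble::tibble(bin1 = b$bin1, bin2 = b$bin2, vb = pixel_values(b, value))
  j <- dplyr::full_join(da, db, by = c("bin1", "bin2"))
  j$va[is.na(j$va)] <- 0; j$vb[is.na(j$vb)] <- 0
  bad <- masked_bins(a) | masked_bins(b)
  ok <- (j$bin2 - j$bin1) <= dmax & !bad[j$bin1 + 1] & !bad[j$bin2 + 1] &
    !is.na(j$va) & !is.na(j$vb)
  va <- j$va[ok]; vb <- j$vb[ok]
  if (length(va) < 3) { warning("fewer than 3 shared pixels; PCC undefined"); return(NA_real_) }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}
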