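#' Build a per-bin track
#'
#' A track is a bedGraph-like tibble (`chrom`, `start`, `end`, `value`) on a
#' bin grid; it carries PC1 values, insulation scores, gene density or ChIP
#' enrichment.
#'
#' @param grid A [bin_grid()].
#' @param values Named list (per chromosome) of per-bin numeric vectors, or a
#'   single vector when the grid has one chromosome.
#' @return A track tibble.
#' @export
bin_track <- function(grid, values) {
  if (!is.list(values)) values <- stats::setNames(list(values), grid$sizes$chrom[1])
  purrr::imap_dfr(values, function(v, ch) {
    b <- grid_bins(grid, ch)
    stopifnot(length(v) == nrow(b))
    tibble::tibble(chrom = b$chrom, start = b$start, end = b$end,
                   value = as.numeric(v))
  })
}

#' Per-bin values of a track on one chromosome
#' @param track Track tibble (`chrom`, `start`, `end`, `value`).
#' @param grid A [bin_grid()].
#' @param chrom Chromosome name.
#' @return Numeric vector over the chromosome's bins (NA where absent).
#' @export
track_values <- function(track, grid, chrom) {
  n <- grid_nbins(grid, chrom)
  v <- rep(NA_real_, n)
  t <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(t)) {
    idx <- floor(t$start / grid$resolution) + 1
    ok <- idx >= 1 & idx <= n
    v[idx[ok]] <- t$value[ok]
  }
  v
}

#' Read / write bedGraph tracks
#' @param path File path.
#' @return For the reader, a track tibble.
#' @export
read_bedgraph <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "numeric", "numeric", "numeric"))
  tibble::as_tibble(x)
}

#' @rdname read_bedgraph
#' @param track Track tibble to write.
#' @export
write_bedgraph <- function(track, path) {
  t <- track[!is.na(track$value), c("chrom", "start", "end", "value")]
  utils::write.table(t, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path File path.
#' @param extra Names of optional extra columns after chrom/start/end.
#' @return Tibble with `chrom`, `start`, `end` and any extra columns present.
#' @export
read_bed <- function(path, extra = c("name", "score", "strand")) {
  x <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(x) <- c("chrom", "start", "end", extra)[seq_len(ncol(x))]
  tibble::as_tibble(x)
}

#' Write intervals as BED
#' @param intervals Tibble with `chrom`, `start`, `end` (+ extra columns).
#' @param path File path.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
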