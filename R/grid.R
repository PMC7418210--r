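#' Chromosome sizes table
#'
#' Builds the ordered chromosome-size table that anchors every bin grid.
#' Chromosome names must be unique and lengths positive.
#'
#' @param chrom Character vector of chromosome names.
#' @param length Integer-ish vector of chromosome lengths in base pairs.
#' @return A tibble with columns `chrom`, `length`.
#' @examples
#' chrom_sizes(c("chr1", "chr2"), c(60e6, 60e6))
#' @export
chrom_sizes <- function(chrom, length) {
  stopifnot(base::length(chrom) == base::length(length))
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  length <- as.numeric(length)
  if (any(!is.finite(length)) || any(length <= 0)) stop("chromosome lengths must be positive")
  tibble::tibble(chrom = as.character(chrom), length = length)
}

#' Read a chrom.sizes file
#'
#' Two-column tab-delimited `name<TAB>length`.
#'
#' @param path Path to a chrom.sizes file.
#' @return A chromosome-sizes tibble.
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  chrom_sizes(x$chrom, x$length)
}

#' Fixed-resolution bin grid over a genome
#'
#' Tiles each chromosome left to right with bins of `resolution` bp
#' (0-based, half-open; the last bin may be short). Bin indices within a
#' chromosome are 0-based: bin index = floor(position / resolution).
#'
#' @param sizes Chromosome-sizes tibble from [chrom_sizes()].
#' @param resolution Bin width in base pairs.
#' @return An object of class `bin_grid`.
#' @examples
#' bin_grid(chrom_sizes("chr1", 1e6), 1e5)
#' @export
bin_grid <- function(sizes, resolution) {
  stopifnot(is.data.frame(sizes), all(c("chrom", "length") %in% names(sizes)))
  resolution <- as.numeric(resolution)
  stopifnot(length(resolution) == 1, is.finite(resolution), resolution > 0)
  n_bins <- as.integer(ceiling(sizes$length / resolution))
  structure(
    list(sizes = tibble::as_tibble(sizes[, c("chrom", "length")]),
         resolution = resolution,
         n_bins = stats::setNames(n_bins, sizes$chrom)),
    class = "bin_grid"
  )
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %d chromosome(s) at %s bp: %s bins total\n",
              nrow(x$sizes), format(x$resolution, big.mark = ","),
              format(sum(x$n_bins), big.mark = ",")))
  invisible(x)
}

grid_nbins <- function(grid, chrom) {
  n <- grid$n_bins[[chrom]]
  if (is.null(n)) stop("unknown chromosome: ", chrom)
  n
}

grid_chrom_length <- function(grid, chrom) {
  i <- match(chrom, grid$sizes$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  grid$sizes$length[i]
}

#' Bin table of a grid
#'
#' @param grid A [bin_grid()].
#' @param chrom Optional chromosome name to restrict to.
#' @return Tibble with `chrom`, `bin` (0-based), `start`, `end`.
#' @export
grid_bins <- function(grid, chrom = NULL) {
  sizes <- grid$sizes
  if (!is.null(chrom)) sizes <- sizes[sizes$chrom %in% chrom, , drop = FALSE]
  purrr::pmap_dfr(sizes, function(chrom, length) {
    n <- as.integer(ceiling(length / grid$resolution))
    start <- (seq_len(n) - 1) * grid$resolution
    tibble::tibble(chrom = chrom, bin = seq_len(n) - 1L,
                   start = start, end = pmin(start + grid$resolution, length))
  })
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$resolution, b$resolution)) &&
    identical(a$sizes$chrom, b$sizes$chrom) &&
    isTRUE(all.equal(a$sizes$length, b$sizes$length))
}
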