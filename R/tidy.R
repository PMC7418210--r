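#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a saddle summary into a long tibble
#' @param x A `saddle_summary`.
#' @param ... Unused.
#' @return Tibble `row`, `col`, `mean_oe`.
#' @export
tidy.saddle_summary <- function(x, ...) {
  m <- x$matrix
  out <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  out$mean_oe <- m[cbind(out$row, out$col)]
  out
}

#' One-row summary of a saddle
#' @param x A `saddle_summary`.
#' @param ... Unused.
#' @return One-row tibble with the corner statistics.
#' @export
glance.saddle_summary <- function(x, ...) x$corners

#' Tidy a compartment profile (defined bins only)
#' @param x A `compartment_profile`.
#' @param ... Unused.
#' @return Tibble of bins with non-NA PC1.
#' @export
tidy.compartment_profile <- function(x, ...) {
  tibble::as_tibble(x[!is.na(x$pc1), ])
}

#' One-row summary of a compartment profile
#' @param x A `compartment_profile`.
#' @param ... Unused.
#' @return Tibble `n_bins`, `n_defined`, `frac_A`, `frac_B`.
#' @export
glance.compartment_profile <- function(x, ...) {
  def <- !is.na(x$label)
  tibble::tibble(n_bins = nrow(x), n_defined = sum(def),
                 frac_A = mean(x$label[def] == "A"),
                 frac_B = mean(x$label[def] == "B"))
}
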