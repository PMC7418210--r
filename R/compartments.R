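#' A/B compartment profile from the contact-correlation eigenvector
#'
#' The O/E matrix of a balanced map is turned into a Pearson correlation
#' matrix over unmasked bins, whose leading eigenvector carries the
#' compartment checkerboard. Because the sign of an eigenvector is
#' arbitrary and the top eigenvector can occasionally capture chromosome-arm
#' scale structure instead, the first two eigenvectors are scored by absolute
#' correlation with an orientation track (gene density or active-chromatin
#' ChIP signal) and the better-correlated one is kept, signed so that
#' positive PC1 (compartment A) has the higher track values. The returned
#' eigenvector is unit-normalized.
#'
#' @param map A `contact_map` (balanced or raw; balancing is applied if
#'   missing).
#' @param orientation Orientation track: a track tibble (see [bin_track()])
#'   or a numeric per-bin vector for the map's chromosome.
#' @param min_bins Minimum unmasked bins for a defined profile (default 20).
#' @return A `compartment_profile` tibble: `chrom`, `bin`, `start`, `end`,
#'   `pc1`, `label` (`"A"`/`"B"`/NA). All-NA (with a `degenerate` attribute)
#'   when the matrix is unusable.
#' @export
pc1_profile <- function(map, orientation, min_bins = 20) {
  if (!is_balanced(map) && !is_oe(map)) map <- balance_kr(map)
  g <- map_grid(map); ch <- map_chrom(map)
  n <- grid_nbins(g, ch)
  bins <- grid_bins(g, ch)
  ov <- if (is.data.frame(orientation)) track_values(orientation, g, ch) else as.numeric(orientation)
  stopifnot(length(ov) == n)
  out <- tibble::tibble(chrom = ch, bin = bins$bin, start = bins$start,
                        end = bins$end, pc1 = NA_real_, label = NA_character_)
  om <- oe_matrix(map)
  keep <- which(colSums(!is.na(om)) > 0 & !masked_bins(map))
  if (length(keep) < min_bins) {
    attr(out, "degenerate") <- "too few unmasked bins"
    return(structure(out, class = c("compartment_profile", class(out))))
  }
  sub <- om[keep, keep, drop = FALSE]
  if (all(apply(sub, 2, stats::sd, na.rm = TRUE) == 0, na.rm = TRUE)) {
    attr(out, "degenerate") <- "constant O/E matrix"
    return(structure(out, class = c("compartment_profile", class(out))))
  }
  cm <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  eg <- eigen(cm, symmetric = TRUE)
  cand <- eg$vectors[, 1:2, drop = FALSE]
  sc <- apply(cand, 2, function(v) {
    if (all(is.na(ov[keep])) || stats::sd(ov[keep], na.rm = TRUE) == 0 ||
        stats::sd(v) == 0) return(0)
    abs(stats::cor(v, ov[keep], use = "complete.obs"))
  })
  v <- cand[, which.max(sc)]
  # orient: A (positive) bins carry the higher orientation-track values
  hi <- mean(ov[keep][v > 0], na.rm = TRUE)
  lo <- mean(ov[keep][v < 0], na.rm = TRUE)
  if (is.finite(hi) && is.finite(lo) && hi < lo) v <- -v
  v <- v / sqrt(sum(v^2))
  out$pc1[keep] <- v
  out$label <- dplyr::case_when(out$pc1 > 0 ~ "A", out$pc1 < 0 ~ "B",
                                TRUE ~ NA_character_)
  structure(out, class = c("compartment_profile", class(out)))
}

profile_pc1 <- function(profile, grid, chrom) {
  p <- profile[profile$chrom == chrom, , drop = FALSE]
  v <- rep(NA_real_, grid_nbins(grid, chrom))
  if (nrow(p)) v[p$bin + 1] <- p$pc1
  v
}

strength_one <- function(map, ref_pc1, min_separation, tail) {
  om <- oe_matrix(map)
  res <- map_grid(map)$resolution
  ok <- which(!is.na(ref_pc1) & !masked_bins(map))
  if (length(ok) < 10) return(c(AA = NA, BB = NA, AB = NA))
  ntail <- max(1L, floor(length(ok) * tail))
  ord <- ok[order(ref_pc1[ok])]
  Bset <- ord[seq_len(ntail)]
  Aset <- ord[seq(length(ord) - ntail + 1, length(ord))]
  dmin <- ceiling(min_separation / res)
  cls_mean <- function(set1, set2) {
    sub <- om[set1, set2, drop = FALSE]
    d <- abs(outer(set1, set2, "-"))
    mean(sub[d >= dmin], na.rm = TRUE)
  }
  c(AA = cls_mean(Aset, Aset), BB = cls_mean(Bset, Bset), AB = cls_mean(Aset, Bset))
}

#' Compartment strength AA*BB/AB^2
#'
#' A-class bins are the top `tail` fraction of the reference PC1, B-class the
#' bottom fraction; over unmasked pixels separated by at least
#' `min_separation` (default 2 Mb, excluding intra-TAD interference), AA, BB
#' and AB are the mean O/E within each bin-pair class and the per-chromosome
#' strength is `AA * BB / AB^2`.
#'
#' @param maps A `contact_map` or named per-chromosome list.
#' @param reference A `compartment_profile` (may span several chromosomes)
#'   used to rank bins.
#' @param min_separation Minimum pixel separation in bp (default 2 Mb).
#' @param tail Eigenvector tail fraction defining each class (default 0.2).
#' @return Tibble `chrom`, `AA`, `BB`, `AB`, `strength`, with the unweighted
#'   cross-chromosome mean in attribute `mean_strength`.
#' @export
compartment_strength <- function(maps, reference, min_separation = 2e6, tail = 0.2) {
  if (inherits(maps, "contact_map")) maps <- stats::setNames(list(maps), map_chrom(maps))
  out <- purrr::map_dfr(maps, function(m) {
    comp <- strength_one(m, profile_pc1(reference, map_grid(m), map_chrom(m)),
                         min_separation, tail)
    tibble::tibble(chrom = map_chrom(m), AA = comp["AA"], BB = comp["BB"],
                   AB = comp["AB"],
                   strength = comp["AA"] * comp["BB"] / comp["AB"]^2)
  })
  attr(out, "mean_strength") <- mean(out$strength, na.rm = TRUE)
  out
}

#' Saddle plot of compartmentalization
#'
#' Bins are sorted ascending by the reference PC1 and partitioned into
#' `n_groups` equal-occupancy groups per chromosome; cell (g, h) is the mean
#' O/E over pixel pairs in groups g and h at separations of at least
#' `min_separation`, accumulated across chromosomes. Corner statistics are
#' means of the `corner` x `corner` corner blocks: AA/AB (A corner over the
#' A-vs-B corner) and BB/BA.
#'
#' @param maps A `contact_map` or named list (typically at 300-kb bins).
#' @param reference A `compartment_profile` on the same grid.
#' @param n_groups Number of PC1 rank groups (default 50).
#' @param corner Corner block size in groups (default 10).
#' @param min_separation Minimum separation in bp (default 2 Mb).
#' @return A `saddle_summary`: list with `matrix` (n_groups^2 mean O/E),
#'   `corners` tibble (`AA`, `BB`, `AB`, `AA_over_AB`, `BB_over_BA`).
#' @export
saddle <- function(maps, reference, n_groups = 50, corner = 10,
                   min_separation = 2e6) {
  if (inherits(maps, "contact_map")) maps <- stats::setNames(list(maps), map_chrom(maps))
  sums <- matrix(0, n_groups, n_groups)
  cnts <- matrix(0, n_groups, n_groups)
  for (m in maps) {
    om <- oe_matrix(m)
    res <- map_grid(m)$resolution
    pc1 <- profile_pc1(reference, map_grid(m), map_chrom(m))
    ok <- which(!is.na(pc1) & !masked_bins(m))
    if (length(ok) < n_groups) next
    grp <- rep(NA_integer_, length(pc1))
    grp[ok] <- ceiling(rank(pc1[ok], ties.method = "first") / length(ok) * n_groups)
    dmin <- ceiling(min_separation / res)
    idx <- which(upper.tri(om, diag = FALSE), arr.ind = TRUE)
    sel <- (idx[, 2] - idx[, 1]) >= dmin
    i <- idx[sel, 1]; j <- idx[sel, 2]
    gi <- grp[i]; gj <- grp[j]; v <- om[idx[sel, , drop = FALSE]]
    good <- !is.na(gi) & !is.na(gj) & !is.na(v)
    if (!any(good)) next
    acc <- tapply(v[good], list(factor(gi[good], 1:n_groups),
                                factor(gj[good], 1:n_groups)), sum)
    nacc <- tapply(rep(1, sum(good)), list(factor(gi[good], 1:n_groups),
                                           factor(gj[good], 1:n_groups)), sum)
    acc[is.na(acc)] <- 0; nacc[is.na(nacc)] <- 0
    sums <- sums + acc + t(acc) - diag(diag(acc))
    cnts <- cnts + nacc + t(nacc) - diag(diag(nacc))
  }
  mat <- ifelse(cnts > 0, sums / cnts, NA)
  hi <- seq(n_groups - corner + 1, n_groups); lo <- seq_len(corner)
  AA <- mean(mat[hi, hi], na.rm = TRUE)
  BB <- mean(mat[lo, lo], na.rm = TRUE)
  AB <- mean(mat[lo, hi], na.rm = TRUE)
  BA <- mean(mat[hi, lo], na.rm = TRUE)
  structure(list(matrix = mat,
                 corners = tibble::tibble(AA = AA, BB = BB, AB = AB,
                                          AA_over_AB = AA / AB,
                                          BB_over_BA = BB / BA)),
            class = "saddle_summary")
}

#' @export
print.saddle_summary <- function(x, ...) {
  cat(sprintf("<saddle_summary> %dx%d | AA/AB = %.3f, BB/BA = %.3f\n",
              nrow(x$matrix), ncol(x$matrix),
              x$corners$AA_over_AB, x$corners$BB_over_BA))
  invisible(x)
}

#' Compare two compartment profiles
#'
#' Pearson correlation of PC1 and the fraction of bins with identical A/B
#' labels (concordance), over bins defined in both profiles. With a
#' cross-assembly homology map, only bins mapping with overlap fraction
#' above `min_overlap` (default 0.6) are compared, each against the
#' destination bin its mapped midpoint falls in.
#'
#' @param a,b `compartment_profile`s (same grid, or two assemblies when
#'   `homology` is given, with `a` on the source assembly).
#' @param homology Optional homology-map tibble.
#' @param min_overlap Minimum mapped-bin overlap fraction (default 0.6).
#' @return Tibble with `pcc`, `concordance`, `n_bins`.
#' @export
compare_compartments <- function(a, b, homology = NULL, min_overlap = 0.6) {
  if (is.null(homology)) {
    j <- dplyr::inner_join(a[, c("chrom", "bin", "pc1", "label")],
                           b[, c("chrom", "bin", "pc1", "label")],
                           by = c("chrom", "bin"), suffix = c("_a", "_b"))
  } else {
    h <- homology[homology$overlap > min_overlap, , drop = FALSE]
    res_b <- b$end[1] - b$start[1]
    h$dst_bin <- floor((h$dst_start + h$dst_end) / 2 / res_b)
    ja <- dplyr::inner_join(a[, c("chrom", "start", "pc1", "label")],
                            h[, c("chrom", "start", "dst_chrom", "dst_bin")],
                            by = c("chrom", "start"))
    j <- dplyr::inner_join(ja, b[, c("chrom", "bin", "pc1", "label")],
                           by = c("dst_chrom" = "chrom", "dst_bin" = "bin"),
                           suffix = c("_a", "_b"))
  }
  j <- j[!is.na(j$pc1_a) & !is.na(j$pc1_b), ]
  pcc <- if (nrow(j) >= 3) stats::cor(j$pc1_a, j$pc1_b) else NA_real_
  conc <- if (nrow(j)) mean(j$label_a == j$label_b, na.rm = TRUE) else NA_real_
  tibble::tibble(pcc = pcc, concordance = conc, n_bins = nrow(j))
}

#' One-tailed A-versus-B comparison of a per-bin signal
#'
#' Mann-Whitney U test of a track (expression, ChIP enrichment) between
#' compartment A and B bins, one-tailed with H1: A > B.
#'
#' @param profile A `compartment_profile`.
#' @param track Track tibble or per-bin numeric vector aligned with the
#'   profile rows.
#' @return Tibble `p_value`, `median_A`, `median_B`, `n_A`, `n_B` (`p_value`
#'   NA when a class is empty).
#' @export
track_ab_test <- function(profile, track) {
  v <- if (is.data.frame(track)) {
    key <- paste(profile$chrom, profile$start)
    tv <- stats::setNames(track$value, paste(track$chrom, track$start))
    unname(tv[key])
  } else as.numeric(track)
  av <- v[!is.na(profile$label) & profile$label == "A" & !is.na(v)]
  bv <- v[!is.na(profile$label) & profile$label == "B" & !is.na(v)]
  p <- if (length(av) && length(bv))
    suppressWarnings(stats::wilcox.test(av, bv, alternative = "greater")$p.value)
  else NA_real_
  tibble::tibble(p_value = p,
                 median_A = if (length(av)) stats::median(av) else NA_real_,
                 median_B = if (length(bv)) stats::median(bv) else NA_real_,
                 n_A = length(av), n_B = length(bv))
}
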