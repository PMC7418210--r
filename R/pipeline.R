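#' Run the stage-comparison workflow
#'
#' Orchestrates the full comparison of several samples (developmental
#' stages and/or embryo types): global depth matching to the shallowest
#' sample, p(s) curves with pairwise Jensen-Shannon divergences,
#' contact-class fractions, PC1 compartment profiles with strength and
#' saddle statistics referenced to one sample (the morula-analogue
#' convention), compartment-domain segmentation with superdomain coverage
#' and cumulative size curves, and insulation scores with aggregate
#' profiles at the reference sample's boundaries. Deterministic given the
#' seed; tables are written as TSV plus a JSON manifest carrying the
#' configuration hash.
#'
#' @param samples Named list of samples; each sample is a named
#'   per-chromosome list of raw-count `contact_map`s on a common grid.
#' @param orientation Orientation track tibble (e.g. gene density) used to
#'   phase PC1.
#' @param outdir Output directory, or NULL to skip writing.
#' @param reference Label of the reference sample for strength/saddle and
#'   boundary profiles (default: the last sample, the most-developed stage).
#' @param target_pairs Depth target; default the minimum sample depth.
#' @param seed Integer seed (downsampling).
#' @param superdomain_threshold Superdomain length cutoff in bp.
#' @return List of result tables (invisibly also written to `outdir`).
#' @export
run_pipeline <- function(samples, orientation, outdir = NULL,
                         reference = names(samples)[length(samples)],
                         target_pairs = NULL, seed = 1L,
                         superdomain_threshold = 1e7) {
  stopifnot(length(samples) >= 1, !is.null(names(samples)))
  if (!reference %in% names(samples))
    stop("reference sample '", reference, "' is not among the samples")
  depths <- vapply(samples, function(s) sum(vapply(s, total_contacts, 0)), 0)
  if (is.null(target_pairs)) target_pairs <- min(depths)
  low <- names(depths)[depths < target_pairs]
  if (length(low))
    stop("downsample target exceeds depth of sample(s): ", paste(low, collapse = ", "))
  ds <- purrr::imap(samples, function(s, nm)
    downsample_contacts(s, target_pairs, seed = seed + match(nm, names(samples))))
  grid <- map_grid(ds[[1]][[1]])

  ps <- purrr::imap_dfr(ds, function(s, nm) {
    out <- ps_curve(s); out$sample <- nm; out
  })
  labs <- names(ds)
  jsd <- tidyr::expand_grid(sample_a = labs, sample_b = labs)
  jsd$jsd <- purrr::map2_dbl(jsd$sample_a, jsd$sample_b, function(a, b)
    ps_jsd(ps[ps$sample == a, ], ps[ps$sample == b, ]))
  classes <- purrr::imap_dfr(ds, function(s, nm) {
    out <- contact_classes(s); out$sample <- nm; out
  })

  profiles <- purrr::imap(ds, function(s, nm)
    dplyr::bind_rows(purrr::map(s, pc1_profile, orientation = orientation)))
  ref_profile <- profiles[[reference]]
  strengths <- purrr::imap_dfr(ds, function(s, nm) {
    st <- compartment_strength(s, ref_profile)
    st$sample <- nm; st$mean_strength <- attr(st, "mean_strength"); st
  })
  saddles <- purrr::map(ds, saddle, reference = ref_profile)
  corners <- purrr::imap_dfr(saddles, function(sd, nm) {
    out <- sd$corners; out$sample <- nm; out
  })

  domains <- purrr::map(profiles, call_compartment_domains)
  coverage <- purrr::imap_dfr(domains, function(d, nm)
    tibble::tibble(sample = nm,
                   coverage = superdomain_coverage(d, superdomain_threshold)$coverage))
  size_curves <- domain_size_curve(domains, grid$sizes)

  is_tracks <- purrr::imap(ds, function(s, nm)
    dplyr::bind_rows(purrr::map(s, insulation_score)))
  ref_bnd <- call_tad_boundaries(is_tracks[[reference]])$boundaries
  is_profiles <- purrr::imap_dfr(is_tracks, function(t, nm) {
    out <- aggregate_boundary_is(t, ref_bnd)
    out$sample <- nm; out$dip <- attr(out, "dip"); out
  })

  results <- list(ps = ps, jsd = jsd, contact_classes = classes,
                  strengths = strengths, saddle_corners = corners,
                  superdomain_coverage = coverage,
                  domain_curves = size_curves$curves,
                  domain_tests = size_curves$tests,
                  boundary_profiles = is_profiles,
                  reference = reference, target_pairs = target_pairs)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    cfg_hash <- rlang::hash(list(labels = labs, reference = reference,
                                 target_pairs = target_pairs, seed = seed,
                                 superdomain_threshold = superdomain_threshold))
    for (nm in c("ps", "jsd", "contact_classes", "strengths", "saddle_corners",
                 "superdomain_coverage", "domain_curves", "boundary_profiles")) {
      tb <- results[[nm]]
      tb$config_hash <- cfg_hash
      readr::write_tsv(tb, file.path(outdir, paste0(nm, ".tsv")))
    }
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("chromstage")),
           config_hash = cfg_hash, seed = seed, reference = reference,
           target_pairs = target_pairs, samples = labs),
      file.path(outdir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  invisible(results)
}

#' One-command synthetic end-to-end demo
#'
#' Generates a three-stage synthetic dataset emulating progressive
#' establishment of compartments and TADs (increasing planted compartment
#' strength and intra-TAD enrichment from a zygote-like to a morula-like
#' stage) on a compact two-chromosome genome, and runs [run_pipeline()] on
#' it with the morula-analogue as the reference.
#'
#' @param seed Integer seed.
#' @param outdir Output directory, or NULL to skip writing.
#' @param depth Contacts per stage (default 5e5 for a fast demo).
#' @return The [run_pipeline()] result list, with `truth` attached.
#' @export
demo_pipeline <- function(seed = 7L, outdir = NULL, depth = 5e5) {
  sizes <- chrom_sizes(c("chrS1", "chrS2"), c(3e7, 3e7))
  stages <- list(zygote = list(gamma = 0.3, beta = 0.4),
                 four_cell = list(gamma = 0.7, beta = 1),
                 morula = list(gamma = 1.5, beta = 2))
  sims <- purrr::imap(stages, function(p, nm) {
    simulate_hic(architecture_spec(sizes = sizes, resolution = 1e5,
                                   gamma = p$gamma, tad_beta = p$beta,
                                   compartments = 5e6, tads = 1.5e6,
                                   depth = depth),
                 seed = seed + match(nm, names(stages)), sample = nm)
  })
  truth <- sims$morula$truth
  orientation <- bin_track(truth$grid,
                           purrr::map(split(truth$bins, truth$bins$chrom),
                                      ~ as.numeric(.x$sign == "A")))
  res <- run_pipeline(purrr::map(sims, "maps"), orientation = orientation,
                      outdir = outdir, reference = "morula", seed = seed)
  attr(res, "truth") <- truth
  res
}
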