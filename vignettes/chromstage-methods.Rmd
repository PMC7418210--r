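---
title: "Methods: chromatin-architecture statistics in chromstage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-architecture statistics in chromstage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

chromstage compares chromatin architecture across Hi-C samples — developmental
stages, embryo types, replicates, or assemblies — at every organizational
level: contact-distance decay, A/B compartments and superdomains, insulation
TADs, chromatin loops, and inter-homolog contacts. This vignette is the
package's account of the underlying models, the tunable parameters, the
numerical choices, and what the synthetic-data validation does and does not
demonstrate.

## The contact-map model

A contact map is a tibble of upper-triangular pixels (`bin1 <= bin2`, 0-based
bins at a fixed resolution, 0-based half-open genomic coordinates) with a raw
`count` column and the bin grid, chromosome, balancing weights, and sample
label carried as attributes. Only intra-chromosomal pixels feed compartment,
TAD and p(s) statistics; inter-chromosomal records are kept solely for
allele-level analysis.

**Balancing.** `balance_kr()` computes weights so that the weighted matrix
`w_i w_j K_ij` has equal row sums over unmasked bins — the matrix-balancing
fixed point — via the symmetric Sinkhorn–Knopp iteration. Bins whose raw
marginal is below 5% of the chromosome's median marginal (`mask_frac`) are
masked first and excluded from every downstream statistic; this low-coverage
rule is standard sparse-Hi-C practice. If the iteration does not reach the
tolerance (`tol`, default `1e-6` maximum relative row-sum deviation — exposed
because published pipelines rarely state theirs) within `max_iter` sweeps,
the map falls back to vanilla square-root-of-coverage weights and is flagged.

**O/E.** The expected value at bin separation *d* is the mean balanced value
over all unmasked pixels at that separation (zero pixels included), so the
O/E matrix has per-diagonal mean exactly 1; diagonals with no unmasked pixels
stay undefined rather than dividing by zero.

**Depth matching.** Cross-sample comparisons of p(s), insulation, and
contact classes are depth-sensitive, so samples are first downsampled to a
common number of contact events, drawn without replacement from the multiset
of recorded events (multivariate hypergeometric across pixels), seeded. The
pipeline matches all samples to the shallowest one, once, globally.

## Distance decay and contact classes

`ps_curve()` aggregates raw off-diagonal counts by genomic separation into 50
log-spaced bins (from one bin width to the longest chromosome) and normalizes
to fractions. Two curves are compared by the Jensen–Shannon divergence with
the natural logarithm, so values live in [0, ln 2]; curves are renormalized
over the union of their populated bins before the two KL terms are evaluated.
The log base is a genuine free choice (conventions differ); it is fixed to
natural log and recorded here because it rescales all absolute JSD values.
Per-bin-distance binning is also supported (`breaks = "distance"`) since the
binning convention behind published JSD values is rarely stated.

Contact classes follow the local (< 20 kb), intermediate (50 kb – 1 Mb) and
distal (> 10 Mb) windows used for staged-embryo comparisons; the cross-sample
test is a two-sided Wilcoxon rank-sum over per-chromosome fractions, a
deliberately assumption-light choice for n ≈ 18–20 chromosomes.

## Compartments

`pc1_profile()` computes O/E, the Pearson correlation matrix over unmasked
bins, and its leading eigenvectors. Two well-known pitfalls are handled
explicitly:

* **Sign ambiguity.** The eigenvector sign is arbitrary; it is oriented so
  that positive PC1 (compartment A) has the higher mean orientation-track
  value (gene density, or an active-chromatin ChIP signal for cell types
  where gene annotation is unreliable).
* **Rank-1 artifacts.** The top eigenvector occasionally captures
  chromosome-arm-scale coverage structure rather than the checkerboard. The
  first two eigenvectors are therefore scored by absolute correlation with
  the orientation track and the better-correlated one is kept — the
  phasing-track practice of the widely used eigenvector tools, chosen over a
  sign-autocorrelation criterion because it needs no assumed block scale.

Compartment strength is `AA * BB / AB^2`, with A the top 20% and B the bottom
20% of bins by the *reference* PC1, over unmasked pixel pairs separated by at
least 2 Mb (removing intra-TAD interference), per chromosome; the summary is
the unweighted cross-chromosome mean. Saddle plots sort bins by reference PC1
into 50 equal-occupancy groups (quantile groups, since "50 bins" alone does
not fix a scheme) and average O/E per group pair at >= 2 Mb; corner
statistics are means of the 10 x 10 corner blocks, reported as AA/AB and
BB/BA. Cross-sample compartment comparisons report the PC1 Pearson
correlation and the A/B label concordance, restricted to homologous bins
mapping with > 60% overlap when a cross-assembly homology map is supplied.

## Superdomains

Compartment domains are maximal same-sign PC1 runs; NA gaps up to 2 bins
inside a run are bridged (unmappable bins should not split a visually
continuous domain; the sensitivity of this tolerance is exposed as an
argument). Superdomains are domains strictly longer than 10 Mb; coverage is
their aggregate length over the analyzed (domain-covered) genome.
Superdomain detection defaults to 300-kb-scale PC1 in the pipeline, which is
robust at embryo-like depth; the resolution is a recorded configuration knob.
The cumulative curve plots genome coverage against relative domain size
(domain length / chromosome length), domains >= 1 Mb only, and mean domain
sizes are compared with a Welch t test (the unequal-variance flavor, since
domain-size variances differ strongly between samples).

## Insulation and TADs

The insulation score at bin *i* is the mean balanced signal in the
`window x window` square just off the diagonal (default 500 kb at 50-kb
bins — the +/-625 kb plotting flank implies w <= 12 bins; 10 is used),
log2-ratioed to the chromosome mean of square means. It is NA near edges and
where more than half the square is masked, and is invariant to global count
scaling.

Boundaries are local insulation minima whose strength — the mean rise toward
the flanking maxima within `delta_span` (100 kb) — reaches `min_strength`
(0.1 log2 units); minima closer than 2 bins keep the deeper one, ties keep
the leftmost. Boundaries are 1-bin intervals; TADs are the >= 2-bin intervals
between consecutive boundaries. This insulation caller is the package's
self-contained default; TAD sets from external callers can be supplied as
plain interval tibbles wherever a reference TAD set is accepted, making
published domain calls first-class inputs.

The aggregate TAD panel rescales each reference TAD plus half-length flanks
onto a 90 x 90 grid by nearest-bin sampling and averages O/E. The scalar
signal is `W / (W + C)` with W the central TAD block mean and C the mean of
the two *diagonal* flank corner blocks — the distance-matched background.
The baseline is exactly 0.5 on flat O/E and under reference shuffles. The
off-diagonal corner (left flank x right flank) was considered and rejected:
it sits at separations beyond the TAD length, where balanced maps
systematically elevate non-TAD bins, which would make the statistic decrease
as planted TAD strength grows.

Differential boundaries z-score the between-condition insulation difference
at each boundary against the genome-wide distribution of differences at
non-boundary bins, two-sided, Benjamini–Hochberg adjusted at `alpha`. This
pooled-null construction is a declared design choice (the test behind
published differential-boundary counts is typically unstated); with
replicates, condition tracks are replicate means, and a single-replicate
design falls back to the same pooled null with a warning.

## Conservation machinery

TAD conservation is the fraction of mappable intra-TAD bin pairs whose two
mapped bins fall inside one TAD of the target set, with bin-to-TAD
membership requiring 60% bin-length overlap (robustness across 0.6–0.9 is a
tested property). The null repositions target TADs uniformly per chromosome,
preserving the size multiset and count; the p value is a rank-sum test of
per-TAD conservation against the pooled shuffled values. Boundary
conservation maps source boundaries through the homology, discards mapped
intervals > 50 kb (liftover inflation), counts >= 1 bp overlaps with target
boundaries, and applies a Fisher exact test against width-matched random
loci. Homologous loops are mapped the same way with a 15-kb anchor-width
cutoff.

## Loops and inter-homolog contacts

Loop significance re-implements the distance-stratified testing idea: the
expected count per pixel at each separation is the per-diagonal empirical
mean smoothed by monotone-decreasing isotonic regression (monotonicity
guaranteed by construction, no knot tuning); each pixel gets a binomial tail
p value against that expectation and BH q values over all tested pixels
(>= 300 kb separation; unrecorded pixels enter as p = 1). Calls require
q < 0.01. Convergent filtering keeps loops whose upstream (smaller
coordinate) anchor has a peak-supported forward motif and downstream anchor
a peak-supported reverse motif. APA averages O/E windows (+/-5 bins) around
loop pixels; the score is the center over the lower-left 3 x 3 corner mean,
exactly 1 on constant O/E.

Inter-homolog statistics take allele-tagged contacts: the per-chromosome
ratio of inter-homolog to intra-allele counts, and the aggregate density of
inter-homolog interactions around TAD boundaries (+/-1 Mb, 100-kb bins) with
a chi-square uniformity test. Each interaction is counted once, at the
midpoint of its two bins: counting both ends would double-count strongly
correlated loci (the two ends of a mostly short-range contact) and inflate
the chi-square beyond its nominal level.

## The synthetic generator

`architecture_spec()` + `simulate_hic()` plant a known architecture:
power-law decay `P(s) ~ s^-alpha` with an optional Gaussian-in-log-distance
local-contact bump below 20 kb (the bump's exact shape is a free choice; only
the phenomenon is specified), a compartment checkerboard multiplying
like-sign pixels by `1 + gamma` and unlike-sign by `1/(1 + gamma)`, intra-TAD
blocks multiplied by `1 + beta`, focal loop pixels by `1 + lambda`, and
multinomial sampling of a finite depth N. In two-allele mode each event is
tagged maternal/paternal and re-routed between homologs with probability
`rho` at the same bin coordinates.

The structure factor (compartments x TADs x loops) is Sinkhorn-equalized
before sampling so planted enrichments live purely on the O/E scale and not
in per-bin coverage — matching real balanced Hi-C, where coverage biases are
technical. Without this step, downstream balancing would partially invert
the planted contrasts. A consequence worth knowing: the realized O/E
contrast of an isolated planted TAD is somewhat below `1 + beta` (part of the
block excess is redistributed into the bins' long-range contacts), so
planted parameters map monotonically — not identically — onto measured
statistics, which is what parameter-recovery testing needs.

Defaults describe the desk-scale study genome: two 60-Mb chromosomes at
100-kb bins (600 bins each), alpha = 1, 6-Mb alternating compartment blocks
at gamma = 1, 1.2-Mb TADs, two million contacts — large enough for every
statistic to stabilize, small enough that the full suite runs in minutes.
TAD-level validation uses a 15-Mb chromosome at 50-kb bins (insulation is a
50-kb-bin statistic and is not representable on the 100-kb default), and
loop-level validation a 6-Mb chromosome at 10-kb bins.

**What passing synthetic tests does not show.** The generator is
multiplicative on an O/E scale with multinomial noise; it does not emulate
read-level artifacts (duplicates, ligation junctions), polymer physics,
nested/overlapping TADs, sub-compartment structure, copy-number variation,
or assembly errors beyond the jitter/inversion/unmappable model of the
synthetic homology map. Recovery on these maps validates the statistical
machinery, not robustness to every failure mode of real libraries.

## Numerical choices and degenerate inputs

* Eigenvector selection and sign handling as above; fewer than 20 unmasked
  bins or a constant O/E matrix give an all-NA profile with a flag.
* Empty strength classes after masking give NA for that chromosome.
* All-NA chromosomes give empty domain sets; a chromosome shorter than the
  loop distance cutoff gives an empty loop set.
* Downsampling beyond a sample's depth fails before computing, naming the
  sample; so does a pipeline reference label not among the samples.
* All randomness (sampling, shuffles, random loci, permutations) is seeded;
  pipeline outputs carry a configuration hash and are byte-identical across
  reruns at a fixed seed.

## Known limitations

* The insulation caller is deliberately simple (Crane-style minima); callers
  based on structural entropy or HMMs segment differently, which is why
  external TAD sets are accepted everywhere as references.
* The loop caller tests marginal pixel significance; it does not model local
  neighborhoods (donut filters) and will merge adjacent significant pixels
  rather than cluster them.
* Compartment strength referenced to a noisy reference PC1 is attenuated
  toward 1; cross-sample strength comparisons should share one reference, as
  the pipeline enforces.
* The homology model is bin-wise; long-range rearrangements (translocations,
  large inversions spanning many bins) are out of scope.
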