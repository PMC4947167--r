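---
title: "Quantifying a lncRNA protein decoy: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a lncRNA protein decoy: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoyscan)
```

## The scientific problem

Some cytoplasmic long noncoding RNAs appear to act as *decoys* (or
"sponges") for RNA-binding proteins: by presenting many copies of a
protein's recognition element, an abundant transcript can sequester a
meaningful fraction of the cellular protein pool and thereby de-repress
the protein's mRNA targets. The canonical case is NORAD, an abundant,
unspliced ~5.3-kb cytoplasmic lncRNA that carries at least 17
non-overlapping Pumilio recognition elements (PREs) and modulates
repression by the two human Pumilio proteins, PUM1 and PUM2.

Establishing a decoy claim computationally requires several independent
lines of evidence, and `decoyscan` implements each as a reusable,
tested stage:

1. **Motif density.** Is the number of recognition elements on the
   transcript larger than expected for a sequence of its composition?
2. **Target definition.** Which genes are targets of the protein, as
   judged by excess motif sites in their 3'-UTRs, and which genes form
   length-matched controls?
3. **Expression response.** Do the targets respond to perturbations of
   the decoy (knockdown, overexpression) more than the controls, in
   the direction the decoy model predicts?
4. **Architecture.** Is the transcript built from repeated units, and
   what structural elements do the units carry?
5. **Abundance.** How many decoy molecules are there per cell, where
   are they, and how does the site capacity compare with the protein
   copy number?

Every stage is paired with a seeded generator that produces synthetic
inputs with the statistical structure the stage assumes, so the whole
pipeline is testable end to end with no external downloads.

## Motif scanning

A PRE is written as a degenerate IUPAC consensus: `UGURUAUA`
(R = A/G) for the strict element used in density statistics and
`UGUANAUA` (N = any base) for the relaxed element used in 3'-UTR target
calling. `parse_iupac()` expands a consensus into per-position
allowed-base sets and `scan_motif()` matches those sets directly.

Counting is *greedy non-overlapping* by default: after accepting a hit
the scan resumes one motif length downstream. Greedy left-to-right
resolution is deterministic and, for these motifs on non-pathological
sequence, coincides with maximal packing. Design choices worth noting:

* coordinates are 0-based half-open (BED-compatible);
* `N` in the subject matches nothing, so masked sequence never
  inflates counts;
* only the sense strand is scanned by default (`revcomp = TRUE` adds
  the reverse complement), because recognition by the protein is
  single-stranded and strand-specific.

```{r}
scan_motif(repeat9_oligos()[["wt"]], "UGURUAUA")
```

## The dinucleotide-preserving permutation null

Motif counts are compared with sequences of identical *dinucleotide*
composition, not just mononucleotide composition, because local
composition (CpG suppression, AT-richness, homopolymer runs) strongly
affects the chance occurrence of short motifs. `dinucleotide_shuffle()`
samples uniformly from all sequences with the identical 16-entry
adjacent-pair count vector using the Altschul–Erickson construction:
the sequence is an Eulerian path on the 4-vertex dinucleotide
multigraph; a last-edge set forming a spanning arborescence into the
terminal vertex is drawn by rejection (uniform because vertex
out-degrees are fixed), remaining out-edges are randomly ordered, and
the path is walked (in compiled code). Endpoints are necessarily
preserved.

`motif_enrichment()` reports the shuffle mean as the expected count
and an add-one empirical p-value, `(1 + #{shuffle >= observed}) /
(1 + n)`, which can never be zero — with the default
`n_shuffles = 1000` the smallest reportable p is just under 0.001,
matching the resolution at which such enrichments are usually quoted.
Shuffled sequences are counted in the same non-overlap mode as the
observed sequence so that the two numbers are commensurable. A closed
form, `expected_analytic()`, gives the i.i.d. occurrence expectation
`(L - m + 1) * prod_i sum_{b in set_i} p(b)` as a fast alternative; it
is an occurrence expectation, not a non-overlap expectation, and is
documented as such.

On a uniform-composition synthetic transcript of NORAD's length the
shuffle expectation for `UGURUAUA` is a fraction of a site (the exact
value depends on composition; the acceptance script recomputes it),
so an observation of 17 sites sits far outside the null.

## 3'-UTR target classification

A gene is called a **target** when its 3'-UTR carries at least two
motif sites in excess of the number expected given the UTR's length
(`excess = observed - expected >= 2`), a **control** when it has no
more sites than expected, and **intermediate** otherwise;
intermediates are excluded from both analysis groups. The expectation
is computed per UTR either by dinucleotide shuffles of that UTR
(default, n = 200, consistent with the transcript statistic) or by the
analytic closed form with mononucleotide frequencies estimated from
the whole UTR set; the mode is recorded on the output.

Because motif-rich genes tend to have longer UTRs, expression
comparisons use **length-matched controls**:
`sample_length_matched_controls()` cuts decile bins over the UTR
lengths of all classified genes (targets and controls together, which
is what "dividing the genes into 10 bins" means operationally) and
samples, without replacement, as many controls per bin as the bin has
targets. A bin with more targets than available controls is an error
naming the bin. Genes with absent or empty UTRs are excluded and
reported. An alternative, experiment-driven target definition —
genes whose 3'-UTR overlaps a binding-site cluster interval (e.g. from
PAR-CLIP) — is available via `targets_from_clusters()`.

## Expression response

The expression stage intentionally mirrors a simple, transparent
analysis rather than a dispersion-modelled differential-expression
fit, because the scientific claim rests on a *group contrast* between
targets and controls rather than on per-gene significance:

* `normalize_rpm()` scales each sample to reads per million;
* `filter_expressed()` keeps genes with mean RPM ≥ 50 across the
  supplied samples (boundary inclusive; the filter is applied over all
  samples of a design, a choice recorded here because per-contrast
  filtering is an equally defensible reading);
* `fold_change()` averages RPM over replicates per condition, adds a
  pseudocount of 0.1 to each condition, and takes log2 ratios;
* `intronic_counts()` subtracts exon-mapping from whole-locus counts
  to approximate pre-mRNA signal, clipping negative cells at zero and
  reporting how many were clipped (multi-mapping artifacts can invert
  the subtraction);
* `compare_groups()` performs a two-sided Wilcoxon rank-sum test of
  target versus control fold changes — by exhaustive enumeration of
  all relabelings for total group size ≤ 10 and by the normal
  approximation with tie correction above that;
* `correlate_perturbations()` reports the Spearman correlation of two
  contrasts over their shared genes (knockdown and overexpression of
  the same decoy should anti-correlate);
* `translation_efficiency()` forms `(footprint + 0.1)/(mRNA + 0.1)`
  ratios so that effects acting purely on mRNA abundance cancel in
  the TE change.

One numerical caveat is worth stating. Per-sample renormalisation
couples genes: when a sizeable fraction of the count mass shifts, all
fold changes absorb a common composition offset. The *difference* of
group medians cancels this offset, which is why planted-shift recovery
is defined on that difference; single-group medians are biased by
composition in exactly the way real RPM data are.

## Repeat architecture

`self_dotplot()` compares a transcript with itself by exact k-word
matching (default k = 8) and summarises matches per offset as a
density. A word-match dotplot was chosen over local alignment because
it is deterministic, dependency-free and sufficient for period
detection; a classical alignment dotplot of a repeat array shows the
same off-diagonal bands this density profile captures.
`estimate_period_and_segment()` takes the smallest offset whose
density is a local maximum above `min_density` (default 0.2) and at
least `min_period` (default 30 nt), then cuts unit boundaries at
period intervals across the span of near-multiple matches. For
diverged repeats the expected exact-8-mer density between two copies
that each accumulated substitutions at rate r is roughly
`((1-r)^2 + r^2/3)^8` — about 0.19 at r = 0.1 — so segmenting arrays
at that divergence calls for `min_density` ≈ 0.1; the default stays at
0.2 to keep the caller honest about random background (whose density
is orders of magnitude lower, ~4^-8 per word).

Repeat units are annotated with the four element classes seen in
structured repeats of this kind: PRE motifs, a short hairpin with a
4-bp stem and variable loop, a U-rich run of 2–5 nt (inclusive bounds;
longer runs fall outside the class), and a long hairpin with an 8–9-bp
stem. Hairpins are contiguous Watson–Crick stems (G-U wobble optional,
off by default since the structural annotation speaks of paired bases)
found by growing the stem outward from every candidate loop; only the
maximal stem per locus is reported. This is deliberately not
thermodynamic folding — it detects the annotated element classes, not
minimum-free-energy structures.

## smFISH spot quantification

Stacks are `(z, y, x)` arrays, by convention 0.13 µm pixels in-plane
and 0.3 µm z-spacing, 4–12 optical sections. Detection follows the
classical single-molecule pipeline:

1. **Filter.** A negated 3D Laplacian-of-Gaussian of support 15 px and
   σ = 1.5 px (applied isotropically in voxel units; an anisotropic σz
   is available but off by default) turns diffraction-limited spots
   into positive peaks. The separable decomposition uses nine 1D
   passes with mirror padding, and the truncated second-derivative
   taps are re-centred to sum to zero so a constant stack maps exactly
   to zero.
2. **Threshold.** Components of the binarised response are counted
   (26-connectivity, compiled) over a uniform grid of 100 thresholds
   spanning the response range, and the threshold least sensitive to
   the choice is selected. Operationally: candidate plateaus are
   maximal runs of constant component count on the decreasing limb of
   the curve (at and after its mode — below the mode the binarisation
   is still dominated by merged background); runs with at least two
   components and at least 5 grid points are preferred, the longest
   wins, ties fall to the lowest threshold, and the plateau centre is
   selected. The preference for multi-component plateaus is what keeps
   a dim spot from being swallowed by a 10-fold brighter one (the
   "count 1" plateau between their peak responses can be very wide but
   represents a segmentation that has already lost signal), while the
   minimum plateau length keeps short noise flats from masquerading as
   stability. The original protocol verified thresholds manually;
   these two rules replace that step.
3. **Spots.** Supra-threshold components become spots with
   intensity-weighted centroids (weights from the raw stack), voxel
   counts and peak intensities.
4. **Background removal.** Spots outside a voxel-count window (default
   2–100) are dropped, as are spots whose centroid lies within 2 px of
   a spot in a *different* channel — the signature of
   autofluorescent debris, typically well under 1% of spots.
5. **Compartments.** The nuclear mask is an Otsu threshold on the
   maximum-intensity z-projection of the DAPI channel with holes
   filled; a spot is nuclear when its (y, x) centroid falls inside.
   Counts and fractions per compartment are reported. Per-cell
   statistics are left to caller-supplied masks; the package reports
   per-stack quantities.

Detected spot counts are invariant to uniform intensity scaling
because the threshold grid is range-relative.

## Stoichiometry

`binding_capacity()` is deliberately plain multiplication: transcript
copies per cell × sites per copy, e.g. ~70 × 17 ≈ 1,200 sites, with an
optional rounding granularity for the headline figure and a
site-to-protein ratio when copy numbers (~200 for PUM1, ~550 for PUM2)
are supplied. No occupancy or competition model is implied — no
dissociation constants are available at this level of description, so
capacity is an upper bound on simultaneous binding, not an estimate of
occupancy. Protein copy numbers come from a linear quantification
standard curve (`fit_standard_curve()`, ordinary least squares over
known amounts of purified protein) inverted at the lysate signal
(`copies_per_cell()`); signals below the intercept invert to zero with
a warning rather than to negative copies.

## The synthetic-data generators

Each generator is deterministic under its seed and returns a
machine-readable truth table.

* `gen_background_seq()` — first-order Markov chain with specified
  dinucleotide frequencies: the generative counterpart of the shuffle
  null.
* `plant_motifs()` — writes concrete instantiations of a degenerate
  motif at random non-overlapping positions. Transcript-scale tests
  plant 17 PREs into a 5.3-kb background whose pre-scan shows no
  chance sites, so recovery is exact by construction.
* `gen_tandem_repeat_seq()` — one ancestral unit duplicated n times,
  each copy independently point-mutated; 12 units of 300 nt at 10%
  divergence emulate an old tandem expansion (two copies of one
  ancestor retain ~81% identity).
* `gen_utr_universe()` — log-normal UTR lengths (median 1 kb, so
  decile length-matching is non-trivial) with planted site excess on
  designated targets.
* `gen_count_matrix()` — negative-binomial counts (gene-wise mean,
  common dispersion, default 0.05; Poisson in the zero-dispersion
  limit) with a planted log2 shift on target genes. NB was chosen
  because it is the accepted overdispersed model for RNA-seq counts;
  no distributional claim is inherited from any particular data set.
* `gen_fish_stack()` — an ellipsoidal nucleus rendered into a DAPI
  channel and 3D Gaussian spots (σ = 1.5 px, matching the detection
  filter's design point) split between compartments, with Poisson
  shot noise plus Gaussian read noise at a stated amplitude-to-noise
  ratio. Spots keep a minimum pairwise separation of 6 px — real
  single-molecule data mostly resolves molecules, but occasional
  merges are exactly what the ±8 tolerance on a 68-spot recovery
  absorbs.

What the generators deliberately do **not** emulate: alignment and
multi-mapping artifacts in counts, isoform structure in UTRs,
cell-to-cell variability and optical aberrations in stacks, or
sequence-composition biases of any particular genome. Passing tests
therefore demonstrate the correctness and calibration of the methods
under their stated models, not performance on any specific real data
set.

## Problem sizes and determinism

The test suite and the acceptance script run at deliberately modest
sizes chosen to exercise each method's statistics: 1,000 shuffles of a
5.3-kb transcript; 200 shuffles per UTR over tens to hundreds of
genes; group comparisons at n = 200/200 over 20 seeds; 1,000
null-calibration simulations; ten 8×96×96 FISH stacks with 68 spots;
12×300-nt repeat arrays. Every stochastic step takes an explicit seed,
and all randomness flows through R's RNG (the compiled Eulerian walk
consumes pre-randomised edge orders), so identical seeds give
byte-identical outputs.

## Known limitations

* The greedy non-overlap count equals maximal packing for the PRE
  motifs on realistic sequence but can undercount by construction on
  adversarial self-overlapping motifs.
* Per-UTR shuffle expectations at n = 200 carry Monte Carlo noise of
  order `sd/√200`; borderline genes near `excess = 2` can flip class
  between seeds. The analytic mode is deterministic but ignores
  dinucleotide structure.
* The dotplot is quadratic in the worst case (low-complexity
  sequence); periods shorter than `min_period` (default 30 nt) are
  deliberately out of scope.
* Hairpin finding reports contiguous stems only; bulged or interrupted
  stems are not modelled.
* Spot detection assumes diffraction-limited, mostly resolved spots;
  no sub-voxel PSF fitting, no transcription-site calling, and no
  segmentation of individual cells.
* Capacity arithmetic ignores binding kinetics and competition from
  the transcriptome-wide site pool, which is the appropriate level of
  caution for an upper-bound statement.
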