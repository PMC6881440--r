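---
title: "Multi-way chromatin contact analysis with tricontact"
author: "tricontact authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-way chromatin contact analysis with tricontact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tricontact)
```

## The question the package addresses

Chromosome-conformation-capture variants that read several ligation
junctions per sequenced molecule (Tri-C and related protocols) observe
*multi-way* chromatin contacts at single alleles. From a capture viewpoint
— typically an enhancer or promoter restriction fragment — each concatemer
read reports which other restriction fragments were in physical proximity
to the viewpoint *simultaneously*, on one allele. Aggregated over reads,
the frequency with which two reporter fragments co-occur with the viewpoint
distinguishes two architectures for a domain with several enhancers and
promoters:

* a **hub**, in which regulatory elements assemble into one complex:
  co-occurrence at the intersection of two elements is *enriched* over what
  their individual (pairwise) contact frequencies predict;
* **mutually exclusive (flip–flop) contacts**, in which the viewpoint
  touches one partner at a time: intersections are *depleted* below the
  independence expectation.

`tricontact` implements the full desk-scale analysis: in-silico digestion,
concatemer read processing and filtering, viewpoint-anchored multi-way
contact matrices, differential matrices between conditions, three-way focus
quantification with replicate statistics, and replicate concordance via
stratum-adjusted correlation. A generative simulator produces reads under
hub, exclusive, or independent topologies with ground truth, so every stage
is testable without external data.

## The simulated locus

The default `locus_model()` is a 180 kb single-TAD toy locus patterned on
an alpha-globin-like domain: three upstream gene promoters (*Snrnp25*,
*Rhbdf1*, *Mpg*), a cluster of five enhancers (R1–R4, Rm), the globin
promoters (*Hba*), and a CTCF-like boundary between *Mpg* and R1. The
default capture viewpoint is the strong central enhancer R2. Two
conditions mirror a boundary-perturbation design: with the boundary
**intact**, complexed contacts that cross it are attenuated
(retained with probability `boundary_block`); with the boundary
**deleted** they are unhindered. The default design is two conditions
with *n* = 3 biological replicates each.

## The generative model

Each allele yields one concatemer read.

1. **Complex formation.** With probability `p_complex` (default 0.5) the
   allele forms a specific complex. Under the *hub* topology the viewpoint
   recruits *k* partners (*k* drawn from `hub_size_dist`, default
   P(2, 3, 4) = 0.5, 0.3, 0.2) sampled without replacement with
   `partner_weights` (default equal). Under the *exclusive* topology
   exactly one weighted partner is recruited. Under the *independent*
   topology each element joins on its own with probability
   `join_scale * w / max(w)` (`join_scale` = 0.5; the specification of this
   model fixes only that the join probability is weight-scaled, so the
   scale is a package choice).
2. **Boundary.** Complexed contacts crossing an active boundary survive
   with probability `boundary_block` (default 0.2 — a strong but not
   absolute insulation, in line with boundary deletions changing contact
   frequency several-fold).
3. **Ligation and capture.** The read contains the viewpoint fragment,
   each complexed partner's fragment with probability `capture_prob`
   (default 0.8), and 0–2 background fragments (P(0, 1, 2) =
   0.3, 0.5, 0.2) drawn with probability proportional to
   `(1 + d)^(-decay_exponent)` where `d` is the distance to the viewpoint
   (default exponent 1, the canonical 3C distance decay).
4. **Sonication and PCR.** Outer sonication ends are drawn within 700 bp
   of the viewpoint fragment (a typical sonication size). With probability
   `duplication_rate` (default 0.1) the read is re-emitted as a PCR
   duplicate with ends jittered uniformly within ±`jitter` bp (default 3).
5. **Rendering (optional).** `render_fastq()` concatenates fragment
   sequences in random order and orientation. Sticky-end ligation
   regenerates the recognition site at junctions, so junctions are
   normalized to carry exactly one site copy; in-silico re-digestion of
   the read then recovers the constituent fragments.

The default `reads_per_replicate` is 5,000. This is far below the depth of
a real capture experiment but is enough to resolve focus proportions on a
180-bin grid with stable replicate statistics, and keeps a full
two-condition, three-replicate analysis in the order of seconds.

What the simulator does **not** emulate: polymer physics and loop
extrusion (contacts are generated probabilistically, since the claims
under test concern co-occurrence structure, not geometry), sequencing
error and base-quality models, capture-efficiency sequence biases,
trans-chromosomal reporters, and mapping ambiguity from repetitive
sequence (the toy reference is random DNA). Passing tests therefore
demonstrate correctness of the analysis contracts, not robustness to
those real-data complications.

## Read processing

`segment_and_map()` splits each read at recognition-site occurrences
(cut offset applied) and locates each segment of at least 20 bp in the
reference by unique exact match on either strand; the segment's midpoint
determines its fragment. Pre-mapped fragment lists (TSV) bypass this stage.

`extract_reporters()` keeps reads containing a viewpoint fragment and
removes, in order: the viewpoint fragment itself; fragments targeted by
other capture oligonucleotides; fragments overlapping the proximity window
(default 1 kb) around the viewpoint, where random polymer proximity
dominates; and fragments immediately adjacent to the viewpoint
(re-ligation artefacts; one fragment each side — the filter class is
standard, its width is a package choice). The surviving reporter set is
independent of filter order, and the funnel counts are reported.

`remove_duplicates()` collapses reads with identical sorted reporter sets
whose outer sonication ends fall in the same fixed `wobble`-bp bin
(default 6 bp, `floor(end / wobble)`). Fixed bins make duplicate classes
transitive and order-independent; the cost is that a true duplicate
jittered across a bin edge escapes collapse, and two distinct alleles that
happen to share a reporter set and both end bins are collapsed. Both
effects are rare at desk scale and inherent to bin-based wobble semantics.

## Contact matrices and normalization

Reads with *k* ≥ 2 reporters contribute their C(*k*, 2) unordered reporter
pairs to a symmetric matrix on a 1 kb bin grid (fragment midpoint
assignment; the midpoint rule is the package's choice of tie-break for
fragments straddling bin boundaries). Reads with one reporter feed the
pairwise profile instead, and the two classes partition the surviving
reads.

`normalize_matrix()` applies, in order,

1. depth normalization: division by the total raw counts in the matrix;
2. fragment-density correction: division by `f_i * f_j / mean(f)^2`,
   where `f_i` counts restriction fragments in bin *i* — a pair of bins'
   expected count scales with both bins' fragment content;
3. a single global rescale so the mean over non-excluded cells equals 100
   ("100 normalized interactions per bin"), making matrices of different
   depth directly comparable.

Zero-fragment bins are excluded throughout. The viewpoint/proximity bins
are masked at this stage (raw counting leaves them untouched so that the
raw matrix total exactly equals the pair enumeration). Scaled matrices of
two conditions subtract cell-wise into a signed differential matrix
(`differential_matrix()`, with `positive_part()` for condition-specific
gains).

Pairwise (Capture-C-style) profiles count each reporter fragment once per
read, are normalized to 100,000 interactions on the analyzed chromosome,
and carry a display scaling constant (default 0.01) recorded in metadata.

## Focus quantification and the independence expectation

A focus is the matrix neighbourhood at the intersection of two elements:
cells whose bin centers lie within a closed 2 kb radius of both anchor bin
centers (a 5×5 block at 1 kb resolution). `quantify_focus()` reports the
block total as a percentage of the matrix total, with both numerator and
denominator taken over one matrix triangle (upper, including the
diagonal) restricted to non-excluded cells — the proportion is then
independent of the symmetric-storage convention and of the global scaling
factor. Masked cells are excluded from numerator and denominator alike.

The independence expectation is built from the pairwise profile: the outer
product of the binned profile, divided by the same fragment-density
correction as an observed matrix (the binned profile carries a factor
`f_i` per bin that a corrected matrix does not), masked identically, and
rescaled to the same mean. The ratio of observed to expected focus
proportion is > 1 for a hub and < 1 for mutually exclusive contacts.
Anchors distal to the viewpoint (for the default locus, the
promoter–promoter intersection *Mpg*–*Hba*) give the cleanest contrast:
near-viewpoint anchors sit where distance-decay background dominates the
marginals, which dilutes the depletion signal of the exclusive topology.

## Statistics

`compare_groups()` performs the unpaired two-tailed Student's *t*-test
with pooled variance (df = n_a + n_b − 2; Welch's correction by flag) on
per-replicate focus proportions, and reports group means and standard
errors for dot-plot style summaries. Degenerate inputs follow a fixed
contract: zero pooled variance with equal means gives p = 1; with unequal
means, p = 0 and a warning.

`scc()` computes the stratum-adjusted correlation coefficient between two
matrices: both are smoothed with a (2h+1)×(2h+1) clipped mean filter
(h = 10 by default; edge windows average over in-bounds, non-excluded
cells only — no padding, so no data are invented at boundaries), cell
pairs are stratified by genomic distance up to 100 kb, each stratum
contributes its Pearson correlation weighted by
`N_k * sqrt(var_a,k * var_b,k)`, and zero-variance strata are skipped.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; `simulate_experiment()`
derives per-replicate subseeds from the master seed, and a fixed seed
makes the entire pipeline byte-identical across reruns (`run_pipeline()`
writes a manifest with parameter values and file checksums).

The test suite exercises the design at these scales, chosen to resolve
each property comfortably: digestion against a brute-force oracle on
100 random 5 kb sequences per enzyme; counting conservation on 10,000
simulated reads; type-I error of the replicate comparison over 1,000
null repetitions (n = 3 vs 3, 600 reads per replicate); and topology
recovery over 100 seeded runs at the default 5,000 reads per replicate,
requiring the hub/exclusive enrichment dichotomy and a significant
hub-vs-exclusive group difference. `scripts/acceptance.R` recomputes the
headline quantities from scratch for any seed.

## Known limitations

* The analysis is single-chromosome and viewpoint-anchored; genome-wide
  matrices, ICE/KR balancing and loop calling are out of scope.
* The exact functional forms used by the original capture pipelines for
  fragment-density correction and depth scaling are not published
  alongside their flags; the forms above are declared interpretations,
  parameterized in the configuration.
* Foci are pre-specified; no multiple-testing correction is applied
  across foci.
* The wobble-bin duplicate filter is approximate at bin edges, as
  discussed above.
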