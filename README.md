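# tricontact

Analysis of single-allele **multi-way chromatin interactions** from Tri-C
style proximity-ligation experiments, plus a generative simulator for
validating every stage.

## The problem

Capture-C-style assays measure how often a chosen viewpoint fragment (an
enhancer or promoter) contacts each other restriction fragment — but only
pairwise. Protocols that read several ligation junctions per molecule
(Tri-C) reveal which fragments contact the viewpoint *simultaneously on
one allele*. For a domain containing several enhancers and promoters, the
frequency with which two elements co-occur with the viewpoint separates
two architectures:

* **hub** — elements assemble in one regulatory complex; the matrix cell
  at the intersection of two elements is *enriched* over the independence
  expectation built from the pairwise profile;
* **flip–flop** — mutually exclusive one-at-a-time contacts; intersections
  are *depleted*.

`tricontact` takes concatemer reads (FASTQ or pre-mapped fragment lists)
to filtered viewpoint/reporter records, viewpoint-anchored multi-way
contact matrices, differential matrices between conditions, three-way
focus statistics across biological replicates, and replicate concordance.

## The method in brief

For each read with reporters \(r_1,\dots,r_k\) (viewpoint, capture-oligo,
proximity-zone and adjacent fragments removed; PCR duplicates collapsed by
identical fragment sets with sonication ends in the same 6 bp wobble bin),
every unordered pair of the \(\binom{k}{2}\) reporter pairs increments a
symmetric matrix on a 1 kb grid. Raw matrices are depth-normalized,
corrected for the number of restriction fragments per bin
(\(f_i f_j / \bar f^2\)) and rescaled so the mean non-excluded cell equals
100. A *focus* — the 5×5 block of cells within 2 kb of two anchor
elements — is quantified as the percentage of the matrix (one triangle)
it contains; conditions are compared with unpaired two-tailed Student's
*t*-tests over replicates, and replicate concordance uses the
stratum-adjusted correlation coefficient (mean-filter smoothing h = 10,
distances up to 100 kb).

The built-in simulator generates alleles under hub / exclusive /
independent topologies on a 180 kb toy locus (clustered enhancers R1–R4 and
Rm, promoters *Snrnp25*, *Rhbdf1*, *Mpg*, *Hba*, a CTCF-like boundary, and
a two-condition boundary-intact vs boundary-deleted design with n = 3
replicates), with distance-decay background, per-element capture
efficiency, sonication-end jitter and PCR duplicates — and ground truth
for every allele.

## Worked example

```r
library(tricontact)

cfg <- run_config(list(seed = 11, outdir = "demo_run",
                       model = "hub", n_replicates = 3))
res <- run_pipeline(cfg)

print(res$mean_matrices$deleted)
res$foci          # focus table; also written to demo_run/foci.tsv
res$scc           # replicate SCC table
```

Output (abridged):

```
<multiway_matrix> scaled | viewpoint R2 | 180 x 180 bins of 1000 bp | 5 excluded bins | triangle total 1534461
R2-R1-Hba:  deleted 1.902% +/- 0.040, intact 3.652% +/- 0.108, t = -15.14, p = 0.0001111
R2-Mpg-Hba: deleted 4.616% +/- 0.246, intact 1.998% +/- 0.213, t =   8.05, p = 0.001292
mean replicate SCC: 0.9393
```

Reading the numbers: each focus value is the share of the multi-way matrix
within 2 kb of the two named elements — three-way contacts of the
viewpoint (R2) with both. The promoter–promoter focus R2–*Mpg*–*Hba*
more than doubles when the boundary separating *Mpg* from the enhancers is
deleted (4.6% vs 2.0%, p ≈ 0.001): the upstream promoter joins the
downstream complex. The downstream focus R2–R1–*Hba* shows the mirror
effect as a *share* (proportions are relative: when the boundary blocks
upstream contacts, downstream cells hold a larger share of the matrix).
The SCC near 0.94 shows the three replicates agree closely. A run
directory also contains per-replicate matrices (dense TSV + triplets +
JSON sidecar), bedGraph profiles, a differential matrix, filtering-funnel
statistics, `report.txt`/`report.json`, and a checksum manifest; reruns
with the same config are byte-identical.

A thin command-line front-end is included:

```sh
Rscript inst/scripts/tric.R run-all --config my_run.yaml
```

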