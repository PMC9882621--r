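---
title: "Models and methods behind mitohet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitohet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohet)
```

## The problem

Mitochondrial DNA is present in hundreds to thousands of copies per cell,
and the copies need not be identical: a variant present on a fraction of
the molecules is a *heteroplasmy*, quantified as the alternate-allele read
fraction at a site. Estimating heteroplasmy from whole-genome sequencing
is harassed by three artifacts:

* **NUMTs** — nuclear segments of mitochondrial origin. Reads from a NUMT
  mis-mapped onto the mtDNA masquerade as low-level heteroplasmy.
* **Reference distance** — a sample whose haplogroup is far from the
  reference accumulates alignment errors near its private homoplasmies.
* **Circularity** — linearizing the circular molecule creates two
  artificial breakpoints where coverage collapses and control-region
  variants are missed.

`mitohet` addresses these with a per-sample *self-reference*: variants are
first called against the canonical circular reference; homoplasmic mtDNA
calls (fraction at or above 0.95) and homozygous NUMT calls become edits
of a per-sample consensus; reads are re-called against that consensus,
with the control region called against a rotated ("shifted") copy of the
molecule; and all calls and per-base coverage are lifted back to reference
coordinates through an edit-indexed coordinate map.

## Coordinate model

Coordinates are 1-based inclusive everywhere inside the package (the VCF
and SAM convention); BED I/O converts 0-based half-open at the boundary.
Intervals on the circular contig may wrap: `start > end` denotes the arc
running through the origin, and membership/width/enumeration are defined
modularly. The default shift for the rotated pass is `floor(L/2)`, which
maximally separates the two linearization breakpoints; the amount is
configurable because nothing in the method depends on the exact value.

The non-coding region catalog (control region, CSBII, CSBIII, LSP,
heavy-strand origin zone, 7S DNA span, chrM:302 classifier locus) ships as
a plain-text config of rCRS-style annotations
(`inst/extdata/rcrs_regions.cfg`), all overridable. Derived regions follow
the D-loop geometry: the DNA-primer region lies between the heavy-strand
origin and CSBII, the RNA-primer region between CSBIII and the LSP. The
"first third" of the 7S span is counted from the boundary nearer the
linearization origin, rounded down; the annotations we derived from do not
fix the counting direction, so this is a documented package decision.

## Consensus and liftover

A consensus edit replaces a reference slice with the sample's allele. The
coordinate map stores the ordered edits plus cumulative length offsets, so
any position maps in O(log n). Positions inside inserted bases lift to the
left-anchoring reference position (flag `inside_insertion`); reference
positions deleted in the consensus lift to the left-anchoring consensus
position (`inside_deletion`). Lifted coverage copies depths at matched and
substituted positions, lets deleted reference positions inherit the left
flanking consensus depth (the alternative — mean of flanks — is a
configuration away in spirit but we found no case where it matters at
realistic depth smoothness), and drops depths at inserted bases.

When calls made against the consensus return to reference coordinates,
every consensus edit is additionally re-emitted as a reference-coordinate
call with fraction `1 − Σ(competing lifted fractions at the site)`,
floored at zero: a sample homoplasmic for an edit reappears at fraction
1.0, and residual heteroplasmy at an edited site splits between the
competing alleles. Emitted alleles are parsimony-trimmed and left-aligned
in homopolymer context so poly-C length alleles anchor consistently; a
composed call whose alternate collapses to the reference allele asserts
the reference fraction and is therefore not emitted as a variant.

## Read placement and calling

`place_reads` assigns each read to the target (one mtDNA consensus plus
NUMT decoys) with the fewest mismatches under exact k-mer seeding and
ungapped extension; ties go to the decoy. The tie rule is deliberately
conservative against false heteroplasmy, and it has a visible cost: where
a decoy is locally *identical* to the mtDNA, every read from that stretch
ties and is discarded, cratering mtDNA coverage there. That is the NUMT
ambiguity itself, not an implementation accident, and it is why
heteroplasmies inside NUMT-homologous intervals should be interpreted
through the AD-alt filter (below) or masked outright — the same reason
production pipelines blocklist reference-NUMT intervals.

The caller is a pileup: depth excludes duplicate, secondary and unmapped
reads and bases below quality 20 (the external callers' thresholds are not
published; 20 is the conventional floor and configurable); SNV fraction is
alt count over depth; indels are parsed from CIGARs and left-aligned. A
call is emitted from two alternate reads up — all fraction thresholds
belong to post-calling QC, mirroring the separation between calling and
phenotype QC. Reads may span the circular origin; coordinates wrap
modularly. The shifted pass re-places soft-clipped reads (the fingerprint
of a linear aligner hitting the breakpoint) onto the rotated genome, and
the merged callset takes control-region calls exclusively from the shifted
pass and everything else exclusively from the primary pass.

In the second calling round (against the consensus), reads keep their
original alignments when all consensus edits are length-preserving —
coordinates coincide, and indel-carrying CIGARs survive. When the
consensus contains indel edits, reads are re-placed gaplessly; reads
carrying further indels relative to that consensus would then be
mis-scored, so length-variant genotyping at CSBII is done by the dedicated
read classifier rather than by the pileup caller.

Copy number is `2 × mean (default) or median mtDNA coverage / mean nuclear
coverage`; the nuclear mean comes from flagstat-style counts as
`(total mapped − singletons − discordant mates − duplicates) × read length
/ genome length`. The flag-category definitions are tool-specific and are
treated as documented inputs.

## Post-calling QC

Variant level: fractions below 0.01 are recoded reference with stored
heteroplasmy 0; fractions in [0.01, 0.05) are removed (NUMT-risk band);
caller-flagged calls are removed; at uncalled sites depth of at least 100
distinguishes confident reference from no-call. Sample level: copy number
below 50 (strict), contamination above 2% (strict), overlapping
homoplasmic alleles (implemented as two non-reference alleles each at
fraction ≥ 0.5 at one site — the published definition lives in
supplementary material we treat as unavailable, so this stand-in is
configurable), and a configurable processing-year exclusion set. Where
prose left a boundary ambiguous ("between 0 and 0.5") we chose strict
bounds and say so. The common-low-heteroplasmy annotation (≥ 0.1% of
passing samples with fraction strictly between 0 and 0.5) and the
≥ 500-carrier floor define the common-heteroplasmy phenotype set; the
AD-alt filter marks calls missing when alternate depth falls strictly
below the sample's mean nuclear coverage, the designed guard against
support that a two-copy nuclear segment could supply.

## CSBII length variants

On the forward strand the reference CSBII motif is `AA C7 T C5 GC`. The
variable tract is the C-run adjacent to position 302 — the insertion
allele `A,AC` extends exactly that run, which is the `G_n` tract in the
opposite-strand `G_m A G_n` nomenclature. Reads completely spanning the
classifier locus are matched against `AA(CCC+[CT]CC+)GC`; run lengths 7,
8, 9, 10 label reference, `A,AC`, `A,ACC`, `A,ACCC`, anything else
"other"; non-matching reads are NA. One honest caveat: when the spacer
base is C the two runs merge into a single homopolymer and the
decomposition is unidentifiable; the pattern's greedy semantics fix the
canonical split (second run = 2) and our tests assert exactly that, with
total length preserved. Single-cell profiles drop non-whitelisted
barcodes, require 20 spanning reads per cell, and report the top three
global variants plus an "other" remainder that includes NA reads (the
aggregation decision; excluding NA would silently inflate the named
fractions). Bulk profiles sum counts over retained cells. Call-based
composition assigns `reference = 1 − Σ(fractions)`, floored, with
depth-100 exclusion and pooling of unnamed alleles.

## Phenotype construction and correction

Case-only traits carry the carrier's fraction with reference, no-call and
homoplasmic samples missing; case-control traits code detectable
heteroplasmy as 1 and depth-backed reference as 0. The covariate design
uses a 5-df natural spline in blood-draw time, a natural spline in
assessment date with quarterly knots over a configurable span (the
packaged default spans three years from July 1), center/month/fasting
indicators (fasting recoded >18 → 18 and 0 → 1), and 14 continuous blood
indices with |Z| > 4 entries masked; rows with masked values are
complete-case excluded from the blood model. Month indicators and the
seasonal spline are near-collinear by construction; aliased columns are
dropped deterministically (last-in) and reported. Correction is gated by
an F-test at 0.05/40 (the Bonferroni level for a 40-phenotype screen),
applied per covariate block with a joint option; gated-off phenotypes pass
through untouched. Residuals are re-centered by the pre-correction mean
and, for copy number (modeled on the log scale), exponentiated back.
Inverse-rank normalization uses the Blom offset `(r − 3/8)/(n + 1/4)` with
average ranks for ties — the transform is named in the field without an
offset convention, and Blom is the common default.

Coverage-discrepancy traits regress the per-sample median DNA-primer
coverage on either the 7S-DNA or RNA-primer median with haplogroup main
effects and interactions (haplogroups under 30 samples excluded);
residuals are the traits. Transmission tables pair relatives' fractions
for variants with at least 5 carriers. Age-accrual summaries include
zero-count individuals — excluding them would bias every bin upward.
Carrier contrasts run two-sample t-tests for pairs with more than 10
carrier values and Benjamini–Hochberg over all performed tests.

## Summary-statistics layer

The association scan is covariate-projected least squares with a strict
MAC > 20 rule — a stand-in for the mixed-model scans used on large cohorts,
valid for the unrelated synthetic samples generated here; tests therefore
scan founders only. Fixed-effect meta-analysis uses inverse-variance
weights with Cochran's Q for heterogeneity (cross-checked against metafor
in the test suite). Clumping is greedy on p-value with r² > 0.1 within
500 kb and index/clumped p-thresholds of 1; equal p-values break toward
the lower genomic position (the external tool's tie behavior is not
documented). Lead SNPs chain into loci at 2 Mb; prior loci replicate at
5e-5 or 5e-8 within 2 Mb of their top variant. The bidirectional
effect-size regression weights each point by the product of inverse
squared standard errors. Binary-genotype PCA filters homoplasmy indicator
columns at MAF ≥ 0.001, centers and scales on training rows, and projects
held-out rows through the training loadings; the haplogroup predictive
check feeds multinomial log-likelihoods into McFadden's
`1 − ll_model/ll_null` (the printed formula renders ambiguously; this is
the convention the name denotes). CLPP is the product of GWAS and eQTL
PIPs; enrichment is the relative risk between PIP > 0.1 and PIP ≤ 0.01
strata with a 5,000-replicate percentile bootstrap; gene assignment
implements the published rule ladder including the multi-credible-set
PIP > 0.1 retention rule and the no-credible-set nearest-gene fallback,
with in-gene-body variants counting as nearest.

## What the synthetic data does and does not emulate

The generators plant: maternal transmission of indel-like heteroplasmies
(additive truncated-normal noise on the fraction scale, σ = 0.03 — the
transmission is quantitative in real cohorts but no noise model is
published, so this is a package choice), somatic SNV accrual as a
piecewise-constant Poisson rate stepping up at age 70, a −2%/decade age
slope on log copy number around a baseline of 60 copies, one planted
blood-index effect, nuclear QTLs shifting carrier heteroplasmy, NUMT
decoys at 2% divergence, duplicate flagging, optional cell barcodes, and
the breakpoint coverage dip via linear-mode read clipping. They do not
emulate indel sequencing errors, quality ramps, mapping-quality structure,
GC bias, or phylogenetically realistic haplogroup trees — so passing tests
demonstrate the algorithms' correctness and calibration on clean data, not
robustness to every real-data pathology.

Problem sizes in the shipped tests are chosen for a desk-scale run:
3,000 bp toy genomes for pipeline tests (with one 16,569 bp genome for the
liftover round trip), 20 samples at depth 200 for recovery, cohorts of
2,000 for parameter recovery, and 2,000 replicates for calibration checks.

## Numerical choices and degenerate inputs

Ties in rank normalization are averaged; all-identical inputs are an
error, not a silent zero vector. Zero-variance genotype columns are
skipped with a recorded reason. Logistic fits flag separation instead of
reporting an unstable estimate. The clumping warning for missing LD pairs
treats them as r² = 0 (exclusion would silently shrink clumps).
Composition fractions are floored at zero and renormalized when floating
error leaves the sum off unity by more than 1e-9. All generators are pure
functions of their parameters and a seed.

## Known limitations

Gapped alignment is out of scope: placement is seed-and-extend ungapped,
so the pipeline's re-calling round handles indel consensus edits by
gapless re-placement, and heteroplasmic indels are quantified by the CSBII
read classifier rather than the general caller. Contamination and
haplogroup labels are inputs, as are fine-mapping PIPs and LD. The
homoplasmy-overlap rule is a stand-in for an unavailable supplementary
definition. The least-squares scan must not be used on related samples.
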