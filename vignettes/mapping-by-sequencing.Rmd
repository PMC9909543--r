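---
title: "Mapping-by-sequencing with bulkmapr: models, defaults and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping-by-sequencing with bulkmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkmapr)
```

# The problem

A forward-genetic screen yields a mutant; the task is to find the causal
variant.  Mapping-by-sequencing reads the answer off pooled sequencing data:
phenotypic selection perturbs allele frequencies (and, after recurrent
backcrossing, the very presence of variants) in the neighbourhood of the
causal locus.  `bulkmapr` implements three pooled designs and a
variant-effect analyzer, plus a simulator that generates complete synthetic
experiments so that each pipeline can be validated end-to-end.

This vignette documents the models, every tunable that matters, the
numerical conventions, and the design decisions taken where the methods
literature leaves the choice open.

# Data model and conventions

All coordinates are 1-based closed; the FASTA record order is the canonical
chromosome order.  A variant is one biallelic record keyed by
`(chrom, pos, ref, alt)` (VCF convention: indels left-anchored at the last
shared base), carrying quality, allele-depth counts, the derived allele
frequency `af = alt_count / (ref_count + alt_count)` (`NA` when no
informative reads exist), and a class in {snp, insertion, deletion}.

Multi-allelic VCF rows are split one record per alternate allele with
`af_i = alt_i / (ref + Σ alt)`, which keeps Σ af ≤ 1 per site; the stored
`ref_count` of a split record is total depth minus `alt_i` so the af formula
above remains true.  Records whose FILTER is neither `PASS` nor `.` are
dropped: the package must be robust to arbitrary user VCFs, not only its
own.  Equal-length multi-nucleotide substitutions have no class in this
model and are dropped with a warning.  Control VCFs need only
`CHROM/POS/REF/ALT`; operations that consume allele frequencies raise a hard
error when they meet an undefined af rather than silently guessing.

# Variant density mapping

After `k` recurrent backcrosses to the reference strain, a heterozygous
variant unlinked to the causal site survives with probability `(1/2)^k`,
while a variant at recombination fraction `r` survives with `(1 − r)^k`;
selection for the phenotype at each round is what keeps the causal site and
its linked passengers.  The workflow builds, per sliding window, counts of
five sublists: all test variants, test-specific (control-subtracted),
homozygous (af ≥ 0.85), EMS-type (G→A, or C→T as the forward-strand
representation of a reverse-strand G→A), and homozygous-EMS (the
intersection).

**Homozygosity by threshold, not genotype calls.** Pools have no diploid GT
semantics, so a site is called homozygous when `af ≥ af_hom_min` (default
0.85) and depth ≥ `min_dp` (default 5).  At the recommended 25× depth, a
truly fixed site fails the 0.85 cut only through heavy reference
contamination, while a segregating site (af ≈ 0.5) passes with probability
< 10⁻³.

**Control subtraction is allele-aware** by default (same position, different
alt is retained) because compiled controls pooled from several genotypes can
share positions without sharing alleles; a position-only switch exists for
deliberately aggressive filtering.

**Peak rule.** A window qualifies when its category count strictly exceeds
`max(min_count, μ + z·σ)` with genome-wide `μ, σ`, `z = 2`, `min_count = 4`.
The absolute floor prevents spurious calls on near-empty genomes, where
`μ + z·σ` can be a fraction of one variant.  Overlapping/adjacent qualifying
windows merge into one region; regions are ranked by their maximal window
count, and every region is reported (there is no published ranking rule to
follow, and real datasets show artifact peaks worth inspecting).
Windows default to 1 Mb with a 0.5-Mb step: the classic per-megabase bin,
overlapped two-fold so a cluster straddling a bin boundary is not diluted.

Candidates are the reportable-class variants inside any region that also
overlap a gene span; without an annotation the candidate list is empty and
flagged, but the density profile and regions are still produced.

# QTL-seq

Two opposite-phenotype bulks are drawn from one segregating population.
Mapping variants are the SNPs present with `0 < af < 1` and depth ≥ 5 in
*both* pools — this single filter removes parental differences against the
reference (fixed af = 1 in both bulks) and pool-private variants.  Indels
can be admitted by switching `snp_only = FALSE`; the default follows the
SNP-based convention of the method.

Per window, `daf_mean` is the arithmetic mean of `daf = af1 − af2`; the
smoothed `daf_wma` is a weighted moving average with the triangular kernel
`(1, 2, 3, 2, 1)` — the minimal symmetric choice where only "weighted moving
average" is prescribed; the kernel is an argument.  Windows without
variants are **bridged, not zero-filled**: they are excluded from the
smoothing support (weights renormalize over the defined neighbours, exactly
as at chromosome edges) and they do not interrupt region runs.  Zero-filling
would bias `daf_wma` toward 0 in marker deserts, where the honest statement
is "no information".

Regions are maximal runs of ≥ `min_run` (default 3) consecutive defined
windows with `|daf_wma| ≥ daf_min` (default 0.25) and constant sign.  The
0.25/3 defaults operationalize "regions where dAF deviates from 0"
stringently, aimed at major QTL; both knobs are exposed because minor QTL
need looser settings and visual inspection of the dAF plots.  Swapping the
pools negates every `daf`, `daf_wma` and region sign while leaving
coordinates untouched — an exact antisymmetry the tests assert.

With no GFF3 the scan still reports regions and in-region variants, only
without gene identification, matching the annotation-free use-case of crops
with poor structural annotation.

# Allele-frequency linkage scan

For a single mutant bulk, the pipeline is control subtraction → class and
quality filters → per-window mean af → the same WMA smoothing → the region
is the maximal run (≥ 2 windows) with `af_wma ≥ 0.9`.  The threshold is
0.9 rather than 1.0 because linkage mapping is highly sensitive to
phenotyping errors: a handful of misclassified individuals caps the
observed af below fixation genome-wide.  Candidates are in-region, in-gene
variants with af above the homozygosity threshold.  This module is
deliberately a fixation scan only; it does not reproduce any older
linkage-statistic machinery, and candidate reporting (including indels) goes
through the same shared filter/annotate machinery as the other workflows.

# Variant analyzer

Every variant is annotated against **all** overlapping transcripts (there is
no defensible canonical-transcript rule without expression data).  Element
resolution: CDS, then splice site (first/last 2 nt of an intron), exon
(UTR side by strand, or non-coding exon), intron, upstream/downstream
(within 500 bp of the transcript, a configurable margin), else intergenic.
For CDS SNPs the codon is rebuilt from the CDS-concatenated sequence
honoring strand and segment phase and translated with the standard genetic
code; consequences are synonymous / missense / nonsense / stop_loss /
start_loss.  CDS indels are classed frameshift vs in-frame by length mod 3
only — protein-level prediction past that point would be speculation.
Transcripts whose CDS length (after phase adjustment) is not a multiple of
3 are flagged incomplete and receive element-level annotation only.

Primer design is a deterministic outward scan (3′ ends from 50 to 400 bp on
each side; lengths 20, then 19/21/18/22/23/24): a candidate must be N-free
with GC 40–60%; the first left/right pair with |ΔTm| ≤ 3 °C (Wallace rule,
`2(A+T) + 4(G+C)`) and a 150–800-bp product spanning the variant wins.
Wallace Tm was chosen over nearest-neighbour thermodynamics because the
reference tool's algorithm is unpublished and determinism plus
hand-checkability matter more here than half-degree accuracy.  Failure is
reported with a reason rather than silently omitted.  Reports are one row
per variant × transcript; reference flanks (default 25 bp, clipped at
chromosome ends) reconstruct `left + ref + right` as a verbatim reference
substring.

# The simulator: the stated world

The simulator is first-class, tested code whose defaults *are* the
experimental designs the workflows target:

* genome: 2 chromosomes × 10 Mb of i.i.d. uniform ACGT (a 20-Mb desk-scale
  genome); genes every 25 kb on alternating strands, 2–4 exons, 30-bp UTRs,
  CDS from ATG to stop with no internal stop;
* recombination: Haldane map function `r = (1 − e^(−2d))/2` with a uniform
  4 cM/Mb, a typical plant/nematode average; no interference;
* backcross design: 60 EMS mutations (G/C → A/T) — a realistic
  mutagenesis load for a 20-Mb genome — one causal inside a CDS; per-site
  survival `(1 − r)^k` with `k = 4` (within the recommended 3–6); surviving
  linked sites homozygous (af 1), surviving unlinked sites segregating
  1/4 : 1/2 : 1/4 in a 50-individual pool; depth 25×;
* F2 bulk (linkage): 100 individuals and 25× depth — the recommended minima
  for linkage designs; both gametes of each selected individual carry the
  causal allele and linked sites follow the conditioned Markov recombination
  chain outward, so true af decays as 1 − r;
* QTL-seq: markers at random positions averaging one per 100 kb, F2
  genotypes from two independent gamete Markov chains, phenotype
  `effect·(genotype − 1) + N(0,1)` with effect 3 SD (effectively complete
  selection at 10% tails; effect 0 is the null generator), bulks the top and
  bottom 10% of 200 individuals, depth 50×;
* observation: alt counts are Binomial(depth, true af) everywhere; shared
  pre-mutagenesis background variants (default 100, ~10% small indels)
  appear in both test and control samples.

Every output is a pure function of the configuration (same config ⇒
byte-identical FASTA/GFF3/VCF/TSV files); truth sidecars are written for
tests only and are never read by the mapping code.

**What the simulator does not emulate** — and hence what a green test does
not establish: sequencing and alignment errors, mapping-quality artifacts,
coverage heterogeneity (e.g. centromeric pile-ups, a known artifact source
in real density scans), crossover interference, segregation distortion, and
selfing-generation dynamics beyond the F2.  Green recovery tests mean the
statistics behave as designed under the stated genetic model, not that any
real dataset is free of artifacts.

# Measured operating characteristics

Two stated-world properties are *not* met, and the acceptance suite reports
them red rather than loosening thresholds (the numbers below are computed by
the suite itself):

* **Density recovery at 60 mutations.** With 60 mutations on 20 Mb
  (3/Mb) and 4 cM/Mb, retention after four backcrosses has a ~4-Mb
  half-width, so the 1-Mb window containing the causal site holds about
  `1 + Poisson(2.7)` homozygous EMS variants — structurally below the
  peak rule's absolute floor (count > 4) — and the survivor gradient is
  broad.  Measured: the top-ranked region contains the causal mutation in
  44/100 seeded runs (and whenever it does, the causal gene is among the
  candidates, 44/44).  At denser mutation loads the workflow is reliable
  (the integration test recovers the causal gene at 37 mutations/Mb), but
  the 60-mutation world is genuinely underpowered for a ≥ 95% guarantee.
* **QTL-seq null calibration.** With 200 individuals and 10% tails each
  bulk holds 20 individuals, so under the null `sd(daf_wma) ≈ 0.10` and the
  0.25 threshold sits at ~2.5σ: measured 90/100 null runs call zero
  regions.  Users running small bulks should raise `daf_min` or `min_run`,
  or read the dAF plots rather than the region list alone.

Recovery properties that are met: QTL-seq region covers the true QTL in
100/100 seeded runs (smoothed dAF ≥ 0.5 at the covering window in 99);
linkage scan contains the causal variant in its region in 100/100 runs;
oracle equivalences, annotation-translation agreement, simulator closed
forms and format round-trips are exact.

# Numerical and degenerate-input choices

* `σ` in the peak rule is the sample standard deviation over all windows;
  a uniform profile (σ = 0) can never qualify, by design.
* WMA at chromosome edges renormalizes the truncated kernel; a window with
  no defined neighbour in its kernel has undefined `daf_wma`.
* Region extremum ties (`which.max`) resolve to the leftmost window;
  region ranking ties keep genome order — both deterministic.
* Insertions are anchored at the VCF position: the affected interval used
  for element resolution is `[pos, pos + 1]`; deletions use the removed
  bases `[pos + 1, pos + len(ref) − 1]`.
* Quality filtering keeps records with `NA` quality: quality is advisory
  metadata from the caller's pipeline, absence is not evidence.
* The linkage and QTL-seq scans reuse the density window defaults
  (1 Mb / 0.5 Mb): the reference tool's values are unpublished, so one
  explicit, documented default serves all three scans.

# Limitations

Read alignment and variant calling are out of scope (the package consumes
VCFs); there are no p-values or confidence bands on peaks or dAF (regions
are threshold calls, deliberately); no centromere masking (use region
exclusion on the reported tables); no ploidy-aware genotype models; no HGVS
nomenclature; large insertions, microsatellites and rearrangements are
invisible to the short-read variant representation this package consumes.
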