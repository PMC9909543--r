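# bulkmapr

Mapping-by-sequencing workflows for bulked segregant and backcross designs,
in tidy R.

Forward-genetic screens end with the same question: which variant causes the
phenotype?  When the mutant is sequenced as a pool of selected segregants,
the answer is written in allele-frequency and variant-density patterns along
the genome.  `bulkmapr` implements the three standard pooled-mapping
strategies plus a variant-effect analyzer, all working from plain FASTA,
GFF3 and VCF files:

* **Variant density mapping** — a mutant is recurrently backcrossed (3–6×)
  to its reference strain; mutations unlinked to the causal site are lost at
  rate 1/2 per backcross while linked ones are retained, so the causal
  region shows up as a cluster of homozygous EMS-type variants.  Windowed
  counts of the test-specific, homozygous, EMS-type and homozygous-EMS
  sublists are scanned for windows whose count exceeds
  `max(min_count, μ + z·σ)`; qualifying windows merge into ranked regions of
  interest and in-gene variants inside them become candidates.
* **QTL-seq** — two bulks with opposite phenotypes are drawn from one
  segregating F2 population.  For every SNP present and segregating
  (0 < af < 1) in *both* pools, the allele-frequency difference
  dAF = af₁ − af₂ is averaged per sliding window, smoothed with a weighted
  moving average (kernel 1 2 3 2 1), and sign-constant runs with
  |dAF_WMA| ≥ 0.25 are called as candidate QTL regions — with or without a
  structural annotation.
* **Allele-frequency linkage mapping** — one bulk of phenotypically mutant
  F2 individuals; the causal region is where the test-specific allele
  frequency approaches fixation (af_WMA ≥ 0.9).
* **Variant analyzer** — per variant × transcript: affected gene element,
  codon and amino-acid change (strand- and phase-aware, standard genetic
  code), frameshift/in-frame calls for indels, reference flanks, and a
  deterministic genotyping primer pair (Wallace-rule Tm = 2(A+T) + 4(G+C),
  GC 40–60%, |ΔTm| ≤ 3 °C, product 150–800 bp spanning the variant).

A mapping-population simulator (`simulate_genome()`,
`simulate_backcross()`, `simulate_qtlseq()`, `simulate_f2_bulk()`) generates
complete synthetic experiments — EMS mutagenesis at G/C sites, recombination
under the Haldane map function r = (1 − e^(−2d))/2, phenotypic selection of
bulks, binomial read-depth sampling — and writes standard files, so every
workflow can be exercised and tested without external data.

## Worked example

Simulate a recurrent-backcross experiment (20-Mb genome, 60 EMS mutations,
4 backcrosses, 25× depth) and map the causal mutation:

```r
library(bulkmapr)

cfg  <- sim_config("backcross", seed = 42)
sim  <- simulate_genome(cfg)
bc   <- simulate_backcross(cfg, sim$genome, sim$genes)
scan <- dens_scan(bc$test, bc$control, sim$genome, sim$genes)
scan
#> <density_scan>
#>   122 test variants, 22 test-specific, 20 homozygous EMS
#>   1 region(s) of interest, 1 candidate variant(s)
#>   top region: chr1:500001-2000000 (peak count 6)

tidy(scan)
#> # A tibble: 1 × 5
#>   chrom  start     end peak_count basis_category
#>   <chr>  <int>   <int>      <dbl> <chr>
#> 1 chr1  500001 2000000          6 hom_ems

scan$candidates[, c("chrom", "pos", "ref", "alt", "af", "vclass", "gene_id")]
#> # A tibble: 1 × 7
#>   chrom     pos ref   alt      af vclass gene_id
#>   <chr>   <int> <chr> <chr> <dbl> <chr>  <chr>
#> 1 chr1  1078010 G     A         1 snp    gene_chr1_0044
```

Of the 122 variants in the test pool, 22 are test-specific after control
subtraction and 20 are homozygous EMS-type.  They cluster on chr1, where one
region exceeds the density threshold; the single in-gene candidate is the
true simulated causal mutation (`bc$causal`: chr1:1078010 G>A in
`gene_chr1_0044`).  `autoplot(scan)` draws the per-chromosome density
panels; `qtl_scan()` and `linkage_scan()` follow the same pattern for the
other two designs, and `analyze_set()` produces the full per-variant report
with effects, primers and flanks.

File-based runs (`run_dens()`, `run_qtlseq()`, `run_linkage()`,
`run_annotate()`, `run_simulate()`) read/write standard formats into a run
directory with TSV reports, VCFs, SVG plots, a resolved `config.json` and a
plain-text summary.  The same workflows are available from the shell via
`exec/mapseq <workflow> [--flags]`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the three mapping workflows end-to-end on freshly simulated
populations under the given seed (density, QTL-seq, linkage, plus the
variant analyzer over the density candidates) and writes the JSON report.

## Method details

See the methods vignette (`vignettes/mapping-by-sequencing.Rmd`) for the
models, the default parameter choices and their rationale, what the
simulator does and does not emulate, and known limitations.
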