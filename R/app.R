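# Workflow runners: read standard files, execute a scan, and write a run
# directory with TSV/VCF reports, SVG plots, the resolved configuration and
# a plain-text summary.  Inputs are never mutated; outputs are confined to
# the run directory.

save_plot <- function(p, path, width = 9, height = 6) {
  ok <- tryCatch({
    if (isTRUE(capabilities("cairo"))) {
      grDevices::svg(path, width = width, height = height)
    } else {
      path <- sub("\\.svg$", ".pdf", path)
      grDevices::pdf(path, width = width, height = height)
    }
    print(p)
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    warn(paste0("plot not written: ", conditionMessage(e)))
    FALSE
  })
  if (ok) path else NA_character_
}

write_run_config <- function(dir, config) {
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

write_summary <- function(dir, lines) {
  writeLines(lines, file.path(dir, "summary.txt"))
}

prep_run <- function(out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  out
}

read_inputs <- function(genome_path, gff_path = NULL, warn_no_gff = TRUE) {
  genome <- read_genome(genome_path)
  genes <- NULL
  if (!is.null(gff_path)) {
    genes <- read_gff(gff_path, genome)
  } else if (warn_no_gff) {
    warn("no structural annotation (GFF3) supplied")
  }
  list(genome = genome, genes = genes)
}

#' Run the variant-density mapping workflow on files
#'
#' @param genome_path Reference genome FASTA.
#' @param test_vcf Test-sample VCF (allele depths required).
#' @param control_vcf Optional control VCF (key only is used); omitting the
#'   control is allowed but logged as unadvisable.
#' @param gff_path Optional GFF3; without it no candidates are extracted.
#' @param out Output directory.
#' @param spec,cfg,category,z,min_count,by_position Passed to [dens_scan()].
#' @return The `density_scan`, invisibly; reports are written under `out`.
#' @export
run_dens <- function(genome_path, test_vcf, control_vcf = NULL,
                     gff_path = NULL, out, spec = window_spec(),
                     cfg = filter_config(), category = "hom_ems", z = 2,
                     min_count = 4L, by_position = FALSE) {
  out <- prep_run(out)
  inp <- read_inputs(genome_path, gff_path)
  test <- read_vcf(test_vcf, genome = inp$genome)
  control <- NULL
  if (is.null(control_vcf)) {
    warn("running without a control sample is highly unadvisable for most mapping scenarios")
  } else {
    control <- read_vcf(control_vcf, genome = inp$genome)
  }
  scan <- dens_scan(test, control, inp$genome, inp$genes, spec, cfg,
                    category, z, min_count, by_position)
  write_report_tsv(as_tibble(scan$profile), file.path(out, "windows.tsv"))
  write_report_tsv(scan$regions, file.path(out, "regions.tsv"))
  write_report_tsv(scan$candidates, file.path(out, "candidates.tsv"))
  write_vcf(select(scan$candidates, -"gene_id"),
            file.path(out, "candidates.vcf"), inp$genome, "candidates")
  save_plot(autoplot(scan), file.path(out, "density.svg"))
  write_run_config(out, list(
    workflow = "dens", genome = genome_path, gff = gff_path,
    test = test_vcf, control = control_vcf,
    window_size = spec$size, window_step = spec$step,
    af_hom_min = cfg$af_hom_min, min_dp = cfg$min_dp,
    min_qual = cfg$min_qual, report_classes = cfg$report_classes,
    category = category, z = z, min_count = min_count,
    by_position = by_position, out = out))
  g <- glance(scan)
  write_summary(out, c(
    "variant density mapping",
    sprintf("test variants: %d; test-specific: %d; homozygous EMS: %d",
            g$n_test, g$n_test_specific, g$n_hom_ems),
    sprintf("regions of interest: %d; candidate variants: %d",
            g$n_regions, g$n_candidates),
    if (nrow(scan$regions)) {
      sprintf("top region: %s:%d-%d (peak count %d)",
              g$top_chrom, g$top_start, g$top_end,
              as.integer(scan$regions$peak_count[1]))
    } else "no region of interest called",
    if (nrow(scan$candidates)) {
      paste("candidate genes:",
            paste(unique(scan$candidates$gene_id), collapse = ", "))
    } else "no candidates"
  ))
  invisible(scan)
}

#' Run the QTL-seq mapping workflow on files
#'
#' @param genome_path Reference genome FASTA.
#' @param pool1_vcf,pool2_vcf VCFs of the two opposite bulks.
#' @param gff_path Optional GFF3; without it regions are still reported but
#'   gene identification is unavailable.
#' @param out Output directory.
#' @param spec,min_dp,snp_only,weights,daf_min,min_run Passed to
#'   [qtl_scan()].
#' @return The `qtl_scan`, invisibly.
#' @export
run_qtlseq <- function(genome_path, pool1_vcf, pool2_vcf, gff_path = NULL,
                       out, spec = window_spec(), min_dp = 5L,
                       snp_only = TRUE, weights = c(1, 2, 3, 2, 1),
                       daf_min = 0.25, min_run = 3L) {
  out <- prep_run(out)
  inp <- read_inputs(genome_path, gff_path, warn_no_gff = FALSE)
  if (is.null(gff_path)) {
    warn("no GFF3: candidate regions will be reported without gene annotation")
  }
  pool1 <- read_vcf(pool1_vcf, genome = inp$genome)
  pool2 <- read_vcf(pool2_vcf, genome = inp$genome)
  scan <- qtl_scan(pool1, pool2, inp$genome, inp$genes, spec, min_dp,
                   snp_only, weights, daf_min, min_run)
  write_report_tsv(as_tibble(scan$profile), file.path(out, "windows.tsv"))
  write_report_tsv(scan$regions, file.path(out, "regions.tsv"))
  write_report_tsv(scan$candidates, file.path(out, "candidates.tsv"))
  save_plot(autoplot(scan), file.path(out, "daf.svg"))
  write_run_config(out, list(
    workflow = "qtlseq", genome = genome_path, gff = gff_path,
    pool1 = pool1_vcf, pool2 = pool2_vcf,
    window_size = spec$size, window_step = spec$step, min_dp = min_dp,
    snp_only = snp_only, weights = weights, daf_min = daf_min,
    min_run = min_run, out = out))
  g <- glance(scan)
  write_summary(out, c(
    "QTL-seq mapping",
    sprintf("mapping variants: %d", g$n_mapping_variants),
    sprintf("QTL regions: %d; candidate variants: %d",
            g$n_regions, g$n_candidates),
    if (nrow(scan$regions)) {
      r <- scan$regions[1, ]
      sprintf("top region: %s:%d-%d (sign %s, extremum %.3f)",
              r$chrom, r$start, r$end, r$sign, r$extremum)
    } else "no QTL region called"
  ))
  invisible(scan)
}

#' Run the allele-frequency linkage workflow on files
#'
#' @param genome_path Reference genome FASTA.
#' @param test_vcf Mutant-bulk VCF (allele depths required).
#' @param control_vcf Optional control VCF.
#' @param gff_path Optional GFF3.
#' @param out Output directory.
#' @param ... Passed to [linkage_scan()].
#' @return The `linkage_scan`, invisibly.
#' @export
run_linkage <- function(genome_path, test_vcf, control_vcf = NULL,
                        gff_path = NULL, out, ...) {
  out <- prep_run(out)
  inp <- read_inputs(genome_path, gff_path)
  test <- read_vcf(test_vcf, genome = inp$genome)
  control <- NULL
  if (is.null(control_vcf)) {
    warn("running without a control sample is highly unadvisable for most mapping scenarios")
  } else {
    control <- read_vcf(control_vcf, genome = inp$genome)
  }
  scan <- linkage_scan(test, control, inp$genome, genes = inp$genes, ...)
  write_report_tsv(as_tibble(scan$profile), file.path(out, "windows.tsv"))
  write_report_tsv(scan$regions, file.path(out, "regions.tsv"))
  write_report_tsv(scan$candidates, file.path(out, "candidates.tsv"))
  save_plot(autoplot(scan), file.path(out, "af.svg"))
  write_run_config(out, list(
    workflow = "linkage", genome = genome_path, gff = gff_path,
    test = test_vcf, control = control_vcf, out = out))
  g <- glance(scan)
  write_summary(out, c(
    "allele-frequency linkage mapping",
    sprintf("test-specific variants: %d", g$n_test_specific),
    sprintf("regions: %d; candidates: %d", g$n_regions, g$n_candidates)
  ))
  invisible(scan)
}

#' Run the variant analyzer on files
#'
#' @param genome_path Reference genome FASTA.
#' @param test_vcf VCF of variants to annotate.
#' @param gff_path Optional GFF3.
#' @param functional_tsv Optional two-column functional-annotation TSV.
#' @param out Output directory.
#' @param ... Passed to [analyze_set()].
#' @return The candidate-record tibble, invisibly.
#' @export
run_annotate <- function(genome_path, test_vcf, gff_path = NULL,
                         functional_tsv = NULL, out, ...) {
  out <- prep_run(out)
  inp <- read_inputs(genome_path, gff_path)
  v <- read_vcf(test_vcf, genome = inp$genome)
  fmap <- if (!is.null(functional_tsv)) read_functional_map(functional_tsv)
  rec <- analyze_set(v, inp$genes %||% empty_gene_models(), inp$genome,
                     functional_map = fmap, ...)
  write_report_tsv(rec, file.path(out, "variant_report.tsv"))
  write_run_config(out, list(
    workflow = "annotate", genome = genome_path, gff = gff_path,
    test = test_vcf, functional = functional_tsv, out = out))
  write_summary(out, c(
    "variant analyzer",
    sprintf("variants: %d; report rows (variant x transcript): %d",
            nrow(v), nrow(rec))
  ))
  invisible(rec)
}

#' Run the population simulator and write standard files
#'
#' @param scenario `"backcross"`, `"qtlseq"` or `"f2"`.
#' @param seed Integer seed.
#' @param out Output directory (genome, annotation, VCFs, truth TSV).
#' @param ... Overrides forwarded to [sim_config()].
#' @return The simulation result list, invisibly.
#' @export
run_simulate <- function(scenario, seed, out, ...) {
  out <- prep_run(out)
  cfg <- sim_config(scenario = scenario, seed = seed, ...)
  sim <- simulate_genome(cfg, dir = out)
  res <- switch(scenario,
    backcross = simulate_backcross(cfg, sim$genome, sim$genes, dir = out),
    f2 = simulate_f2_bulk(cfg, sim$genome, sim$genes, dir = out),
    qtlseq = simulate_qtlseq(cfg, sim$genome, dir = out)
  )
  write_run_config(out, c(list(workflow = "simulate"),
                          unclass(cfg)[!vapply(unclass(cfg), is.null,
                                               logical(1))]))
  invisible(c(sim, res))
}
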