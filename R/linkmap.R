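# Simplified allele-frequency linkage mapping for one mutant bulk: locate
# the genomic region where test-specific variant allele frequency approaches
# fixation under phenotypic selection.

#' Windowed allele-frequency profile
#'
#' Mean test-specific allele frequency per sliding window, with the same
#' empty-window bridging as the dAF profile.
#'
#' @param v Variant tibble with defined `af`.
#' @param genome A genome.
#' @param spec A [window_spec()].
#' @return A window tibble with `n_variants`, `af_mean`, class `af_profile`.
#' @export
window_af <- function(v, genome, spec = window_spec()) {
  if (anyNA(v$af)) abort("linkage scan requires defined allele frequencies")
  prof <- window_mean(v, v$af, genome, spec) |> rename(af_mean = "mean")
  class(prof) <- c("af_profile", class(prof))
  prof
}

#' Allele-frequency linkage scan of one mutant bulk
#'
#' Pipeline: control subtraction, class/quality filtering, per-window mean
#' allele frequency, weighted-moving-average smoothing (same kernel as the
#' QTL-seq scan), then the region of interest is the maximal run of at least
#' `min_run` windows with `af_wma >= af_peak_min`.  Candidates are in-region,
#' in-gene variants with `af >= cfg$af_hom_min`.  The threshold default 0.9
#' (not 1.0) tolerates the phenotyping errors to which linkage mapping is
#' most sensitive.
#'
#' @param test Test-bulk variant tibble (defined af).
#' @param control Optional control variant tibble.
#' @param genome A genome.
#' @param spec A [window_spec()].
#' @param genes Optional gene models (no candidates without them).
#' @param cfg A [filter_config()].
#' @param af_peak_min Fixation threshold on the smoothed profile.
#' @param min_run Minimum run length in windows.
#' @param weights Smoothing kernel, as in [wma_smooth()].
#' @param by_position Position-only control subtraction.
#' @return An object of class `linkage_scan`: a list with `profile`,
#'   `regions`, `candidates`, and the parameters used.
#' @export
linkage_scan <- function(test, control = NULL, genome, spec = window_spec(),
                         genes = NULL, cfg = filter_config(),
                         af_peak_min = 0.9, min_run = 2L,
                         weights = c(1, 2, 3, 2, 1), by_position = FALSE) {
  ts <- subtract_control(test, control, by_position = by_position)
  ts <- filter_qual(filter_by_class(ts, cfg), cfg)
  profile <- wma_smooth(window_af(ts, genome, spec), weights)
  regions <- call_qtl_regions(profile, daf_min = af_peak_min,
                              min_run = min_run) |>
    filter(.data$sign == "+") |>
    select(-"sign")
  if (nrow(regions) == 0L) {
    warn(sprintf("no window reaches af_wma >= %g; no region called",
                 af_peak_min))
  }
  candidates <- mutate(ts[0, ], gene_id = character())
  if (nrow(regions) > 0L && !is.null(genes) && nrow(genes) > 0L) {
    hom <- filter(ts, .data$af >= cfg$af_hom_min)
    candidates <- extract_candidates(regions, hom, genes, cfg)
  }
  structure(
    list(profile = profile, regions = regions, candidates = candidates,
         n_test_specific = nrow(ts),
         params = list(spec = spec, cfg = cfg, af_peak_min = af_peak_min,
                       min_run = min_run, weights = weights)),
    class = "linkage_scan"
  )
}
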