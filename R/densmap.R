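# Variant-density mapping: windowed counts of the filtered variant
# categories, high-density peak detection, and candidate extraction.

#' Windowed variant-density profile
#'
#' Builds the category sublists of the density workflow from a test and an
#' optional control sample, then counts each category per sliding window:
#' `all` (every test variant), `test_specific` (after control subtraction),
#' `hom` (homozygous by allele-frequency threshold), `ems` (EMS-type), and
#' `hom_ems` (intersection of the last two).
#'
#' @param test Test-sample variant tibble (must carry defined allele
#'   frequencies for the homozygosity categories).
#' @param control Optional control variant tibble (only the key is needed).
#' @param genome A genome.
#' @param spec A [window_spec()].
#' @param cfg A [filter_config()].
#' @param by_position Position-only control subtraction (see
#'   [subtract_control()]).
#' @return A tibble of windows with columns `n_all, n_test_specific, n_hom,
#'   n_ems, n_hom_ems`, with class `density_profile`.
#' @export
density_profile <- function(test, control = NULL, genome,
                            spec = window_spec(), cfg = filter_config(),
                            by_position = FALSE) {
  ts <- subtract_control(test, control, by_position = by_position)
  ts <- filter_qual(ts, cfg)
  hom <- filter_homozygous(ts, cfg)
  ems <- filter_ems(ts)
  hom_ems <- intersect_variants(hom, ems)
  prof <- bin_counts(test, genome, spec) |> rename(n_all = "n")
  prof$n_test_specific <- bin_counts(ts, genome, spec)$n
  prof$n_hom <- bin_counts(hom, genome, spec)$n
  prof$n_ems <- bin_counts(ems, genome, spec)$n
  prof$n_hom_ems <- bin_counts(hom_ems, genome, spec)$n
  attr(prof, "sets") <- list(test_specific = ts, hom = hom, ems = ems,
                             hom_ems = hom_ems)
  class(prof) <- c("density_profile", class(prof))
  prof
}

#' Detect high-density variant peaks
#'
#' A window qualifies when its count strictly exceeds
#' `max(min_count, mu + z * sigma)`, where `mu` and `sigma` are the mean and
#' standard deviation of the category's counts over all windows genome-wide.
#' Overlapping or adjacent qualifying windows are merged into one region of
#' interest; regions are ranked by their maximal window count.
#'
#' @param profile A [density_profile()] (or any window tibble with an
#'   `n_<category>` column).
#' @param category One of `"hom_ems"` (default: the final sublist of the
#'   density workflow), `"hom"`, `"ems"`, `"test_specific"`, `"all"`.
#' @param z Number of standard deviations above the genome-wide mean.
#' @param min_count Absolute floor preventing spurious calls on near-empty
#'   genomes.
#' @return A tibble `chrom, start, end, peak_count, basis_category`, sorted
#'   by `peak_count` descending.
#' @export
detect_peaks <- function(profile, category = "hom_ems", z = 2,
                         min_count = 4L) {
  col <- paste0("n_", category)
  if (!col %in% names(profile)) abort(paste0("no such category: ", category))
  cnt <- profile[[col]]
  if (nrow(profile) == 0L) abort("empty profile")
  thr <- max(min_count, mean(cnt) + z * sd(cnt))
  qual <- which(cnt > thr)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  peak_count = integer(), basis_category = character())
  if (!length(qual)) return(empty)
  qw <- profile[qual, ]
  gr <- GenomicRanges::GRanges(qw$chrom, IRanges::IRanges(qw$start, qw$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  ov <- GenomicRanges::findOverlaps(gr, red)
  regions <- tibble(
    chrom = as.character(GenomeInfoDb::seqnames(red)),
    start = BiocGenerics::start(red),
    end = BiocGenerics::end(red)
  )
  regions$peak_count <- vapply(seq_len(nrow(regions)), function(r) {
    max(cnt[qual[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == r]]])
  }, numeric(1))
  regions$basis_category <- category
  arrange(regions, desc(.data$peak_count))
}

#' Extract candidate variants from regions of interest
#'
#' A variant is a candidate when it falls inside any region, overlaps any
#' gene span, and belongs to a reportable class.  With no annotation the
#' result is empty and flagged (`attr(., "no_annotation")`).
#'
#' @param regions Region tibble from [detect_peaks()].
#' @param v Variant tibble to draw candidates from.
#' @param genes Gene models from [read_gff()] (may be empty).
#' @param cfg A [filter_config()]; `report_classes` applies.
#' @return Candidate variant tibble with a `gene_id` column.
#' @export
extract_candidates <- function(regions, v, genes, cfg = filter_config()) {
  empty <- mutate(variant_tbl(), gene_id = character())
  if (is.null(genes) || nrow(genes) == 0L) {
    warn("no structural annotation: candidate list is empty")
    attr(empty, "no_annotation") <- TRUE
    return(empty)
  }
  if (nrow(regions) == 0L || nrow(v) == 0L) return(empty)
  v <- filter_by_class(v, cfg)
  if (nrow(v) == 0L) return(empty)
  vgr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start, regions$end))
  sp <- gene_spans(genes)
  ggr <- GenomicRanges::GRanges(sp$chrom, IRanges::IRanges(sp$start, sp$end))
  in_region <- GenomicRanges::countOverlaps(vgr, rgr) > 0L
  gh <- GenomicRanges::findOverlaps(vgr, ggr)
  gene_of <- tibble(p = S4Vectors::queryHits(gh),
                    gene_id = sp$gene_id[S4Vectors::subjectHits(gh)]) |>
    group_by(.data$p) |>
    summarise(gene_id = paste(.data$gene_id, collapse = ";"),
              .groups = "drop")
  v$gene_id <- NA_character_
  v$gene_id[gene_of$p] <- gene_of$gene_id
  filter(v, in_region, !is.na(.data$gene_id))
}
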