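# High-level scan objects tying the workflows together, with broom-style
# tidy()/glance() accessors and ggplot2 autoplot() panels.

#' Variant-density mapping scan
#'
#' Runs the full density workflow: control subtraction, the homozygous /
#' EMS-type / homozygous-EMS sublists, windowed counts, peak detection, and
#' in-gene candidate extraction from the regions of interest.
#'
#' @param test,control Variant tibbles (control optional).
#' @param genome A genome.
#' @param genes Optional gene models; without them candidates are empty.
#' @param spec A [window_spec()].
#' @param cfg A [filter_config()].
#' @param category Peak-detection category (default `"hom_ems"`).
#' @param z,min_count Peak rule, see [detect_peaks()].
#' @param by_position Position-only control subtraction.
#' @return An object of class `density_scan` with `profile`, `regions`,
#'   `candidates`.
#' @export
dens_scan <- function(test, control = NULL, genome, genes = NULL,
                      spec = window_spec(), cfg = filter_config(),
                      category = "hom_ems", z = 2, min_count = 4L,
                      by_position = FALSE) {
  profile <- density_profile(test, control, genome, spec, cfg, by_position)
  regions <- detect_peaks(profile, category, z, min_count)
  sets <- attr(profile, "sets")
  candidates <- if (!is.null(genes) && nrow(genes) > 0L) {
    extract_candidates(regions, sets$hom, genes, cfg)
  } else {
    if (nrow(regions)) warn("no structural annotation: candidate list is empty")
    mutate(variant_tbl(), gene_id = character())
  }
  structure(
    list(profile = profile, regions = regions, candidates = candidates,
         n_test = nrow(test), n_test_specific = nrow(sets$test_specific),
         n_hom_ems = nrow(sets$hom_ems),
         params = list(spec = spec, cfg = cfg, category = category, z = z,
                       min_count = min_count)),
    class = "density_scan"
  )
}

#' QTL-seq mapping scan
#'
#' Runs the full QTL-seq workflow: mapping-variant selection from the two
#' bulks, windowed dAF, weighted-moving-average smoothing, region calling,
#' and candidate listing (annotation-free when `genes` is absent).
#'
#' @param pool1,pool2 Variant tibbles of the two opposite bulks.
#' @param genome A genome.
#' @param genes Optional gene models.
#' @param spec A [window_spec()].
#' @param min_dp,snp_only See [select_mapping_variants()].
#' @param weights Smoothing kernel.
#' @param daf_min,min_run Region-calling rule, see [call_qtl_regions()].
#' @return An object of class `qtl_scan` with `mvars`, `profile`,
#'   `regions`, `candidates`.
#' @export
qtl_scan <- function(pool1, pool2, genome, genes = NULL,
                     spec = window_spec(), min_dp = 5L, snp_only = TRUE,
                     weights = c(1, 2, 3, 2, 1), daf_min = 0.25,
                     min_run = 3L) {
  mvars <- select_mapping_variants(pool1, pool2, min_dp, snp_only)
  profile <- wma_smooth(window_daf(mvars, genome, spec), weights)
  regions <- call_qtl_regions(profile, daf_min, min_run)
  candidates <- qtl_candidates(regions, mvars, genes)
  structure(
    list(mvars = mvars, profile = profile, regions = regions,
         candidates = candidates,
         params = list(spec = spec, min_dp = min_dp, snp_only = snp_only,
                       weights = weights, daf_min = daf_min,
                       min_run = min_run)),
    class = "qtl_scan"
  )
}

#' @export
tidy.density_scan <- function(x, ...) as_tibble(x$regions)
#' @export
tidy.qtl_scan <- function(x, ...) as_tibble(x$regions)
#' @export
tidy.linkage_scan <- function(x, ...) as_tibble(x$regions)

#' @export
glance.density_scan <- function(x, ...) {
  tibble(n_test = x$n_test, n_test_specific = x$n_test_specific,
         n_hom_ems = x$n_hom_ems, n_regions = nrow(x$regions),
         n_candidates = nrow(x$candidates),
         top_chrom = if (nrow(x$regions)) x$regions$chrom[1] else NA_character_,
         top_start = if (nrow(x$regions)) x$regions$start[1] else NA_integer_,
         top_end = if (nrow(x$regions)) x$regions$end[1] else NA_integer_)
}

#' @export
glance.qtl_scan <- function(x, ...) {
  tibble(n_mapping_variants = nrow(x$mvars), n_regions = nrow(x$regions),
         n_candidates = nrow(x$candidates),
         max_abs_daf_wma = if (any(!is.na(x$profile$daf_wma))) {
           max(abs(x$profile$daf_wma), na.rm = TRUE)
         } else NA_real_)
}

#' @export
glance.linkage_scan <- function(x, ...) {
  tibble(n_test_specific = x$n_test_specific, n_regions = nrow(x$regions),
         n_candidates = nrow(x$candidates),
         max_af_wma = if (any(!is.na(x$profile$af_wma))) {
           max(x$profile$af_wma, na.rm = TRUE)
         } else NA_real_)
}

#' @export
print.density_scan <- function(x, ...) {
  cat("<density_scan>\n")
  cat(sprintf("  %d test variants, %d test-specific, %d homozygous EMS\n",
              x$n_test, x$n_test_specific, x$n_hom_ems))
  cat(sprintf("  %d region(s) of interest, %d candidate variant(s)\n",
              nrow(x$regions), nrow(x$candidates)))
  if (nrow(x$regions)) {
    r <- x$regions[1, ]
    cat(sprintf("  top region: %s:%d-%d (peak count %d)\n",
                r$chrom, r$start, r$end, as.integer(r$peak_count)))
  }
  invisible(x)
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat("<qtl_scan>\n")
  cat(sprintf("  %d mapping variants; %d QTL region(s), %d candidate(s)\n",
              nrow(x$mvars), nrow(x$regions), nrow(x$candidates)))
  if (nrow(x$regions)) {
    r <- x$regions[1, ]
    cat(sprintf("  top region: %s:%d-%d (sign %s, extremum %.2f)\n",
                r$chrom, r$start, r$end, r$sign, r$extremum))
  }
  invisible(x)
}

#' @export
print.linkage_scan <- function(x, ...) {
  cat("<linkage_scan>\n")
  cat(sprintf("  %d test-specific variants; %d region(s), %d candidate(s)\n",
              x$n_test_specific, nrow(x$regions), nrow(x$candidates)))
  if (nrow(x$regions)) {
    r <- x$regions[1, ]
    cat(sprintf("  region: %s:%d-%d (max af_wma %.2f)\n",
                r$chrom, r$start, r$end, r$extremum))
  }
  invisible(x)
}

shade_regions <- function(regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(NULL)
  ggplot2::geom_rect(
    data = regions,
    ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
    ymin = -Inf, ymax = Inf, fill = "pink", alpha = 0.4,
    inherit.aes = FALSE
  )
}

#' Plot a variant-density profile
#'
#' One panel per chromosome and category, window counts as bars (mirroring
#' the per-megabase density plots of the workflow's report).
#'
#' @param object A `density_profile`.
#' @param regions Optional regions to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_profile <- function(object, regions = NULL, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(dplyr::starts_with("n_"), names_to = "category",
                        names_prefix = "n_", values_to = "count") |>
    mutate(category = factor(.data$category,
                             c("all", "test_specific", "hom", "ems",
                               "hom_ems")))
  ggplot2::ggplot(long, ggplot2::aes((.data$start + .data$end) / 2e6,
                                     .data$count)) +
    shade_regions(regions) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::facet_grid(category ~ chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "variants per window") +
    ggplot2::theme_minimal()
}

#' Plot a dAF profile
#'
#' Window dAF means as points and the smoothed dAF_WMA as a line, faceted by
#' chromosome, with called regions shaded.
#'
#' @param object A `daf_profile` (smoothed or not).
#' @param regions Optional regions to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.daf_profile <- function(object, regions = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes((.data$start + .data$end) / 2e6,
                                        .data$daf_mean)) +
    shade_regions(regions) +
    ggplot2::geom_point(na.rm = TRUE, size = 0.8, colour = "grey30") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "position (Mb)", y = "dAF") +
    ggplot2::theme_minimal()
  if ("daf_wma" %in% names(df)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$daf_wma),
                                colour = "red", na.rm = TRUE)
  }
  p
}

#' Plot an allele-frequency profile
#'
#' @param object An `af_profile` from the linkage scan.
#' @param regions Optional regions to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.af_profile <- function(object, regions = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes((.data$start + .data$end) / 2e6,
                                        .data$af_mean)) +
    shade_regions(regions) +
    ggplot2::geom_point(na.rm = TRUE, size = 0.8, colour = "grey30") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (Mb)", y = "allele frequency") +
    ggplot2::theme_minimal()
  if ("af_wma" %in% names(df)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$af_wma),
                                colour = "red", na.rm = TRUE)
  }
  p
}

#' @export
autoplot.density_scan <- function(object, ...) {
  autoplot(object$profile, regions = object$regions, ...)
}
#' @export
autoplot.qtl_scan <- function(object, ...) {
  autoplot(object$profile, regions = object$regions, ...)
}
#' @export
autoplot.linkage_scan <- function(object, ...) {
  autoplot(object$profile, regions = object$regions, ...)
}
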