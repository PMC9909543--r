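# QTL-seq mapping: mapping-variant selection from two opposite bulks,
# per-window delta allele frequency (dAF), weighted-moving-average
# smoothing, and calling of regions under opposite linkage disequilibrium.

#' Select mapping variants shared by two bulks
#'
#' Keeps keys present in both pools with `0 < af < 1` and depth `>= min_dp`
#' in each.  This discards variants fixed in both bulks (differences of the
#' two parental lines against the reference genome, af = 1 in both) and
#' variants private to one pool.  The per-variant signal is
#' `daf = af1 - af2`.
#'
#' @param pool1,pool2 Variant tibbles for the two bulks (defined af
#'   required).
#' @param min_dp Minimum depth in each pool.
#' @param snp_only Restrict to SNPs (default); indels admitted when `FALSE`.
#' @return A tibble `chrom, pos, ref, alt, af1, af2, daf`.
#' @export
select_mapping_variants <- function(pool1, pool2, min_dp = 5L,
                                    snp_only = TRUE) {
  for (p in list(pool1, pool2)) {
    if (anyNA(p$af)) abort("mapping pools must carry defined allele frequencies")
  }
  if (snp_only) {
    pool1 <- filter(pool1, .data$vclass == "snp")
    pool2 <- filter(pool2, .data$vclass == "snp")
  }
  m <- inner_join(
    pool1 |> select(all_of(KEY), af1 = "af", rc1 = "ref_count",
                    ac1 = "alt_count"),
    pool2 |> select(all_of(KEY), af2 = "af", rc2 = "ref_count",
                    ac2 = "alt_count"),
    by = KEY
  )
  m |>
    filter(.data$af1 > 0, .data$af1 < 1, .data$af2 > 0, .data$af2 < 1,
           .data$rc1 + .data$ac1 >= min_dp, .data$rc2 + .data$ac2 >= min_dp) |>
    mutate(daf = .data$af1 - .data$af2) |>
    select(all_of(KEY), "af1", "af2", "daf")
}

#' Windowed dAF profile
#'
#' Arithmetic mean of `daf` over the mapping variants in each sliding
#' window.  Windows without variants carry `NA` (they are bridged by the
#' smoother, not zero-filled, to avoid biasing marker deserts toward 0).
#'
#' @param mvars Mapping variants from [select_mapping_variants()].
#' @param genome A genome.
#' @param spec A [window_spec()].
#' @return A tibble of windows with `n_variants`, `daf_mean`, class
#'   `daf_profile`.
#' @export
window_daf <- function(mvars, genome, spec = window_spec()) {
  prof <- window_mean(mvars, mvars$daf, genome, spec) |>
    rename(daf_mean = "mean")
  class(prof) <- c("daf_profile", class(prof))
  prof
}

#' Smooth a windowed profile by weighted moving average
#'
#' Per chromosome, each window receives the kernel-weighted average of the
#' defined window means in its neighborhood; weights are renormalized at
#' chromosome edges and across empty windows, so empty windows are bridged
#' rather than treated as zero.  The default triangular kernel
#' `(1, 2, 3, 2, 1)` is the minimal symmetric choice.
#'
#' @param profile A `daf_profile` from [window_daf()] (or an `af_profile`
#'   from the linkage scan).
#' @param weights Positive odd-length kernel.
#' @return The profile with a smoothed column (`daf_wma` or `af_wma`).
#' @export
wma_smooth <- function(profile, weights = c(1, 2, 3, 2, 1)) {
  value_col <- if ("daf_mean" %in% names(profile)) "daf_mean" else
    if ("af_mean" %in% names(profile)) "af_mean" else
      abort("profile has no daf_mean/af_mean column")
  out_col <- sub("_mean$", "_wma", value_col)
  profile |>
    group_by(.data$chrom) |>
    group_modify(~ {
      .x[[out_col]] <- wma_vec(.x[[value_col]], weights)
      .x
    }) |>
    ungroup() |>
    `class<-`(class(profile))
}

#' Call QTL regions from a smoothed dAF profile
#'
#' Scans each chromosome for maximal runs of at least `min_run` consecutive
#' defined windows with `|daf_wma| >= daf_min` and constant sign; each run
#' becomes one region spanning the first window start to the last window
#' end.  Empty (bridged) windows do not interrupt a run.
#'
#' @param profile A smoothed profile from [wma_smooth()].
#' @param daf_min Calling threshold on `|daf_wma|` (the operational meaning
#'   of "nonzero"; default 0.25, stringent, aimed at major QTL).
#' @param min_run Minimum run length in windows.
#' @return A tibble `chrom, start, end, sign, extremum` (signed `daf_wma` of
#'   largest magnitude inside), ordered by `|extremum|` descending.
#' @export
call_qtl_regions <- function(profile, daf_min = 0.25, min_run = 3L) {
  wma_col <- if ("daf_wma" %in% names(profile)) "daf_wma" else "af_wma"
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  sign = character(), extremum = numeric(),
                  n_windows = integer())
  defined <- filter(as_tibble(profile), !is.na(.data[[wma_col]]))
  if (nrow(defined) == 0L) return(empty)
  regions <- list()
  for (cn in unique(defined$chrom)) {
    d <- defined[defined$chrom == cn, ]
    x <- d[[wma_col]]
    state <- ifelse(abs(x) >= daf_min, ifelse(x >= 0, 1L, -1L), 0L)
    if (!any(state != 0L)) next
    rl <- rle(state)
    hi <- cumsum(rl$lengths)
    lo <- hi - rl$lengths + 1L
    for (k in seq_along(rl$values)) {
      if (rl$values[k] == 0L || rl$lengths[k] < min_run) next
      seg <- lo[k]:hi[k]
      xi <- x[seg]
      regions[[length(regions) + 1L]] <- tibble(
        chrom = cn, start = min(d$start[seg]), end = max(d$end[seg]),
        sign = if (rl$values[k] > 0L) "+" else "-",
        extremum = xi[which.max(abs(xi))], n_windows = length(seg)
      )
    }
  }
  if (!length(regions)) return(empty)
  arrange(list_rbind(regions), desc(abs(.data$extremum)))
}

#' Candidate variants and genes inside called QTL regions
#'
#' With gene models, reports in-region mapping variants that overlap a gene
#' span (annotated downstream by the variant analyzer); without annotation
#' it reports every in-region variant with empty gene fields, as the
#' annotation-free QTL-seq mode prescribes.
#'
#' @param regions Regions from [call_qtl_regions()].
#' @param mvars Mapping variants.
#' @param genes Optional gene models.
#' @return Tibble of in-region variants with a `gene_id` column (`NA`
#'   without annotation).
#' @export
qtl_candidates <- function(regions, mvars, genes = NULL) {
  if (nrow(regions) == 0L || nrow(mvars) == 0L) {
    return(mutate(mvars[0, ], gene_id = character()))
  }
  vgr <- GenomicRanges::GRanges(mvars$chrom,
                                IRanges::IRanges(mvars$pos, mvars$pos))
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start, regions$end))
  inside <- GenomicRanges::countOverlaps(vgr, rgr) > 0L
  out <- mvars[inside, ]
  out$gene_id <- NA_character_
  if (!is.null(genes) && nrow(genes) > 0L && nrow(out) > 0L) {
    sp <- gene_spans(genes)
    ggr <- GenomicRanges::GRanges(sp$chrom,
                                  IRanges::IRanges(sp$start, sp$end))
    ogr <- GenomicRanges::GRanges(out$chrom,
                                  IRanges::IRanges(out$pos, out$pos))
    gh <- GenomicRanges::findOverlaps(ogr, ggr)
    ann <- tibble(p = S4Vectors::queryHits(gh),
                  gene_id = sp$gene_id[S4Vectors::subjectHits(gh)]) |>
      group_by(.data$p) |>
      summarise(gene_id = paste(.data$gene_id, collapse = ";"),
                .groups = "drop")
    out$gene_id[ann$p] <- ann$gene_id
    out <- filter(out, !is.na(.data$gene_id))
  }
  out
}
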