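# Variant classification, filtering and set algebra shared by all mapping
# workflows.  Sets are plain variant tibbles keyed by (chrom, pos, ref, alt).

KEY <- c("chrom", "pos", "ref", "alt")

#' Filtering configuration
#'
#' @param af_hom_min Minimum allele frequency to call a pooled site
#'   homozygous (must exceed 0.5; default 0.85, chosen to absorb binomial
#'   sampling noise at a read depth of ~25x).
#' @param min_dp Minimum informative read depth (`ref_count + alt_count`).
#' @param min_qual Minimum variant quality (records with `NA` quality pass).
#' @param report_classes Variant class labels eligible for reporting, a
#'   subset of `c("ems", "non_ems_snp", "insertion", "deletion")`.
#' @return A list with class `filter_config`.
#' @export
filter_config <- function(af_hom_min = 0.85, min_dp = 5L, min_qual = 20,
                          report_classes = c("ems", "non_ems_snp",
                                             "insertion", "deletion")) {
  if (af_hom_min <= 0.5 || af_hom_min > 1) {
    abort("af_hom_min must be in (0.5, 1]")
  }
  if (min_dp < 0) abort("min_dp must be >= 0")
  bad <- setdiff(report_classes,
                 c("ems", "non_ems_snp", "insertion", "deletion"))
  if (length(bad)) abort(paste0("unknown report class: ", bad[1]))
  structure(list(af_hom_min = af_hom_min, min_dp = as.integer(min_dp),
                 min_qual = min_qual, report_classes = report_classes),
            class = "filter_config")
}

#' Is a variant an EMS-type mutation?
#'
#' EMS induces G>A transitions; on a forward-strand VCF the reverse-strand
#' event appears as C>T, so both orientations count.  Non-SNP input is
#' `FALSE`, not an error.
#'
#' @param ref,alt Allele character vectors.
#' @return Logical vector.
#' @export
classify_ems <- function(ref, alt) {
  (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

#' Class label of each record for reporting
#'
#' SNPs split into `ems` / `non_ems_snp`; indels keep their `vclass`.
#'
#' @param v A variant tibble.
#' @return Character vector parallel to rows of `v`.
#' @export
class_label <- function(v) {
  dplyr::case_when(
    v$vclass == "snp" & classify_ems(v$ref, v$alt) ~ "ems",
    v$vclass == "snp" ~ "non_ems_snp",
    TRUE ~ v$vclass
  )
}

#' Subtract control variants from a test set
#'
#' Removes test records whose key is present in the control set.  The
#' default is allele-aware (same position with a different alt allele is
#' retained); `by_position = TRUE` removes any test record at a control
#' position, for controls compiled from pooled samples of mixed genotypes.
#'
#' @param test,control Variant tibbles; `control` may be `NULL` or empty
#'   (no-control mode).
#' @param by_position Match on `(chrom, pos)` only.
#' @return The test-specific variant tibble.
#' @export
subtract_control <- function(test, control = NULL, by_position = FALSE) {
  if (is.null(control) || nrow(control) == 0L) return(test)
  by <- if (by_position) c("chrom", "pos") else KEY
  anti_join(test, control, by = by)
}

#' Keep homozygous records of a pooled sample
#'
#' Retains records with `af >= af_hom_min` and depth `>= min_dp`.  Any
#' record with undefined allele frequency is a hard error (the caller fed a
#' countless VCF into an af-consuming workflow).
#'
#' @param v A variant tibble.
#' @param cfg A [filter_config()].
#' @return Filtered variant tibble.
#' @export
filter_homozygous <- function(v, cfg = filter_config()) {
  if (anyNA(v$af)) {
    bad <- v[is.na(v$af), ][1, ]
    abort(sprintf("undefined allele frequency at %s:%d %s>%s",
                  bad$chrom, bad$pos, bad$ref, bad$alt))
  }
  filter(v, .data$af >= cfg$af_hom_min,
         .data$ref_count + .data$alt_count >= cfg$min_dp)
}

#' Keep EMS-type records
#' @param v A variant tibble.
#' @return Records where [classify_ems()] is true (SNPs only).
#' @export
filter_ems <- function(v) {
  filter(v, .data$vclass == "snp", classify_ems(.data$ref, .data$alt))
}

#' Intersect two variant sets
#'
#' Keys present in both sets; record fields (counts, quality) come from `a`.
#'
#' @param a,b Variant tibbles.
#' @return Variant tibble.
#' @export
intersect_variants <- function(a, b) {
  semi_join(a, b, by = KEY)
}

#' Keep records of the reportable classes
#'
#' @param v A variant tibble.
#' @param cfg A [filter_config()]; its `report_classes` decides which of
#'   `ems`, `non_ems_snp`, `insertion`, `deletion` survive.
#' @return Filtered variant tibble.
#' @export
filter_by_class <- function(v, cfg = filter_config()) {
  if (!length(cfg$report_classes)) abort("report_classes must not be empty")
  v[class_label(v) %in% cfg$report_classes, ]
}

#' Keep records meeting the quality cutoff
#'
#' Records with `NA` quality are retained (quality is advisory metadata from
#' the caller's variant-calling pipeline).
#'
#' @param v A variant tibble.
#' @param cfg A [filter_config()].
#' @return Filtered variant tibble.
#' @export
filter_qual <- function(v, cfg = filter_config()) {
  filter(v, is.na(.data$qual) | .data$qual >= cfg$min_qual)
}
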