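# Deterministic genotyping-primer design around a variant.  Melting
# temperature by the Wallace rule (2(A+T) + 4(G+C)); candidates are scanned
# outward from the variant so identical inputs always yield the same pair.

#' Wallace-rule melting temperature
#'
#' `Tm = 2 * (A+T) + 4 * (G+C)` in degrees Celsius; the simplest
#' deterministic rule, adequate for the short genotyping primers designed
#' here.
#'
#' @param seq Character vector of primer sequences.
#' @return Numeric Tm vector; `NA` for sequences containing N.
#' @export
wallace_tm <- function(seq) {
  vapply(seq, function(s) {
    if (grepl("[^ACGT]", s)) return(NA_real_)
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

gc_percent <- function(seq) {
  vapply(seq, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    100 * sum(b %in% c("G", "C")) / length(b)
  }, numeric(1), USE.NAMES = FALSE)
}

# first acceptable primer (GC in [gc_min, gc_max], no N) whose 3' end sits
# at each scanned distance; lengths tried 20 first, then outward
side_candidates <- function(chrom_seq, ends, left, lens, gc_min, gc_max) {
  n <- nchar(chrom_seq)
  out <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    e <- ends[i]
    for (len in lens) {
      if (left) {
        s1 <- e - len + 1L; s2 <- e
      } else {
        s1 <- e; s2 <- e + len - 1L
      }
      if (s1 < 1L || s2 > n) next
      pseq <- substr(chrom_seq, s1, s2)
      if (grepl("[^ACGT]", pseq)) next
      gc <- gc_percent(pseq)
      if (gc < gc_min || gc > gc_max) next
      seq5to3 <- if (left) pseq else revcomp(pseq)
      out[[i]] <- list(start = s1, end = s2, seq = seq5to3,
                       tm = wallace_tm(seq5to3))
      break
    }
  }
  purrr::compact(out)
}

#' Design a genotyping primer pair for a variant
#'
#' Deterministic outward scan: candidate primers (length 20, widened to
#' 18-24) are evaluated with their 3' ends from `min_dist` to `max_dist`
#' away from the variant on each side; a candidate must be N-free with GC%
#' in `[gc_min, gc_max]`.  The first left/right combination (ordered by
#' scan distance) whose melting temperatures differ by at most `tm_diff_max`
#' and whose product of 150-800 bp spans the variant is returned.
#'
#' @param v One-row variant tibble.
#' @param genome A genome.
#' @param min_dist,max_dist Scan range of the primer 3' end from the variant
#'   (bp).
#' @param lens Candidate primer lengths in preference order.
#' @param gc_min,gc_max Acceptable GC percentage.
#' @param tm_diff_max Maximum Tm difference between the primers.
#' @param product_min,product_max Acceptable product size (bp).
#' @return A one-row tibble `fwd_seq, rev_seq, fwd_start, rev_start,
#'   fwd_tm, rev_tm, product_size`; when no pair satisfies the constraints,
#'   an empty list carrying attribute `reason` (`"no_valid_primer"` when a
#'   whole side has no acceptable candidate, `"no_compatible_pair"`
#'   otherwise).
#' @export
design_primers <- function(v, genome, min_dist = 50L, max_dist = 400L,
                           lens = c(20L, 19L, 21L, 18L, 22L, 23L, 24L),
                           gc_min = 40, gc_max = 60, tm_diff_max = 3,
                           product_min = 150L, product_max = 800L) {
  chrom_seq <- as.character(genome[[v$chrom]])
  anchor_r <- v$pos + nchar(v$ref) - 1L
  dists <- seq.int(min_dist, max_dist)
  lc <- side_candidates(chrom_seq, v$pos - dists, left = TRUE, lens,
                        gc_min, gc_max)
  rc <- side_candidates(chrom_seq, anchor_r + dists, left = FALSE, lens,
                        gc_min, gc_max)
  if (!length(lc) || !length(rc)) {
    return(structure(list(), reason = "no_valid_primer"))
  }
  for (l in lc) {
    for (r in rc) {
      prod <- r$end - l$start + 1L
      if (prod < product_min || prod > product_max) next
      if (abs(l$tm - r$tm) > tm_diff_max) next
      return(tibble(fwd_seq = l$seq, rev_seq = r$seq,
                    fwd_start = l$start, rev_start = r$start,
                    fwd_tm = l$tm, rev_tm = r$tm,
                    product_size = prod))
    }
  }
  structure(list(), reason = "no_compatible_pair")
}
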