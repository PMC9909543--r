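# Sliding-window scaffolding shared by the density, QTL-seq and linkage
# scans.  Windows are 1-based closed, tile each chromosome at `step`, and the
# last window is clipped at the chromosome end.

#' Sliding-window specification
#'
#' @param size Window width in bp (default 1 Mb, the classic density-plot
#'   bin).
#' @param step Offset between window starts; defaults to `size / 2` so that
#'   windows overlap two-fold.  Must satisfy `0 < step <= size`.
#' @return A list with class `window_spec`.
#' @export
window_spec <- function(size = 1e6, step = size / 2) {
  size <- as.integer(round(size))
  step <- as.integer(round(step))
  if (step <= 0L || step > size) abort("window step must be in (0, size]")
  structure(list(size = size, step = step), class = "window_spec")
}

#' Tile a genome into sliding windows
#'
#' @param genome A genome from [read_genome()].
#' @param spec A [window_spec()].
#' @return A tibble `chrom, start, end, win` (per-chromosome window index),
#'   in canonical chromosome order.
#' @export
genome_windows <- function(genome, spec = window_spec()) {
  cl <- chrom_lengths(genome)
  out <- map(seq_len(nrow(cl)), function(i) {
    len <- cl$length[i]
    starts <- seq.int(1L, len, by = spec$step)
    tibble(chrom = cl$chrom[i], start = starts,
           end = pmin(starts + spec$size - 1L, len),
           win = seq_along(starts))
  })
  list_rbind(out)
}

# rows of `windows` hit by each point; returns tibble(w = window row index,
# p = point row index) using interval overlap on (chrom, pos)
window_hits <- function(windows, chrom, pos) {
  if (!length(pos)) return(tibble(w = integer(), p = integer()))
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start, windows$end))
  pgr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(pgr, wgr)
  tibble(w = S4Vectors::subjectHits(hits), p = S4Vectors::queryHits(hits))
}

#' Count variants per window
#'
#' Each variant is counted in every window whose `[start, end]` contains its
#' position.  Variants on chromosomes absent from the genome are skipped
#' with a warning.
#'
#' @param v A variant tibble.
#' @param genome A genome.
#' @param spec A [window_spec()].
#' @return [genome_windows()] plus a count column `n`.
#' @export
bin_counts <- function(v, genome, spec = window_spec()) {
  win <- genome_windows(genome, spec)
  unknown <- !v$chrom %in% names(genome)
  if (any(unknown)) {
    warn(sprintf("skipping %d variant(s) on unknown chromosomes",
                 sum(unknown)))
    v <- v[!unknown, ]
  }
  hits <- window_hits(win, v$chrom, v$pos)
  cnt <- hits |> count(.data$w)
  win$n <- 0L
  win$n[cnt$w] <- cnt$n
  win
}

# per-window mean of `value` (NA where no variant falls in the window)
window_mean <- function(v, value, genome, spec) {
  win <- genome_windows(genome, spec)
  v <- v[v$chrom %in% names(genome), ]
  hits <- window_hits(win, v$chrom, v$pos)
  agg <- hits |>
    mutate(val = value[.data$p]) |>
    group_by(.data$w) |>
    summarise(n_variants = dplyr::n(), m = mean(.data$val), .groups = "drop")
  win$n_variants <- 0L
  win$mean <- NA_real_
  win$n_variants[agg$w] <- agg$n_variants
  win$mean[agg$w] <- agg$m
  win
}

# weighted moving average of x with an odd symmetric-length kernel;
# NA entries are excluded from the support and weights renormalized
# (chromosome edges and empty windows).  Every position with at least one
# defined neighbor in its kernel gets a value, so empty windows are bridged.
wma_vec <- function(x, weights) {
  k <- length(weights)
  if (k %% 2L == 0L || any(weights <= 0)) {
    abort("weights must be a positive odd-length kernel")
  }
  half <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- (i - half):(i + half)
    keep <- idx >= 1L & idx <= n
    w <- weights[keep]
    xv <- x[idx[keep]]
    def <- !is.na(xv)
    if (!any(def)) return(NA_real_)
    sum(w[def] * xv[def]) / sum(w[def])
  }, numeric(1))
}
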