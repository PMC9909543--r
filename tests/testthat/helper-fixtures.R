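# Shared fixtures and independent brute-force oracles.  Everything is built
# in code; oracles deliberately avoid the package's own code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

make_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- names(seqs)
  g
}

# one-row transcript tibble matching read_gff()'s schema
mk_tx <- function(gene_id, chrom, strand, exons, cds = exons[0, ],
                  phase = NULL, incomplete = FALSE, note = NA_character_,
                  transcript_id = paste0(gene_id, ".t1")) {
  cds <- as.data.frame(cds)
  if (nrow(cds)) {
    cds$phase <- phase %||% rep(0L, nrow(cds))
  } else {
    cds$phase <- integer(0)
  }
  tibble::tibble(
    gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
    strand = strand, tx_start = min(exons$start), tx_end = max(exons$end),
    exons = list(tibble::as_tibble(exons)),
    cds = list(tibble::as_tibble(cds)),
    incomplete = incomplete, functional_note = note
  )
}

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random variant tibble on the given chromosome lengths
rand_variants <- function(n, chrom_lens = c(c1 = 1e6, c2 = 1e6)) {
  chrom <- sample(names(chrom_lens), n, replace = TRUE)
  pos <- vapply(chrom, function(cn) sample.int(chrom_lens[[cn]], 1L),
                integer(1))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(seq_len(n), function(i) {
    if (runif(1) < 0.8) sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
    else if (runif(1) < 0.5) paste0(ref[i], rand_bases(sample(1:3, 1)))
    else ref[i]
  }, character(1))
  del <- alt == ref
  ref[del] <- vapply(which(del), function(i) {
    paste0(ref[i], rand_bases(sample(1:3, 1)))
  }, character(1))
  dedup <- !duplicated(paste(chrom, pos))
  dp <- sample(5:60, n, replace = TRUE)
  ac <- rbinom(n, dp, runif(n))
  variant_tbl(chrom[dedup], pos[dedup], ref[dedup], alt[dedup],
              qual = round(runif(sum(dedup), 20, 99)),
              ref_count = (dp - ac)[dedup], alt_count = ac[dedup])
}

# ---- brute-force oracles -------------------------------------------------

# windows by direct enumeration (no IRanges)
bf_windows <- function(chrom_lens, size, step) {
  out <- list()
  for (cn in names(chrom_lens)) {
    s <- seq.int(1L, chrom_lens[[cn]], by = step)
    out[[cn]] <- data.frame(chrom = cn, start = s,
                            end = pmin(s + size - 1, chrom_lens[[cn]]))
  }
  do.call(rbind, out)
}

# count by looping over every window x variant pair
bf_bin_counts <- function(v, chrom_lens, size, step) {
  w <- bf_windows(chrom_lens, size, step)
  vapply(seq_len(nrow(w)), function(i) {
    sum(v$chrom == w$chrom[i] & v$pos >= w$start[i] & v$pos <= w$end[i])
  }, numeric(1))
}

bf_window_mean <- function(v, val, chrom_lens, size, step) {
  w <- bf_windows(chrom_lens, size, step)
  vapply(seq_len(nrow(w)), function(i) {
    sel <- v$chrom == w$chrom[i] & v$pos >= w$start[i] & v$pos <= w$end[i]
    if (!any(sel)) NA_real_ else mean(val[sel])
  }, numeric(1))
}

# WMA with NA-renormalization, straight loop per chromosome
bf_wma <- function(x, w) {
  half <- (length(w) - 1) / 2
  sapply(seq_along(x), function(i) {
    num <- 0; den <- 0
    for (j in -half:half) {
      k <- i + j
      if (k >= 1 && k <= length(x) && !is.na(x[k])) {
        num <- num + w[j + half + 1] * x[k]
        den <- den + w[j + half + 1]
      }
    }
    if (den == 0) NA_real_ else num / den
  })
}

# run enumeration for region calling on one chromosome's defined wma values
bf_runs <- function(x, thr, min_run) {
  runs <- list()
  i <- 1
  while (i <= length(x)) {
    if (!is.na(x[i]) && abs(x[i]) >= thr) {
      s <- sign(x[i])
      j <- i
      while (j < length(x) && !is.na(x[j + 1]) && abs(x[j + 1]) >= thr &&
             sign(x[j + 1]) == s) {
        j <- j + 1
      }
      if (j - i + 1 >= min_run) runs[[length(runs) + 1]] <- c(i, j, s)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

# ---- annotation oracle ---------------------------------------------------

# consequence of a CDS SNP by mutating the chromosome, re-extracting the CDS
# and translating both proteins with Biostrings
oracle_snp_consequence <- function(genome, tx, v) {
  chrom <- as.character(genome[[v$chrom]])
  stopifnot(substr(chrom, v$pos, v$pos) == v$ref)
  mut <- chrom
  substr(mut, v$pos, v$pos) <- v$alt
  extract_cds <- function(seqstr) {
    cd <- tx$cds[[1]]
    cd <- cd[order(cd$start), ]
    s <- paste(vapply(seq_len(nrow(cd)), function(k) {
      substr(seqstr, cd$start[k], cd$end[k])
    }, character(1)), collapse = "")
    if (tx$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      ph <- cd$phase[which.max(cd$end)]
    } else {
      ph <- cd$phase[which.min(cd$start)]
    }
    substr(s, ph + 1, nchar(s))
  }
  p_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(extract_cds(chrom)), no.init.codon = TRUE))
  p_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(extract_cds(mut)), no.init.codon = TRUE))
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  if (!length(d)) {
    return(list(consequence = "synonymous", aa_change = NULL))
  }
  i <- d[1]
  ra <- substr(p_ref, i, i)
  aa <- substr(p_alt, i, i)
  cons <- if (i == 1 && ra == "M") "start_loss"
  else if (aa == "*") "nonsense"
  else if (ra == "*") "stop_loss"
  else "missense"
  list(consequence = cons, aa_change = paste0(ra, i, aa))
}

# random single-gene fixture on a short chromosome, returning genome + tx;
# both strands, 1-3 exons, valid ATG..stop CDS written into the sequence
random_gene_fixture <- function() {
  n_ex <- sample(1:3, 1)
  ex_len <- sample(c(30, 60, 90), n_ex, replace = TRUE)
  in_len <- if (n_ex > 1) sample(20:60, n_ex - 1, replace = TRUE) else integer(0)
  g_start <- sample(20:60, 1)
  starts <- g_start + cumsum(c(0, head(ex_len, -1) + in_len))
  ends <- starts + ex_len - 1
  chrom_len <- max(ends) + sample(20:60, 1)
  strand <- sample(c("+", "-"), 1)
  chrom <- strsplit(rand_bases(chrom_len), "")[[1]]
  total <- sum(ex_len)
  n_cod <- total %/% 3
  cds_seq <- c("ATG",
               sample(setdiff(names(Biostrings::GENETIC_CODE),
                              c("TAA", "TAG", "TGA", "ATG")),
                      n_cod - 2, replace = TRUE),
               sample(c("TAA", "TAG", "TGA"), 1))
  cds_chars <- strsplit(paste(cds_seq, collapse = ""), "")[[1]]
  P <- unlist(Map(seq.int, starts, ends))
  P <- P[seq_len(n_cod * 3)]        # CDS occupies leading exonic positions
  tx_order <- if (strand == "+") P else rev(P)
  wr <- if (strand == "+") cds_chars else chartr("ACGT", "TGCA", cds_chars)
  chrom[tx_order] <- wr
  # CDS genomic intervals: runs of consecutive positions
  gp <- sort(P)
  brk <- c(0, which(diff(gp) != 1), length(gp))
  seg <- data.frame(start = gp[head(brk, -1) + 1], end = gp[brk[-1]])
  lens <- seg$end - seg$start + 1
  tx_lens <- if (strand == "+") lens else rev(lens)
  ph_tx <- (3 - cumsum(c(0, head(tx_lens, -1))) %% 3) %% 3
  seg$phase <- if (strand == "+") ph_tx else rev(ph_tx)
  genome <- make_genome(list(cX = paste(chrom, collapse = "")))
  tx <- mk_tx("gX", "cX", strand, data.frame(start = starts, end = ends),
              cds = seg[, c("start", "end")], phase = seg$phase)
  list(genome = genome, tx = tx, cds_positions = gp)
}
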