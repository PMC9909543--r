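# Variant analyzer: effect of SNPs and small indels on gene models and
# their products.  Codons are rebuilt from the CDS-concatenated sequence
# honoring strand and phase and translated with the standard genetic code.

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_base(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

translate_codon <- function(codon) {
  if (grepl("N", codon)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon])
}

# coding-strand base vector and genomic position vector of a transcript's
# CDS, in translation order, with the leading phase bases trimmed
cds_map <- function(tx, genome) {
  cd <- tx$cds[[1]]
  if (nrow(cd) == 0L) return(NULL)
  minus <- tx$strand == "-"
  ord <- if (minus) order(-cd$start) else order(cd$start)
  pos <- integer(0)
  bases <- character(0)
  for (k in ord) {
    seg <- strsplit(genome_seq(genome, tx$chrom, cd$start[k], cd$end[k]),
                    "", fixed = TRUE)[[1]]
    p <- cd$start[k]:cd$end[k]
    if (minus) {
      seg <- comp_base(rev(seg))
      p <- rev(p)
    }
    pos <- c(pos, p)
    bases <- c(bases, seg)
  }
  ph <- cd$phase[ord[1]]
  if (ph > 0L) {
    pos <- pos[-seq_len(ph)]
    bases <- bases[-seq_len(ph)]
  }
  list(pos = pos, bases = bases)
}

overlaps_any <- function(a1, a2, s, e) any(a1 <= e & a2 >= s)

annotation_row <- function(gene_id = NA_character_,
                           transcript_id = NA_character_,
                           element, codon_change = NA_character_,
                           aa_change = NA_character_, consequence,
                           flags = NA_character_) {
  tibble(gene_id = gene_id, transcript_id = transcript_id, element = element,
         codon_change = codon_change, aa_change = aa_change,
         consequence = consequence, flags = flags)
}

annotate_one_tx <- function(v, tx, genome) {
  # affected genomic interval: SNP = the base itself; deletion = the removed
  # bases (left-anchored VCF); insertion = the anchor base and its right
  # neighbor
  if (v$vclass == "snp") {
    a1 <- v$pos; a2 <- v$pos
  } else if (v$vclass == "deletion") {
    a1 <- v$pos + 1L; a2 <- v$pos + nchar(v$ref) - 1L
  } else {
    a1 <- v$pos; a2 <- v$pos + 1L
  }
  base <- annotation_row(gene_id = tx$gene_id,
                         transcript_id = tx$transcript_id,
                         element = "intergenic", consequence = "intergenic")
  ex <- tx$exons[[1]]
  cd <- tx$cds[[1]]
  in_cds <- nrow(cd) > 0L &&
    overlaps_any(a1, a2, cd$start, cd$end) |> any()
  if (in_cds) {
    base$element <- "cds"
    if (v$vclass != "snp") {
      shift <- abs(nchar(v$ref) - nchar(v$alt))
      base$consequence <- if (shift %% 3L == 0L) "inframe_indel" else
        "frameshift"
      return(base)
    }
    if (isTRUE(tx$incomplete)) {
      base$consequence <- NA_character_
      base$flags <- "incomplete_model"
      return(base)
    }
    map <- cds_map(tx, genome)
    idx <- match(v$pos, map$pos)
    if (is.na(idx)) {
      base$consequence <- NA_character_
      base$flags <- "phase_trimmed"
      return(base)
    }
    codon_i <- (idx - 1L) %/% 3L
    off <- (idx - 1L) %% 3L + 1L
    cidx <- codon_i * 3L + 1:3
    if (max(cidx) > length(map$bases)) {
      base$consequence <- NA_character_
      base$flags <- "partial_codon"
      return(base)
    }
    ref_codon <- map$bases[cidx]
    alt_codon <- ref_codon
    alt_codon[off] <- if (tx$strand == "-") comp_base(v$alt) else v$alt
    ref_c <- paste(ref_codon, collapse = "")
    alt_c <- paste(alt_codon, collapse = "")
    ref_aa <- translate_codon(ref_c)
    alt_aa <- translate_codon(alt_c)
    base$codon_change <- paste0(ref_c, ">", alt_c)
    base$aa_change <- paste0(ref_aa, codon_i + 1L, alt_aa)
    base$consequence <- dplyr::case_when(
      is.na(ref_aa) | is.na(alt_aa) ~ NA_character_,
      ref_aa == alt_aa ~ "synonymous",
      codon_i == 0L & ref_aa == "M" ~ "start_loss",
      alt_aa == "*" ~ "nonsense",
      ref_aa == "*" ~ "stop_loss",
      TRUE ~ "missense"
    )
    return(base)
  }
  # splice sites: first/last 2 nt of each intron
  if (nrow(ex) > 1L) {
    istart <- ex$end[-nrow(ex)] + 1L
    iend <- ex$start[-1] - 1L
    ok <- iend >= istart
    istart <- istart[ok]; iend <- iend[ok]
    if (length(istart)) {
      ss <- c(istart, pmin(istart + 1L, iend),
              iend, pmax(iend - 1L, istart))
      se <- ss
      if (overlaps_any(a1, a2, ss, se)) {
        base$element <- "splice_site"
        base$consequence <- "splice_disruption"
        return(base)
      }
    }
  }
  if (overlaps_any(a1, a2, ex$start, ex$end)) {
    if (nrow(cd) == 0L) {
      base$element <- "exon_noncoding"
    } else {
      cds_lo <- min(cd$start); cds_hi <- max(cd$end)
      left_of_cds <- a2 < cds_lo
      base$element <- if (left_of_cds == (tx$strand == "+")) {
        "five_prime_utr"
      } else {
        "three_prime_utr"
      }
    }
    base$consequence <- "noncoding"
    return(base)
  }
  if (a1 <= tx$tx_end && a2 >= tx$tx_start) {
    base$element <- "intron"
    base$consequence <- "noncoding"
    return(base)
  }
  # flanking the transcript, within the margin (handled by the caller's
  # pre-selection): upstream/downstream by strand
  before <- a2 < tx$tx_start
  base$element <- if (before == (tx$strand == "+")) "upstream" else
    "downstream"
  base$consequence <- "noncoding"
  base
}

#' Annotate variants against gene models
#'
#' One annotation row per (variant, overlapping transcript); all overlapping
#' transcripts are reported (no canonical-transcript selection).  A variant
#' within `margin` bp of a transcript but outside it is `upstream` /
#' `downstream`; a variant touching no transcript yields one `intergenic`
#' row.  CDS SNPs receive codon and amino-acid changes; CDS indels are
#' classed `frameshift` / `inframe_indel` by length; transcripts flagged
#' incomplete get element-level annotation only.
#'
#' @param v A variant tibble.
#' @param genes Gene models from [read_gff()] (may be empty).
#' @param genome A genome.
#' @param margin Upstream/downstream margin in bp (default 500).
#' @return A tibble: the variant columns plus `gene_id, transcript_id,
#'   element, codon_change, aa_change, consequence, flags`.
#' @export
annotate_variants <- function(v, genes, genome, margin = 500L) {
  ann_of <- function(i) {
    vi <- v[i, ]
    hits <- if (is.null(genes) || nrow(genes) == 0L) genes[0, ] else
      filter(genes, .data$chrom == vi$chrom,
             .data$tx_start - margin <= vi$pos + nchar(vi$ref),
             .data$tx_end + margin >= vi$pos)
    ann <- if (nrow(hits) == 0L) {
      annotation_row(element = "intergenic", consequence = "intergenic")
    } else {
      list_rbind(map(seq_len(nrow(hits)),
                     ~ annotate_one_tx(vi, hits[.x, ], genome)))
    }
    bind_cols(vi[rep(1L, nrow(ann)), ], ann)
  }
  if (nrow(v) == 0L) {
    empty_ann <- tibble(gene_id = character(), transcript_id = character(),
                        element = character(), codon_change = character(),
                        aa_change = character(), consequence = character(),
                        flags = character())
    return(bind_cols(v, empty_ann))
  }
  list_rbind(map(seq_len(nrow(v)), ann_of))
}

#' Reference sequences flanking a variant
#'
#' @param v One-row variant tibble.
#' @param genome A genome.
#' @param flank_len Flank length in bp (default 25); clipped at chromosome
#'   ends.
#' @return A list with `left` and `right` strings;
#'   `left + ref + right` is a verbatim reference substring.
#' @export
flanks <- function(v, genome, flank_len = 25L) {
  len <- length(genome[[v$chrom]])
  l1 <- max(1L, v$pos - flank_len)
  l2 <- v$pos - 1L
  r1 <- v$pos + nchar(v$ref)
  r2 <- min(len, r1 + flank_len - 1L)
  list(left = if (l2 >= l1) genome_seq(genome, v$chrom, l1, l2) else "",
       right = if (r2 >= r1) genome_seq(genome, v$chrom, r1, r2) else "")
}

#' Full variant-analyzer report
#'
#' One record per (variant, overlapping transcript), carrying everything the
#' analyzer reports: position, quality, read counts, allele frequency,
#' nucleotide/amino-acid changes, gene and gene element, functional
#' annotation, a genotyping primer pair, and reference flanking sequences.
#' Variants without read counts keep an empty af column and are retained.
#'
#' @param v A variant tibble.
#' @param genes Gene models (may be empty: effect fields become intergenic).
#' @param genome A genome.
#' @param functional_map Optional tibble from [read_functional_map()];
#'   falls back to the GFF `Note`/`description` attribute.
#' @param flank_len Flank length for [flanks()].
#' @param margin Upstream/downstream margin for [annotate_variants()].
#' @param primers Design genotyping primers per variant (see
#'   [design_primers()]).
#' @param primer_opts Named list of overrides passed to [design_primers()].
#' @return A candidate-record tibble.
#' @export
analyze_set <- function(v, genes, genome, functional_map = NULL,
                        flank_len = 25L, margin = 500L, primers = TRUE,
                        primer_opts = list()) {
  ann <- annotate_variants(v, genes, genome, margin = margin)
  note <- if (!is.null(functional_map)) {
    functional_map
  } else if (!is.null(genes) && nrow(genes) > 0L) {
    gene_spans(genes) |> select("gene_id", "functional_note")
  } else {
    tibble(gene_id = character(), functional_note = character())
  }
  ann <- left_join(ann, note, by = "gene_id")
  per_var <- map(seq_len(nrow(v)), function(i) {
    vi <- v[i, ]
    fl <- flanks(vi, genome, flank_len)
    pr <- if (primers) {
      do.call(design_primers, c(list(vi, genome), primer_opts))
    } else {
      NULL
    }
    tibble(
      flank_left = fl$left, flank_right = fl$right,
      fwd_primer = pr$fwd_seq %||% NA_character_,
      rev_primer = pr$rev_seq %||% NA_character_,
      fwd_tm = pr$fwd_tm %||% NA_real_,
      rev_tm = pr$rev_tm %||% NA_real_,
      product_size = pr$product_size %||% NA_integer_,
      primer_note = attr(pr, "reason") %||% NA_character_
    )
  }) |> list_rbind()
  per_var <- bind_cols(v[, KEY], per_var)
  left_join(ann, per_var, by = KEY)
}
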