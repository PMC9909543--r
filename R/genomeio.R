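# Readers/writers for FASTA, GFF3, VCF and TSV reports, plus the variant
# tibble that every other module consumes.  Coordinates are 1-based closed
# throughout; chromosome order is canonical FASTA order.

#' Read a reference genome from FASTA
#'
#' Headers are tokenized at the first whitespace; sequences are uppercased.
#' The FASTA record order defines the canonical chromosome order used by all
#' windowing and sorting operations.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome id.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  g <- Biostrings::readDNAStringSet(path)
  if (length(g) == 0L) abort(paste0("empty FASTA file: ", path))
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) {
    abort(paste0("duplicate chromosome id in ", path, ": ",
                 names(g)[duplicated(names(g))][1]))
  }
  ok <- Biostrings::DNAStringSet(toupper(as.character(g)))
  names(ok) <- names(g)
  ok
}

#' Write a genome to FASTA
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Chromosome ids and lengths of a genome
#' @param genome A [Biostrings::DNAStringSet] from [read_genome()].
#' @return A tibble with columns `chrom`, `length` in canonical order.
#' @export
chrom_lengths <- function(genome) {
  tibble(chrom = names(genome), length = Biostrings::width(genome))
}

#' Extract a genome subsequence
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param chrom Chromosome id.
#' @param start,end 1-based closed interval; must lie within the chromosome.
#' @return An uppercase DNA string.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) abort(paste0("unknown chromosome: ", chrom))
  len <- length(genome[[chrom]])
  if (start < 1L || end > len || start > end) {
    abort(sprintf("slice [%d,%d] outside [1,%d] on %s", start, end, len, chrom))
  }
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

variant_cols <- c("chrom", "pos", "ref", "alt", "qual",
                  "ref_count", "alt_count", "af", "vclass")

#' Classify a variant as SNP, insertion or deletion
#'
#' A record is a SNP iff both alleles are single bases; otherwise the longer
#' allele decides.  Equal-length multi-nucleotide records have no class in
#' this model and yield `NA`.
#'
#' @param ref,alt Character vectors of reference/alternate alleles.
#' @return Character vector in `{"snp","insertion","deletion"}` (or `NA`).
#' @export
variant_class <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  dplyr::case_when(
    lr == 1L & la == 1L ~ "snp",
    la > lr ~ "insertion",
    la < lr ~ "deletion",
    TRUE ~ NA_character_
  )
}

#' Build a variant tibble
#'
#' The common currency of the package: one row per biallelic record, keyed by
#' `(chrom, pos, ref, alt)`.  Allele frequency is `alt_count / (ref_count +
#' alt_count)` and is `NA` when no informative reads are available.
#'
#' @param chrom,pos,ref,alt Record key (VCF convention: `pos` is the first
#'   reference base of the event, indels left-anchored).
#' @param qual Variant quality (`NA` allowed).
#' @param ref_count,alt_count Allele-depth counts (`NA` allowed).
#' @param sample_id Optional sample label, stored as an attribute.
#' @return A tibble with columns `chrom, pos, ref, alt, qual, ref_count,
#'   alt_count, af, vclass`.
#' @export
variant_tbl <- function(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        qual = NA_real_, ref_count = NA_integer_,
                        alt_count = NA_integer_, sample_id = NULL) {
  v <- tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    qual = as.numeric(qual),
    ref_count = as.integer(ref_count), alt_count = as.integer(alt_count)
  )
  if (any(v$ref == v$alt)) abort("ref and alt alleles must differ")
  v <- v |>
    mutate(
      dp = .data$ref_count + .data$alt_count,
      af = ifelse(!is.na(.data$dp) & .data$dp > 0,
                  .data$alt_count / .data$dp, NA_real_),
      vclass = variant_class(.data$ref, .data$alt)
    ) |>
    select(-"dp")
  if (!is.null(sample_id)) attr(v, "sample_id") <- sample_id
  v
}

#' Sort a variant tibble in canonical genome order
#'
#' @param v A variant tibble.
#' @param genome Optional genome; when given, chromosomes follow FASTA order,
#'   otherwise first-appearance order.
#' @return The sorted tibble.
#' @export
arrange_variants <- function(v, genome = NULL) {
  lev <- if (is.null(genome)) unique(v$chrom) else names(genome)
  v |>
    mutate(.ord = match(.data$chrom, lev)) |>
    arrange(.data$.ord, .data$pos, .data$ref, .data$alt) |>
    select(-".ord")
}

#' Read variants from a VCF file
#'
#' Allele depths are taken from FORMAT `AD` when present, falling back to
#' INFO `DP4` (ref = fields 1+2, alt = fields 3+4), and finally to `NA`
#' counts (undefined allele frequency).  Multi-allelic rows are split into
#' one record per alternate allele with `af_i = alt_i / (ref + sum(alt))`
#' (so per-record `ref_count` is total depth minus `alt_i`).  Records whose
#' FILTER is neither `PASS` nor `.` are dropped, as are symbolic alleles and
#' equal-length multi-nucleotide substitutions.
#'
#' @param path Path to a VCF 4.x file (plain text or bgzipped).
#' @param sample Sample name whose `AD` field to use; defaults to the first
#'   sample in the file.
#' @param genome Optional genome used to order chromosomes canonically.
#' @return A variant tibble (see [variant_tbl()]) with a `sample_id`
#'   attribute.
#' @export
read_vcf <- function(path, sample = NULL, genome = NULL) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  n <- nrow(vcf)
  samp_names <- colnames(vcf)
  if (is.null(sample)) {
    sample <- if (length(samp_names)) samp_names[1] else "sample"
  } else if (length(samp_names) && !sample %in% samp_names) {
    abort(paste0("sample not in VCF: ", sample))
  }
  if (n == 0L) return(variant_tbl(sample_id = sample))

  rr <- SummarizedExperiment::rowRanges(vcf)
  fx <- VariantAnnotation::fixed(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(fx$REF)
  alt_l <- fx$ALT
  qual <- fx$QUAL
  filt <- fx$FILTER

  gen <- VariantAnnotation::geno(vcf)
  ad <- NULL
  if ("AD" %in% names(gen) && length(samp_names)) {
    j <- match(sample, samp_names)
    adm <- gen$AD
    # list-matrix for ragged AD, 3-d array when every row has the same arity
    ad <- if (is.list(adm)) {
      lapply(seq_len(n), function(i) adm[[i, j]])
    } else if (length(dim(adm)) == 3L) {
      lapply(seq_len(n), function(i) adm[i, j, ])
    }
  }
  dp4 <- NULL
  inf <- VariantAnnotation::info(vcf)
  if ("DP4" %in% colnames(inf)) dp4 <- inf$DP4

  rows <- map(seq_len(n), function(i) {
    if (!filt[i] %in% c("PASS", ".")) return(NULL)
    alts <- as.character(alt_l[[i]])
    keep <- !is.na(alts) & grepl("^[ACGTN]+$", alts) & alts != ref[i]
    alts <- alts[keep]
    if (!length(alts)) return(NULL)
    mnp <- nchar(alts) == nchar(ref[i]) & nchar(alts) > 1L
    if (any(mnp)) {
      warn(sprintf("dropping %d multi-nucleotide substitution(s) at %s:%d",
                   sum(mnp), chrom[i], pos[i]))
      alts <- alts[!mnp]
      if (!length(alts)) return(NULL)
    }
    ad_i <- if (!is.null(ad)) suppressWarnings(as.integer(ad[[i]])) else NULL
    if (!is.null(ad_i) && length(ad_i) >= 2L && !all(is.na(ad_i))) {
      tot <- sum(ad_i, na.rm = TRUE)
      # ad_i is (ref, alt1, alt2, ...) in original allele order; map to the
      # retained alleles
      orig <- as.character(alt_l[[i]])
      ac <- ad_i[1L + match(alts, orig)]
      rc <- tot - ac
    } else if (!is.null(dp4) && !all(is.na(unlist(dp4[i])))) {
      d <- as.integer(unlist(dp4[i]))
      rc <- rep(d[1] + d[2], length(alts))
      ac <- rep(d[3] + d[4], length(alts))
    } else {
      rc <- rep(NA_integer_, length(alts))
      ac <- rep(NA_integer_, length(alts))
    }
    tibble(chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alts,
           qual = as.numeric(qual[i]), ref_count = rc, alt_count = ac)
  })
  rows <- list_rbind(purrr::compact(rows))
  if (nrow(rows) == 0L) return(variant_tbl(sample_id = sample))
  v <- variant_tbl(rows$chrom, rows$pos, rows$ref, rows$alt, rows$qual,
                   rows$ref_count, rows$alt_count, sample_id = sample)
  arrange_variants(distinct(v, .data$chrom, .data$pos, .data$ref, .data$alt,
                            .keep_all = TRUE), genome)
}

#' Write a variant tibble to VCF
#'
#' Emits a minimal VCF 4.2 file with QUAL, `FILTER=PASS`, and a single
#' sample column carrying FORMAT `AD`.  Reading the file back with
#' [read_vcf()] reproduces the key, quality and counts.
#'
#' @param v A variant tibble.
#' @param path Output path.
#' @param genome Optional genome; adds `##contig` headers and canonical
#'   sorting.
#' @param sample_id Sample column name; defaults to the tibble's attribute.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(v, path, genome = NULL, sample_id = NULL) {
  sample_id <- sample_id %||% attr(v, "sample_id") %||% "sample"
  v <- arrange_variants(v, genome)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=bulkmapr",
    if (!is.null(genome)) {
      sprintf("##contig=<ID=%s,length=%d>", names(genome),
              Biostrings::width(genome))
    },
    paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
           "Description=\"Genotype\">"),
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref,alt)\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  body <- character(0)
  if (nrow(v)) {
    ad <- ifelse(is.na(v$ref_count) | is.na(v$alt_count), ".",
                 paste0(v$ref_count, ",", v$alt_count))
    qual <- ifelse(is.na(v$qual), ".", format(v$qual, trim = TRUE,
                                              scientific = FALSE))
    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, qual, "PASS", ".",
                  "GT:AD", paste0("./.:", ad), sep = "\t")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Write a tabular report to TSV
#'
#' UTF-8, tab-delimited, header row; list-columns are collapsed with `;`.
#'
#' @param records A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(records, path) {
  flat <- records |>
    mutate(across(where(is.list),
                  ~ map_chr(.x, function(el) paste(unlist(el), collapse = ";"))))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' Read a two-column functional-annotation map
#'
#' Expects a headerless two-column TSV: gene id, free-text description.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene_id`, `functional_note`.
#' @export
read_functional_map <- function(path) {
  readr::read_tsv(path, col_names = c("gene_id", "functional_note"),
                  col_types = "cc", progress = FALSE)
}
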