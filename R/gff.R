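# GFF3 gene models.  One row per transcript; exon and CDS intervals live in
# list-columns of tibbles (1-based closed, sorted by coordinate).

empty_gene_models <- function() {
  tibble(gene_id = character(), transcript_id = character(),
         chrom = character(), strand = character(),
         tx_start = integer(), tx_end = integer(),
         exons = list(), cds = list(),
         incomplete = logical(), functional_note = character())
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`/`mRNA`/`exon`/`CDS` features linked by `ID`/`Parent` into a
#' transcript-level tibble.  Lines that are not 9-column GFF are skipped with
#' a warning; features on chromosomes absent from `genome` are dropped with a
#' warning; a file without gene features yields an empty model table (the
#' annotation-free QTL-seq path).  A transcript whose CDS length (after
#' phase adjustment) is not divisible by 3 is flagged `incomplete` and is
#' excluded from amino-acid calls downstream.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional genome used to validate chromosome ids.
#' @return A tibble with columns `gene_id, transcript_id, chrom, strand,
#'   tx_start, tx_end, exons, cds, incomplete, functional_note`.
#' @export
read_gff <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  data_ln <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  nfield <- lengths(strsplit(data_ln, "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    warn(sprintf("skipping %d unparseable GFF line(s) in %s",
                 sum(nfield != 9L), path))
    data_ln <- data_ln[nfield == 9L]
  }
  if (!length(data_ln)) return(empty_gene_models())
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp))
  writeLines(c("##gff-version 3", data_ln), tmp)
  gr <- rtracklayer::import(tmp, format = "gff3")

  feat <- tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(gr$type),
    phase = if (!is.null(gr$phase)) as.integer(gr$phase) else NA_integer_,
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = if (!is.null(gr$Parent)) {
      map_chr(as.list(gr$Parent), ~ if (length(.x)) .x[1] else NA_character_)
    } else NA_character_,
    note = if (!is.null(gr$Note)) {
      map_chr(as.list(gr$Note), ~ if (length(.x)) .x[1] else NA_character_)
    } else NA_character_,
    description = if (!is.null(gr$description)) {
      as.character(gr$description)
    } else NA_character_
  )
  if (!is.null(genome)) {
    bad <- !feat$chrom %in% names(genome)
    if (any(bad)) {
      warn(sprintf("dropping %d GFF feature(s) on chromosomes absent from genome",
                   sum(bad)))
      feat <- feat[!bad, ]
    }
  }

  genes <- filter(feat, .data$type == "gene", !is.na(.data$id))
  if (nrow(genes) == 0L) return(empty_gene_models())
  txs <- filter(feat, .data$type %in% c("mRNA", "transcript"),
                .data$parent %in% genes$id)
  parts <- filter(feat, .data$type %in% c("exon", "CDS"))

  # exon/CDS hanging directly off a gene get a synthesized transcript
  orphan <- filter(parts, .data$parent %in% genes$id)
  if (nrow(orphan)) {
    synth <- distinct(orphan, gene = .data$parent) |>
      mutate(id = paste0(.data$gene, ".t1"))
    txs <- bind_rows(txs, genes |>
                       filter(.data$id %in% synth$gene) |>
                       mutate(parent = .data$id,
                              id = paste0(.data$id, ".t1"),
                              type = "mRNA"))
    parts <- parts |>
      mutate(parent = ifelse(.data$parent %in% synth$gene,
                             paste0(.data$parent, ".t1"), .data$parent))
  }
  parts <- filter(parts, .data$parent %in% txs$id)

  note_of <- function(g_row) {
    if (!is.na(g_row$note)) g_row$note
    else if (!is.na(g_row$description)) g_row$description
    else NA_character_
  }

  out <- map(seq_len(nrow(txs)), function(i) {
    tx <- txs[i, ]
    g <- genes[match(tx$parent, genes$id), ]
    p <- filter(parts, .data$parent == tx$id)
    ex <- p |> filter(.data$type == "exon") |>
      arrange(.data$start) |> select("start", "end")
    cd <- p |> filter(.data$type == "CDS") |>
      arrange(.data$start) |>
      mutate(phase = ifelse(is.na(.data$phase), 0L, .data$phase)) |>
      select("start", "end", "phase")
    if (nrow(ex) == 0L && nrow(cd) > 0L) {
      ex <- select(cd, "start", "end")
    }
    if (nrow(ex) == 0L) {
      ex <- tibble(start = tx$start, end = tx$end)
    }
    incomplete <- FALSE
    if (nrow(cd)) {
      ph1 <- if (tx$strand == "-") cd$phase[nrow(cd)] else cd$phase[1]
      cds_len <- sum(cd$end - cd$start + 1L) - ph1
      incomplete <- cds_len %% 3L != 0L
    }
    tibble(gene_id = g$id, transcript_id = tx$id, chrom = tx$chrom,
           strand = tx$strand, tx_start = min(ex$start), tx_end = max(ex$end),
           exons = list(ex), cds = list(cd), incomplete = incomplete,
           functional_note = note_of(g))
  })
  list_rbind(out) |> arrange(.data$chrom, .data$tx_start)
}

#' Per-gene genomic spans
#'
#' @param genes A gene-model tibble from [read_gff()].
#' @return One row per gene: `gene_id, chrom, strand, start, end,
#'   functional_note`.
#' @export
gene_spans <- function(genes) {
  if (nrow(genes) == 0L) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  functional_note = character()))
  }
  genes |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$tx_start), end = max(.data$tx_end),
              functional_note = first(.data$functional_note),
              .groups = "drop")
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff()] for the feature subset this package models
#' (gene/mRNA/exon/CDS with phase and an optional `Note`).
#'
#' @param genes A gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  spans <- gene_spans(genes)
  for (gi in seq_len(nrow(spans))) {
    g <- spans[gi, ]
    attr_g <- paste0("ID=", g$gene_id,
                     if (!is.na(g$functional_note)) {
                       paste0(";Note=", g$functional_note)
                     } else "")
    writeLines(paste(g$chrom, "bulkmapr", "gene", g$start, g$end, ".",
                     g$strand, ".", attr_g, sep = "\t"), con)
    txr <- filter(genes, .data$gene_id == g$gene_id)
    for (ti in seq_len(nrow(txr))) {
      tx <- txr[ti, ]
      writeLines(paste(tx$chrom, "bulkmapr", "mRNA", tx$tx_start, tx$tx_end,
                       ".", tx$strand, ".",
                       paste0("ID=", tx$transcript_id, ";Parent=", g$gene_id),
                       sep = "\t"), con)
      ex <- tx$exons[[1]]
      for (k in seq_len(nrow(ex))) {
        writeLines(paste(tx$chrom, "bulkmapr", "exon", ex$start[k], ex$end[k],
                         ".", tx$strand, ".",
                         paste0("Parent=", tx$transcript_id), sep = "\t"), con)
      }
      cd <- tx$cds[[1]]
      for (k in seq_len(nrow(cd))) {
        writeLines(paste(tx$chrom, "bulkmapr", "CDS", cd$start[k], cd$end[k],
                         ".", tx$strand, cd$phase[k],
                         paste0("ID=", tx$transcript_id, ".cds;Parent=",
                                tx$transcript_id), sep = "\t"), con)
      }
    }
  }
  invisible(path)
}
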