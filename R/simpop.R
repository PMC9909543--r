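# Mapping-population simulator: random genomes with valid gene models, EMS
# mutagenesis, recurrent backcrossing with recombination-dependent variant
# retention (Haldane map function, uniform cM/Mb), F2 bulks under phenotypic
# selection, and binomial read-depth sampling of pooled allele counts.
# Everything is reproducible from the seed, and all outputs are standard
# FASTA/GFF3/VCF files plus a TSV truth sidecar that the mapping code never
# reads.

#' Haldane map function
#'
#' Converts genetic distance `d` (Morgans) to a recombination fraction
#' `r = (1 - exp(-2d)) / 2`.
#'
#' @param d Genetic distance in Morgans.
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane <- function(d) (1 - exp(-2 * d)) / 2

#' Simulation configuration
#'
#' Defaults encode the recommended experimental designs: 4 backcrosses
#' (within the advised 3-6), a 25x read depth and 100-individual bulk for
#' linkage mapping, a 50x depth and 200-individual population with 10% tails
#' for QTL-seq, and a 20-Mb two-chromosome genome at 4 cM/Mb.
#'
#' @param scenario One of `"backcross"`, `"qtlseq"`, `"f2"`.
#' @param seed Mandatory integer seed; every simulator output is a pure
#'   function of the configuration.
#' @param n_chrom,chrom_len Genome shape (chromosomes of equal length, bp).
#' @param cm_per_mb Uniform recombination rate (centimorgan per megabase).
#' @param read_depth Sequencing depth per site in the pooled sample.
#' @param population_size Individuals in the pool (backcross/F2 bulk) or in
#'   the segregating population (QTL-seq).
#' @param n_backcrosses Recurrent backcrosses `k`; an unlinked heterozygous
#'   variant survives with probability `(1/2)^k`.
#' @param n_mutations EMS mutations induced (G/C positions, one causal
#'   inside a gene CDS).
#' @param n_background Pre-mutagenesis background variants shared with the
#'   control (about 10% small indels).
#' @param marker_spacing Marker interval for QTL-seq (bp).
#' @param gene_spacing Gene interval for the simulated annotation (bp).
#' @param qtl_chrom,qtl_pos QTL location (defaults: middle of the first
#'   chromosome).
#' @param qtl_effect Additive effect in phenotype SD units per allele copy;
#'   3 yields essentially complete selection at 10% tails, 0 is the null
#'   generator.
#' @param tail_fraction Fraction of the population bulked into each extreme
#'   pool.
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(scenario = c("backcross", "qtlseq", "f2"),
                       seed,
                       n_chrom = 2L, chrom_len = 1e7, cm_per_mb = 4,
                       read_depth = NULL, population_size = NULL,
                       n_backcrosses = 4L, n_mutations = 60L,
                       n_background = 100L, marker_spacing = 1e5,
                       gene_spacing = 2.5e4,
                       qtl_chrom = NULL, qtl_pos = NULL, qtl_effect = 3,
                       tail_fraction = 0.1) {
  scenario <- match.arg(scenario)
  if (missing(seed) || is.null(seed)) abort("sim_config requires a seed")
  read_depth <- read_depth %||% switch(scenario, qtlseq = 50L, 25L)
  population_size <- population_size %||%
    switch(scenario, backcross = 50L, f2 = 100L, qtlseq = 200L)
  cfg <- list(scenario = scenario, seed = as.integer(seed),
              n_chrom = as.integer(n_chrom),
              chrom_len = as.integer(chrom_len), cm_per_mb = cm_per_mb,
              read_depth = as.integer(read_depth),
              population_size = as.integer(population_size),
              n_backcrosses = as.integer(n_backcrosses),
              n_mutations = as.integer(n_mutations),
              n_background = as.integer(n_background),
              marker_spacing = as.integer(marker_spacing),
              gene_spacing = as.integer(gene_spacing),
              qtl_chrom = qtl_chrom, qtl_pos = qtl_pos,
              qtl_effect = qtl_effect, tail_fraction = tail_fraction)
  stopifnot(cfg$n_chrom > 0, cfg$chrom_len > 0, cfg$cm_per_mb > 0,
            cfg$read_depth > 0, cfg$population_size > 0,
            cfg$n_backcrosses > 0, cfg$tail_fraction > 0)
  structure(cfg, class = "sim_config")
}

NON_STOP_CODONS <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}
STOP_CODONS <- c("TAA", "TAG", "TGA")

# one random chromosome as a raw vector of A/C/G/T bytes
random_chrom_raw <- function(len) {
  charToRaw("ACGT")[sample.int(4L, len, replace = TRUE)]
}

# phase column for CDS segments given translation order lengths
cds_phases <- function(lens) {
  as.integer((3L - cumsum(c(0L, lens[-length(lens)])) %% 3L) %% 3L)
}

#' Simulate a genome with a valid structural annotation
#'
#' Chromosomes are i.i.d. uniform ACGT; genes are placed on alternating
#' strands every `gene_spacing` bp, each with 2-4 exons, 30-bp UTRs and a
#' CDS that starts with ATG, ends in a stop, and contains no internal stop.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; writes `genome.fa`,
#'   `annotation.gff3` and `functional_map.tsv`.
#' @return A list with `genome` (DNAStringSet) and `genes` (gene-model
#'   tibble as from [read_gff()]).
#' @export
simulate_genome <- function(cfg, dir = NULL) {
  withr::with_seed(cfg$seed, {
    chroms <- paste0("chr", seq_len(cfg$n_chrom))
    raws <- lapply(seq_len(cfg$n_chrom), function(i) {
      random_chrom_raw(cfg$chrom_len)
    })
    names(raws) <- chroms
    gene_rows <- list()
    for (ci in seq_len(cfg$n_chrom)) {
      n_genes <- floor(cfg$chrom_len / cfg$gene_spacing)
      for (gi in seq_len(n_genes)) {
        g_start <- as.integer((gi - 1L) * cfg$gene_spacing + 501L)
        strand <- if (gi %% 2L == 1L) "+" else "-"
        n_ex <- sample(2:4, 1L)
        ex_len <- sample(200:600, n_ex, replace = TRUE)
        in_len <- if (n_ex > 1L) sample(150:400, n_ex - 1L, replace = TRUE)
          else integer(0)
        starts <- g_start + cumsum(c(0L, head(ex_len, -1) + in_len))
        ends <- starts + ex_len - 1L
        if (max(ends) > cfg$chrom_len) next
        total_ex <- sum(ex_len)
        cds_len <- total_ex - 60L
        cds_len <- cds_len - cds_len %% 3L
        # exonic genomic positions, ascending
        P <- unlist(Map(seq.int, starts, ends), use.names = FALSE)
        tx_order <- if (strand == "+") P else rev(P)
        cds_pos <- tx_order[31:(30L + cds_len)]   # translation order
        cds_seq <- c("ATG",
                     sample(NON_STOP_CODONS, cds_len / 3L - 2L,
                            replace = TRUE),
                     sample(STOP_CODONS, 1L))
        cds_chars <- strsplit(paste(cds_seq, collapse = ""), "",
                              fixed = TRUE)[[1]]
        write_chars <- if (strand == "+") cds_chars else comp_base(cds_chars)
        raws[[ci]][cds_pos] <- charToRaw(paste(write_chars, collapse = ""))
        # CDS genomic intervals = runs of consecutive positions
        gp <- sort(cds_pos)
        brk <- c(0L, which(diff(gp) != 1L), length(gp))
        seg <- tibble(start = gp[head(brk, -1) + 1L], end = gp[brk[-1]])
        seg_tx <- if (strand == "+") seg else seg[rev(seq_len(nrow(seg))), ]
        ph <- cds_phases(seg_tx$end - seg_tx$start + 1L)
        seg_tx$phase <- ph
        seg <- arrange(seg_tx, .data$start)
        gene_id <- sprintf("gene_%s_%04d", chroms[ci], gi)
        gene_rows[[length(gene_rows) + 1L]] <- tibble(
          gene_id = gene_id,
          transcript_id = paste0(gene_id, ".t1"),
          chrom = chroms[ci], strand = strand,
          tx_start = min(starts), tx_end = max(ends),
          exons = list(tibble(start = starts, end = ends)),
          cds = list(seg), incomplete = FALSE,
          functional_note = paste("simulated protein-coding gene", gi)
        )
      }
    }
    genome <- Biostrings::DNAStringSet(vapply(raws, rawToChar, character(1)))
    names(genome) <- chroms
    genes <- list_rbind(gene_rows)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_genome(genome, file.path(dir, "genome.fa"))
      write_gff(genes, file.path(dir, "annotation.gff3"))
      readr::write_tsv(gene_spans(genes)[, c("gene_id", "functional_note")],
                       file.path(dir, "functional_map.tsv"),
                       col_names = FALSE, progress = FALSE)
    }
    list(genome = genome, genes = genes)
  })
}

base_at <- function(chrom_seq, pos) substring(chrom_seq, pos, pos)

# n distinct EMS-mutable (G/C) sites across the genome, avoiding `exclude`
sample_gc_sites <- function(chrom_seqs, n, exclude = NULL) {
  lens <- nchar(chrom_seqs)
  out <- tibble(chrom = character(), pos = integer())
  guard <- 0L
  while (nrow(out) < n && guard < 50L) {
    guard <- guard + 1L
    need <- (n - nrow(out)) * 3L
    ci <- sample.int(length(lens), need, replace = TRUE,
                     prob = lens / sum(lens))
    pos <- vapply(ci, function(i) sample.int(lens[i], 1L), integer(1))
    cand <- tibble(chrom = names(chrom_seqs)[ci], pos = pos)
    cand$base <- map2_chr_base(chrom_seqs, cand$chrom, cand$pos)
    cand <- cand[cand$base %in% c("G", "C"), c("chrom", "pos")]
    out <- distinct(bind_rows(out, cand))
    if (!is.null(exclude)) out <- anti_join(out, exclude,
                                            by = c("chrom", "pos"))
  }
  if (nrow(out) < n) abort("not enough G/C positions available")
  out[seq_len(n), ]
}

map2_chr_base <- function(chrom_seqs, chrom, pos) {
  out <- character(length(pos))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    out[sel] <- base_at(chrom_seqs[[cn]], pos[sel])
  }
  out
}

ems_alt <- function(ref) ifelse(ref == "G", "A", "T")

# shared pre-mutagenesis background variants (SNPs + ~10% small indels)
sim_background <- function(cfg, chrom_seqs, exclude = NULL) {
  n <- cfg$n_background
  if (n == 0L) return(tibble(chrom = character(), pos = integer(),
                             ref = character(), alt = character()))
  lens <- nchar(chrom_seqs)
  ci <- sample.int(length(lens), n, replace = TRUE, prob = lens / sum(lens))
  pos <- vapply(ci, function(i) sample.int(lens[i] - 5L, 1L), integer(1))
  bg <- distinct(tibble(chrom = names(chrom_seqs)[ci], pos = pos))
  if (!is.null(exclude)) bg <- anti_join(bg, exclude, by = c("chrom", "pos"))
  kind <- sample(c("snp", "ins", "del"), nrow(bg), replace = TRUE,
                 prob = c(0.9, 0.05, 0.05))
  ref1 <- map2_chr_base(chrom_seqs, bg$chrom, bg$pos)
  alt_snp <- vapply(ref1, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1), USE.NAMES = FALSE)
  ins_len <- sample(1:3, nrow(bg), replace = TRUE)
  del_len <- sample(1:3, nrow(bg), replace = TRUE)
  bg$ref <- ref1
  bg$alt <- alt_snp
  is_ins <- kind == "ins"
  bg$alt[is_ins] <- paste0(ref1[is_ins], vapply(ins_len[is_ins], function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1)))
  is_del <- kind == "del"
  if (any(is_del)) {
    bg$ref[is_del] <- substring(chrom_seqs[bg$chrom[is_del]], bg$pos[is_del],
                                bg$pos[is_del] + del_len[is_del])
    bg$alt[is_del] <- ref1[is_del]
  }
  bg
}

# causal EMS site inside a random gene's CDS
pick_causal <- function(genes, chrom_seqs) {
  for (gi in sample.int(nrow(genes))) {
    tx <- genes[gi, ]
    cd <- tx$cds[[1]]
    if (nrow(cd) == 0L) next
    pos <- unlist(Map(seq.int, cd$start, cd$end), use.names = FALSE)
    base <- base_at(chrom_seqs[[tx$chrom]], pos)
    gc <- pos[base %in% c("G", "C")]
    if (!length(gc)) next
    p <- sample(gc, 1L)
    b <- base_at(chrom_seqs[[tx$chrom]], p)
    return(tibble(chrom = tx$chrom, pos = p, ref = b, alt = ems_alt(b),
                  gene_id = tx$gene_id))
  }
  abort("no G/C position available in any CDS")
}

sample_depths <- function(af_true, depth) {
  alt <- rbinom(length(af_true), depth, af_true)
  tibble(ref_count = depth - alt, alt_count = alt)
}

finish_sample <- function(sites, depth, sample_id, drop_uncalled = TRUE) {
  d <- sample_depths(sites$af_true, depth)
  v <- variant_tbl(sites$chrom, sites$pos, sites$ref, sites$alt, qual = 99,
                   ref_count = d$ref_count, alt_count = d$alt_count,
                   sample_id = sample_id)
  if (drop_uncalled) v <- filter(v, .data$alt_count > 0L)
  v
}

#' Simulate a recurrent-backcross mapping population
#'
#' EMS mutations (G/C to A/T) are induced at random G/C positions, one of
#' them causal inside a gene CDS.  Each non-causal mutation survives each of
#' the `k` backcrosses with probability `1 - r`, where `r` is the Haldane
#' recombination fraction to the causal site (0.5 on other chromosomes).
#' In the final selfed, phenotypically selected bulk, surviving linked
#' mutations are homozygous (true af 1) while surviving unlinked mutations
#' segregate (per-individual genotypes 1/4 : 1/2 : 1/4).  Observed counts
#' are binomial draws at `read_depth`.  The control sample carries exactly
#' the shared pre-mutagenesis background variants.
#'
#' @param cfg A [sim_config()] with scenario `"backcross"`.
#' @param genome,genes Output of [simulate_genome()].
#' @param dir Optional directory for `test.vcf`, `control.vcf`,
#'   `truth.tsv`.
#' @return A list with `test`, `control` (variant tibbles), `truth` (per
#'   EMS site: survival, true af, causal flag) and `causal` (one row).
#' @export
simulate_backcross <- function(cfg, genome, genes, dir = NULL) {
  withr::with_seed(cfg$seed + 1L, {
    chrom_seqs <- setNames(as.character(genome), names(genome))
    causal <- pick_causal(genes, chrom_seqs)
    bg <- sim_background(cfg, chrom_seqs, exclude = causal[, c("chrom", "pos")])
    muts <- sample_gc_sites(chrom_seqs, cfg$n_mutations - 1L,
                            exclude = bind_rows(causal[, c("chrom", "pos")],
                                                bg[, c("chrom", "pos")]))
    muts$ref <- map2_chr_base(chrom_seqs, muts$chrom, muts$pos)
    muts$alt <- ems_alt(muts$ref)
    linked <- muts$chrom == causal$chrom
    d_morgan <- abs(muts$pos - causal$pos) / 1e6 * cfg$cm_per_mb / 100
    r <- ifelse(linked, haldane(d_morgan), 0.5)
    p_surv <- (1 - r)^cfg$n_backcrosses
    survived <- runif(nrow(muts)) < p_surv
    af_true <- rep(NA_real_, nrow(muts))
    af_true[survived & linked] <- 1
    unl <- which(survived & !linked)
    if (length(unl)) {
      g <- matrix(rbinom(length(unl) * cfg$population_size, 2L, 0.5),
                  nrow = length(unl))
      af_true[unl] <- rowMeans(g) / 2
    }
    causal_gene <- causal$gene_id
    truth <- bind_rows(
      mutate(causal[, c("chrom", "pos", "ref", "alt")], causal = TRUE,
             survived = TRUE, af_true = 1, gene_id = causal_gene),
      mutate(muts, causal = FALSE, survived = survived, af_true = af_true,
             gene_id = NA_character_)
    )
    test_sites <- bind_rows(
      mutate(bg, af_true = 1),
      filter(truth, .data$survived)[, c("chrom", "pos", "ref", "alt",
                                        "af_true")]
    )
    test <- finish_sample(test_sites, cfg$read_depth, "test") |>
      arrange_variants(genome)
    control <- finish_sample(mutate(bg, af_true = 1), cfg$read_depth,
                             "control") |>
      arrange_variants(genome)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_vcf(test, file.path(dir, "test.vcf"), genome, "test")
      write_vcf(control, file.path(dir, "control.vcf"), genome, "control")
      readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
    }
    list(test = test, control = control, truth = truth, causal = causal)
  })
}

# Markov recombination chain: matrix of parental-origin indicators for
# `n_gametes` gametes over loci with inter-locus recombination fractions
# `r` (length = loci - 1); `init` gives the first-column indicator.
gamete_chains <- function(n_gametes, r, init = NULL) {
  m <- length(r) + 1L
  G <- matrix(0L, n_gametes, m)
  G[, 1L] <- init %||% rbinom(n_gametes, 1L, 0.5)
  if (m > 1L) {
    for (j in 2:m) {
      sw <- rbinom(n_gametes, 1L, r[j - 1L])
      G[, j] <- bitwXor(G[, j - 1L], sw)
    }
  }
  G
}

#' Simulate a QTL-seq experiment
#'
#' Biallelic markers every `marker_spacing` bp distinguish parents A and B.
#' Each F2 individual receives two independent gametes, each a Markov chain
#' of parental origin along the markers with Haldane switch probabilities.
#' Phenotype = `qtl_effect * (genotype at the QTL marker - 1) + N(0, 1)`;
#' the top and bottom `tail_fraction` of the population are bulked.  Pool
#' allele frequency of the A allele at each marker is the genotype sum over
#' the bulk divided by twice the bulk size, and read counts are binomial
#' draws at `read_depth`.  `qtl_effect = 0` yields the null generator.
#'
#' @param cfg A [sim_config()] with scenario `"qtlseq"`.
#' @param genome A genome.
#' @param dir Optional directory for `pool_high.vcf`, `pool_low.vcf`,
#'   `truth.tsv`.
#' @return A list with `pool1` (high bulk), `pool2` (low bulk), `truth`
#'   (per-marker true pool afs) and `qtl` (one-row tibble of the QTL
#'   marker).
#' @export
simulate_qtlseq <- function(cfg, genome, dir = NULL) {
  withr::with_seed(cfg$seed + 2L, {
    N <- cfg$population_size
    n_tail <- floor(N * cfg$tail_fraction)
    if (n_tail < 1L) abort("tail_fraction * population_size < 1")
    chrom_seqs <- setNames(as.character(genome), names(genome))
    qtl_chrom <- cfg$qtl_chrom %||% names(genome)[1]
    qtl_pos <- cfg$qtl_pos %||% floor(length(genome[[qtl_chrom]]) / 2)
    markers <- list()
    geno <- list()
    for (cn in names(genome)) {
      len <- nchar(chrom_seqs[[cn]])
      # markers at random positions with mean density 1 / marker_spacing
      pos <- sort(sample.int(len, max(2L, floor(len / cfg$marker_spacing))))
      ref <- base_at(chrom_seqs[[cn]], pos)
      alt <- chartr("ACGT", "CATG", ref)   # fixed transversion partner
      markers[[cn]] <- tibble(chrom = cn, pos = as.integer(pos),
                              ref = ref, alt = alt)
      r <- haldane(diff(pos) / 1e6 * cfg$cm_per_mb / 100)
      g1 <- gamete_chains(N, r)
      g2 <- gamete_chains(N, r)
      geno[[cn]] <- g1 + g2
    }
    qtl_idx <- which.min(abs(markers[[qtl_chrom]]$pos - qtl_pos))
    g_qtl <- geno[[qtl_chrom]][, qtl_idx]
    pheno <- cfg$qtl_effect * (g_qtl - 1) + rnorm(N)
    hi <- order(pheno, decreasing = TRUE)[seq_len(n_tail)]
    lo <- order(pheno)[seq_len(n_tail)]
    mk <- list_rbind(markers)
    af_hi <- unlist(lapply(geno, function(g) colSums(g[hi, , drop = FALSE])),
                    use.names = FALSE) / (2 * n_tail)
    af_lo <- unlist(lapply(geno, function(g) colSums(g[lo, , drop = FALSE])),
                    use.names = FALSE) / (2 * n_tail)
    pool1 <- finish_sample(mutate(mk, af_true = af_hi), cfg$read_depth,
                           "pool_high", drop_uncalled = FALSE)
    pool2 <- finish_sample(mutate(mk, af_true = af_lo), cfg$read_depth,
                           "pool_low", drop_uncalled = FALSE)
    qtl <- markers[[qtl_chrom]][qtl_idx, ]
    truth <- mutate(mk, af_true_high = af_hi, af_true_low = af_lo,
                    is_qtl = .data$chrom == qtl$chrom & .data$pos == qtl$pos)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_vcf(pool1, file.path(dir, "pool_high.vcf"), genome, "pool_high")
      write_vcf(pool2, file.path(dir, "pool_low.vcf"), genome, "pool_low")
      readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
    }
    list(pool1 = pool1, pool2 = pool2, truth = truth, qtl = qtl)
  })
}

#' Simulate an F2 mutant bulk for linkage mapping
#'
#' Single-cross F2 design: EMS mutations as in [simulate_backcross()], a
#' bulk of `population_size` individuals selected homozygous at the causal
#' site.  Both gametes of every individual carry the causal allele; linked
#' sites follow the same Markov recombination chain outward from the causal
#' locus, so their true allele frequency decays with the Haldane distance,
#' while unlinked sites segregate around 0.5.  Read counts are binomial at
#' `read_depth`.
#'
#' @param cfg A [sim_config()] with scenario `"f2"`.
#' @param genome,genes Output of [simulate_genome()].
#' @param dir Optional directory for `test.vcf`, `control.vcf`, `truth.tsv`.
#' @return A list with `test`, `control`, `truth`, `causal`.
#' @export
simulate_f2_bulk <- function(cfg, genome, genes, dir = NULL) {
  withr::with_seed(cfg$seed + 3L, {
    chrom_seqs <- setNames(as.character(genome), names(genome))
    causal <- pick_causal(genes, chrom_seqs)
    bg <- sim_background(cfg, chrom_seqs, exclude = causal[, c("chrom", "pos")])
    muts <- sample_gc_sites(chrom_seqs, cfg$n_mutations - 1L,
                            exclude = bind_rows(causal[, c("chrom", "pos")],
                                                bg[, c("chrom", "pos")]))
    muts$ref <- map2_chr_base(chrom_seqs, muts$chrom, muts$pos)
    muts$alt <- ems_alt(muts$ref)
    sites <- bind_rows(
      mutate(causal[, c("chrom", "pos", "ref", "alt")], causal = TRUE),
      mutate(muts, causal = FALSE)
    ) |> arrange(.data$chrom, .data$pos)
    n_gam <- 2L * cfg$population_size
    sites$af_true <- NA_real_
    for (cn in unique(sites$chrom)) {
      idx <- which(sites$chrom == cn)
      pos <- sites$pos[idx]
      r <- haldane(diff(pos) / 1e6 * cfg$cm_per_mb / 100)
      if (cn == causal$chrom) {
        ci <- which(sites$causal[idx])
        # chain conditioned on carrying the causal allele, run outward
        G <- matrix(1L, n_gam, length(idx))
        if (ci < length(idx)) {
          for (j in (ci + 1L):length(idx)) {
            sw <- rbinom(n_gam, 1L, r[j - 1L])
            G[, j] <- bitwXor(G[, j - 1L], sw)
          }
        }
        if (ci > 1L) {
          for (j in (ci - 1L):1L) {
            sw <- rbinom(n_gam, 1L, r[j])
            G[, j] <- bitwXor(G[, j + 1L], sw)
          }
        }
      } else {
        G <- gamete_chains(n_gam, r)
      }
      sites$af_true[idx] <- colMeans(G)
    }
    causal_gene <- causal$gene_id
    truth <- mutate(sites, gene_id = ifelse(.data$causal, causal_gene,
                                            NA_character_))
    test_sites <- bind_rows(mutate(bg, af_true = 1),
                            sites[, c("chrom", "pos", "ref", "alt",
                                      "af_true")])
    test <- finish_sample(test_sites, cfg$read_depth, "test") |>
      arrange_variants(genome)
    control <- finish_sample(mutate(bg, af_true = 1), cfg$read_depth,
                             "control") |>
      arrange_variants(genome)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_vcf(test, file.path(dir, "test.vcf"), genome, "test")
      write_vcf(control, file.path(dir, "control.vcf"), genome, "control")
      readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
    }
    list(test = test, control = control, truth = truth, causal = causal)
  })
}
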