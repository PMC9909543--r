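toy_gene_genome <- function() {
  # CDS 1-9 = ATGGCTTAA on the plus strand, then spacer sequence
  make_genome(list(c1 = paste0("ATGGCTTAA", strrep("ACGT", 300))))
}

toy_tx <- function() {
  mk_tx("g1", "c1", "+", data.frame(start = 1, end = 9),
        cds = data.frame(start = 1, end = 9))
}

ann1 <- function(v, genes, genome, ...) {
  annotate_variants(v, genes, genome, ...)
}

test_that("CDS SNP consequences: missense, stop loss, start loss, nonsense", {
  g <- toy_gene_genome()
  tx <- toy_tx()
  v <- variant_tbl("c1", 4, "G", "A", ref_count = 0, alt_count = 9)
  a <- ann1(v, tx, g)
  expect_identical(a$element, "cds")
  expect_identical(a$codon_change, "GCT>ACT")
  expect_identical(a$aa_change, "A2T")
  expect_identical(a$consequence, "missense")
  # TAA stop codon destroyed
  a2 <- ann1(variant_tbl("c1", 7, "T", "A", ref_count = 0, alt_count = 9),
             tx, g)
  expect_identical(a2$consequence, "stop_loss")
  expect_identical(a2$aa_change, "*3K")
  # start codon destroyed
  a3 <- ann1(variant_tbl("c1", 1, "A", "C", ref_count = 0, alt_count = 9),
             tx, g)
  expect_identical(a3$consequence, "start_loss")
  # premature stop: GCT -> TGA needs two changes, use C5 -> A? GAT; instead
  # mutate T6 -> A: GCA (still Ala, synonymous)
  a4 <- ann1(variant_tbl("c1", 6, "T", "A", ref_count = 0, alt_count = 9),
             tx, g)
  expect_identical(a4$consequence, "synonymous")
})

test_that("indel, splice, UTR, intron and intergenic elements resolve", {
  g <- toy_gene_genome()
  tx <- toy_tx()
  # 1-bp deletion inside CDS: frameshift; 3-bp: inframe
  d1 <- ann1(variant_tbl("c1", 3, "GG", "G", ref_count = 0, alt_count = 9),
             tx, g)
  expect_identical(d1$element, "cds")
  expect_identical(d1$consequence, "frameshift")
  d3 <- ann1(variant_tbl("c1", 3, "GGCT", "G", ref_count = 0, alt_count = 9),
             tx, g)
  expect_identical(d3$consequence, "inframe_indel")
  # far from any gene: intergenic
  far <- ann1(variant_tbl("c1", 1100, "A", "C", ref_count = 0, alt_count = 9),
              tx, g)
  expect_identical(far$element, "intergenic")
  expect_true(is.na(far$gene_id))
  # two-exon gene: splice sites are the first/last 2 intron nucleotides
  tx2 <- mk_tx("g2", "c1", "+", data.frame(start = c(101, 201),
                                           end = c(160, 260)),
               cds = data.frame(start = c(131, 201), end = c(160, 230)),
               phase = c(0L, 0L))
  sp <- ann1(variant_tbl("c1", 161, "A", "C", ref_count = 0, alt_count = 9),
             tx2, g)
  expect_identical(sp$element, "splice_site")
  expect_identical(sp$consequence, "splice_disruption")
  deep <- ann1(variant_tbl("c1", 180, "A", "C", ref_count = 0, alt_count = 9),
               tx2, g)
  expect_identical(deep$element, "intron")
  utr5 <- ann1(variant_tbl("c1", 110, "A", "C", ref_count = 0, alt_count = 9),
               tx2, g)
  expect_identical(utr5$element, "five_prime_utr")
  utr3 <- ann1(variant_tbl("c1", 240, "A", "C", ref_count = 0, alt_count = 9),
               tx2, g)
  expect_identical(utr3$element, "three_prime_utr")
  up <- ann1(variant_tbl("c1", 60, "A", "C", ref_count = 0, alt_count = 9),
             tx2, g)
  expect_identical(up$element, "upstream")
  # incomplete model: element only, flagged
  tx3 <- mk_tx("g3", "c1", "+", data.frame(start = 301, end = 330),
               cds = data.frame(start = 301, end = 310), incomplete = TRUE)
  inc <- ann1(variant_tbl("c1", 305, "A", "C", ref_count = 0, alt_count = 9),
              tx3, g)
  expect_identical(inc$element, "cds")
  expect_true(is.na(inc$aa_change))
  expect_identical(inc$flags, "incomplete_model")
})

test_that("consequences agree with the mutate-and-translate oracle", {
  set.seed(61)
  n_ok <- 0L
  for (i in 1:150) {
    fx <- random_gene_fixture()
    p <- sample(fx$cds_positions, 1)
    ref <- genome_seq(fx$genome, "cX", p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- variant_tbl("cX", p, ref, alt, ref_count = 0, alt_count = 9)
    got <- annotate_variants(v, fx$tx, fx$genome)
    expect_identical(got$element, "cds")
    orc <- oracle_snp_consequence(fx$genome, fx$tx, v)
    expect_identical(got$consequence, orc$consequence)
    if (!is.null(orc$aa_change) && got$consequence != "synonymous") {
      expect_identical(got$aa_change, orc$aa_change)
    }
    n_ok <- n_ok + 1L
  }
  expect_identical(n_ok, 150L)
})

test_that("minus-strand annotation equals the reverse-complemented mirror", {
  set.seed(62)
  for (i in 1:25) {
    fx <- random_gene_fixture()
    L <- length(fx$genome[[1]])
    # mirrored genome and coordinates
    g_rc <- make_genome(list(
      cX = as.character(Biostrings::reverseComplement(fx$genome[[1]]))))
    tx <- fx$tx
    flip <- function(df) {
      out <- data.frame(start = L - df$end + 1, end = L - df$start + 1,
                        df[setdiff(names(df), c("start", "end"))])
      out[order(out$start), , drop = FALSE]
    }
    tx_rc <- mk_tx("gX", "cX", ifelse(tx$strand == "+", "-", "+"),
                   flip(tx$exons[[1]]),
                   cds = flip(tx$cds[[1]])[c("start", "end")],
                   phase = flip(tx$cds[[1]])$phase)
    p <- sample(fx$cds_positions, 1)
    ref <- genome_seq(fx$genome, "cX", p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    a <- annotate_variants(variant_tbl("cX", p, ref, alt, ref_count = 0,
                                       alt_count = 9), fx$tx, fx$genome)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    b <- annotate_variants(variant_tbl("cX", L - p + 1, comp[[ref]],
                                       comp[[alt]], ref_count = 0,
                                       alt_count = 9), tx_rc, g_rc)
    expect_identical(a$consequence, b$consequence)
    expect_identical(a$aa_change, b$aa_change)
    expect_identical(a$codon_change, b$codon_change)
  }
})

test_that("flanks clip at chromosome ends and reconstruct the reference", {
  g <- make_genome(list(c1 = strrep("ACGTT", 20)))
  v <- variant_tbl("c1", 3, "G", "A", ref_count = 0, alt_count = 9)
  fl <- flanks(v, g, 25)
  expect_identical(fl$left, "AC")
  expect_identical(nchar(fl$right), 25L)
  mid <- variant_tbl("c1", 50, "T", "A", ref_count = 0, alt_count = 9)
  fm <- flanks(mid, g, 25)
  expect_identical(nchar(fm$left), 25L)
  expect_identical(nchar(fm$right), 25L)
  # left + ref + right is a verbatim reference substring (incl. indels)
  set.seed(63)
  for (i in 1:20) {
    pos <- sample(5:90, 1)
    ref <- genome_seq(g, "c1", pos, pos + sample(0:2, 1))
    alt <- if (nchar(ref) > 1) substr(ref, 1, 1) else
      setdiff(c("A", "C", "G", "T"), ref)[1]
    vv <- variant_tbl("c1", pos, ref, alt, ref_count = 0, alt_count = 9)
    f <- flanks(vv, g, 10)
    whole <- paste0(f$left, vv$ref, f$right)
    expect_true(grepl(whole, as.character(g[["c1"]]), fixed = TRUE))
  }
})

test_that("primer design: Wallace Tm, determinism, constraints, failures", {
  expect_equal(wallace_tm("ATGCATGCATGCATGCATGC"), 60)
  expect_equal(wallace_tm("AAAA"), 8)
  expect_true(is.na(wallace_tm("AANA")))
  set.seed(64)
  for (i in 1:20) {
    g <- make_genome(list(c1 = rand_bases(1200)))
    v <- variant_tbl("c1", 600, genome_seq(g, "c1", 600, 600),
                     ifelse(genome_seq(g, "c1", 600, 600) == "A", "C", "A"),
                     ref_count = 0, alt_count = 9)
    pr <- design_primers(v, g)
    if (is.null(attr(pr, "reason"))) {
      # product interval spans the variant, constraints hold
      expect_lte(pr$fwd_start, 600L)
      expect_gte(pr$rev_start + nchar(pr$rev_seq) - 1L, 600L)
      expect_gte(pr$product_size, 150L)
      expect_lte(pr$product_size, 800L)
      expect_lte(abs(pr$fwd_tm - pr$rev_tm), 3)
      for (s in c(pr$fwd_seq, pr$rev_seq)) {
        gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
        expect_gte(gc, 0.4)
        expect_lte(gc, 0.6)
        expect_gte(nchar(s), 18L)
        expect_lte(nchar(s), 24L)
      }
      # primers are verbatim genome sequence (fwd) / reverse complement (rev)
      expect_identical(pr$fwd_seq,
                       genome_seq(g, "c1", pr$fwd_start,
                                  pr$fwd_start + nchar(pr$fwd_seq) - 1L))
      # determinism
      expect_identical(design_primers(v, g), pr)
    }
  }
  # AT-only flanks: no GC-acceptable primer exists
  g_at <- make_genome(list(c1 = strrep("AT", 600)))
  v_at <- variant_tbl("c1", 600, "A", "C", ref_count = 0, alt_count = 9)
  pr_at <- design_primers(v_at, g_at)
  expect_identical(attr(pr_at, "reason"), "no_valid_primer")
})

test_that("analyze_set reports one row per variant-transcript with full schema", {
  cfg <- sim_config("backcross", seed = 65, n_chrom = 1, chrom_len = 1e5,
                    gene_spacing = 2.5e4, n_mutations = 5, n_background = 5)
  sim <- simulate_genome(cfg)
  bc <- simulate_backcross(cfg, sim$genome, sim$genes)
  v <- bc$test
  rec <- analyze_set(v, sim$genes, sim$genome)
  expect_true(all(c("chrom", "pos", "ref", "alt", "qual", "ref_count",
                    "alt_count", "af", "gene_id", "transcript_id", "element",
                    "codon_change", "aa_change", "consequence",
                    "functional_note", "fwd_primer", "rev_primer",
                    "fwd_tm", "rev_tm", "product_size", "flank_left",
                    "flank_right") %in% names(rec)))
  # every variant appears at least once; no extra variants invented
  expect_setequal(paste(rec$chrom, rec$pos, rec$ref, rec$alt),
                  paste(v$chrom, v$pos, v$ref, v$alt))
  # countless variants keep an empty af but are retained
  nc <- variant_tbl("chr1", 12345, genome_seq(sim$genome, "chr1", 12345, 12345),
                    ifelse(genome_seq(sim$genome, "chr1", 12345, 12345) == "A",
                           "C", "A"))
  rec2 <- analyze_set(nc, sim$genes, sim$genome, primers = FALSE)
  expect_gte(nrow(rec2), 1L)
  expect_true(all(is.na(rec2$af)))
  # in-gene annotated rows carry the functional note
  in_gene <- rec[!is.na(rec$gene_id) & rec$element == "cds", ]
  if (nrow(in_gene)) {
    expect_true(all(grepl("simulated", in_gene$functional_note)))
  }
})
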