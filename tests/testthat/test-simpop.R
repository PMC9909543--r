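test_that("identical configurations give byte-identical output files", {
  cfg <- sim_config("backcross", seed = 71, n_chrom = 1, chrom_len = 3e5,
                    gene_spacing = 2.5e4, n_mutations = 20, n_background = 20)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  unlink(c(d1, d2), recursive = TRUE)
  sim1 <- simulate_genome(cfg, dir = d1)
  simulate_backcross(cfg, sim1$genome, sim1$genes, dir = d1)
  sim2 <- simulate_genome(cfg, dir = d2)
  simulate_backcross(cfg, sim2$genome, sim2$genes, dir = d2)
  for (f in c("genome.fa", "annotation.gff3", "test.vcf", "control.vcf",
              "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the output
  cfg2 <- sim_config("backcross", seed = 72, n_chrom = 1, chrom_len = 3e5,
                     gene_spacing = 2.5e4, n_mutations = 20,
                     n_background = 20)
  sim3 <- simulate_genome(cfg2)
  expect_false(identical(as.character(sim1$genome), as.character(sim3$genome)))
})

test_that("every simulated CDS translates start-to-stop without internal stops", {
  cfg <- sim_config("backcross", seed = 73, n_chrom = 2, chrom_len = 2e5,
                    gene_spacing = 2.5e4)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$genes), 2 * floor(2e5 / 2.5e4))
  for (i in seq_len(nrow(sim$genes))) {
    tx <- sim$genes[i, ]
    cd <- tx$cds[[1]]
    s <- paste(vapply(seq_len(nrow(cd)), function(k) {
      genome_seq(sim$genome, tx$chrom, cd$start[k], cd$end[k])
    }, character(1)), collapse = "")
    if (tx$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    expect_identical(nchar(s) %% 3L, 0L)
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_identical(substr(prot, 1, 1), "M")
    expect_identical(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
  }
})

test_that("backcross simulator: unlinked survival matches (1/2)^k closed form", {
  # small genome, many mutations; pool unlinked sites over seeded runs
  cfg0 <- sim_config("backcross", seed = 74, n_chrom = 2, chrom_len = 1e5,
                     gene_spacing = 2.5e4, n_mutations = 40,
                     n_background = 0)
  sim <- simulate_genome(cfg0)
  surv <- 0L
  tot <- 0L
  for (s in 1:60) {
    cfg <- sim_config("backcross", seed = s, n_chrom = 2, chrom_len = 1e5,
                      gene_spacing = 2.5e4, n_mutations = 40,
                      n_background = 0)
    bc <- simulate_backcross(cfg, sim$genome, sim$genes)
    unl <- bc$truth[!bc$truth$causal &
                      bc$truth$chrom != bc$causal$chrom, ]
    surv <- surv + sum(unl$survived)
    tot <- tot + nrow(unl)
  }
  p_hat <- surv / tot
  p <- 0.5^cfg0$n_backcrosses
  se <- sqrt(p * (1 - p) / tot)
  expect_lt(abs(p_hat - p), 3 * se + 1e-12)
  # causal site: survival forced, af 1, full-depth alt count at high depth
  cfgd <- sim_config("backcross", seed = 75, n_chrom = 1, chrom_len = 1e5,
                     gene_spacing = 2.5e4, n_mutations = 10,
                     n_background = 0, read_depth = 5000)
  simd <- simulate_genome(cfgd)
  bcd <- simulate_backcross(cfgd, simd$genome, simd$genes)
  crow <- dplyr::inner_join(bcd$test, bcd$causal,
                            by = c("chrom", "pos", "ref", "alt"))
  expect_identical(nrow(crow), 1L)
  expect_identical(crow$alt_count, 5000L)
  expect_equal(crow$af, 1)
})

test_that("QTL-seq simulator: unselected pools sit at af 0.5; saturation at the QTL", {
  cfg0 <- sim_config("qtlseq", seed = 76, n_chrom = 1, chrom_len = 2e6,
                     qtl_effect = 0)
  sim <- simulate_genome(cfg0)
  afs <- c()
  for (s in 1:15) {
    cfg <- sim_config("qtlseq", seed = s, n_chrom = 1, chrom_len = 2e6,
                      qtl_effect = 0)
    qq <- simulate_qtlseq(cfg, sim$genome)
    afs <- c(afs, qq$truth$af_true_high, qq$truth$af_true_low)
  }
  # genotype-frequency sampling: mean 0.5, sd 1/sqrt(8 * bulk) per marker;
  # markers within a run are correlated, so test the global mean loosely
  # against 3 SE computed from the empirical sd
  se <- sd(afs) / sqrt(length(afs) / 20)  # ~20 correlated markers per chrom
  expect_lt(abs(mean(afs) - 0.5), 3 * se)
  # strong effect: high bulk fixed at the QTL marker, daf -> 1 nearby
  cfg1 <- sim_config("qtlseq", seed = 77, n_chrom = 1, chrom_len = 2e6,
                     qtl_effect = 50)
  q1 <- simulate_qtlseq(cfg1, sim$genome)
  at_qtl <- q1$truth[q1$truth$is_qtl, ]
  expect_equal(at_qtl$af_true_high, 1)
  expect_lt(at_qtl$af_true_low, 0.1)
})

test_that("F2 bulk: causal fixed, linked af decays monotonically with distance", {
  cfg0 <- sim_config("f2", seed = 78, n_chrom = 2, chrom_len = 5e6,
                     n_mutations = 60)
  sim <- simulate_genome(cfg0)
  dist_bins <- seq(0, 5e6, by = 1e6)
  sums <- numeric(length(dist_bins) - 1)
  cnts <- numeric(length(dist_bins) - 1)
  unlinked_af <- c()
  for (s in 1:15) {
    cfg <- sim_config("f2", seed = s, n_chrom = 2, chrom_len = 5e6,
                      n_mutations = 60)
    ff <- simulate_f2_bulk(cfg, sim$genome, sim$genes)
    expect_equal(ff$truth$af_true[ff$truth$causal], 1)
    linked <- ff$truth[!ff$truth$causal &
                         ff$truth$chrom == ff$causal$chrom, ]
    d <- abs(linked$pos - ff$causal$pos)
    b <- cut(d, dist_bins, labels = FALSE)
    for (k in unique(b)) {
      sums[k] <- sums[k] + sum(linked$af_true[b == k])
      cnts[k] <- cnts[k] + sum(b == k)
    }
    unlinked_af <- c(unlinked_af,
                     ff$truth$af_true[ff$truth$chrom != ff$causal$chrom])
  }
  means <- sums / cnts
  keep <- cnts > 20
  expect_true(all(diff(means[keep]) < 0.02))  # non-increasing trend
  expect_gt(means[1], 0.9)
  expect_lt(abs(mean(unlinked_af) - 0.5), 0.05)
})

test_that("simulator VCF outputs are re-readable with defined af everywhere", {
  d <- file.path(tempdir(), "sim_reread")
  unlink(d, recursive = TRUE)
  cfg <- sim_config("qtlseq", seed = 79, n_chrom = 1, chrom_len = 1e6)
  sim <- simulate_genome(cfg, dir = d)
  simulate_qtlseq(cfg, sim$genome, dir = d)
  g <- read_genome(file.path(d, "genome.fa"))
  expect_identical(chrom_lengths(g)$length, 1000000L)
  p1 <- read_vcf(file.path(d, "pool_high.vcf"), genome = g)
  p2 <- read_vcf(file.path(d, "pool_low.vcf"), genome = g)
  expect_false(anyNA(p1$af))
  expect_false(anyNA(p2$af))
  genes <- read_gff(file.path(d, "annotation.gff3"), g)
  expect_gt(nrow(genes), 0L)
})
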