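test_that("mapping-variant selection keeps shared segregating sites only", {
  p1 <- variant_tbl(rep("c1", 4), c(10, 20, 30, 40), rep("G", 4),
                    rep("A", 4), ref_count = c(10, 0, 10, 10),
                    alt_count = c(10, 20, 10, 10))
  p2 <- variant_tbl(rep("c1", 3), c(20, 30, 40), rep("G", 3), rep("A", 3),
                    ref_count = c(0, 12, 2), alt_count = c(20, 8, 1))
  m <- select_mapping_variants(p1, p2)
  # pos 10 only in pool1; pos 20 fixed (af = 1) in both; pos 40 fails depth
  expect_identical(m$pos, 30L)
  expect_equal(m$daf, 0.5 - 0.4)
  expect_equal(m$af1, 0.5)
  # af = 0.5 in both pools is kept with daf 0
  expect_equal(select_mapping_variants(p1[3, ], p1[3, ])$daf, 0)
  # indels excluded by default, admitted on request
  pi1 <- variant_tbl("c1", 50, "G", "GAT", ref_count = 5, alt_count = 5)
  expect_identical(nrow(select_mapping_variants(pi1, pi1)), 0L)
  expect_identical(nrow(select_mapping_variants(pi1, pi1,
                                                snp_only = FALSE)), 1L)
  und <- variant_tbl("c1", 60, "G", "A")
  expect_error(select_mapping_variants(und, und), "defined allele")
})

test_that("windowed dAF is the per-window arithmetic mean (oracle check)", {
  g <- make_genome(list(c1 = strrep("A", 1000)))
  m <- tibble::tibble(chrom = "c1", pos = c(100L, 200L, 700L),
                      ref = "G", alt = "A",
                      af1 = c(0.9, 0.8, 0.4), af2 = c(0.1, 0.2, 0.4))
  m$daf <- m$af1 - m$af2
  prof <- window_daf(m, g, window_spec(500, 500))
  expect_equal(prof$daf_mean, c(0.7, 0))
  expect_identical(prof$n_variants, c(2L, 1L))
  # empty window undefined
  prof2 <- window_daf(m[3, ], g, window_spec(500, 500))
  expect_true(is.na(prof2$daf_mean[1]))
  expect_identical(prof2$n_variants[1], 0L)
  # 1000-variant brute-force equality
  set.seed(31)
  lens <- c(c1 = 4e5, c2 = 2e5)
  gg <- make_genome(list(c1 = strrep("A", 4e5), c2 = strrep("A", 2e5)))
  v <- rand_variants(1000, lens)
  mv <- tibble::tibble(chrom = v$chrom, pos = v$pos, ref = v$ref,
                       alt = v$alt, af1 = runif(nrow(v)),
                       af2 = runif(nrow(v)))
  mv$daf <- mv$af1 - mv$af2
  spec <- window_spec(5e4, 2.5e4)
  got <- window_daf(mv, gg, spec)
  expect_equal(got$daf_mean,
               bf_window_mean(mv, mv$daf, lens, spec$size, spec$step))
})

test_that("WMA smoothing renormalizes at edges and bridges empty windows", {
  g <- make_genome(list(c1 = strrep("A", 5000)))
  mk_prof <- function(vals) {
    p <- genome_windows(g, window_spec(1000, 1000))
    p$n_variants <- ifelse(is.na(vals), 0L, 5L)
    p$daf_mean <- vals
    class(p) <- c("daf_profile", class(p))
    p
  }
  # constant profile is unchanged
  sm <- wma_smooth(mk_prof(rep(0.4, 5)))
  expect_equal(sm$daf_wma, rep(0.4, 5))
  # single interior spike with zero neighbors: center = 0.9 * 3 / 9
  sm2 <- wma_smooth(mk_prof(c(0, 0, 0.9, 0, 0)))
  expect_equal(sm2$daf_wma[3], 0.3)
  # first window of a chromosome: truncated kernel, renormalized weights
  g3 <- make_genome(list(c1 = strrep("A", 3000)))
  p3 <- genome_windows(g3, window_spec(1000, 1000))
  p3$n_variants <- 5L
  p3$daf_mean <- c(0.6, 0.3, 0.9)
  class(p3) <- c("daf_profile", class(p3))
  sm3 <- wma_smooth(p3)
  expect_equal(sm3$daf_wma[1], (3 * 0.6 + 2 * 0.3 + 1 * 0.9) / 6)
  expect_equal(sm3$daf_wma[2], (2 * 0.6 + 3 * 0.3 + 2 * 0.9) / 7)
  # NA window is bridged: excluded from support, receives a value
  sm4 <- wma_smooth(mk_prof(c(0.5, NA, 0.7, 0.6, 0.4)))
  expect_equal(sm4$daf_wma[2], (2 * 0.5 + 2 * 0.7 + 1 * 0.6) / 5,
               tolerance = 1e-12)
  # property: smoothing preserves the per-chromosome range (seeded)
  set.seed(32)
  for (rep in 1:20) {
    vals <- runif(12, -1, 1)
    vals[sample(12, 3)] <- NA
    gg <- make_genome(list(c1 = strrep("A", 12000)))
    pp <- genome_windows(gg, window_spec(1000, 1000))
    pp$n_variants <- ifelse(is.na(vals), 0L, 2L)
    pp$daf_mean <- vals
    class(pp) <- c("daf_profile", class(pp))
    smp <- wma_smooth(pp)
    expect_true(all(smp$daf_wma >= min(vals, na.rm = TRUE) - 1e-12,
                    na.rm = TRUE))
    expect_true(all(smp$daf_wma <= max(vals, na.rm = TRUE) + 1e-12,
                    na.rm = TRUE))
    # and equals the brute-force kernel loop
    expect_equal(smp$daf_wma, bf_wma(vals, c(1, 2, 3, 2, 1)))
  }
})

test_that("region calling finds sign-constant runs above threshold", {
  g <- make_genome(list(c1 = strrep("A", 10000)))
  mk_sm <- function(wma) {
    p <- genome_windows(g, window_spec(1000, 1000))
    p$n_variants <- 1L
    p$daf_mean <- wma
    p$daf_wma <- wma
    class(p) <- c("daf_profile", class(p))
    p
  }
  expect_identical(nrow(call_qtl_regions(mk_sm(rep(0.2, 10)))), 0L)
  r <- call_qtl_regions(mk_sm(c(0, 0, 0.6, 0.6, 0.6, 0.6, 0.6, 0, 0, 0)))
  expect_identical(nrow(r), 1L)
  expect_identical(r$sign, "+")
  expect_identical(c(r$start, r$end), c(2001L, 7000L))
  expect_equal(r$extremum, 0.6)
  # sign flip splits a run
  r2 <- call_qtl_regions(mk_sm(c(0.4, 0.4, 0.4, -0.4, -0.4, -0.4,
                                 0, 0, 0, 0)))
  expect_identical(nrow(r2), 2L)
  expect_setequal(r2$sign, c("+", "-"))
  # short runs are dropped by min_run
  r3 <- call_qtl_regions(mk_sm(c(0.4, 0.4, 0, 0, 0, 0, 0, 0, 0, 0)))
  expect_identical(nrow(r3), 0L)
  # brute-force run enumeration on random profiles
  set.seed(33)
  for (rep in 1:20) {
    wma <- round(runif(10, -1, 1), 2)
    wma[sample(10, 2)] <- NA
    got <- call_qtl_regions(mk_sm(wma), daf_min = 0.3, min_run = 2)
    runs <- bf_runs(wma[!is.na(wma)], 0.3, 2)
    expect_identical(nrow(got), length(runs))
  }
})

test_that("swapping the pools negates dAF and region signs exactly", {
  cfg <- sim_config("qtlseq", seed = 44, n_chrom = 2, chrom_len = 5e6)
  sim <- simulate_genome(cfg)
  qq <- simulate_qtlseq(cfg, sim$genome)
  a <- qtl_scan(qq$pool1, qq$pool2, sim$genome)
  b <- qtl_scan(qq$pool2, qq$pool1, sim$genome)
  expect_equal(a$profile$daf_mean, -b$profile$daf_mean)
  expect_equal(a$profile$daf_wma, -b$profile$daf_wma)
  expect_identical(nrow(a$regions), nrow(b$regions))
  if (nrow(a$regions)) {
    aa <- dplyr::arrange(a$regions, chrom, start)
    bb <- dplyr::arrange(b$regions, chrom, start)
    expect_identical(aa$start, bb$start)
    expect_identical(aa$end, bb$end)
    expect_equal(aa$extremum, -bb$extremum)
    expect_true(all(aa$sign != bb$sign))
  }
})
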