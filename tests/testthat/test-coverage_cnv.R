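# Coverage statistics and depth-rate CNV detection

toy_panel <- function(width = 100L) {
  gene_panel(data.frame(chrom = "c1", start = 0L, end = width, gene = "G1",
                        region_class = "CDS", exon_index = 1L))
}

test_that("coverage statistics match per-base counting", {
  p <- toy_panel()
  uni <- depth_table(data.frame(chrom = "c1", pos = 1:100, depth = 50L))
  r <- coverage_stats(uni, p, thresholds = c(1, 20, 51))
  expect_equal(r$mean_depth_target, 50)
  expect_equal(unname(r$coverage_at), c(100, 100, 0))

  zero <- depth_table(data.frame(chrom = character(), pos = integer(),
                                 depth = integer()))
  r0 <- coverage_stats(zero, p, thresholds = c(1, 20))
  expect_equal(r0$mean_depth_target, 0)
  expect_equal(unname(r0$coverage_at), c(0, 0))

  # half at 10x, half at 30x: direct per-base oracle
  half <- depth_table(data.frame(chrom = "c1", pos = 1:100,
                                 depth = rep(c(10L, 30L), each = 50)))
  rh <- coverage_stats(half, p, thresholds = c(1, 20))
  expect_equal(rh$coverage_at[["20"]], 50.0)
  expect_equal(rh$mean_depth_target, 20.0)

  expect_error(coverage_stats(uni, gene_panel(data.frame())), "empty panel")
})

test_that("coverage_at is non-increasing in the threshold", {
  set.seed(11)
  p <- toy_panel(400L)
  d <- depth_table(data.frame(chrom = "c1", pos = 1:400,
                              depth = rpois(400, 30)))
  r <- coverage_stats(d, p, thresholds = c(1, 5, 10, 20, 40, 80))
  expect_true(all(diff(unname(r$coverage_at)) <= 0))
  expect_true(all(r$coverage_at >= 0 & r$coverage_at <= 100))
})

test_that("flanking regions exclude target bases and clip at the origin", {
  p <- toy_panel()  # target 1..100 (1-based)
  d <- depth_table(data.frame(chrom = "c1", pos = 1:300,
                              depth = rep(7L, 300)))
  r <- coverage_stats(d, p, flank_bp = 200)
  # left flank would be -199..0 -> clipped away entirely; right 101..300
  expect_equal(r$mean_depth_flanking, 7)
  expect_equal(r$coverage_flanking_1x, 100)
  # capture specificity is a plain ratio of the supplied totals
  r2 <- coverage_stats(d, p, mapped_total = 48535673,
                       mapped_on_target = 25879159)
  expect_equal(r2$capture_specificity, 100 * 25879159 / 48535673)
})

test_that("depth rates normalize out per-sample scale", {
  p <- gen_panel(sim_config(genes = c("G1", "G2"), n_regions_per_gene = 1L))
  m <- rbind(a = c(412, 412), b = c(100, 300), c = c(600, 600))
  dm <- depth_matrix(m, p, sample_mean_depth = c(a = 412, b = 200, c = 600))
  rates <- region_depth_rates(dm)
  expect_equal(unname(rates["a", 1]), 1.0)
  expect_equal(unname(rates["b", ]), c(0.5, 1.5))
  # scaling a sample's depths leaves its rates unchanged
  m2 <- m; m2["b", ] <- m2["b", ] * 3
  dm2 <- depth_matrix(m2, p, sample_mean_depth = c(a = 412, b = 600, c = 600))
  expect_equal(region_depth_rates(dm2)["b", ], rates["b", ])
  # zero-mean samples are excluded with a warning
  dm0 <- depth_matrix(m, p, sample_mean_depth = c(a = 412, b = 0, c = 600))
  expect_warning(r0 <- region_depth_rates(dm0), "zero mean depth")
  expect_equal(rownames(r0), c("a", "c"))
})

test_that("z-scores match hand arithmetic and the two-pass oracle", {
  rates <- rbind(t1 = c(0.4), b1 = c(1.0), b2 = c(0.9), b3 = c(1.1),
                 b4 = c(1.0))
  z <- cnv_zscores(rates, "t1")
  expect_equal(unname(z), (0.4 - 1.0) / sd(c(1.0, 0.9, 1.1, 1.0)))
  expect_equal(unname(z), -7.348, tolerance = 1e-3)

  # test rate equal to the baseline mean -> z = 0
  rates2 <- rbind(t1 = 1.0, b1 = 0.9, b2 = 1.0, b3 = 1.1)
  expect_equal(unname(cnv_zscores(rates2, "t1")), 0)

  # degenerate baseline (identical rates) -> uninformative
  rates3 <- rbind(t1 = 1.0, b1 = 1.0, b2 = 1.0, b3 = 1.0)
  expect_true(is.na(cnv_zscores(rates3, "t1")))

  # fewer than 3 baseline samples is an error
  expect_error(cnv_zscores(rates3[1:3, , drop = FALSE], "t1"), "baseline")

  set.seed(77)
  for (i in 1:20) {
    r <- matrix(runif(6 * 8, 0.5, 1.5), nrow = 6,
                dimnames = list(paste0("s", 1:6), NULL))
    s <- sample(6, 1)
    expect_equal(unname(cnv_zscores(r, s)), oracle_zscores(r, s),
                 tolerance = 1e-9)
  }
})

test_that("CNV calling is strict at the cutoff and merges within genes", {
  p <- gen_panel(sim_config(genes = c("GA", "GB"), n_regions_per_gene = 5L))
  # boundary: exactly -3 / +3 is not called
  z <- c(-3.0, 3.0, rep(0, 8))
  expect_equal(nrow(call_cnvs(z, p)), 0L)

  # 5 exons of GA: three deletions then quiet -> one merged call
  z <- c(-5, -6, -4, 0.2, 0.1, rep(0, 5))
  calls <- call_cnvs(z, p, sample_id = "s1")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$direction, "deletion")
  expect_equal(calls$regions[[1]], 1:3)
  expect_equal(calls$z_extreme, -6)
  expect_equal(calls$gene, "GA")

  # single-exon duplication
  z <- c(rep(0, 7), 3.5, 0, 0)
  calls <- call_cnvs(z, p)
  expect_equal(calls$direction, "duplication")
  expect_equal(calls$n_regions, 1L)

  # same-direction runs crossing a gene boundary stay separate calls
  z <- c(rep(0, 3), -4, -5, -4.5, rep(0, 4))  # exons 4-5 of GA, exon 1 of GB
  calls <- call_cnvs(z, p)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$gene, c("GA", "GB"))
})

test_that("the z cutoff maps to the stated one-tailed normal percentile", {
  expect_equal(zscore_percentile(0), 50.0)
  expect_equal(round(zscore_percentile(3), 1), 99.9)
  expect_equal(zscore_percentile(Inf), 100.0)
})

test_that("null depth matrices are calibrated and implants are recovered", {
  # null calibration: no implants, 20 samples
  zs <- c()
  for (seed in 1:3) {
    dm <- gen_depth_matrix(sim_config(seed = seed, n_samples = 20,
                                      run_size = 20))
    rates <- region_depth_rates(dm$runs[[1]])
    zs <- c(zs, unlist(lapply(rownames(rates), function(s)
      cnv_zscores(rates, s))))
  }
  expect_lt(mean(abs(zs) > 3, na.rm = TRUE), 0.02)
  expect_lt(abs(mean(zs, na.rm = TRUE)), 0.1)
  expect_gt(sd(zs, na.rm = TRUE), 0.8)
  expect_lt(sd(zs, na.rm = TRUE), 1.3)

  # implant recovery over replicates: het events >= 95%, hom 100%
  hit <- data.frame(het_del = logical(0), dup = logical(0),
                    hom_del = logical(0))
  for (seed in 1:40) {
    ev <- data.frame(sample = c("S01", "S02", "S03"),
                     gene = c("GCK", "HNF1A", "INS"),
                     exon_from = c(3L, 5L, 2L), exon_to = c(3L, 5L, 2L),
                     copy_factor = c(0.5, 1.5, 0))
    dm <- gen_depth_matrix(sim_config(seed = 1000 + seed, n_samples = 20,
                                      run_size = 20, cnv_events = ev))
    rates <- region_depth_rates(dm$runs[[1]])
    got <- vapply(1:3, function(i) {
      z <- cnv_zscores(rates, ev$sample[i])
      calls <- call_cnvs(z, dm$panel, sample_id = ev$sample[i])
      want <- if (ev$copy_factor[i] < 1) "deletion" else "duplication"
      ridx <- dm$manifest$region_from[i]:dm$manifest$region_to[i]
      any(vapply(seq_len(nrow(calls)), function(j)
        calls$direction[j] == want &&
          length(intersect(calls$regions[[j]], ridx)) > 0, logical(1)))
    }, logical(1))
    hit <- rbind(hit, data.frame(het_del = got[1], dup = got[2],
                                 hom_del = got[3]))
  }
  expect_gte(mean(hit$het_del), 0.95)
  expect_gte(mean(hit$dup), 0.95)
  expect_equal(mean(hit$hom_del), 1.0)
})
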