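# Truth-set confusion counting and accuracy/precision reporting

cov1000 <- data.frame(chrom = "panelsim1", pos = 1:1000,
                      stringsAsFactors = FALSE)
empty_vt <- function() variant_table(data.frame(
  chrom = character(), pos = integer(), ref = character(),
  alt = character()))

test_that("confusion counting handles the definition cases", {
  c0 <- confusion_counts(empty_vt(), empty_vt(), cov1000)
  expect_equal(c0$tn, 1000L)
  expect_equal(c0$tp + c0$fp + c0$fn, 0L)

  cov100 <- cov1000[1:100, ]
  calls <- make_variants(make_variant(10, "intron"))
  truth <- make_variants(make_variant(10, "intron"),
                         make_variant(20, "intron"))
  cc <- confusion_counts(calls, truth, cov100)
  expect_equal(cc$tp, 1L)
  expect_equal(cc$fn, 1L)
  expect_equal(cc$fp, 0L)
  expect_equal(cc$tn, 98L)

  # calls outside the covered set are ignored but counted
  calls2 <- make_variants(make_variant(10, "intron"),
                          make_variant(500, "intron"))
  cc2 <- confusion_counts(calls2, truth, cov100)
  expect_equal(cc2$n_outside, 1L)
  expect_equal(cc2$tp, 1L)

  # sub-threshold calls are discarded before counting
  low <- make_variants(make_variant(10, "intron", quality = 5))
  cc3 <- confusion_counts(low, truth, cov100)
  expect_equal(cc3$tp, 0L)
  expect_equal(cc3$fn, 2L)
})

test_that("randomized fixtures agree with a position-by-position oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 300L
    covered <- data.frame(chrom = "panelsim1", pos = sort(sample(2000, n)))
    tpos <- sample(covered$pos, 25)
    truth <- variant_table(do.call(rbind, lapply(tpos, function(p)
      make_variant(p, "intron"))))
    # calls: most truth sites, some with wrong alt, some noise, some low-qual
    cpos <- sample(tpos, 18)
    rows <- lapply(cpos, function(p) {
      r <- make_variant(p, "intron")
      if (runif(1) < 0.2) r$alt <- "C"  # allele mismatch
      r
    })
    noise <- sample(setdiff(covered$pos, tpos), 10)
    rows <- c(rows, lapply(noise, function(p)
      make_variant(p, "intron",
                   quality = sample(c(5, 60), 1))))
    calls <- variant_table(do.call(rbind, rows))
    got <- confusion_counts(calls, truth, covered)
    want <- oracle_confusion(calls, truth, covered)
    expect_equal(got[c("tp", "tn", "fp", "fn")], want)
    # conservation
    expect_equal(got$tp + got$tn + got$fp + got$fn, nrow(covered))
  }
})

test_that("swapping calls and truth swaps FP with FN", {
  set.seed(8)
  covered <- data.frame(chrom = "panelsim1", pos = 1:500)
  truth <- variant_table(do.call(rbind, lapply(sample(500, 20), function(p)
    make_variant(p, "intron"))))
  calls <- variant_table(do.call(rbind, lapply(sample(500, 20), function(p)
    make_variant(p, "intron"))))
  a <- confusion_counts(calls, truth, covered)
  b <- confusion_counts(truth, calls, covered)
  expect_equal(a$tp, b$tp)
  expect_equal(a$tn, b$tn)
  expect_equal(a$fp, b$fn)
  expect_equal(a$fn, b$fp)
})

test_that("reports compute the ratio arithmetic at stated rounding", {
  perfect <- structure(list(covered_bp = 100L, tp = 5L, tn = 95L, fp = 0L,
                            fn = 0L, n_outside = 0L),
                       class = "confusion_counts")
  r <- bench_report(perfect)
  expect_equal(r$accuracy, 100)
  expect_equal(r$precision, 100)
  expect_equal(r$tp_ratio, 100)

  none <- structure(list(covered_bp = 100L, tp = 0L, tn = 99L, fp = 1L,
                         fn = 0L, n_outside = 0L),
                    class = "confusion_counts")
  r0 <- bench_report(none)
  expect_true(is.na(r0$tp_ratio))
  expect_true(is.na(r0$fn_ratio))

  # the text-formula variant of precision equals the TP ratio
  some <- structure(list(covered_bp = 1000L, tp = 90L, tn = 890L, fp = 10L,
                         fn = 10L, n_outside = 0L),
                    class = "confusion_counts")
  expect_equal(bench_report(some, "tp_over_tp_fn")$precision,
               bench_report(some)$tp_ratio)
})

test_that("planted error rates are recovered within 3 binomial SEs", {
  # pooled over replicates of 10,000 covered sites each
  tot <- list(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (seed in 13:17) {
    cfg <- sim_config(seed = seed, error_rates = c(fp = 0.002, fn = 0.1))
    g <- gen_bench_pair(n_covered = 10000L, n_truth = 400L, cfg = cfg)
    cc <- confusion_counts(g$calls, g$truth, g$covered)
    # generator-side tally is the exact oracle for its own pair
    expect_equal(cc[c("tp", "tn", "fp", "fn")],
                 g$expected[c("tp", "tn", "fp", "fn")])
    for (k in names(tot)) tot[[k]] <- tot[[k]] + cc[[k]]
  }
  fn_hat <- tot$fn / (tot$tp + tot$fn)
  se_fn <- sqrt(0.1 * 0.9 / (tot$tp + tot$fn))
  expect_lt(abs(fn_hat - 0.1), 3 * se_fn)
  fp_hat <- tot$fp / (tot$tn + tot$fp)
  se_fp <- sqrt(0.002 * 0.998 / (tot$tn + tot$fp))
  expect_lt(abs(fp_hat - 0.002), 3 * se_fp)
})

test_that("covered positions derive from depth and the panel", {
  p <- gene_panel(data.frame(chrom = "c1", start = 0L, end = 10L,
                             gene = "G", region_class = "CDS",
                             exon_index = 1L))
  d <- depth_table(data.frame(chrom = "c1", pos = 1:10,
                              depth = c(rep(25L, 6), rep(5L, 4))))
  cov <- covered_positions(d, p, min_depth = 20)
  expect_equal(cov$pos, 1:6)
})
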