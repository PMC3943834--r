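# Candidate filtering and pathogenicity triage

test_that("filter keeps functional rare variants and drops the rest", {
  cfg <- triage_config(restrict_genes = c("GCK", "HNF1A"))
  v <- make_variants(
    make_variant(1, "missense", quality = 35),                 # keep
    make_variant(2, "synonymous", quality = 99),               # non-functional
    make_variant(3, "missense", afs = c(g1000 = 0.05)),        # common
    make_variant(4, "missense", quality = 10),                 # low quality
    make_variant(5, "missense", gene = "TTN"),                 # off panel
    make_variant(6, "frameshift", vtype = "deletion"),         # keep
    make_variant(7, "intron", vtype = "deletion"),             # non-functional
    make_variant(8, "missense", afs = c(g1000 = 0.005)))       # rare: keep
  out <- filter_candidates(v, cfg)
  expect_equal(out$pos, c(1, 6, 8))
  # rarity means rare in every database where observed
  both <- make_variants(make_variant(9, "missense",
                                     afs = c(g1000 = 0.005, hapmap = 0.02)))
  expect_equal(nrow(filter_candidates(both, cfg)), 0L)
})

test_that("filter agrees with an enumerated predicate oracle on 200 variants", {
  set.seed(5)
  genes <- c("GCK", "HNF1A", "HNF4A")
  rows <- lapply(1:200, function(i) {
    make_variant(i,
                 consequence = sample(c("missense", "synonymous", "intron",
                                        "nonsense", "frameshift"), 1),
                 vtype = sample(c("SNV", "deletion"), 1,
                                prob = c(0.8, 0.2)),
                 quality = sample(c(10, 25, 60), 1),
                 afs = if (runif(1) < 0.4)
                   c(g1000 = sample(c(0.001, 0.05), 1)) else numeric(),
                 gene = sample(c(genes, "TTN"), 1))
  })
  # vtype/consequence pairings must stay coherent for the fixture
  rows <- lapply(rows, function(r) {
    if (r$vtype != "SNV" && r$consequence %in% c("missense", "nonsense"))
      r$consequence <- "frameshift"
    if (r$vtype == "SNV" && r$consequence == "frameshift")
      r$consequence <- "missense"
    r
  })
  v <- variant_table(do.call(rbind, rows))
  cfg <- triage_config(restrict_genes = genes)
  keep <- oracle_filter(v, min_q = 20, max_af = 0.01, genes = genes)
  out <- filter_candidates(v, cfg)
  expect_equal(out$pos, v$pos[keep])
  expect_gt(sum(keep), 0)

  # idempotent and order-independent
  expect_equal(filter_candidates(out, cfg), out)
  shuf <- v[sample(nrow(v)), , drop = FALSE]
  out2 <- filter_candidates(shuf, cfg)
  expect_setequal(out2$pos, out$pos)
})

test_that("tiers follow the four-rule decision order", {
  known <- structure(data.frame(chrom = "panelsim1", pos = 50L, ref = "A",
                                alt = "G", gene = "GCK",
                                citation_id = "LSDB1",
                                stringsAsFactors = FALSE),
                     class = c("known_table", "data.frame"))
  cfg <- triage_config()
  tier_of <- function(v) as.character(classify_variants(v, known, cfg)$tier)

  # novel stop-gain -> pathogenic
  expect_equal(tier_of(make_variants(make_variant(1, "nonsense"))),
               "pathogenic")
  # knowledge-table match -> pathogenic even as missense
  expect_equal(tier_of(make_variants(make_variant(50, "missense"))),
               "pathogenic")
  # conserved novel missense with a single damaging verdict -> suspected
  v <- make_variants(make_variant(2, "missense", conserved = TRUE,
                                  preds = c(SIFT = "damaging")))
  cls <- classify_variants(v, known, cfg)
  expect_equal(as.character(cls$tier), "suspected_pathogenic")
  expect_true("conserved_missense" %in% cls$evidence[[1]])
  # GT/AG-breaking splice variant -> suspected
  expect_equal(tier_of(make_variants(make_variant(3, "splice_site",
                                                  gtat = TRUE))),
               "suspected_pathogenic")
  # predictor consensus (2 damaging of 4) -> suspected
  expect_equal(tier_of(make_variants(
    make_variant(4, "missense",
                 preds = c(SIFT = "damaging", PolyPhen2 = "damaging",
                           MutationTaster = "benign", BDGP = "unknown")))),
    "suspected_pathogenic")
  # control-cohort variant with no other evidence -> polymorphism
  expect_equal(tier_of(make_variants(make_variant(5, "missense",
                                                  afs = c(control = 0.004)))),
               "polymorphism")
  # nothing fires -> unknown significance
  expect_equal(tier_of(make_variants(
    make_variant(6, "missense", preds = c(SIFT = "damaging")))),
    "unknown_significance")
})

test_that("every variant gets exactly one tier and evidence is monotone", {
  b <- gen_cohort70(seed = 2)
  cfg <- triage_config(restrict_genes = attr(b$panel, "genes"))
  for (s in c("S01", "S12", "S33")) {
    cand <- filter_candidates(b$samples[[s]], cfg)
    cls <- classify_variants(cand, b$known, cfg, b$panel)
    expect_false(any(is.na(cls$tier)))
    expect_true(all(lengths(cls$evidence) >= 1))
  }
  # adding a damaging verdict never demotes below suspected_pathogenic
  base <- make_variant(7, "missense", conserved = TRUE)
  before <- classify_variants(make_variants(base), NULL, cfg)
  base$predictor_calls <- list(c(SIFT = "damaging", PolyPhen2 = "damaging"))
  after <- classify_variants(make_variants(base), NULL, cfg)
  rank <- function(x) match(as.character(x$tier),
                            c("unknown_significance", "polymorphism",
                              "suspected_pathogenic", "pathogenic"))
  expect_gte(rank(after), rank(before))
})

test_that("splice GT/AG breakage can come from panel splice_site regions", {
  panel <- gene_panel(data.frame(
    chrom = "panelsim1", start = c(0L, 100L), end = c(100L, 102L),
    gene = "GCK", region_class = c("CDS", "splice_site"),
    exon_index = c(1L, NA)))
  v <- make_variants(make_variant(101, "splice_site"))  # inside 100-102
  cls <- classify_variants(v, NULL, triage_config(), panel)
  expect_equal(as.character(cls$tier), "suspected_pathogenic")
  v2 <- make_variants(make_variant(50, "splice_site"))  # in CDS, flag off
  expect_equal(as.character(classify_variants(v2, NULL, triage_config(),
                                              panel)$tier),
               "unknown_significance")
})

test_that("variant summaries tally classes and zygosity with 2-decimal ratios", {
  v <- make_variants(
    make_variant(1, "missense"), make_variant(2, "missense"),
    make_variant(3, "synonymous", zygosity = "hom"),
    make_variant(4, "frameshift", vtype = "deletion"),
    make_variant(5, "inframe_indel", vtype = "insertion", zygosity = "hom"))
  s <- summarize_variants(v)
  expect_equal(s$snv$total, 3L)
  expect_equal(s$indel$total, 2L)
  bc <- s$snv$by_class
  expect_equal(bc$n[bc$class == "missense"], 2L)
  expect_equal(bc$ratio[bc$class == "missense"], 66.67)
  zy <- s$snv$zygosity
  expect_equal(zy$ratio, c(66.67, 33.33))
  # empty input: zero counts, zero percents
  s0 <- summarize_variants(variant_table(data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character())))
  expect_equal(s0$total, 0L)
  expect_true(all(s0$snv$zygosity$ratio == 0))
})

test_that("cohort summaries group by gene with mean (range) [missing] cells", {
  rec <- data.frame(
    sample_id = c("a", "b", "c"),
    pathogenic_gene = c("GCK", "GCK", "HNF1A"),
    sex = c("m", "f", "f"),
    age_at_examination = c(10, 30, NA),
    age_at_diagnosis = c(8, 25, 20),
    height = c(150, 170, NA),
    weight = c(45, 70, NA),
    bmi = c(20, 24.22, NA),
    hba1c = c(6.5, 7.5, NA),
    treatment = c("ins", "diet", NA),
    stringsAsFactors = FALSE)
  s <- summarize_cohort(rec)
  expect_equal(s$gene, c("GCK", "HNF1A", "Total"))
  expect_equal(s$n, c(2L, 1L, 3L))
  expect_equal(s$share_pct, c(67, 33, 100))
  expect_equal(s$age_at_examination[1], "20 (10-30) [0]")
  expect_equal(s$sex[1], "1/1")
  expect_equal(s$treatment[1], "1/0/0/1 [0]")
  # single record: mean = value, degenerate range
  expect_equal(s$age_at_diagnosis[2], "20 (20-20) [0]")
  # all-missing field reported as NA with the missing count
  expect_equal(s$age_at_examination[2], "NA [1]")
})
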