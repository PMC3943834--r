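# Synthetic fixture generation.
#
# Everything the pipeline consumes can be generated here, on a fictional
# contig ("panelsim1") so nothing can silently depend on a real reference:
#   * gene panels with per-gene exon grids
#   * per-run depth matrices with shared per-region capture efficiencies
#     (inducing the strong cross-sample correlation capture data shows),
#     negative-binomial noise, and implanted copy-number events
#   * annotated variant cohorts whose implanted classes force known tiers
#   * defective read sets with exact expected QC reports
#   * truth/call pairs with planted error rates and exact expected counts
# Identical configuration (including seed) gives byte-identical outputs.

MODY_GENES <- c("HNF4A", "GCK", "HNF1A", "HNF1B", "INS", "KCNJ11")

#' Simulation configuration
#'
#' Defaults describe a plausible capture run of the diagnostic panel: mean
#' on-target depth 412x, per-region capture efficiencies spread on the log
#' scale (sd 0.4, so regions differ several-fold, as hybridization capture
#' does), negative-binomial overdispersion `size = 150` (~9% extra CV at
#' depth 400), per-sample library-size spread 0.2 on the log scale, and
#' runs of 14 samples sharing a lane.
#'
#' @param seed integer RNG seed; fixes every downstream draw.
#' @param n_samples samples in the cohort.
#' @param genes gene symbols on the panel.
#' @param n_regions_per_gene exons simulated per gene.
#' @param region_bp exon width in bp.
#' @param depth_mean grand mean on-target depth (fold).
#' @param region_effect_sd log-scale sd of per-region capture efficiency.
#' @param dispersion negative-binomial size parameter of depth noise.
#' @param sample_scale_sd log-scale sd of per-sample library size.
#' @param run_size samples per sequencing run (CNV baseline group).
#' @param cnv_events data.frame(sample, gene, exon_from, exon_to,
#'   copy_factor) with copy factors in \{0, 0.5, 1.5, 2\}; `NULL` for none.
#' @param error_rates c(fp =, fn =) per-base false-call and per-site miss
#'   rates for benchmark pairs.
#' @param read_len read length for generated FASTQ reads (bp).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 20L, genes = MODY_GENES,
                       n_regions_per_gene = 10L, region_bp = 150L,
                       depth_mean = 412, region_effect_sd = 0.4,
                       dispersion = 150, sample_scale_sd = 0.2,
                       run_size = 14L, cnv_events = NULL,
                       error_rates = c(fp = 6e-5, fn = 0.09),
                       read_len = 90L) {
  if (!is.null(cnv_events) &&
      !all(cnv_events$copy_factor %in% c(0, 0.5, 1.5, 2)))
    stop_input("copy_factor must be one of 0, 0.5, 1.5, 2")
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 genes = genes,
                 n_regions_per_gene = as.integer(n_regions_per_gene),
                 region_bp = as.integer(region_bp), depth_mean = depth_mean,
                 region_effect_sd = region_effect_sd, dispersion = dispersion,
                 sample_scale_sd = sample_scale_sd,
                 run_size = as.integer(run_size), cnv_events = cnv_events,
                 error_rates = error_rates, read_len = as.integer(read_len)),
            class = "sim_config")
}

#' Generate a synthetic gene panel
#'
#' Lays `n_regions_per_gene` CDS exons per gene along the fictional contig
#' `panelsim1` (width `region_bp`, 500 bp apart, genes 100 kb apart).
#'
#' @param cfg a [sim_config].
#' @return a [gene_panel].
#' @export
gen_panel <- function(cfg = sim_config()) {
  rows <- list()
  for (gi in seq_along(cfg$genes)) {
    gene_start <- (gi - 1L) * 100000L
    for (e in seq_len(cfg$n_regions_per_gene)) {
      start <- gene_start + (e - 1L) * 500L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "panelsim1", start = start, end = start + cfg$region_bp,
        gene = cfg$genes[gi], region_class = "CDS", exon_index = e,
        stringsAsFactors = FALSE)
    }
  }
  gene_panel(do.call(rbind, rows))
}

#' Generate per-run depth matrices with implanted CNVs
#'
#' Region mean depths are drawn as
#' `NB(mu = depth_mean * sample_scale * region_effect * copy_factor,
#' size = dispersion)`. The per-region capture efficiency `region_effect`
#' is shared by all samples, which is what makes depths of one region
#' strongly correlated across the samples of a run.
#'
#' @param cfg a [sim_config].
#' @return list with `runs` (list of [depth_matrix], samples split into
#'   groups of `run_size`), `panel`, `manifest` (the implanted events with
#'   their region spans), and `run_of` (named run assignment).
#' @export
gen_depth_matrix <- function(cfg = sim_config()) {
  panel <- gen_panel(cfg)
  n_regions <- nrow(panel)
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  set.seed(cfg$seed)
  region_effect <- exp(stats::rnorm(n_regions, 0, cfg$region_effect_sd))
  sample_scale <- exp(stats::rnorm(cfg$n_samples, 0, cfg$sample_scale_sd))
  copy <- matrix(1, cfg$n_samples, n_regions, dimnames = list(samples, NULL))
  manifest <- data.frame(sample = character(), gene = character(),
                         exon_from = integer(), exon_to = integer(),
                         copy_factor = numeric(), region_from = integer(),
                         region_to = integer(), stringsAsFactors = FALSE)
  if (!is.null(cfg$cnv_events)) {
    for (i in seq_len(nrow(cfg$cnv_events))) {
      ev <- cfg$cnv_events[i, ]
      ridx <- which(panel$gene == ev$gene &
                      panel$exon_index >= ev$exon_from &
                      panel$exon_index <= ev$exon_to)
      if (!length(ridx)) stop_input("CNV event outside panel: %s", ev$gene)
      copy[ev$sample, ridx] <- ev$copy_factor
      manifest <- rbind(manifest, data.frame(
        sample = ev$sample, gene = ev$gene, exon_from = ev$exon_from,
        exon_to = ev$exon_to, copy_factor = ev$copy_factor,
        region_from = min(ridx), region_to = max(ridx),
        stringsAsFactors = FALSE))
    }
  }
  mu <- outer(cfg$depth_mean * sample_scale, region_effect) * copy
  depth <- matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$dispersion),
                  nrow(mu), ncol(mu), dimnames = dimnames(copy))
  run_of <- stats::setNames(
    paste0("run", (seq_len(cfg$n_samples) - 1L) %/% cfg$run_size + 1L),
    samples)
  runs <- lapply(split(samples, run_of), function(ss)
    depth_matrix(depth[ss, , drop = FALSE], panel,
                 run_id = run_of[[ss[1]]]))
  list(runs = runs, panel = panel, manifest = manifest, run_of = run_of)
}

# deterministic filler/causal variant builders -------------------------------

sim_variant_row <- function(chrom, pos, ref, alt, consequence, gene,
                            zygosity = "het", quality = 60, depth = 100,
                            alt_fraction = 0.48, db_afs = numeric(),
                            predictor_calls = character(), conserved = FALSE,
                            gtat = FALSE, known_id = NA_character_) {
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   zygosity = zygosity, call_quality = quality, depth = depth,
                   alt_fraction = alt_fraction, gene = gene,
                   consequence = consequence, known_id = known_id,
                   conserved = conserved, gtat = gtat,
                   stringsAsFactors = FALSE)
  df$db_afs <- list(db_afs)
  df$predictor_calls <- list(predictor_calls)
  df
}

# one variant of a named class at a deterministic in-gene position
sim_class_variant <- function(class, gene, panel, slot) {
  g <- panel[panel$gene == gene, , drop = FALSE]
  region <- g[1 + (slot %% nrow(g)), ]
  pos <- region$start + 1L + (slot * 7L) %% (region$end - region$start)
  chrom <- region$chrom
  preds4 <- c(SIFT = "benign", PolyPhen2 = "benign",
              MutationTaster = "benign", BDGP = "unknown")
  switch(class,
    known_pathogenic = sim_variant_row(chrom, pos, "A", "G", "missense", gene,
      conserved = TRUE, known_id = sprintf("LSDB_%s_%d", gene, slot)),
    novel_nonsense = sim_variant_row(chrom, pos, "C", "T", "nonsense", gene),
    novel_frameshift = sim_variant_row(chrom, pos, "CA", "C", "frameshift",
                                       gene),
    novel_conserved_missense = sim_variant_row(chrom, pos, "G", "A",
      "missense", gene, conserved = TRUE),
    novel_damaging_missense = sim_variant_row(chrom, pos, "G", "C",
      "missense", gene,
      predictor_calls = c(SIFT = "damaging", PolyPhen2 = "damaging",
                          MutationTaster = "damaging", BDGP = "unknown")),
    novel_gtat_splice = sim_variant_row(chrom, pos, "G", "T", "splice_site",
                                        gene, gtat = TRUE),
    common_polymorphism = sim_variant_row(chrom, pos, "T", "C", "missense",
      gene, db_afs = c(g1000 = 0.05, dbsnp = 0.04),
      predictor_calls = preds4),
    control_polymorphism = sim_variant_row(chrom, pos, "A", "C", "missense",
      gene, db_afs = c(control = 0.005), predictor_calls = preds4),
    benign_rare = sim_variant_row(chrom, pos, "A", "T", "missense", gene,
      predictor_calls = c(SIFT = "damaging", PolyPhen2 = "benign",
                          MutationTaster = "benign", BDGP = "unknown")),
    synonymous = sim_variant_row(chrom, pos, "C", "G", "synonymous", gene),
    stop_input("unknown variant class '%s'", class))
}

# expected fate of each class under the default triage configuration
SIM_EXPECTED_TIER <- c(
  known_pathogenic = "pathogenic",
  novel_nonsense = "pathogenic",
  novel_frameshift = "pathogenic",
  novel_conserved_missense = "suspected_pathogenic",
  novel_damaging_missense = "suspected_pathogenic",
  novel_gtat_splice = "suspected_pathogenic",
  control_polymorphism = "polymorphism",
  benign_rare = "unknown_significance")
SIM_FILTERED_OUT <- c("common_polymorphism", "synonymous")

#' Generate an annotated variant cohort
#'
#' Builds one variant table per sample from a per-sample class recipe. Each
#' implanted class carries annotations that force its tier under the default
#' triage configuration (recorded in the returned `expected` table); filler
#' classes (synonymous, common polymorphisms) are built to be removed by the
#' candidate filter so the per-sample candidate count lands in a narrow,
#' clinic-like band.
#'
#' @param recipes named list: for each sample, a character vector of variant
#'   class names (one variant generated per entry). Classes:
#'   `known_pathogenic`, `novel_nonsense`, `novel_frameshift`,
#'   `novel_conserved_missense`, `novel_damaging_missense`,
#'   `novel_gtat_splice`, `common_polymorphism`, `control_polymorphism`,
#'   `benign_rare`, `synonymous`.
#' @param panel a [gene_panel]; variants are placed inside its genes.
#' @param genes gene assignment per sample (recycled); causal classes land
#'   on this gene, fillers rotate over the panel.
#' @return list: `samples` (named list of [variant_table]), `known`
#'   (knowledge table covering the `known_pathogenic` implants), `expected`
#'   (data.frame sample/class/pos/expected fate).
#' @export
gen_variant_cohort <- function(recipes, panel, genes = attr(panel, "genes")) {
  genes <- rep(genes, length.out = length(recipes))
  known_rows <- list()
  expected <- list()
  samples <- vector("list", length(recipes))
  names(samples) <- names(recipes)
  all_genes <- attr(panel, "genes")
  for (si in seq_along(recipes)) {
    rows <- list()
    for (ci in seq_along(recipes[[si]])) {
      class <- recipes[[si]][ci]
      causal <- class %in% names(SIM_EXPECTED_TIER) &&
        !(class %in% c("benign_rare", "control_polymorphism"))
      gene <- if (causal) genes[si]
              else all_genes[1 + (si + ci) %% length(all_genes)]
      v <- sim_class_variant(class, gene, panel, slot = si * 37L + ci)
      if (class == "known_pathogenic") {
        known_rows[[length(known_rows) + 1L]] <- data.frame(
          chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
          gene = v$gene, citation_id = v$known_id, stringsAsFactors = FALSE)
      }
      expected[[length(expected) + 1L]] <- data.frame(
        sample = names(recipes)[si], class = class, chrom = v$chrom,
        pos = v$pos, ref = v$ref, alt = v$alt, gene = v$gene,
        expected_tier = if (class %in% names(SIM_EXPECTED_TIER))
          SIM_EXPECTED_TIER[[class]] else NA_character_,
        filtered_out = class %in% SIM_FILTERED_OUT,
        stringsAsFactors = FALSE)
      rows[[ci]] <- v
    }
    tab <- do.call(rbind, rows)
    tab <- tab[!duplicated(paste(tab$chrom, tab$pos)), , drop = FALSE]
    samples[[si]] <- variant_table(tab[order(tab$pos), , drop = FALSE])
  }
  known <- if (length(known_rows)) do.call(rbind, known_rows)
           else data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           gene = character(), citation_id = character(),
                           stringsAsFactors = FALSE)
  known <- known[!duplicated(paste(known$chrom, known$pos)), , drop = FALSE]
  class(known) <- c("known_table", "data.frame")
  list(samples = samples, known = known,
       expected = do.call(rbind, expected))
}

#' Generate reads with exact defect counts
#'
#' Builds a [read_set] containing exactly the requested number of clean
#' reads and of reads failing each QC rule (and no other), so the expected
#' QC report is exact, not statistical.
#'
#' @param n_clean,n_adapter,n_n_fraction,n_mean_quality,n_low_qual counts
#'   per class.
#' @param cfg a [sim_config] (seed and read length are used).
#' @param t the [qc_thresholds] the reads are built against.
#' @return list: `reads` (a [read_set], shuffled deterministically) and
#'   `expected` (`qc_report` the filter must reproduce).
#' @export
gen_reads <- function(n_clean = 100L, n_adapter = 5L, n_n_fraction = 4L,
                      n_mean_quality = 3L, n_low_qual = 2L,
                      cfg = sim_config(), t = qc_thresholds()) {
  set.seed(cfg$seed + 101L)
  len <- cfg$read_len
  rand_seq <- function() {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
      if (!is_adapter_polluted(s, t)) return(s)
    }
  }
  q30 <- function() rep(30L, len)
  reads <- list()
  add <- function(seq, qual) {
    reads[[length(reads) + 1L]] <<- list(seq = seq, qual = qual)
  }
  for (i in seq_len(n_clean)) add(rand_seq(), q30())
  for (i in seq_len(n_adapter)) {
    s <- rand_seq()
    ins <- nchar(t$adapter_seq)
    at <- 30L
    s <- paste0(substr(s, 1, at - 1),
                substr(t$adapter_seq, 1, min(ins, len - at + 1)),
                substr(s, at + min(ins, len - at + 1), len))
    add(substr(s, 1, len), q30())
  }
  n_ns <- ceiling(t$max_n_fraction * len) + 1L  # just over the N cutoff
  for (i in seq_len(n_n_fraction)) {
    s <- strsplit(rand_seq(), "")[[1]]
    s[seq_len(n_ns) * 2L] <- "N"
    add(paste(s, collapse = ""), q30())
  }
  for (i in seq_len(n_mean_quality))
    add(rand_seq(), rep(as.integer(t$min_mean_quality) - 1L, len))
  n_low <- ceiling(t$max_low_qual_fraction * len)
  for (i in seq_len(n_low_qual))
    add(rand_seq(), c(rep(as.integer(t$low_qual_threshold) - 1L, n_low),
                      rep(30L, len - n_low)))
  ord <- sample(length(reads))
  reads <- reads[ord]
  rs <- read_set(read_id = sprintf("read%04d", seq_along(reads)),
                 sequence = vapply(reads, `[[`, character(1), "seq"),
                 qualities = lapply(reads, `[[`, "qual"))
  expected <- structure(list(
    n_input = nrow(rs),
    n_kept = n_clean,
    removal_counts = c(adapter = n_adapter, n_fraction = n_n_fraction,
                       mean_quality = n_mean_quality,
                       low_quality_bases = n_low_qual),
    n_invalid = 0L), class = "qc_report")
  list(reads = rs, expected = expected)
}

#' Generate a truth/calls benchmark pair with planted error rates
#'
#' Plants `n_truth` true SNVs on `n_covered` covered bases, then builds a
#' call set that misses each truth site with probability `fn` and adds a
#' false call at each remaining covered base with probability `fp`; the
#' generator tallies the expected confusion counts as it draws them. A few
#' additional low-quality calls (below the benchmark score filter) are
#' planted to exercise the filtering step; they must not appear in the
#' counts.
#'
#' @param n_covered covered base count.
#' @param n_truth planted truth SNVs.
#' @param cfg a [sim_config]; `error_rates` and `seed` are used.
#' @param n_lowqual planted sub-threshold calls.
#' @return list: `truth`, `calls` ([variant_table]s), `covered`
#'   (data.frame chrom/pos), `expected` (list tp/tn/fp/fn).
#' @export
gen_bench_pair <- function(n_covered = 10000L, n_truth = 100L,
                           cfg = sim_config(), n_lowqual = 20L) {
  set.seed(cfg$seed + 202L)
  e_fp <- cfg$error_rates[["fp"]]
  e_fn <- cfg$error_rates[["fn"]]
  stopifnot(e_fp >= 0, e_fp < 1, e_fn >= 0, e_fn < 1)
  covered <- data.frame(chrom = "panelsim1", pos = seq_len(n_covered),
                        stringsAsFactors = FALSE)
  truth_pos <- sort(sample(n_covered, n_truth))
  bases <- c("A", "C", "G", "T")
  truth_rows <- lapply(truth_pos, function(p)
    sim_variant_row("panelsim1", p, "A", sample(c("C", "G", "T"), 1),
                    "intron", gene = ""))
  truth <- variant_table(do.call(rbind, truth_rows))
  miss <- stats::runif(n_truth) < e_fn
  calls <- truth[!miss, , drop = FALSE]
  free <- setdiff(seq_len(n_covered), truth_pos)
  fp_pos <- free[stats::runif(length(free)) < e_fp]
  if (length(fp_pos)) {
    fp_rows <- do.call(rbind, lapply(fp_pos, function(p)
      sim_variant_row("panelsim1", p, "A", sample(c("C", "G", "T"), 1),
                      "intron", gene = "")))
    calls <- rbind(calls, variant_table(fp_rows))
  }
  lq_pos <- sample(setdiff(free, fp_pos), n_lowqual)
  if (n_lowqual) {
    lq_rows <- do.call(rbind, lapply(lq_pos, function(p)
      sim_variant_row("panelsim1", p, "A", "C", "intron", gene = "",
                      quality = 5)))
    calls <- rbind(calls, variant_table(lq_rows))
  }
  calls <- variant_table(calls[order(calls$pos), , drop = FALSE])
  expected <- list(tp = sum(!miss), fn = sum(miss), fp = length(fp_pos),
                   tn = n_covered - sum(!miss) - sum(miss) - length(fp_pos))
  list(truth = truth, calls = calls, covered = covered, expected = expected)
}
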