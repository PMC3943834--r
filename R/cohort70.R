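# The `cohort70` preset: a fixed-design synthetic emulation of a 70-sample
# positive diagnostic cohort, and the end-to-end recovery pipeline run on it.
#
# Design of the preset (chosen once, stated in the methods vignette):
#   * 70 samples on the six-gene candidate panel, sequenced in runs of 14
#   * 63 samples carry one implanted small causal variant: 15 frameshift
#     indels, 5 nonsense, 36 missense (31 known / 5 novel conserved) and
#     7 canonical-splice variants — i.e. 51 expected pathogenic and 12
#     expected suspected-pathogenic
#   * 7 samples carry one implanted whole-exon CNV (4 heterozygous
#     deletions at copy factor 0.5, 3 duplications at 1.5)
#   * per-gene sample shares follow the clinical cohort: GCK 26, HNF1A 28,
#     HNF4A 9, KCNJ11 3, HNF1B 2, INS 2
#   * every sample additionally carries filler variants (synonymous, common
#     and control-cohort polymorphisms, rare benign missense) tuned so the
#     post-filter candidate count per sample lands in the 3-10 band

COHORT70_GENE_N <- c(GCK = 26L, HNF1A = 28L, HNF4A = 9L, KCNJ11 = 3L,
                     HNF1B = 2L, INS = 2L)

cohort70_cnv_events <- function() {
  data.frame(
    sample = c("S10", "S20", "S30", "S40", "S50", "S60", "S70"),
    gene = c("GCK", "HNF1A", "HNF4A", "GCK", "HNF1B", "HNF1A", "KCNJ11"),
    exon_from = c(3L, 2L, 7L, 5L, 1L, 8L, 2L),
    exon_to = c(3L, 4L, 7L, 6L, 1L, 8L, 3L),
    copy_factor = c(0.5, 1.5, 0.5, 1.5, 0.5, 0.5, 1.5),
    stringsAsFactors = FALSE)
}

#' Generate the `cohort70` synthetic cohort
#'
#' Builds the full fixed-design cohort described in the file header: panel,
#' per-run depth matrices with the 7 implanted exon CNVs, 70 annotated
#' per-sample variant tables with 63 implanted causal small variants, the
#' knowledge table backing the known-mutation implants, phenotype records,
#' and the manifests of everything implanted.
#'
#' @param seed integer seed; the whole bundle is a deterministic function
#'   of it.
#' @return list of class `truth_bundle` with components `panel`, `runs`,
#'   `run_of`, `samples`, `known`, `expected_variants`, `expected_cnvs`,
#'   `phenotypes`, `genes_of`, `cfg`.
#' @export
gen_cohort70 <- function(seed = 1L) {
  cnv <- cohort70_cnv_events()
  cfg <- sim_config(seed = seed, n_samples = 70L, run_size = 14L,
                    cnv_events = cnv)
  dm <- gen_depth_matrix(cfg)
  samples <- sprintf("S%02d", 1:70)
  cnv_samples <- cnv$sample

  # causal small-variant classes, 63 of them
  classes <- c(rep("novel_frameshift", 15), rep("novel_nonsense", 5),
               rep("known_pathogenic", 31), rep("novel_conserved_missense", 5),
               rep("novel_gtat_splice", 7))
  # gene assignment honouring the per-gene totals net of the CNV carriers
  small_n <- COHORT70_GENE_N -
    table(factor(cnv$gene, levels = names(COHORT70_GENE_N)))
  genes63 <- rep(names(small_n), times = as.integer(small_n))
  small_samples <- setdiff(samples, cnv_samples)
  set.seed(seed + 7L)
  classes <- sample(classes)           # decouple class from gene/sample order
  recipes <- list()
  genes_of <- character(length(samples))
  names(genes_of) <- samples
  ci <- 0L
  for (s in samples) {
    i <- match(s, samples)
    fillers <- c(rep("synonymous", 8), rep("common_polymorphism", 3),
                 "control_polymorphism",
                 rep("benign_rare", 2L + (i %% 6L)))
    if (s %in% cnv_samples) {
      genes_of[s] <- cnv$gene[cnv$sample == s]
      recipes[[s]] <- fillers
    } else {
      ci <- ci + 1L
      genes_of[s] <- genes63[ci]
      recipes[[s]] <- c(classes[ci], fillers)
    }
  }
  cohort <- gen_variant_cohort(recipes, dm$panel, genes = genes_of)

  set.seed(seed + 11L)
  phen <- data.frame(
    sample_id = samples,
    pathogenic_gene = genes_of,
    sex = sample(c("m", "f"), 70, replace = TRUE),
    age_at_examination = round(stats::runif(70, 2, 70), 1),
    age_at_diagnosis = round(stats::runif(70, 0.5, 45), 1),
    height = round(stats::rnorm(70, 162, 15), 1),
    weight = round(stats::rnorm(70, 61, 15), 1),
    hba1c = round(stats::rnorm(70, 7.0, 0.7), 1),
    treatment = sample(c("ins", "ins+OHA", "OHA", "diet"), 70,
                       replace = TRUE),
    stringsAsFactors = FALSE)
  phen$bmi <- round(phen$weight / (phen$height / 100)^2, 2)

  structure(list(panel = dm$panel, runs = dm$runs, run_of = dm$run_of,
                 samples = cohort$samples, known = cohort$known,
                 expected_variants = cohort$expected,
                 expected_cnvs = dm$manifest,
                 phenotypes = phen, genes_of = genes_of, cfg = cfg),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf(
    "<truth_bundle> %d samples, %d runs, %d implanted CNVs, %d implanted causal variants\n",
    length(x$samples), length(x$runs), nrow(x$expected_cnvs),
    sum(!is.na(x$expected_variants$expected_tier) &
          !x$expected_variants$class %in%
            c("benign_rare", "control_polymorphism"))))
  invisible(x)
}

#' Run the full triage + CNV pipeline on a truth bundle
#'
#' For every sample: filter and classify its variants against the bundle's
#' knowledge table with the candidate genes restricted to the panel, and
#' score every sample's regions against its run's leave-one-out baseline.
#' An implanted small variant counts as recovered when it survives the
#' filter and is tiered pathogenic or suspected pathogenic; an implanted
#' CNV when a call of the correct direction overlaps the implanted exons.
#'
#' @param bundle a `truth_bundle` from [gen_cohort70].
#' @param cutoff CNV z cutoff, default 3.
#' @return list of class `recovery_report`: `n_events`, `n_recovered`,
#'   `recovery_pct`, per-event `detail`, and `candidate_counts` per sample.
#' @export
recover_cohort <- function(bundle, cutoff = 3) {
  cfg_triage <- triage_config(restrict_genes = attr(bundle$panel, "genes"))
  rates <- lapply(bundle$runs, region_depth_rates)
  candidate_counts <- integer(0)
  detail <- list()

  causal <- bundle$expected_variants[
    !is.na(bundle$expected_variants$expected_tier) &
      !bundle$expected_variants$class %in%
        c("benign_rare", "control_polymorphism"), , drop = FALSE]
  for (s in names(bundle$samples)) {
    cand <- filter_candidates(bundle$samples[[s]], cfg_triage)
    cls <- classify_variants(cand, bundle$known, cfg_triage, bundle$panel)
    candidate_counts[s] <- nrow(cand)
    cv <- causal[causal$sample == s, , drop = FALSE]
    for (i in seq_len(nrow(cv))) {
      hit <- which(cls$chrom == cv$chrom[i] & cls$pos == cv$pos[i] &
                     cls$alt == cv$alt[i])
      ok <- length(hit) > 0 && as.character(cls$tier[hit[1]]) %in%
        c("pathogenic", "suspected_pathogenic")
      detail[[length(detail) + 1L]] <- data.frame(
        sample = s, type = "small_variant", gene = cv$gene[i],
        recovered = ok, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(bundle$expected_cnvs))) {
    ev <- bundle$expected_cnvs[i, ]
    run <- bundle$run_of[[ev$sample]]
    z <- cnv_zscores(rates[[run]], ev$sample)
    calls <- call_cnvs(z, bundle$panel, sample_id = ev$sample,
                       cutoff = cutoff)
    want_dir <- if (ev$copy_factor < 1) "deletion" else "duplication"
    ok <- FALSE
    for (j in seq_len(nrow(calls))) {
      idx <- calls$regions[[j]]
      if (calls$direction[j] == want_dir &&
          length(intersect(idx, ev$region_from:ev$region_to)))
        ok <- TRUE
    }
    detail[[length(detail) + 1L]] <- data.frame(
      sample = ev$sample, type = "cnv", gene = ev$gene, recovered = ok,
      stringsAsFactors = FALSE)
  }
  detail <- do.call(rbind, detail)
  structure(list(n_events = nrow(detail),
                 n_recovered = sum(detail$recovered),
                 recovery_pct = 100 * sum(detail$recovered) / nrow(detail),
                 detail = detail,
                 candidate_counts = candidate_counts),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d/%d implanted events recovered (%.1f%%)\n",
              x$n_recovered, x$n_events, x$recovery_pct))
  cat(sprintf("  candidate variants per sample: median %d (range %d-%d)\n",
              as.integer(stats::median(x$candidate_counts)),
              min(x$candidate_counts), max(x$candidate_counts)))
  invisible(x)
}

#' Write a truth bundle's fixture files to disk
#'
#' Emits the panel BED, one region-depth TSV per run (samples x regions),
#' one VCF per sample, the knowledge TSV, the phenotype TSV and the implant
#' manifests. Output is a deterministic function of the bundle: writing the
#' same bundle twice gives byte-identical files.
#'
#' @param bundle a `truth_bundle`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, "panel.bed")
  write_panel(bundle$panel, p)
  paths <- c(paths, p)
  for (run in names(bundle$runs)) {
    p <- file.path(dir, paste0("depth_", run, ".tsv"))
    m <- bundle$runs[[run]]$mean_depth
    utils::write.table(data.frame(sample = rownames(m), m,
                                  check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (s in names(bundle$samples)) {
    p <- file.path(dir, paste0(s, ".vcf"))
    write_variants(bundle$samples[[s]], p, sample_id = s)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "known.tsv")
  write_known_table(bundle$known, p)
  paths <- c(paths, p)
  p <- file.path(dir, "phenotypes.tsv")
  utils::write.table(bundle$phenotypes, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "manifest_cnv.tsv")
  utils::write.table(bundle$expected_cnvs, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "manifest_variants.tsv")
  utils::write.table(bundle$expected_variants, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
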