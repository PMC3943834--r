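# Candidate-variant filtering and four-tier pathogenicity triage.
#
# Filtering keeps a variant iff all of:
#   * caller quality >= min_call_quality (default 20)
#   * functional: SNVs with consequence nonsense/splice_site/missense;
#     indels that are frameshift, in-frame coding, or splice-site
#   * rare: allele frequency < max_af (default 0.01) in EVERY database where
#     the variant is observed; absence from all databases passes
#   * optionally restricted to a phenotype-specific candidate-gene set
# Triage then assigns exactly one of four tiers by the first matching rule:
#   1. pathogenic            known mutation, or loss of function
#                            (nonsense / frameshift)
#   2. suspected_pathogenic  novel with supporting evidence: conserved
#                            missense, splice variant breaking the canonical
#                            GT/AG dinucleotides, or a damaging consensus of
#                            the in-silico predictors
#   3. polymorphism          seen in the local control cohort
#   4. unknown_significance  everything else

TIERS <- c("pathogenic", "suspected_pathogenic", "polymorphism",
           "unknown_significance")

#' Triage configuration
#'
#' @param min_call_quality minimum caller quality score (default 20).
#' @param max_af database allele-frequency cutoff (default 0.01); a variant
#'   passes when rare in every database it is observed in.
#' @param functional_snv SNV consequence classes counted as functional.
#' @param functional_indel indel consequence classes counted as functional
#'   (coding or splice-region).
#' @param min_damaging_predictors damaging verdicts needed for the predictor
#'   consensus clause (default 2 of the four standard tools).
#' @param restrict_genes optional character vector: the phenotype-specific
#'   candidate-gene panel; `NULL` disables the restriction.
#' @param control_db name of the local control cohort in `db_afs`; presence
#'   there marks a variant a polymorphism.
#' @return list of class `triage_config`.
#' @export
triage_config <- function(min_call_quality = 20,
                          max_af = 0.01,
                          functional_snv = c("nonsense", "splice_site",
                                             "missense"),
                          functional_indel = c("frameshift", "inframe_indel",
                                               "splice_site"),
                          min_damaging_predictors = 2L,
                          restrict_genes = NULL,
                          control_db = "control") {
  stopifnot(max_af > 0, max_af < 1, min_damaging_predictors >= 1)
  structure(list(min_call_quality = min_call_quality, max_af = max_af,
                 functional_snv = functional_snv,
                 functional_indel = functional_indel,
                 min_damaging_predictors = as.integer(min_damaging_predictors),
                 restrict_genes = restrict_genes, control_db = control_db),
            class = "triage_config")
}

#' Filter variants to potential mutation candidates
#'
#' @param variants a [variant_table].
#' @param cfg a [triage_config].
#' @return the subset of `variants` passing all predicates, same class.
#' @export
filter_candidates <- function(variants, cfg = triage_config()) {
  if (nrow(variants) == 0L) return(variants)
  quality_ok <- !is.na(variants$call_quality) &
    variants$call_quality >= cfg$min_call_quality
  functional <- ifelse(
    variants$vtype == "SNV",
    variants$consequence %in% cfg$functional_snv,
    variants$consequence %in% cfg$functional_indel)
  functional[is.na(variants$consequence)] <- FALSE
  rare <- vapply(variants$db_afs, function(afs)
    length(afs) == 0L || max(afs) < cfg$max_af, logical(1))
  in_panel <- if (is.null(cfg$restrict_genes)) TRUE
              else variants$gene %in% cfg$restrict_genes
  keep <- quality_ok & functional & rare & in_panel
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign pathogenicity tiers
#'
#' Classifies each candidate variant into one of the four tiers (see the
#' file header for the decision order) and records every satisfied evidence
#' clause. Known-mutation matching is exact on (chrom, pos, ref, alt)
#' against the knowledge table, or via a `KNOWN_ID` annotation.
#'
#' @param variants a [variant_table] of filtered candidates.
#' @param known a `known_table` (see [load_known_table]) or `NULL`.
#' @param cfg a [triage_config].
#' @param panel optional [gene_panel]; when given, a splice variant is also
#'   treated as GT/AG-breaking if it falls inside a `splice_site` region.
#' @return `variants` with added `tier` (factor over the four tiers) and
#'   `evidence` (list-column of fired-rule tags).
#' @export
classify_variants <- function(variants, known = NULL, cfg = triage_config(),
                              panel = NULL) {
  n <- nrow(variants)
  known_key <- if (!is.null(known) && nrow(known))
    paste(known$chrom, known$pos, known$ref, known$alt) else character()
  splice_gr <- if (!is.null(panel) && any(panel$region_class == "splice_site"))
    merge_regions(panel[panel$region_class == "splice_site", , drop = FALSE])
  else NULL
  tier <- character(n)
  evidence <- vector("list", n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    ev <- character()
    is_known <- (length(known_key) &&
                   paste(v$chrom, v$pos, v$ref, v$alt) %in% known_key) ||
      (!is.na(v$known_id))
    if (is_known) ev <- c(ev, "known_pathogenic")
    if (v$consequence %in% c("nonsense", "frameshift"))
      ev <- c(ev, "loss_of_function")
    conserved_missense <- isTRUE(v$conserved) && v$consequence == "missense"
    if (conserved_missense) ev <- c(ev, "conserved_missense")
    gtat <- v$consequence == "splice_site" &&
      (isTRUE(v$gtat) || (!is.null(splice_gr) &&
                            pos_in_ranges(v$chrom, v$pos, splice_gr)))
    if (gtat) ev <- c(ev, "gtat_splice")
    n_damaging <- sum(v$predictor_calls[[1]] == "damaging")
    consensus <- n_damaging >= cfg$min_damaging_predictors
    if (consensus) ev <- c(ev, "predictor_consensus")
    in_control <- cfg$control_db %in% names(v$db_afs[[1]]) &&
      v$db_afs[[1]][[cfg$control_db]] > 0
    if (in_control) ev <- c(ev, "control_database")
    tier[i] <- if (is_known || v$consequence %in% c("nonsense", "frameshift"))
      "pathogenic"
    else if (conserved_missense || gtat || consensus)
      "suspected_pathogenic"
    else if (in_control)
      "polymorphism"
    else
      "unknown_significance"
    if (!length(ev)) ev <- "no_evidence"
    evidence[[i]] <- ev
  }
  variants$tier <- factor(tier, levels = TIERS)
  variants$evidence <- evidence
  variants
}

pos_in_ranges <- function(chrom, pos, gr) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  length(GenomicRanges::findOverlaps(q, gr)) > 0
}

#' Summaries of a variant table
#'
#' Tallies SNVs and indels by consequence/location class and by zygosity,
#' with percents of the respective totals (rounded to 2 decimals).
#'
#' @param variants a [variant_table].
#' @return list of class `variant_summary` with `snv` and `indel`
#'   components, each holding `by_class` and `zygosity` data.frames
#'   (columns `n`, `ratio`), plus `total`.
#' @export
summarize_variants <- function(variants) {
  one <- function(v) {
    cls <- table(factor(v$consequence, levels = CONSEQUENCES))
    zyg <- table(factor(v$zygosity, levels = c("het", "hom")))
    list(by_class = data.frame(class = names(cls), n = as.integer(cls),
                               ratio = count_percents(as.numeric(cls)),
                               stringsAsFactors = FALSE),
         zygosity = data.frame(zygosity = names(zyg), n = as.integer(zyg),
                               ratio = count_percents(as.numeric(zyg)),
                               stringsAsFactors = FALSE),
         total = nrow(v))
  }
  structure(list(snv = one(variants[variants$vtype == "SNV", , drop = FALSE]),
                 indel = one(variants[variants$vtype != "SNV", , drop = FALSE]),
                 total = nrow(variants)),
            class = "variant_summary")
}

#' @export
print.variant_summary <- function(x, ...) {
  cat(sprintf("<variant_summary> %d variants (%d SNVs, %d indels)\n",
              x$total, x$snv$total, x$indel$total))
  for (part in c("snv", "indel")) {
    z <- x[[part]]$zygosity
    if (sum(z$n))
      cat(sprintf("  %s het/hom: %.2f%% / %.2f%%\n", part,
                  z$ratio[z$zygosity == "het"], z$ratio[z$zygosity == "hom"]))
  }
  invisible(x)
}

#' Cohort phenotype summary by pathogenic gene
#'
#' Groups patient records by their pathogenic gene and reports, per gene and
#' in total: n, the integer percent share of samples, the sex split, for
#' each numeric field `mean (min-max) [n missing]` (missing values excluded
#' from means), and the treatment split.
#'
#' @param records data.frame with columns `sample_id`, `pathogenic_gene`,
#'   `sex` ("m"/"f"), `age_at_examination`, `age_at_diagnosis`, `height`,
#'   `weight`, `bmi`, `hba1c`, `treatment` (ins / ins+OHA / OHA / diet);
#'   any field may be `NA`.
#' @return data.frame of class `cohort_summary`, one row per gene plus a
#'   `Total` row; numeric columns `n` and `share_pct` plus formatted cells.
#' @export
summarize_cohort <- function(records) {
  num_fields <- c("age_at_examination", "age_at_diagnosis", "height",
                  "weight", "bmi", "hba1c")
  total_n <- nrow(records)
  fmt_num <- function(x) {
    miss <- sum(is.na(x))
    x <- x[!is.na(x)]
    if (!length(x)) return(sprintf("NA [%d]", miss))
    sprintf("%s (%s-%s) [%d]", format(round(mean(x), 2)),
            format(min(x)), format(max(x)), miss)
  }
  fmt_grp <- function(g) {
    sex <- table(factor(g$sex, levels = c("m", "f")))
    trt <- table(factor(g$treatment,
                        levels = c("ins", "ins+OHA", "OHA", "diet")))
    row <- data.frame(n = nrow(g),
                      share_pct = round(100 * nrow(g) / total_n),
                      sex = sprintf("%d/%d", sex[["m"]], sex[["f"]]),
                      stringsAsFactors = FALSE)
    for (f in num_fields) row[[f]] <- fmt_num(g[[f]])
    row$treatment <- sprintf("%d/%d/%d/%d [%d]", trt[["ins"]],
                             trt[["ins+OHA"]], trt[["OHA"]], trt[["diet"]],
                             sum(is.na(g$treatment)))
    row
  }
  genes <- sort(unique(records$pathogenic_gene))
  rows <- lapply(genes, function(g)
    fmt_grp(records[records$pathogenic_gene == g, , drop = FALSE]))
  out <- do.call(rbind, c(rows, list(fmt_grp(records))))
  out <- cbind(data.frame(gene = c(genes, "Total"), stringsAsFactors = FALSE),
               out)
  out$share_pct[nrow(out)] <- 100L
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", "data.frame")
  out
}
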