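# Truth-set benchmarking of SNV calls over covered target bases.
#
# Counting is positional over the covered base set: a covered position is a
# TP when a surviving call matches the truth allele there, an FP when a
# surviving call has no matching truth allele, an FN when a truth allele has
# no surviving matching call, and a TN otherwise, so TP+TN+FP+FN equals the
# number of covered bases. Calls first pass the quality filters (caller
# score, depth, alt-supporting read fraction); indels are excluded — the
# assessment is defined for SNVs.

#' Benchmark quality filters
#'
#' @param min_score minimum caller quality score (default 20).
#' @param min_depth minimum read depth (default 20).
#' @param min_alt_fraction minimum fraction of reads supporting the variant
#'   (default 0.28).
#' @return list of class `bench_filters`.
#' @export
bench_filters <- function(min_score = 20, min_depth = 20,
                          min_alt_fraction = 0.28) {
  stopifnot(min_alt_fraction >= 0, min_alt_fraction <= 1)
  structure(list(min_score = min_score, min_depth = min_depth,
                 min_alt_fraction = min_alt_fraction),
            class = "bench_filters")
}

#' Confusion counts of SNV calls against a truth set
#'
#' @param calls a [variant_table] of calls for the evaluated sample.
#' @param truth a [variant_table] of truth SNVs.
#' @param covered data.frame(chrom, pos) of evaluable target positions
#'   (e.g. from [covered_positions]).
#' @param f a [bench_filters]; calls failing it are discarded before
#'   counting. Filter fields that are `NA` on a call pass (annotation
#'   absent, not evidence of failure).
#' @return list of class `confusion_counts`: `covered_bp`, `tp`, `tn`,
#'   `fp`, `fn`, and `n_outside` (calls ignored for falling outside the
#'   covered set).
#' @export
confusion_counts <- function(calls, truth, covered, f = bench_filters()) {
  cov_key <- unique(position_key(covered$chrom, covered$pos))
  covered_bp <- length(cov_key)
  snv <- function(v) v[v$vtype == "SNV", , drop = FALSE]
  calls <- snv(calls)
  truth <- snv(truth)
  pass <- (is.na(calls$call_quality) | calls$call_quality >= f$min_score) &
    (is.na(calls$depth) | calls$depth >= f$min_depth) &
    (is.na(calls$alt_fraction) | calls$alt_fraction >= f$min_alt_fraction)
  calls <- calls[pass, , drop = FALSE]
  call_pos <- position_key(calls$chrom, calls$pos)
  inside <- call_pos %in% cov_key
  n_outside <- sum(!inside)
  calls <- calls[inside, , drop = FALSE]
  call_pos <- call_pos[inside]
  truth_pos <- position_key(truth$chrom, truth$pos)
  truth <- truth[truth_pos %in% cov_key, , drop = FALSE]
  truth_pos <- truth_pos[truth_pos %in% cov_key]
  call_allele <- split(calls$alt, call_pos)
  truth_allele <- split(truth$alt, truth_pos)
  pos_all <- union(names(call_allele), names(truth_allele))
  tp <- fp <- fn <- 0L
  for (p in pos_all) {
    ca <- call_allele[[p]]
    ta <- truth_allele[[p]]
    if (!is.null(ca) && !is.null(ta)) {
      if (length(intersect(ca, ta))) tp <- tp + 1L
      else { fp <- fp + 1L; fn <- fn + 1L }  # wrong allele: both a false
                                            # call and a missed truth
    } else if (!is.null(ca)) {
      fp <- fp + 1L
    } else {
      fn <- fn + 1L
    }
  }
  structure(list(covered_bp = covered_bp, tp = tp,
                 tn = covered_bp - tp - fp - fn, fp = fp, fn = fn,
                 n_outside = n_outside),
            class = "confusion_counts")
}

#' Covered positions from a depth table
#'
#' The evaluable base set: target positions whose depth reaches `min_depth`
#' in the evaluated sample.
#'
#' @param depth a `depth_table`.
#' @param panel a [gene_panel].
#' @param min_depth coverage threshold, default 20.
#' @return data.frame(chrom, pos).
#' @export
covered_positions <- function(depth, panel, min_depth = 20) {
  target <- merge_regions(panel)
  rows <- lapply(seq_along(target), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(target))[i]
    pos <- seq(GenomicRanges::start(target)[i], GenomicRanges::end(target)[i])
    m <- match(position_key(chrom, pos), position_key(depth$chrom, depth$pos))
    d <- depth$depth[m]
    d[is.na(d)] <- 0
    data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)[
      d >= min_depth, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Accuracy and precision report from confusion counts
#'
#' Ratios are percents at the conventional denominators: TP and FN ratios
#' over the truth positives, FP and TN ratios over the truth negatives,
#' accuracy over all covered bases. Precision defaults to the positive
#' predictive value TP/(TP+FP); `precision_formula = "tp_over_tp_fn"`
#' selects the sensitivity-style alternative TP/(TP+FN).
#'
#' @param c a [confusion_counts].
#' @param precision_formula `"ppv"` (default) or `"tp_over_tp_fn"`.
#' @return list of class `bench_report` with `tp_ratio`, `tn_ratio`,
#'   `fp_ratio`, `fn_ratio`, `accuracy`, `precision` (percents; TP/FN
#'   ratios `NA` when there are no truth positives). TP/TN/FN and accuracy
#'   round to 2 decimals, the FP ratio to 3.
#' @export
bench_report <- function(c, precision_formula = c("ppv", "tp_over_tp_fn")) {
  precision_formula <- match.arg(precision_formula)
  pos <- c$tp + c$fn
  neg <- c$tn + c$fp
  tot <- c$covered_bp
  pct <- function(num, den, digits = 2)
    if (den > 0) round(100 * num / den, digits) else NA_real_
  precision <- switch(precision_formula,
                      ppv = pct(c$tp, c$tp + c$fp),
                      tp_over_tp_fn = pct(c$tp, pos))
  structure(list(counts = c,
                 tp_ratio = pct(c$tp, pos),
                 fn_ratio = pct(c$fn, pos),
                 tn_ratio = pct(c$tn, neg),
                 fp_ratio = pct(c$fp, neg, 3),
                 accuracy = pct(c$tp + c$tn, tot),
                 precision = precision),
            class = "bench_report")
}

#' @export
print.bench_report <- function(x, ...) {
  c <- x$counts
  cat("<bench_report>\n")
  cat(sprintf("  covered: %d bp | TP %d  TN %d  FP %d  FN %d\n",
              c$covered_bp, c$tp, c$tn, c$fp, c$fn))
  cat(sprintf("  TP ratio %.2f%%  TN ratio %.2f%%  FN ratio %.2f%%  FP ratio %.3f%%\n",
              x$tp_ratio, x$tn_ratio, x$fn_ratio, x$fp_ratio))
  cat(sprintf("  accuracy %.2f%%  precision %.2f%%\n", x$accuracy, x$precision))
  invisible(x)
}
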