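# Per-region coverage statistics and read-depth CNV detection.
#
# The CNV method normalizes each region's mean depth by its sample's overall
# mean depth (the "depth rate"), then scores a sample's rate for a region
# against the leave-one-out baseline of the other samples sequenced in the
# same run: z = (rate - baseline mean) / baseline SD (n-1 denominator).
# Regions with z < -cutoff are deletion candidates, z > +cutoff duplication
# candidates (strict inequalities); consecutive flagged exons of one gene
# merge into a single call. The default cutoff 3 corresponds to the ~99.9th
# one-tailed percentile of a standard normal baseline.

#' Coverage statistics over a target panel
#'
#' Computes panel-wide coverage from a per-base depth table: mean target
#' depth, percent of target bases at or above each depth threshold, capture
#' specificity (fraction of mapped output on target), and depth/breadth of
#' the flanking regions (`flank_bp` on each side of every merged target
#' interval, excluding bases inside the target). Positions absent from the
#' depth table count as depth 0.
#'
#' @param depth a `depth_table` (see [load_depth]).
#' @param panel a [gene_panel].
#' @param thresholds positive integer depth thresholds (default `c(1, 20)`).
#' @param flank_bp flanking width on each side, default 200.
#' @param mapped_total,mapped_on_target optional mapped read (or base)
#'   counts used for capture specificity.
#' @param mean_read_length optional, carried into the report.
#' @return list of class `coverage_report`.
#' @export
coverage_stats <- function(depth, panel, thresholds = c(1L, 20L),
                           flank_bp = 200L, mapped_total = NULL,
                           mapped_on_target = NULL, mean_read_length = NULL) {
  stopifnot(length(thresholds) > 0, all(thresholds > 0))
  if (nrow(panel) == 0L) stop_input("empty panel")
  target <- merge_regions(panel)
  total_bp <- sum(GenomicRanges::width(target))
  d_target <- depth_at_ranges(depth, target)
  cov_at <- vapply(thresholds, function(t) 100 * mean(d_target >= t),
                   numeric(1))
  names(cov_at) <- as.character(thresholds)
  # flanks: +-flank_bp around each merged interval, minus the target itself
  flank <- flank_ranges(target, flank_bp)
  d_flank <- depth_at_ranges(depth, flank)
  structure(list(
    total_target_bp = total_bp,
    mean_depth_target = mean(d_target),
    coverage_at = cov_at,
    capture_specificity = if (!is.null(mapped_total) &&
                              !is.null(mapped_on_target))
      100 * mapped_on_target / mapped_total else NA_real_,
    mean_depth_flanking = if (length(d_flank)) mean(d_flank) else NA_real_,
    coverage_flanking_1x = if (length(d_flank)) 100 * mean(d_flank >= 1)
                           else NA_real_,
    mean_read_length = mean_read_length %||% NA_real_),
    class = "coverage_report")
}

# per-base depths (0 where absent) over a set of GRanges
depth_at_ranges <- function(depth, gr) {
  if (length(gr) == 0L) return(numeric())
  pos <- unlist(lapply(seq_along(gr), function(i)
    position_key(as.character(GenomicRanges::seqnames(gr))[i],
                 seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))))
  m <- match(pos, position_key(depth$chrom, depth$pos))
  out <- depth$depth[m]
  out[is.na(out)] <- 0
  out
}

flank_ranges <- function(target, flank_bp) {
  if (length(target) == 0L || flank_bp <= 0) return(GenomicRanges::GRanges())
  left <- GenomicRanges::flank(target, flank_bp, start = TRUE)
  right <- GenomicRanges::flank(target, flank_bp, start = FALSE)
  fl <- GenomicRanges::reduce(c(left, right))
  fl <- GenomicRanges::setdiff(fl, target)
  fl <- fl[GenomicRanges::end(fl) >= 1]
  GenomicRanges::start(fl) <- pmax(GenomicRanges::start(fl), 1L)
  fl
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report>\n")
  cat(sprintf("  target bp (merged):      %d\n", x$total_target_bp))
  cat(sprintf("  mean depth of target:    %.2f\n", x$mean_depth_target))
  for (t in names(x$coverage_at))
    cat(sprintf("  coverage >= %sX (%%):      %.2f\n", t, x$coverage_at[[t]]))
  if (!is.na(x$capture_specificity))
    cat(sprintf("  capture specificity (%%): %.2f\n", x$capture_specificity))
  if (!is.na(x$mean_depth_flanking))
    cat(sprintf("  flanking depth / >=1X%%:  %.2f / %.2f\n",
                x$mean_depth_flanking, x$coverage_flanking_1x))
  invisible(x)
}

#' Per-sample, per-region mean-depth matrix for one sequencing run
#'
#' @param mean_depth numeric matrix, samples in rows, panel regions in
#'   columns (column order matches the panel's region order).
#' @param panel the [gene_panel] whose regions the columns describe.
#' @param run_id label of the sequencing run/lane the samples shared.
#' @param sample_mean_depth optional per-sample mean depth over all panel
#'   bases; computed as the region-length-weighted mean when omitted.
#' @return object of class `depth_matrix`.
#' @export
depth_matrix <- function(mean_depth, panel, run_id = "run1",
                         sample_mean_depth = NULL) {
  stopifnot(is.matrix(mean_depth), ncol(mean_depth) == nrow(panel),
            all(mean_depth >= 0))
  if (is.null(rownames(mean_depth)))
    rownames(mean_depth) <- paste0("S", seq_len(nrow(mean_depth)))
  if (is.null(sample_mean_depth)) {
    w <- panel$end - panel$start
    sample_mean_depth <- as.numeric(mean_depth %*% w) / sum(w)
    names(sample_mean_depth) <- rownames(mean_depth)
  }
  structure(list(run_id = run_id, mean_depth = mean_depth, panel = panel,
                 sample_mean_depth = sample_mean_depth),
            class = "depth_matrix")
}

#' Mean depth of each panel region from a per-base depth table
#'
#' @param depth a `depth_table`.
#' @param panel a [gene_panel].
#' @return numeric vector of per-region mean depths, in panel region order.
#' @export
region_mean_depth <- function(depth, panel) {
  vapply(seq_len(nrow(panel)), function(i) {
    pos <- seq(panel$start[i] + 1L, panel$end[i])
    m <- match(position_key(panel$chrom[i], pos),
               position_key(depth$chrom, depth$pos))
    d <- depth$depth[m]
    d[is.na(d)] <- 0
    mean(d)
  }, numeric(1))
}

#' Normalized depth rates
#'
#' Divides every region's mean depth by its sample's overall mean depth,
#' removing per-sample library-size differences. Samples with zero overall
#' depth are excluded with a warning.
#'
#' @param dm a [depth_matrix].
#' @return numeric matrix of rates (samples x regions) with attribute
#'   `panel`.
#' @export
region_depth_rates <- function(dm) {
  stopifnot(inherits(dm, "depth_matrix"))
  zero <- dm$sample_mean_depth <= 0
  if (any(zero)) {
    warning(sprintf("excluding %d sample(s) with zero mean depth: %s",
                    sum(zero),
                    paste(rownames(dm$mean_depth)[zero], collapse = ", ")),
            call. = FALSE)
  }
  rates <- dm$mean_depth[!zero, , drop = FALSE] / dm$sample_mean_depth[!zero]
  attr(rates, "panel") <- dm$panel
  rates
}

#' Leave-one-out CNV z-scores for one sample
#'
#' For each region, the tested sample's depth rate is standardized against
#' the other samples of the run: `z = (rate - mean(others)) / sd(others)`
#' with the sample (n-1) standard deviation. Regions whose baseline SD falls
#' below `sd_floor` are uninformative and return `NA`.
#'
#' @param rates matrix from [region_depth_rates].
#' @param sample row name (or index) of the tested sample.
#' @param sd_floor minimum baseline SD, default `1e-6`.
#' @param min_baseline minimum number of other samples required (default 3).
#' @return numeric vector of per-region z-scores (NA where uninformative).
#' @export
cnv_zscores <- function(rates, sample, sd_floor = 1e-6, min_baseline = 3L) {
  if (is.character(sample)) sample <- match(sample, rownames(rates))
  if (is.na(sample) || sample < 1 || sample > nrow(rates))
    stop_input("unknown sample")
  base <- rates[-sample, , drop = FALSE]
  if (nrow(base) < min_baseline)
    stop_input("CNV baseline needs >= %d other samples in the run, got %d",
               min_baseline, nrow(base))
  mu <- colMeans(base)
  sd0 <- apply(base, 2, stats::sd)
  z <- (rates[sample, ] - mu) / sd0
  z[sd0 < sd_floor] <- NA_real_
  z
}

#' Call large deletions and duplications from per-region z-scores
#'
#' Flags regions with `z < -cutoff` as deletion candidates and `z > cutoff`
#' as duplication candidates (strictly: a region at exactly the cutoff is
#' not called), then merges runs of consecutively flagged same-direction
#' regions of the same gene into single calls.
#'
#' @param z per-region z-scores in panel region order (NA = uninformative).
#' @param panel the [gene_panel] the scores refer to.
#' @param sample_id label recorded on the calls.
#' @param cutoff z threshold, default 3.
#' @return data.frame of class `cnv_calls`: one row per merged call with
#'   chrom, start, end, gene, direction, `z_extreme`, number of regions and
#'   list-columns of constituent region indices and z values.
#' @export
call_cnvs <- function(z, panel, sample_id = "sample", cutoff = 3) {
  stopifnot(length(z) == nrow(panel))
  dir <- ifelse(is.na(z), "none",
                ifelse(z < -cutoff, "deletion",
                       ifelse(z > cutoff, "duplication", "none")))
  calls <- list()
  i <- 1L
  n <- length(z)
  while (i <= n) {
    if (dir[i] == "none") { i <- i + 1L; next }
    j <- i
    while (j < n && dir[j + 1L] == dir[i] &&
           panel$gene[j + 1L] == panel$gene[i]) j <- j + 1L
    idx <- i:j
    zs <- z[idx]
    calls[[length(calls) + 1L]] <- data.frame(
      sample_id = sample_id,
      chrom = panel$chrom[i],
      start = min(panel$start[idx]),
      end = max(panel$end[idx]),
      gene = panel$gene[i],
      direction = dir[i],
      z_extreme = if (dir[i] == "deletion") min(zs) else max(zs),
      n_regions = length(idx),
      stringsAsFactors = FALSE)
    calls[[length(calls)]]$regions <- list(idx)
    calls[[length(calls)]]$per_region_z <- list(zs)
    i <- j + 1L
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample_id = character(), chrom = character(),
               start = integer(), end = integer(), gene = character(),
               direction = character(), z_extreme = numeric(),
               n_regions = integer(), stringsAsFactors = FALSE)
  class(out) <- c("cnv_calls", "data.frame")
  out
}

#' One-tailed standard-normal percentile of a z cutoff
#'
#' The percentile of the baseline distribution that a cutoff corresponds to
#' under normality: `100 * pnorm(cutoff)`. A cutoff of 3 sits at the 99.9th
#' percentile (one decimal), the usual justification for the +-3 rule.
#'
#' @param cutoff z-score cutoff.
#' @return percentile in \[0, 100\].
#' @export
zscore_percentile <- function(cutoff = 3) {
  100 * stats::pnorm(cutoff)
}

#' Write CNV calls as a BED-like TSV
#' @param calls a `cnv_calls` data.frame.
#' @param path output path.
#' @export
write_cnv_calls <- function(calls, path) {
  utils::write.table(
    as.data.frame(calls)[, c("chrom", "start", "end", "sample_id", "gene",
                             "direction", "z_extreme", "n_regions")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
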