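# Pre-alignment read quality filter ("unqualified reads").
#
# A read is unqualified — and removed whole, never trimmed — when any of
# four rules fires, tested in fixed order:
#   1. adapter:          a stretch of the adapter aligns within the read
#   2. n_fraction:       ambiguous (N) bases exceed 10% of the read length
#   3. mean_quality:     arithmetic mean Phred < 10
#   4. low_quality_bases: >= 50% of bases below Phred 5
# Paired-end mates are removed together when either mate fails.

DEFAULT_ADAPTER <- "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAG"  # Illumina PE adapter

#' QC thresholds for the unqualified-read filter
#'
#' @param adapter_seq adapter sequence to screen for (default: standard
#'   Illumina paired-end adapter).
#' @param adapter_min_match minimum aligned adapter stretch, bases.
#' @param adapter_max_mismatch mismatches tolerated inside that stretch.
#' @param max_n_fraction maximum tolerated N fraction (strict `>` removes).
#' @param min_mean_quality reads with mean Phred below this are removed.
#' @param low_qual_threshold Phred value defining a "low quality" base.
#' @param max_low_qual_fraction reads with at least this fraction of bases
#'   below `low_qual_threshold` are removed (`>=`).
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(adapter_seq = DEFAULT_ADAPTER,
                          adapter_min_match = 10L,
                          adapter_max_mismatch = 1L,
                          max_n_fraction = 0.10,
                          min_mean_quality = 10,
                          low_qual_threshold = 5,
                          max_low_qual_fraction = 0.50) {
  stopifnot(nzchar(adapter_seq), adapter_min_match >= 1,
            adapter_max_mismatch >= 0,
            max_n_fraction >= 0, max_n_fraction <= 1,
            max_low_qual_fraction >= 0, max_low_qual_fraction <= 1,
            min_mean_quality >= 0, low_qual_threshold >= 0)
  structure(list(adapter_seq = toupper(adapter_seq),
                 adapter_min_match = as.integer(adapter_min_match),
                 adapter_max_mismatch = as.integer(adapter_max_mismatch),
                 max_n_fraction = max_n_fraction,
                 min_mean_quality = min_mean_quality,
                 low_qual_threshold = low_qual_threshold,
                 max_low_qual_fraction = max_low_qual_fraction),
            class = "qc_thresholds")
}

#' Construct an in-memory read set
#'
#' @param read_id character vector of read names.
#' @param sequence uppercase base strings.
#' @param qualities list of integer Phred vectors, one per read, each the
#'   same length as its sequence.
#' @param mate optional integer vector in \{1, 2\}; mates pair by `read_id`.
#' @return data.frame of class `read_set` with a `qualities` list-column.
#' @export
read_set <- function(read_id, sequence, qualities, mate = NA_integer_) {
  df <- data.frame(read_id = read_id, sequence = toupper(sequence),
                   mate = rep(as.integer(mate), length.out = length(read_id)),
                   stringsAsFactors = FALSE)
  df$qualities <- qualities
  class(df) <- c("read_set", "data.frame")
  df
}

#' Test a read for adapter pollution
#'
#' True iff some alignment of the adapter within the read covers at least
#' `adapter_min_match` bases with at most `adapter_max_mismatch` mismatches.
#' The adapter may run off the 3' end of the read (read-through), so every
#' start offset is tried and the overlap is the shorter of the remaining
#' read and the adapter.
#'
#' @param sequence a single read sequence (character scalar).
#' @param t a [qc_thresholds].
#' @return logical scalar.
#' @export
is_adapter_polluted <- function(sequence, t = qc_thresholds()) {
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  ad_chars <- strsplit(t$adapter_seq, "")[[1]]
  len <- length(seq_chars)
  alen <- length(ad_chars)
  if (len < t$adapter_min_match) return(FALSE)
  for (s in seq_len(len - t$adapter_min_match + 1L)) {
    overlap <- min(len - s + 1L, alen)
    if (overlap < t$adapter_min_match) break
    mm <- sum(seq_chars[s:(s + overlap - 1L)] != ad_chars[seq_len(overlap)])
    if (mm <= t$adapter_max_mismatch) return(TRUE)
  }
  FALSE
}

qc_reason <- function(sequence, quals, t) {
  # first-firing rule in the fixed order; NA when the read is clean
  if (is_adapter_polluted(sequence, t)) return("adapter")
  chars <- strsplit(sequence, "")[[1]]
  if (mean(chars == "N") > t$max_n_fraction) return("n_fraction")
  if (mean(quals) < t$min_mean_quality) return("mean_quality")
  if (mean(quals < t$low_qual_threshold) >= t$max_low_qual_fraction)
    return("low_quality_bases")
  NA_character_
}

#' Filter unqualified reads
#'
#' Applies the four-rule unqualified-read filter to a [read_set]. A read is
#' removed iff any rule fires; the first firing rule (order: adapter,
#' n_fraction, mean_quality, low_quality_bases) is recorded as its removal
#' reason. When mate labels are present, the surviving mate of a failed read
#' is removed too and counted under the partner's reason. Reads whose
#' quality vector length mismatches the sequence are dropped and counted
#' separately as invalid.
#'
#' @param reads a [read_set].
#' @param t a [qc_thresholds].
#' @return list of class `qc_result`: `kept` (a [read_set]) and `report`
#'   (class `qc_report`: `n_input`, `n_kept`, `removal_counts`, `n_invalid`).
#' @export
filter_reads <- function(reads, t = qc_thresholds()) {
  n_input <- nrow(reads)
  valid <- nchar(reads$sequence) == lengths(reads$qualities)
  n_invalid <- sum(!valid)
  r <- reads[valid, , drop = FALSE]
  reason <- vapply(seq_len(nrow(r)), function(i)
    qc_reason(r$sequence[i], r$qualities[[i]], t), character(1))
  # drag the mate down with the failing read
  paired <- !is.na(r$mate)
  if (any(paired)) {
    fail <- !is.na(reason)
    by_id <- split(which(paired), r$read_id[paired])
    for (idx in by_id) {
      f <- idx[fail[idx]]
      if (length(f) && length(idx) > 1L) {
        drag <- setdiff(idx, f)
        reason[drag[is.na(reason[drag])]] <- reason[f[1]]
      }
    }
  }
  reasons <- c("adapter", "n_fraction", "mean_quality", "low_quality_bases")
  counts <- stats::setNames(
    vapply(reasons, function(x) sum(reason == x, na.rm = TRUE), integer(1)),
    reasons)
  kept <- r[is.na(reason), , drop = FALSE]
  report <- structure(list(n_input = n_input,
                           n_kept = nrow(kept),
                           removal_counts = counts,
                           n_invalid = n_invalid),
                      class = "qc_report")
  structure(list(kept = kept, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> input %d, kept %d (%.2f%%), invalid %d\n",
              x$n_input, x$n_kept,
              if (x$n_input) 100 * x$n_kept / x$n_input else 0, x$n_invalid))
  for (r in names(x$removal_counts))
    cat(sprintf("  removed %-18s %d\n", paste0(r, ":"), x$removal_counts[[r]]))
  invisible(x)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ path (optionally gzipped).
#' @param encoding quality encoding: `"phred33"` (default) or `"phred64"`.
#' @param mate optional mate label \{1, 2\} applied to every read.
#' @return a [read_set].
#' @export
read_fastq <- function(path, encoding = c("phred33", "phred64"), mate = NA) {
  encoding <- match.arg(encoding)
  scoring <- if (encoding == "phred33") "phred" else "illumina"
  # coercions drop (unused) FASTQ metadata columns; silence that chatter
  x <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path,
                                              quality.scoring = scoring))
  quals <- suppressWarnings(as(Biostrings::quality(x), "IntegerList"))
  read_set(read_id = sub("\\s.*$", "", names(x)),
           sequence = as.character(x),
           qualities = as.list(quals),
           mate = mate)
}

#' Write a read set as FASTQ (Phred+33)
#' @param reads a [read_set].
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    qual <- intToUtf8(reads$qualities[[i]] + 33L)
    writeLines(c(paste0("@", reads$read_id[i]), reads$sequence[i], "+", qual),
               con)
  }
  invisible(path)
}

#' Filter paired FASTQ files
#'
#' File-level wrapper around [filter_reads]: reads one or two FASTQ files,
#' filters in lock-step (mates removed together), writes the surviving reads
#' and returns the QC report.
#'
#' @param in1 R1 FASTQ path.
#' @param in2 optional R2 FASTQ path.
#' @param out_prefix output prefix; writes `<prefix>_1.fq` (and `_2.fq`).
#' @param t a [qc_thresholds].
#' @param encoding quality encoding, see [read_fastq].
#' @return the `qc_report`, invisibly.
#' @export
filter_fastq <- function(in1, in2 = NULL, out_prefix = "filtered",
                         t = qc_thresholds(),
                         encoding = c("phred33", "phred64")) {
  encoding <- match.arg(encoding)
  r1 <- read_fastq(in1, encoding, mate = if (is.null(in2)) NA else 1L)
  reads <- r1
  if (!is.null(in2)) {
    r2 <- read_fastq(in2, encoding, mate = 2L)
    if (nrow(r1) != nrow(r2))
      stop_input("paired FASTQ files differ in read count")
    reads <- rbind(r1, r2)
    class(reads) <- class(r1)
  }
  res <- filter_reads(reads, t)
  if (is.null(in2)) {
    write_fastq(res$kept, paste0(out_prefix, "_1.fq"))
  } else {
    write_fastq(res$kept[res$kept$mate == 1L, ], paste0(out_prefix, "_1.fq"))
    write_fastq(res$kept[res$kept$mate == 2L, ], paste0(out_prefix, "_2.fq"))
  }
  invisible(res$report)
}
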