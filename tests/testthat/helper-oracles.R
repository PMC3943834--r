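# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# adapter detection: compare every adapter placement base by base
oracle_adapter <- function(sequence, adapter, min_match, max_mismatch) {
  s <- strsplit(toupper(sequence), "")[[1]]
  a <- strsplit(toupper(adapter), "")[[1]]
  for (start in seq_along(s)) {
    n <- min(length(s) - start + 1, length(a))
    if (n < min_match) next
    mm <- 0
    for (k in 0:(n - 1)) if (s[start + k] != a[1 + k]) mm <- mm + 1
    if (mm <= max_mismatch) return(TRUE)
  }
  FALSE
}

# candidate filter: re-state the predicates longhand, row by row
oracle_filter <- function(v, min_q = 20, max_af = 0.01, genes = NULL) {
  keep <- logical(nrow(v))
  snv_classes <- c("nonsense", "splice_site", "missense")
  indel_classes <- c("frameshift", "inframe_indel", "splice_site")
  for (i in seq_len(nrow(v))) {
    q <- !is.na(v$call_quality[i]) && v$call_quality[i] >= min_q
    fun <- if (is.na(v$consequence[i])) FALSE
           else if (v$vtype[i] == "SNV") v$consequence[i] %in% snv_classes
           else v$consequence[i] %in% indel_classes
    afs <- v$db_afs[[i]]
    rare <- if (length(afs) == 0) TRUE else all(afs < max_af)
    g <- is.null(genes) || v$gene[i] %in% genes
    keep[i] <- q && fun && rare && g
  }
  keep
}

# confusion counting: walk every covered position independently
oracle_confusion <- function(calls, truth, covered,
                             min_q = 20, min_dp = 20, min_af = 0.28) {
  calls <- calls[calls$vtype == "SNV", , drop = FALSE]
  truth <- truth[truth$vtype == "SNV", , drop = FALSE]
  ok <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (!is.na(calls$call_quality[i]) && calls$call_quality[i] < min_q)
      ok[i] <- FALSE
    if (!is.na(calls$depth[i]) && calls$depth[i] < min_dp) ok[i] <- FALSE
    if (!is.na(calls$alt_fraction[i]) && calls$alt_fraction[i] < min_af)
      ok[i] <- FALSE
  }
  calls <- calls[ok, , drop = FALSE]
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(covered))) {
    ch <- covered$chrom[i]; p <- covered$pos[i]
    ca <- calls$alt[calls$chrom == ch & calls$pos == p]
    ta <- truth$alt[truth$chrom == ch & truth$pos == p]
    if (length(ca) && length(ta)) {
      if (length(intersect(ca, ta))) tp <- tp + 1L
      else { fp <- fp + 1L; fn <- fn + 1L; tn <- tn - 1L }
    } else if (length(ca)) fp <- fp + 1L
    else if (length(ta)) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, tn = tn + 0L, fp = fp, fn = fn)
}

# z-scores: naive two-pass mean/SD per region
oracle_zscores <- function(rates, sample_row) {
  others <- rates[-sample_row, , drop = FALSE]
  z <- numeric(ncol(rates))
  for (r in seq_len(ncol(rates))) {
    m <- sum(others[, r]) / nrow(others)
    ss <- sum((others[, r] - m)^2) / (nrow(others) - 1)
    s <- sqrt(ss)
    z[r] <- if (s < 1e-6) NA_real_ else (rates[sample_row, r] - m) / s
  }
  z
}

# small hand-built variant tables for triage tests
make_variant <- function(pos, consequence, vtype = "SNV", quality = 60,
                         afs = numeric(), preds = character(),
                         conserved = FALSE, gtat = FALSE,
                         known_id = NA_character_, gene = "GCK",
                         zygosity = "het") {
  ref_alt <- switch(vtype, SNV = c("A", "G"), insertion = c("A", "AT"),
                    deletion = c("AT", "A"))
  df <- data.frame(chrom = "panelsim1", pos = pos, ref = ref_alt[1],
                   alt = ref_alt[2], vtype = vtype, zygosity = zygosity,
                   call_quality = quality, depth = 100L, alt_fraction = 0.5,
                   gene = gene, consequence = consequence,
                   known_id = known_id, conserved = conserved, gtat = gtat,
                   stringsAsFactors = FALSE)
  df$db_afs <- list(afs)
  df$predictor_calls <- list(preds)
  df
}

make_variants <- function(...) variant_table(do.call(rbind, list(...)))
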