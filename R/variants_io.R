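# Variant records and VCF transport.
#
# Annotations (consequence, database allele frequencies, predictor verdicts,
# conservation, known-mutation ids) are *consumed* from INFO fields, never
# computed here: the external predictors and frequency databases are upstream
# producers. INFO-key contract (VCF 4.x, single-sample):
#   GENE        String  gene symbol
#   CSQ         String  consequence token (see `CONSEQUENCES`)
#   AF_<db>     Float   allele frequency in database <db> (open set of names)
#   PRED_<tool> String  damaging | benign | unknown
#   CONSERVED   Flag    missense falls in a cross-species conserved region
#   GTAT        Flag    splice variant disrupts a canonical GT/AG dinucleotide
#   KNOWN_ID    String  citation id into the knowledge table
# Genotype from GT; depth from FORMAT DP (else INFO DP); alt-supporting read
# fraction from FORMAT AD when present.

#' Construct a variant table
#'
#' The package-wide container for called variants: one row per ALT allele
#' with genotype, caller quality, depth, alt-read fraction and annotations.
#' `db_afs` and `predictor_calls` are list-columns of named vectors so new
#' frequency databases or predictors need no schema change.
#'
#' @param df data.frame with at least `chrom`, `pos` (1-based), `ref`, `alt`.
#'   Missing optional columns are filled with defaults.
#' @return data.frame of class `variant_table`.
#' @export
variant_table <- function(df) {
  n <- nrow(df)
  defaults <- list(
    vtype = NA_character_, zygosity = NA_character_,
    call_quality = NA_real_, depth = NA_integer_, alt_fraction = NA_real_,
    gene = "", consequence = NA_character_, known_id = NA_character_,
    conserved = FALSE, gtat = FALSE)
  for (col in names(defaults))
    if (is.null(df[[col]])) df[[col]] <- rep(defaults[[col]], length.out = n)
  if (is.null(df$db_afs)) df$db_afs <- rep(list(numeric()), n)
  if (is.null(df$predictor_calls)) df$predictor_calls <- rep(list(character()), n)
  if (n) {
    df$vtype <- ifelse(!is.na(df$vtype), df$vtype, infer_vtype(df$ref, df$alt))
    ok <- infer_vtype(df$ref, df$alt) == df$vtype
    if (any(!ok))
      stop_input("vtype inconsistent with ref/alt at row %d", which(!ok)[1])
    af <- df$alt_fraction
    if (any(!is.na(af) & (af < 0 | af > 1)))
      stop_input("alt_fraction outside [0,1]")
    badc <- !is.na(df$consequence) & !(df$consequence %in% CONSEQUENCES)
    if (any(badc))
      stop_input("unknown consequence '%s'", df$consequence[badc][1])
  }
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

infer_vtype <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt) & nchar(ref) == 1L, "SNV",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d variants\n", nrow(x)))
  if (nrow(x))
    print(utils::head(as.data.frame(x)[, c("chrom", "pos", "ref", "alt",
                                           "vtype", "zygosity", "gene",
                                           "consequence")], 8))
  invisible(x)
}

#' Load variants from a single-sample VCF
#'
#' Reads a VCF 4.x file via `VariantAnnotation` and returns one row per ALT
#' allele (multi-allelic sites are split). Records without a usable GT are
#' skipped with a warning rather than aborting the load.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return a [variant_table].
#' @export
load_variants <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0L) return(variant_table(empty_variant_df()))
  info <- VariantAnnotation::info(vcf)
  geno <- VariantAnnotation::geno(vcf)
  gt <- if ("GT" %in% names(geno)) geno$GT[, 1] else rep(NA_character_, n)
  dp <- if ("DP" %in% names(geno)) geno$DP[, 1]
        else if ("DP" %in% names(info)) info$DP else rep(NA_integer_, n)
  ad <- if ("AD" %in% names(geno)) geno$AD[, 1] else NULL
  alts <- VariantAnnotation::alt(vcf)
  af_keys <- grep("^AF_", names(info), value = TRUE)
  pred_keys <- grep("^PRED_", names(info), value = TRUE)

  scalar <- function(v) if (methods::is(v, "List")) unlist(v[[1]])[1] else v[1]
  rows <- vector("list", n)
  skipped <- 0L
  for (i in seq_len(n)) {
    g <- gt[i]
    if (is.na(g) || g %in% c(".", "./.", ".|.")) {
      skipped <- skipped + 1L
      next
    }
    a_idx <- as.integer(strsplit(g, "[/|]")[[1]])
    alt_i <- as.character(alts[[i]])
    ad_i <- if (!is.null(ad)) unlist(ad[i]) else NULL
    if (!is.null(ad_i) && any(is.na(ad_i))) ad_i <- NULL
    sub <- lapply(seq_along(alt_i), function(k) {
      zyg <- if (all(a_idx == k)) "hom" else "het"
      frac <- if (!is.null(ad_i) && length(ad_i) >= k + 1L &&
                  sum(ad_i) > 0) ad_i[k + 1L] / sum(ad_i) else NA_real_
      kid <- if ("KNOWN_ID" %in% names(info)) scalar(info$KNOWN_ID[i])
             else NA_character_
      data.frame(
        chrom = as.character(GenomicRanges::seqnames(rr))[i],
        pos = GenomicRanges::start(rr)[i],
        ref = as.character(rr$REF[i]),
        alt = alt_i[k],
        zygosity = zyg,
        call_quality = rr$QUAL[i],
        depth = as.integer(scalar(dp[i])),
        alt_fraction = frac,
        gene = if ("GENE" %in% names(info)) {
          v <- scalar(info$GENE[i]); if (is.na(v)) "" else v
        } else "",
        consequence = if ("CSQ" %in% names(info)) scalar(info$CSQ[i])
                      else NA_character_,
        known_id = if (!is.null(kid) && !is.na(kid) && nzchar(kid)) kid
                   else NA_character_,
        conserved = isTRUE(info$CONSERVED[i]),
        gtat = isTRUE(info$GTAT[i]),
        stringsAsFactors = FALSE)
    })
    sub <- do.call(rbind, sub)
    sub$db_afs <- rep(list(afs_of(info, af_keys, i)), nrow(sub))
    sub$predictor_calls <- rep(list(preds_of(info, pred_keys, i)), nrow(sub))
    rows[[i]] <- sub
  }
  if (skipped)
    warning(sprintf("skipped %d record(s) without GT in %s", skipped,
                    basename(path)), call. = FALSE)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(variant_table(empty_variant_df()))
  variant_table(do.call(rbind, rows))
}

afs_of <- function(info, af_keys, i) {
  afs <- numeric()
  for (key in af_keys) {
    v <- info[[key]][i]
    v <- if (methods::is(v, "List")) unlist(v)[1] else v
    if (length(v) && !is.na(v)) afs[sub("^AF_", "", key)] <- as.numeric(v)
  }
  afs
}

preds_of <- function(info, pred_keys, i) {
  preds <- character()
  for (key in pred_keys) {
    v <- info[[key]][i]
    v <- if (methods::is(v, "List")) unlist(v)[1] else v
    if (length(v) && !is.na(v)) preds[sub("^PRED_", "", key)] <- as.character(v)
  }
  preds
}

empty_variant_df <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), stringsAsFactors = FALSE)
}

#' Write a variant table as a single-sample VCF
#'
#' Emits VCF 4.2 with the package's INFO-key contract (see [load_variants])
#' so that `load_variants(write_variants(v, f))` round-trips. The header
#' carries no timestamp: identical inputs give byte-identical files.
#'
#' @param variants a [variant_table].
#' @param path output VCF path.
#' @param sample_id sample column name.
#' @param extra_info optional character vector of extra INFO header lines.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, sample_id = "SAMPLE") {
  v <- as.data.frame(variants)
  db_names <- sort(unique(unlist(lapply(v$db_afs, names))))
  pred_names <- sort(unique(unlist(lapply(v$predictor_calls, names))))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=paneldx",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=CONSERVED,Number=0,Type=Flag,Description="Conserved missense position">',
    '##INFO=<ID=GTAT,Number=0,Type=Flag,Description="Disrupts canonical GT/AG splice dinucleotide">',
    '##INFO=<ID=KNOWN_ID,Number=1,Type=String,Description="Knowledge-table citation id">',
    sprintf('##INFO=<ID=AF_%s,Number=1,Type=Float,Description="Allele frequency in %s">',
            db_names, db_names),
    sprintf('##INFO=<ID=PRED_%s,Number=1,Type=String,Description="Verdict of predictor %s">',
            pred_names, pred_names),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t"))
  body <- character(nrow(v))
  for (i in seq_len(max(nrow(v), 0L))) {
    inf <- character()
    if (nzchar(v$gene[i])) inf <- c(inf, paste0("GENE=", v$gene[i]))
    if (!is.na(v$consequence[i])) inf <- c(inf, paste0("CSQ=", v$consequence[i]))
    afs <- v$db_afs[[i]]
    if (length(afs))
      inf <- c(inf, sprintf("AF_%s=%s", names(afs),
                            formatC(afs, format = "g", digits = 6)))
    preds <- v$predictor_calls[[i]]
    if (length(preds)) inf <- c(inf, sprintf("PRED_%s=%s", names(preds), preds))
    if (isTRUE(v$conserved[i])) inf <- c(inf, "CONSERVED")
    if (isTRUE(v$gtat[i])) inf <- c(inf, "GTAT")
    if (!is.na(v$known_id[i])) inf <- c(inf, paste0("KNOWN_ID=", v$known_id[i]))
    gt <- if (identical(v$zygosity[i], "hom")) "1/1" else "0/1"
    dp <- v$depth[i]
    fmt <- "GT"
    smp <- gt
    if (!is.na(dp)) { fmt <- paste0(fmt, ":DP"); smp <- paste0(smp, ":", dp) }
    if (!is.na(v$alt_fraction[i]) && !is.na(dp)) {
      alt_reads <- round(v$alt_fraction[i] * dp)
      fmt <- paste0(fmt, ":AD")
      smp <- paste0(smp, ":", dp - alt_reads, ",", alt_reads)
    }
    body[i] <- paste(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i],
                     if (is.na(v$call_quality[i])) "." else
                       formatC(v$call_quality[i], format = "g", digits = 6),
                     "PASS",
                     if (length(inf)) paste(inf, collapse = ";") else ".",
                     fmt, smp, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
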