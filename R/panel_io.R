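# Panel, depth-table and knowledge-table data model and I/O.
#
# Coordinate conventions: BED input is 0-based half-open and so is the
# in-memory panel (start 0-based inclusive, end exclusive); depth tables and
# VCF positions are 1-based. Strand is ignored throughout.

REGION_CLASSES <- c("CDS", "intron", "UTR5", "UTR3", "promoter",
                    "splice_site", "intergenic")

CONSEQUENCES <- c("missense", "nonsense", "splice_site", "synonymous",
                  "frameshift", "inframe_indel", "UTR5", "UTR3", "intron",
                  "intergenic", "promoter", "read_through")

#' Construct a gene panel from target regions
#'
#' A gene panel is the coordinate backbone of every downstream stage: an
#' ordered table of capture target regions, each annotated with the gene it
#' belongs to and a region class (CDS, intron, UTR, ...). Regions are sorted
#' by (chrom, start); `total_target_bp` is the footprint after merging
#' overlapping intervals, so double-tiled bases are counted once.
#'
#' @param regions data.frame with columns `chrom`, `start` (0-based),
#'   `end` (exclusive), `gene`, `region_class`, and optionally `exon_index`.
#' @return object of class `gene_panel`: the sorted region data.frame with
#'   attributes `genes` and `total_target_bp`.
#' @export
gene_panel <- function(regions) {
  if (nrow(regions) == 0L) {
    regions <- data.frame(chrom = character(), start = integer(),
                          end = integer(), gene = character(),
                          region_class = character(), exon_index = integer(),
                          stringsAsFactors = FALSE)
  }
  need <- c("chrom", "start", "end", "gene", "region_class")
  if (!all(need %in% names(regions)))
    stop_input("panel regions need columns: %s", paste(need, collapse = ", "))
  if (is.null(regions$exon_index)) regions$exon_index <- NA_integer_
  bad <- which(!(regions$region_class %in% REGION_CLASSES))
  if (length(bad))
    stop_input("unknown region_class '%s' (row %d)",
               regions$region_class[bad[1]], bad[1])
  if (any(regions$start >= regions$end))
    stop_input("region with start >= end (row %d)",
               which(regions$start >= regions$end)[1])
  regions <- regions[order(regions$chrom, regions$start, regions$end), ,
                     drop = FALSE]
  rownames(regions) <- NULL
  structure(regions,
            genes = sort(unique(regions$gene)),
            total_target_bp = sum(GenomicRanges::width(merge_regions(regions))),
            class = c("gene_panel", "data.frame"))
}

#' Merge overlapping target regions
#'
#' Collapses a region table to its union of intervals (0-based half-open),
#' per chromosome. Idempotent.
#'
#' @param regions a `gene_panel` or plain region data.frame.
#' @return a `GRanges` of merged intervals (1-based internally, as GRanges
#'   always is; widths equal the half-open lengths).
#' @export
merge_regions <- function(regions) {
  if (nrow(regions) == 0L)
    return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  GenomicRanges::reduce(gr)
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %d regions, %d genes, %d target bp (merged)\n",
              nrow(x), length(attr(x, "genes")), attr(x, "total_target_bp")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Load a gene panel from a BED file
#'
#' Expects BED (0-based half-open) whose name column (4th) carries
#' `GENE|CLASS` or `GENE|CLASS|EXON`, e.g. `GCK|CDS|1`. Unknown region-class
#' tokens are rejected.
#'
#' @param path BED file path.
#' @return a [gene_panel].
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) return(gene_panel(data.frame()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 4L)
      stop_input("malformed BED line %d: expected >= 4 columns", i)
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stop_input("malformed BED line %d: non-numeric coordinates", i)
    name <- strsplit(f[4], "|", fixed = TRUE)[[1]]
    if (length(name) < 2L)
      stop_input("malformed BED line %d: name must be GENE|CLASS[|EXON]", i)
    data.frame(chrom = f[1], start = start, end = end, gene = name[1],
               region_class = name[2],
               exon_index = if (length(name) >= 3L) as.integer(name[3])
                            else NA_integer_,
               stringsAsFactors = FALSE)
  })
  gene_panel(do.call(rbind, rows))
}

#' Write a gene panel as BED
#'
#' Inverse of [load_panel]; `load_panel(write_panel(p, f))` reproduces `p`.
#'
#' @param panel a [gene_panel].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  name <- ifelse(is.na(panel$exon_index),
                 paste(panel$gene, panel$region_class, sep = "|"),
                 paste(panel$gene, panel$region_class, panel$exon_index,
                       sep = "|"))
  writeLines(paste(panel$chrom, panel$start, panel$end, name, sep = "\t"),
             path)
  invisible(path)
}

#' Load a per-base depth table
#'
#' Reads the 3-column `chrom<TAB>pos<TAB>depth` format that standard depth
#' tools emit (positions 1-based). Positions absent from the table are
#' interpreted as depth 0 by consumers.
#'
#' @param path TSV path.
#' @param sample_id optional sample label (defaults to the file stem).
#' @return a `depth_table`: data.frame(chrom, pos, depth) with attribute
#'   `sample_id`.
#' @export
load_depth <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  if (file.size(path) == 0L)
    return(depth_table(data.frame(chrom = character(), pos = integer(),
                                  depth = integer()), sample_id))
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "pos", "depth"),
                         colClasses = c("character", "integer", "integer"))
  depth_table(d, sample_id)
}

#' @rdname load_depth
#' @param records data.frame(chrom, pos, depth).
#' @export
depth_table <- function(records, sample_id = "sample") {
  if (any(records$depth < 0))
    stop_input("negative depth at %s:%d",
               records$chrom[records$depth < 0][1],
               records$pos[records$depth < 0][1])
  if (anyDuplicated(position_key(records$chrom, records$pos)))
    stop_input("duplicate position in depth table")
  structure(records, sample_id = sample_id,
            class = c("depth_table", "data.frame"))
}

#' Write a depth table as 3-column TSV
#' @param depth a `depth_table`.
#' @param path output path.
#' @export
write_depth <- function(depth, path) {
  utils::write.table(as.data.frame(depth)[, c("chrom", "pos", "depth")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load the knowledge table of known pathogenic variants
#'
#' A 6-column TSV (`chrom`, `pos`, `ref`, `alt`, `gene`, `citation_id`)
#' playing the role of a locus-specific mutation database: triage rule (1)
#' promotes any exact (chrom, pos, ref, alt) match to the pathogenic tier.
#'
#' @param path TSV path with header.
#' @return data.frame of class `known_table`.
#' @export
load_known_table <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  k <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "integer", "character",
                                        "character", "character", "character"))
  need <- c("chrom", "pos", "ref", "alt", "gene", "citation_id")
  if (!identical(names(k), need))
    stop_input("knowledge table must have columns: %s",
               paste(need, collapse = ", "))
  if (any(is.na(k$pos)) || any(!nzchar(k$ref)) || any(!nzchar(k$alt)))
    stop_input("malformed knowledge table row")
  structure(k, class = c("known_table", "data.frame"))
}

#' @rdname load_known_table
#' @param known data.frame with the knowledge-table columns.
#' @export
write_known_table <- function(known, path) {
  utils::write.table(as.data.frame(known), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
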