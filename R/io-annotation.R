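# GFF3 "type" column -> internal feature type. Documented dialect: anything
# not listed maps to "other".
GFF_TYPE_MAP <- c(
  CDS = "CDS", gene = "CDS", mRNA = "CDS", protein_coding_gene = "CDS",
  rRNA = "rRNA", rRNA_gene = "rRNA",
  tRNA = "tRNA", tRNA_gene = "tRNA",
  intron = "intron",
  sRNA = "sRNA", ncRNA = "sRNA", snoRNA = "sRNA", snRNA = "sRNA"
)

#' Genome annotation container
#'
#' Bundles chromosome sequences with typed, stranded features. Features are
#' stored in a data frame with 0-based half-open coordinates.
#'
#' @param sequences named character vector of chromosome sequences (RNA
#'   alphabet; use [read_fasta()]).
#' @param features data frame with columns `id`, `chrom`,
#'   `strand` (`+`/`-`), `start`, `end` (0-based half-open) and `ftype`
#'   (one of `CDS`, `rRNA`, `tRNA`, `intron`, `sRNA`, `other`).
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(sequences, features) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "strand", "start", "end", "ftype")
  stopifnot(all(need %in% names(features)))
  bad <- !features$chrom %in% names(sequences)
  if (any(bad))
    stop("feature(s) on unknown chromosome: ",
         paste(features$id[bad], collapse = ", "))
  len <- nchar(sequences)[features$chrom]
  off <- features$start < 0 | features$start >= features$end |
    features$end > len
  if (any(off))
    stop("feature(s) with coordinates outside chromosome: ",
         paste(features$id[off], collapse = ", "))
  if (!all(features$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'")
  structure(list(sequences = sequences, features = features[, need]),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$sequences), "chromosome(s),",
      sum(nchar(x$sequences)), "nt,", nrow(x$features), "feature(s)\n")
  print(table(x$features$ftype))
  invisible(x)
}

# features of given types overlapping [start,end) on chrom (any strand)
features_overlapping <- function(annotation, chrom, start, end,
                                 ftypes = NULL) {
  f <- annotation$features
  keep <- f$chrom == chrom & f$start < end & f$end > start
  if (!is.null(ftypes)) keep <- keep & f$ftype %in% ftypes
  f[keep, , drop = FALSE]
}

#' Read and write GFF3 annotation
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention on read, and back on write. The GFF3
#' `type` column is mapped to internal feature types via a fixed table
#' (`CDS`/`gene`/`mRNA` -> `CDS`, `rRNA` -> `rRNA`, `tRNA` -> `tRNA`,
#' `intron` -> `intron`, `sRNA`/`ncRNA`/`snoRNA`/`snRNA` -> `sRNA`,
#' anything else -> `other`).
#'
#' @param path GFF3 file path.
#' @param sequences named character vector of chromosome sequences.
#' @return a [genome_annotation()] object.
#' @export
read_gff3 <- function(path, sequences) {
  gr <- rtracklayer::import(path, format = "gff3")
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids)) ids <- paste0("feat", seq_along(gr))
  ids[is.na(ids)] <- paste0("feat", which(is.na(ids)))
  ty <- as.character(gr$type)
  ftype <- unname(GFF_TYPE_MAP[ty])
  ftype[is.na(ftype)] <- "other"
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("unstranded feature(s) in GFF3: ",
         paste(ids[strand == "*"], collapse = ", "))
  feats <- data.frame(
    id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = GenomicRanges::start(gr) - 1L, # 1-based inclusive -> 0-based
    end = GenomicRanges::end(gr),
    ftype = ftype,
    stringsAsFactors = FALSE
  )
  genome_annotation(sequences, feats)
}

#' @param annotation a [genome_annotation()] object.
#' @param source value for the GFF3 source column.
#' @rdname read_gff3
#' @export
write_gff3 <- function(annotation, path, source = "nmsrna") {
  f <- annotation$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$chrom,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand
  )
  gr$source <- source
  gr$type <- ifelse(f$ftype == "other", "region", f$ftype)
  gr$phase <- ifelse(f$ftype == "CDS", 0L, NA_integer_)
  gr$ID <- f$id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read and write sRNA read intervals (BED6)
#'
#' BED6 with the score column reused as read multiplicity (a documented
#' dialect: score 0 or missing means count 1, supporting collapsed reads).
#' Intervals are 0-based half-open as in BED. Reads without a `+`/`-`
#' strand are rejected, since locus calling is strand-aware.
#'
#' @param path BED6 file path.
#' @return data frame with columns `chrom`, `strand`, `start`, `end`,
#'   `count`.
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("read interval(s) without +/- strand in ", path)
  count <- gr$score
  if (is.null(count)) count <- rep(1, length(gr))
  count[is.na(count) | count == 0] <- 1
  if (any(count < 0)) stop("negative read multiplicity in ", path)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    count = as.integer(round(count)),
    stringsAsFactors = FALSE
  )
}

#' @param reads data frame of read intervals as returned by
#'   [read_reads_bed()].
#' @rdname read_reads_bed
#' @export
write_reads_bed <- function(reads, path) {
  df <- data.frame(
    chrom = reads$chrom, start = reads$start, end = reads$end,
    name = sprintf("r%d", seq_len(nrow(reads))),
    score = reads$count, strand = reads$strand
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write a library manifest
#'
#' Tab-separated table with one row per sRNA-seq library and columns
#' `library_id`, `condition` (`light`/`dark`), `replicate`, `te_treated`
#' (logical; Terminator-exonuclease treatment) and `reads_path`.
#'
#' @param path TSV file path.
#' @return data frame with the manifest columns.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("library_id", "condition", "replicate", "te_treated", "reads_path")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$library_id)) stop("duplicate library ids in manifest")
  if (nrow(m) < 1) stop("manifest must list at least one library")
  if (!all(m$condition %in% c("light", "dark")))
    stop("manifest condition must be 'light' or 'dark'")
  m$te_treated <- as.logical(m$te_treated)
  m
}

#' @param manifest manifest data frame.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
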