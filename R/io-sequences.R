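#' @rdname read_fasta
#' @name alphabet
NULL

IUPAC_RNA <- c(
  A = "A", C = "C", G = "G", U = "U",
  R = "AG", Y = "CU", S = "CG", W = "AU", K = "GU", M = "AC",
  B = "CGU", D = "AGU", H = "ACU", V = "ACG", N = "ACGU"
)

# nucleotide -> bitmask (A=1, C=2, G=4, U=8); subject N deliberately maps
# to 0 so an unknown subject base never satisfies a pattern class
BASE_BIT <- c(A = 1L, C = 2L, G = 4L, U = 8L)

pattern_masks <- function(pattern) {
  ltr <- strsplit(pattern, "")[[1]]
  bad <- setdiff(ltr, names(IUPAC_RNA))
  if (length(bad))
    stop("invalid IUPAC letter(s) in pattern: ", paste(unique(bad), collapse = ", "))
  vapply(IUPAC_RNA[ltr], function(x) sum(BASE_BIT[strsplit(x, "")[[1]]]),
         integer(1), USE.NAMES = FALSE)
}

subject_masks <- function(subject) {
  ltr <- strsplit(subject, "")[[1]]
  m <- BASE_BIT[ltr]
  m[is.na(m)] <- 0L # N (and only N survives normalization) matches nothing
  unname(m)
}

normalize_rna <- function(x, id = "<sequence>") {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  ltr <- unique(strsplit(paste(x, collapse = ""), "")[[1]])
  amb <- setdiff(intersect(ltr, names(IUPAC_RNA)), c("A", "C", "G", "U", "N"))
  if (length(amb)) {
    warning("ambiguity codes ", paste(amb, collapse = ","),
            " replaced by N in ", id)
    x <- chartr(paste(amb, collapse = ""),
                strrep("N", length(amb)), x)
  }
  bad <- setdiff(unique(strsplit(paste(x, collapse = ""), "")[[1]]),
                 c("A", "C", "G", "U", "N"))
  if (length(bad))
    stop("illegal character(s) ", paste(bad, collapse = ","), " in ", id)
  x
}

#' Read and write RNA/DNA FASTA files
#'
#' Sequences are normalized to the package's internal RNA alphabet:
#' uppercase, `T` converted to `U`, IUPAC ambiguity codes other than `N`
#' replaced by `N` with a warning. Characters outside the IUPAC alphabet
#' raise a format error naming the offending line.
#'
#' @param path file path.
#' @return `read_fasta`: a named character vector of RNA sequences; names
#'   are the first whitespace-delimited token of each header, with the full
#'   header kept in the `"description"` attribute.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' write_fasta(c(x = "ACGU"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0) stop("no records in FASTA file ", path)
  seqs <- as.character(set)
  desc <- names(seqs)
  ids <- vapply(strsplit(desc, "\\s+"), `[`, character(1), 1)
  if (any(!nzchar(ids)) || anyNA(ids))
    stop("malformed/empty FASTA header in ", path)
  if (any(!nzchar(seqs)))
    stop("empty FASTA record '", ids[which(!nzchar(seqs))[1]], "' in ", path)
  out <- character(length(seqs))
  for (i in seq_along(seqs)) {
    out[i] <- tryCatch(normalize_rna(seqs[i], id = ids[i]),
      error = function(e) {
        # locate offending line for the format error
        lines <- readLines(path, warn = FALSE)
        hdr <- grep("^>", lines)
        rec_start <- hdr[i]
        body <- lines[seq(rec_start + 1,
                          if (i < length(hdr)) hdr[i + 1] - 1 else length(lines))]
        badln <- rec_start + which(grepl("[^ACGTUacgtuNnRYSWKMBDHVryswkmbdhv-]",
                                         body))[1]
        stop("FASTA format error at line ",
             ifelse(is.na(badln), rec_start, badln), " of ", path, ": ",
             conditionMessage(e), call. = FALSE)
      })
  }
  names(out) <- ids
  attr(out, "description") <- desc
  out
}

#' @param sequences named character vector of sequences.
#' @param width line width for wrapping.
#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  stopifnot(!is.null(names(sequences)))
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of RNA sequences
#'
#' Vectorized over `x`; handles IUPAC degeneracy (R<->Y, K<->M, B<->V,
#' D<->H, S/W/N self-complementary). The empty string maps to itself.
#'
#' @param x character vector of RNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("ACUUAC") # "GUAAGU", the canonical 5' splice site
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGUNRYSWKMBDHV", "UGCANYRSWMKVHDB", x)
  vapply(comp, function(s) {
    if (!nzchar(s)) return(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# plain (WC-only) complement of a single sequence, unreversed
wc_complement <- function(x) chartr("ACGU", "UGCA", x)

# substring in 0-based half-open coordinates
substr0 <- function(x, start, end) substr(x, start + 1, end)

# extract stranded sequence from a chromosome (0-based half-open)
extract_sequence <- function(chrom_seq, strand, start, end) {
  s <- substr0(chrom_seq, start, end)
  if (strand == "-") reverse_complement(s) else s
}
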