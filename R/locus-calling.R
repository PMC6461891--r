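#' Build per-library, per-strand coverage profiles
#'
#' Depth at each base is the multiplicity-weighted number of reads
#' covering it, computed per chromosome, strand and library.
#'
#' @param reads named list (one element per library) of read-interval
#'   data frames as returned by [read_reads_bed()].
#' @param annotation a [genome_annotation()].
#' @return object of class `coverage_profile`: nested list
#'   `profiles[[chrom]][[strand]]` holding length-of-chromosome x
#'   n-library depth matrices, plus `libraries`.
#' @export
build_coverage <- function(reads, annotation) {
  stopifnot(is.list(reads), length(reads) >= 1)
  libs <- names(reads)
  chroms <- names(annotation$sequences)
  lens <- nchar(annotation$sequences)
  profiles <- lapply(seq_along(chroms), function(ci) {
    L <- lens[ci]
    list("+" = matrix(0, nrow = L, ncol = length(libs),
                      dimnames = list(NULL, libs)),
         "-" = matrix(0, nrow = L, ncol = length(libs),
                      dimnames = list(NULL, libs)))
  })
  names(profiles) <- chroms
  for (li in seq_along(libs)) {
    rd <- reads[[li]]
    if (!nrow(rd)) next
    bad <- !rd$chrom %in% chroms
    if (any(bad)) stop("read(s) on unknown chromosome: ",
                       paste(unique(rd$chrom[bad]), collapse = ", "))
    oob <- rd$start < 0 | rd$end > lens[rd$chrom] | rd$end <= rd$start
    if (any(oob)) {
      i <- which(oob)[1]
      stop(sprintf("read interval out of bounds: %s:%d-%d",
                   rd$chrom[i], rd$start[i], rd$end[i]))
    }
    for (ch in unique(rd$chrom)) {
      for (st in c("+", "-")) {
        sel <- rd$chrom == ch & rd$strand == st
        if (!any(sel)) next
        # difference-array accumulation of weighted interval coverage
        d <- numeric(lens[ch] + 1)
        s <- rd$start[sel]; e <- rd$end[sel]; w <- rd$count[sel]
        for (k in seq_along(s)) {
          d[s[k] + 1] <- d[s[k] + 1] + w[k]
          d[e[k] + 1] <- d[e[k] + 1] - w[k]
        }
        profiles[[ch]][[st]][, li] <- cumsum(d[seq_len(lens[ch])])
      }
    }
  }
  structure(list(profiles = profiles, libraries = libs),
            class = "coverage_profile")
}

#' Default locus-calling parameters
#'
#' The thresholds are a reproducible proxy for manual inspection of
#' mapped sRNA reads: candidate intervals are maximal runs of pooled
#' depth, trimmed at their ends, and must be supported by reads in every
#' library.
#'
#' @param depth_min minimum pooled depth defining a run.
#' @param gap_max sub-threshold gaps up to this length are merged.
#' @param end_frac ends are trimmed to the outermost positions with
#'   pooled depth at least `end_frac` times the peak depth.
#' @param support_min minimum multiplicity-weighted reads overlapping the
#'   locus in every library.
#' @param min_locus_len minimum locus length (nt).
#' @param r_high,r_low cap-status thresholds on the TE/untreated
#'   reads-per-million ratio.
#' @return list of parameters.
#' @export
locus_params <- function(depth_min = 3, gap_max = 5L, end_frac = 0.1,
                         support_min = 3, min_locus_len = 16L,
                         r_high = 0.5, r_low = 0.2) {
  list(depth_min = depth_min, gap_max = gap_max, end_frac = end_frac,
       support_min = support_min, min_locus_len = min_locus_len,
       r_high = r_high, r_low = r_low)
}

# multiplicity-weighted reads overlapping [start,end) per library
.locus_read_support <- function(reads, chrom, strand, start, end) {
  vapply(reads, function(rd) {
    sel <- rd$chrom == chrom & rd$strand == strand &
      rd$start < end & rd$end > start
    sum(rd$count[sel])
  }, numeric(1))
}

#' Call intergenic sRNA-expressing loci from coverage
#'
#' Candidate intervals are maximal runs where pooled (all-library) depth
#' meets `depth_min`, after merging gaps up to `gap_max`; ends are
#' trimmed to the outermost positions with depth at least
#' `end_frac * peak`. A candidate is retained only if every library
#' contributes at least `support_min` (multiplicity-weighted) overlapping
#' reads, it is not fully contained in a CDS/rRNA/tRNA feature, does not
#' overlap an rRNA or tRNA feature at all (degradation fragments of
#' stable RNAs dominate sRNA libraries), and is at least `min_locus_len`
#' long. Overlap annotation is added by [classify_overlaps()].
#'
#' @param coverage a [build_coverage()] result.
#' @param reads the read list the coverage was built from.
#' @param annotation a [genome_annotation()].
#' @param params see [locus_params()].
#' @return data frame of loci with 0-based half-open coordinates and
#'   per-library support columns.
#' @export
call_loci <- function(coverage, reads, annotation, params = locus_params()) {
  out <- list()
  for (ch in names(coverage$profiles)) {
    for (st in c("+", "-")) {
      depth <- coverage$profiles[[ch]][[st]]
      pooled <- rowSums(depth)
      above <- pooled >= params$depth_min
      if (!any(above)) next
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      runs <- data.frame(start = starts[r$values], end = ends[r$values])
      # merge runs separated by gaps <= gap_max
      if (nrow(runs) > 1) {
        keep <- list(runs[1, ])
        for (i in 2:nrow(runs)) {
          last <- keep[[length(keep)]]
          if (runs$start[i] - last$end - 1 <= params$gap_max)
            keep[[length(keep)]]$end <- runs$end[i]
          else keep[[length(keep) + 1]] <- runs[i, ]
        }
        runs <- do.call(rbind, keep)
      }
      for (i in seq_len(nrow(runs))) {
        s <- runs$start[i]; e <- runs$end[i] # 1-based inclusive
        peak <- max(pooled[s:e])
        thr <- params$end_frac * peak
        idx <- s:e
        good <- idx[pooled[idx] >= thr]
        s2 <- min(good); e2 <- max(good)
        start0 <- s2 - 1L; end0 <- e2 # 0-based half-open
        if (end0 - start0 < params$min_locus_len) next
        support <- .locus_read_support(reads, ch, st, start0, end0)
        if (any(support < params$support_min)) next
        ov <- features_overlapping(annotation, ch, start0, end0,
                                   ftypes = c("CDS", "rRNA", "tRNA"))
        if (any(ov$ftype %in% c("rRNA", "tRNA"))) next
        contained <- any(ov$start <= start0 & ov$end >= end0)
        if (contained) next
        maxd <- apply(depth[s2:e2, , drop = FALSE], 2, max)
        row <- data.frame(chrom = ch, strand = st, start = start0,
                          end = end0, length = end0 - start0,
                          peak_depth = peak,
                          stringsAsFactors = FALSE)
        for (lib in coverage$libraries) {
          row[[paste0("maxdepth_", lib)]] <- maxd[[lib]]
          row[[paste0("reads_", lib)]] <- support[[lib]]
        }
        out[[length(out) + 1]] <- row
      }
    }
  }
  if (!length(out)) {
    df <- data.frame(locus = character(), chrom = character(),
                     strand = character(), start = integer(),
                     end = integer(), length = integer(),
                     peak_depth = numeric(), stringsAsFactors = FALSE)
    return(df)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  df <- cbind(locus = sprintf("L%03d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  rownames(df) <- NULL
  classify_overlaps(df, annotation)
}

#' Annotate loci with strand-aware gene overlaps
#'
#' Computes, in transcript orientation, how far a neighbouring gene
#' reaches over each locus end: `overlap5` is the overlap at the locus'
#' own 5' terminus, `overlap3` at its 3' terminus. On the minus strand
#' the genomic left/right overlaps are swapped accordingly.
#' `contained_in_gene` flags full containment.
#'
#' @param loci locus data frame from [call_loci()].
#' @param annotation a [genome_annotation()].
#' @return `loci` with `overlap5`, `overlap3`, `contained_in_gene` added.
#' @export
classify_overlaps <- function(loci, annotation) {
  loci$overlap5 <- 0L
  loci$overlap3 <- 0L
  loci$contained_in_gene <- FALSE
  for (i in seq_len(nrow(loci))) {
    ov <- features_overlapping(annotation, loci$chrom[i], loci$start[i],
                               loci$end[i],
                               ftypes = c("CDS", "rRNA", "tRNA", "other"))
    if (!nrow(ov)) next
    left <- right <- 0L
    for (j in seq_len(nrow(ov))) {
      if (ov$start[j] <= loci$start[i] && ov$end[j] >= loci$end[i]) {
        loci$contained_in_gene[i] <- TRUE
        next
      }
      if (ov$start[j] < loci$start[i]) # gene reaches over the left end
        left <- max(left, min(ov$end[j], loci$end[i]) - loci$start[i])
      if (ov$end[j] > loci$end[i])     # gene reaches over the right end
        right <- max(right, loci$end[i] - max(ov$start[j], loci$start[i]))
    }
    if (loci$strand[i] == "+") {
      loci$overlap5[i] <- left; loci$overlap3[i] <- right
    } else {
      loci$overlap5[i] <- right; loci$overlap3[i] <- left
    }
  }
  loci
}

#' Infer 5'-cap status from Terminator-exonuclease libraries
#'
#' Terminator exonuclease degrades 5'-monophosphate RNAs, so transcripts
#' that survive the treatment are inferred to carry a 5' cap (or
#' gamma-monomethyl) structure. The ratio `r` of TE-treated to untreated
#' reads-per-million at the locus is thresholded: `r >= r_high` is
#' capped-like, `r <= r_low` monophosphate-like, else ambiguous.
#'
#' @param loci locus data frame.
#' @param reads named list of read data frames (one per library).
#' @param manifest library manifest (see [read_manifest()]).
#' @param params see [locus_params()].
#' @return `loci` with `te_ratio` and `cap_status` columns added.
#' @export
infer_cap_status <- function(loci, reads, manifest, params = locus_params()) {
  te_libs <- manifest$library_id[manifest$te_treated]
  un_libs <- manifest$library_id[!manifest$te_treated]
  loci$te_ratio <- NA_real_
  loci$cap_status <- "ambiguous"
  if (!length(te_libs)) {
    warning("no TE-treated library in manifest; cap status is ambiguous")
    return(loci)
  }
  libsize <- vapply(reads, function(rd) sum(rd$count), numeric(1))
  for (i in seq_len(nrow(loci))) {
    rpm <- function(libs) {
      v <- vapply(libs, function(lb) {
        if (libsize[[lb]] == 0) return(0) # empty library: no signal
        rd <- reads[[lb]]
        sel <- rd$chrom == loci$chrom[i] & rd$strand == loci$strand[i] &
          rd$start < loci$end[i] & rd$end > loci$start[i]
        sum(rd$count[sel]) / libsize[[lb]] * 1e6
      }, numeric(1))
      mean(v)
    }
    te <- rpm(te_libs); un <- rpm(un_libs)
    r <- if (un > 0) te / un else NA_real_
    loci$te_ratio[i] <- r
    loci$cap_status[i] <-
      if (is.na(r)) "ambiguous"
      else if (r >= params$r_high) "capped-like"
      else if (r <= params$r_low) "monophosphate-like"
      else "ambiguous"
  }
  loci
}
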