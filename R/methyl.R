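guide_pair_classes <- function(guide, target_window) {
  # antiparallel register: guide offset k (1 = base adjacent to the box,
  # i.e. the guide 3' end) pairs target window position k-1 (0-based)
  g <- rev(strsplit(guide, "")[[1]]) # g[k] = guide base at offset k
  t <- strsplit(target_window, "")[[1]]
  cls <- character(length(g))
  for (k in seq_along(g)) {
    pr <- paste0(g[k], t[k])
    cls[k] <- if (pr %in% c("AU", "UA", "GC", "CG")) "WC"
              else if (pr %in% c("GU", "UG")) "GU"
              else "MM"
  }
  cls
}

#' Find guide-target duplexes for a snoRNA guide
#'
#' Slides the guide along a target RNA and reports antiparallel,
#' contiguous (bulge-free) duplex windows that satisfy the acceptance
#' thresholds: at least `min_pairs` paired positions (Watson-Crick plus
#' G-U), at most `max_mm` mismatches and `max_gu` G-U wobbles, and a
#' strictly Watson-Crick pair at the +5 position (the guide base five
#' residues from the box).
#'
#' @param guide guide sequence (5'->3', the box-adjacent base last);
#'   must be at least 9 nt.
#' @param target target RNA sequence.
#' @param min_pairs minimum paired positions; default `length(guide) - 1`.
#' @param max_mm maximum mismatches (default 1).
#' @param max_gu maximum G-U pairs (default 2).
#' @return data frame with 0-based half-open `target_start`, `target_end`,
#'   `pair_string` (one symbol per offset, `W`/`G`/`M`), `wc_count`,
#'   `gu_count`, `mismatch_count`.
#' @export
find_guide_duplex <- function(guide, target, min_pairs = NULL,
                              max_mm = 1L, max_gu = 2L) {
  glen <- nchar(guide)
  if (glen < 9) stop("guide must be at least 9 nt, got ", glen)
  if (is.null(min_pairs)) min_pairs <- glen - 1L
  n <- nchar(target)
  out <- list()
  if (n >= glen) {
    for (w in 0:(n - glen)) {
      win <- substr0(target, w, w + glen)
      cls <- guide_pair_classes(guide, win)
      wc <- sum(cls == "WC"); gu <- sum(cls == "GU"); mm <- sum(cls == "MM")
      if (wc + gu >= min_pairs && mm <= max_mm && gu <= max_gu &&
          cls[5] == "WC") {
        out[[length(out) + 1]] <- data.frame(
          target_start = w, target_end = w + glen,
          pair_string = paste(substr(cls, 1, 1), collapse = ""),
          wc_count = wc, gu_count = gu, mismatch_count = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(target_start = integer(), target_end = integer(),
                      pair_string = character(), wc_count = integer(),
                      gu_count = integer(), mismatch_count = integer()))
  do.call(rbind, out)
}

#' Predict 2'-O-methylation sites for a C/D snoRNA candidate
#'
#' Applies the +5 rule to every accepted guide-target duplex: the
#' methylated nucleotide is the target base paired with the guide base at
#' offset 5 from the D or D' box, which with the antiparallel register is
#' `target_start + 4` (0-based). Sites from D and D' guides are reported
#' separately. Guides shorter than 9 nt are skipped.
#'
#' @param candidate a `cd_candidate` from [assemble_cd_candidates()].
#' @param targets named character vector of target RNA sequences.
#' @param params duplex thresholds passed to [find_guide_duplex()]
#'   (`min_pairs`, `max_mm`, `max_gu`).
#' @return data frame with columns `snorna`, `box` (`D`/`Dprime`),
#'   `target`, `position` (0-based), `residue`, `label` (1-based display
#'   label, e.g. `"LSU-A1363"`), duplex columns as in
#'   [find_guide_duplex()], and `guide`.
#' @export
predict_sites <- function(candidate, targets,
                          params = list(min_pairs = NULL, max_mm = 1L,
                                        max_gu = 2L)) {
  guides <- list(D = candidate$guide_D, Dprime = candidate$guide_Dprime)
  out <- list()
  for (box in names(guides)) {
    gw <- guides[[box]]
    if (is.null(gw) || nchar(gw$sequence) < 9) next
    for (tg in names(targets)) {
      dup <- find_guide_duplex(gw$sequence, targets[[tg]],
                               min_pairs = params$min_pairs,
                               max_mm = params$max_mm,
                               max_gu = params$max_gu)
      if (!nrow(dup)) next
      pos <- dup$target_start + 4L
      res <- substring(targets[[tg]], pos + 1, pos + 1)
      out[[length(out) + 1]] <- cbind(
        data.frame(snorna = candidate$locus_id, box = box, target = tg,
                   position = pos, residue = res,
                   label = sprintf("%s-%s%d", tg, res, pos + 1L),
                   stringsAsFactors = FALSE),
        dup, data.frame(guide = gw$sequence, stringsAsFactors = FALSE))
    }
  }
  if (!length(out))
    return(data.frame(snorna = character(), box = character(),
                      target = character(), position = integer(),
                      residue = character(), label = character(),
                      target_start = integer(), target_end = integer(),
                      pair_string = character(), wc_count = integer(),
                      gu_count = integer(), mismatch_count = integer(),
                      guide = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Coordinate maps between ungapped positions and alignment columns
#'
#' Builds, from a multiple alignment (aligned FASTA, `-` gaps), a
#' bijective map per sequence between ungapped positions and non-gap
#' alignment columns, used to transfer modification sites across species.
#'
#' @param aligned named character vector of aligned sequences (equal
#'   lengths) as returned by [read_fasta()] on an aligned FASTA file.
#' @return object of class `position_map`.
#' @export
position_map <- function(aligned) {
  w <- unique(nchar(aligned))
  if (length(w) != 1) stop("aligned sequences must have equal length")
  maps <- lapply(aligned, function(s) {
    ch <- strsplit(s, "")[[1]]
    cols <- which(ch != "-") # 1-based columns of ungapped positions
    pos_at_col <- rep(NA_integer_, w)
    pos_at_col[cols] <- seq_along(cols) - 1L # 0-based ungapped positions
    list(col_of = cols, pos_at_col = pos_at_col)
  })
  structure(list(maps = maps, width = w, names = names(aligned)),
            class = "position_map")
}

#' Map an ungapped position across an alignment
#'
#' @param pm a [position_map()].
#' @param from_seq,to_seq sequence names in the alignment.
#' @param pos 0-based ungapped position in `from_seq`.
#' @return 0-based ungapped position in `to_seq` at the same alignment
#'   column, or `NA` if `to_seq` is gapped there.
#' @export
map_position <- function(pm, from_seq, pos, to_seq) {
  if (!from_seq %in% names(pm$maps)) stop("unknown sequence: ", from_seq)
  if (!to_seq %in% names(pm$maps)) stop("unknown sequence: ", to_seq)
  cols <- pm$maps[[from_seq]]$col_of
  if (pos < 0 || pos >= length(cols))
    stop("position ", pos, " out of range for ", from_seq)
  col <- cols[pos + 1]
  pm$maps[[to_seq]]$pos_at_col[col]
}

# alignment column (1-based) of an ungapped position
position_column <- function(pm, seq, pos) {
  cols <- pm$maps[[seq]]$col_of
  if (pos < 0 || pos >= length(cols))
    stop("position ", pos, " out of range for ", seq)
  cols[pos + 1]
}

# 3'-anchored guide identity: guides end adjacent to the box, so they are
# compared from their 3' ends; identity = matches / longer length
guide_identity <- function(g1, g2) {
  n1 <- nchar(g1); n2 <- nchar(g2)
  k <- min(n1, n2)
  if (k == 0) return(0)
  a <- strsplit(substr(g1, n1 - k + 1, n1), "")[[1]]
  b <- strsplit(substr(g2, n2 - k + 1, n2), "")[[1]]
  sum(a == b) / max(n1, n2)
}

#' Call conserved methylation sites and snoRNA homologs
#'
#' A predicted site is "conserved" if its alignment column coincides with
#' a reference species' experimentally characterized site; the guiding
#' snoRNA is additionally flagged as a homolog of the reference snoRNA if
#' the two guides are at least `id_min` identical (3'-anchored
#' comparison), a sequence-identity stand-in for covariance-model
#' homology.
#'
#' @param sites data frame from [predict_sites()].
#' @param reference_table data frame with columns `species`, `rna`
#'   (the name of that species' sequence in the alignment is
#'   `"<species>:<rna>"`), `position` (1-based), `snorna`, and optionally
#'   `guide`.
#' @param pm a [position_map()] whose sequences include the nucleomorph
#'   targets (named as in `sites$target`) and the reference sequences.
#' @param id_min guide identity threshold for the homolog flag.
#' @return `sites` with added columns `conserved`, `ref_species`,
#'   `ref_label`, `ref_snorna`, `guide_identity`, `homolog`.
#' @export
call_conserved_and_homologs <- function(sites, reference_table, pm,
                                        id_min = 0.70) {
  sites$conserved <- FALSE
  sites$ref_species <- NA_character_
  sites$ref_label <- NA_character_
  sites$ref_snorna <- NA_character_
  sites$guide_identity <- NA_real_
  sites$homolog <- FALSE
  if (!nrow(sites)) return(sites)
  ref_cols <- rep(NA_integer_, nrow(reference_table))
  for (r in seq_len(nrow(reference_table))) {
    seqid <- paste0(reference_table$species[r], ":", reference_table$rna[r])
    if (!seqid %in% names(pm$maps)) {
      warning("reference sequence ", seqid, " not in alignment; row skipped")
      next
    }
    ref_cols[r] <- tryCatch(
      position_column(pm, seqid, reference_table$position[r] - 1L),
      error = function(e) {
        warning("reference position outside aligned sequence ", seqid,
                "; row skipped")
        NA_integer_
      })
  }
  for (i in seq_len(nrow(sites))) {
    if (!sites$target[i] %in% names(pm$maps)) next
    col <- position_column(pm, sites$target[i], sites$position[i])
    hit <- which(ref_cols == col)
    if (!length(hit)) next
    hit <- hit[1]
    sites$conserved[i] <- TRUE
    sites$ref_species[i] <- reference_table$species[hit]
    sites$ref_label[i] <- sprintf("%s-%d", reference_table$rna[hit],
                                  reference_table$position[hit])
    sites$ref_snorna[i] <- reference_table$snorna[hit]
    if (!is.null(reference_table$guide) &&
        !is.na(reference_table$guide[hit])) {
      idf <- guide_identity(sites$guide[i], reference_table$guide[hit])
      sites$guide_identity[i] <- idf
      sites$homolog[i] <- idf >= id_min
    }
  }
  sites
}
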