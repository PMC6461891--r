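#' Find intermolecular helices between two RNAs
#'
#' Enumerates all maximal antiparallel contiguous pairing runs
#' (Watson-Crick plus G-U wobble, no internal mismatches) of at least
#' `min_len` base pairs between two sequences.
#'
#' @param rnaA,rnaB RNA sequences.
#' @param min_len minimum helix length in base pairs (default 6).
#' @return data frame with 0-based half-open intervals `a_start`, `a_end`,
#'   `b_start`, `b_end`, plus `length`, `wc_count`, `gu_count`. The run
#'   pairs `rnaA[a_start + k]` with `rnaB[b_end - 1 - k]`.
#' @export
find_intermolecular_helices <- function(rnaA, rnaB, min_len = 6L) {
  empty <- data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      length = integer(), wc_count = integer(),
                      gu_count = integer())
  na <- nchar(rnaA); nb <- nchar(rnaB)
  if (na < min_len || nb < min_len) return(empty)
  a <- strsplit(rnaA, "")[[1]]
  br <- rev(strsplit(rnaB, "")[[1]]) # br[k] = rnaB[nb + 1 - k]
  out <- list()
  # diagonals of the a x reversed-b pairing matrix
  for (d in (-(nb - 1)):(na - 1)) {
    i0 <- max(1, 1 + d); k0 <- i0 - d
    len <- min(na - i0, nb - k0) + 1
    if (len < min_len) next
    ii <- i0:(i0 + len - 1); kk <- k0:(k0 + len - 1)
    ok <- can_pair(a[ii], br[kk])
    r <- rle(ok)
    pos <- cumsum(c(1, r$lengths))
    for (j in seq_along(r$values)) {
      if (!r$values[j] || r$lengths[j] < min_len) next
      s <- pos[j]; L <- r$lengths[j]
      ai <- ii[s]; ki <- kk[s]
      seg_a <- a[ai:(ai + L - 1)]
      seg_b <- br[ki:(ki + L - 1)]
      wc <- sum(paste0(seg_a, seg_b) %in% c("AU", "UA", "GC", "CG"))
      out[[length(out) + 1]] <- data.frame(
        a_start = ai - 1L, a_end = ai + L - 1L,
        b_start = nb - (ki + L - 1), b_end = nb - ki + 1L,
        length = L, wc_count = wc, gu_count = L - wc)
    }
  }
  if (!length(out)) return(empty)
  df <- do.call(rbind, out)
  # drop runs contained, on both molecules, inside a longer run on a
  # neighbouring register (sub-helices of a longer duplex are not
  # distinct helices)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    dom <- df$length > df$length[i] &
      df$a_start <= df$a_start[i] & df$a_end >= df$a_end[i] &
      df$b_start <= df$b_start[i] & df$b_end >= df$b_end[i]
    if (any(dom)) keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$a_start, df$b_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Default parameters for snRNA candidate evaluation
#'
#' @param first5_window length of the 5'-terminal window searched for the
#'   U1 splice-site recognition motif.
#' @param u1_mm mismatches allowed against the 5'SS-binding consensus.
#' @param u2_bp_pattern U2 branch-point interaction motif.
#' @param u5_mm mismatches allowed against the U5 loop I motif.
#' @param u5_stem_min minimum stem flanking U5 loop I.
#' @param helix_min minimum intermolecular helix length with U6 (U2).
#' @param u4_helix_min minimum helix length with U6 for the U4 rule; the
#'   two U4/U6 helices are extensive (11 and 16 bp in the cryptophyte
#'   pair), and short WC+GU runs against a ~100-nt U6 arise by chance, so
#'   U4 demands longer helices than U2.
#' @param min_stem,min_loop hairpin requirements for the U4 inter-helix
#'   spacer.
#' @param sm_regex Sm/Lsm site consensus (regular expression), searched in
#'   the 3' third; informative only, never a veto.
#' @param u6_u_tract minimum number of U residues in the last 10 nt of U6.
#' @return list of parameters.
#' @export
snrna_params <- function(first5_window = 12L, u1_mm = 0L,
                         u2_bp_pattern = "GUAG", u5_mm = 6L,
                         u5_stem_min = 4L, helix_min = 6L,
                         u4_helix_min = 10L,
                         min_stem = 5L, min_loop = 3L,
                         sm_regex = "[AG]AU{4,6}G", u6_u_tract = 4L) {
  list(first5_window = first5_window, u1_mm = u1_mm,
       u2_bp_pattern = u2_bp_pattern, u5_mm = u5_mm,
       u5_stem_min = u5_stem_min, helix_min = helix_min,
       u4_helix_min = u4_helix_min,
       min_stem = min_stem, min_loop = min_loop,
       sm_regex = sm_regex, u6_u_tract = u6_u_tract)
}

U1_5SS_BINDING <- "ACUUAC" # reverse complement of the GUAAGU donor site
U5_LOOP1 <- "UGCCUUUUACY"
U6_5SS_BINDING <- "ACAGAGA"

# two longest non-overlapping helices on the candidate (rnaA side)
pick_two_helices <- function(hx) {
  hx <- hx[order(-hx$length, hx$a_start), , drop = FALSE]
  for (i in seq_len(nrow(hx) - 1)) {
    for (j in (i + 1):nrow(hx)) {
      if (hx$a_end[i] <= hx$a_start[j] || hx$a_end[j] <= hx$a_start[i]) {
        pair <- hx[c(i, j), , drop = FALSE]
        return(pair[order(pair$a_start), , drop = FALSE])
      }
    }
  }
  NULL
}

#' Evaluate a sequence as a spliceosomal snRNA candidate
#'
#' Applies per-kind mandatory rules: U1 -- a window within the 5'-terminal
#' `first5_window` nt whose reverse complement matches the intron donor
#' consensus `GUAAGU`; U2 -- the branch-point interaction motif (`GUAG`)
#' in the 5' half plus at least two intermolecular helices with U6;
#' U4 -- two helices with U6 with a hairpin folding in the inter-helix
#' spacer (a K-turn-style note on the stem flanks is reported,
#' descriptive only); U5 -- the loop I motif `UGCCUUUUACY` within `u5_mm`
#' mismatches, flanked by a stem of at least `u5_stem_min` pairs;
#' U6 -- the 5' splice-site binding sequence `ACAGAGA` plus an Lsm-style
#' 3' U-tract. An Sm/Lsm-site search in the 3' third is reported for all
#' kinds but never vetoes a candidate.
#'
#' @param sequence candidate RNA sequence.
#' @param kind one of `"U1"`, `"U2"`, `"U4"`, `"U5"`, `"U6"`.
#' @param u6_sequence U6 reference sequence; required for U2 and U4.
#' @param params see [snrna_params()].
#' @return object of class `snrna_report`: list with `kind`, `pass`,
#'   `reasons` (failure reasons), `motifs`, `helices`, `hairpin`,
#'   `sm_site`.
#' @export
evaluate_snrna_candidate <- function(sequence, kind, u6_sequence = NULL,
                                     params = snrna_params()) {
  if (!kind %in% c("U1", "U2", "U4", "U5", "U6"))
    stop("unknown snRNA kind: ", kind)
  n <- nchar(sequence)
  reasons <- character()
  motifs <- list()
  helices <- NULL
  hairpin <- NULL

  third <- substr0(sequence, floor(2 * n / 3), n)
  sm_m <- regmatches(third, regexpr(params$sm_regex, third))
  sm_site <- if (length(sm_m)) sm_m else NA_character_

  need_u6 <- kind %in% c("U2", "U4")
  if (need_u6 && is.null(u6_sequence))
    stop("u6_sequence is required for kind ", kind)
  if (need_u6)
    helices <- find_intermolecular_helices(sequence, u6_sequence,
                                           min_len = params$helix_min)

  if (kind == "U1") {
    hit <- NULL
    for (s in 0:max(0, params$first5_window - nchar(U1_5SS_BINDING))) {
      win <- substr0(sequence, s, s + nchar(U1_5SS_BINDING))
      if (nchar(win) < nchar(U1_5SS_BINDING)) break
      if (iupac_mismatches(win, U1_5SS_BINDING) <= params$u1_mm) {
        hit <- list(start = s, sequence = win,
                    pairs_donor = reverse_complement(win))
        break
      }
    }
    motifs$ss5_binding <- hit
    if (is.null(hit))
      reasons <- c(reasons, "no 5' splice-site binding motif in 5' window")
  } else if (kind == "U2") {
    half <- substr0(sequence, 0, ceiling(n / 2))
    bp <- search_pattern(half, params$u2_bp_pattern)
    motifs$bp_interaction <- if (nrow(bp)) bp[1, ] else NULL
    if (!nrow(bp))
      reasons <- c(reasons, "no branch-point interaction motif in 5' half")
    if (nrow(helices) < 2)
      reasons <- c(reasons, "fewer than two helices with U6")
  } else if (kind == "U4") {
    helices <- helices[helices$length >= params$u4_helix_min, ,
                       drop = FALSE]
    two <- if (nrow(helices) >= 2) pick_two_helices(helices) else NULL
    if (is.null(two)) {
      reasons <- c(reasons, "fewer than two helices with U6")
    } else {
      sp <- c(two$a_end[1], two$a_start[2])
      hairpin <- find_hairpin(substr0(sequence, sp[1], sp[2]),
                              min_stem = params$min_stem,
                              min_loop = params$min_loop)
      if (is.null(hairpin)) {
        reasons <- c(reasons, "no hairpin between the two U6 helices")
      } else {
        # descriptive K-turn note: G/A bases flanking the stem base
        flank <- c(substr0(sequence, sp[1] + hairpin$arm5[1] - 1,
                           sp[1] + hairpin$arm5[1]),
                   substr0(sequence, sp[1] + hairpin$arm3[2],
                           sp[1] + hairpin$arm3[2] + 1))
        motifs$kturn_note <- sprintf(
          "stem-base flanking bases %s/%s (%s sheared G-A-capable)",
          flank[1], flank[2],
          if (all(flank %in% c("G", "A"))) "both" else "not all")
        motifs$u4_helices <- two
      }
    }
  } else if (kind == "U5") {
    hit <- NULL
    L <- nchar(U5_LOOP1)
    if (n >= L + 2 * params$u5_stem_min) {
      for (s in params$u5_stem_min:(n - L - params$u5_stem_min)) {
        win <- substr0(sequence, s, s + L)
        if (iupac_mismatches(win, U5_LOOP1) > params$u5_mm) next
        k <- params$u5_stem_min
        f5 <- strsplit(substr0(sequence, s - k, s), "")[[1]]
        f3 <- strsplit(substr0(sequence, s + L, s + L + k), "")[[1]]
        if (all(can_pair(f5, rev(f3)))) {
          hit <- list(start = s, sequence = win, stem = k)
          break
        }
      }
    }
    motifs$loop1 <- hit
    if (is.null(hit))
      reasons <- c(reasons,
                   "no loop I motif with flanking stem")
  } else if (kind == "U6") {
    has_acagaga <- grepl(U6_5SS_BINDING, sequence, fixed = TRUE)
    motifs$ss5_binding <- if (has_acagaga) U6_5SS_BINDING else NULL
    if (!has_acagaga)
      reasons <- c(reasons, "no ACAGAGA 5' splice-site binding sequence")
    tail10 <- substr0(sequence, max(0, n - 10), n)
    n_u <- sum(strsplit(tail10, "")[[1]] == "U")
    motifs$u_tract <- n_u
    if (n_u < params$u6_u_tract)
      reasons <- c(reasons, "no Lsm-style 3' U-tract")
  }

  structure(list(kind = kind, pass = length(reasons) == 0,
                 reasons = reasons, motifs = motifs,
                 helices = helices, hairpin = hairpin,
                 sm_site = sm_site),
            class = "snrna_report")
}

#' @export
print.snrna_report <- function(x, ...) {
  cat("snRNA", x$kind, "evaluation:", if (x$pass) "PASS" else "fail", "\n")
  if (length(x$reasons)) cat(" reasons:", paste(x$reasons, collapse = "; "),
                             "\n")
  if (!is.null(x$helices) && nrow(x$helices))
    cat(" helices with U6:", nrow(x$helices), "(longest",
        max(x$helices$length), "bp)\n")
  cat(" Sm/Lsm site:", x$sm_site, "\n")
  invisible(x)
}

#' Predict the branch-point adenosine of an intron
#'
#' Searches for branch-point motif occurrences (default `DURAU`, with the
#' classical `YURAC` as fallback) whose 3' end lies 2-6 nt upstream of
#' the intron 3' splice site. A branch adenosine is called when removing
#' (bulging) that A leaves the remaining bases of a window covering the
#' motif contiguously Watson-Crick paired to a substring of the U2
#' branch-point interaction region. The 3'-most valid call is returned.
#'
#' @param intron_sequence intron sequence ending with the 3' splice site
#'   `AG`.
#' @param u2_bp_region U2 branch-point interaction sequence.
#' @param motif_pattern IUPAC branch-point motif (default `DURAU`).
#' @param fallback_pattern motif tried when `motif_pattern` yields no
#'   valid call (default `YURAC`); `NULL` to disable.
#' @param dist_range allowed distance (nt) from motif 3' end to intron
#'   3' end.
#' @return `NULL` if no call, else list with `motif` (0-based half-open
#'   interval), `motif_seq`, `branch_pos` (0-based position of the
#'   bulged A), `paired_window`, `u2_region` (0-based half-open interval
#'   of the paired U2 substring), `pattern`.
#' @export
predict_branch_point <- function(intron_sequence, u2_bp_region,
                                 motif_pattern = "DURAU",
                                 fallback_pattern = "YURAC",
                                 dist_range = c(2L, 6L)) {
  n <- nchar(intron_sequence)
  if (n < nchar(motif_pattern) + dist_range[1]) return(NULL)
  if (substr0(intron_sequence, n - 2, n) != "AG") {
    warning("intron does not end with AG; no branch point called")
    return(NULL)
  }
  for (pat in c(motif_pattern, fallback_pattern)) {
    if (is.null(pat)) next
    call <- .bp_scan(intron_sequence, u2_bp_region, pat, dist_range)
    if (!is.null(call)) return(call)
  }
  NULL
}

.bp_scan <- function(intron, u2, pat, dist_range) {
  n <- nchar(intron)
  m <- nchar(pat)
  occ <- search_pattern(intron, pat)
  if (!nrow(occ)) return(NULL)
  dist <- n - occ$end
  occ <- occ[dist >= dist_range[1] & dist <= dist_range[2], , drop = FALSE]
  if (!nrow(occ)) return(NULL)
  occ <- occ[order(-occ$start), , drop = FALSE] # 3'-most first
  nu <- nchar(u2)
  ch <- strsplit(intron, "")[[1]]
  for (o in seq_len(nrow(occ))) {
    s <- occ$start[o]; e <- occ$end[o]
    a_pos <- s + which(ch[(s + 1):e] == "A") - 1L
    for (p in rev(a_pos)) { # 3'-most branch A first
      for (Lp in nu:4) { # prefer the longest paired U2 substring
        for (u0 in 0:(nu - Lp)) {
          target <- reverse_complement(substr0(u2, u0, u0 + Lp))
          if (grepl("[^ACGU]", target)) next
          # window of Lp + 1 intron bases containing the bulged A,
          # covering the motif
          lo <- max(0L, e - Lp - 1L, p - Lp)
          hi <- min(s, p, n - Lp - 1L)
          if (lo > hi) next
          for (a in lo:hi) {
            b <- a + Lp + 1L
            if (p < a || p >= b || b > n) next
            if (b < e || a > s) next
            kept <- paste(ch[setdiff((a + 1):b, p + 1)], collapse = "")
            if (kept == target)
              return(list(motif = c(s, e),
                          motif_seq = substr0(intron, s, e),
                          branch_pos = p,
                          paired_window = c(a, b),
                          u2_region = c(u0, u0 + Lp),
                          pattern = pat))
          }
        }
      }
    }
  }
  NULL
}

#' Census of branch-point motifs over a set of introns
#'
#' Counts introns containing at least one occurrence of the branch-point
#' motif whose 3' end lies within `dist_range` nt of the intron 3' end.
#'
#' @param introns character vector of intron sequences.
#' @param motif_pattern IUPAC motif (default `DURAU`).
#' @param dist_range allowed distance from motif 3' end to intron 3' end.
#' @return named list with `n_introns` and `n_with_motif`.
#' @export
census_branch_points <- function(introns, motif_pattern = "DURAU",
                                 dist_range = c(2L, 6L)) {
  hit <- vapply(introns, function(x) {
    occ <- search_pattern(x, motif_pattern)
    if (!nrow(occ)) return(FALSE)
    d <- nchar(x) - occ$end
    any(d >= dist_range[1] & d <= dist_range[2])
  }, logical(1), USE.NAMES = FALSE)
  list(n_introns = length(introns), n_with_motif = sum(hit))
}
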