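#' Degenerate pattern search with independent edit budgets
#'
#' PatScan-style search of an IUPAC pattern against an RNA subject, with
#' separate (not summed) budgets for mismatches, insertions (extra subject
#' bases) and deletions (skipped pattern bases). A degenerate pattern
#' letter never consumes budget when the subject base belongs to its class.
#' `N` in the subject always counts as a mismatch. Insertions are internal
#' to the alignment, so matches are not redundant shifts of one another.
#'
#' One match is reported per feasible start position: the alignment
#' minimizing total edits, ties broken by fewer indels, then leftmost end.
#' Overlapping matches at different starts are all reported.
#'
#' @param subject RNA sequence (A/C/G/U/N).
#' @param pattern IUPAC pattern string.
#' @param max_mm,max_ins,max_del non-negative edit budgets.
#' @return data frame with 0-based half-open columns `start`, `end`, plus
#'   `mismatches`, `insertions`, `deletions` and the `matched` substring.
#' @examples
#' search_pattern("CCAUGAUCC", "DURAU") # matches [2,7) "AUGAU"
#' @export
search_pattern <- function(subject, pattern, max_mm = 0L, max_ins = 0L,
                           max_del = 0L) {
  stopifnot(nchar(pattern) > 0, max_mm >= 0, max_ins >= 0, max_del >= 0)
  pm <- pattern_masks(pattern)
  sm <- subject_masks(subject)
  res <- .patscan_core(sm, pm, as.integer(max_mm), as.integer(max_ins),
                       as.integer(max_del))
  df <- as.data.frame(res)
  df$matched <- substr(rep(subject, nrow(df)), df$start + 1, df$end)
  df
}

# exact hamming-style IUPAC mismatch count between equal-length strings
# (pattern may be degenerate); NA if lengths differ
iupac_mismatches <- function(window, pattern) {
  if (nchar(window) != nchar(pattern)) return(NA_integer_)
  pm <- pattern_masks(pattern)
  sm <- subject_masks(window)
  sum(bitwAnd(pm, sm) == 0L)
}

# TRUE where base a can pair base b (Watson-Crick, optionally wobble G-U)
can_pair <- function(a, b, gu = TRUE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  if (gu) wc | (a == "G" & b == "U") | (a == "U" & b == "G") else wc
}

#' Find a hairpin in a sequence
#'
#' Combinatorial (not thermodynamic) hairpin check: a pair of
#' antiparallel complementary substrings (Watson-Crick plus G-U wobble),
#' each at least `min_stem` long, separated by at least `min_loop`
#' unpaired bases. The longest stem is returned.
#'
#' @param sequence RNA sequence to scan.
#' @param min_stem minimum stem length in base pairs.
#' @param min_loop minimum loop length in nucleotides.
#' @param gu allow G-U wobble pairs in the stem.
#' @return `NULL` if no hairpin, else a list with `stem_len`, `arm5`
#'   and `arm3` (0-based half-open intervals of the two stem arms).
#' @export
find_hairpin <- function(sequence, min_stem = 5L, min_loop = 3L, gu = TRUE) {
  n <- nchar(sequence)
  if (n < 2 * min_stem + min_loop) return(NULL)
  s <- strsplit(sequence, "")[[1]]
  for (L in seq(floor((n - min_loop) / 2), min_stem)) {
    for (a in 0:(n - 2 * L - min_loop)) {
      arm5 <- s[(a + 1):(a + L)]
      for (b in seq(a + L + min_loop, n - L)) {
        arm3 <- s[(b + 1):(b + L)]
        if (all(can_pair(arm5, rev(arm3), gu = gu)))
          return(list(stem_len = L,
                      arm5 = c(a, a + L), arm3 = c(b, b + L)))
      }
    }
  }
  NULL
}

#' Two-helix search with an interior hairpin (U4-style architecture)
#'
#' Scans a subject for loci able to form two intermolecular helices with a
#' partner RNA (typically U6): the subject must contain, within budget, the
#' reverse complements of the two given helix patterns, separated by a
#' spacer of bounded length that can fold into a hairpin. By default the
#' helix II region lies 5' of the helix I region on the subject, matching
#' U4 snRNA architecture; edit budgets apply per helix.
#'
#' @param subject RNA sequence to scan.
#' @param pattern1,pattern2 helix I and helix II sequences on the partner
#'   RNA (IUPAC allowed).
#' @param max_mm,max_ins,max_del per-helix edit budgets.
#' @param spacer_min,spacer_max allowed spacer length between the two
#'   helix regions on the subject.
#' @param min_stem,min_loop hairpin requirements for the spacer (see
#'   [find_hairpin()]).
#' @param helix2_first if `TRUE` (default) the helix II region must lie
#'   5' of the helix I region on the subject.
#' @return list of hits; each hit has `helix1`, `helix2` (match rows from
#'   [search_pattern()]), `spacer` (0-based half-open interval) and
#'   `stem_len`.
#' @export
find_two_helix_candidates <- function(subject, pattern1, pattern2,
                                      max_mm = 2L, max_ins = 2L, max_del = 2L,
                                      spacer_min = 20L, spacer_max = 120L,
                                      min_stem = 5L, min_loop = 3L,
                                      helix2_first = TRUE) {
  stopifnot(spacer_min <= spacer_max)
  m1 <- search_pattern(subject, reverse_complement(pattern1),
                       max_mm, max_ins, max_del)
  m2 <- search_pattern(subject, reverse_complement(pattern2),
                       max_mm, max_ins, max_del)
  first <- if (helix2_first) m2 else m1
  second <- if (helix2_first) m1 else m2
  hits <- list()
  if (nrow(first) == 0 || nrow(second) == 0) return(hits)
  for (i in seq_len(nrow(first))) {
    for (j in seq_len(nrow(second))) {
      sp_start <- first$end[i]
      sp_end <- second$start[j]
      sp_len <- sp_end - sp_start
      if (sp_len < spacer_min || sp_len > spacer_max) next
      hp <- find_hairpin(substr0(subject, sp_start, sp_end),
                         min_stem = min_stem, min_loop = min_loop)
      if (is.null(hp)) next
      hits[[length(hits) + 1]] <- list(
        helix1 = if (helix2_first) second[j, ] else first[i, ],
        helix2 = if (helix2_first) first[i, ] else second[j, ],
        spacer = c(sp_start, sp_end),
        stem_len = hp$stem_len
      )
    }
  }
  hits
}
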