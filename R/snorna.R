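#' Default C/D box motif sets
#'
#' Consensus and near-canonical variants of the C, D, C' and D' boxes of
#' C/D box snoRNAs, including the noncanonical compensatory pairs observed
#' in nucleomorph snoRNAs (`AUGAUU` with `AUGA`, and `GUGAAG`) and the
#' shortened C' motif.
#'
#' @return named list of character vectors, one per box kind.
#' @export
cd_motif_sets <- function() {
  list(
    C = c("RUGAUGA", "AUGAUGA", "AUGAUG", "AUGAUU", "GUGAAG"),
    D = c("CUGA", "AUGA"),
    Cprime = c("UUGA", "AUGA"),
    Dprime = c("UUGA", "AUGA")
  )
}

#' Locate C/D box motifs in a sequence
#'
#' Reports all exact occurrences of all members of the motif sets,
#' labelled by box kind and by which consensus entry matched.
#'
#' @param sequence RNA sequence.
#' @param motif_sets as returned by [cd_motif_sets()].
#' @return data frame with columns `kind`, `consensus_id`, `start`, `end`
#'   (0-based half-open), `sequence`.
#' @export
find_boxes <- function(sequence, motif_sets = cd_motif_sets()) {
  out <- list()
  for (kind in names(motif_sets)) {
    for (motif in motif_sets[[kind]]) {
      m <- search_pattern(sequence, motif)
      if (nrow(m))
        out[[length(out) + 1]] <- data.frame(
          kind = kind, consensus_id = motif,
          start = m$start, end = m$end, sequence = m$matched,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(kind = character(), consensus_id = character(),
                      start = integer(), end = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$start, df$kind, -nchar(df$sequence)), , drop = FALSE]
}

pair_class <- function(a, b) {
  if (paste0(a, b) %in% c("AU", "UA", "GC", "CG")) "WC"
  else if (a == "U" && b == "U") "UU"
  else "other"
}

#' Validate the C/D box kink-turn pairing register
#'
#' The C and D boxes of a C/D snoRNA pair with each other to form a
#' K-turn. In the register used here, C-box positions 3-6 pair D-box
#' positions 4-1 (1-based from each motif's 5' end): `(C3,D4)`, `(C4,D3)`,
#' `(C5,D2)`, `(C6,D1)`. A valid K-turn requires the two sheared G-A
#' pairs at the base of stem II -- `C3=G` opposite `D4=A` and `C4=A`
#' opposite `D3=G` -- a Watson-Crick pair between the 3' nucleotide of
#' box C and the 5' nucleotide of box D (`C6-D1`), and either the
#' conserved U-U pair or a compensatory Watson-Crick pair at `C5-D2`.
#' A 7th C-box nucleotide, when present, is treated as bulged/unpaired.
#'
#' @param c_box_seq C-box sequence (6 or 7 nt).
#' @param d_box_seq D-box sequence (4 nt).
#' @return an object of class `kturn_report`: list with `pairs` (data
#'   frame of register pairs), `sheared_GA_count`, `pair_C5D2`,
#'   `pair_C6D1`, `valid` and `notes`.
#' @examples
#' validate_kturn("AUGAUGA", "CUGA")$valid  # canonical boxes: TRUE
#' validate_kturn("AUGAUU", "AUGA")$valid   # compensatory U-A: TRUE
#' validate_kturn("AUGAUC", "CUGA")$valid   # C-C terminal pair: FALSE
#' @export
validate_kturn <- function(c_box_seq, d_box_seq) {
  nc <- nchar(c_box_seq)
  if (!nc %in% c(6L, 7L)) stop("C box must be 6 or 7 nt, got ", nc)
  if (nchar(d_box_seq) != 4L) stop("D box must be 4 nt, got ", nchar(d_box_seq))
  cb <- strsplit(c_box_seq, "")[[1]]
  db <- strsplit(d_box_seq, "")[[1]]
  notes <- character()
  if (nc == 7L) notes <- c(notes, "7th C-box nucleotide treated as bulged")
  if (cb[1] == "G")
    notes <- c(notes, "5' purine G at C-box position 1")
  pairs <- data.frame(
    c_pos = 3:6, d_pos = 4:1,
    c_base = cb[3:6], d_base = db[4:1],
    stringsAsFactors = FALSE)
  pairs$class <- mapply(pair_class, pairs$c_base, pairs$d_base)
  sheared <- sum(cb[3] == "G" && db[4] == "A", cb[4] == "A" && db[3] == "G")
  c5d2 <- pair_class(cb[5], db[2])
  c6d1 <- if (pair_class(cb[6], db[1]) == "WC") "WC" else "other"
  if (c5d2 == "WC" && paste0(cb[5], db[2]) %in% c("AU", "UA"))
    notes <- c(notes, "Watson-Crick A-U replaces U-U at base of stem II")
  valid <- sheared == 2L && c6d1 == "WC" && c5d2 %in% c("WC", "UU")
  structure(list(pairs = pairs, sheared_GA_count = sheared,
                 pair_C5D2 = c5d2, pair_C6D1 = c6d1,
                 valid = valid, notes = notes),
            class = "kturn_report")
}

#' @export
print.kturn_report <- function(x, ...) {
  cat("K-turn:", if (x$valid) "valid" else "invalid",
      sprintf("(sheared G-A: %d, C5-D2: %s, C6-D1: %s)\n",
              x$sheared_GA_count, x$pair_C5D2, x$pair_C6D1))
  if (length(x$notes)) cat(" notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Default parameters for C/D snoRNA candidate assembly
#'
#' @param terminal_margin the C box must start, and the D box end, within
#'   this many nt of the candidate 5'/3' ends.
#' @param len_range allowed candidate length (nt).
#' @param guide_max maximum guide window length extracted 5' of D/D'.
#' @param dpcp_spacing allowed spacing (nt) between the D' box end and the
#'   C' box start.
#' @return list of parameters.
#' @export
cd_params <- function(terminal_margin = 12L, len_range = c(50L, 250L),
                      guide_max = 20L, dpcp_spacing = c(2L, 12L)) {
  list(terminal_margin = terminal_margin, len_range = len_range,
       guide_max = guide_max, dpcp_spacing = dpcp_spacing)
}

#' Assemble C/D box snoRNA candidates from a locus sequence
#'
#' A candidate requires a C box starting within `terminal_margin` of the
#' 5' end (5'-most such match), a D box ending within `terminal_margin`
#' of the 3' end (3'-most such match), a valid K-turn between them
#' ([validate_kturn()]), and length within `len_range`. An internal D'
#' box with a C' box 2-12 nt downstream is optional. Guide windows of up
#' to `guide_max` nt are extracted immediately 5' of the D and D' boxes,
#' truncated at the nearest upstream box.
#'
#' @param locus_sequence RNA sequence of a called sRNA locus.
#' @param params see [cd_params()].
#' @param motif_sets see [cd_motif_sets()].
#' @param locus_id identifier carried into the result.
#' @return list of candidates (length 0 or 1); each of class
#'   `cd_candidate` with elements `locus_id`, `sequence`, `boxes`,
#'   `kturn`, `guide_D`, `guide_Dprime`, `length`.
#' @export
assemble_cd_candidates <- function(locus_sequence, params = cd_params(),
                                   motif_sets = cd_motif_sets(),
                                   locus_id = NA_character_) {
  n <- nchar(locus_sequence)
  if (n < params$len_range[1] || n > params$len_range[2]) return(list())
  boxes <- find_boxes(locus_sequence, motif_sets)
  if (!nrow(boxes)) return(list())

  cc <- boxes[boxes$kind == "C" & boxes$start < params$terminal_margin, ,
              drop = FALSE]
  if (!nrow(cc)) return(list())
  cmin <- min(cc$start)
  cc <- cc[cc$start == cmin, , drop = FALSE]
  cbox <- cc[which.max(nchar(cc$sequence)), , drop = FALSE] # prefer 7-mer

  dd <- boxes[boxes$kind == "D" & boxes$end > n - params$terminal_margin &
              boxes$start >= cbox$end, , drop = FALSE]
  if (!nrow(dd)) return(list())
  dbox <- dd[which.max(dd$end), , drop = FALSE]

  kt <- validate_kturn(cbox$sequence, dbox$sequence)
  if (!kt$valid) return(list())

  # optional internal D' + C' (C' must sit 2-12 nt 3' of the D' box)
  dp <- boxes[boxes$kind == "Dprime" & boxes$start > cbox$end &
              boxes$end < dbox$start, , drop = FALSE]
  cp <- boxes[boxes$kind == "Cprime", , drop = FALSE]
  dpbox <- cpbox <- NULL
  if (nrow(dp)) {
    dp <- dp[order(dp$start), , drop = FALSE]
    for (i in seq_len(nrow(dp))) {
      ok <- cp[cp$start - dp$end[i] >= params$dpcp_spacing[1] &
               cp$start - dp$end[i] <= params$dpcp_spacing[2] &
               cp$end < dbox$start, , drop = FALSE]
      if (nrow(ok)) {
        dpbox <- dp[i, , drop = FALSE]
        cpbox <- ok[which.min(ok$start), , drop = FALSE]
        break
      }
    }
  }

  guide_window <- function(box_start, upstream_end) {
    gs <- max(upstream_end, box_start - params$guide_max)
    list(sequence = substr0(locus_sequence, gs, box_start),
         start = gs, end = box_start)
  }
  up_d <- if (!is.null(cpbox)) cpbox$end
          else if (!is.null(dpbox)) dpbox$end else cbox$end
  guide_D <- guide_window(dbox$start, up_d)
  guide_Dprime <- if (!is.null(dpbox)) guide_window(dpbox$start, cbox$end)
                  else NULL

  box_df <- rbind(
    data.frame(box = "C", cbox[, c("consensus_id", "start", "end",
                                   "sequence")]),
    if (!is.null(dpbox))
      data.frame(box = "Dprime", dpbox[, c("consensus_id", "start", "end",
                                           "sequence")]),
    if (!is.null(cpbox))
      data.frame(box = "Cprime", cpbox[, c("consensus_id", "start", "end",
                                           "sequence")]),
    data.frame(box = "D", dbox[, c("consensus_id", "start", "end",
                                   "sequence")]))
  rownames(box_df) <- NULL

  cand <- structure(list(
    locus_id = locus_id, sequence = locus_sequence, boxes = box_df,
    kturn = kt, guide_D = guide_D, guide_Dprime = guide_Dprime,
    length = n), class = "cd_candidate")
  list(cand)
}

#' @export
print.cd_candidate <- function(x, ...) {
  cat("C/D snoRNA candidate", x$locus_id, sprintf("(%d nt)\n", x$length))
  print(x$boxes)
  cat(" D guide:", x$guide_D$sequence, "\n")
  if (!is.null(x$guide_Dprime))
    cat(" D' guide:", x$guide_Dprime$sequence, "\n")
  print(x$kturn)
  invisible(x)
}
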