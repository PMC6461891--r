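# Independent brute-force oracles used to cross-check the package's
# search primitives. Deliberately different formulations: the pattern
# oracle is a min-mismatch dynamic program over explicit
# (insertions, deletions) layers; the helix oracle walks the full
# pairing matrix.

.oracle_iupac <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"), B = c("C", "G", "U"),
  D = c("A", "G", "U"), H = c("A", "C", "U"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "U"))

oracle_search <- function(subject, pattern, mm_max, ins_max, del_max) {
  n <- nchar(subject); m <- nchar(pattern)
  S <- strsplit(subject, "")[[1]]
  P <- strsplit(pattern, "")[[1]]
  M <- array(Inf, c(m + 1, ins_max + 1, del_max + 1, n))
  M[1, 1, 1, ] <- 0
  for (j in 0:m) for (i in 0:ins_max) for (d in 0:del_max) {
    cur <- M[j + 1, i + 1, d + 1, ]
    if (!any(is.finite(cur))) next
    idx <- seq_len(n) + (j - d) + i # next subject char, 1-based
    ok <- idx <= n
    if (j < m) {
      cmp <- rep(FALSE, n)
      cmp[ok] <- S[idx[ok]] %in% .oracle_iupac[[P[j + 1]]]
      val <- ifelse(ok, cur + ifelse(cmp, 0, 1), Inf)
      M[j + 2, i + 1, d + 1, ] <- pmin(M[j + 2, i + 1, d + 1, ], val)
      if (d < del_max)
        M[j + 2, i + 1, d + 2, ] <- pmin(M[j + 2, i + 1, d + 2, ], cur)
    }
    if (i < ins_max && j > 0 && j < m) {
      val <- ifelse(ok, cur, Inf)
      M[j + 1, i + 2, d + 1, ] <- pmin(M[j + 1, i + 2, d + 1, ], val)
    }
  }
  rows <- list()
  for (s in seq_len(n)) {
    best <- NULL
    for (i in 0:ins_max) for (d in 0:del_max) {
      mm <- M[m + 1, i + 1, d + 1, s]
      if (!is.finite(mm) || mm > mm_max) next
      if ((m - d) + i < 1) next
      cand <- c(cost = mm + i + d, indel = i + d,
                end = (s - 1) + (m - d) + i, mm = mm, ins = i, del = d)
      if (is.null(best) ||
          cand["cost"] < best["cost"] ||
          (cand["cost"] == best["cost"] && cand["indel"] < best["indel"]) ||
          (cand["cost"] == best["cost"] && cand["indel"] == best["indel"] &&
             cand["end"] < best["end"]))
        best <- cand
    }
    if (!is.null(best))
      rows[[length(rows) + 1]] <- data.frame(
        start = s - 1L, end = unname(best["end"]),
        mismatches = unname(best["mm"]), insertions = unname(best["ins"]),
        deletions = unname(best["del"]))
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      mismatches = integer(), insertions = integer(),
                      deletions = integer()))
  do.call(rbind, rows)
}

.oracle_pairs <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE,
                   GU = TRUE, UG = TRUE)

oracle_helices <- function(a, b, min_len) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  mat <- matrix(FALSE, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb))
    mat[i, j] <- isTRUE(.oracle_pairs[paste0(A[i], B[j])])
  rows <- list()
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (!mat[i, j]) next
    if (i > 1 && j < nb && mat[i - 1, j + 1]) next # not a run start
    L <- 0
    while (i + L <= na && j - L >= 1 && mat[i + L, j - L]) L <- L + 1
    if (L >= min_len)
      rows[[length(rows) + 1]] <- data.frame(
        a_start = i - 1L, a_end = i - 1L + L,
        b_start = j - L, b_end = j)
  }
  if (!length(rows))
    return(data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer()))
  df <- do.call(rbind, rows)
  # same dominance rule as the implementation, applied independently:
  # a run nested in a longer run on both molecules is not distinct
  drop <- logical(nrow(df))
  L <- df$a_end - df$a_start
  for (i in seq_len(nrow(df)))
    drop[i] <- any(L > L[i] &
                     df$a_start <= df$a_start[i] & df$a_end >= df$a_end[i] &
                     df$b_start <= df$b_start[i] & df$b_end >= df$b_end[i])
  df <- df[!drop, , drop = FALSE]
  df <- df[order(df$a_start, df$b_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# independent spacer stem scan: is there a hairpin with a k-pair stem and
# a loop of at least min_loop?
oracle_has_hairpin <- function(sp, min_stem, min_loop) {
  ch <- strsplit(sp, "")[[1]]
  n <- length(ch)
  k <- min_stem
  if (n < 2 * k + min_loop) return(FALSE)
  for (p in 1:(n - 2 * k - min_loop + 1)) {
    for (q in (p + 2 * k + min_loop - 1):n) {
      all_pair <- TRUE
      for (t in 0:(k - 1)) {
        if (!isTRUE(.oracle_pairs[paste0(ch[p + t], ch[q - t])])) {
          all_pair <- FALSE; break
        }
      }
      if (all_pair) return(TRUE)
    }
  }
  FALSE
}

# independent duplex scorer: compares the target window to the
# Watson-Crick partner string of the guide, position by position
oracle_duplex_windows <- function(guide, target, min_pairs, max_mm, max_gu) {
  glen <- nchar(guide)
  wc_partner <- rev(strsplit(chartr("ACGU", "UGCA", guide), "")[[1]])
  gu_partner <- rev(strsplit(chartr("GU", "UG", guide), "")[[1]])
  g_rev <- rev(strsplit(guide, "")[[1]])
  n <- nchar(target)
  hits <- integer()
  if (n < glen) return(hits)
  for (w in 0:(n - glen)) {
    tw <- strsplit(substr(target, w + 1, w + glen), "")[[1]]
    wc <- tw == wc_partner
    gu <- !wc & ((g_rev == "G" & tw == "U") | (g_rev == "U" & tw == "G"))
    mm <- sum(!wc & !gu)
    if (sum(wc) + sum(gu) >= min_pairs && mm <= max_mm &&
        sum(gu) <= max_gu && wc[5]) hits <- c(hits, w)
  }
  hits
}

random_rna_str <- function(n)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
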