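#' Count reads per locus and library
#'
#' A read is assigned to a locus when at least `min_overlap_frac` of the
#' read interval overlaps it (same strand); counts are multiplicity
#' weighted.
#'
#' @param loci locus data frame (disjoint per strand).
#' @param reads named list of read data frames (one per library).
#' @param min_overlap_frac minimum fraction of the read covered by the
#'   locus (default 0.5).
#' @return object of class `count_matrix`: list with integer `counts`
#'   (loci x libraries), `lengths`, `lib_sizes`.
#' @export
quantify <- function(loci, reads, min_overlap_frac = 0.5) {
  counts <- matrix(0, nrow = nrow(loci), ncol = length(reads),
                   dimnames = list(loci$locus, names(reads)))
  for (li in seq_along(reads)) {
    rd <- reads[[li]]
    if (!nrow(rd)) next
    for (i in seq_len(nrow(loci))) {
      sel <- rd$chrom == loci$chrom[i] & rd$strand == loci$strand[i] &
        rd$start < loci$end[i] & rd$end > loci$start[i]
      if (!any(sel)) next
      ov <- pmin(rd$end[sel], loci$end[i]) - pmax(rd$start[sel], loci$start[i])
      frac <- ov / (rd$end[sel] - rd$start[sel])
      counts[i, li] <- sum(rd$count[sel][frac >= min_overlap_frac])
    }
  }
  structure(list(counts = counts,
                 lengths = setNames(loci$end - loci$start, loci$locus),
                 lib_sizes = colSums(counts)),
            class = "count_matrix")
}

#' Library- and length-normalized expression matrices
#'
#' CPM divides by library size; TPM additionally divides by locus length
#' before rescaling each library to one million, so that TPM columns sum
#' to 1e6.
#'
#' @param cm a [quantify()] result.
#' @param method `"cpm"` or `"tpm"`.
#' @return numeric matrix (loci x libraries).
#' @export
normalize_counts <- function(cm, method = c("cpm", "tpm")) {
  method <- match.arg(method)
  counts <- cm$counts
  if (any(cm$lib_sizes == 0))
    stop("zero library size for: ",
         paste(colnames(counts)[cm$lib_sizes == 0], collapse = ", "))
  if (method == "cpm") {
    sweep(counts, 2, cm$lib_sizes, "/") * 1e6
  } else {
    rate <- sweep(counts, 1, cm$lengths, "/")
    sweep(rate, 2, colSums(rate), "/") * 1e6
  }
}

#' Test loci for light/dark differential expression
#'
#' Flags loci as differentially expressed when `|log2FC| >= lfc_min` and
#' Benjamini-Hochberg FDR `< fdr_max` (defaults 1.3 and 0.05). The fold
#' change is `log2` of the ratio of condition-mean CPM with a 0.5
#' pseudocount (TMM-scaled CPM under the `"exact"` engine, removing the
#' compositional shift a strongly induced locus imposes on the rest).
#' Two inference engines are available: the default
#' `"exact"` uses the edgeR negative-binomial exact test with TMM
#' normalization and tagwise dispersion (the standard small-count sRNA
#' engine); `"welch"` is a simple Welch two-sample t-test on
#' `log2(CPM + 0.5)`. Terminator-treated libraries are excluded: the
#' treatment is biochemical, not a biological condition.
#'
#' @param cm a [quantify()] result.
#' @param manifest library manifest (see [read_manifest()]).
#' @param method `"exact"` (edgeR) or `"welch"`.
#' @param lfc_min,fdr_max differential-expression thresholds.
#' @return data frame with columns `locus`, `mean_cpm_light`,
#'   `mean_cpm_dark`, `log2fc`, `p`, `q`, `de_flag`.
#' @export
test_de <- function(cm, manifest, method = c("exact", "welch"),
                    lfc_min = 1.3, fdr_max = 0.05) {
  method <- match.arg(method)
  man <- manifest[!manifest$te_treated, , drop = FALSE]
  man <- man[man$library_id %in% colnames(cm$counts), , drop = FALSE]
  light <- man$library_id[man$condition == "light"]
  dark <- man$library_id[man$condition == "dark"]
  if (length(light) < 2 || length(dark) < 2)
    stop("need at least 2 untreated replicates per condition")
  counts <- cm$counts[, c(light, dark), drop = FALSE]
  sub <- structure(list(counts = counts, lengths = cm$lengths,
                        lib_sizes = cm$lib_sizes[c(light, dark)]),
                   class = "count_matrix")
  cpm <- normalize_counts(sub, "cpm")

  if (method == "welch") {
    lg <- log2(cpm + 0.5)
    p <- vapply(seq_len(nrow(lg)), function(i) {
      x <- lg[i, light]; y <- lg[i, dark]
      if (stats::sd(x) == 0 && stats::sd(y) == 0)
        return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
      t.test(y, x)$p.value
    }, numeric(1))
  } else {
    grp <- factor(c(rep("light", length(light)), rep("dark", length(dark))),
                  levels = c("light", "dark"))
    y <- edgeR::DGEList(counts = counts, group = grp,
                        lib.size = unname(sub$lib_sizes))
    y <- edgeR::calcNormFactors(y)
    # TMM-scaled CPM for the fold change: corrects the compositional
    # shift a strongly induced locus imposes on all other loci
    cpm <- edgeR::cpm(y, normalized.lib.sizes = TRUE)
    colnames(cpm) <- c(light, dark)
    y <- edgeR::estimateDisp(y)
    et <- edgeR::exactTest(y)
    p <- et$table$PValue
  }
  m_light <- rowMeans(cpm[, light, drop = FALSE])
  m_dark <- rowMeans(cpm[, dark, drop = FALSE])
  log2fc <- log2((m_dark + 0.5) / (m_light + 0.5))
  q <- p.adjust(p, method = "BH")
  data.frame(locus = rownames(counts),
             mean_cpm_light = m_light, mean_cpm_dark = m_dark,
             log2fc = log2fc, p = p, q = q,
             de_flag = abs(log2fc) >= lfc_min & q < fdr_max,
             row.names = NULL, stringsAsFactors = FALSE)
}
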