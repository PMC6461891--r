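# Shared in-code fixtures: a reduced simulation configuration (keeps the
# study design -- library layout, depths, dispersion, retentions -- but a
# smaller genome so module tests stay fast), and builders for tiny
# hand-constructed annotations and read sets.

small_sim_config <- function(...) {
  simulation_config(genome_length = 40000L, n_cds = 20L,
                    n_planted_snorna = 6L, n_orphan = 3L, ...)
}

tiny_annotation <- function(len = 1000L, features = NULL) {
  set.seed(99)
  seqs <- c(chrA = random_rna_str(len))
  if (is.null(features))
    features <- data.frame(id = "cds1", chrom = "chrA", strand = "+",
                           start = 400L, end = 700L, ftype = "CDS")
  genome_annotation(seqs, features)
}

# n identical reads spanning [start,end) on chrom/strand
make_reads <- function(start, end, n = 5L, chrom = "chrA", strand = "+",
                       count = 1L) {
  data.frame(chrom = chrom, strand = strand,
             start = rep(start, n), end = rep(end, n), count = count,
             stringsAsFactors = FALSE)
}

bind_reads <- function(...) do.call(rbind, list(...))

empty_reads <- function() {
  data.frame(chrom = character(), strand = character(), start = integer(),
             end = integer(), count = integer(), stringsAsFactors = FALSE)
}

# match called loci to planted truth intervals (same strand, >=50% of the
# planted interval covered)
match_planted <- function(loci, planted) {
  vapply(seq_len(nrow(planted)), function(i) {
    p <- planted[i, ]
    sel <- loci$chrom == p$chrom & loci$strand == p$strand &
      loci$start < p$end & loci$end > p$start
    if (!any(sel)) return(NA_character_)
    ov <- pmin(loci$end[sel], p$end) - pmax(loci$start[sel], p$start)
    if (max(ov) < 0.5 * (p$end - p$start)) return(NA_character_)
    loci$locus[which(sel)[which.max(ov)]]
  }, character(1))
}

tiny_manifest <- function(libs, te = rep(FALSE, length(libs)),
                          condition = rep("light", length(libs))) {
  data.frame(library_id = libs, condition = condition,
             replicate = seq_along(libs), te_treated = te,
             reads_path = NA_character_, stringsAsFactors = FALSE)
}
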