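# Fixed planted spliceosomal snRNA sequences. snRNAs are strongly
# conserved, so the generator plants fixed hand-designed sequences
# carrying the class-defining elements (5'SS-binding motif, BP motif +
# U6 helices, U6-helix pair with interior hairpin, loop I + stem,
# ACAGAGA + U-tract, Sm/Lsm sites) and verified to satisfy exactly their
# own kind's rules; only placement and expression are randomized.
.NM_U6 <- paste0(
  "GU", "ACAGAGA",              # 5' splice-site binding
  "CAUGCUAAUCU",                # U4 helix I region
  "AA",
  "AUCCUUAUACAGGGGC",           # U4 helix II region
  "AU",
  "CCUUGGCA",                   # U2 helix Ib region
  "AA",
  "GAUCAGGU",                   # U2 helix Ia region
  "AAUCUUUUUG")                 # Lsm site / 3' U-tract

.NM_U4 <- paste0(
  "AAUU",
  "GCCCCUGUAUAAGGAU",           # pairs U6 helix II region
  "AAUG", "GGAUUC", "UUCG", "GAAUCC", "AAUC", # 5' SL: 6-bp stem hairpin
  "AGAUUAGCAUG",                # pairs U6 helix I region
  "AAUUUUUGG", "CA")            # Sm site

.NM_U2 <- paste0(
  "AU", "GUAGUA",               # branch-point interaction region
  "CU", "ACCUGAUC",             # pairs U6 U2-helix Ia region
  "AAU", "UGCCAAGG",            # pairs U6 U2-helix Ib region
  "ACAAUCGGAAUCCA",
  "AAUUUUUG", "CC")             # Sm site

.NM_U1 <- paste0(
  "ACUUAC",                     # 5' splice-site recognition (rc = GUAAGU)
  "CCAGGCAAUGGCUUAAGCGAAUCCGCAAC",
  "AAUUUUG", "CACC")            # Sm site

.NM_U5 <- paste0(
  "GA", "GGAUC",                # loop I 5' stem arm
  "UGCCUUUUACC",                # loop I
  "GAUCC",                      # loop I 3' stem arm
  "AAACGCAAGC",
  "GAUUUUUG", "CA")             # Sm site

.NM_SNRNAS <- c(U6 = .NM_U6, U1 = .NM_U1, U2 = .NM_U2, U4 = .NM_U4,
                U5 = .NM_U5)

random_rna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

#' Configuration for the synthetic nucleomorph simulator
#'
#' Defaults emulate a miniaturized, gene-dense nucleomorph genome at toy
#' scale: ~120 kb over 3 chromosomes, 80 protein-coding genes with short
#' (geometric, mean ~130 nt) intergenic spaces, an rRNA operon (SSU, LSU,
#' 5.8S), 20 planted C/D box snoRNA genes whose guides are exact reverse
#' complements of rRNA windows, the five spliceosomal snRNAs, 5 orphan
#' loci (one induced 6-fold in darkness), and one unexpressed 34-nt
#' truncated snoRNA pseudogene. Libraries follow a light/dark replicated
#' design with one Terminator-exonuclease (TE) treated library; TE
#' retention is 0.9 for capped and 0.05 for 5'-monophosphate loci.
#'
#' @param seed RNG seed; all stochastic draws flow from one generator.
#' @param genome_length total genome length (nt).
#' @param n_chrom number of chromosomes.
#' @param n_cds number of protein-coding genes.
#' @param n_planted_snorna,n_planted_snrna,n_orphan planted gene counts.
#' @param rrna_lengths named lengths of the rRNA species.
#' @param replicates replicates per condition (light and dark).
#' @param te_libraries number of TE-treated libraries.
#' @param mean_depth expected reads per expressed locus per library.
#' @param dispersion negative-binomial dispersion (0 gives Poisson).
#' @param dark_induced_fold fold induction of the dark-induced locus.
#' @param te_capped_retention,te_monop_retention TE survival fractions.
#' @param read_len read length range (nt).
#' @param offset_geom_p geometric parameter of read 5'/3' end offsets.
#' @param background_depth_frac background noise depth as a fraction of
#'   the pooled locus-calling depth threshold.
#' @param overlap_frac fraction of planted sRNA genes overlapping a
#'   flanking CDS by 13-43 nt.
#' @param cds_len CDS length range.
#' @param intergenic_mean mean intergenic space (nt).
#' @param min_gap minimum intergenic space (nt).
#' @param guide_len snoRNA guide length range.
#' @param orphan_len orphan locus length range.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(seed = 42L, genome_length = 120000L,
                              n_chrom = 3L, n_cds = 80L,
                              n_planted_snorna = 20L,
                              n_planted_snrna = 5L, n_orphan = 5L,
                              rrna_lengths = c(SSU = 1500L, LSU = 2900L,
                                               `5.8S` = 160L),
                              replicates = 2L, te_libraries = 1L,
                              mean_depth = 200, dispersion = 0.1,
                              dark_induced_fold = 6,
                              te_capped_retention = 0.9,
                              te_monop_retention = 0.05,
                              read_len = c(18L, 76L),
                              offset_geom_p = 0.15,
                              background_depth_frac = 0.1,
                              overlap_frac = 0.2,
                              cds_len = c(450L, 1200L),
                              intergenic_mean = 130L, min_gap = 20L,
                              guide_len = c(10L, 14L),
                              orphan_len = c(60L, 100L)) {
  cfg <- as.list(environment())
  counts <- c(cfg$genome_length, cfg$n_chrom, cfg$n_cds,
              cfg$n_planted_snorna, cfg$n_planted_snrna, cfg$n_orphan,
              cfg$replicates, cfg$te_libraries, cfg$mean_depth)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (cfg$te_capped_retention < 0 || cfg$te_capped_retention > 1 ||
      cfg$te_monop_retention < 0 || cfg$te_monop_retention > 1)
    stop("TE retention fractions must lie in [0, 1]")
  if (cfg$n_planted_snrna > 5) stop("at most 5 snRNA kinds can be planted")
  libs <- list()
  for (cond in c("light", "dark"))
    for (r in seq_len(cfg$replicates))
      libs[[length(libs) + 1]] <- data.frame(
        library_id = sprintf("%s_%d", cond, r), condition = cond,
        replicate = r, te_treated = FALSE, stringsAsFactors = FALSE)
  for (r in seq_len(cfg$te_libraries))
    libs[[length(libs) + 1]] <- data.frame(
      library_id = sprintf("te_%d", r), condition = "light",
      replicate = r, te_treated = TRUE, stringsAsFactors = FALSE)
  cfg$libraries <- do.call(rbind, libs)
  structure(cfg, class = "sim_config")
}

# one planted snoRNA, rejection-sampled until the detector recovers the
# planted boxes and guides exactly (guarantees truth self-consistency)
.make_snorna <- function(id, targets, cfg, variant) {
  for (try in 1:200) {
    g_dp_len <- sample(cfg$guide_len[1]:cfg$guide_len[2], 1)
    g_d_len <- sample(cfg$guide_len[1]:cfg$guide_len[2], 1)
    pick_guide <- function(len) {
      tg <- sample(names(targets), 1,
                   prob = c(0.45, 0.45, 0.10)[seq_along(targets)])
      w <- sample(0:(nchar(targets[[tg]]) - len), 1)
      list(target = tg, start = w, end = w + len,
           guide = reverse_complement(substr0(targets[[tg]], w, w + len)),
           site = w + 4L)
    }
    gdp <- pick_guide(g_dp_len)
    gd <- pick_guide(g_d_len)
    cbox <- variant$C
    dbox <- variant$D
    dpbox <- sample(c("UUGA", "AUGA"), 1)
    cpbox <- sample(c("UUGA", "AUGA"), 1)
    pad5 <- random_rna(sample(2:5, 1))
    sp <- random_rna(sample(2:8, 1))
    pad3 <- random_rna(sample(2:5, 1))
    seqs <- c(pad5, cbox, gdp$guide, dpbox, sp, cpbox, gd$guide, dbox, pad3)
    seq <- paste(seqs, collapse = "")
    offs <- cumsum(c(0, nchar(seqs)))
    cand <- assemble_cd_candidates(seq, locus_id = id)
    if (length(cand) != 1) next
    cd <- cand[[1]]
    if (cd$boxes$start[cd$boxes$box == "C"] != offs[2]) next
    if (!"Dprime" %in% cd$boxes$box || !"Cprime" %in% cd$boxes$box) next
    if (cd$boxes$start[cd$boxes$box == "Dprime"] != offs[4]) next
    if (cd$boxes$start[cd$boxes$box == "Cprime"] != offs[6]) next
    if (cd$boxes$start[cd$boxes$box == "D"] != offs[8]) next
    if (cd$guide_D$sequence != gd$guide) next
    if (is.null(cd$guide_Dprime) || cd$guide_Dprime$sequence != gdp$guide)
      next
    return(list(id = id, sequence = seq,
                boxes = cd$boxes,
                guides = data.frame(
                  snorna = id, box = c("Dprime", "D"),
                  guide = c(gdp$guide, gd$guide),
                  guide_start = c(offs[3], offs[7]),
                  guide_end = c(offs[4], offs[8]),
                  target = c(gdp$target, gd$target),
                  target_start = c(gdp$start, gd$start),
                  target_end = c(gdp$end, gd$end),
                  site = c(gdp$site, gd$site),
                  stringsAsFactors = FALSE)))
  }
  stop("could not construct planted snoRNA ", id)
}

.snrna_is_clean <- function(seq, u6) {
  length(assemble_cd_candidates(seq)) == 0 &&
    !any(vapply(c("U1", "U2", "U4", "U5", "U6"), function(k)
      evaluate_snrna_candidate(seq, k, u6_sequence = u6)$pass, logical(1)))
}

#' Generate a synthetic nucleomorph genome with planted sRNA genes
#'
#' Deterministic given `config$seed`. Chromosomes are assembled from
#' protein-coding genes, the rRNA genes, and the planted sRNA genes,
#' separated by geometric intergenic spacers; a configurable fraction of
#' sRNA genes overlaps a flanking CDS by 13-43 nt (realized by extending
#' the CDS annotation over the sRNA interval; the sRNA sequence itself is
#' untouched). snoRNA guides are exact reverse complements of randomly
#' chosen rRNA windows, so the planted +5-rule methylation position is
#' `window_start + 4` by construction; the generator re-detects each
#' planted snoRNA before accepting it, enforcing self-consistency. One
#' truncated (34 nt) snoRNA pseudogene lacking the C'/D boxes is planted
#' with zero expression as a negative control. The annotation contains
#' only the CDS and rRNA features -- planted sRNA genes are recorded in
#' the truth object and must be re-discovered by the pipeline.
#'
#' @param config a [simulation_config()].
#' @return list with `annotation` (a [genome_annotation()]) and `truth`
#'   (class `synthetic_truth`: planted loci, snoRNA guides and sites,
#'   snRNA sequences, rRNA target sequences, U6 sequence, config echo).
#' @export
generate_genome <- function(config = simulation_config()) {
  cfg <- config
  set.seed(cfg$seed)
  targets <- vapply(cfg$rrna_lengths, random_rna, character(1))

  variants <- list(canonical = list(C = "AUGAUGA", D = "CUGA"),
                   comp_UA = list(C = "AUGAUU", D = "AUGA"),
                   comp_AU = list(C = "GUGAAG", D = "CUGA"))
  n_sno <- cfg$n_planted_snorna
  snornas <- list()
  if (n_sno > 0) {
    v_idx <- rep(1L, n_sno)
    if (n_sno >= 3) {
      n_nc <- max(1L, round(0.3 * n_sno))
      v_idx[seq_len(n_nc)] <- rep(c(2L, 3L), length.out = n_nc)
      v_idx <- sample(v_idx)
    }
    for (i in seq_len(n_sno))
      snornas[[i]] <- .make_snorna(sprintf("sno%02d", i), targets, cfg,
                                   variants[[v_idx[i]]])
  }

  kinds <- head(c("U6", "U1", "U2", "U4", "U5"), cfg$n_planted_snrna)
  snrnas <- lapply(kinds, function(k)
    list(id = paste0("snRNA_", k), kind = k, sequence = .NM_SNRNAS[[k]]))

  orphans <- list()
  for (i in seq_len(cfg$n_orphan)) {
    for (try in 1:200) {
      seq <- random_rna(sample(cfg$orphan_len[1]:cfg$orphan_len[2], 1))
      if (.snrna_is_clean(seq, .NM_U6)) break
      if (try == 200) stop("could not construct orphan locus")
    }
    orphans[[i]] <- list(id = sprintf("orph%02d", i), sequence = seq)
  }

  pseudo <- if (n_sno > 0)
    list(id = "pseudo01",
         sequence = substr(snornas[[1]]$sequence, 1, 34)) else NULL

  # elements to lay out
  elements <- list()
  add <- function(id, kind, seq, strand = sample(c("+", "-"), 1)) {
    elements[[length(elements) + 1]] <<- list(id = id, kind = kind,
                                              seq = seq, strand = strand)
  }
  for (i in seq_len(cfg$n_cds))
    add(sprintf("cds%03d", i), "CDS",
        random_rna(sample(cfg$cds_len[1]:cfg$cds_len[2], 1)))
  for (tg in names(targets)) add(paste0("rrna_", tg), "rRNA", targets[[tg]],
                                 strand = "+")
  for (s in snornas) add(s$id, "snoRNA", s$sequence)
  for (s in snrnas) add(s$id, "snRNA", s$sequence)
  for (s in orphans) add(s$id, "orphan", s$sequence)
  if (!is.null(pseudo)) add(pseudo$id, "pseudogene", pseudo$sequence)

  total_needed <- sum(vapply(elements, function(e) nchar(e$seq), numeric(1))) +
    (length(elements) + cfg$n_chrom) * cfg$min_gap
  if (total_needed > cfg$genome_length)
    stop("genome too small: need at least ", total_needed,
         " nt for the requested features, have ", cfg$genome_length)

  # chromosome assignment proportional to target lengths, then layout
  w <- seq(cfg$n_chrom, 1) / sum(seq(cfg$n_chrom, 1))
  target_len <- round(cfg$genome_length * w)
  for (try in 1:200) {
    assign <- sample(seq_len(cfg$n_chrom), length(elements), replace = TRUE,
                     prob = w)
    per_len <- vapply(seq_len(cfg$n_chrom), function(ci) {
      el <- elements[assign == ci]
      sum(vapply(el, function(e) nchar(e$seq), numeric(1))) +
        (length(el) + 1) * cfg$min_gap
    }, numeric(1))
    if (all(per_len <= target_len)) break
    if (try == 200)
      stop("genome too small: features do not fit on the chromosomes")
  }

  seqs <- character(cfg$n_chrom)
  feats <- list()
  truth_loci <- list()
  gmean <- max(1, cfg$intergenic_mean - cfg$min_gap)
  for (ci in seq_len(cfg$n_chrom)) {
    chrom <- sprintf("nmchr%d", ci)
    el <- elements[assign == ci]
    el <- el[sample(length(el))]
    parts <- character()
    cursor <- 0L
    el_lens <- vapply(el, function(e) nchar(e$seq), numeric(1))
    # space that must stay reserved for element k..n at minimum gaps
    need_after <- rev(cumsum(rev(el_lens + cfg$min_gap)))
    for (k in seq_along(el)) {
      e <- el[[k]]
      gap <- cfg$min_gap + rgeom(1, 1 / gmean)
      avail <- target_len[ci] - cursor - (need_after[k] - cfg$min_gap)
      gap <- min(gap, max(cfg$min_gap, avail))
      parts <- c(parts, random_rna(gap))
      start <- cursor + gap
      genomic <- if (e$strand == "-") reverse_complement(e$seq) else e$seq
      parts <- c(parts, genomic)
      cursor <- start + nchar(e$seq)
      if (e$kind %in% c("CDS", "rRNA")) {
        feats[[length(feats) + 1]] <- data.frame(
          id = e$id, chrom = chrom, strand = e$strand,
          start = start, end = cursor, ftype = e$kind,
          stringsAsFactors = FALSE)
      } else {
        truth_loci[[length(truth_loci) + 1]] <- data.frame(
          id = e$id, chrom = chrom, strand = e$strand,
          start = start, end = cursor, class = e$kind,
          stringsAsFactors = FALSE)
      }
    }
    pad <- target_len[ci] - cursor
    if (pad < 0) stop("genome too small: chromosome ", chrom, " overflows")
    parts <- c(parts, random_rna(pad))
    seqs[ci] <- paste(parts, collapse = "")
    names(seqs)[ci] <- chrom
  }
  feats <- do.call(rbind, feats)
  tl <- do.call(rbind, truth_loci)

  tl$expressed <- tl$class != "pseudogene"
  tl$expression_class <- "constitutive"
  orph_idx <- which(tl$class == "orphan")
  if (length(orph_idx)) tl$expression_class[orph_idx[1]] <- "dark_induced"
  tl$cap_class <- ifelse(tl$class %in% c("snoRNA", "snRNA"), "capped",
                         "monophosphate")
  if (length(orph_idx) > 1) # mixed 5'-end classes among orphans
    tl$cap_class[orph_idx[seq(2, length(orph_idx), by = 2)]] <- "capped"
  tl$cap_class[tl$class == "pseudogene"] <- "monophosphate"

  # CDS overlap (13-43 nt) at one end of a subset of expressed sRNA genes
  n_ov <- round(cfg$overlap_frac * sum(tl$expressed))
  if (n_ov > 0 && nrow(feats)) {
    cand <- which(tl$expressed)
    cand <- sample(cand, min(n_ov, length(cand)))
    for (i in cand) {
      cds <- feats[feats$chrom == tl$chrom[i] & feats$ftype == "CDS", ,
                   drop = FALSE]
      if (!nrow(cds)) next
      o <- sample(13:43, 1)
      # nothing else may lie between the CDS and the sRNA gene
      clear <- function(lo, hi) {
        !any(feats$chrom == tl$chrom[i] & feats$start < hi &
               feats$end > lo) &&
          !any(tl$chrom == tl$chrom[i] & tl$start < hi & tl$end > lo &
                 tl$id != tl$id[i])
      }
      prev <- cds[cds$end <= tl$start[i], , drop = FALSE]
      nxt <- cds[cds$start >= tl$end[i], , drop = FALSE]
      side <- sample(c("left", "right"), 1)
      if (side == "left" && nrow(prev)) {
        j <- rownames(prev)[which.max(prev$end)]
        if (clear(feats[j, "end"], tl$start[i]))
          feats[j, "end"] <- tl$start[i] + o
      } else if (side == "right" && nrow(nxt)) {
        j <- rownames(nxt)[which.min(nxt$start)]
        if (clear(tl$end[i], feats[j, "start"]))
          feats[j, "start"] <- tl$end[i] - o
      }
    }
  }

  annotation <- genome_annotation(seqs, feats)
  truth <- structure(list(
    loci = tl,
    snorna_guides = if (length(snornas))
      do.call(rbind, lapply(snornas, `[[`, "guides")) else NULL,
    snorna_boxes = if (length(snornas))
      do.call(rbind, lapply(snornas, function(s)
        cbind(snorna = s$id, s$boxes))) else NULL,
    snrnas = if (length(snrnas)) data.frame(
      id = vapply(snrnas, `[[`, character(1), "id"),
      kind = vapply(snrnas, `[[`, character(1), "kind"),
      sequence = vapply(snrnas, `[[`, character(1), "sequence"),
      stringsAsFactors = FALSE) else NULL,
    targets = targets,
    u6 = .NM_U6,
    config = cfg), class = "synthetic_truth")
  list(annotation = annotation, truth = truth)
}

#' Simulate replicate sRNA-seq read libraries
#'
#' Per-locus, per-library counts are negative binomial with the
#' configured mean and dispersion (Poisson when dispersion is 0); the
#' dark-induced locus has its mean multiplied by `dark_induced_fold` in
#' dark libraries; in TE-treated libraries the mean is scaled by the
#' retention fraction of the locus's 5'-end class. Reads are
#' sub-intervals of the locus with their outer ends concentrated at the
#' locus termini (geometric offsets, half anchored at each end), plus
#' uniform low-rate background reads genome-wide (scaled by the
#' monophosphate retention in TE libraries, as background is dominated
#' by degradation fragments).
#'
#' @param annotation a [genome_annotation()] from [generate_genome()].
#' @param truth the matching `synthetic_truth`.
#' @param config the [simulation_config()] used (defaults to the one
#'   echoed in `truth`).
#' @param seed optional; set to make this call reproducible on its own
#'   (by default the RNG stream continues from the caller's state).
#' @return named list (one element per library) of read-interval data
#'   frames with columns `chrom`, `strand`, `start`, `end`, `count`.
#' @export
simulate_libraries <- function(annotation, truth, config = truth$config,
                               seed = NULL) {
  cfg <- config
  if (!is.null(seed)) set.seed(seed)
  libs <- cfg$libraries
  loci <- truth$loci[truth$loci$expressed, , drop = FALSE]
  lens <- nchar(annotation$sequences)
  total_len <- sum(lens)
  mean_read <- mean(cfg$read_len)
  bg_pooled <- cfg$background_depth_frac * locus_params()$depth_min
  bg_per_lib <- bg_pooled / nrow(libs)

  draw_count <- function(mu) {
    if (mu <= 0) return(0L)
    if (cfg$dispersion <= 0) rpois(1, mu)
    else rnbinom(1, size = 1 / cfg$dispersion, mu = mu)
  }

  out <- list()
  for (bi in seq_len(nrow(libs))) {
    lib <- libs[bi, ]
    rows <- list()
    for (i in seq_len(nrow(loci))) {
      mu <- cfg$mean_depth
      if (loci$expression_class[i] == "dark_induced" &&
          lib$condition == "dark")
        mu <- mu * cfg$dark_induced_fold
      if (lib$te_treated)
        mu <- mu * if (loci$cap_class[i] == "capped")
          cfg$te_capped_retention else cfg$te_monop_retention
      nreads <- draw_count(mu)
      if (nreads == 0) next
      L <- loci$end[i] - loci$start[i]
      len <- sample(cfg$read_len[1]:cfg$read_len[2], nreads, replace = TRUE)
      offs <- pmin(rgeom(nreads, cfg$offset_geom_p),
                   pmax(0L, L - cfg$read_len[1]))
      anchor5 <- runif(nreads) < 0.5
      s <- ifelse(anchor5, loci$start[i] + offs,
                  pmax(loci$start[i], loci$end[i] - offs - len))
      e <- ifelse(anchor5, pmin(loci$end[i], loci$start[i] + offs + len),
                  loci$end[i] - offs)
      keep <- e - s >= 1
      if (!any(keep)) next
      rows[[length(rows) + 1]] <- data.frame(
        chrom = loci$chrom[i], strand = loci$strand[i],
        start = as.integer(s[keep]), end = as.integer(e[keep]),
        stringsAsFactors = FALSE)
    }
    # uniform background noise
    bg_depth <- bg_per_lib * if (lib$te_treated) cfg$te_monop_retention else 1
    n_bg <- rpois(1, bg_depth * total_len / mean_read)
    if (n_bg > 0) {
      ch <- sample(names(lens), n_bg, replace = TRUE, prob = lens / total_len)
      len <- sample(cfg$read_len[1]:cfg$read_len[2], n_bg, replace = TRUE)
      st <- floor(runif(n_bg) * pmax(1, lens[ch] - len))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, strand = sample(c("+", "-"), n_bg, replace = TRUE),
        start = as.integer(st),
        end = as.integer(pmin(st + len, lens[ch])),
        stringsAsFactors = FALSE)
    }
    if (!length(rows)) {
      out[[lib$library_id]] <- data.frame(
        chrom = character(), strand = character(), start = integer(),
        end = integer(), count = integer(), stringsAsFactors = FALSE)
      next
    }
    df <- do.call(rbind, rows)
    agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                            by = df[c("chrom", "strand", "start", "end")],
                            FUN = sum)
    agg <- agg[order(agg$chrom, agg$start, agg$strand), , drop = FALSE]
    rownames(agg) <- NULL
    out[[lib$library_id]] <- agg
  }
  out
}

#' Construct a synthetic intron set with planted branch-point motifs
#'
#' Builds GU..AG introns; `n_with_motif` of them carry a branch-point
#' motif instance (default `DURAU`) ending 2-6 nt before the intron 3'
#' end (biased toward 2-3 nt), the remainder are rejection-sampled to
#' lack one in that window. Used to exercise the branch-point census on
#' data with known composition.
#'
#' @param n number of introns.
#' @param n_with_motif introns carrying the motif.
#' @param motif_pattern IUPAC motif planted.
#' @param len_range intron length range.
#' @return character vector of intron sequences.
#' @export
generate_intron_set <- function(n = 17L, n_with_motif = 12L,
                                motif_pattern = "DURAU",
                                len_range = c(45L, 70L)) {
  has_hit <- function(x) {
    occ <- search_pattern(x, motif_pattern)
    if (!nrow(occ)) return(FALSE)
    d <- nchar(x) - occ$end
    any(d >= 2 & d <= 6)
  }
  introns <- character(n)
  for (i in seq_len(n)) {
    repeat {
      L <- sample(len_range[1]:len_range[2], 1)
      if (i <= n_with_motif) {
        motif <- paste0(sample(c("A", "G", "U"), 1), "U",
                        sample(c("A", "G"), 1), "AU")
        d <- sample(2:6, 1, prob = c(0.35, 0.35, 0.12, 0.1, 0.08))
        body_len <- L - 6 - 5 - d
        if (body_len < 4) next
        x <- paste0("GUAAGU", random_rna(body_len), motif,
                    random_rna(d - 2), "AG")
        if (has_hit(x)) { introns[i] <- x; break }
      } else {
        x <- paste0("GUAAGU", random_rna(L - 8), "AG")
        if (!has_hit(x)) { introns[i] <- x; break }
      }
    }
  }
  introns
}

#' Write a simulated dataset to disk
#'
#' Writes `genome.fasta`, `annotation.gff3`, `reads_<lib>.bed` per
#' library, `targets.fasta` (rRNA target sequences), `u6.fasta`,
#' `manifest.tsv` and `truth.json`.
#'
#' @param sim list with `annotation` and `truth` from [generate_genome()].
#' @param reads read list from [simulate_libraries()].
#' @param dir output directory (created if needed).
#' @return the manifest data frame (invisibly).
#' @export
write_simulation <- function(sim, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$annotation$sequences, file.path(dir, "genome.fasta"))
  write_gff3(sim$annotation, file.path(dir, "annotation.gff3"))
  write_fasta(sim$truth$targets, file.path(dir, "targets.fasta"))
  write_fasta(c(U6 = sim$truth$u6), file.path(dir, "u6.fasta"))
  manifest <- sim$truth$config$libraries
  manifest$reads_path <- file.path(dir, paste0("reads_",
                                               manifest$library_id, ".bed"))
  for (lb in manifest$library_id)
    write_reads_bed(reads[[lb]], file.path(dir, paste0("reads_", lb, ".bed")))
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  tr <- sim$truth
  tr$config$libraries <- NULL
  jsonlite::write_json(tr[c("loci", "snorna_guides", "snrnas")],
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
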