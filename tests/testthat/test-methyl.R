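test_that("a perfect guide-target complement yields one clean duplex", {
  set.seed(61)
  target <- random_rna_str(60)
  guide <- reverse_complement(substr(target, 11, 22)) # window [10,22)
  dup <- find_guide_duplex(guide, target)
  expect_equal(nrow(dup), 1)
  expect_equal(dup$target_start, 10L)
  expect_equal(dup$target_end, 22L)
  expect_equal(dup$wc_count, 12L)
  expect_equal(dup$mismatch_count, 0L)

  # one G-U wobble is tolerated and counted
  g2 <- guide
  gch <- strsplit(g2, "")[[1]]
  k <- which(gch == "C")[1] # C -> U turns a G-C pair into G-U
  if (!is.na(k) && !k %in% c(5, 8)) { # keep the +5 pair intact
    substr(g2, k, k) <- "U"
    dup2 <- find_guide_duplex(g2, target)
    hit <- dup2[dup2$target_start == 10, ]
    expect_equal(hit$gu_count, 1L)
  }

  expect_error(find_guide_duplex("ACGUACGU", target), "at least 9")
})

test_that("duplex finder matches the all-windows oracle on random pairs", {
  set.seed(62)
  for (r in 1:100) {
    glen <- sample(9:14, 1)
    target <- random_rna_str(sample(40:120, 1))
    guide <- if (r %% 2 == 0) {
      w <- sample(0:(nchar(target) - glen), 1)
      g <- reverse_complement(substr(target, w + 1, w + glen))
      # corrupt up to 2 positions so near-misses get exercised
      for (k in sample(glen, sample(0:2, 1)))
        substr(g, k, k) <- sample(c("A", "C", "G", "U"), 1)
      g
    } else random_rna_str(glen)
    got <- find_guide_duplex(guide, target)$target_start
    want <- oracle_duplex_windows(guide, target, glen - 1, 1, 2)
    expect_equal(got, want, info = paste(guide, "vs", nchar(target)))
  }
})

test_that("the +5 rule places the site five guide residues from the box", {
  set.seed(63)
  target <- random_rna_str(80)
  guide <- reverse_complement(substr(target, 11, 22))
  cand <- structure(list(
    locus_id = "x", sequence = NA,
    guide_D = list(sequence = guide, start = 0, end = 12),
    guide_Dprime = NULL), class = "cd_candidate")
  s <- predict_sites(cand, c(tgt = target))
  expect_equal(s$position, 14L) # window [10,22) -> site 10 + 4
  expect_equal(s$residue, substr(target, 15, 15))
  expect_equal(s$label, sprintf("tgt-%s15", s$residue))

  # shifting the guide window one nt toward the target 5' end shifts the
  # predicted site by one
  cand$guide_D$sequence <- reverse_complement(substr(target, 10, 21))
  s2 <- predict_sites(cand, c(tgt = target))
  expect_equal(s2$position, 13L)

  # every emitted site satisfies the +5 pairing invariant
  for (df in list(s, s2)) {
    off5 <- substr(df$guide, nchar(df$guide) - 4, nchar(df$guide) - 4)
    expect_true(paste0(off5, df$residue) %in% c("AU", "UA", "GC", "CG"))
  }
})

test_that("position maps transfer sites across alignment columns", {
  aln <- c(s1 = "AC-GU", s2 = "ACUGU")
  pm <- position_map(aln)
  expect_equal(map_position(pm, "s1", 2, "s2"), 3L) # G column
  expect_equal(map_position(pm, "s2", 2, "s1"), NA_integer_) # s1 gapped
  expect_equal(map_position(pm, "s1", 0, "s1"), 0L) # identity
  expect_error(map_position(pm, "s1", 9, "s2"), "out of range")

  # round trip whenever neither sequence is gapped at the column
  set.seed(64)
  for (r in 1:20) {
    n <- 40
    base <- random_rna_str(n)
    gap1 <- sort(sample(n, 5)); gap2 <- sort(sample(n, 5))
    s1 <- strsplit(base, "")[[1]]; s1[gap1] <- "-"
    s2 <- strsplit(base, "")[[1]]; s2[gap2] <- "-"
    pm2 <- position_map(c(a = paste(s1, collapse = ""),
                          b = paste(s2, collapse = "")))
    for (p in 0:(sum(s1 != "-") - 1)) {
      q <- map_position(pm2, "a", p, "b")
      if (!is.na(q))
        expect_equal(map_position(pm2, "b", q, "a"), p)
    }
  }
})

test_that("conservation and homolog calls follow column identity and guide identity", {
  set.seed(65)
  target <- random_rna_str(50)
  guide <- reverse_complement(substr(target, 11, 22))
  cand <- structure(list(
    locus_id = "snoX", sequence = NA,
    guide_D = list(sequence = guide, start = 0, end = 12),
    guide_Dprime = NULL), class = "cd_candidate")
  sites <- predict_sites(cand, c(LSU = target))
  # reference species identical to the nucleomorph target (columns align)
  aln <- c(LSU = target, `human:LSU` = target)
  pm <- position_map(aln)
  ref <- data.frame(species = "human", rna = "LSU",
                    position = sites$position + 1L, snorna = "SNORD99",
                    guide = guide, stringsAsFactors = FALSE)
  out <- call_conserved_and_homologs(sites, ref, pm)
  expect_true(out$conserved)
  expect_true(out$homolog)
  expect_equal(out$ref_snorna, "SNORD99")

  # different column: not conserved
  ref2 <- ref; ref2$position <- ref$position + 5L
  out2 <- call_conserved_and_homologs(sites, ref2, pm)
  expect_false(out2$conserved)

  # conserved but divergent guide: homolog flag stays off
  ref3 <- ref; ref3$guide <- random_rna_str(12)
  out3 <- call_conserved_and_homologs(sites, ref3, pm)
  if (out3$guide_identity < 0.7) expect_false(out3$homolog)

  # reference position beyond the aligned sequence: warning, row skipped
  ref4 <- ref; ref4$position <- 500L
  expect_warning(out4 <- call_conserved_and_homologs(sites, ref4, pm),
                 "outside")
  expect_false(out4$conserved)
})

test_that("rRNA-derived guides predict no sites on the planted snRNAs", {
  sim <- generate_genome(small_sim_config(seed = 66))
  tr <- sim$truth
  snrna_targets <- setNames(tr$snrnas$sequence, tr$snrnas$kind)
  g <- tr$snorna_guides
  n_sites <- 0
  for (i in seq_len(nrow(g))) {
    cand <- structure(list(
      locus_id = g$snorna[i], sequence = NA,
      guide_D = list(sequence = g$guide[i]), guide_Dprime = NULL),
      class = "cd_candidate")
    n_sites <- n_sites + nrow(predict_sites(cand, snrna_targets))
  }
  expect_equal(n_sites, 0)
})
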