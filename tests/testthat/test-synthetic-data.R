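test_that("genome generation is deterministic given the seed", {
  cfg <- small_sim_config(seed = 202)
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(a$annotation$sequences, b$annotation$sequences)
  expect_identical(a$annotation$features, b$annotation$features)
  expect_identical(a$truth$loci, b$truth$loci)
  expect_identical(a$truth$snorna_guides, b$truth$snorna_guides)
})

test_that("planted snoRNA guides obey the +5 rule by construction", {
  sim <- generate_genome(simulation_config(seed = 9, genome_length = 25000,
                                           n_cds = 8, n_planted_snorna = 1,
                                           n_planted_snrna = 0, n_orphan = 0))
  tr <- sim$truth
  expect_equal(sum(tr$loci$class == "snoRNA"), 1)
  g <- tr$snorna_guides
  expect_equal(nrow(g), 2) # D and D' guides
  for (i in seq_len(nrow(g))) {
    window <- substr(tr$targets[[g$target[i]]], g$target_start[i] + 1,
                     g$target_end[i])
    expect_identical(g$guide[i], reverse_complement(window))
    expect_equal(g$site[i], g$target_start[i] + 4L)
    # the +5 guide base is Watson-Crick paired with the site residue
    offset5 <- substr(g$guide[i], nchar(g$guide[i]) - 4,
                      nchar(g$guide[i]) - 4)
    site_res <- substr(tr$targets[[g$target[i]]], g$site[i] + 1,
                       g$site[i] + 1)
    expect_true(paste0(offset5, site_res) %in% c("AU", "UA", "GC", "CG"))
  }
})

test_that("a genome too small for the requested features is a sizing error", {
  expect_error(generate_genome(simulation_config(genome_length = 1000,
                                                 n_cds = 80)),
               "too small")
})

test_that("planted features are inside the genome and mutually disjoint", {
  sim <- generate_genome(small_sim_config(seed = 88))
  tl <- sim$truth$loci
  lens <- nchar(sim$annotation$sequences)
  expect_true(all(tl$start >= 0 & tl$end <= lens[tl$chrom]))
  for (part in split(tl, tl$chrom)) {
    part <- part[order(part$start), ]
    if (nrow(part) < 2) next
    expect_true(all(part$start[-1] >= part$end[-nrow(part)]))
  }
  # planted sequence is retrievable from the genome
  for (i in seq_len(nrow(tl))) {
    seq <- nmsrna:::extract_sequence(
      sim$annotation$sequences[[tl$chrom[i]]], tl$strand[i],
      tl$start[i], tl$end[i])
    if (tl$class[i] == "snRNA") {
      kind <- sim$truth$snrnas$kind[sim$truth$snrnas$id == tl$id[i]]
      expect_identical(seq, sim$truth$snrnas$sequence[
        sim$truth$snrnas$kind == kind])
    }
  }
})

test_that("with zero dispersion per-locus counts converge to their means", {
  cfg <- small_sim_config(seed = 41, dispersion = 0)
  sim <- generate_genome(cfg)
  reads <- simulate_libraries(sim$annotation, sim$truth)
  tl <- sim$truth$loci[sim$truth$loci$expressed &
                         sim$truth$loci$expression_class == "constitutive", ]
  un <- cfg$libraries$library_id[!cfg$libraries$te_treated]
  counts <- vapply(un, function(lb) {
    rd <- reads[[lb]]
    vapply(seq_len(nrow(tl)), function(i) {
      sel <- rd$chrom == tl$chrom[i] & rd$strand == tl$strand[i] &
        rd$start >= tl$start[i] & rd$end <= tl$end[i]
      sum(rd$count[sel])
    }, numeric(1))
  }, numeric(nrow(tl)))
  expect_lt(abs(mean(counts) - cfg$mean_depth) / cfg$mean_depth, 0.05)
})

test_that("TE retention scales library counts by 5'-end class", {
  cfg <- small_sim_config(seed = 43)
  sim <- generate_genome(cfg)
  tr <- sim$truth
  te_lib <- cfg$libraries$library_id[cfg$libraries$te_treated][1]
  sum_counts <- function(reads, ids) {
    tl <- tr$loci[tr$loci$id %in% ids, ]
    vapply(seq_len(nrow(tl)), function(i) {
      rd <- reads[[te_lib]]
      sel <- rd$chrom == tl$chrom[i] & rd$strand == tl$strand[i] &
        rd$start >= tl$start[i] & rd$end <= tl$end[i]
      sum(rd$count[sel])
    }, numeric(1))
  }
  capped_ids <- tr$loci$id[tr$loci$cap_class == "capped" & tr$loci$expressed]
  mono_ids <- tr$loci$id[tr$loci$cap_class == "monophosphate" &
                           tr$loci$expressed &
                           tr$loci$expression_class == "constitutive"]
  caps <- c(); monos <- c()
  for (r in 1:10) {
    reads <- simulate_libraries(sim$annotation, tr)
    caps <- c(caps, sum_counts(reads, capped_ids))
    monos <- c(monos, sum_counts(reads, mono_ids))
  }
  expect_lt(abs(mean(caps) - cfg$te_capped_retention * cfg$mean_depth) /
              (cfg$te_capped_retention * cfg$mean_depth), 0.08)
  expect_lt(abs(mean(monos) - cfg$te_monop_retention * cfg$mean_depth) /
              (cfg$te_monop_retention * cfg$mean_depth), 0.35)
})

test_that("the dark/light count ratio approaches the induction fold without noise", {
  cfg <- small_sim_config(seed = 44, dispersion = 0)
  sim <- generate_genome(cfg)
  tr <- sim$truth
  dark_id <- tr$loci$id[tr$loci$expression_class == "dark_induced"]
  tl <- tr$loci[tr$loci$id == dark_id, ]
  dk <- cfg$libraries$library_id[cfg$libraries$condition == "dark"]
  lt <- cfg$libraries$library_id[cfg$libraries$condition == "light" &
                                   !cfg$libraries$te_treated]
  tot_d <- tot_l <- 0
  for (r in 1:10) {
    reads <- simulate_libraries(sim$annotation, tr)
    cnt <- function(lb) {
      rd <- reads[[lb]]
      sel <- rd$chrom == tl$chrom & rd$strand == tl$strand &
        rd$start >= tl$start & rd$end <= tl$end
      sum(rd$count[sel])
    }
    tot_d <- tot_d + sum(vapply(dk, cnt, numeric(1))) / length(dk)
    tot_l <- tot_l + sum(vapply(lt, cnt, numeric(1))) / length(lt)
  }
  expect_lt(abs(tot_d / tot_l - cfg$dark_induced_fold), 0.5)
})

test_that("the truncated pseudogene is silent and rejected by the detector", {
  sim <- generate_genome(small_sim_config(seed = 45))
  tr <- sim$truth
  ps <- tr$loci[tr$loci$class == "pseudogene", ]
  expect_equal(nrow(ps), 1)
  expect_equal(ps$end - ps$start, 34L)
  expect_false(ps$expressed)
  seq <- nmsrna:::extract_sequence(sim$annotation$sequences[[ps$chrom]],
                                   ps$strand, ps$start, ps$end)
  expect_length(assemble_cd_candidates(seq), 0)
  reads <- simulate_libraries(sim$annotation, tr)
  for (rd in reads) {
    sel <- rd$chrom == ps$chrom & rd$strand == ps$strand &
      rd$start >= ps$start & rd$end <= ps$end
    expect_equal(sum(rd$count[sel]), 0)
  }
})

test_that("simulation outputs round-trip through the on-disk formats", {
  sim <- generate_genome(simulation_config(seed = 46, genome_length = 25000,
                                           n_cds = 8, n_planted_snorna = 2,
                                           n_orphan = 1))
  reads <- simulate_libraries(sim$annotation, sim$truth)
  dir <- tempfile("simout")
  manifest <- write_simulation(sim, reads, dir)
  expect_true(file.exists(file.path(dir, "genome.fasta")))
  genome <- read_fasta(file.path(dir, "genome.fasta"))
  expect_identical(as.character(genome), unname(sim$annotation$sequences))
  ann <- read_gff3(file.path(dir, "annotation.gff3"), genome)
  expect_equal(nrow(ann$features), nrow(sim$annotation$features))
  man2 <- read_manifest(file.path(dir, "manifest.tsv"))
  rd <- read_reads_bed(man2$reads_path[1])
  orig <- reads[[man2$library_id[1]]]
  expect_equal(sum(rd$count), sum(orig$count))
})
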