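four_libs <- function(reads_per_lib) {
  setNames(reads_per_lib, paste0("lib", seq_along(reads_per_lib)))
}

test_that("coverage accumulates multiplicity-weighted depth per strand", {
  ann <- tiny_annotation()
  rd <- data.frame(chrom = "chrA", strand = "+", start = 10L, end = 20L,
                   count = 3L)
  cov <- build_coverage(list(l1 = rd), ann)
  d <- cov$profiles$chrA[["+"]][, "l1"]
  expect_equal(d[11:20], rep(3, 10))
  expect_equal(sum(d), 30)
  expect_equal(sum(cov$profiles$chrA[["-"]]), 0)

  rd2 <- rbind(rd, data.frame(chrom = "chrA", strand = "+", start = 15L,
                              end = 25L, count = 1L))
  cov2 <- build_coverage(list(l1 = rd2), ann)
  expect_equal(unname(cov2$profiles$chrA[["+"]][16, "l1"]), 4)

  cov0 <- build_coverage(list(l1 = empty_reads()), ann)
  expect_equal(sum(cov0$profiles$chrA[["+"]]), 0)

  bad <- data.frame(chrom = "chrA", strand = "+", start = 990L, end = 1100L,
                    count = 1L)
  expect_error(build_coverage(list(l1 = bad), ann), "out of bounds")
})

test_that("loci require support in all libraries and exclude gene-contained peaks", {
  ann <- tiny_annotation() # CDS at [400,700)
  peak <- make_reads(100L, 140L, n = 5L)
  libs <- four_libs(list(peak, peak, peak, peak))
  cov <- build_coverage(libs, ann)
  loci <- call_loci(cov, libs, ann)
  expect_equal(nrow(loci), 1)
  expect_lte(loci$start, 100L)
  expect_gte(loci$end, 140L)

  # zero reads in one library: the peak is rejected
  libs2 <- four_libs(list(peak, peak, peak, empty_reads()))
  cov2 <- build_coverage(libs2, ann)
  expect_equal(nrow(call_loci(cov2, libs2, ann)), 0)

  # peak fully inside the CDS: rejected
  inside <- make_reads(500L, 540L, n = 5L)
  libs3 <- four_libs(list(inside, inside, inside, inside))
  cov3 <- build_coverage(libs3, ann)
  expect_equal(nrow(call_loci(cov3, libs3, ann)), 0)

  # peak overlapping the CDS 3' end by 20 nt on the plus strand
  over <- make_reads(680L, 740L, n = 5L)
  libs4 <- four_libs(list(over, over, over, over))
  cov4 <- build_coverage(libs4, ann)
  loci4 <- call_loci(cov4, libs4, ann)
  expect_equal(nrow(loci4), 1)
  expect_equal(loci4$overlap5, 20L)
  expect_equal(loci4$overlap3, 0L)

  # any overlap with an rRNA feature excludes the locus
  ann_r <- tiny_annotation(features = data.frame(
    id = "rrna1", chrom = "chrA", strand = "+", start = 120L, end = 200L,
    ftype = "rRNA"))
  cov5 <- build_coverage(libs, ann_r)
  expect_equal(nrow(call_loci(cov5, libs, ann_r)), 0)
})

test_that("overlap orientation is strand aware", {
  ann <- tiny_annotation(features = data.frame(
    id = "cds1", chrom = "chrA", strand = "+", start = 180L, end = 400L,
    ftype = "CDS"))
  loci <- data.frame(locus = "L1", chrom = "chrA", strand = "+",
                     start = 100L, end = 200L)
  out <- classify_overlaps(loci, ann)
  expect_equal(out$overlap3, 20L)
  expect_equal(out$overlap5, 0L)

  loci$strand <- "-"
  out2 <- classify_overlaps(loci, ann)
  expect_equal(out2$overlap5, 20L)
  expect_equal(out2$overlap3, 0L)

  loci_far <- data.frame(locus = "L1", chrom = "chrA", strand = "+",
                         start = 700L, end = 800L)
  ann0 <- tiny_annotation(features = data.frame(
    id = "cds1", chrom = "chrA", strand = "+", start = 10L, end = 60L,
    ftype = "CDS"))
  out3 <- classify_overlaps(loci_far, ann0)
  expect_equal(out3$overlap5 + out3$overlap3, 0L)
})

test_that("raising the depth threshold never increases the locus count", {
  set.seed(31)
  sim <- generate_genome(small_sim_config(seed = 31))
  reads <- simulate_libraries(sim$annotation, sim$truth)
  cov <- build_coverage(reads, sim$annotation)
  n_prev <- Inf
  for (dm in c(2, 3, 6, 12, 40)) {
    n <- nrow(call_loci(cov, reads, sim$annotation,
                        locus_params(depth_min = dm)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("called loci are pairwise disjoint and satisfy retention predicates", {
  set.seed(32)
  sim <- generate_genome(small_sim_config(seed = 32))
  reads <- simulate_libraries(sim$annotation, sim$truth)
  cov <- build_coverage(reads, sim$annotation)
  pars <- locus_params()
  loci <- call_loci(cov, reads, sim$annotation, pars)
  expect_gt(nrow(loci), 0)
  for (key in split(loci, paste(loci$chrom, loci$strand))) {
    if (nrow(key) < 2) next
    key <- key[order(key$start), ]
    expect_true(all(key$start[-1] >= key$end[-nrow(key)]))
  }
  expect_true(all(loci$end - loci$start >= pars$min_locus_len))
  for (i in seq_len(nrow(loci))) {
    sup <- vapply(reads, function(rd) {
      sel <- rd$chrom == loci$chrom[i] & rd$strand == loci$strand[i] &
        rd$start < loci$end[i] & rd$end > loci$start[i]
      sum(rd$count[sel])
    }, numeric(1))
    expect_true(all(sup >= pars$support_min))
    expect_false(loci$contained_in_gene[i])
  }
})

test_that("cap status thresholds the TE / untreated signal ratio", {
  ann <- tiny_annotation()
  loci <- data.frame(locus = "L1", chrom = "chrA", strand = "+",
                     start = 100L, end = 140L)
  peak <- make_reads(100L, 140L, n = 10L)
  man <- tiny_manifest(c("un1", "te1"), te = c(FALSE, TRUE))

  eq <- infer_cap_status(loci, list(un1 = peak, te1 = peak), man)
  expect_equal(eq$cap_status, "capped-like") # r = 1

  zero <- infer_cap_status(loci, list(un1 = peak, te1 = empty_reads()), man)
  expect_equal(zero$cap_status, "monophosphate-like") # r = 0

  man0 <- tiny_manifest(c("un1", "un2"))
  expect_warning(
    amb <- infer_cap_status(loci, list(un1 = peak, un2 = peak), man0),
    "no TE-treated")
  expect_equal(amb$cap_status, "ambiguous")
})

test_that("a simulated capped locus is called capped-like almost always", {
  sim <- generate_genome(simulation_config(seed = 7, genome_length = 30000,
                                           n_cds = 10, n_planted_snorna = 2,
                                           n_orphan = 2))
  tr <- sim$truth
  capped <- tr$loci[tr$loci$cap_class == "capped" & tr$loci$expressed, ][1, ]
  loci <- data.frame(locus = "cap", chrom = capped$chrom,
                     strand = capped$strand, start = capped$start,
                     end = capped$end)
  man <- tr$config$libraries
  man$reads_path <- NA_character_
  ok <- 0
  n_sim <- 200
  for (r in seq_len(n_sim)) {
    reads <- simulate_libraries(sim$annotation, tr)
    st <- infer_cap_status(loci, reads, man)$cap_status
    ok <- ok + (st == "capped-like")
  }
  expect_gte(ok / n_sim, 0.95)
})
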