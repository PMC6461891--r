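two_locus_cm <- function(counts, lengths = c(100L, 200L),
                         lib_sizes = NULL) {
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  structure(list(counts = counts,
                 lengths = setNames(lengths, rownames(counts)),
                 lib_sizes = setNames(lib_sizes, colnames(counts))),
            class = "count_matrix")
}

test_that("reads are assigned to loci by the 50% overlap rule", {
  loci <- data.frame(locus = "L1", chrom = "chrA", strand = "+",
                     start = 100L, end = 200L)
  reads <- list(lib1 = data.frame(
    chrom = "chrA", strand = "+",
    start = c(120L, 60L, 150L), end = c(150L, 160L, 250L),
    count = c(1L, 1L, 5L)))
  # read 2: 60 of 100 nt inside -> counted; read 3: 50 of 100 -> counted
  cm <- quantify(loci, reads)
  expect_equal(unname(cm$counts[1, 1]), 7)

  reads40 <- list(lib1 = data.frame(
    chrom = "chrA", strand = "+", start = 60L, end = 160L, count = 1L))
  # 60 of 100 nt inside: counted; shrink overlap below half:
  reads39 <- list(lib1 = data.frame(
    chrom = "chrA", strand = "+", start = 61L, end = 161L, count = 1L))
  expect_equal(unname(quantify(loci, reads40)$counts[1, 1]), 1)
  reads_small <- list(lib1 = data.frame(
    chrom = "chrA", strand = "+", start = 20L, end = 140L, count = 1L))
  # 40 of 120 nt (33%) inside: not counted
  expect_equal(unname(quantify(loci, reads_small)$counts[1, 1]), 0)
  # strand mismatch is never counted
  reads_minus <- list(lib1 = data.frame(
    chrom = "chrA", strand = "-", start = 120L, end = 150L, count = 3L))
  expect_equal(unname(quantify(loci, reads_minus)$counts[1, 1]), 0)
})

test_that("CPM and TPM follow their definitions", {
  counts <- matrix(c(10L, 10L), nrow = 2, ncol = 1,
                   dimnames = list(c("a", "b"), "l1"))
  cm <- two_locus_cm(counts, lengths = c(100L, 200L),
                     lib_sizes = c(l1 = 1000))
  cpm <- normalize_counts(cm, "cpm")
  expect_equal(unname(cpm["a", 1]), 10000) # 10 / 1000 * 1e6
  tpm <- normalize_counts(cm, "tpm")
  expect_equal(unname(tpm["a", 1] / tpm["b", 1]), 2) # length 100 vs 200
  expect_equal(unname(colSums(tpm)), 1e6)

  cm0 <- two_locus_cm(matrix(0L, 2, 1, dimnames = list(c("a", "b"), "l1")))
  expect_error(normalize_counts(cm0, "cpm"), "zero library size")
})

test_that("the Welch engine reproduces the pseudocount fold change", {
  counts <- matrix(c(10, 10, 10, 60, 60, 60), nrow = 1,
                   dimnames = list("L1", paste0("lib", 1:6)))
  cm <- two_locus_cm(counts, lengths = 50L, lib_sizes = rep(1e6, 6))
  man <- data.frame(library_id = paste0("lib", 1:6),
                    condition = rep(c("light", "dark"), each = 3),
                    replicate = rep(1:3, 2), te_treated = FALSE,
                    reads_path = NA)
  de <- test_de(cm, man, method = "welch")
  expect_equal(de$log2fc, log2(60.5 / 10.5), tolerance = 1e-12)
  expect_true(de$de_flag) # zero within-group variance, huge shift

  counts2 <- matrix(rep(25, 6), nrow = 1,
                    dimnames = list("L1", paste0("lib", 1:6)))
  cm2 <- two_locus_cm(counts2, lengths = 50L, lib_sizes = rep(1e6, 6))
  de2 <- test_de(cm2, man, method = "welch")
  expect_equal(de2$log2fc, 0)
  expect_false(de2$de_flag)

  man_thin <- man[c(1, 4, 5, 6), ]
  cm3 <- two_locus_cm(counts[, c(1, 4, 5, 6), drop = FALSE],
                      lengths = 50L, lib_sizes = rep(1e6, 4))
  expect_error(test_de(cm3, man_thin), "2 untreated replicates")
})

test_that("BH adjustment is monotone, dominates p, and matches the step-up rule", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(81)
  sim <- generate_genome(small_sim_config(seed = 81, replicates = 3))
  reads <- simulate_libraries(sim$annotation, sim$truth)
  tl <- sim$truth$loci[sim$truth$loci$expressed, ]
  tl$locus <- tl$id
  man <- sim$truth$config$libraries
  man$reads_path <- NA
  de <- test_de(quantify(tl, reads), man)
  expect_true(all(de$q >= de$p - 1e-12))
  ord <- order(de$p)
  expect_true(all(diff(de$q[ord]) >= -1e-12))
  expect_equal(de$de_flag, abs(de$log2fc) >= 1.3 & de$q < 0.05)
})

test_that("the planted dark-induced locus is the one flagged", {
  set.seed(82)
  sim <- generate_genome(small_sim_config(seed = 82, replicates = 3))
  tr <- sim$truth
  reads <- simulate_libraries(sim$annotation, tr)
  tl <- tr$loci[tr$loci$expressed, ]
  tl$locus <- tl$id
  man <- tr$config$libraries
  man$reads_path <- NA
  de <- test_de(quantify(tl, reads), man)
  dark_id <- tr$loci$id[tr$loci$expression_class == "dark_induced"]
  expect_true(de$de_flag[de$locus == dark_id])
  expect_gte(de$log2fc[de$locus == dark_id], 1.3)
})

test_that("permuting condition labels yields almost no flagged loci", {
  set.seed(83)
  sim <- generate_genome(small_sim_config(seed = 83, replicates = 3))
  tr <- sim$truth
  reads <- simulate_libraries(sim$annotation, tr)
  tl <- tr$loci[tr$loci$expressed, ]
  tl$locus <- tl$id
  man <- tr$config$libraries
  man$reads_path <- NA
  un <- which(!man$te_treated)
  # swap one replicate between conditions: the contrast becomes null-ish
  man$condition[un] <- c("light", "dark", "light", "dark", "light", "dark")
  de <- test_de(quantify(tl, reads), man)
  expect_lte(mean(de$de_flag), 0.05)
})
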