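toy_cm <- function(counts, lens = NULL, lib = NULL) {
  ng <- nrow(counts)
  if (is.null(lens)) lens <- stats::setNames(rep(1000, ng), rownames(counts))
  meta <- data.frame(genotype = "g", treatment = rep(c("pre", "post"),
                                                     length.out = ncol(counts)),
                     replicate = seq_len(ncol(counts)))
  rownames(meta) <- colnames(counts)
  count_matrix(counts, lens, meta, library_sizes = lib)
}

test_that("fpkm implements the formula and its scaling identities", {
  counts <- matrix(100, 1, 1, dimnames = list("g1", "s1"))
  cm <- toy_cm(counts, lens = c(g1 = 2000), lib = 1e6)
  expect_equal(unname(fpkm(cm)[1, 1]), 50)
  counts0 <- matrix(c(0, 10), 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(fpkm(toy_cm(counts0, lib = c(1e6, 1e6)))[1, 1]), 0)
  # random matrix against an elementwise oracle
  set.seed(8)
  counts <- matrix(rpois(200 * 6, 50), 200, 6,
                   dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:6)))
  lens <- stats::setNames(sample(500:3000, 200), rownames(counts))
  lib <- stats::setNames(runif(6, 5e5, 2e6), colnames(counts))
  cm <- toy_cm(counts, lens, lib)
  fp <- fpkm(cm)
  for (i in sample(200, 20)) for (j in 1:6) {
    expect_equal(fp[i, j], counts[i, j] * 1e9 / (lens[[i]] * lib[[j]]))
  }
  # doubling gene length halves FPKM exactly; row order is immaterial
  cm2 <- toy_cm(counts, lens * 2, lib)
  expect_equal(fpkm(cm2), fp / 2)
  perm <- sample(200)
  cmp <- toy_cm(counts[perm, ], lens[perm], lib)
  expect_equal(fpkm(cmp), fp[perm, ])
  expect_error(count_matrix(counts, lens, cm$meta,
                            library_sizes = c(0, lib[-1])), "positive")
})

test_that("the expressed-gene filter requires all replicates in >= 1 treatment", {
  expr <- rbind(
    g1 = c(5, 5, 5, 0, 0, 0),     # kept: all pre replicates pass
    g2 = c(5, 5, 4.9, 5, 5, 4.9), # dropped: no group has all replicates >= 5
    g3 = c(0, 0, 0, 6, 7, 8))     # kept via post
  colnames(expr) <- sprintf("s%d", 1:6)
  groups <- rep(c("pre", "post"), each = 3)
  expect_setequal(filter_expressed(expr, groups, 5), c("g1", "g3"))
  expect_error(filter_expressed(expr, c(groups[-1], NA), 5), "missing group")
  # random matrices vs a brute-force set-comprehension oracle
  set.seed(12)
  for (rep in 1:10) {
    m <- matrix(runif(50 * 6, 0, 12), 50, 6,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
    keep <- filter_expressed(m, groups, 5)
    oracle <- rownames(m)[vapply(seq_len(nrow(m)), function(i) {
      any(vapply(unique(groups), function(g) all(m[i, groups == g] >= 5), logical(1)))
    }, logical(1))]
    expect_setequal(keep, oracle)
  }
})

test_that("BH adjustment matches hand values and a brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(19)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
  # and against R's reference implementation on larger vectors
  p <- runif(5000)
  expect_equal(bh_fdr(p), p.adjust(p, "BH"))
})

test_that("partition_sets does the unique/common/opposite set algebra", {
  deA <- de_table(c("g1", "g2", "g3"), c(2, 1.5, 0.3), c(0.001, 0.002, 0.5))
  deB <- de_table(c("g1", "g2", "g3"), c(-1, 2, -2), c(0.9, 0.001, 0.004))
  expressed <- c("g1", "g2", "g3")
  ps <- partition_sets(deA, deB, expressed, expressed)
  expect_equal(ps$per_genotype$n_unique, c(1L, 1L))
  expect_equal(ps$shared$n_common, 1L)
  expect_equal(ps$shared$n_opposite, 0L)
  expect_equal(ps$shared$n_common_up, 1L)
  # flip B's g2 downward -> opposite
  deB2 <- de_table(c("g1", "g2", "g3"), c(-1, -2, -2), c(0.9, 0.001, 0.004))
  ps2 <- partition_sets(deA, deB2, expressed, expressed)
  expect_equal(ps2$shared$n_opposite, 1L)
})

test_that("partition reconciliation identities hold on random toy DE tables", {
  set.seed(31)
  for (i in 1:20) {
    genes <- sprintf("g%03d", 1:500)
    deA <- de_table(genes, rnorm(500), runif(500)^2)
    deB <- de_table(genes, rnorm(500), runif(500)^2)
    exA <- sample(genes, 400); exB <- sample(genes, 400)
    ps <- partition_sets(deA, deB, exA, exB)
    union_sig <- union(ps$sets$significant_A, ps$sets$significant_B)
    expect_equal(ps$per_genotype$n_unique[1] + ps$per_genotype$n_unique[2] +
                   ps$shared$n_common, length(union_sig))
    expect_equal(ps$shared$n_common,
                 ps$shared$n_common_up + ps$shared$n_common_down + ps$shared$n_opposite)
    # oracle: exhaustive set enumeration
    sigA <- deA$gene[deA$fdr <= 0.05 & deA$gene %in% exA]
    sigB <- deB$gene[deB$fdr <= 0.05 & deB$gene %in% exB]
    expect_setequal(ps$sets$common, intersect(sigA, sigB))
    expect_setequal(ps$sets$unique_A, setdiff(sigA, sigB))
    fa <- stats::setNames(deA$log2fc, deA$gene); fb <- stats::setNames(deB$log2fc, deB$gene)
    expect_setequal(ps$sets$opposite,
                    intersect(sigA, sigB)[sign(fa[intersect(sigA, sigB)]) !=
                                            sign(fb[intersect(sigA, sigB)])])
  }
})

test_that("estimate_fold is exact on means and recovers programmed folds", {
  expr <- matrix(c(32, 32, 32, 2, 2, 2), 1, 6,
                 dimnames = list("flc", sprintf("s%d", 1:6)))
  groups <- rep(c("winter", "summer"), each = 3)
  ef <- estimate_fold(expr, "flc", groups)
  expect_equal(ef$fold, 16)
  expect_equal(ef$numerator, "winter")
  expect_equal(estimate_fold(expr * 0 + 7, "flc", groups)$fold, 1)
  zero <- matrix(c(3, 3, 3, 0, 0, 0), 1, 6, dimnames = dimnames(expr))
  ez <- estimate_fold(zero, "flc", groups, numerator = "winter")
  expect_true(ez$infinite)
  # simulation: a single-draw estimate at dispersion 0.1 / n = 3 has ~28%
  # log-scale sd, so recovery is asserted on the geometric mean over 31
  # independent draws (sd ~5%), well inside the 20% band
  log_folds <- vapply(1:31, function(s) {
    eff <- list(flc = matrix(c(1, 8, 1, 1), 2, 2,
                             dimnames = list(c("summer", "winter"), c("pre", "post"))))
    cm <- simulate_rnaseq_counts(effects = eff, n_background = 20,
                                 dispersion = 0.1, seed = 100 + s)
    fp <- fpkm(cm)
    sel <- cm$meta$treatment == "pre"
    log(estimate_fold(fp[, sel, drop = FALSE], "flc", cm$meta$genotype[sel],
                      numerator = "winter")$fold)
  }, numeric(1))
  expect_lt(abs(exp(mean(log_folds)) - 8) / 8, 0.2)
})

test_that("the stand-in DE test flags programmed effects and not nulls", {
  eff <- list(hit = matrix(c(1, 1, 8, 1), 2, 2,
                           dimnames = list(c("summer", "winter"), c("pre", "post"))))
  cm <- simulate_rnaseq_counts(effects = eff, n_background = 100, seed = 77)
  de <- de_test(cm, "summer")
  expect_s3_class(de, "de_table")
  expect_lt(de$fdr[de$gene == "hit"], 0.05)
  expect_gt(de$log2fc[de$gene == "hit"], 2)  # programmed log2 fold = 3
  # null genes are mostly non-significant
  expect_lt(mean(de$fdr[de$gene != "hit"] < 0.05), 0.1)
  expect_true(all(de$fdr >= de$pvalue - 1e-12))
})

test_that("count matrices roundtrip through the CSV pair", {
  cm <- simulate_rnaseq_counts(n_background = 30, seed = 5)
  stem <- file.path(withr::local_tempdir(), "rna")
  write_count_matrix(cm, stem)
  back <- read_count_matrix(paste0(stem, "_counts.csv"), paste0(stem, "_meta.csv"))
  expect_equal(back$counts, cm$counts)
  expect_equal(back$gene_lengths, cm$gene_lengths)
  expect_equal(back$library_sizes, cm$library_sizes)
  expect_equal(back$meta$treatment, cm$meta$treatment)
})
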