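# Expression quantification and filtering: FPKM, the expressed-gene filter
# (FPKM >= threshold in every replicate of at least one treatment),
# Benjamini-Hochberg FDR, the unique/common/opposite set partition of two
# genotypes' differential-expression results, and group fold-change
# estimation. Differential-test p-values are an input; a simple
# overdispersed-Poisson stand-in test is provided for synthetic pipelines.

#' Bundle a gene-by-sample count matrix with lengths and sample metadata
#'
#' @param counts Integer matrix, genes in rows, samples in columns; dimnames
#'   required.
#' @param gene_lengths Named numeric, bp per gene (matching rownames).
#' @param meta Data frame with one row per sample (matching colnames) and at
#'   least columns `genotype`, `treatment`, `replicate`.
#' @param library_sizes Total mapped fragments per sample; defaults to
#'   column sums.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, gene_lengths, meta, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  gene_lengths <- gene_lengths[rownames(counts)]
  if (anyNA(gene_lengths) || any(gene_lengths <= 0)) {
    stop("gene_lengths must cover all genes and be positive", call. = FALSE)
  }
  meta <- as.data.frame(meta)
  if (!is.null(rownames(meta)) && !identical(rownames(meta), as.character(seq_len(nrow(meta))))) {
    meta <- meta[colnames(counts), , drop = FALSE]
  }
  if (nrow(meta) != ncol(counts)) stop("meta rows must match samples", call. = FALSE)
  need <- c("genotype", "treatment", "replicate")
  if (!all(need %in% colnames(meta))) {
    stop("meta must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  rownames(meta) <- colnames(counts)
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  library_sizes <- stats::setNames(as.numeric(library_sizes), colnames(counts))
  if (any(library_sizes <= 0)) stop("library sizes must be positive", call. = FALSE)
  structure(list(counts = counts, gene_lengths = gene_lengths, meta = meta,
                 library_sizes = library_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `FPKM[g, s] = counts[g, s] * 1e9 / (length[g] * library_size[s])`.
#'
#' @param cm A [count_matrix()].
#' @return Numeric matrix of the same shape as the counts.
#' @examples
#' # 100 fragments on a 2 kb transcript in a 1e6-fragment library -> FPKM 50
#' @export
fpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  sweep(sweep(cm$counts, 1, cm$gene_lengths, "/"), 2, cm$library_sizes, "/") * 1e9
}

#' Expressed-gene filter
#'
#' A gene is kept iff, within at least one treatment group, its expression
#' is at or above `threshold` in every replicate of that group.
#'
#' @param expr FPKM (or other expression) matrix, genes x samples.
#' @param groups Treatment group label per sample (character/factor).
#' @param threshold Expression floor (default 5 FPKM).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(expr, groups, threshold = 5) {
  expr <- as.matrix(expr)
  if (length(groups) != ncol(expr)) stop("one group label per sample required", call. = FALSE)
  if (anyNA(groups)) stop("missing group labels", call. = FALSE)
  groups <- as.character(groups)
  keep <- rep(FALSE, nrow(expr))
  for (g in unique(groups)) {
    sub <- expr[, groups == g, drop = FALSE]
    keep <- keep | (apply(sub, 1, min) >= threshold)
  }
  rownames(expr)[keep]
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return FDR (adjusted p) vector in the input order.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]", call. = FALSE)
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Assemble a differential-expression table
#'
#' @param gene Gene ids.
#' @param log2fc Log2 fold change (post relative to pre: positive =
#'   increase post).
#' @param pvalue Per-gene p-values from any differential test.
#' @param fdr Optional pre-computed FDR; defaults to [bh_fdr()] of `pvalue`.
#' @return Data frame of class `de_table` with columns `gene`, `log2fc`,
#'   `pvalue`, `fdr`.
#' @export
de_table <- function(gene, log2fc, pvalue, fdr = NULL) {
  if (is.null(fdr)) fdr <- bh_fdr(pvalue)
  out <- data.frame(gene = as.character(gene), log2fc = as.numeric(log2fc),
                    pvalue = as.numeric(pvalue), fdr = as.numeric(fdr),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Two-group overdispersed-count test (stand-in)
#'
#' A deliberately simple per-gene two-group test for synthetic pipelines:
#' group rates are estimated as total counts over total library size, and a
#' Wald z statistic on the log rate ratio uses a negative-binomial variance
#' `mu + phi * mu^2` with fixed dispersion `phi`. It is not a replacement
#' for edgeR/DESeq2; any external per-gene p-value column can be supplied to
#' [de_table()] instead.
#'
#' @param cm A [count_matrix()].
#' @param genotype Genotype whose samples are tested (pre vs post treatment).
#' @param pre,post Treatment labels for the baseline and comparison groups.
#' @param phi Fixed dispersion used in the variance (default 0.1).
#' @param pseudo Count added to group totals to stabilize zero rates.
#' @return A [de_table()] (log2fc = post vs pre).
#' @export
de_test <- function(cm, genotype, pre = "pre", post = "post", phi = 0.1,
                    pseudo = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  sel <- cm$meta$genotype == genotype
  if (!any(sel)) stop("no samples for genotype ", genotype, call. = FALSE)
  meta <- cm$meta[sel, , drop = FALSE]
  y <- cm$counts[, sel, drop = FALSE]
  N <- cm$library_sizes[sel]
  i1 <- meta$treatment == pre
  i2 <- meta$treatment == post
  if (!any(i1) || !any(i2)) stop("need samples in both treatments", call. = FALSE)
  tot1 <- rowSums(y[, i1, drop = FALSE]) + pseudo
  tot2 <- rowSums(y[, i2, drop = FALSE]) + pseudo
  N1 <- sum(N[i1]); N2 <- sum(N[i2])
  l1 <- tot1 / N1
  l2 <- tot2 / N2
  # var(log total) ~ sum(mu_i + phi mu_i^2) / total^2 by the delta method
  v1 <- (tot1 + phi * rowSums((l1 %o% N[i1])^2)) / tot1^2
  v2 <- (tot2 + phi * rowSums((l2 %o% N[i2])^2)) / tot2^2
  z <- (log(l2) - log(l1)) / sqrt(v1 + v2)
  p <- 2 * stats::pnorm(-abs(z))
  de_table(rownames(y), log2(l2 / l1), p)
}

#' Partition two genotypes' significant genes into unique/common/opposite
#'
#' Significant = expressed and `fdr <= fdr_cut`. Genes significant in only
#' one genotype are unique to it; genes significant in both are common, and
#' common genes whose fold changes disagree in sign are opposite. The
#' `>= fold_cut`-fold classes use `|log2fc| >= log2(fold_cut)`.
#'
#' @param deA,deB [de_table()] for genotypes A and B (shared gene universe).
#' @param expressedA,expressedB Gene ids passing [filter_expressed()] in
#'   each genotype.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param fold_cut Fold-change threshold (default 2).
#' @param labels Length-2 character: display names of the two genotypes.
#' @return A `partition_summary`: `per_genotype` data frame (rows A, B) with
#'   `n_expressed`, `n_significant`, `n_up2x`, `n_down2x`, `n_unique`,
#'   `n_unique_up`, `n_unique_down`; `shared` list with `n_common`,
#'   `n_common_up`, `n_common_down`, `n_opposite`; and the underlying gene
#'   `sets`.
#' @export
partition_sets <- function(deA, deB, expressedA, expressedB,
                           fdr_cut = 0.05, fold_cut = 2,
                           labels = c("A", "B")) {
  lf <- log2(fold_cut)
  sig_set <- function(de, expressed) {
    de$gene[de$fdr <= fdr_cut & de$gene %in% expressed]
  }
  fc <- function(de) stats::setNames(de$log2fc, de$gene)
  sigA <- sig_set(deA, expressedA); sigB <- sig_set(deB, expressedB)
  fcA <- fc(deA); fcB <- fc(deB)
  common <- intersect(sigA, sigB)
  uniqA <- setdiff(sigA, sigB); uniqB <- setdiff(sigB, sigA)
  opp <- common[sign(fcA[common]) != sign(fcB[common])]
  same_up <- common[fcA[common] > 0 & fcB[common] > 0]
  same_down <- common[fcA[common] < 0 & fcB[common] < 0]
  per <- function(sig, uniq, fcv, n_expr) {
    data.frame(
      n_expressed = n_expr,
      n_significant = length(sig),
      n_up2x = sum(fcv[sig] >= lf),
      n_down2x = sum(fcv[sig] <= -lf),
      n_unique = length(uniq),
      n_unique_up = sum(fcv[uniq] > 0),
      n_unique_down = sum(fcv[uniq] < 0))
  }
  per_genotype <- rbind(per(sigA, uniqA, fcA, length(expressedA)),
                        per(sigB, uniqB, fcB, length(expressedB)))
  rownames(per_genotype) <- labels
  structure(list(
    per_genotype = per_genotype,
    shared = list(n_common = length(common),
                  n_common_up = length(same_up),
                  n_common_down = length(same_down),
                  n_opposite = length(opp)),
    sets = list(significant_A = sigA, significant_B = sigB,
                unique_A = uniqA, unique_B = uniqB,
                common = common, opposite = opp)
  ), class = "partition_summary")
}

#' @export
print.partition_summary <- function(x, ...) {
  cat("<partition_summary>\n")
  print(x$per_genotype)
  cat(sprintf("common: %d (up/up %d, down/down %d, opposite %d)\n",
              x$shared$n_common, x$shared$n_common_up,
              x$shared$n_common_down, x$shared$n_opposite))
  invisible(x)
}

#' Write a partition summary as CSV
#' @param ps A `partition_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_partition_csv <- function(ps, path) {
  per <- cbind(genotype = rownames(ps$per_genotype), ps$per_genotype)
  shared <- data.frame(genotype = "shared",
                       n_expressed = NA, n_significant = NA,
                       n_up2x = ps$shared$n_common_up,
                       n_down2x = ps$shared$n_common_down,
                       n_unique = ps$shared$n_common,
                       n_unique_up = NA, n_unique_down = ps$shared$n_opposite)
  utils::write.csv(rbind(per, stats::setNames(shared, colnames(per))), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write / read a count matrix as a CSV pair
#'
#' `<stem>_counts.csv` holds `gene`, `length` and one column per sample;
#' `<stem>_meta.csv` holds `sample`, `genotype`, `treatment`, `replicate`,
#' `library_size`.
#'
#' @param cm A [count_matrix()].
#' @param stem Output path stem.
#' @return The two paths, invisibly.
#' @export
write_count_matrix <- function(cm, stem) {
  stopifnot(inherits(cm, "count_matrix"))
  cpath <- paste0(stem, "_counts.csv")
  mpath <- paste0(stem, "_meta.csv")
  utils::write.csv(data.frame(gene = rownames(cm$counts),
                              length = cm$gene_lengths, cm$counts,
                              check.names = FALSE),
                   cpath, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(sample = rownames(cm$meta), cm$meta,
                              library_size = cm$library_sizes),
                   mpath, row.names = FALSE, quote = FALSE)
  invisible(c(cpath, mpath))
}

#' @rdname write_count_matrix
#' @param counts_path,meta_path Paths written by `write_count_matrix`.
#' @export
read_count_matrix <- function(counts_path, meta_path) {
  cdf <- utils::read.csv(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  mdf <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  counts <- as.matrix(cdf[, setdiff(colnames(cdf), c("gene", "length")), drop = FALSE])
  rownames(counts) <- cdf$gene
  lens <- stats::setNames(cdf$length, cdf$gene)
  meta <- mdf[, c("genotype", "treatment", "replicate"), drop = FALSE]
  rownames(meta) <- mdf$sample
  count_matrix(counts[, mdf$sample, drop = FALSE], lens, meta,
               library_sizes = stats::setNames(mdf$library_size, mdf$sample))
}

#' Fold change between two sample groups for one gene
#'
#' Ratio of group-mean expression (FPKM) for a single gene.
#'
#' @param expr Expression matrix, genes x samples.
#' @param gene Gene id (must be a rowname of `expr`).
#' @param groups Group label per sample; exactly two distinct labels.
#' @param numerator Which group goes on top; `NULL` (default) puts the
#'   higher group mean in the numerator so the fold is >= 1.
#' @return List with `fold`, `group_means`, `numerator`, `denominator`, and
#'   `infinite` flag (zero denominator).
#' @export
estimate_fold <- function(expr, gene, groups, numerator = NULL) {
  expr <- as.matrix(expr)
  if (!gene %in% rownames(expr)) stop("unknown gene: ", gene, call. = FALSE)
  groups <- as.character(groups)
  if (length(groups) != ncol(expr)) stop("one group label per sample required", call. = FALSE)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups required", call. = FALSE)
  means <- vapply(lv, function(g) mean(expr[gene, groups == g]), numeric(1))
  if (is.null(numerator)) numerator <- lv[which.max(means)]
  if (!numerator %in% lv) stop("numerator must be one of the groups", call. = FALSE)
  denominator <- setdiff(lv, numerator)
  fold <- means[numerator] / means[denominator]
  list(fold = unname(fold), group_means = means,
       numerator = numerator, denominator = denominator,
       infinite = !is.finite(fold))
}
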