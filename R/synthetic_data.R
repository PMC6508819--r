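# Seeded generators for every input the pipeline consumes: homeologous
# paralog references diverged from a common ancestor, deletion genotypes as
# allele pools, short reads with substitution errors, clone sets sampled
# proportional to transcript abundance, negative-binomial RNA-seq count
# matrices with genotype x treatment fold effects, and logistic growth
# trajectories with Gaussian noise. Every generator is a pure function of
# its arguments and seed: reruns are identical.

.STAGE_OFFSETS <- c(paralogs = 101L, genotype = 202L, reads = 303L,
                    rnaseq = 404L, clones = 505L, growth = 606L)

#' Derive a per-stage substream seed from one global seed
#'
#' Keeps independently rerunnable stages reproducible under a single seed.
#' Result stays below 2^31.
#'
#' @param seed Global integer seed.
#' @param stage One of `"paralogs"`, `"genotype"`, `"reads"`, `"rnaseq"`,
#'   `"clones"`, `"growth"`.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  off <- .STAGE_OFFSETS[[match.arg(stage, names(.STAGE_OFFSETS))]]
  as.integer((as.double(seed) * 2654435.0 + off * 97.0) %% 2147483629)
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

.mutate_sites <- function(chars, idx) {
  if (length(idx) == 0L) return(chars)
  bases <- c("A", "C", "G", "T")
  cur <- chars[idx]
  # shift each hit base by 1-3 positions in the base cycle: always different
  shift <- sample.int(3L, length(idx), replace = TRUE)
  chars[idx] <- bases[((match(cur, bases) - 1L + shift) %% 4L) + 1L]
  chars
}

#' Simulate a set of homeologous paralog references
#'
#' One random ancestor sequence is mutated independently into each paralog:
#' exactly `round(divergence / 2 * sequence_length)` sites per paralog
#' (uniformly placed, each to a different base), so that the realized
#' pairwise divergence concentrates tightly around the requested value
#' (only the small overlap between the two site sets is random).
#'
#' @param n_paralogs Number of paralogs (>= 2, default 3).
#' @param sequence_length Reference length in bp (default 2000).
#' @param divergence Target pairwise divergence, in `[0, 0.25)`; default
#'   0.05 (5-10% is typical of homeologous subgenomes).
#' @param seed Integer seed.
#' @param ids Paralog ids; default `chr1..chrN`-style labels.
#' @param copies_per_paralog,alleles_per_copy Passed to [homeolog_set()].
#' @return A [homeolog_set()].
#' @export
make_paralogs <- function(n_paralogs = 3L, sequence_length = 2000L,
                          divergence = 0.05, seed = 1L, ids = NULL,
                          copies_per_paralog = 1L, alleles_per_copy = 2L) {
  if (divergence < 0 || divergence >= 0.25) {
    stop("divergence must be in [0, 0.25)", call. = FALSE)
  }
  if (sequence_length < 20L) stop("sequence_length too short", call. = FALSE)
  if (is.null(ids)) ids <- paste0("chr", seq_len(n_paralogs) * 4L)
  stopifnot(length(ids) == n_paralogs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  anc <- strsplit(.random_dna(sequence_length), "")[[1]]
  n_mut <- round(divergence / 2 * sequence_length)
  paralogs <- lapply(ids, function(id) {
    hit <- sample.int(sequence_length, n_mut)
    nuc_seq(paste(.mutate_sites(anc, hit), collapse = ""), id = id)
  })
  names(paralogs) <- ids
  homeolog_set(paralogs, copies_per_paralog, alleles_per_copy)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Mean pairwise divergence between paralogs of equal length
#' @param refs A [homeolog_set()].
#' @return Numeric matrix of pairwise mismatch fractions.
#' @export
pairwise_divergence <- function(refs) {
  stopifnot(inherits(refs, "homeolog_set"))
  seqs <- lapply(refs$paralogs, function(x) strsplit(x$seq, "")[[1]])
  n <- length(seqs)
  out <- matrix(0, n, n, dimnames = list(names(refs$paralogs), names(refs$paralogs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    out[i, j] <- out[j, i] <- mean(seqs[[i]] != seqs[[j]])
  }
  out
}

#' Parse a copy-configuration label into a genotype
#'
#' Each token describes one gene copy: `"TT"` = homozygous reference,
#' `"T-"` = heterozygous, `"-"` or `"--"` = homozygous deletion (any of the
#' common dash characters is accepted). For example, with three copies,
#' `"(-,-,TT)"` has deletion fraction 4/6 and `"(TT,TT,T-)"` has 1/6.
#'
#' @param x Configuration string, e.g. `"(TT,TT,T-)"`, or a character vector
#'   of per-copy tokens.
#' @return A `genotype_config`: `copies` (list of 2-vectors over
#'   `REF`/`DEL`), `n_del`, `m`, `deletion_fraction`, `label`.
#' @export
genotype_config <- function(x) {
  if (length(x) == 1L && grepl("[(),]", x)) {
    x <- strsplit(gsub("[()\\s]", "", x, perl = TRUE), ",")[[1]]
  }
  x <- trimws(x)
  dash <- "[-‐‒–—−]"
  copies <- lapply(x, function(tok) {
    tok <- gsub(dash, "-", tok)
    if (!grepl("^[T-]{1,2}$", tok)) stop("bad copy token: ", tok, call. = FALSE)
    if (nchar(tok) == 1L) tok <- strrep(tok, 2L)  # "-" means -/- ; "T" means T/T
    ifelse(strsplit(tok, "")[[1]] == "T", "REF", "DEL")
  })
  n_del <- sum(vapply(copies, function(cp) sum(cp == "DEL"), integer(1)))
  m <- 2L * length(copies)
  structure(list(copies = copies, n_del = n_del, m = m,
                 deletion_fraction = n_del / m,
                 label = paste0("(", paste(x, collapse = ","), ")")),
            class = "genotype_config")
}

#' @export
print.genotype_config <- function(x, ...) {
  cat(sprintf("<genotype_config> %s: %d of %d alleles deleted (fraction %.3f)\n",
              x$label, x$n_del, x$m, x$deletion_fraction))
  invisible(x)
}

#' Expand a genotype into the allele pool of the target paralog
#'
#' @param refs A [homeolog_set()].
#' @param target Paralog id carrying the segregating deletion.
#' @param variant A [deletion_spec()] in target coordinates.
#' @param config A [genotype_config()] (or its label string); its copy count
#'   must match `refs$copies_per_paralog` when that is > 1, otherwise the
#'   config defines the copy count of the locus.
#' @return Named list of `m` allele [nuc_seq()]s; `DEL` alleles carry the
#'   deletion. Attributes: `allele` (REF/DEL per sequence),
#'   `deletion_fraction`.
#' @export
apply_genotype <- function(refs, target, variant, config) {
  stopifnot(inherits(refs, "homeolog_set"))
  if (is.character(config)) config <- genotype_config(config)
  stopifnot(inherits(config, "genotype_config"))
  if (!target %in% names(refs$paralogs)) stop("unknown target: ", target, call. = FALSE)
  ref <- refs$paralogs[[target]]
  alt <- apply_deletion(ref, variant)
  pool <- list()
  lab <- character(0)
  for (ci in seq_along(config$copies)) {
    for (ai in 1:2) {
      allele <- config$copies[[ci]][ai]
      s <- if (allele == "DEL") alt else ref
      nm <- sprintf("%s_copy%d_allele%d_%s", target, ci, ai, allele)
      pool[[nm]] <- nuc_seq(s$seq, id = nm)
      lab <- c(lab, allele)
    }
  }
  attr(pool, "allele") <- lab
  attr(pool, "deletion_fraction") <- config$deletion_fraction
  pool
}

.sim_reads_from_templates <- function(templates, weights, n_reads, read_length,
                                      error_rate) {
  lens <- vapply(templates, nchar, integer(1))
  if (any(lens < read_length)) stop("read_length exceeds a template length", call. = FALSE)
  idx <- sample.int(length(templates), n_reads, replace = TRUE,
                    prob = weights)
  starts <- floor(stats::runif(n_reads) * (lens[idx] - read_length + 1)) + 1L
  reads <- substring(templates[idx], starts, starts + read_length - 1L)
  flip <- stats::runif(n_reads) < 0.5
  if (any(flip)) {
    reads[flip] <- vapply(reads[flip],
                          function(s) reverse_complement(s)$seq, character(1),
                          USE.NAMES = FALSE)
  }
  if (error_rate > 0 && n_reads > 0) {
    chars <- matrix(unlist(strsplit(reads, ""), use.names = FALSE),
                    nrow = read_length)
    hit <- which(stats::runif(length(chars)) < error_rate)
    chars[hit] <- .mutate_sites(chars[hit], seq_along(hit))
    reads <- apply(chars, 2, paste, collapse = "")
  }
  names(reads) <- sprintf("read%06d tpl=%s", seq_len(n_reads),
                          names(templates)[idx])
  reads
}

#' Simulate short reads from an allele pool plus background paralogs
#'
#' Read templates are the `m` allele sequences of the target locus (equal
#' copy weight each, or `copy_weights` if supplied) plus every non-target
#' paralog weighted by its own allele count, so homeologous background reads
#' are present just as in real data. Read start positions are uniform,
#' strand is a fair coin, and substitution errors are i.i.d. per base (no
#' simulated indels: an indel error model would confound the deletion-probe
#' signal this pipeline is designed to detect).
#'
#' @param pool Allele pool from [apply_genotype()].
#' @param refs The [homeolog_set()]; non-target paralogs are used as
#'   background templates. `NULL` restricts reads to the pool.
#' @param target Target paralog id (excluded from the background).
#' @param n_reads Number of reads to draw.
#' @param read_length Read length in bp (default 100).
#' @param error_rate Per-base substitution error probability (default 0.005).
#' @param copy_weights Optional per-allele weight vector (length m) to model
#'   copy-specific abundance bias; default equal weights.
#' @param seed Integer seed.
#' @return Named character vector of reads (template recorded in the name).
#' @export
simulate_reads <- function(pool, refs = NULL, target = NULL, n_reads,
                           read_length = 100L, error_rate = 0.005,
                           copy_weights = NULL, seed = 1L) {
  templates <- vapply(pool, function(x) x$seq, character(1))
  weights <- if (is.null(copy_weights)) rep(1, length(templates)) else copy_weights
  stopifnot(length(weights) == length(templates))
  if (!is.null(refs)) {
    stopifnot(inherits(refs, "homeolog_set"))
    m <- allele_count(refs)
    for (id in setdiff(names(refs$paralogs), target)) {
      templates[[id]] <- refs$paralogs[[id]]$seq
      weights <- c(weights, m)
    }
  }
  if (n_reads == 0L) return(stats::setNames(character(0), character(0)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  .sim_reads_from_templates(templates, weights, n_reads, read_length, error_rate)
}

#' Simulate a negative-binomial RNA-seq count matrix
#'
#' Emulates a 2-genotype x 2-treatment x n-replicate design. Expected counts
#' are `baseline_fpkm * fold * length_kb * library_size / 1e6`, so FPKM
#' computed from the result recovers the programmed baselines and folds up
#' to sampling noise; counts are NB with the given dispersion.
#'
#' @param effects Named list: gene id -> 2x2 fold matrix with
#'   `dimnames = list(genotypes, treatments)`. These genes are added on top
#'   of the background.
#' @param n_background Background genes at fold 1 everywhere (default 200).
#' @param baseline_fpkm Baseline expression of effect genes (default 50);
#'   background baselines are drawn log-uniform in [1, 100].
#' @param genotypes,treatments Factor levels of the design.
#' @param n_replicates Replicates per cell (default 3).
#' @param dispersion NB dispersion `phi` (`var = mu + phi mu^2`), default 0.1.
#' @param library_size Fragments per sample (default 1e6).
#' @param gene_length_range Gene lengths drawn uniformly in this bp range.
#' @param seed Integer seed.
#' @return A [count_matrix()]; the programmed truth is attached as
#'   attribute `truth`.
#' @export
simulate_rnaseq_counts <- function(effects = list(),
                                   n_background = 200L,
                                   baseline_fpkm = 50,
                                   genotypes = c("summer", "winter"),
                                   treatments = c("pre", "post"),
                                   n_replicates = 3L,
                                   dispersion = 0.1,
                                   library_size = 1e6,
                                   gene_length_range = c(500L, 3000L),
                                   seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  eff_genes <- names(effects)
  bg_genes <- if (n_background > 0L) sprintf("gene%04d", seq_len(n_background)) else character(0)
  genes <- c(eff_genes, bg_genes)
  n_genes <- length(genes)
  if (n_genes == 0L) stop("no genes to simulate", call. = FALSE)
  lens <- stats::setNames(
    round(stats::runif(n_genes, gene_length_range[1], gene_length_range[2])), genes)
  base <- stats::setNames(
    c(rep(baseline_fpkm, length(eff_genes)),
      exp(stats::runif(length(bg_genes), log(1), log(100)))), genes)
  meta <- expand.grid(replicate = seq_len(n_replicates),
                      treatment = treatments, genotype = genotypes,
                      stringsAsFactors = FALSE)
  meta <- meta[, c("genotype", "treatment", "replicate")]
  samples <- sprintf("%s_%s_r%d", meta$genotype, meta$treatment, meta$replicate)
  rownames(meta) <- samples
  counts <- matrix(0L, n_genes, nrow(meta), dimnames = list(genes, samples))
  for (s in seq_len(nrow(meta))) {
    fold <- rep(1, n_genes)
    for (g in eff_genes) {
      fold[match(g, genes)] <- effects[[g]][meta$genotype[s], meta$treatment[s]]
    }
    mu <- base * fold * (lens / 1000) * (library_size / 1e6)
    counts[, s] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }
  cm <- count_matrix(counts, lens, meta,
                     library_sizes = rep(library_size, nrow(meta)))
  attr(cm, "truth") <- list(effects = effects, baseline_fpkm = base,
                            dispersion = dispersion)
  cm
}

#' Sample cloned cDNA sequences proportional to transcript abundance
#'
#' Clones are drawn multinomially from the paralog transcripts; the true
#' source is retained in each clone id (`cloneNNN|true=<paralog>`).
#'
#' @param refs A [homeolog_set()]; paralog sequences act as transcripts.
#' @param proportions Transcript abundance proportions (one per paralog,
#'   summing to 1).
#' @param n_clones Number of clones.
#' @param error_rate Optional per-base substitution rate applied to clones
#'   (default 0, i.e. perfect cDNA sequences).
#' @param seed Integer seed.
#' @return List of [nuc_seq()] clones, with attribute `truth` (character
#'   vector of source paralog ids).
#' @export
simulate_clones <- function(refs, proportions, n_clones, error_rate = 0,
                            seed = 1L) {
  stopifnot(inherits(refs, "homeolog_set"))
  proportions <- as.numeric(proportions)
  stopifnot(length(proportions) == length(refs$paralogs))
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1", call. = FALSE)
  if (n_clones == 0L) return(structure(list(), truth = character(0)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- names(refs$paralogs)
  src <- sample(ids, n_clones, replace = TRUE, prob = proportions)
  clones <- lapply(seq_len(n_clones), function(i) {
    s <- refs$paralogs[[src[i]]]$seq
    if (error_rate > 0) {
      chars <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(length(chars)) < error_rate)
      s <- paste(.mutate_sites(chars, hit), collapse = "")
    }
    nuc_seq(s, id = sprintf("clone%03d|true=%s", i, src[i]))
  })
  structure(clones, truth = src)
}

#' Simulate logistic growth trajectories with Gaussian noise
#'
#' Weekly heights follow `A / (1 + exp(-r (t - t_half)))` plus i.i.d.
#' Gaussian noise with sd `noise_frac * A`, truncated at 0. Per-plant truth
#' is drawn uniformly from the stated parameter ranges. A non-bolting
#' (winter-annual, unvernalized) group can be represented by a near-zero
#' growth rate.
#'
#' @param n_plants Number of plants (default 36).
#' @param A_range Asymptotic height range in cm (default 30-60).
#' @param r_range Growth rate range per week (default 0.8-1.5).
#' @param t_half_range Half-height time range in weeks (default 3-5).
#' @param times Observation weeks (default 0:8).
#' @param noise_frac Noise sd as a fraction of A (default 0.05).
#' @param genotype,vernalization_weeks Metadata recycled over plants.
#' @param seed Integer seed.
#' @return Long data frame (`plant_id`, `genotype`, `weeks_vernalized`,
#'   `week`, `height_cm`) with the per-plant truth attached as attribute
#'   `truth` (data frame of `plant_id`, `A`, `r`, `t_half`).
#' @export
simulate_growth <- function(n_plants = 36L, A_range = c(30, 60),
                            r_range = c(0.8, 1.5), t_half_range = c(3, 5),
                            times = 0:8, noise_frac = 0.05,
                            genotype = "summer", vernalization_weeks = 0L,
                            seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  genotype <- rep_len(genotype, n_plants)
  vernalization_weeks <- rep_len(vernalization_weeks, n_plants)
  A <- stats::runif(n_plants, A_range[1], A_range[2])
  r <- stats::runif(n_plants, r_range[1], r_range[2])
  th <- stats::runif(n_plants, t_half_range[1], t_half_range[2])
  rows <- lapply(seq_len(n_plants), function(i) {
    mu <- .logistic(times, A[i], r[i], th[i])
    h <- pmax(0, mu + stats::rnorm(length(times), 0, noise_frac * A[i]))
    data.frame(plant_id = sprintf("plant%03d", i), genotype = genotype[i],
               weeks_vernalized = vernalization_weeks[i],
               week = times, height_cm = h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(plant_id = sprintf("plant%03d", seq_len(n_plants)),
                                   A = A, r = r, t_half = th,
                                   stringsAsFactors = FALSE)
  out
}
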