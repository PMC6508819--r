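# Shared fixtures and independent oracles. Oracles deliberately use a
# different route than the implementation (Biostrings pattern matching /
# translation, brute-force loops) so the two can disagree.

# the two probe query strings printed for the chr20-unique deletion site,
# used as designed inputs throughout
PROBE_REF_39 <- "CCATAACTAGAGCGAAGAAGACAGAACTAATGTTGAAGC"
PROBE_REF_RC <- "GCTTCAACATTAGTTCTGTCTTCTTCGCTCTAGTTATGG"
PROBE_ALT_38 <- "CCATAACTAGAGCGAAGAAGACAGAACTAATGTGAAGC"
PROBE_ALT_RC <- "GCTTCACATTAGTTCTGTCTTCTTCGCTCTAGTTATGG"

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random CDS: ATG + non-stop codons + stop
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  codons <- character(0)
  while (length(codons) < n_codons - 2L) {
    cand <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    if (!cand %in% c("TAA", "TAG", "TGA")) codons <- c(codons, cand)
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

# independent translation oracle via Biostrings
oracle_translate <- function(s, frame = 0) {
  s <- substr(s, frame + 1, nchar(s))
  s <- substr(s, 1, (nchar(s) %/% 3) * 3)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           if.fuzzy.codon = "X",
                                           no.init.codon = TRUE))
  sub("\\*.*$", "", aa)
}

# independent exact-substring counter via Biostrings
oracle_contains <- function(reads, pattern) {
  Biostrings::vcountPattern(pattern, Biostrings::DNAStringSet(reads),
                            fixed = TRUE) > 0
}

# brute-force BH step-up: find largest k with p_(k) <= k q / n for each gene
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[o[i]] <- min(1, min(p[o[i:n]] * n / (i:n)))
  }
  adj
}

small_refs <- function(seed = 1, len = 400L, divergence = 0.05) {
  make_paralogs(n_paralogs = 3L, sequence_length = len,
                divergence = divergence, seed = seed)
}

logistic_curve <- function(t, A, r, t_half) A / (1 + exp(-r * (t - t_half)))
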