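test_that("reverse_complement handles the printed probe pairs and is an involution", {
  expect_equal(as.character(reverse_complement(PROBE_REF_39)), PROBE_REF_RC)
  expect_equal(as.character(reverse_complement(PROBE_ALT_38)), PROBE_ALT_RC)
  expect_equal(as.character(reverse_complement("A")), "T")
  set.seed(11)
  for (i in 1:25) {
    s <- random_dna(sample(1:200, 1))
    expect_equal(as.character(reverse_complement(reverse_complement(s))), s)
  }
  # oracle agreement on random sequences
  s <- random_dna(500, seed = 5)
  expect_equal(as.character(reverse_complement(s)),
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
  expect_error(nuc_seq("ACGU"), "invalid nucleotide")
  expect_error(nuc_seq(""), "empty")
})

test_that("apply_deletion removes bases and leftmost-normalizes in homopolymers", {
  expect_equal(as.character(apply_deletion(nuc_seq("AATGTTGA"), deletion_spec(4))),
               "AATGTGA")
  d5 <- apply_deletion(nuc_seq("AATGTTGA"), deletion_spec(5))
  expect_equal(as.character(d5), "AATGTGA")
  expect_equal(attr(d5, "canonical_deletion")$position, 4L)
  expect_equal(as.character(apply_deletion(nuc_seq("ACGT"), deletion_spec(0))), "CGT")
  expect_error(apply_deletion(nuc_seq("ACGT"), deletion_spec(4)), "out of bounds")
  # any T of a run deletes to the same output and canonical spec
  s <- nuc_seq("ACGTTTTTACG")
  outs <- lapply(3:7, function(p) apply_deletion(s, deletion_spec(p)))
  expect_length(unique(vapply(outs, as.character, character(1))), 1L)
  expect_true(all(vapply(outs, function(o) attr(o, "canonical_deletion")$position, integer(1)) == 3L))
  # oracle equivalence: delete-then-translate equals translate of an
  # independently edited string
  set.seed(21)
  for (i in 1:20) {
    cds <- random_cds(50)
    pos <- sample(0:(nchar(cds) - 1), 1)
    edited <- paste0(substr(cds, 1, pos), substr(cds, pos + 2, nchar(cds)))
    canon <- attr(apply_deletion(nuc_seq(cds), deletion_spec(pos)), "canonical_deletion")
    expect_equal(as.character(translate_seq(apply_deletion(nuc_seq(cds), deletion_spec(pos)))),
                 as.character(translate_seq(edited)),
                 info = sprintf("pos %d canonical %d", pos, canon$position))
  }
})

test_that("translate_seq follows the standard code, frames, stops and N codons", {
  tr <- translate_seq("ATGGCTTAA")
  expect_equal(as.character(tr), "MA")
  expect_equal(attr(tr, "stop_codon"), 3L)
  expect_equal(as.character(translate_seq("AATGGCT", frame = 1)), "MA")
  expect_equal(as.character(translate_seq("ATGNCTGGA")), "MXG")
  expect_error(translate_seq("AC"), "too short")
  # random 300-mers against the independent codon-table oracle
  set.seed(33)
  for (i in 1:10) {
    s <- random_dna(300)
    for (fr in 0:2) {
      expect_equal(as.character(translate_seq(s, fr)), oracle_translate(s, fr))
    }
  }
})

test_that("frameshift_consequence locates divergence, stops and intact fraction", {
  # 60-codon toy CDS built so the deletion visibly changes codon 40:
  # codons 1-39 = GCT (A), codon 40 = GAA (E), 41-59 = TTT (F), stop
  cds <- paste0(strrep("GCT", 39), "GAA", strrep("TTT", 19), "TAA")
  # delete the G of codon 40 (0-based nt 117): codon 40 becomes AAT (N)
  alt <- apply_deletion(nuc_seq(cds), deletion_spec(117))
  rep <- frameshift_consequence(cds, alt)
  expect_true(rep$is_divergent)
  expect_equal(rep$first_divergent_codon, 40L)
  expect_equal(rep$fraction_intact, 39 / nchar(rep$ref_protein))
  expect_equal(nchar(rep$ref_protein), 59L)
  # identical input -> empty report
  none <- frameshift_consequence(cds, cds)
  expect_false(none$is_divergent)
  expect_true(is.na(none$first_divergent_codon))
  expect_equal(none$fraction_intact, 1)
})

test_that("frameshift reports match a residue-by-residue oracle on random 1-bp deletions", {
  set.seed(99)
  n_within_bound <- 0L
  n_div <- 0L
  for (i in 1:100) {
    cds <- random_cds(sample(20:80, 1))
    pos <- sample(0:(nchar(cds) - 4), 1)
    alt <- apply_deletion(nuc_seq(cds), deletion_spec(pos))
    rep <- frameshift_consequence(cds, alt)
    rp <- oracle_translate(cds)
    ap <- oracle_translate(as.character(alt))
    expect_equal(rep$ref_protein, rp)
    expect_equal(rep$alt_protein, ap)
    k <- min(nchar(rp), nchar(ap))
    rr <- strsplit(rp, "")[[1]]; aa <- strsplit(ap, "")[[1]]
    lead <- 0L
    while (lead < k && rr[lead + 1] == aa[lead + 1]) lead <- lead + 1L
    if (lead == nchar(rp) && lead == nchar(ap)) {
      expect_false(rep$is_divergent)
    } else {
      expect_equal(rep$first_divergent_codon, lead + 1L)
      expect_equal(rep$fraction_intact, lead / nchar(rp))
      # divergence can never precede the codon hit by the deletion ...
      canon <- attr(alt, "canonical_deletion")$position
      expect_gte(rep$first_divergent_codon, ceiling((canon + 1) / 3))
      # ... and usually lands on it or the next codon (synonymous shifted
      # codons can postpone it, so this is a frequency, not a certainty)
      n_div <- n_div + 1L
      if (rep$first_divergent_codon <= ceiling((canon + 1) / 3) + 1) {
        n_within_bound <- n_within_bound + 1L
      }
    }
  }
  expect_gte(n_within_bound / n_div, 0.9)
})

test_that("assign_paralog picks the strict best match and reports ties", {
  refs <- small_refs(seed = 2)
  ids <- names(refs$paralogs)
  hit <- assign_paralog(refs$paralogs[[1]], refs)
  expect_equal(hit$best_paralog, ids[1])
  expect_equal(unname(hit$identities[ids[1]]), 1.0)
  # one mismatch to paralog 1 still wins over ~5%-diverged others
  clone <- refs$paralogs[[1]]$seq
  substr(clone, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(clone, 10, 10))[1]
  expect_equal(assign_paralog(nuc_seq(clone, "c1"), refs)$best_paralog, ids[1])
  # exact tie -> ambiguous
  dup <- homeolog_set(list(a = nuc_seq("ACGTACGTACGT", "a"),
                           b = nuc_seq("ACGTACGTACGT", "b")))
  expect_equal(assign_paralog("ACGTACGTACGT", dup)$best_paralog, "ambiguous")
  # permutation invariance in reference order
  perm <- homeolog_set(refs$paralogs[c(3, 1, 2)])
  a1 <- assign_paralog(nuc_seq(clone, "c1"), refs)
  a2 <- assign_paralog(nuc_seq(clone, "c1"), perm)
  expect_equal(a1$best_paralog, a2$best_paralog)
  expect_equal(a1$identities[ids], a2$identities[ids])
})

test_that("simulated clones are assigned to their true paralog (>= 99%)", {
  refs <- make_paralogs(n_paralogs = 3, sequence_length = 1000,
                        divergence = 0.05, seed = 4)
  clones <- simulate_clones(refs, c(0.4, 0.3, 0.3), n_clones = 200,
                            error_rate = 0.002, seed = 8)
  truth <- attr(clones, "truth")
  got <- vapply(clones, function(cl) assign_paralog(cl, refs)$best_paralog,
                character(1))
  expect_gte(mean(got == truth), 0.99)
})
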