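# Nucleotide/protein sequence primitives: orientation, indel application with
# canonical (leftmost) placement, translation, frameshift-consequence
# reporting, and paralog assignment of cloned cDNA sequences.

NUC_ALPHABET <- c("A", "C", "G", "T", "N")

# Standard genetic code (NCBI table 1), codon order TTT, TTC, TTA, TTG, TCT, ...
# with base order T, C, A, G from the slowest to the fastest digit.
.AA64 <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", ""
)[[1]]
.BASE_IDX <- c(T = 0L, C = 1L, A = 2L, G = 3L)

#' Construct a nucleotide sequence
#'
#' A `nuc_seq` is a plain 5'->3' nucleotide string over the alphabet
#' `{A, C, G, T, N}` with a text identifier. All coordinates used by this
#' package are 0-based, half-open.
#'
#' @param residues Single non-empty string over `A/C/G/T/N` (case-insensitive).
#' @param id Text label.
#' @return An object of class `nuc_seq` with fields `id` and `seq`.
#' @examples
#' nuc_seq("ACGTN", id = "toy")
#' @export
nuc_seq <- function(residues, id = "seq") {
  if (inherits(residues, "nuc_seq")) return(residues)
  if (!is.character(residues) || length(residues) != 1L || is.na(residues)) {
    stop("residues must be a single string", call. = FALSE)
  }
  residues <- toupper(residues)
  if (nchar(residues) == 0L) stop("empty sequence", call. = FALSE)
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), NUC_ALPHABET)
  if (length(bad) > 0L) {
    stop("invalid nucleotide character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(id = as.character(id), seq = residues), class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  n <- nchar(x$seq)
  shown <- if (n > 60L) paste0(substr(x$seq, 1L, 57L), "...") else x$seq
  cat(sprintf("<nuc_seq> %s (%d bp)\n%s\n", x$id, n, shown))
  invisible(x)
}

#' @export
as.character.nuc_seq <- function(x, ...) x$seq

seq_len_nt <- function(x) nchar(nuc_seq(x)$seq)

#' Reverse complement
#'
#' Watson-Crick reverse complement; `N` maps to `N`. The operation is an
#' involution: applying it twice returns the input.
#'
#' @param seq A [nuc_seq()] or a plain nucleotide string.
#' @return A `nuc_seq` (id suffixed with `_rc`).
#' @examples
#' as.character(reverse_complement("ACGT"))
#' @export
reverse_complement <- function(seq) {
  x <- nuc_seq(seq)
  rc <- chartr("ACGTN", "TGCAN", x$seq)
  rc <- paste(rev(strsplit(rc, "")[[1]]), collapse = "")
  nuc_seq(rc, id = paste0(x$id, "_rc"))
}

#' Specify a deletion
#'
#' @param position 0-based start of the deleted bases in the reference.
#' @param length Number of bases removed (positive integer).
#' @return A `deletion_spec` object.
#' @export
deletion_spec <- function(position, length = 1L) {
  position <- as.integer(position)
  length <- as.integer(length)
  if (is.na(position) || position < 0L) stop("position must be >= 0", call. = FALSE)
  if (is.na(length) || length < 1L) stop("length must be >= 1", call. = FALSE)
  structure(list(position = position, length = length), class = "deletion_spec")
}

#' @export
print.deletion_spec <- function(x, ...) {
  cat(sprintf("<deletion_spec> -%dbp at 0-based position %d\n", x$length, x$position))
  invisible(x)
}

#' Leftmost-normalize a deletion within its homopolymer/repeat context
#'
#' Deleting any one base of a homopolymer run yields the same sequence; the
#' canonical representation places the deletion at the leftmost equivalent
#' position (the usual left-alignment rule for indels).
#'
#' @param seq Reference [nuc_seq()].
#' @param del A [deletion_spec()].
#' @return A `deletion_spec` with the canonical (leftmost) position.
#' @export
normalize_deletion <- function(seq, del) {
  x <- nuc_seq(seq)
  stopifnot(inherits(del, "deletion_spec"))
  n <- nchar(x$seq)
  p <- del$position
  L <- del$length
  if (p + L > n) stop("deletion out of bounds", call. = FALSE)
  chars <- strsplit(x$seq, "")[[1]]
  # shift left while the base entering the deleted window equals the one leaving
  while (p > 0L && chars[p] == chars[p + L]) p <- p - 1L
  deletion_spec(p, L)
}

#' Apply a deletion to a sequence
#'
#' The deletion is first leftmost-normalized (see [normalize_deletion()]);
#' the canonical spec actually applied is attached as attribute
#' `canonical_deletion`.
#'
#' @inheritParams normalize_deletion
#' @return A `nuc_seq` shorter by `del$length` bases.
#' @examples
#' as.character(apply_deletion(nuc_seq("AATGTTGA"), deletion_spec(4)))
#' @export
apply_deletion <- function(seq, del) {
  x <- nuc_seq(seq)
  canon <- normalize_deletion(x, del)
  p <- canon$position
  L <- canon$length
  out <- paste0(substr(x$seq, 1L, p), substr(x$seq, p + L + 1L, nchar(x$seq)))
  res <- nuc_seq(out, id = paste0(x$id, "_del", p, "-", L))
  attr(res, "canonical_deletion") <- canon
  res
}

#' Translate a nucleotide sequence (standard code)
#'
#' Translates from the given frame using NCBI translation table 1. Translation
#' stops at (and excludes) the first stop codon; its 1-based codon index is
#' attached as attribute `stop_codon` (`NA` if none). Codons containing `N`
#' translate to `X`. A trailing partial codon is ignored.
#'
#' @param seq A [nuc_seq()] or string.
#' @param frame 0, 1 or 2: number of 5' bases skipped.
#' @return Amino-acid string with attribute `stop_codon`.
#' @examples
#' translate_seq("ATGGCTTAA")
#' @export
translate_seq <- function(seq, frame = 0L) {
  x <- nuc_seq(seq)
  frame <- as.integer(frame)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2", call. = FALSE)
  s <- substr(x$seq, frame + 1L, nchar(x$seq))
  ncod <- nchar(s) %/% 3L
  if (ncod == 0L) stop("sequence too short to translate in this frame", call. = FALSE)
  chars <- strsplit(substr(s, 1L, 3L * ncod), "")[[1]]
  m <- matrix(chars, nrow = 3L)
  hasN <- colSums(m == "N") > 0L
  idx <- 16L * .BASE_IDX[m[1L, ]] + 4L * .BASE_IDX[m[2L, ]] + .BASE_IDX[m[3L, ]]
  aa <- ifelse(hasN, "X", .AA64[idx + 1L])
  stop_at <- which(aa == "*")
  stop_codon <- if (length(stop_at)) stop_at[1L] else NA_integer_
  if (!is.na(stop_codon)) aa <- aa[seq_len(stop_codon - 1L)]
  structure(paste(aa, collapse = ""), stop_codon = stop_codon)
}

#' Protein-level consequence of a coding-sequence edit
#'
#' Translates both coding sequences from frame 0 and reports where the
#' proteins diverge, whether the variant protein gains a premature stop, and
#' the fraction of the reference protein left intact. For a 1-bp (frameshift)
#' deletion every downstream codon is scrambled and a premature stop usually
#' truncates the protein.
#'
#' @param ref_cds,alt_cds Reference and variant coding sequences
#'   ([nuc_seq()] or string), both read from frame 0.
#' @return A `frameshift_report` with fields `is_divergent`,
#'   `first_divergent_codon` (1-based, `NA` if proteins identical),
#'   `premature_stop_codon` (1-based codon index of the variant stop when it
#'   precedes the reference stop, else `NA`), `ref_protein`, `alt_protein`,
#'   `fraction_intact`.
#' @export
frameshift_consequence <- function(ref_cds, alt_cds) {
  rp <- translate_seq(ref_cds, 0L)
  ap <- translate_seq(alt_cds, 0L)
  ref_stop <- attr(rp, "stop_codon")
  alt_stop <- attr(ap, "stop_codon")
  r <- strsplit(as.character(rp), "")[[1]]
  a <- strsplit(as.character(ap), "")[[1]]
  k <- min(length(r), length(a))
  same <- if (k > 0L) r[seq_len(k)] == a[seq_len(k)] else logical(0)
  lead <- if (all(same)) k else which(!same)[1L] - 1L
  identical_prot <- length(r) == length(a) && lead == length(r)
  first_div <- if (identical_prot) NA_integer_ else lead + 1L
  prem <- NA_integer_
  if (!is.na(alt_stop) && (is.na(ref_stop) || alt_stop < ref_stop)) prem <- alt_stop
  frac <- if (length(r) == 0L) 1 else lead / length(r)
  structure(list(
    is_divergent = !identical_prot,
    first_divergent_codon = first_div,
    premature_stop_codon = prem,
    ref_protein = as.character(rp),
    alt_protein = as.character(ap),
    fraction_intact = frac
  ), class = "frameshift_report")
}

#' @export
print.frameshift_report <- function(x, ...) {
  if (!x$is_divergent) {
    cat("<frameshift_report> proteins identical (no consequence)\n")
  } else {
    cat(sprintf(
      "<frameshift_report> diverges at codon %d; premature stop: %s; %.1f%% of reference protein intact\n",
      x$first_divergent_codon,
      if (is.na(x$premature_stop_codon)) "none" else sprintf("codon %d", x$premature_stop_codon),
      100 * x$fraction_intact
    ))
  }
  invisible(x)
}

# identity = matches / alignment length under global alignment with
# match = 1, mismatch = 0, linear gap = -1 (N never scores as a match)
.align_identity <- function(a, b) {
  mat <- matrix(0, 5L, 5L, dimnames = list(NUC_ALPHABET, NUC_ALPHABET))
  diag(mat) <- 1
  mat["N", "N"] <- 0
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

#' Assign a cloned cDNA sequence to its best-matching paralog
#'
#' Computes a global pairwise alignment of the clone against every paralog
#' reference (match = 1, mismatch = 0, linear gap penalty = -1) and reports
#' the identity fraction (matches / alignment length) per paralog. The
#' paralog with strictly maximal identity wins; exact ties are reported as
#' `"ambiguous"`, never broken arbitrarily.
#'
#' @param clone A [nuc_seq()] or string.
#' @param refs A [homeolog_set()] (>= 2 paralogs).
#' @return A `paralog_assignment` with fields `clone_id`, `best_paralog`
#'   (a paralog id or `"ambiguous"`) and `identities` (named numeric).
#' @export
assign_paralog <- function(clone, refs) {
  x <- nuc_seq(clone)
  stopifnot(inherits(refs, "homeolog_set"))
  ids <- names(refs$paralogs)
  identities <- vapply(
    refs$paralogs, function(r) .align_identity(x$seq, r$seq), numeric(1)
  )
  names(identities) <- ids
  top <- max(identities)
  winners <- ids[identities >= top - 1e-9]
  best <- if (length(winners) == 1L) winners else "ambiguous"
  structure(list(clone_id = x$id, best_paralog = best, identities = identities),
            class = "paralog_assignment")
}

#' @export
print.paralog_assignment <- function(x, ...) {
  cat(sprintf("<paralog_assignment> %s -> %s\n", x$clone_id, x$best_paralog))
  print(round(x$identities, 4))
  invisible(x)
}
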