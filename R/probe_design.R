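# Paralog-unique, allele-discriminating probe design around a variant site,
# with exact-substring uniqueness checks against all other references on
# both strands.

#' Bundle homeologous paralog references with the locus copy structure
#'
#' @param paralogs Named list of [nuc_seq()] (or named character vector),
#'   one reference per paralog; >= 2 required, ids unique.
#' @param copies_per_paralog Gene copies behaving as one locus per paralog
#'   (default 1).
#' @param alleles_per_copy Alleles per copy (2 for a diploid-behaving copy).
#' @return A `homeolog_set`. The total allele count per paralog is
#'   `m = copies_per_paralog * alleles_per_copy`.
#' @export
homeolog_set <- function(paralogs, copies_per_paralog = 1L, alleles_per_copy = 2L) {
  if (is.character(paralogs)) {
    if (is.null(names(paralogs))) stop("paralogs must be named", call. = FALSE)
    paralogs <- mapply(nuc_seq, paralogs, names(paralogs), SIMPLIFY = FALSE)
  }
  paralogs <- lapply(paralogs, nuc_seq)
  ids <- vapply(paralogs, function(x) x$id, character(1))
  if (is.null(names(paralogs)) || any(!nzchar(names(paralogs)))) names(paralogs) <- ids
  if (length(paralogs) < 2L) stop("need >= 2 paralogs", call. = FALSE)
  if (anyDuplicated(names(paralogs))) stop("paralog ids must be unique", call. = FALSE)
  copies_per_paralog <- as.integer(copies_per_paralog)
  alleles_per_copy <- as.integer(alleles_per_copy)
  stopifnot(copies_per_paralog >= 1L, alleles_per_copy >= 1L)
  structure(list(paralogs = paralogs,
                 copies_per_paralog = copies_per_paralog,
                 alleles_per_copy = alleles_per_copy),
            class = "homeolog_set")
}

#' @export
print.homeolog_set <- function(x, ...) {
  cat(sprintf("<homeolog_set> %d paralogs (%s), %d copies x %d alleles per paralog\n",
              length(x$paralogs), paste(names(x$paralogs), collapse = ", "),
              x$copies_per_paralog, x$alleles_per_copy))
  invisible(x)
}

#' Total allele count per paralog locus
#' @param refs A [homeolog_set()].
#' @return Integer `m`.
#' @export
allele_count <- function(refs) {
  stopifnot(inherits(refs, "homeolog_set"))
  refs$copies_per_paralog * refs$alleles_per_copy
}

#' Find every exact occurrence of a probe outside one paralog
#'
#' Scans each non-excluded reference and its reverse complement for exact
#' substring occurrences (grep semantics: no mismatches).
#'
#' @param probe A [nuc_seq()] or string (length >= 1).
#' @param refs A [homeolog_set()].
#' @param exclude Paralog id to skip (the probe's own target); `NULL` scans all.
#' @return Data frame with columns `paralog`, `offset` (0-based, on the
#'   scanned strand), `strand` (`+`/`-`); zero rows means the probe is unique.
#' @export
check_uniqueness <- function(probe, refs, exclude = NULL) {
  p <- nuc_seq(probe)$seq
  stopifnot(inherits(refs, "homeolog_set"))
  hits <- list()
  for (id in setdiff(names(refs$paralogs), exclude)) {
    fwd <- refs$paralogs[[id]]$seq
    rev <- reverse_complement(fwd)$seq
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") fwd else rev
      # zero-width lookahead so overlapping occurrences are all reported
      m <- gregexpr(paste0("(?=", p, ")"), subject, perl = TRUE)[[1]]
      if (m[1L] != -1L) {
        hits[[length(hits) + 1L]] <- data.frame(
          paralog = id, offset = as.integer(m) - 1L, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(paralog = character(0), offset = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Design an allele-discriminating probe pair around a deletion
#'
#' Extracts a window of `flank_left + del_length + flank_right` bases around
#' the (leftmost-normalized) deletion in the target paralog as the
#' reference-allele probe, derives the deletion-allele probe by applying the
#' deletion, and verifies that all four strings (both probes and their
#' reverse complements) occur nowhere in any other paralog on either strand.
#' Defaults give a 39-nt reference probe / 38-nt deletion probe for a 1-bp
#' deletion.
#'
#' @param refs A [homeolog_set()].
#' @param target Paralog id carrying the variant.
#' @param variant A [deletion_spec()] in target-paralog coordinates.
#' @param flank_left,flank_right Bases kept on each side of the deleted
#'   base(s); the window is anchored on the canonical (leftmost) deletion
#'   position.
#' @return A `probe_set` with fields `target_paralog`, `ref_probe`,
#'   `alt_probe`, `ref_probe_rc`, `alt_probe_rc`, `variant` (probe
#'   coordinates) and `source_window` (`[start, end)` 0-based in the target).
#' @export
design_probes <- function(refs, target, variant, flank_left = 19L, flank_right = 19L) {
  stopifnot(inherits(refs, "homeolog_set"), inherits(variant, "deletion_spec"))
  if (!target %in% names(refs$paralogs)) {
    stop("unknown target paralog: ", target, call. = FALSE)
  }
  tseq <- refs$paralogs[[target]]
  n <- nchar(tseq$seq)
  canon <- normalize_deletion(tseq, variant)
  flank_left <- as.integer(flank_left); flank_right <- as.integer(flank_right)
  stopifnot(flank_left >= 1L, flank_right >= 1L)
  start <- canon$position - flank_left
  end <- canon$position + canon$length + flank_right  # half-open
  if (start < 0L || end > n) {
    stop("probe window [", start, ",", end, ") outside target sequence", call. = FALSE)
  }
  ref_probe <- nuc_seq(substr(tseq$seq, start + 1L, end),
                       id = paste0(target, "_ref_probe"))
  probe_var <- deletion_spec(flank_left, canon$length)
  alt_probe <- apply_deletion(ref_probe, probe_var)
  alt_probe$id <- paste0(target, "_alt_probe")
  probes <- list(ref_probe = ref_probe, alt_probe = alt_probe,
                 ref_probe_rc = reverse_complement(ref_probe),
                 alt_probe_rc = reverse_complement(alt_probe))
  offenders <- lapply(probes[c("ref_probe", "alt_probe")], function(p) {
    check_uniqueness(p, refs, exclude = target)
  })
  nhit <- vapply(offenders, nrow, integer(1))
  if (any(nhit > 0L)) {
    bad <- do.call(rbind, offenders[nhit > 0L])
    stop("no unique probe at these flanks; off-target hits:\n",
         paste(utils::capture.output(print(bad)), collapse = "\n"),
         call. = FALSE)
  }
  structure(list(target_paralog = target,
                 ref_probe = ref_probe, alt_probe = alt_probe,
                 ref_probe_rc = probes$ref_probe_rc,
                 alt_probe_rc = probes$alt_probe_rc,
                 variant = attr(alt_probe, "canonical_deletion"),
                 source_window = c(start = start, end = end)),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("<probe_set> target %s, window [%d,%d)\n  ref (%d nt): %s\n  alt (%d nt): %s\n",
              x$target_paralog, x$source_window["start"], x$source_window["end"],
              nchar(x$ref_probe$seq), x$ref_probe$seq,
              nchar(x$alt_probe$seq), x$alt_probe$seq))
  invisible(x)
}

#' Serialize a probe set to a tab-delimited file
#'
#' Columns: `role` (ref/alt, fwd/rc), `sequence`, `target`, `window_start`,
#' `window_end`, `variant_pos`, `variant_len`.
#'
#' @param probes A `probe_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_probes <- function(probes, path) {
  stopifnot(inherits(probes, "probe_set"))
  df <- data.frame(
    role = c("ref", "alt", "ref_rc", "alt_rc"),
    sequence = c(probes$ref_probe$seq, probes$alt_probe$seq,
                 probes$ref_probe_rc$seq, probes$alt_probe_rc$seq),
    target = probes$target_paralog,
    window_start = unname(probes$source_window["start"]),
    window_end = unname(probes$source_window["end"]),
    variant_pos = probes$variant$position,
    variant_len = probes$variant$length,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe set written by [write_probes()]
#' @param path TSV path.
#' @return A `probe_set`.
#' @export
read_probes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  rows <- stats::setNames(df$sequence, df$role)
  target <- df$target[1]
  structure(list(target_paralog = target,
                 ref_probe = nuc_seq(rows[["ref"]], paste0(target, "_ref_probe")),
                 alt_probe = nuc_seq(rows[["alt"]], paste0(target, "_alt_probe")),
                 ref_probe_rc = nuc_seq(rows[["ref_rc"]], paste0(target, "_ref_probe_rc")),
                 alt_probe_rc = nuc_seq(rows[["alt_rc"]], paste0(target, "_alt_probe_rc")),
                 variant = deletion_spec(df$variant_pos[1], df$variant_len[1]),
                 source_window = c(start = df$window_start[1], end = df$window_end[1])),
            class = "probe_set")
}
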