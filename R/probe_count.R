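# Exact-match allele counting in sequencing reads: the in-silico analogue of
# grepping trimmed read files for the two probe strings and their reverse
# complements, with per-read accounting.

#' Count reads matching the deletion vs reference probe
#'
#' A read counts as `alt` if it contains the deletion-allele probe or its
#' reverse complement as an exact substring, as `ref` likewise for the
#' reference-allele probe, and as `ambiguous` if it contains both kinds.
#' Each read contributes to at most one category, regardless of how many
#' times a probe occurs inside it. No trimming or quality filtering is
#' performed here; reads are used as-is.
#'
#' @param reads Character vector of read sequences, or a path to a
#'   FASTQ/FASTA file (optionally gzipped; see [read_reads()]).
#' @param probes A `probe_set` from [design_probes()] / [read_probes()].
#' @param sample_id Sample label recorded in the result.
#' @param paired_dedup If `TRUE`, reads whose ids differ only by a `/1`,
#'   `/2` or ` 1:`/` 2:` mate suffix are collapsed to one fragment before
#'   counting (off by default; mates are otherwise independent reads).
#' @return An `allele_count_table`: list with `sample_id`, `n_alt`, `n_ref`,
#'   `n_ambiguous`, `n_scanned`.
#' @export
count_probe_matches <- function(reads, probes, sample_id = "sample",
                                paired_dedup = FALSE) {
  stopifnot(inherits(probes, "probe_set"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      !grepl("^[ACGTNacgtn]+$", reads)) {
    reads <- read_reads(reads)
  }
  ids <- names(reads)
  reads <- toupper(as.character(reads))
  alt_hit <- grepl(probes$alt_probe$seq, reads, fixed = TRUE) |
    grepl(probes$alt_probe_rc$seq, reads, fixed = TRUE)
  ref_hit <- grepl(probes$ref_probe$seq, reads, fixed = TRUE) |
    grepl(probes$ref_probe_rc$seq, reads, fixed = TRUE)
  n_units <- length(reads)
  if (paired_dedup && !is.null(ids) && length(reads)) {
    # a fragment matches if either mate matches
    frag <- sub("[/ ][12].*$", "", ids)
    alt_hit <- as.logical(tapply(alt_hit, frag, any))
    ref_hit <- as.logical(tapply(ref_hit, frag, any))
    n_units <- length(unique(frag))
  }
  structure(list(
    sample_id = sample_id,
    n_alt = sum(alt_hit & !ref_hit),
    n_ref = sum(ref_hit & !alt_hit),
    n_ambiguous = sum(alt_hit & ref_hit),
    n_scanned = n_units
  ), class = "allele_count_table")
}

#' Construct an allele count table directly from counts
#'
#' @param n_alt,n_ref,n_ambiguous,n_scanned Non-negative counts;
#'   `n_scanned` defaults to the category total.
#' @param sample_id Sample label.
#' @return An `allele_count_table`.
#' @export
allele_count_table <- function(n_alt, n_ref, n_ambiguous = 0L,
                               n_scanned = NULL, sample_id = "sample") {
  n_alt <- as.integer(n_alt); n_ref <- as.integer(n_ref)
  n_ambiguous <- as.integer(n_ambiguous)
  if (is.null(n_scanned)) n_scanned <- n_alt + n_ref + n_ambiguous
  n_scanned <- as.integer(n_scanned)
  if (any(c(n_alt, n_ref, n_ambiguous, n_scanned) < 0L)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (n_alt + n_ref + n_ambiguous > n_scanned) {
    stop("category counts exceed n_scanned", call. = FALSE)
  }
  structure(list(sample_id = sample_id, n_alt = n_alt, n_ref = n_ref,
                 n_ambiguous = n_ambiguous, n_scanned = n_scanned),
            class = "allele_count_table")
}

#' @export
print.allele_count_table <- function(x, ...) {
  cat(sprintf("<allele_count_table> %s: alt=%d ref=%d ambiguous=%d (scanned %d)\n",
              x$sample_id, x$n_alt, x$n_ref, x$n_ambiguous, x$n_scanned))
  invisible(x)
}

#' Merge allele count tables from chunks of the same sample
#'
#' Counting is additive over any split of a read file, so summing chunk
#' tables equals counting the whole file.
#'
#' @param tables List of `allele_count_table` for one sample.
#' @return A single merged `allele_count_table`.
#' @export
merge_count_tables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  allele_count_table(
    n_alt = sum(vapply(tables, `[[`, integer(1), "n_alt")),
    n_ref = sum(vapply(tables, `[[`, integer(1), "n_ref")),
    n_ambiguous = sum(vapply(tables, `[[`, integer(1), "n_ambiguous")),
    n_scanned = sum(vapply(tables, `[[`, integer(1), "n_scanned")),
    sample_id = tables[[1L]]$sample_id)
}

#' Tidy long-format summary of allele count tables
#'
#' @param tables A single `allele_count_table` or a list of them
#'   (unique sample ids required).
#' @param keep_zero_ambiguous Include the `ambiguous` row even when zero.
#' @return Data frame with columns `sample`, `category`, `count`.
#' @export
count_report <- function(tables, keep_zero_ambiguous = FALSE) {
  if (inherits(tables, "allele_count_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  ids <- vapply(tables, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(tables, function(tb) {
    df <- data.frame(sample = tb$sample_id,
                     category = c("alt", "ref", "ambiguous"),
                     count = c(tb$n_alt, tb$n_ref, tb$n_ambiguous),
                     stringsAsFactors = FALSE)
    if (!keep_zero_ambiguous && tb$n_ambiguous == 0L) {
      df <- df[df$category != "ambiguous", , drop = FALSE]
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write allele counts as CSV (columns sample, category, count)
#' @param tables As in [count_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_count_csv <- function(tables, path) {
  utils::write.csv(count_report(tables, keep_zero_ambiguous = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read allele counts written by [write_count_csv()]
#' @param path CSV path.
#' @return List of `allele_count_table`, one per sample.
#' @export
read_count_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$sample), function(d) {
    g <- function(cat) { v <- d$count[d$category == cat]; if (length(v)) v[1] else 0L }
    allele_count_table(g("alt"), g("ref"), g("ambiguous"), sample_id = d$sample[1])
  })
}
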