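# File format helpers: FASTA via Biostrings, FASTQ via a strict 4-line-block
# parser (so malformed records are reported with their index). Gzip input is
# supported for both formats.

#' Read a FASTA file into a list of `nuc_seq`
#'
#' @param path FASTA file (optionally gzipped), wrapped or unwrapped lines.
#' @return Named list of [nuc_seq()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  out <- lapply(seq_along(ss), function(i) nuc_seq(as.character(ss[[i]]), id = ids[i]))
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A list of [nuc_seq()] (or a named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    ids <- if (is.null(names(seqs))) paste0("seq", seq_along(seqs)) else names(seqs)
    seqs <- mapply(nuc_seq, seqs, ids, SIMPLIFY = FALSE)
  }
  ids <- vapply(seqs, function(x) x$id, character(1))
  ss <- Biostrings::DNAStringSet(vapply(seqs, function(x) x$seq, character(1)))
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

.read_lines_any <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read sequencing reads from FASTQ or FASTA
#'
#' FASTQ records must be strict 4-line blocks (`@id`, sequence, `+`,
#' qualities); a malformed block raises an error naming the record index.
#' Qualities are ignored. The format is taken from the file extension
#' (`.fq`/`.fastq`[.gz] vs `.fa`/`.fasta`[.gz]) or sniffed from the first
#' character.
#'
#' @param path Reads file, optionally gzipped.
#' @return Character vector of read sequences (names = read ids).
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  base <- sub("\\.gz$", "", path)
  ext <- tolower(tools::file_ext(base))
  fmt <- if (ext %in% c("fq", "fastq")) {
    "fastq"
  } else if (ext %in% c("fa", "fasta", "fna")) {
    "fasta"
  } else {
    first <- substr(.read_lines_any(path)[1], 1, 1)
    if (identical(first, "@")) "fastq" else "fasta"
  }
  if (fmt == "fasta") {
    seqs <- read_fasta(path)
    return(stats::setNames(vapply(seqs, function(x) x$seq, character(1)),
                           names(seqs)))
  }
  lines <- .read_lines_any(path)
  if (length(lines) == 0L) return(character(0))
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ: %d lines is not a multiple of 4 (record %d truncated)",
                 length(lines), length(lines) %/% 4L + 1L), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(substr(hdr, 1, 1) != "@" | substr(plus, 1, 1) != "+" |
                 nchar(seqs) != nchar(qual))
  if (length(bad) > 0L) {
    stop(sprintf("malformed FASTQ record %d in %s", bad[1L], path), call. = FALSE)
  }
  stats::setNames(toupper(seqs), sub("^@", "", sub("\\s.*$", "", hdr)))
}

#' Write reads to a FASTQ file
#'
#' Constant quality `I` (Phred 40) is written for every base; qualities carry
#' no information in this package.
#'
#' @param reads Character vector of read sequences; names become read ids.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- if (is.null(names(reads)) && length(reads))
    paste0("read", seq_along(reads)) else names(reads)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (length(reads)) {
    block <- paste0("@", ids, "\n", reads, "\n+\n",
                    vapply(nchar(reads), function(k) strrep("I", k), character(1)))
    writeLines(block, con)
  }
  invisible(path)
}
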