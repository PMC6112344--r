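#' Read a small-RNA FASTQ file
#'
#' Minimal 4-line FASTQ reader (Phred+33) tolerant of RNA alphabet
#' (\code{U}), lowercase bases and ambiguity codes, which downstream
#' filters handle.  Records whose sequence and quality lengths disagree,
#' or whose header lines are malformed, are rejected individually and
#' counted rather than aborting the whole file.
#'
#' @param path path to a FASTQ file.
#' @return list with \code{reads}, a data.frame of \code{read_id},
#'   \code{sequence}, \code{quality}, and \code{n_parse_errors}, the
#'   number of rejected records.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4 != 0) {
    # drop the trailing partial record but keep parsing what is whole
    lines <- lines[seq_len((length(lines) %/% 4) * 4)]
  }
  n <- length(lines) %/% 4
  if (n == 0L) {
    return(list(reads = empty_reads(), n_parse_errors = 0L))
  }
  idx <- seq_len(n)
  hdr <- lines[(idx - 1L) * 4L + 1L]
  seq <- lines[(idx - 1L) * 4L + 2L]
  plus <- lines[(idx - 1L) * 4L + 3L]
  qual <- lines[(idx - 1L) * 4L + 4L]
  ok <- startsWith(hdr, "@") & startsWith(plus, "+") &
    nchar(seq) == nchar(qual) & nchar(seq) >= 1L
  reads <- data.frame(
    read_id = sub("^@", "", sub("\\s.*$", "", hdr[ok])),
    sequence = seq[ok],
    quality = qual[ok],
    stringsAsFactors = FALSE
  )
  list(reads = reads, n_parse_errors = sum(!ok))
}

#' Read reads from a FASTA file
#'
#' Wrapped or unwrapped FASTA; qualities are absent (`NA`).
#'
#' @param path path to a FASTA file.
#' @return list with \code{reads} data.frame (\code{quality} all NA)
#'   and \code{n_parse_errors} (always 0; Biostrings validates).
#' @export
read_fasta_reads <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  reads <- data.frame(
    read_id = sub("\\s.*$", "", names(ss)),
    sequence = as.character(ss),
    quality = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(reads) <- NULL
  list(reads = reads, n_parse_errors = 0L)
}

#' Read a collapsed-FASTA file
#'
#' Collapsed FASTA uses headers of the form \code{>seq<rank>_x<count>};
#' each entry is one unique sequence carrying its read count.
#'
#' @param path path to a collapsed FASTA file.
#' @return data.frame of \code{sequence}, \code{count}.
#' @export
read_collapsed_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(ss))
  m <- regmatches(ids, regexpr("_x[0-9]+$", ids))
  if (length(m) != length(ids)) {
    stop("collapsed FASTA headers must end in '_x<count>'")
  }
  count <- as.integer(sub("^_x", "", m))
  data.frame(sequence = as.character(ss), count = count,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write unique sequences as collapsed FASTA
#'
#' @param unique_seqs data.frame of \code{sequence}, \code{count}.
#' @param path output path.
#' @export
write_collapsed_fasta <- function(unique_seqs, path) {
  ids <- sprintf("seq%d_x%d", seq_len(nrow(unique_seqs)),
                 unique_seqs$count)
  ss <- Biostrings::BStringSet(stats::setNames(unique_seqs$sequence, ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write unique sequences as a two-column TSV
#'
#' @param unique_seqs data.frame of \code{sequence}, \code{count}.
#' @param path output path.
#' @export
write_unique_tsv <- function(unique_seqs, path) {
  utils::write.table(unique_seqs[, c("sequence", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample reads in any supported format
#'
#' @param path input file.
#' @param format one of \code{"fastq"}, \code{"fasta"},
#'   \code{"collapsed"}.
#' @return for fastq/fasta, the \code{read_fastq()}-style list; for
#'   collapsed, a list whose \code{unique} element is the collapsed
#'   table (reads are not re-expanded).
#' @export
read_reads <- function(path, format = c("fastq", "fasta", "collapsed")) {
  format <- match.arg(format)
  switch(format,
    fastq = read_fastq(path),
    fasta = read_fasta_reads(path),
    collapsed = list(unique = read_collapsed_fasta(path),
                     n_parse_errors = 0L)
  )
}

empty_reads <- function() {
  data.frame(read_id = character(), sequence = character(),
             quality = character(), stringsAsFactors = FALSE)
}
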