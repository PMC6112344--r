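# Pre-processing: adapter trimming, length/alphabet filtering, collapsing
# raw reads into unique sequences with counts ("clean reads").

#' Trim a 3' sequencing adapter from reads
#'
#' Scans each read left to right for the leftmost placement of the
#' adapter: the placement must overlap the read by at least
#' `min_overlap` bases (the overlap is a prefix of the adapter) and its
#' mismatch fraction must not exceed `max_error_rate`.  The adapter and
#' everything 3' of it are removed; quality strings are truncated in
#' lockstep.  Reads with no qualifying placement are returned unchanged
#' (no-match is not an error).
#'
#' @param reads data.frame with columns \code{read_id}, \code{sequence}
#'   and (optionally NA) \code{quality}.
#' @param adapter 3' adapter sequence (non-empty DNA string).
#' @param min_overlap minimum read/adapter overlap (default 6).
#' @param max_error_rate maximum mismatch fraction within the overlap
#'   (default 0.1).
#' @return the reads data.frame with trimmed \code{sequence}/
#'   \code{quality}; attribute \code{n_adapter_trimmed} counts reads in
#'   which an adapter was found.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L,
                         max_error_rate = 0.1) {
  stopifnot(is.character(adapter), length(adapter) == 1L,
            nchar(adapter) >= 1L)
  adapter <- toupper(chartr("U", "T", adapter))
  araw <- charToRaw(adapter)
  pos <- vapply(toupper(chartr("uU", "tT", reads$sequence)),
                find_adapter_start, integer(1),
                araw = araw, min_overlap = as.integer(min_overlap),
                max_error_rate = max_error_rate, USE.NAMES = FALSE)
  hit <- !is.na(pos)
  if (any(hit)) {
    keep_len <- pos[hit] - 1L
    reads$sequence[hit] <- substr(reads$sequence[hit], 1L, keep_len)
    has_q <- hit & !is.na(reads$quality)
    reads$quality[has_q] <- substr(reads$quality[has_q], 1L,
                                   pos[has_q] - 1L)
  }
  attr(reads, "n_adapter_trimmed") <- sum(hit)
  reads
}

# Leftmost adapter placement on one read; NA if none qualifies.
find_adapter_start <- function(seq, araw, min_overlap, max_error_rate) {
  sraw <- charToRaw(seq)
  n <- length(sraw)
  la <- length(araw)
  if (n < min_overlap) return(NA_integer_)
  for (i in seq_len(n - min_overlap + 1L)) {
    ov <- min(la, n - i + 1L)
    mm <- sum(sraw[i:(i + ov - 1L)] != araw[seq_len(ov)])
    if (mm / ov <= max_error_rate) return(i)
  }
  NA_integer_
}

#' Filter reads to clean reads
#'
#' Normalizes sequences (uppercase, U to T) before testing the
#' alphabet; discards reads containing bases outside A/C/G/T (counted
#' as alphabet discards) and reads outside the \code{[min_len, max_len]}
#' length window (counted as length discards).  A read failing both
#' tests is counted once, as an alphabet discard.
#'
#' @param reads data.frame of raw reads (see [read_fastq()]).
#' @param min_len,max_len inclusive length window (defaults 15 and 45,
#'   covering miRNA through tsRNA/rsRNA size classes).
#' @param n_adapter_trimmed,n_parse_errors bookkeeping counts carried
#'   into the returned stats.
#' @return list with \code{reads} (the clean reads, DNA-space) and
#'   \code{stats}, a \code{preprocess_stats} object.
#' @export
clean_reads <- function(reads, min_len = 15L, max_len = 45L,
                        n_adapter_trimmed = 0L, n_parse_errors = 0L) {
  stopifnot(min_len >= 1L, min_len <= max_len)
  n_input <- nrow(reads)
  reads$sequence <- toupper(reads$sequence)
  reads$sequence <- chartr("U", "T", reads$sequence)
  ok_alpha <- grepl("^[ACGT]+$", reads$sequence)
  len <- nchar(reads$sequence)
  ok_len <- len >= min_len & len <= max_len
  n_alpha <- sum(!ok_alpha)
  n_len <- sum(ok_alpha & !ok_len)
  clean <- reads[ok_alpha & ok_len, , drop = FALSE]
  rownames(clean) <- NULL
  stats <- preprocess_stats(
    n_input_reads = n_input,
    n_adapter_trimmed = as.integer(n_adapter_trimmed),
    n_discarded_length = n_len,
    n_discarded_alphabet = n_alpha,
    n_clean_reads = nrow(clean),
    n_unique_sequences = NA_integer_,
    n_parse_errors = as.integer(n_parse_errors)
  )
  list(reads = clean, stats = stats)
}

#' Preprocessing statistics
#'
#' @param n_input_reads,n_adapter_trimmed,n_discarded_length,n_discarded_alphabet,n_clean_reads,n_unique_sequences,n_parse_errors
#'   integer tallies of the pre-processing step.  \code{n_clean_reads}
#'   must equal \code{n_input_reads - n_discarded_length -
#'   n_discarded_alphabet}; adapter trimming by itself discards nothing.
#' @return a \code{preprocess_stats} object (named list).
#' @export
preprocess_stats <- function(n_input_reads, n_adapter_trimmed = 0L,
                             n_discarded_length = 0L,
                             n_discarded_alphabet = 0L,
                             n_clean_reads = NULL,
                             n_unique_sequences = NA_integer_,
                             n_parse_errors = 0L) {
  if (is.null(n_clean_reads)) {
    n_clean_reads <- n_input_reads - n_discarded_length -
      n_discarded_alphabet
  }
  stopifnot(n_clean_reads ==
              n_input_reads - n_discarded_length - n_discarded_alphabet)
  structure(list(
    n_input_reads = as.integer(n_input_reads),
    n_adapter_trimmed = as.integer(n_adapter_trimmed),
    n_discarded_length = as.integer(n_discarded_length),
    n_discarded_alphabet = as.integer(n_discarded_alphabet),
    n_clean_reads = as.integer(n_clean_reads),
    n_unique_sequences = as.integer(n_unique_sequences),
    n_parse_errors = as.integer(n_parse_errors)
  ), class = "preprocess_stats")
}

#' @export
print.preprocess_stats <- function(x, ...) {
  cat("Pre-processing statistics\n")
  for (f in names(x)) cat(sprintf("  %-22s %d\n", f, x[[f]]))
  invisible(x)
}

#' Collapse clean reads into unique sequences
#'
#' @param reads data.frame of clean reads, or a character vector of
#'   sequences.
#' @return data.frame of \code{sequence}, \code{count}, sorted by
#'   descending count then lexicographic sequence (deterministic; the
#'   output is invariant to the input read order).
#' @export
collapse_reads <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  if (length(seqs) == 0L) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full pre-processing step on an input file
#'
#' Reads the input, trims the 3' adapter (if given), applies length and
#' alphabet filters, and collapses to unique sequences.  For
#' \code{format = "collapsed"} the input is already unique sequences
#' with counts; filters are applied to the unique table and counts are
#' propagated into the stats.
#'
#' @param input path to the reads file.
#' @param format input format (\code{fastq}, \code{fasta},
#'   \code{collapsed}).
#' @param adapter optional 3' adapter to trim; NULL disables trimming.
#' @param min_len,max_len clean-read length window.
#' @param min_overlap,max_error_rate adapter-trimming tolerances.
#' @return list with \code{unique} (sequence, count) and \code{stats}.
#' @export
preprocess <- function(input, format = c("fastq", "fasta", "collapsed"),
                       adapter = NULL, min_len = 15L, max_len = 45L,
                       min_overlap = 6L, max_error_rate = 0.1) {
  format <- match.arg(format)
  if (format == "collapsed") {
    uq <- read_collapsed_fasta(input)
    uq$sequence <- toupper(chartr("U", "T", uq$sequence))
    ok_alpha <- grepl("^[ACGT]+$", uq$sequence)
    len <- nchar(uq$sequence)
    ok_len <- len >= min_len & len <= max_len
    stats <- preprocess_stats(
      n_input_reads = sum(uq$count),
      n_discarded_length = sum(uq$count[ok_alpha & !ok_len]),
      n_discarded_alphabet = sum(uq$count[!ok_alpha])
    )
    uq <- uq[ok_alpha & ok_len, , drop = FALSE]
    # re-collapse: U->T normalization may merge entries
    uq <- stats::aggregate(count ~ sequence, data = uq, FUN = sum)
    uq <- uq[order(-uq$count, uq$sequence), , drop = FALSE]
    rownames(uq) <- NULL
    stats$n_unique_sequences <- nrow(uq)
    return(list(unique = uq, stats = stats))
  }
  parsed <- read_reads(input, format)
  reads <- parsed$reads
  n_trimmed <- 0L
  if (!is.null(adapter)) {
    reads <- trim_adapter(reads, adapter, min_overlap, max_error_rate)
    n_trimmed <- attr(reads, "n_adapter_trimmed")
  }
  cl <- clean_reads(reads, min_len, max_len,
                    n_adapter_trimmed = n_trimmed,
                    n_parse_errors = parsed$n_parse_errors)
  uq <- collapse_reads(cl$reads)
  cl$stats$n_unique_sequences <- nrow(uq)
  stopifnot(sum(uq$count) == cl$stats$n_clean_reads)
  list(unique = uq, stats = cl$stats)
}
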